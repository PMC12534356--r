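#' Z-score standardisation
#'
#' Centres each column to mean 0 and scales to sample standard deviation
#' 1, the transformation applied before all multivariate source analyses.
#'
#' @param m numeric matrix (sites x analytes), at least two rows, no
#'   missing cells (resolve censored values first).
#' @return Matrix of the same shape with standardised columns.
#' @export
standardize <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 rows to standardise")
  if (anyNA(m)) stop("matrix contains missing cells; resolve censoring first")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  scale(m, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' KMO and Bartlett sampling-adequacy diagnostics
#'
#' The Kaiser-Meyer-Olkin measure compares observed correlations with
#' anti-image partial correlations: KMO = sum(r^2) / (sum(r^2) +
#' sum(q^2)) over off-diagonal elements, where the partials q come from
#' the scaled inverse correlation matrix. Bartlett's sphericity statistic
#' is -(n - 1 - (2p + 5)/6) log det(R) on p(p-1)/2 degrees of freedom.
#' KMO > 0.5 and p < 0.001 are conventional adequacy thresholds for
#' factor analysis.
#'
#' @param m numeric matrix (observations x variables).
#' @return list with `kmo`, `bartlett_stat`, `bartlett_df`, `bartlett_p`.
#' @export
kmo_bartlett <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  p <- ncol(m)
  R <- stats::cor(m)
  Rinv <- tryCatch(solve(R), error = function(e) {
    stop("singular correlation matrix; consider removing collinear variables")
  })
  d <- 1 / sqrt(diag(Rinv))
  Q <- -Rinv * tcrossprod(d)  # partial correlations (anti-image)
  off <- upper.tri(R)
  kmo <- sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
  stat <- -(n - 1 - (2 * p + 5) / 6) * determinant(R, logarithm = TRUE)$modulus[1]
  df <- p * (p - 1) / 2
  list(kmo = kmo, bartlett_stat = as.numeric(stat), bartlett_df = df,
       bartlett_p = stats::pchisq(as.numeric(stat), df, lower.tail = FALSE))
}

#' Principal component analysis with varimax rotation
#'
#' Extracts principal components from the correlation matrix of a
#' standardised data matrix, retains components with eigenvalue > 1
#' (Kaiser criterion), and varimax-rotates the retained loadings with
#' Kaiser normalisation (convergence tolerance 1e-6, at most 100
#' sweeps). Factor signs are fixed so each factor's largest-magnitude
#' loading is positive, making loading tables deterministic. Loadings are
#' labelled strong (|loading| > 0.75), moderate (0.50-0.75) or weak
#' (< 0.50).
#'
#' @param m numeric matrix (sites x analytes); standardised internally
#'   via [standardize()].
#' @param min_eigenvalue retention threshold (default 1).
#' @return list of class `"pem_factor_model"`: `variables`, `loadings`
#'   (variables x retained factors), `eigenvalues` (all p), `variance_pct`
#'   and `cumulative_pct` for retained factors, `communality`,
#'   `strength_labels`, `kmo`, `bartlett_stat`, `bartlett_p`,
#'   `n_retained`.
#' @export
pca_varimax <- function(m, min_eigenvalue = 1) {
  z <- standardize(m)
  # adequacy diagnostics need an invertible correlation matrix; a
  # rank-deficient input still has a well-defined PCA, so degrade to NA
  diag_tests <- tryCatch(kmo_bartlett(z), error = function(e) {
    list(kmo = NA_real_, bartlett_stat = NA_real_, bartlett_p = NA_real_)
  })
  R <- stats::cor(z)
  eig <- eigen(R, symmetric = TRUE)
  keep <- which(eig$values > min_eigenvalue)
  if (!length(keep)) {
    stop("no eigenvalue exceeds ", min_eigenvalue, "; spectrum: ",
         paste(signif(eig$values, 3), collapse = ", "))
  }
  L <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eig$values[keep]), length(keep))
  rownames(L) <- colnames(z)
  if (length(keep) > 1) {
    rot <- stats::varimax(L, normalize = TRUE, eps = 1e-6)
    L <- L %*% rot$rotmat
  }
  # deterministic sign: largest |loading| per factor is positive
  for (j in seq_len(ncol(L))) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  colnames(L) <- paste0("Factor", seq_len(ncol(L)))
  var_pct <- 100 * colSums(L^2) / ncol(z)
  ord <- order(var_pct, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  colnames(L) <- paste0("Factor", seq_len(ncol(L)))
  var_pct <- var_pct[ord]
  names(var_pct) <- colnames(L)
  strength <- matrix(
    c("weak", "moderate", "strong")[findInterval(abs(L), c(0.50, 0.75)) + 1L],
    nrow(L), ncol(L), dimnames = dimnames(L))
  structure(
    list(variables = colnames(z), loadings = L,
         eigenvalues = eig$values, variance_pct = var_pct,
         cumulative_pct = cumsum(var_pct),
         communality = rowSums(L^2),
         strength_labels = strength,
         kmo = diag_tests$kmo, bartlett_stat = diag_tests$bartlett_stat,
         bartlett_p = diag_tests$bartlett_p,
         n_retained = ncol(L)),
    class = "pem_factor_model"
  )
}

#' @export
print.pem_factor_model <- function(x, cutoff = 0.3, ...) {
  cat(sprintf(
    "<varimax factor model: %d of %d components retained>\nKMO = %.3f, Bartlett chi^2 = %.1f (p = %.2g)\n",
    x$n_retained, length(x$eigenvalues), x$kmo, x$bartlett_stat,
    x$bartlett_p))
  L <- round(x$loadings, 3)
  shown <- format(L)
  shown[abs(L) < cutoff] <- ""  # sparse display; full matrix in $loadings
  print(shown, quote = FALSE)
  cat("Variance %: ", paste(sprintf("%.1f", x$variance_pct), collapse = ", "),
      " (cumulative ", sprintf("%.1f", max(x$cumulative_pct)), ")\n", sep = "")
  invisible(x)
}

#' Average-linkage hierarchical clustering
#'
#' Agglomerative clustering (UPGMA / between-groups average linkage) on
#' Euclidean distances between the rows of a column-standardised matrix,
#' with merge heights rescaled to (D_link / D_max) x 100. To cluster
#' variables rather than observations, pass the transposed standardised
#' matrix (`standardize = FALSE`).
#'
#' @param m numeric matrix; rows are the items to cluster.
#' @param standardize z-score the columns first (default TRUE).
#' @return list of class `"pem_cluster"`: `hclust` (the stats::hclust
#'   tree), `items`, `rescaled_heights` in `[0, 100]`.
#' @export
pem_cluster <- function(m, standardize = TRUE) {
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need at least 2 items to cluster")
  if (standardize) m <- standardize(m)
  hc <- stats::hclust(stats::dist(m), method = "average")
  dmax <- max(hc$height)
  structure(
    list(hclust = hc, items = rownames(m),
         rescaled_heights = if (dmax > 0) 100 * hc$height / dmax
                            else rep(0, length(hc$height))),
    class = "pem_cluster"
  )
}

#' Cut a cluster tree at a rescaled height
#'
#' Cluster membership when the dendrogram is cut where
#' (D_link / D_max) x 100 equals `rescaled_height` (defaults: 10 used for
#' site dendrograms, 15 for variable dendrograms in this package's
#' examples).
#'
#' @param tree a [pem_cluster()] object.
#' @param rescaled_height cut level on the 0-100 rescaled-distance axis
#'   (ignored when `k` is given).
#' @param k number of clusters to cut into, as an alternative to a height.
#' @return Named integer vector of cluster ids.
#' @export
cluster_cut <- function(tree, rescaled_height = 10, k = NULL) {
  stopifnot(inherits(tree, "pem_cluster"))
  if (!is.null(k)) return(stats::cutree(tree$hclust, k = k))
  h <- rescaled_height / 100 * max(tree$hclust$height)
  stats::cutree(tree$hclust, h = h)
}

#' Export a cluster tree in Newick format
#'
#' Writes the dendrogram as a Newick tree with branch lengths derived
#' from the merge heights.
#'
#' @param tree a [pem_cluster()] object.
#' @param path output file path.
#' @return The ape phylo object, invisibly.
#' @export
write_cluster_newick <- function(tree, path) {
  stopifnot(inherits(tree, "pem_cluster"))
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(phy)
}

#' @export
print.pem_cluster <- function(x, ...) {
  cat(sprintf("<average-linkage cluster tree, %d items>\n",
              length(x$items)))
  cat("rescaled merge heights: ",
      paste(sprintf("%.1f", x$rescaled_heights), collapse = ", "), "\n")
  invisible(x)
}
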