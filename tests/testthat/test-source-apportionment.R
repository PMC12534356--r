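test_that("z-score standardisation centres and scales each column", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- standardize(m)
  expect_equal(z[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(colMeans(z), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), c(a = 1, b = 1))
  expect_equal(standardize(z), z, ignore_attr = TRUE)  # idempotent
  expect_error(standardize(cbind(a = c(1, 1, 1), b = 1:3)), "zero-variance")
  expect_error(standardize(m[1, , drop = FALSE]), "at least 2")
})

test_that("KMO and Bartlett match a brute-force oracle on random matrices", {
  # oracle: partial correlations via regression residuals, Bartlett via the
  # eigenvalue log-determinant
  oracle <- function(m) {
    p <- ncol(m); n <- nrow(m)
    R <- cor(m)
    Q <- diag(p)
    for (i in 1:(p - 1)) for (j in (i + 1):p) {
      others <- setdiff(1:p, c(i, j))
      ri <- resid(lm(m[, i] ~ m[, others]))
      rj <- resid(lm(m[, j] ~ m[, others]))
      Q[i, j] <- Q[j, i] <- cor(ri, rj)
    }
    off <- upper.tri(R)
    kmo <- sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
    stat <- -(n - 1 - (2 * p + 5) / 6) * sum(log(eigen(R)$values))
    list(kmo = kmo, stat = stat)
  }
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(rnorm(5 * 4), 5, 4)
    got <- kmo_bartlett(m)
    want <- oracle(m)
    expect_equal(got$kmo, want$kmo, tolerance = 1e-8)
    expect_equal(got$bartlett_stat, want$stat, tolerance = 1e-8)
    expect_true(got$kmo >= 0 && got$kmo <= 1)
    expect_equal(got$bartlett_df, 6)
  }
})

test_that("two-variable KMO is exactly one half", {
  set.seed(3)
  for (rep in 1:5) {
    m <- matrix(rnorm(40), 20, 2)
    if (abs(cor(m)[1, 2]) < 1e-8) next
    expect_equal(kmo_bartlett(m)$kmo, 0.5)
  }
})

test_that("uncorrelated variables give a null Bartlett statistic", {
  # construct exactly orthogonal centred columns
  m <- cbind(c(1, -1, 0, 0), c(0, 0, 1, -1))
  kb <- kmo_bartlett(m)
  expect_equal(kb$bartlett_stat, 0, tolerance = 1e-12)
  expect_equal(kb$bartlett_p, 1)
})

test_that("varimax PCA retains by eigenvalue and preserves communality", {
  nl <- non_lake()
  m <- conc_matrix(nl, quantified_pems())
  fm <- pca_varimax(m)
  expect_equal(fm$n_retained, sum(fm$eigenvalues > 1))
  # eigenvalue sum equals the number of variables
  expect_equal(sum(fm$eigenvalues), ncol(m))
  # rotation preserves per-variable communality
  eig <- eigen(cor(standardize(m)), symmetric = TRUE)
  keep <- eig$values > 1
  unrot <- eig$vectors[, keep] %*% diag(sqrt(eig$values[keep]))
  expect_equal(fm$communality, rowSums(unrot^2), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_true(all(fm$variance_pct > 0))
  expect_true(all(diff(fm$cumulative_pct) >= 0))
  expect_lte(max(fm$cumulative_pct), 100)
})

test_that("the fixture factor model recovers the published source pattern", {
  fm <- pca_varimax(conc_matrix(non_lake(), quantified_pems()))
  expect_equal(fm$n_retained, 2)
  expect_gt(fm$kmo, 0.5)
  expect_lt(fm$bartlett_p, 0.001)
  top <- apply(abs(fm$loadings), 1, which.max)
  mining <- c("Mn", "Co", "As", "Mo", "Ni")
  expect_true(all(top[mining] == top[["Mn"]]))
  expect_true(top[["Cu"]] != top[["Mn"]])
  # strength labelling convention
  expect_equal(unname(fm$strength_labels["Mn", top[["Mn"]]]), "strong")
  expect_equal(unname(fm$strength_labels["Pb", top[["Cu"]]]), "moderate")
  expect_equal(fm$cumulative_pct[[2]], 80.9, tolerance = 0.01)
})

test_that("degenerate PCA inputs behave as documented", {
  # two perfectly correlated variables: one component, all variance
  x <- rnorm(20)
  m <- cbind(a = x, b = 2 * x + 1)
  fm <- pca_varimax(m)
  expect_equal(fm$n_retained, 1)
  expect_equal(fm$variance_pct[[1]], 100)
  # sign convention: the largest-|loading| variable is positive
  expect_gt(max(fm$loadings[, 1]), 0)
  # no retained component is an error, not an empty model
  set.seed(5)
  big <- matrix(rnorm(4000), 1000, 4)
  expect_error(pca_varimax(big, min_eigenvalue = 2), "eigenvalue")
})

test_that("block-structured data yield near-simple rotated loadings", {
  # two uncorrelated variable blocks of different size, so the leading
  # components are well separated and rotation recovers the blocks
  set.seed(21)
  x <- rnorm(80)
  y <- residuals(stats::lm(rnorm(80) ~ x))  # exactly orthogonal to x
  m <- cbind(a1 = x + rnorm(80, sd = 0.1), a2 = x + rnorm(80, sd = 0.15),
             a3 = x + rnorm(80, sd = 0.2), b1 = y + rnorm(80, sd = 0.1),
             b2 = y + rnorm(80, sd = 0.15))
  fm <- pca_varimax(m)
  expect_equal(fm$n_retained, 2)
  top <- apply(abs(fm$loadings), 1, which.max)
  expect_equal(unname(top[c("a1", "a2", "a3")]), rep(top[["a1"]], 3))
  expect_equal(top[["b1"]], top[["b2"]])
  expect_true(top[["a1"]] != top[["b1"]])
  # rotation drives the cross-loadings towards zero
  for (v in rownames(fm$loadings)) {
    expect_gt(abs(fm$loadings[v, top[[v]]]), 0.9)
    expect_lt(abs(fm$loadings[v, 3 - top[[v]]]), 0.25)
  }
})

test_that("average-linkage clustering matches hand-worked UPGMA", {
  m <- matrix(c(0, 1, 10), ncol = 1, dimnames = list(c("p0", "p1", "p10"), "x"))
  tree <- pem_cluster(m, standardize = FALSE)
  hc <- tree$hclust
  # first merge {p0, p1} at distance 1; then with p10 at mean(10, 9) = 9.5
  expect_equal(hc$height, c(1, 9.5))
  expect_equal(tree$rescaled_heights, c(100 / 9.5, 100))
  # identical items merge at height zero
  dup <- pem_cluster(matrix(c(1, 1, 5), ncol = 1), standardize = FALSE)
  expect_equal(dup$hclust$height[1], 0)
  expect_error(pem_cluster(m[1, , drop = FALSE]), "at least 2")
})

test_that("cluster heights are monotone and the rescaling is bounded", {
  z <- standardize(conc_matrix(non_lake(), quantified_pems()))
  tree <- pem_cluster(z, standardize = FALSE)
  expect_true(all(diff(tree$hclust$height) >= 0))
  expect_true(all(tree$rescaled_heights >= 0 & tree$rescaled_heights <= 100))
})

test_that("fixture site and analyte clusters isolate the contamination sources", {
  nl <- non_lake()
  z <- standardize(conc_matrix(nl, quantified_pems()))
  sites3 <- split(names(cluster_cut(pem_cluster(z, standardize = FALSE), k = 3)),
                  cluster_cut(pem_cluster(z, standardize = FALSE), k = 3))
  sizes <- lengths(sites3)
  expect_setequal(sizes, c(13, 1, 1))
  singletons <- unlist(sites3[sizes == 1])
  expect_setequal(singletons, c("NY-02", "NY-06"))
  vars3 <- cluster_cut(pem_cluster(t(z), standardize = FALSE), k = 3)
  expect_equal(length(unique(vars3[c("As", "Co", "Cu", "Mn", "Mo", "Ni", "Zn")])), 1)
  expect_equal(length(unique(vars3[c("Al", "Fe")])), 1)
  expect_true(vars3[["Pb"]] != vars3[["Al"]] && vars3[["Pb"]] != vars3[["As"]])
})

test_that("clustering is invariant to input row order", {
  z <- standardize(conc_matrix(non_lake(), quantified_pems()))
  set.seed(9)
  perm <- sample(nrow(z))
  t1 <- pem_cluster(z, standardize = FALSE)
  t2 <- pem_cluster(z[perm, ], standardize = FALSE)
  expect_equal(sort(t1$hclust$height), sort(t2$hclust$height))
  partition <- function(cut) {
    unname(lapply(split(names(cut), cut), sort))
  }
  p1 <- partition(cluster_cut(t1, k = 3))
  p2 <- partition(cluster_cut(t2, k = 3))
  expect_true(all(p1 %in% p2) && all(p2 %in% p1))
})

test_that("newick export writes a readable tree over all items", {
  z <- standardize(conc_matrix(non_lake(), quantified_pems()))
  tree <- pem_cluster(z, standardize = FALSE)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_cluster_newick(tree, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, rownames(z))
})
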