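#' Derive a background (baseline) profile
#'
#' Per-analyte baseline concentrations C_b, taken as the arithmetic mean of
#' the resolved concentrations at a set of reference sites considered
#' uncontaminated. For the packaged fixture the reference sites are NY-01
#' (upstream of the mining area) and NY-13 (the Rukoki tributary), and
#' censored values enter at half their detection limit.
#'
#' @param x a [pem_samples] object (raw sets are resolved with `policy`;
#'   already-resolved sets are used as-is).
#' @param reference_sites character vector of site ids, all present in `x`.
#' @param policy censoring policy applied when `x` is raw (see
#'   [resolve_censored()]).
#' @param analytes analytes to include (default [quantified_pems()]).
#' @return Named numeric vector of baseline concentrations (µg/L), class
#'   `"pem_background"`, with the derivation recorded in attributes.
#' @export
derive_background <- function(x, reference_sites = c("NY-01", "NY-13"),
                              policy = "half_dl",
                              analytes = quantified_pems()) {
  stopifnot(inherits(x, "pem_samples"))
  missing <- setdiff(reference_sites, x$sites$site_id)
  if (length(missing)) {
    stop("reference site(s) not in sample set: ", paste(missing, collapse = ", "))
  }
  if (identical(x$censor_policy, "raw")) x <- resolve_censored(x, policy)
  m <- conc_matrix(x, analytes)[reference_sites, , drop = FALSE]
  cb <- colMeans(m)
  if (any(cb <= 0)) {
    stop("non-positive background for: ",
         paste(names(cb)[cb <= 0], collapse = ", "))
  }
  structure(cb, class = "pem_background",
            reference_sites = reference_sites, policy = x$censor_policy)
}

#' Contamination factors
#'
#' Element-wise ratio of measured (or mean) concentrations to the baseline:
#' CF_i = C_i / C_b,i.
#'
#' @param conc named numeric vector of resolved concentrations (µg/L).
#' @param background a [derive_background()] profile (or named vector)
#'   covering every analyte in `conc`.
#' @return Named numeric vector of contamination factors.
#' @export
contamination_factors <- function(conc, background) {
  missing <- setdiff(names(conc), names(background))
  if (length(missing)) {
    stop("no background concentration for: ", paste(missing, collapse = ", "))
  }
  cf <- as.numeric(conc) / as.numeric(background[names(conc)])
  names(cf) <- names(conc)
  cf
}

index_report <- function(index, sites, value, classification, components) {
  structure(
    data.frame(site_id = sites, value = value,
               classification = classification, stringsAsFactors = FALSE,
               row.names = NULL),
    index = index, components = components,
    class = c("pem_index", "data.frame")
  )
}

#' @export
print.pem_index <- function(x, digits = 3, ...) {
  cat(sprintf("<%s index, %d site(s)>\n", toupper(attr(x, "index")), nrow(x)))
  print.data.frame(cbind(x[1], value = signif(x$value, digits), x[3]),
                   row.names = FALSE)
  invisible(x)
}

#' Per-analyte contributions behind an index report
#'
#' @param x an index report from [hei()], [pli()] or [wqi()].
#' @return Numeric matrix, sites x parameters: concentration/limit ratios
#'   for HEI, contamination factors for PLI, weighted sub-index terms for
#'   WQI.
#' @export
index_components <- function(x) attr(x, "components")

#' Heavy metal evaluation index (HEI)
#'
#' Sum of concentration-to-permissible-limit ratios over the assessed
#' PEMs: HEI = sum_i C_i / MPL_i. Bands: HEI <= 40 low, 40 < HEI <= 80
#' medium, HEI > 80 high.
#'
#' @param x a [pem_samples] object (raw input is resolved at half the
#'   detection limit).
#' @param plan a [limit_plan()] supplying MPL_i (default UNBS with the BC
#'   Co guideline of 110 µg/L).
#' @param analytes PEMs to include (default [quantified_pems()]); every
#'   one must have a limit under the plan.
#' @return An index report: data.frame with `site_id`, `value`,
#'   `classification`; per-analyte ratios via [index_components()].
#' @export
hei <- function(x, plan = limit_plan(), analytes = quantified_pems()) {
  if (identical(x$censor_policy, "raw")) x <- resolve_censored(x, "half_dl")
  mpl <- plan$limits[analytes]
  if (anyNA(mpl)) {
    stop("no permissible limit for: ",
         paste(analytes[is.na(mpl)], collapse = ", "))
  }
  m <- conc_matrix(x, analytes)
  ratios <- sweep(m, 2, mpl, "/")
  value <- rowSums(ratios)
  # HEI bands as printed are right-closed (HEI <= 40 low); classify_index
  # uses left-closed intervals, identical except exactly at a boundary,
  # where the printed right-closed rule is applied here.
  cls <- ifelse(value <= 40, "low", ifelse(value <= 80, "medium", "high"))
  index_report("hei", rownames(m), value, cls, ratios)
}

#' Pollution load index (PLI)
#'
#' Geometric mean of the contamination factors: PLI = (CF_1 x ... x
#' CF_n)^(1/n), computed in log space for numerical stability. Bands:
#' < 1 none, 1-2 moderate, 2-5 severe, >= 5 extreme.
#'
#' @inheritParams hei
#' @param background a [derive_background()] profile.
#' @return An index report; contamination factors via [index_components()].
#' @export
pli <- function(x, background, analytes = quantified_pems()) {
  if (identical(x$censor_policy, "raw")) x <- resolve_censored(x, "half_dl")
  m <- conc_matrix(x, analytes)
  cf <- sweep(m, 2, unclass(background)[analytes], "/")
  if (any(cf <= 0)) stop("non-positive contamination factor")
  value <- exp(rowMeans(log(cf)))
  index_report("pli", rownames(m), value, classify_index(value, "pli"), cf)
}

#' Weighted water quality index (WQI)
#'
#' Toxicity-weighted sum of concentration/standard ratios scaled to 100:
#' WQI = sum_i 100 * C_i * W_i / (S_i * sum(W)). pH enters as an ordinary
#' parameter with its upper objective as the standard, so when every
#' parameter sits exactly at its standard the index is 100 regardless of
#' the weights. Bands: < 50 excellent, 50-100 good, 100-200 poor, 200-300
#' very poor, >= 300 unsuitable.
#'
#' @inheritParams hei
#' @param scheme a [wqi_scheme()] of weights and standards.
#' @return An index report; weighted sub-index terms via
#'   [index_components()].
#' @export
wqi <- function(x, scheme = wqi_scheme()) {
  if (identical(x$censor_policy, "raw")) x <- resolve_censored(x, "half_dl")
  pars <- names(scheme$weights)
  m <- conc_matrix(x, setdiff(pars, "pH"))
  if ("pH" %in% pars) {
    if (anyNA(x$sites$pH)) stop("pH missing for some sites")
    m <- cbind(m, pH = x$sites$pH)
  }
  m <- m[, pars, drop = FALSE]
  terms <- sweep(m, 2, scheme$s_values[pars], "/")
  terms <- sweep(terms, 2, scheme$weights[pars], "*") * 100 / scheme$weight_sum
  value <- rowSums(terms)
  index_report("wqi", rownames(terms), value, classify_index(value, "wqi"),
               terms)
}

#' CCME water quality index
#'
#' The Canadian Council of Ministers of the Environment index combines the
#' scope (F1, % of parameters failing at least once), frequency (F2, % of
#' individual tests failing) and amplitude (F3, from the normalised sum of
#' excursions nse) of objective exceedances:
#' \deqn{CCME = 100 - \sqrt{F_1^2 + F_2^2 + F_3^2} / 1.732.}
#' Upper-bound objectives fail when the value strictly exceeds them
#' (excursion = value/objective - 1); lower bounds when the value falls
#' strictly below (excursion = objective/value - 1); pH is checked against
#' both bounds of its range. The model minimum is four parameters and four
#' tests. Bands: > 95 excellent, 80-95 good, 65-80 fair, 45-65 marginal,
#' < 45 poor.
#'
#' @param x a [pem_samples] object; all its sites form the test set
#'   (subset first with [pem_subset()] to set the scope).
#' @param plan a [limit_plan()] of objectives.
#' @param parameters parameters to assess (default pH plus
#'   [quantified_pems()]).
#' @return list of class `"ccme_wqi"`: `value`, `classification`, `f1`,
#'   `f2`, `f3`, `nse`, counts (`n_parameters`, `n_tests`,
#'   `n_failed_parameters`, `n_failed_tests`) and an `excursions`
#'   data.frame (site, parameter, excursion).
#' @export
ccme_wqi <- function(x, plan = limit_plan(),
                     parameters = c("pH", quantified_pems())) {
  if (identical(x$censor_policy, "raw")) x <- resolve_censored(x, "half_dl")
  analytes <- setdiff(parameters, "pH")
  m <- conc_matrix(x, analytes)
  if ("pH" %in% parameters) m <- cbind(m, pH = x$sites$pH)
  m <- m[, parameters, drop = FALSE]
  n_par <- ncol(m)
  n_tests <- sum(!is.na(m))
  if (n_par < 4 || n_tests < 4) {
    stop("the CCME WQI model requires at least 4 parameters and 4 tests")
  }
  exc <- list()
  for (p in parameters) {
    v <- m[, p]
    if (p == "pH") {
      lo <- plan$ph_range[1]; hi <- plan$ph_range[2]
      e <- ifelse(v > hi, v / hi - 1, ifelse(v < lo, lo / v - 1, 0))
    } else {
      obj <- plan$limits[p]
      if (is.na(obj)) stop("no objective for parameter ", p)
      e <- ifelse(v > obj, v / obj - 1, 0)
    }
    fail <- e > 0
    if (any(fail)) {
      exc[[p]] <- data.frame(site_id = rownames(m)[fail], parameter = p,
                             excursion = e[fail], stringsAsFactors = FALSE)
    }
  }
  exc <- if (length(exc)) do.call(rbind, exc) else
    data.frame(site_id = character(), parameter = character(),
               excursion = numeric())
  rownames(exc) <- NULL
  n_failed_par <- length(unique(exc$parameter))
  n_failed_tests <- nrow(exc)
  f1 <- 100 * n_failed_par / n_par
  f2 <- 100 * n_failed_tests / n_tests
  nse <- sum(exc$excursion) / n_tests
  f3 <- 100 * nse / (nse + 1)
  value <- 100 - sqrt(f1^2 + f2^2 + f3^2) / 1.732
  value <- max(value, 0)
  structure(
    list(value = value, classification = classify_index(value, "ccme"),
         f1 = f1, f2 = f2, f3 = f3, nse = nse,
         n_parameters = n_par, n_tests = n_tests,
         n_failed_parameters = n_failed_par, n_failed_tests = n_failed_tests,
         excursions = exc),
    class = "ccme_wqi"
  )
}

#' @export
print.ccme_wqi <- function(x, ...) {
  cat(sprintf(
    "CCME WQI = %.1f (%s)\n  F1 (scope) = %.2f, F2 (frequency) = %.2f, F3 (amplitude) = %.2f\n  %d/%d parameters failed, %d/%d tests failed, nse = %.4f\n",
    x$value, x$classification, x$f1, x$f2, x$f3,
    x$n_failed_parameters, x$n_parameters, x$n_failed_tests, x$n_tests,
    x$nse))
  invisible(x)
}

#' Exceedance summary for one analyte
#'
#' Count and percentage of samples whose resolved concentration strictly
#' exceeds a threshold (ties at the limit count as not exceeded).
#'
#' @inheritParams hei
#' @param analyte one analyte symbol.
#' @param threshold concentration threshold (µg/L).
#' @return list with `count`, `n` and `percent`.
#' @export
exceedance_summary <- function(x, analyte, threshold) {
  if (identical(x$censor_policy, "raw")) x <- resolve_censored(x, "half_dl")
  v <- conc_matrix(x, analyte)[, 1]
  count <- sum(v > threshold)
  list(count = count, n = length(v), percent = 100 * count / length(v))
}
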