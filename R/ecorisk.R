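#' Mean concentration profile
#'
#' Per-analyte arithmetic mean of resolved concentrations over a sample
#' set. The Hakanson risk formulation calls for the mean over at least
#' five sampling points; fewer than five triggers a warning.
#'
#' @inheritParams hei
#' @param analytes analytes to average (default [quantified_pems()]).
#' @return Named numeric vector of mean concentrations (µg/L).
#' @export
mean_profile <- function(x, analytes = quantified_pems()) {
  stopifnot(inherits(x, "pem_samples"))
  if (nrow(x$sites) == 0) stop("empty sample set")
  if (nrow(x$sites) < 5) {
    warning("mean profile from fewer than 5 sampling points")
  }
  if (identical(x$censor_policy, "raw")) x <- resolve_censored(x, "half_dl")
  colMeans(conc_matrix(x, analytes))
}

#' Hakanson ecological risk factors
#'
#' Per-element ecological risk Er_i = Tr_i x CF_i, where Tr_i is the
#' toxic-response factor and CF_i the contamination factor of the mean
#' concentration against the baseline. Er bands: < 40 low, 40-80
#' moderate, 80-160 considerable, 160-320 high, >= 320 extremely high.
#'
#' @param mean_conc named numeric vector of mean concentrations (µg/L),
#'   e.g. from [mean_profile()].
#' @param background a [derive_background()] profile covering the same
#'   analytes.
#' @param tr toxic-response factors (default
#'   [toxic_response_factors()]); every analyte must have an entry.
#' @return data.frame of class `"eco_risk"` with one row per analyte:
#'   `analyte`, `mean_concentration`, `cb`, `cf`, `tr`, `er`, `er_class`.
#' @export
ecological_risk <- function(mean_conc, background,
                            tr = toxic_response_factors()) {
  cf <- contamination_factors(mean_conc, background)
  missing <- setdiff(names(mean_conc), names(tr))
  if (length(missing)) {
    stop("no toxic-response factor for: ", paste(missing, collapse = ", "))
  }
  tr <- tr[names(mean_conc)]
  er <- tr * cf
  structure(
    data.frame(analyte = names(mean_conc),
               mean_concentration = unname(mean_conc),
               cb = unname(unclass(background)[names(mean_conc)]),
               cf = unname(cf), tr = unname(tr), er = unname(er),
               er_class = classify_index(er, "er"),
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("eco_risk", "data.frame")
  )
}

#' Potential ecological risk index (PERI)
#'
#' Sum of the per-element ecological risks: PERI = sum_i Er_i. Bands:
#' < 150 low, 150-300 moderate, 300-600 considerable, 600-1200 high,
#' >= 1200 extremely high (left-closed intervals).
#'
#' @param e an [ecological_risk()] table.
#' @return list with `value` and `classification`.
#' @export
peri <- function(e) {
  stopifnot(inherits(e, "eco_risk"))
  value <- sum(e$er)
  list(value = value, classification = classify_index(value, "peri"))
}

#' @export
print.eco_risk <- function(x, digits = 3, ...) {
  cat(sprintf("<ecological risk table, %d analytes>\n", nrow(x)))
  shown <- x
  for (col in c("mean_concentration", "cb", "cf", "er")) {
    shown[[col]] <- signif(shown[[col]], digits)
  }
  print.data.frame(shown, row.names = FALSE)
  p <- peri(x)
  cat(sprintf("PERI = %s (%s)\n", format(signif(p$value, 4)),
              p$classification))
  invisible(x)
}
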