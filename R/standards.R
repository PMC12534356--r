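#' Regulatory standards registry
#'
#' Per-analyte maximum permissible limits (µg/L) and pH objective ranges
#' for the authorities used throughout the package: the Uganda National
#' Bureau of Standards potable-water standard (UNBS, pH 5.5-9.5), the WHO
#' drinking-water guideline (pH 6.5-8.5), and the British Columbia
#' aquatic-life guideline for Co (110 µg/L), which fills the gap left by
#' UNBS/WHO, neither of which sets a Co limit.
#'
#' @return data.frame with columns `authority`, `parameter`, `lower`,
#'   `upper`. Metal limits have `lower = NA`; pH rows carry both bounds.
#' @export
pem_standards <- function() {
  metals_unbs <- c(Al = 200, As = 10, Cu = 1000, Fe = 300, Mn = 100,
                   Mo = 70, Ni = 20, Pb = 10, Zn = 5000)
  metals_who <- c(Al = 200, As = 10, Cu = 2000, Fe = 300, Mn = 100,
                  Mo = 70, Ni = 70, Pb = 10, Zn = 3000)
  rbind(
    data.frame(authority = "UNBS", parameter = names(metals_unbs),
               lower = NA_real_, upper = unname(metals_unbs)),
    data.frame(authority = "UNBS", parameter = "pH", lower = 5.5, upper = 9.5),
    data.frame(authority = "WHO", parameter = names(metals_who),
               lower = NA_real_, upper = unname(metals_who)),
    data.frame(authority = "WHO", parameter = "pH", lower = 6.5, upper = 8.5),
    data.frame(authority = "BC_Co", parameter = "Co", lower = NA_real_,
               upper = 110)
  )
}

#' Default limit plan for index computation
#'
#' Assembles the per-parameter objectives used by [hei()], [wqi()] and
#' [ccme_wqi()]: upper limits for the ten quantified PEMs plus the pH
#' objective range. The default plan takes UNBS limits with the Co gap
#' filled from the British Columbia aquatic-life guideline (110 µg/L).
#'
#' @param authority `"UNBS"` or `"WHO"`.
#' @param co_from_bc fill a missing Co limit from the BC guideline
#'   (default TRUE; required for UNBS/WHO, neither of which covers Co).
#' @param overrides optional named numeric vector of per-analyte upper
#'   limits overriding the registry.
#' @return list with `limits` (named numeric vector, µg/L) and `ph_range`
#'   (length-2 numeric `c(lower, upper)`).
#' @export
limit_plan <- function(authority = "UNBS", co_from_bc = TRUE,
                       overrides = NULL) {
  std <- pem_standards()
  rows <- std[std$authority == authority & std$parameter != "pH", ]
  limits <- stats::setNames(rows$upper, rows$parameter)
  if (co_from_bc && !"Co" %in% names(limits)) {
    limits["Co"] <- std$upper[std$authority == "BC_Co" & std$parameter == "Co"]
  }
  if (!is.null(overrides)) limits[names(overrides)] <- overrides
  if (any(limits <= 0, na.rm = TRUE)) stop("limits must be positive")
  ph <- std[std$authority == authority & std$parameter == "pH", ]
  list(limits = limits[order(match(names(limits), pem_analytes()))],
       ph_range = c(ph$lower, ph$upper))
}

#' Hakanson toxic-response factors
#'
#' Per-element weights reflecting relative ecotoxicity, used by
#' [ecological_risk()]: Al 5, As 10, Cd 30, Co 5, Cr 2, Cu 5, Fe 1, Mn 1,
#' Mo 15, Ni 5, Pb 5, Zn 1.
#'
#' @param overrides optional named numeric vector overriding defaults.
#' @return Named numeric vector over [pem_analytes()].
#' @export
toxic_response_factors <- function(overrides = NULL) {
  tr <- c(Al = 5, As = 10, Cd = 30, Co = 5, Cr = 2, Cu = 5,
          Fe = 1, Mn = 1, Mo = 15, Ni = 5, Pb = 5, Zn = 1)
  if (!is.null(overrides)) tr[names(overrides)] <- overrides
  tr
}

#' Weighted WQI scheme
#'
#' Parameter weights (integers 1-5, 5 = most toxic for drinking use) and
#' standard values S_i for the weighted water quality index. Default
#' weights: pH 4, Al 2, As 5, Co 2, Cu 2, Fe 4, Mn 5, Mo 3, Ni 4, Pb 5,
#' Zn 1 (sum 37). S_i defaults to the [limit_plan()] upper limits, with
#' the pH upper objective (9.5 under UNBS) as the pH standard.
#'
#' @param weights named integer vector of weights (must include every
#'   parameter to be scored).
#' @param plan a [limit_plan()] supplying S_i values.
#' @param s_values optional named numeric overrides for S_i.
#' @return list with `weights`, `weight_sum` and `s_values`, class
#'   `"wqi_scheme"`.
#' @export
wqi_scheme <- function(weights = c(pH = 4, Al = 2, As = 5, Co = 2, Cu = 2,
                                   Fe = 4, Mn = 5, Mo = 3, Ni = 4, Pb = 5,
                                   Zn = 1),
                       plan = limit_plan(), s_values = NULL) {
  if (any(weights < 1 | weights > 5)) stop("weights must lie in 1..5")
  s <- plan$limits[setdiff(names(weights), "pH")]
  if ("pH" %in% names(weights)) s <- c(s, pH = plan$ph_range[2])
  if (!is.null(s_values)) s[names(s_values)] <- s_values
  missing <- names(weights)[!names(weights) %in% names(s) | is.na(s[names(weights)])]
  if (length(missing)) {
    stop("no standard value S_i for: ", paste(missing, collapse = ", "))
  }
  structure(list(weights = weights, weight_sum = sum(weights),
                 s_values = s[names(weights)]),
            class = "wqi_scheme")
}

# ---- classification band tables -------------------------------------------
# All bands are left-closed intervals [lower, upper) as printed for the
# indices; each table is total over the non-negative reals.

band_tables <- function() {
  list(
    hei = data.frame(upper = c(40, 80, Inf),
                     label = c("low", "medium", "high")),
    pli = data.frame(upper = c(1, 2, 5, Inf),
                     label = c("none", "moderate", "severe", "extreme")),
    wqi = data.frame(upper = c(50, 100, 200, 300, Inf),
                     label = c("excellent", "good", "poor", "very poor",
                               "unsuitable")),
    # CCME bands are defined top-down (> 95 excellent ... < 45 poor);
    # expressed here as [lower, upper) on the 0-100 scale.
    ccme = data.frame(upper = c(45, 65, 80, 95, Inf),
                      label = c("poor", "marginal", "fair", "good",
                                "excellent")),
    er = data.frame(upper = c(40, 80, 160, 320, Inf),
                    label = c("low", "moderate", "considerable", "high",
                              "extremely high")),
    peri = data.frame(upper = c(150, 300, 600, 1200, Inf),
                      label = c("low", "moderate", "considerable", "high",
                                "extremely high")),
    hq = data.frame(upper = c(1, 10, Inf),
                    label = c("negligible", "moderately significant",
                              "highly significant")),
    hi = data.frame(upper = c(1, Inf),
                    label = c("no harmful effect", "potential harmful impact"))
  )
}

#' Classify an index value
#'
#' Maps a computed index value to its qualitative band. Bands are
#' left-closed intervals, so every value maps to exactly one label.
#' Supported indices: `"hei"`, `"pli"`, `"wqi"`, `"ccme"`, `"er"`,
#' `"peri"`, `"hq"`, `"hi"`. Cancer risk uses [classify_cancer_risk()].
#'
#' @param value numeric vector of index values.
#' @param index which band table to use.
#' @return Character vector of band labels.
#' @export
classify_index <- function(value, index = c("hei", "pli", "wqi", "ccme",
                                            "er", "peri", "hq", "hi")) {
  index <- match.arg(index)
  tab <- band_tables()[[index]]
  idx <- vapply(value, function(v) which(v < tab$upper)[1], 1L)
  tab$label[idx]
}

#' Classify a total cancer risk
#'
#' Default three-band rule: unacceptable when CR > 1e-4, negligible when
#' CR < 1e-6, acceptable otherwise. An alternative band table (e.g. an
#' extended low/medium/elevated scale) can be supplied as a data.frame
#' with `upper` (right-open bounds, increasing, last `Inf`) and `label`.
#'
#' @param cr numeric vector of total cancer risks.
#' @param bands optional replacement band table.
#' @return Character vector of band labels.
#' @export
classify_cancer_risk <- function(cr, bands = NULL) {
  if (is.null(bands)) {
    bands <- data.frame(upper = c(1e-6, 1e-4, Inf),
                        label = c("negligible", "acceptable", "unacceptable"))
  }
  # "negligible when CR < 1e-6" is strict, "unacceptable when CR > 1e-4" is
  # strict: the first band is right-open, later bands right-closed.
  idx <- vapply(cr, function(v) {
    hit <- c(v < bands$upper[1], v <= bands$upper[-1])
    which(hit)[1]
  }, 1L)
  bands$label[idx]
}
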