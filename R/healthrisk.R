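#' Exposure scenarios
#'
#' Cohort exposure parameters for the ingestion and dermal pathways. The
#' shipped `"child"` and `"adult"` cohorts are generic US-EPA residential
#' defaults (RAGS-style), editable field by field; they are defaults of
#' this package, not site-measured values, so downstream results should be
#' read as screening-level estimates.
#'
#' Both averaging times default to AT = ED x 365 days. For carcinogens the
#' textbook lifetime convention (70 years x 365 days) can be set via
#' `AT_cancer`; the exposure-duration average is the default because it is
#' the convention under which child risks exceed adult risks whenever the
#' child's intake-to-body-weight ratio does, the ordering reported for
#' residential scenarios of this kind (a fixed lifetime denominator would
#' instead scale risk with exposure duration and invert the cohorts).
#'
#' @param cohort `"child"`, `"adult"`, or `"custom"` (all parameters
#'   required for `"custom"`).
#' @param IR water ingestion rate (L/day).
#' @param ED exposure duration (years).
#' @param EF exposure frequency (days/year).
#' @param BW body weight (kg).
#' @param ET exposure time per bathing/contact event (hours).
#' @param SA exposed skin surface area (cm^2).
#' @param AT_noncancer,AT_cancer averaging times (days).
#' @return list of class `"exposure_scenario"`.
#' @export
exposure_scenario <- function(cohort = c("child", "adult", "custom"),
                              IR = NULL, ED = NULL, EF = NULL, BW = NULL,
                              ET = NULL, SA = NULL, AT_noncancer = NULL,
                              AT_cancer = NULL) {
  cohort <- match.arg(cohort)
  defaults <- switch(cohort,
    child = list(IR = 1, ED = 6, EF = 350, BW = 15, ET = 1, SA = 6600),
    adult = list(IR = 2, ED = 30, EF = 350, BW = 70, ET = 0.58, SA = 18000),
    custom = list(IR = IR, ED = ED, EF = EF, BW = BW, ET = ET, SA = SA)
  )
  given <- list(IR = IR, ED = ED, EF = EF, BW = BW, ET = ET, SA = SA)
  for (nm in names(given)) if (!is.null(given[[nm]])) defaults[[nm]] <- given[[nm]]
  if (any(vapply(defaults, is.null, TRUE))) {
    stop("custom scenario requires IR, ED, EF, BW, ET and SA")
  }
  sc <- defaults
  sc$AT_noncancer <- if (is.null(AT_noncancer)) sc$ED * 365 else AT_noncancer
  sc$AT_cancer <- if (is.null(AT_cancer)) sc$ED * 365 else AT_cancer
  sc$cohort <- cohort
  if (any(unlist(sc[c("IR", "ED", "EF", "BW", "ET", "SA", "AT_noncancer",
                      "AT_cancer")]) <= 0)) {
    stop("all exposure parameters must be positive")
  }
  structure(sc, class = "exposure_scenario")
}

#' Toxicological parameter table
#'
#' Per-analyte dermal permeability coefficient Kp (cm/hour), oral
#' reference dose RfD_ing (mg/kg-day), gastrointestinal absorption
#' fraction ABS_g (unitless, in (0, 1]), and oral cancer slope factor
#' CSF_oral ((mg/kg-day)^-1; NA where no slope factor exists - only As,
#' Ni and Pb carry one). The absorbed-dose quantities are always derived,
#' never stored: RfD_ABS = RfD_ing x ABS_g and CSF_ABS = CSF_oral / ABS_g.
#'
#' The shipped values are generic US-EPA-derived screening defaults
#' (IRIS/RSL-style), editable via `overrides`; they are defaults of this
#' package rather than site-specific toxicology.
#'
#' @param overrides optional data.frame with column `analyte` plus any of
#'   `Kp`, `RfD_ing`, `ABS_g`, `CSF_oral` to replace defaults.
#' @return data.frame with columns `analyte`, `Kp`, `RfD_ing`, `ABS_g`,
#'   `CSF_oral`.
#' @export
toxicity_table <- function(overrides = NULL) {
  tab <- data.frame(
    analyte = c("Al", "As", "Co", "Cu", "Fe", "Mn", "Mo", "Ni", "Pb", "Zn"),
    Kp = c(1e-3, 1e-3, 4e-4, 1e-3, 1e-3, 1e-3, 1e-3, 2e-4, 1e-4, 6e-4),
    RfD_ing = c(1, 3e-4, 3e-4, 0.04, 0.7, 0.024, 5e-3, 0.02, 3.5e-3, 0.3),
    ABS_g = c(1, 1, 1, 1, 1, 0.04, 1, 0.04, 1, 1),
    CSF_oral = c(NA, 1.5, NA, NA, NA, NA, NA, 0.91, 8.5e-3, NA),
    stringsAsFactors = FALSE
  )
  if (!is.null(overrides)) {
    idx <- match(overrides$analyte, tab$analyte)
    if (anyNA(idx)) stop("override for unknown analyte")
    for (col in intersect(names(overrides), c("Kp", "RfD_ing", "ABS_g", "CSF_oral"))) {
      tab[idx, col] <- overrides[[col]]
    }
  }
  if (any(tab$ABS_g <= 0 | tab$ABS_g > 1)) stop("ABS_g must lie in (0, 1]")
  tab
}

scenario_at <- function(sc, mode = c("noncancer", "cancer")) {
  mode <- match.arg(mode)
  if (mode == "noncancer") sc$AT_noncancer else sc$AT_cancer
}

#' Chronic daily dose via ingestion
#'
#' CDD = (C x IR x ED x EF) / (AT x BW), in mg per kg body weight per
#' day. `C` is in mg/L (the health-risk boundary; river concentrations in
#' µg/L are divided by 1000 before entering).
#'
#' @param C concentration in water (mg/L).
#' @param sc an [exposure_scenario()].
#' @param mode `"noncancer"` or `"cancer"`, selecting the scenario's
#'   averaging time.
#' @return Dose (mg/kg-day).
#' @export
chronic_daily_dose <- function(C, sc, mode = c("noncancer", "cancer")) {
  stopifnot(inherits(sc, "exposure_scenario"), all(C >= 0))
  at <- scenario_at(sc, mode)
  C * sc$IR * sc$ED * sc$EF / (at * sc$BW)
}

#' Dermally absorbed dose
#'
#' DAD = (C x Kp x ED x EF x ET x SA x CF) / (AT x BW), in mg/kg-day,
#' where CF = 1e-3 L/cm^3 is the volumetric conversion making the
#' mg/L x cm/h x cm^2 product dimensionally consistent.
#'
#' @inheritParams chronic_daily_dose
#' @param Kp dermal permeability coefficient (cm/hour).
#' @return Dose (mg/kg-day).
#' @export
dermally_absorbed_dose <- function(C, Kp, sc, mode = c("noncancer", "cancer")) {
  stopifnot(inherits(sc, "exposure_scenario"), all(C >= 0), all(Kp >= 0))
  at <- scenario_at(sc, mode)
  C * Kp * sc$ED * sc$EF * sc$ET * sc$SA * 1e-3 / (at * sc$BW)
}

risk_conc_matrix <- function(x, analytes) {
  if (identical(x$censor_policy, "raw")) x <- resolve_censored(x, "half_dl")
  conc_matrix(x, analytes) / 1000  # µg/L -> mg/L at the module boundary
}

#' Non-carcinogenic hazard assessment
#'
#' Per site, cohort and analyte: chronic daily dose (ingestion), dermally
#' absorbed dose, hazard quotients HQ_ing = CDD / RfD_ing and HQ_dermal =
#' DAD / RfD_ABS with RfD_ABS = RfD_ing x ABS_g, and their sum HQ.
#' Analytes without an RfD are skipped with an explicit warning, never
#' silently. HQ bands: < 1 negligible, 1-10 moderately significant,
#' >= 10 highly significant.
#'
#' @param x a [pem_samples] object (raw input resolved at half DL).
#' @param sc an [exposure_scenario()].
#' @param tox a [toxicity_table()].
#' @param analytes analytes to assess (default [quantified_pems()]).
#' @return data.frame, one row per site x analyte: `site_id`, `cohort`,
#'   `analyte`, `cdd`, `dad`, `hq_ing`, `hq_dermal`, `hq`, `hq_class`.
#' @seealso [hazard_index()] for the per-site aggregate.
#' @export
hazard_assessment <- function(x, sc, tox = toxicity_table(),
                              analytes = quantified_pems()) {
  known <- analytes[analytes %in% tox$analyte &
                      !is.na(tox$RfD_ing[match(analytes, tox$analyte)])]
  skipped <- setdiff(analytes, known)
  if (length(skipped)) {
    warning("no reference dose for ", paste(skipped, collapse = ", "),
            "; skipped from hazard assessment")
  }
  m <- risk_conc_matrix(x, known)
  ti <- match(known, tox$analyte)
  long <- expand.grid(site_id = rownames(m), analyte = known,
                      stringsAsFactors = FALSE)
  C <- m[cbind(match(long$site_id, rownames(m)), match(long$analyte, known))]
  kp <- tox$Kp[ti][match(long$analyte, known)]
  rfd <- tox$RfD_ing[ti][match(long$analyte, known)]
  absg <- tox$ABS_g[ti][match(long$analyte, known)]
  cdd <- chronic_daily_dose(C, sc, "noncancer")
  dad <- dermally_absorbed_dose(C, kp, sc, "noncancer")
  hq_ing <- cdd / rfd
  hq_dermal <- dad / (rfd * absg)
  hq <- hq_ing + hq_dermal
  data.frame(site_id = long$site_id, cohort = sc$cohort,
             analyte = long$analyte, cdd = cdd, dad = dad,
             hq_ing = hq_ing, hq_dermal = hq_dermal, hq = hq,
             hq_class = classify_index(hq, "hq"),
             stringsAsFactors = FALSE)
}

#' Hazard index per site
#'
#' HI = sum of the per-analyte hazard quotients at a site. HI < 1: no
#' harmful effect expected; HI >= 1: potential harmful impact.
#'
#' @param hazard a [hazard_assessment()] table.
#' @return data.frame with `site_id`, `cohort`, `hi`, `hi_class`.
#' @export
hazard_index <- function(hazard) {
  agg <- stats::aggregate(hq ~ site_id + cohort, data = hazard, FUN = sum)
  agg <- agg[order(match(agg$site_id, unique(hazard$site_id))), ]
  data.frame(site_id = agg$site_id, cohort = agg$cohort, hi = agg$hq,
             hi_class = classify_index(agg$hq, "hi"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Carcinogenic risk assessment
#'
#' Per site, cohort and carcinogen: excess lifetime cancer risks
#' ELCR_ing = CDD x CSF_oral and ELCR_dermal = DAD x CSF_ABS with
#' CSF_ABS = CSF_oral / ABS_g, and their total CR. Only analytes with an
#' oral slope factor can be assessed (As, Ni, Pb in the default table);
#' requesting any other is an error naming the analyte. Default bands:
#' CR > 1e-4 unacceptable, CR < 1e-6 negligible, otherwise acceptable.
#'
#' @inheritParams hazard_assessment
#' @param analytes carcinogens to assess (default: all with a CSF).
#' @return data.frame, one row per site x analyte: `site_id`, `cohort`,
#'   `analyte`, `cdd`, `dad`, `elcr_ing`, `elcr_dermal`, `cr`, `cr_class`.
#' @seealso [total_cancer_risk()] for the per-site sum over carcinogens.
#' @export
cancer_assessment <- function(x, sc, tox = toxicity_table(),
                              analytes = NULL) {
  with_csf <- tox$analyte[!is.na(tox$CSF_oral)]
  if (is.null(analytes)) analytes <- with_csf
  no_csf <- setdiff(analytes, with_csf)
  if (length(no_csf)) {
    stop("no cancer slope factor for: ", paste(no_csf, collapse = ", "))
  }
  m <- risk_conc_matrix(x, analytes)
  ti <- match(analytes, tox$analyte)
  long <- expand.grid(site_id = rownames(m), analyte = analytes,
                      stringsAsFactors = FALSE)
  C <- m[cbind(match(long$site_id, rownames(m)),
               match(long$analyte, analytes))]
  kp <- tox$Kp[ti][match(long$analyte, analytes)]
  csf <- tox$CSF_oral[ti][match(long$analyte, analytes)]
  absg <- tox$ABS_g[ti][match(long$analyte, analytes)]
  cdd <- chronic_daily_dose(C, sc, "cancer")
  dad <- dermally_absorbed_dose(C, kp, sc, "cancer")
  elcr_ing <- cdd * csf
  elcr_dermal <- dad * (csf / absg)
  cr <- elcr_ing + elcr_dermal
  data.frame(site_id = long$site_id, cohort = sc$cohort,
             analyte = long$analyte, cdd = cdd, dad = dad,
             elcr_ing = elcr_ing, elcr_dermal = elcr_dermal, cr = cr,
             cr_class = classify_cancer_risk(cr),
             stringsAsFactors = FALSE)
}

#' Total cancer risk per site
#'
#' Sum of the per-carcinogen total risks CR at each site, with the share
#' of the largest contributor.
#'
#' @param cancer a [cancer_assessment()] table.
#' @return data.frame with `site_id`, `cohort`, `cr`, `cr_class`,
#'   `dominant_analyte`, `dominant_share` (fraction of the site total).
#' @export
total_cancer_risk <- function(cancer) {
  split_rows <- split(cancer, cancer$site_id)
  out <- do.call(rbind, lapply(split_rows, function(d) {
    tot <- sum(d$cr)
    top <- which.max(d$cr)
    data.frame(site_id = d$site_id[1], cohort = d$cohort[1], cr = tot,
               cr_class = classify_cancer_risk(tot),
               dominant_analyte = d$analyte[top],
               dominant_share = d$cr[top] / tot,
               stringsAsFactors = FALSE)
  }))
  out <- out[match(unique(cancer$site_id), out$site_id), ]
  rownames(out) <- NULL
  out
}
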