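# Shared fixtures and frozen reference values for the River Nyamwamba
# survey (the package's canonical dataset).

fixture_raw <- function() nyamwamba_waters()

fixture_resolved <- function(policy = "half_dl") {
  resolve_censored(nyamwamba_waters(), policy)
}

main_stem <- function() pem_subset(fixture_resolved(), "main_stem")

non_lake <- function() {
  pem_subset(fixture_resolved(), c("main_stem", "tributary", "mine_drainage"))
}

fixture_background <- function() derive_background(fixture_raw())

main_stem_sites <- c("NY-01", "NY-04", "NY-05", "NY-07", "NY-08",
                     "NY-11", "NY-12", "NY-14", "NY-15")

# published per-site contamination indices (survey report, main stem)
published_hei <- c(0.85, 14.6, 15.2, 17.3, 5.83, 6.62, 5.88, 5.49, 4.66)
published_pli <- c(0.91, 13.6, 14.5, 13.9, 8.11, 8.84, 9.25, 9.23, 8.70)
published_wqi_band <- c("excellent", "poor", "poor", "poor",
                        "good", "good", "good", "good", "good")

# published background (baseline) row and ecological-risk rows
published_cb <- c(Al = 47.0, As = 0.28, Co = 0.03, Cu = 1.07, Fe = 199,
                  Mn = 19.8, Mo = 0.43, Ni = 0.05, Pb = 0.27, Zn = 2.45)
published_mean <- c(Al = 55.5, As = 0.21, Co = 251, Cu = 98.9, Fe = 150,
                    Mn = 281, Mo = 0.45, Ni = 49.8, Pb = 0.17, Zn = 23.5)
published_cf <- c(Al = 1.18, As = 0.75, Co = 9470, Cu = 92.6, Fe = 0.76,
                  Mn = 14.2, Mo = 1.03, Ni = 1015, Pb = 0.63, Zn = 9.58)
published_er <- c(Al = 5.91, As = 7.46, Co = 47400, Cu = 463, Fe = 0.76,
                  Mn = 14.2, Mo = 15.4, Ni = 5080, Pb = 3.17, Zn = 9.58)

# small hand-built raw sample set for unit tests
toy_samples <- function() {
  sites <- data.frame(site_id = c("A", "B", "C"),
                      group = c("main_stem", "main_stem", "tributary"),
                      distance_km = c(0, 5, NA), pH = c(7, 7.5, 6.9))
  conc <- rbind(
    data.frame(site_id = "A", analyte = c("Co", "Ni"),
               value = c(NA, 10), censored = c(TRUE, FALSE),
               detection_limit = c(0.053, NA)),
    data.frame(site_id = "B", analyte = c("Co", "Ni"),
               value = c(4, 20), censored = FALSE, detection_limit = NA),
    data.frame(site_id = "C", analyte = c("Co", "Ni"),
               value = c(2, NA), censored = c(FALSE, TRUE),
               detection_limit = c(NA, 0.098))
  )
  pem_samples(sites, conc)
}

# scenario with two sources feeding disjoint analyte groups, used by the
# source-recovery simulations
two_source_scenario <- function(noise_sigma = 0.1) {
  river_scenario(
    n_main_stem = 30, n_tributaries = 0, reach_km = 30,
    sources = list(
      list(position_km = 5, multipliers = c(Co = 50, Ni = 40, Mn = 30)),
      list(position_km = 15, multipliers = c(Cu = 50, Pb = 40, Zn = 30))),
    noise_sigma = noise_sigma, detection_limits = NULL)
}

# build a resolved pem_samples object directly from a concentration matrix
samples_from_matrix <- function(m, group = "main_stem", pH = 7) {
  sites <- data.frame(site_id = rownames(m), group = group,
                      distance_km = NA_real_, pH = pH)
  conc <- do.call(rbind, lapply(colnames(m), function(a) {
    data.frame(site_id = rownames(m), analyte = a, value = m[, a],
               censored = FALSE, detection_limit = NA_real_)
  }))
  pem_samples(sites, conc, censor_policy = "half_dl")
}
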