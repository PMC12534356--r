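test_that("background derivation averages the reference sites", {
  bg <- fixture_background()
  expect_s3_class(bg, "pem_background")
  expect_equal(bg[["Cu"]], 1.07, tolerance = 0.01)
  expect_equal(bg[["Mn"]], 19.8)
  expect_equal(bg[["Al"]], 47.0)
  expect_equal(bg[["Pb"]], (0.41 + 0.13) / 2)  # hand mean of the two sites
  # mean of a single reference site is that site's resolved profile
  one <- derive_background(fixture_raw(), "NY-13")
  m13 <- conc_matrix(fixture_resolved(), quantified_pems())["NY-13", ]
  expect_equal(c(one), m13)
  expect_error(derive_background(fixture_raw(), "NY-99"), "NY-99")
})

test_that("contamination factors are element-wise ratios to background", {
  bg <- fixture_background()
  ms <- conc_matrix(main_stem(), quantified_pems())
  cf <- contamination_factors(colMeans(ms), bg)
  expect_equal(cf[["Ni"]], 1015, tolerance = 1 / 1015)
  expect_equal(contamination_factors(unclass(bg), bg),
               setNames(rep(1, length(bg)), names(bg)))
  expect_equal(ms["NY-05", "Co"] / 0.0265, 18604, tolerance = 1e-3)
  expect_error(contamination_factors(c(Hg = 1), bg), "Hg")
})

test_that("HEI sums concentration-to-limit ratios and classifies bands", {
  h <- hei(main_stem())
  expect_equal(h$value[h$site_id == "NY-07"], 17.3, tolerance = 0.05 / 17.3)
  expect_equal(h$value[h$site_id == "NY-01"], 0.852, tolerance = 1e-3)
  expect_true(all(h$classification == "low"))
  # additivity: the index is the sum of its per-analyte components
  expect_equal(rowSums(index_components(h)), setNames(h$value, h$site_id))
  # zero concentrations give a zero index
  z <- samples_from_matrix(matrix(0, 2, 3,
         dimnames = list(c("A", "B"), c("Co", "Ni", "Mn"))))
  expect_equal(hei(z, analytes = c("Co", "Ni", "Mn"))$value, c(0, 0))
  expect_error(hei(main_stem(), limit_plan(co_from_bc = FALSE)), "Co")
})

test_that("HEI is linear: doubling every concentration doubles the index", {
  m <- conc_matrix(main_stem(), quantified_pems())
  h1 <- hei(samples_from_matrix(m))
  h2 <- hei(samples_from_matrix(2 * m))
  expect_equal(h2$value, 2 * h1$value)
})

test_that("PLI is the geometric mean of contamination factors", {
  bg <- fixture_background()
  p <- pli(main_stem(), bg)
  expect_equal(p$value[p$site_id == "NY-05"], 14.5, tolerance = 0.5 / 14.5)
  expect_equal(p$value[p$site_id == "NY-01"], 0.91, tolerance = 0.02 / 0.91)
  # all contamination factors equal to one give PLI exactly one
  ones <- samples_from_matrix(matrix(bg, 1, length(bg), byrow = TRUE,
            dimnames = list("X", names(bg))))
  expect_equal(pli(ones, bg)$value, 1)
})

test_that("log-space PLI equals the direct n-th-root product oracle", {
  bg <- fixture_background()
  p <- pli(main_stem(), bg)
  cf <- index_components(p)
  direct <- apply(cf, 1, function(r) prod(r)^(1 / length(r)))  # oracle
  expect_equal(p$value, unname(direct[p$site_id]))
})

test_that("PLI is scale-equivariant in the concentrations", {
  bg <- fixture_background()
  m <- conc_matrix(main_stem(), quantified_pems())
  p1 <- pli(samples_from_matrix(m), bg)
  p3 <- pli(samples_from_matrix(3 * m), bg)
  expect_equal(p3$value, 3 * p1$value)
})

test_that("WQI reproduces the upstream site and calibrates to 100", {
  q <- wqi(main_stem())
  expect_equal(q$value[q$site_id == "NY-01"], 17.4, tolerance = 0.2 / 17.4)
  expect_equal(q$classification, published_wqi_band)
  # with every parameter at its standard the weights cancel: WQI = 100
  sch <- wqi_scheme()
  at_std <- samples_from_matrix(
    matrix(sch$s_values[setdiff(names(sch$weights), "pH")], 1, 10,
           byrow = TRUE,
           dimnames = list("S", setdiff(names(sch$weights), "pH"))),
    pH = sch$s_values[["pH"]])
  expect_equal(wqi(at_std, sch)$value, 100)
  expect_equal(classify_index(171, "wqi"), "poor")
  expect_error(wqi(main_stem(), wqi_scheme(weights = c(pH = 4, Hg = 9))),
               "1..5|Hg")
})

test_that("CCME WQI reproduces scope, frequency and amplitude", {
  cc <- ccme_wqi(main_stem())
  expect_equal(cc$f1, 100 * 3 / 11)
  expect_equal(cc$f2, 100 * 22 / 99)
  expect_equal(cc$f3, 31.05, tolerance = 0.01)
  expect_equal(cc$value, 72.9, tolerance = 0.3 / 72.9)
  expect_equal(cc$classification, "fair")
  expect_equal(cc$n_failed_parameters, 3)
  expect_equal(cc$n_failed_tests, 22)
})

test_that("CCME hand-worked single-excursion case and clean case", {
  # one parameter over four tests, one failure at twice the objective
  m <- matrix(c(50, 50, 50, 100, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
              4, 4, dimnames = list(paste0("S", 1:4),
                                    c("Mn", "Al", "As", "Pb")))
  plan <- limit_plan(overrides = c(Mn = 50))
  cc <- ccme_wqi(samples_from_matrix(m), plan, parameters = colnames(m))
  expect_equal(cc$excursions$excursion, 1)  # 100/50 - 1
  expect_equal(cc$f1, 25)
  expect_equal(cc$f2, 100 * 1 / 16)
  expect_equal(cc$nse, 1 / 16)
  # all objectives met: F1 = F2 = F3 = 0 and the index is 100
  clean <- ccme_wqi(samples_from_matrix(m * 0 + 1), plan,
                    parameters = colnames(m))
  expect_equal(c(clean$f1, clean$f2, clean$f3), c(0, 0, 0))
  expect_equal(clean$value, 100)
})

test_that("a fully failed single-parameter system collapses to 13.4", {
  # one parameter, one test, value at twice its objective:
  # F1 = F2 = 100, excursion 1, nse 1, F3 = 50, index 13.4
  f1 <- 100; f2 <- 100; f3 <- 100 * 1 / (1 + 1)
  expect_equal(100 - sqrt(f1^2 + f2^2 + f3^2) / 1.732, 13.4, tolerance = 1e-2)
  # the model minimum is enforced rather than extrapolated
  m <- matrix(2, 1, 1, dimnames = list("S1", "Mn"))
  expect_error(ccme_wqi(samples_from_matrix(m), limit_plan(overrides = c(Mn = 1)),
                        parameters = "Mn"), "at least 4")
})

test_that("CCME output is bounded and improves when a failing test passes", {
  cc <- ccme_wqi(main_stem())
  expect_true(cc$value >= 0 && cc$value <= 100)
  expect_true(cc$f3 < 100)
  # lowering any one failing measurement to its objective never lowers the index
  m <- conc_matrix(main_stem(), quantified_pems())
  plan <- limit_plan()
  exc <- cc$excursions[cc$excursions$parameter != "pH", ]
  for (i in seq_len(min(5, nrow(exc)))) {
    m2 <- m
    m2[exc$site_id[i], exc$parameter[i]] <- plan$limits[exc$parameter[i]]
    cc2 <- ccme_wqi(samples_from_matrix(m2, pH = main_stem()$sites$pH), plan)
    expect_gte(cc2$value, cc$value)
  }
})

test_that("pH is tested against both bounds of its objective range", {
  m <- matrix(1, 2, 3, dimnames = list(c("A", "B"), c("Al", "As", "Pb")))
  low_ph <- samples_from_matrix(m, pH = c(4, 7))  # 4 below the 5.5 floor
  cc <- ccme_wqi(low_ph, parameters = c("pH", colnames(m)))
  expect_equal(cc$excursions$parameter, "pH")
  expect_equal(cc$excursions$excursion, 5.5 / 4 - 1)
})

test_that("exceedance counts use strict inequality over the stated scope", {
  nl <- non_lake()
  expect_equal(exceedance_summary(nl, "Mn", 100)$count, 11)
  expect_equal(exceedance_summary(nl, "Ni", 70)$count, 5)
  expect_equal(exceedance_summary(nl, "Mn", 100)$percent, 100 * 11 / 15)
  expect_equal(exceedance_summary(nl, "Mn", 1e6)$count, 0)
  # ties at the limit do not count as exceedances
  m <- matrix(c(100, 101), 2, 1, dimnames = list(c("A", "B"), "Mn"))
  expect_equal(exceedance_summary(samples_from_matrix(m), "Mn", 100)$count, 1)
})

test_that("classification tables are total and non-overlapping", {
  set.seed(7)
  values <- c(0, 10^stats::runif(200, -7, 5))
  for (index in c("hei", "pli", "wqi", "er", "peri", "hq", "hi")) {
    labels <- classify_index(values, index)
    expect_false(anyNA(labels))
  }
  expect_false(anyNA(classify_index(stats::runif(100, 0, 100), "ccme")))
  expect_false(anyNA(classify_cancer_risk(10^stats::runif(100, -9, 0))))
  expect_equal(classify_cancer_risk(c(5e-7, 2e-4, 1e-5)),
               c("negligible", "unacceptable", "acceptable"))
})
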