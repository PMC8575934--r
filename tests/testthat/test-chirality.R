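test_that("derive_chirality reproduces the worked 75:25 case and edge cases", {
  # 11.25 mM R + 3.75 mM S -> total 15, er 75:25, R major
  d <- derive_chirality(11.25, 3.75)
  expect_equal(d$total, 15)
  expect_equal(d$er, c(75.0, 25.0))
  expect_identical(d$major, "R")
  expect_equal(d$ee, 0.5)
  # racemate
  r <- derive_chirality(2, 2)
  expect_equal(r$er, c(50.0, 50.0))
  expect_identical(r$major, "rac")
  # enantiopure
  p <- derive_chirality(5, 0)
  expect_equal(p$er, c(100.0, 0.0))
  expect_equal(p$ee, 1)
  # mirror symmetry: swapping arguments swaps the label only
  a <- derive_chirality(1.2, 3.4)
  b <- derive_chirality(3.4, 1.2)
  expect_equal(a$er, b$er)
  expect_equal(a$total, b$total)
  expect_identical(sort(c(a$major, b$major)), c("R", "S"))
  # er pair sums to 100 at printing precision
  set.seed(40)
  for (i in 1:50) {
    x <- runif(2, 0, 10)
    d <- derive_chirality(x[1], x[2])
    expect_equal(sum(d$er), 100, tolerance = 0.05)
  }
  # degenerate totals flagged, optionally clipped
  z <- derive_chirality(-1, 0.5)
  expect_false(z$defined)
  zc <- derive_chirality(-1, 0.5, clip = TRUE)
  expect_true(zc$defined)
  expect_equal(zc$er, c(100.0, 0.0))
  expect_identical(format_er(c(70.4, 29.6)), "70.4:29.6")
})

test_that("univariate calibration inverts exactly on noiseless mixtures", {
  g <- as.numeric(default_grid())
  bases <- list(make_preset_basis("PEA"), make_preset_basis("PMP"))
  tot <- 5
  ee_grid <- seq(-1, 1, length.out = 10)
  cd340 <- cd400 <- dpe <- dpm <- numeric(0)
  for (e in ee_grid) {
    comp <- composition(PEA = c(R = tot * (1 + e) / 2, S = tot * (1 - e) / 2),
                        PMP = c(R = tot * (1 - e) / 2, S = tot * (1 + e) / 2))
    sp <- simulate_mixture(bases, comp, "DCE")
    cd340 <- c(cd340, sp$cd$intensities[g == 340])
    cd400 <- c(cd400, sp$cd$intensities[g == 400])
    dpe <- c(dpe, tot * e); dpm <- c(dpm, -tot * e)
  }
  calPEA <- univariate_calibrate(cd340, dpe, "PEA", 340)
  calPMP <- univariate_calibrate(cd400, dpm, "PMP", 400)
  # noiseless test mixture: er recovered to numerical precision
  comp <- composition(PEA = c(R = 4, S = 1), PMP = c(R = 1.5, S = 3.5))
  sp <- simulate_mixture(bases, comp, "DCE")
  pe <- univariate_predict_er(calPEA, sp$cd$intensities[g == 340], 5)
  pm <- univariate_predict_er(calPMP, sp$cd$intensities[g == 400], 5)
  expect_equal(pe$ee, 0.6, tolerance = 1e-6)
  # PMP readout at 400 nm sees residual PEA crosstalk bounded by the
  # preset silence constraint (|PEA CD(400)| < 1% of max), not exactly 0
  expect_equal(pm$ee, -0.4, tolerance = 1e-4)
  expect_identical(pe$major, "R")
  expect_identical(pm$major, "S")
  # wavelength orthogonality: varying the OTHER analyte's er leaves the
  # readout unchanged (PMP crosses zero at 340, PEA silent at 400)
  comp2 <- composition(PEA = c(R = 4, S = 1), PMP = c(R = 5, S = 0))
  sp2 <- simulate_mixture(bases, comp2, "DCE")
  pe2 <- univariate_predict_er(calPEA, sp2$cd$intensities[g == 340], 5)
  expect_equal(pe2$ee, pe$ee, tolerance = 1e-6)
  # negating every ee negates the slope, keeps the intercept
  calNeg <- univariate_calibrate(cd340, -dpe, "PEA", 340)
  expect_equal(calNeg$slope, -calPEA$slope, tolerance = 1e-10)
  expect_equal(calNeg$intercept, calPEA$intercept, tolerance = 1e-8)
  # degenerate designs rejected
  expect_error(univariate_calibrate(rep(0.5, 5), rep(1, 5), "PEA", 340),
               "degenerate")
  expect_error(univariate_calibrate(cd340[1:2], dpe[1:2], "PEA", 340),
               ">= 3")
  # out-of-range readings clip with a warning
  expect_warning(big <- univariate_predict_er(calPEA, 1e4, 5), "clipped")
  expect_equal(abs(big$ee), 1)
})

test_that("campaign evaluation bins errors with left-closed boundaries", {
  expect_identical(as.character(chiromet:::bin_abs_error(c(0, 0.49, 0.5, 1.49,
                                                           1.5, 3))),
                   c("green", "green", "yellow", "yellow", "red", "red"))
  ds <- quaternary_noiseless()
  rep <- evaluate_campaign(ds, pipeline("pcr"), k = 4, k_max = 5)
  expect_true(all(rep$errors$bin == "green"))
  expect_lt(rep$test_rmse, 1e-6)
  expect_equal(rep$test_r2, 1, tolerance = 1e-9)
  # deterministic under a fixed seed
  ds1 <- simulate_design("quaternary", 10, 3, seed = 77)
  ds2 <- simulate_design("quaternary", 10, 3, seed = 77)
  r1 <- evaluate_campaign(ds1, pipeline("pcr"), k = 4, k_max = 4)
  r2_ <- evaluate_campaign(ds2, pipeline("pcr"), k = 4, k_max = 4)
  expect_identical(r1$predictions, r2_$predictions)
  expect_identical(r1$errors$abs_error_mM, r2_$errors$abs_error_mM)
})

test_that("chirality tables and reports serialize", {
  ds <- simulate_design("quaternary", 10, 3, seed = 78)
  rep <- evaluate_campaign(ds, pipeline("pcr"), k = 4, k_max = 4)
  tab <- chirality_table(rep$predictions)
  expect_equal(nrow(tab), 3 * 2)  # 3 test samples x 2 analytes
  expect_true(all(c("total_mM", "er", "major") %in% names(tab)))
  csvp <- withr::local_tempfile(fileext = ".csv")
  jsonp <- withr::local_tempfile(fileext = ".json")
  write_campaign_report(rep, csvp, jsonp)
  expect_true(file.exists(csvp) && file.exists(jsonp))
  back <- jsonlite::read_json(jsonp)
  expect_equal(back$test_rmse, rep$test_rmse, tolerance = 1e-10)
  # block-importance table from an MBPLS fit
  oc <- simulate_design("octonary", 12, 2, seed = 79)
  parts <- split_design(oc)
  fit <- fit_pipeline(pipeline("mbpls"), parts$train, 4)
  bt <- block_importance_table(fit)
  expect_equal(unname(rowSums(bt[, -1])), rep(1, 4), tolerance = 1e-10)
})

test_that("end-to-end noiseless pipeline reports the generator's er to 0.1", {
  ds <- quaternary_noiseless()
  rep <- evaluate_campaign(ds, pipeline("pcr"), k = 4, k_max = 5)
  parts <- split_design(ds)
  tab_pred <- chirality_table(rep$predictions)
  tab_true <- chirality_table(parts$test$Y)
  expect_identical(tab_pred$er, tab_true$er)
  expect_identical(tab_pred$major, tab_true$major)
})
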