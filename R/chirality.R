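# Chemistry-facing outputs: total concentration, enantiomeric ratio (er),
# enantiomeric excess (ee) and absolute configuration from per-enantiomer
# concentrations, plus the univariate complementary-wavelength er mode and
# whole-campaign evaluation reports.

#' Derive chirality quantities from per-enantiomer concentrations
#'
#' @param c_R,c_S concentrations (mM) of the R and S enantiomers (for PPA
#'   the (1R,2S) and (1S,2R) diastereomers).
#' @param clip if `TRUE`, negative predicted concentrations are set to 0
#'   before forming ratios; by default they are kept raw, since clipping
#'   biases low-concentration channels.
#' @param racemate_tol |ee| below this is reported as configuration
#'   `"rac"` (default 0.01).
#' @return list with `total` (mM), `er` (ordered major:minor pair, one
#'   decimal, summing to 100), `ee` (fraction), `major` (`"R"`, `"S"` or
#'   `"rac"`), `defined` (`FALSE` when total <= 0 makes er meaningless).
#' @export
derive_chirality <- function(c_R, c_S, clip = FALSE, racemate_tol = 0.01) {
  if (!is.finite(c_R) || !is.finite(c_S)) {
    stop("concentrations must be finite", call. = FALSE)
  }
  if (clip) { c_R <- max(c_R, 0); c_S <- max(c_S, 0) }
  total <- c_R + c_S
  if (total <= 0) {
    return(list(total = total, er = c(NA_real_, NA_real_), ee = NA_real_,
                major = NA_character_, defined = FALSE))
  }
  major_is_R <- c_R >= c_S
  major_frac <- max(c_R, c_S) / total
  er_major <- round(100 * major_frac, 1)
  er <- c(er_major, round(100 - er_major, 1))
  ee <- abs(c_R - c_S) / total
  major <- if (ee < racemate_tol) "rac" else if (major_is_R) "R" else "S"
  list(total = total, er = er, ee = ee, major = major, defined = TRUE)
}

#' Format an er pair in major:minor style
#' @param er numeric length-2 vector from [derive_chirality()].
#' @return character like `"70.4:29.6"`.
#' @export
format_er <- function(er) sprintf("%.1f:%.1f", er[1], er[2])

# Univariate complementary-wavelength mode -------------------------------

#' Calibrate the univariate CD readout of one analyte
#'
#' Ordinary least-squares line through (signed enantiomer difference
#' `ee * total` in mM, CD at the readout wavelength in mdeg). The
#' complementary wavelengths for the PEA/PMP pair are 340 nm (PEA
#' readout; PMP crosses zero there) and 400 nm (PMP readout; PEA is
#' CD-silent there).
#'
#' @param cd_values CD intensities (mdeg) at the readout wavelength, one
#'   per calibration mixture.
#' @param diff_mM signed `c_R - c_S` (mM) of the analyte, per mixture.
#' @param analyte analyte label.
#' @param wavelength_nm readout wavelength.
#' @return object of class `univariate_cal` with `slope`, `intercept`.
#' @export
univariate_calibrate <- function(cd_values, diff_mM, analyte, wavelength_nm) {
  if (length(cd_values) != length(diff_mM) || length(cd_values) < 3L) {
    stop("need >= 3 calibration points of matching length", call. = FALSE)
  }
  if (stats::sd(diff_mM) < .Machine$double.eps^0.5) {
    stop("degenerate calibration design: all compositions identical",
         call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, diff_mM), cd_values)
  slope <- unname(fit$coefficients[2])
  if (!is.finite(slope) || abs(slope) < .Machine$double.eps^0.5) {
    stop("unusable calibration: zero slope", call. = FALSE)
  }
  structure(list(analyte = analyte, wavelength_nm = wavelength_nm,
                 slope = slope, intercept = unname(fit$coefficients[1])),
            class = "univariate_cal")
}

#' Predict er and configuration from one CD reading
#'
#' Inverts the calibration line; requires the total concentration, the
#' stated limitation of the univariate mode. Out-of-range ee estimates
#' are clipped to +/-1 with a warning.
#'
#' @param cal `univariate_cal`.
#' @param cd_value CD (mdeg) at the calibrated wavelength.
#' @param total_mM known total concentration of the analyte.
#' @return list with `er`, `ee` (signed fraction, + meaning R major),
#'   `major`, `defined`.
#' @export
univariate_predict_er <- function(cal, cd_value, total_mM) {
  stopifnot(inherits(cal, "univariate_cal"))
  if (total_mM <= 0) {
    return(list(er = c(NA_real_, NA_real_), ee = NA_real_,
                major = NA_character_, defined = FALSE))
  }
  diff_hat <- (cd_value - cal$intercept) / cal$slope
  ee_signed <- diff_hat / total_mM
  if (abs(ee_signed) > 1) {
    warning(sprintf("predicted |ee| = %.3f > 1 clipped to 1", abs(ee_signed)),
            call. = FALSE)
    ee_signed <- sign(ee_signed)
  }
  c_R <- total_mM * (1 + ee_signed) / 2
  c_S <- total_mM - c_R
  out <- derive_chirality(c_R, c_S)
  out$ee <- ee_signed
  out
}

# Campaign evaluation ----------------------------------------------------

bin_abs_error <- function(err) {
  # left-closed bins matching the heat-map convention: green < 0.5 mM,
  # yellow 0.5-1.5 mM, red above
  cut(err, breaks = c(-Inf, 0.5, 1.5, Inf), labels = c("green", "yellow", "red"),
      right = FALSE)
}

#' Evaluate a calibration pipeline on a simulated or measured campaign
#'
#' Runs LOOCV on the training rows to pick the component count (unless
#' `k` is given), fits the pipeline, predicts the test rows, and tabulates
#' per-sample per-channel absolute errors with the green/yellow binning
#' (< 0.5 / 0.5--1.5 / > 1.5 mM) plus averaged R-squared and RMSE for both
#' cross-validation and test.
#'
#' @param dataset `multiblock_dataset` with a `roles` attribute and known
#'   test compositions.
#' @param spec `pipeline_spec`.
#' @param k component count; `NULL` selects it by LOOCV.
#' @param k_max LOOCV search ceiling (default `min(n_train - 2, 12)`).
#' @return object of class `campaign_report`: `cv` (`cv_result`),
#'   `selected_k`, `train_rmse_cv`, `train_r2_cv`, `test_rmse`,
#'   `test_r2`, `errors` (long data frame with bins), `predictions`.
#' @export
evaluate_campaign <- function(dataset, spec, k = NULL, k_max = NULL) {
  parts <- split_design(dataset)
  train <- parts$train; test <- parts$test
  n_train <- length(train$sample_ids)
  if (is.null(k_max)) k_max <- min(n_train - 2L, 12L)
  cv <- loocv(spec, train, k_max)
  if (is.null(k)) k <- cv$selected_k
  fit <- fit_pipeline(spec, train, k)
  pred <- predict_pipeline(fit, test)
  Yt <- test$Y
  err <- abs(Yt - pred)
  errors <- data.frame(
    sample_id = rep(test$sample_ids, times = ncol(Yt)),
    channel = rep(colnames(Yt), each = nrow(Yt)),
    actual_mM = as.vector(Yt),
    predicted_mM = as.vector(pred),
    abs_error_mM = as.vector(err),
    bin = bin_abs_error(as.vector(err))
  )
  structure(list(spec = spec, cv = cv, selected_k = k,
                 train_rmse_cv = cv$rmse_per_k[k],
                 train_r2_cv = cv$r2_per_k[k],
                 test_rmse = rmse(Yt, pred),
                 test_r2 = r2(Yt, pred),
                 errors = errors, predictions = pred, fit = fit),
            class = "campaign_report")
}

#' @export
print.campaign_report <- function(x, ...) {
  cat(sprintf(
    "<campaign_report> %s/%s, k=%d | CV: RMSE %.3f mM, R2 %.3f | test: RMSE %.3f mM, R2 %.3f\n",
    x$spec$method, x$spec$scaling, x$selected_k,
    x$train_rmse_cv, x$train_r2_cv, x$test_rmse, x$test_r2))
  tab <- table(x$errors$bin)
  cat(sprintf("  error bins: green %d, yellow %d, red %d\n",
              tab["green"], tab["yellow"], tab["red"]))
  invisible(x)
}

#' Write a campaign report to CSV and JSON
#'
#' @param report `campaign_report`.
#' @param csv_path,json_path output paths (either may be `NULL`).
#' @return invisibly, a list of written paths.
#' @export
write_campaign_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(report$errors, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      method = report$spec$method, scaling = report$spec$scaling,
      selected_k = report$selected_k,
      train_rmse_cv = report$train_rmse_cv, train_r2_cv = report$train_r2_cv,
      test_rmse = report$test_rmse, test_r2 = report$test_r2,
      errors = report$errors
    ), json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(csv = csv_path, json = json_path))
}

#' Chirality summary of a prediction matrix
#'
#' @param pred samples x channels matrix with `analyte_R`/`analyte_S`
#'   column pairs.
#' @param clip passed to [derive_chirality()].
#' @return data frame with one row per sample-analyte: total, er string,
#'   ee, major configuration.
#' @export
chirality_table <- function(pred, clip = FALSE) {
  pred <- as.matrix(pred)
  analytes <- unique(sub("_[RS]$", "", colnames(pred)))
  rows <- list()
  for (i in seq_len(nrow(pred))) {
    for (a in analytes) {
      d <- derive_chirality(pred[i, paste0(a, "_R")], pred[i, paste0(a, "_S")],
                            clip = clip)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = if (is.null(rownames(pred))) as.character(i) else
          rownames(pred)[i],
        analyte = a, total_mM = d$total,
        er = if (d$defined) format_er(d$er) else NA_character_,
        ee = d$ee, major = d$major, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Block-importance table of a fitted MBPLS pipeline
#'
#' Emits the per-LV block-importance rows (the pie-chart content of a
#' multiblock analysis) as a data frame, optionally written to CSV.
#'
#' @param fit `pipeline_fit` with method `"mbpls"` (or an `mbpls_model`).
#' @param path optional CSV output path.
#' @return data frame `lv x block` of importances.
#' @export
block_importance_table <- function(fit, path = NULL) {
  model <- if (inherits(fit, "pipeline_fit")) fit$model else fit
  stopifnot(inherits(model, "mbpls_model"))
  imp <- block_importance(model)
  df <- data.frame(lv = seq_len(nrow(imp)), imp, check.names = FALSE)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
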