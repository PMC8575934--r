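# Calibration pipelines, LOOCV model selection, and error metrics.
#
# A pipeline couples a preprocessing choice with an estimator. LOOCV
# refits the preprocessing inside every fold, so no scaling parameter ever
# sees the held-out sample.

.METHODS <- c("pcr", "pls", "mbpls", "mbpca_ols", "lasso_pcr", "lasso_pls")

#' Describe a calibration pipeline
#'
#' @param method `"pcr"`, `"pls"`, `"mbpls"`, `"mbpca_ols"` (MBPCA super
#'   scores + OLS), `"lasso_pcr"` or `"lasso_pls"` (LASSO variable
#'   selection, then PCR/PLS on the retained wavelengths).
#' @param scaling preprocessing: `"uv"` (mean center + unit variance,
#'   default), `"center"`, `"hard"` or `"soft"` (block scaling on top of
#'   unit variance).
#' @param lambda LASSO penalty for the `lasso_*` methods; `NULL` picks it
#'   by LOOCV over a 20-point log grid `10^[-4, 1] * lambda_max`.
#' @return list of class `pipeline_spec`.
#' @export
pipeline <- function(method = c("pcr", "pls", "mbpls", "mbpca_ols",
                                "lasso_pcr", "lasso_pls"),
                     scaling = c("uv", "center", "hard", "soft"),
                     lambda = NULL) {
  structure(list(method = match.arg(method), scaling = match.arg(scaling),
                 lambda = lambda),
            class = "pipeline_spec")
}

#' Fit a calibration pipeline
#'
#' @param spec `pipeline_spec`.
#' @param dataset training `multiblock_dataset` with known `Y`.
#' @param k number of components / latent variables.
#' @return object of class `pipeline_fit`.
#' @export
fit_pipeline <- function(spec, dataset, k) {
  stopifnot(inherits(spec, "pipeline_spec"))
  Y <- dataset$Y
  if (is.null(Y) || anyNA(Y)) {
    stop("training dataset must carry a complete Y", call. = FALSE)
  }
  prep <- preprocess_fit(dataset, spec$scaling)
  pp <- preprocess_apply(prep, dataset)
  selected <- NULL
  lambda <- spec$lambda
  X <- pp$matrix
  if (spec$method %in% c("lasso_pcr", "lasso_pls")) {
    if (is.null(lambda)) {
      lambda <- choose_lasso_lambda(X, Y)
    }
    selected <- lasso_select(X, Y, lambda)
    if (length(selected) == 0L) {
      stop("LASSO selected no variables; decrease lambda", call. = FALSE)
    }
    X <- X[, selected, drop = FALSE]
  }
  model <- switch(spec$method,
    pcr = ,
    lasso_pcr = {
      m <- pcr_fit(X, Y, min(k, min(nrow(X) - 1L, ncol(X))))
      m$train_scores <- if (m$n_pc_effective > 0) pca_transform(m$pca, X) else
        matrix(0, nrow(X), 0)
      m$train_Y <- Y
      m
    },
    pls = ,
    lasso_pls = pls_fit(X, Y, min(k, min(nrow(X) - 1L, ncol(X)))),
    mbpls = mbpls_fit(pp$blocks, Y, k),
    mbpca_ols = {
      mb <- mbpca_fit(pp$blocks, k)
      list(mbpca = mb, ols = ols_fit(mb$T_super, Y),
           ols_per_k = lapply(seq_len(k), function(kk) {
             ols_fit(mb$T_super[, seq_len(kk), drop = FALSE], Y)
           }))
    })
  structure(list(spec = spec, prep = prep, model = model, k = k,
                 lambda = lambda, selected = selected,
                 channel_names = dataset$channel_names),
            class = "pipeline_fit")
}

#' Predict concentrations with a fitted pipeline
#'
#' @param fit `pipeline_fit`.
#' @param dataset `multiblock_dataset` (Y may be absent).
#' @param k predict with the first `k` components (defaults to the fitted
#'   number; only meaningful for nested models).
#' @return samples x channels matrix of predicted concentrations (mM).
#' @export
predict_pipeline <- function(fit, dataset, k = fit$k) {
  pp <- preprocess_apply(fit$prep, dataset)
  X <- pp$matrix
  if (!is.null(fit$selected)) X <- X[, fit$selected, drop = FALSE]
  Yhat <- switch(fit$spec$method,
    pcr = ,
    lasso_pcr = {
      m <- fit$model
      if (k >= m$n_pc) {
        pcr_predict(m, X)
      } else {
        scores <- pca_transform(m$pca, X)[, seq_len(min(k, m$n_pc_effective)),
                                          drop = FALSE]
        tr <- m$train_scores[, seq_len(min(k, m$n_pc_effective)), drop = FALSE]
        ols_predict(ols_fit(tr, m$train_Y), scores)
      }
    },
    pls = ,
    lasso_pls = pls_predict(fit$model, X, n_lv = min(k, fit$model$n_lv)),
    mbpls = mbpls_predict(fit$model, pp$blocks, n_lv = min(k, fit$model$n_lv)),
    mbpca_ols = {
      kk <- min(k, fit$model$mbpca$n_pc)
      scores <- mbpca_project(fit$model$mbpca, pp$blocks, kk)
      ols_predict(fit$model$ols_per_k[[kk]], scores)
    })
  colnames(Yhat) <- fit$channel_names
  rownames(Yhat) <- dataset$sample_ids
  Yhat
}

# Project new preprocessed blocks onto MBPCA super scores using the
# stored consensus deflation loadings (sequential score-then-deflate, as
# at fit time).
mbpca_project <- function(mb, blocks_new, k = mb$n_pc) {
  X <- do.call(cbind, lapply(blocks_new, `[[`, "matrix"))
  scores <- matrix(0, nrow(X), k)
  E <- X
  for (a in seq_len(k)) {
    pl <- mb$P_concat[, a]
    t <- E %*% pl / sum(pl^2)
    scores[, a] <- t
    E <- E - t %*% t(pl)
  }
  scores
}

choose_lasso_lambda <- function(X, Y, n_grid = 20L) {
  lmax <- max(apply(as.matrix(Y), 2L, function(y) lasso_lambda_max(X, y)))
  grid <- lmax * 10^seq(-4, 1, length.out = n_grid)
  n <- nrow(X)
  press <- numeric(length(grid))
  for (g in seq_along(grid)) {
    errs <- 0
    for (i in seq_len(n)) {
      sel <- tryCatch(lasso_select(X[-i, , drop = FALSE],
                                   Y[-i, , drop = FALSE], grid[g]),
                      error = function(e) integer(0))
      if (length(sel) == 0L) {
        pred <- matrix(colMeans(Y[-i, , drop = FALSE]), 1)
      } else {
        ols <- tryCatch(
          ols_fit(X[-i, sel, drop = FALSE], Y[-i, , drop = FALSE]),
          error = function(e) NULL)
        pred <- if (is.null(ols)) matrix(colMeans(Y[-i, , drop = FALSE]), 1)
                else ols_predict(ols, X[i, sel, drop = FALSE])
      }
      errs <- errs + sum((Y[i, ] - pred)^2)
    }
    press[g] <- errs
  }
  grid[which.min(press)]
}

# Metrics ----------------------------------------------------------------

#' Root mean squared error over all sample-channel cells
#' @param Y,Yhat equal-shaped matrices (mM).
#' @return scalar RMSE in mM.
#' @export
rmse <- function(Y, Yhat) {
  Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
  if (!all(dim(Y) == dim(Yhat))) stop("shape mismatch", call. = FALSE)
  sqrt(mean((Y - Yhat)^2))
}

#' Averaged coefficient of determination
#'
#' R-squared is computed per channel as `1 - SSE/SST` and averaged over
#' channels; zero-variance channels are excluded with a warning.
#'
#' @param Y,Yhat equal-shaped matrices.
#' @return scalar averaged R-squared.
#' @export
r2 <- function(Y, Yhat) {
  Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
  if (!all(dim(Y) == dim(Yhat))) stop("shape mismatch", call. = FALSE)
  vals <- vapply(seq_len(ncol(Y)), function(ch) {
    sst <- sum((Y[, ch] - mean(Y[, ch]))^2)
    if (sst < .Machine$double.eps) return(NA_real_)
    1 - sum((Y[, ch] - Yhat[, ch])^2) / sst
  }, 0)
  if (anyNA(vals)) {
    warning(sprintf("%d zero-variance channel(s) excluded from R^2",
                    sum(is.na(vals))), call. = FALSE)
  }
  mean(vals, na.rm = TRUE)
}

# LOOCV ------------------------------------------------------------------

#' Leave-one-out cross-validation over component counts
#'
#' For every left-out sample the preprocessing and the model are refit on
#' the remaining rows (leak-free) and the held-out sample is predicted
#' with 1..`k_max` components; the per-k RMSE is the root mean square over
#' every held-out sample-channel cell.
#'
#' @param spec `pipeline_spec`.
#' @param dataset training `multiblock_dataset` (>= 3 samples).
#' @param k_max largest component count to score, `<= n - 2`.
#' @return object of class `cv_result` with `rmse_per_k`, `selected_k`,
#'   `r2_per_k`, and a `duplicate_rows` flag (duplicated samples make
#'   LOOCV optimistic; flagged, not rejected).
#' @export
loocv <- function(spec, dataset, k_max) {
  n <- length(dataset$sample_ids)
  if (n < 3L) stop("LOOCV needs at least 3 training samples", call. = FALSE)
  if (k_max > n - 2L) {
    stop(sprintf("k_max must be <= n - 2 = %d", n - 2L), call. = FALSE)
  }
  Y <- dataset$Y
  fused <- do.call(cbind, lapply(dataset$blocks, `[[`, "matrix"))
  dup <- anyDuplicated(round(fused, 12)) > 0L
  sq_err <- matrix(0, k_max, ncol(Y))   # accumulated squared errors per k
  for (i in seq_len(n)) {
    train <- subset_dataset(dataset, setdiff(seq_len(n), i))
    test <- subset_dataset(dataset, i)
    fit <- fit_pipeline(spec, train, k_max)
    for (k in seq_len(k_max)) {
      pred <- predict_pipeline(fit, test, k = k)
      sq_err[k, ] <- sq_err[k, ] + (Y[i, ] - pred[1, ])^2
    }
  }
  rmse_per_k <- sqrt(rowMeans(sq_err / n))
  # per-channel R^2 at each k against the channel totals
  sst <- vapply(seq_len(ncol(Y)), function(ch) sum((Y[, ch] - mean(Y[, ch]))^2), 0)
  r2_per_k <- vapply(seq_len(k_max), function(k) {
    mean(1 - sq_err[k, ] / sst)
  }, 0)
  res <- structure(list(method = spec$method, scaling = spec$scaling,
                        rmse_per_k = rmse_per_k, r2_per_k = r2_per_k,
                        selected_k = NA_integer_, duplicate_rows = dup,
                        n = n),
                   class = "cv_result")
  res$selected_k <- select_k(res)
  res
}

#' Select the component count from a cross-validation result
#'
#' Argmin of the RMSE curve with smallest-k tie-breaking: a smaller k wins
#' whenever its RMSE is within relative tolerance 1e-6 of any larger k's.
#'
#' @param cv `cv_result` (or a bare numeric RMSE vector).
#' @return integer component count.
#' @export
select_k <- function(cv) {
  r <- if (inherits(cv, "cv_result")) cv$rmse_per_k else as.numeric(cv)
  if (length(r) == 0L) stop("empty rmse_per_k", call. = FALSE)
  best <- min(r)
  which(r <= best * (1 + 1e-6))[1]
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s/%s, n=%d, selected k=%d (RMSE %.4g mM)%s\n",
              x$method, x$scaling, x$n, x$selected_k,
              x$rmse_per_k[x$selected_k],
              if (x$duplicate_rows) " [duplicate rows: optimistic]" else ""))
  invisible(x)
}

#' Write a cross-validation curve as CSV
#'
#' Emits `k,rmse` rows, the data behind an RMSE-versus-latent-variables
#' plot.
#'
#' @param cv `cv_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cv_csv <- function(cv, path) {
  df <- data.frame(k = seq_along(cv$rmse_per_k), rmse = cv$rmse_per_k)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
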