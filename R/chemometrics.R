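# Single-block decomposition and regression.
#
# PCA is computed by SVD of the centered matrix (not NIPALS) for numerical
# stability and exact reproducibility; PLS2 uses the classical NIPALS
# algorithm; LASSO is cyclic coordinate descent on the standardized
# least-squares objective. These are the calibration engines behind the
# PCR / PLS / LASSO-assisted concentration models.

# PCA --------------------------------------------------------------------

#' Fit a PCA model by singular value decomposition
#'
#' The matrix is column-centered, decomposed as `X = U S V'`, and each
#' component's sign is fixed so its largest-|loading| entry is positive,
#' making serialized models comparable across runs.
#'
#' @param X samples x variables matrix.
#' @param n_components number of components to keep,
#'   `<= min(nrow(X) - 1, ncol(X))`.
#' @return object of class `pca_model` with fields `means`, `loadings`
#'   (variables x components), `singular_values`,
#'   `explained_variance_ratio`, `n_components`.
#' @export
pca_fit <- function(X, n_components) {
  X <- as.matrix(X)
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (n_components < 0 || n_components > kmax) {
    stop(sprintf("n_components must be in [0, %d]", kmax), call. = FALSE)
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0, nv = min(kmax, ncol(X)))
  d <- sv$d[seq_len(kmax)]
  evr <- d^2 / sum(sv$d^2)
  k <- n_components
  V <- sv$v[, seq_len(max(k, 1L)), drop = FALSE][, seq_len(k), drop = FALSE]
  if (k > 0) {
    for (j in seq_len(k)) {
      i <- which.max(abs(V[, j]))
      if (V[i, j] < 0) V[, j] <- -V[, j]
    }
  }
  structure(list(means = mu, loadings = V, singular_values = d[seq_len(k)],
                 explained_variance_ratio = evr[seq_len(k)],
                 n_components = k, all_singular_values = d),
            class = "pca_model")
}

#' Project data onto PCA components
#' @param model `pca_model`.
#' @param X matrix with the model's variable count.
#' @return scores matrix (samples x components).
#' @export
pca_transform <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$means)) {
    stop("variable count does not match the PCA model", call. = FALSE)
  }
  sweep(X, 2L, model$means) %*% model$loadings
}

#' Reconstruct data from PCA scores
#' @param model `pca_model`.
#' @param scores samples x components matrix.
#' @return reconstructed matrix in the original variable space.
#' @export
pca_inverse_transform <- function(model, scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != model$n_components) {
    stop("score count does not match the PCA model", call. = FALSE)
  }
  sweep(scores %*% t(model$loadings), 2L, model$means, `+`)
}

# OLS --------------------------------------------------------------------

#' Ordinary least squares with intercept
#'
#' Solves the normal equations explicitly and refuses rank-deficient
#' designs rather than silently pseudo-inverting.
#'
#' @param T samples x k predictor matrix.
#' @param Y samples x channels response matrix.
#' @return list of class `ols_model` with `coef` ((k+1) x channels; first
#'   row is the intercept).
#' @export
ols_fit <- function(T, Y) {
  T <- as.matrix(T); Y <- as.matrix(Y)
  n <- nrow(T)
  if (nrow(Y) != n) stop("T and Y row counts differ", call. = FALSE)
  if (n <= ncol(T)) {
    stop("need more samples than predictors", call. = FALSE)
  }
  A <- cbind(`(Intercept)` = 1, T)
  G <- crossprod(A)
  if (rcond(G) < 1e-12) {
    stop("rank-deficient design: normal equations are singular", call. = FALSE)
  }
  coef <- solve(G, crossprod(A, Y))
  structure(list(coef = coef), class = "ols_model")
}

#' @rdname ols_fit
#' @param model `ols_model`.
#' @param T_new new predictor matrix.
#' @export
ols_predict <- function(model, T_new) {
  cbind(1, as.matrix(T_new)) %*% model$coef
}

# PCR --------------------------------------------------------------------

#' Principal component regression
#'
#' PCA on X followed by OLS of Y on the retained scores; the PCA
#' centering is frozen at training time.
#'
#' @param X samples x variables matrix.
#' @param Y samples x channels matrix.
#' @param n_pc number of principal components (0 predicts channel means).
#' @return object of class `pcr_model`.
#' @export
pcr_fit <- function(X, Y, n_pc) {
  Y <- as.matrix(Y)
  kmax <- min(nrow(as.matrix(X)) - 1L, ncol(as.matrix(X)))
  if (n_pc < 0 || n_pc > kmax) {
    stop(sprintf("n_pc must be in [0, %d]", kmax), call. = FALSE)
  }
  pca <- pca_fit(X, n_pc)
  # retain only components above the numerical-rank floor so OLS on the
  # scores stays well-posed (requesting more PCs than rank is common in
  # LOOCV sweeps on noiseless data)
  if (n_pc > 0L) {
    d <- pca$all_singular_values
    keff <- min(n_pc, sum(d > d[1] * 1e-9))
    if (keff < n_pc) pca <- pca_fit(X, keff)
  } else {
    keff <- 0L
  }
  if (keff == 0L) {
    ols <- structure(list(coef = rbind(colMeans(Y))), class = "ols_model")
  } else {
    ols <- ols_fit(pca_transform(pca, X), Y)
  }
  structure(list(pca = pca, ols = ols, n_pc = n_pc, n_pc_effective = keff),
            class = "pcr_model")
}

#' @rdname pcr_fit
#' @param model `pcr_model`.
#' @param X_new new data matrix.
#' @export
pcr_predict <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (model$n_pc_effective == 0L) {
    return(matrix(model$ols$coef, nrow(X_new), ncol(model$ols$coef),
                  byrow = TRUE, dimnames = list(NULL, colnames(model$ols$coef))))
  }
  ols_predict(model$ols, pca_transform(model$pca, X_new))
}

# PLS2 (NIPALS) ----------------------------------------------------------

#' Fit a PLS2 regression model by NIPALS
#'
#' Per latent variable: the weight vector w is the dominant eigenvector of
#' `X'YY'X` (found by the NIPALS inner iteration), scores `t = Xw`,
#' X-loadings `p = X't/t't`, Y-loadings `q = Y't/t't`, then X is deflated
#' by `t p'`. The coefficient matrix is `B = W (P'W)^-1 Q'` on centered
#' data, with the intercept restored from the column means.
#'
#' @param X samples x variables matrix.
#' @param Y samples x channels matrix.
#' @param n_lv number of latent variables.
#' @param tol inner-iteration convergence tolerance on the weight vector.
#' @param max_iter inner-iteration cap per latent variable.
#' @return object of class `pls_model` with `W`, `T`, `P`, `Q`, `B`,
#'   `x_means`, `y_means`, `n_lv`.
#' @export
pls_fit <- function(X, Y, n_lv, tol = 1e-10, max_iter = 10000L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y row counts differ", call. = FALSE)
  if (n_lv < 1 || n_lv > min(n - 1L, ncol(X))) {
    stop(sprintf("n_lv must be in [1, %d]", min(n - 1L, ncol(X))),
         call. = FALSE)
  }
  xm <- colMeans(X); ym <- colMeans(Y)
  E <- sweep(X, 2L, xm); F <- sweep(Y, 2L, ym)
  p <- ncol(X); m <- ncol(Y)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv); Q <- matrix(0, m, n_lv)
  E0 <- sum(E^2); F0 <- sum(F^2)
  extracted <- 0L
  for (a in seq_len(n_lv)) {
    # residual exhausted (noiseless data of low rank): keep what we have
    if (a > 1L && (sum(E^2) < 1e-24 * E0 || sum(F^2) < 1e-24 * F0 ||
                   max(abs(crossprod(E, F))) < 1e-12 * sqrt(E0 * F0))) {
      break
    }
    if (sum(F^2) < .Machine$double.eps) {
      stop(sprintf(
        "PLS weight undefined at LV %d: Y carries no residual covariance with X",
        a), call. = FALSE)
    }
    # NIPALS inner loop: the update w <- E'u, u <- Fq/q'q collapses to the
    # power step w <- C C'w with C = E'F, so iterate that directly
    C <- crossprod(E, F)
    if (max(abs(C)) < .Machine$double.eps) {
      stop(sprintf("PLS weight undefined at LV %d: zero X-Y covariance", a),
           call. = FALSE)
    }
    w <- C[, which.max(colSums(C^2))]
    w <- w / sqrt(sum(w^2))
    w_old <- w
    converged <- (m == 1L)
    if (!converged) {
      for (it in seq_len(max_iter)) {
        w <- C %*% crossprod(C, w)
        nw <- sqrt(sum(w^2))
        if (nw < .Machine$double.eps) {
          stop(sprintf("PLS weight undefined at LV %d: zero X-Y covariance", a),
               call. = FALSE)
        }
        w <- w / nw
        if (sqrt(sum((w - w_old)^2)) < tol) { converged <- TRUE; break }
        w_old <- w
      }
    }
    if (!converged) {
      stop(sprintf("NIPALS did not converge at LV %d within %d iterations",
                   a, max_iter), call. = FALSE)
    }
    t <- E %*% w
    pvec <- crossprod(E, t) / sum(t^2)
    q <- crossprod(F, t) / sum(t^2)
    E <- E - t %*% t(pvec)
    F <- F - t %*% t(q)
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t; Q[, a] <- q
    extracted <- a
  }
  idx <- seq_len(extracted)
  W <- W[, idx, drop = FALSE]; P <- P[, idx, drop = FALSE]
  Tm <- Tm[, idx, drop = FALSE]; Q <- Q[, idx, drop = FALSE]
  R <- W %*% solve(t(P) %*% W)   # X-rotation: T = Xc %*% R
  B <- R %*% t(Q)
  structure(list(W = W, T = Tm, P = P, Q = Q, R = R, B = B,
                 x_means = xm, y_means = ym, n_lv = extracted,
                 n_lv_requested = n_lv),
            class = "pls_model")
}

#' @rdname pls_fit
#' @param model `pls_model`.
#' @param X_new new data matrix.
#' @param n_lv optionally predict with fewer latent variables than fitted.
#' @export
pls_predict <- function(model, X_new, n_lv = model$n_lv) {
  if (n_lv < 1) stop("n_lv out of range for this model", call. = FALSE)
  n_lv <- min(n_lv, model$n_lv)  # clamp past rank exhaustion
  X_new <- as.matrix(X_new)
  if (n_lv == model$n_lv) {
    B <- model$B
  } else {
    idx <- seq_len(n_lv)
    W <- model$W[, idx, drop = FALSE]
    P <- model$P[, idx, drop = FALSE]
    Q <- model$Q[, idx, drop = FALSE]
    B <- W %*% solve(t(P) %*% W) %*% t(Q)
  }
  sweep(sweep(X_new, 2L, model$x_means) %*% B, 2L, model$y_means, `+`)
}

# LASSO (cyclic coordinate descent) --------------------------------------

#' Fit a LASSO model by cyclic coordinate descent
#'
#' Minimizes `1/(2n) ||y - X b||^2 + lambda ||b||_1` on centered data (the
#' intercept is handled by centering and never penalized). Convergence:
#' maximum coefficient change below `tol` in a full sweep.
#'
#' @param X samples x variables matrix (standardize beforehand; the solver
#'   centers but does not rescale).
#' @param y single response vector.
#' @param lambda penalty, >= 0.
#' @param tol convergence tolerance (default 1e-8).
#' @param max_sweeps cap on full coordinate sweeps (default 1e4).
#' @return object of class `lasso_model` with `coef`, `intercept`,
#'   `lambda`, `selected` (indices of nonzero coefficients).
#' @export
lasso_fit <- function(X, y, lambda, tol = 1e-8, max_sweeps = 10000L) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2L, xm); yc <- y - ym
  col_ss <- colSums(Xc^2) / n
  beta <- rep(0, p)
  r <- yc   # residual y - X beta
  soft <- function(z, g) sign(z) * max(abs(z) - g, 0)
  converged <- FALSE
  for (sweep_i in seq_len(max_sweeps)) {
    delta_max <- 0
    for (j in seq_len(p)) {
      if (col_ss[j] < .Machine$double.eps) next
      bj_old <- beta[j]
      rho <- sum(Xc[, j] * r) / n + col_ss[j] * bj_old
      bj <- soft(rho, lambda) / col_ss[j]
      if (bj != bj_old) {
        r <- r - Xc[, j] * (bj - bj_old)
        beta[j] <- bj
        delta_max <- max(delta_max, abs(bj - bj_old))
      }
    }
    if (delta_max < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    stop(sprintf("LASSO did not converge within %d sweeps", max_sweeps),
         call. = FALSE)
  }
  structure(list(coef = beta, intercept = ym - sum(xm * beta),
                 lambda = lambda, selected = which(beta != 0)),
            class = "lasso_model")
}

#' LASSO objective value
#' @param X,y problem data as in [lasso_fit()].
#' @param beta coefficient vector (centered parameterization).
#' @param lambda penalty.
#' @return scalar objective `1/(2n)||yc - Xc b||^2 + lambda ||b||_1`.
#' @export
lasso_objective <- function(X, y, beta, lambda) {
  X <- as.matrix(X)
  Xc <- sweep(X, 2L, colMeans(X)); yc <- y - mean(y)
  sum((yc - Xc %*% beta)^2) / (2 * nrow(X)) + lambda * sum(abs(beta))
}

#' Smallest penalty that zeroes all LASSO coefficients
#' @param X,y problem data.
#' @return `max |Xc' yc| / n`.
#' @export
lasso_lambda_max <- function(X, y) {
  X <- as.matrix(X)
  Xc <- sweep(X, 2L, colMeans(X)); yc <- y - mean(y)
  max(abs(crossprod(Xc, yc))) / nrow(X)
}

#' Union of LASSO-selected variables across response channels
#'
#' Fits one LASSO per channel of `Y` and returns the sorted union of the
#' nonzero-coefficient indices — the wavelength set the LASSO-assisted
#' PCR/PLS pipelines restrict themselves to before refitting.
#'
#' @param X samples x variables matrix (standardized).
#' @param Y samples x channels matrix.
#' @param lambda penalty shared across channels.
#' @return integer vector of selected column indices.
#' @export
lasso_select <- function(X, Y, lambda) {
  Y <- as.matrix(Y)
  sel <- integer(0)
  for (ch in seq_len(ncol(Y))) {
    sel <- union(sel, lasso_fit(X, Y[, ch], lambda)$selected)
  }
  sort(sel)
}
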