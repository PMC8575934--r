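# Multiblock (consensus) decomposition and regression.
#
# Both algorithms follow the consensus formulation with super-score
# deflation: every latent variable has per-block weights/scores/loadings
# plus a super score combining the block scores. With this formulation the
# MBPLS predictions coincide with ordinary PLS2 run on the concatenated,
# identically preprocessed matrix -- an exact correctness oracle used by
# the test suite -- while exposing the block-level structure (block
# loadings, block importance) that makes the fused model interpretable.

#' Consensus multiblock PCA
#'
#' NIPALS consensus PCA: per principal component, iterate block loadings
#' `p_b = X_b' t / t't` (normalized), block scores `t_b = X_b p_b`, super
#' weights from regressing the super score on the block scores, and super
#' score `t = T_block w` until convergence; all blocks are then deflated
#' by the super score. The super-score subspace equals the PCA subspace of
#' the concatenated matrix.
#'
#' @param blocks list of preprocessed `spectral_block`s (centered; scale
#'   as desired).
#' @param n_pc number of components.
#' @param tol convergence tolerance on the super score.
#' @param max_iter iteration cap per component.
#' @return object of class `mbpca_model` with per-component block scores
#'   `Tb` (list of matrices), block loadings `Pb`, super scores `T_super`,
#'   super weights `W_super` (components x blocks), explained variance per
#'   block and overall.
#' @export
mbpca_fit <- function(blocks, n_pc, tol = 1e-10, max_iter = 1000L) {
  if (length(blocks) == 0L) stop("need at least one block", call. = FALSE)
  Xb <- lapply(blocks, `[[`, "matrix")
  B <- length(Xb)
  n <- nrow(Xb[[1]])
  bn <- vapply(blocks, `[[`, "", "name")
  ss_tot_b <- vapply(Xb, function(M) sum(M^2), 0)
  ss_tot <- sum(ss_tot_b)
  Tb <- lapply(Xb, function(M) matrix(0, n, n_pc))
  Pb <- lapply(Xb, function(M) matrix(0, ncol(M), n_pc))
  T_super <- matrix(0, n, n_pc)
  P_concat <- matrix(0, sum(vapply(Xb, ncol, 0L)), n_pc)
  W_super <- matrix(0, n_pc, B, dimnames = list(NULL, bn))
  evr_block <- matrix(0, n_pc, B, dimnames = list(NULL, bn))
  evr <- numeric(n_pc)
  E <- Xb
  for (a in seq_len(n_pc)) {
    concat <- do.call(cbind, E)
    t <- concat[, which.max(colSums(concat^2))]
    if (sum(t^2) < 1e-20 * max(ss_tot, 1)) {
      stop(sprintf("MBPCA residual exhausted before component %d", a),
           call. = FALSE)
    }
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      pb <- lapply(E, function(M) {
        p <- crossprod(M, t) / sum(t^2)
        np <- sqrt(sum(p^2))
        if (np > 0) p / np else p
      })
      tb <- mapply(function(M, p) M %*% p, E, pb, SIMPLIFY = FALSE)
      Tmat <- do.call(cbind, tb)
      w <- crossprod(Tmat, t) / sum(t^2)
      w <- w / sqrt(sum(w^2))
      t_new <- Tmat %*% w
      if (sqrt(sum((t_new - t)^2)) < tol * sqrt(sum(t_new^2))) {
        t <- t_new; converged <- TRUE; break
      }
      t <- t_new
    }
    if (!converged) {
      stop(sprintf("MBPCA did not converge at component %d within %d iterations",
                   a, max_iter), call. = FALSE)
    }
    pb <- lapply(E, function(M) {
      p <- crossprod(M, t) / sum(t^2)
      np <- sqrt(sum(p^2)); if (np > 0) p / np else p
    })
    tb <- mapply(function(M, p) M %*% p, E, pb, SIMPLIFY = FALSE)
    w <- crossprod(do.call(cbind, tb), t) / sum(t^2)
    w <- w / sqrt(sum(w^2))
    # super-score deflation of every block
    p_defl_all <- vector("list", B)
    for (b in seq_len(B)) {
      p_defl <- crossprod(E[[b]], t) / sum(t^2)
      removed <- sum((t %*% t(p_defl))^2)
      evr_block[a, b] <- removed / ss_tot_b[b]
      E[[b]] <- E[[b]] - t %*% t(p_defl)
      Tb[[b]][, a] <- tb[[b]]
      Pb[[b]][, a] <- pb[[b]]
      p_defl_all[[b]] <- p_defl
    }
    P_concat[, a] <- unlist(p_defl_all, use.names = FALSE)
    evr[a] <- sum(evr_block[a, ] * ss_tot_b) / ss_tot
    T_super[, a] <- t
    W_super[a, ] <- w
  }
  names(Tb) <- bn; names(Pb) <- bn
  structure(list(block_scores = Tb, block_loadings = Pb, T_super = T_super,
                 P_concat = P_concat,
                 W_super = W_super, explained_variance_block = evr_block,
                 explained_variance_ratio = evr, n_pc = n_pc,
                 block_names = bn),
            class = "mbpca_model")
}

#' Multiblock PLS2 (consensus formulation)
#'
#' Per latent variable the concatenated weight vector is built block-wise
#' from the covariance with the Y residual (`w_b = X_b' u`), jointly
#' normalized, split into block weights; block scores are
#' `t_b = X_b w_b / ||w_b||`, the super score is their
#' `omega_b = ||w_b||`-weighted sum (identically the score of the
#' concatenated data), Y-loadings follow as in PLS2 and each block is
#' deflated by the super score. Predictions therefore agree with ordinary
#' PLS2 on the concatenated matrix.
#'
#' @param blocks list of preprocessed `spectral_block`s (training rows).
#' @param Y samples x channels response matrix.
#' @param n_lv number of latent variables.
#' @param tol,max_iter NIPALS inner-iteration controls.
#' @return object of class `mbpls_model`: per-LV block weights `Wb`,
#'   block scores `Tb`, block loadings `Pb`, super scores `T_super`,
#'   super weights `omega` (LV x blocks, squared rows give block
#'   importance), Y-loadings `Q`, coefficient matrix `B` on the
#'   concatenated space, and `block_importance`.
#' @export
mbpls_fit <- function(blocks, Y, n_lv, tol = 1e-10, max_iter = 10000L) {
  if (length(blocks) == 0L) stop("need at least one block", call. = FALSE)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  bn <- vapply(blocks, `[[`, "", "name")
  Xb <- lapply(blocks, `[[`, "matrix")
  for (b in seq_along(Xb)) {
    if (nrow(Xb[[b]]) != n) {
      stop(sprintf("block '%s' rows do not align with Y", bn[b]), call. = FALSE)
    }
  }
  p_b <- vapply(Xb, ncol, 0L)
  p_tot <- sum(p_b)
  if (n_lv < 1 || n_lv > min(n - 1L, p_tot)) {
    stop(sprintf("n_lv must be in [1, %d]", min(n - 1L, p_tot)), call. = FALSE)
  }
  xm <- lapply(Xb, colMeans)
  ym <- colMeans(Y)
  E <- mapply(function(M, m) sweep(M, 2L, m), Xb, xm, SIMPLIFY = FALSE)
  F <- sweep(Y, 2L, ym)
  E0 <- sum(vapply(E, function(M) sum(M^2), 0)); F0 <- sum(F^2)
  m <- ncol(Y)
  W <- matrix(0, p_tot, n_lv); P <- matrix(0, p_tot, n_lv)
  Tm <- matrix(0, n, n_lv); Q <- matrix(0, m, n_lv)
  Wb <- lapply(p_b, function(p) matrix(0, p, n_lv))
  Tb <- lapply(p_b, function(p) matrix(0, n, n_lv))
  Pb <- lapply(p_b, function(p) matrix(0, p, n_lv))
  omega <- matrix(0, n_lv, length(Xb), dimnames = list(NULL, bn))
  splits <- rep(seq_along(Xb), p_b)
  extracted <- 0L
  for (a in seq_len(n_lv)) {
    resE <- sum(vapply(E, function(M) sum(M^2), 0))
    if (a > 1L && (resE < 1e-24 * E0 || sum(F^2) < 1e-24 * F0)) break
    if (sum(F^2) < .Machine$double.eps) {
      stop(sprintf("MBPLS weight undefined at LV %d", a), call. = FALSE)
    }
    # block-wise NIPALS inner loop as the equivalent power step on the
    # stacked covariance C = [E_b' F]_b
    Cb <- lapply(E, function(M) crossprod(M, F))
    C <- do.call(rbind, Cb)
    if (max(abs(C)) < .Machine$double.eps) {
      stop(sprintf("MBPLS weight undefined at LV %d: zero X-Y covariance", a),
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
          stop(sprintf("MBPLS weight undefined at LV %d: zero X-Y covariance",
                       a), call. = FALSE)
        }
        w <- w / nw
        if (sqrt(sum((w - w_old)^2)) < tol) { converged <- TRUE; break }
        w_old <- w
      }
    }
    if (!converged) {
      stop(sprintf("MBPLS did not converge at LV %d within %d iterations",
                   a, max_iter), call. = FALSE)
    }
    wb <- split(w, splits)
    t <- Reduce(`+`, mapply(function(M, wv) M %*% wv, E, wb, SIMPLIFY = FALSE))
    q <- crossprod(F, t) / sum(t^2)
    for (b in seq_along(E)) {
      nwb <- sqrt(sum(wb[[b]]^2))
      omega[a, b] <- nwb
      Wb[[b]][, a] <- wb[[b]]
      Tb[[b]][, a] <- if (nwb > 0) E[[b]] %*% wb[[b]] / nwb else 0
      pbv <- crossprod(E[[b]], t) / sum(t^2)
      Pb[[b]][, a] <- pbv
      E[[b]] <- E[[b]] - t %*% t(pbv)
    }
    F <- F - t %*% t(q)
    W[, a] <- w
    P[, a] <- unlist(lapply(Pb, function(M) M[, a]), use.names = FALSE)
    Tm[, a] <- t
    Q[, a] <- q
    extracted <- a
  }
  idx <- seq_len(extracted)
  W <- W[, idx, drop = FALSE]; P <- P[, idx, drop = FALSE]
  Tm <- Tm[, idx, drop = FALSE]; Q <- Q[, idx, drop = FALSE]
  omega <- omega[idx, , drop = FALSE]
  Wb <- lapply(Wb, function(M) M[, idx, drop = FALSE])
  Tb <- lapply(Tb, function(M) M[, idx, drop = FALSE])
  Pb <- lapply(Pb, function(M) M[, idx, drop = FALSE])
  names(Wb) <- bn; names(Tb) <- bn; names(Pb) <- bn
  B <- W %*% solve(t(P) %*% W) %*% t(Q)
  imp <- omega^2 / rowSums(omega^2)
  structure(list(block_weights = Wb, block_scores = Tb, block_loadings = Pb,
                 T_super = Tm, omega = omega, Q = Q, W = W, P = P, B = B,
                 x_means = unlist(xm, use.names = FALSE), y_means = ym,
                 n_lv = extracted, n_lv_requested = n_lv,
                 block_importance = imp, block_names = bn,
                 block_widths = p_b),
            class = "mbpls_model")
}

#' @rdname mbpls_fit
#' @param model `mbpls_model`.
#' @param blocks_new list of `spectral_block`s preprocessed with the same
#'   frozen record as the training blocks.
#' @param n_lv optionally predict with fewer latent variables.
#' @export
mbpls_predict <- function(model, blocks_new, n_lv = model$n_lv) {
  if (n_lv < 1) stop("n_lv out of range", call. = FALSE)
  n_lv <- min(n_lv, model$n_lv)
  bn_new <- vapply(blocks_new, `[[`, "", "name")
  if (!identical(unname(bn_new), unname(model$block_names))) {
    stop("blocks do not match the fitted model (names/order)", call. = FALSE)
  }
  X <- do.call(cbind, lapply(blocks_new, `[[`, "matrix"))
  if (ncol(X) != length(model$x_means)) {
    stop("block widths do not match the fitted model", call. = FALSE)
  }
  idx <- seq_len(n_lv)
  W <- model$W[, idx, drop = FALSE]
  P <- model$P[, idx, drop = FALSE]
  Q <- model$Q[, idx, drop = FALSE]
  B <- W %*% solve(t(P) %*% W) %*% t(Q)
  sweep(sweep(X, 2L, model$x_means) %*% B, 2L, model$y_means, `+`)
}

#' Per-LV block importance of a fitted MBPLS model
#'
#' `importance(a, b) = ||w_{b,a}||^2 / sum_b' ||w_{b',a}||^2` on the
#' block-scaled space; each row is a probability vector over blocks
#' telling how much each measurement block drives that latent variable.
#'
#' @param model `mbpls_model`.
#' @return LV x blocks matrix with rows summing to 1.
#' @export
block_importance <- function(model) {
  stopifnot(inherits(model, "mbpls_model"))
  model$block_importance
}
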