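# Independent oracles and fixture builders used across the suite.

# Kernel PLS2 (Dayal & MacGregor improved kernel algorithm): works on the
# cross-product matrices only, never deflates X, and reconstructs the
# rotation recursively -- an algorithm independent of the NIPALS code path
# it checks.
kernel_pls2 <- function(X, Y, n_lv) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2L, xm); Yc <- sweep(Y, 2L, ym)
  XtX <- crossprod(Xc); XtY <- crossprod(Xc, Yc)
  p <- ncol(X); m <- ncol(Y)
  R <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv); Q <- matrix(0, m, n_lv)
  for (a in seq_len(n_lv)) {
    w <- svd(XtY)$u[, 1]
    r <- w
    if (a > 1L) {
      for (j in seq_len(a - 1L)) r <- r - sum(P[, j] * r) * R[, j]
    }
    tt <- drop(crossprod(r, XtX %*% r))
    p_a <- XtX %*% r / tt
    q_a <- crossprod(XtY, r) / tt
    XtY <- XtY - (p_a * tt) %*% t(q_a)
    R[, a] <- r; P[, a] <- p_a; Q[, a] <- q_a
  }
  B <- R %*% t(Q)
  list(B = B, x_means = xm, y_means = ym,
       predict = function(Xn) {
         sweep(sweep(as.matrix(Xn), 2L, xm) %*% B, 2L, ym, `+`)
       })
}

# FISTA (accelerated proximal gradient) LASSO oracle: independent of the
# coordinate-descent solver, run to much tighter tolerance.
fista_lasso <- function(X, y, lambda, max_iter = 200000L, tol = 1e-13) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  Xc <- sweep(X, 2L, colMeans(X)); yc <- y - mean(y)
  L <- max(eigen(crossprod(Xc) / n, symmetric = TRUE,
                 only.values = TRUE)$values)
  b <- rep(0, ncol(X)); z <- b; tk <- 1
  for (i in seq_len(max_iter)) {
    g <- crossprod(Xc, Xc %*% z - yc) / n
    bn <- z - g / L
    bn <- sign(bn) * pmax(abs(bn) - lambda / L, 0)
    tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- bn + ((tk - 1) / tk1) * (bn - b)
    if (max(abs(bn - b)) < tol) { b <- bn; break }
    b <- bn; tk <- tk1
  }
  b
}

# random preprocessed spectral blocks sharing sample ids
rand_blocks <- function(n, widths, seed = 1) {
  set.seed(seed)
  ids <- sprintf("s%02d", seq_len(n))
  lapply(seq_along(widths), function(i) {
    p <- widths[i]
    M <- matrix(rnorm(n * p), n, p)
    M <- sweep(M, 2L, colMeans(M))
    spectral_block(paste0("B", i), M, wl_grid(seq(250, 450, length.out = p)),
                   ids)
  })
}

quaternary_noiseless <- function(n_train = 16, n_test = 5, seed = 3) {
  simulate_design("quaternary", n_train, n_test, seed = seed, noise = NULL)
}
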