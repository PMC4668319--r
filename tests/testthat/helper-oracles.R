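# Independent oracles, coded separately from the package internals.

# Textbook NIPALS PLS1 with y-deflation; prediction by sequential deflation
# of the new sample (a different route than the package's regression-vector
# form W (P'W)^{-1} q).
oracle_nipals_fit <- function(X, y, A) {
  X <- as.matrix(X)
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  W <- P <- matrix(0, ncol(X), A); q <- numeric(A)
  for (a in seq_len(A)) {
    w <- drop(crossprod(E, f))
    w <- w / sqrt(sum(w^2))
    tt <- drop(E %*% w)
    q[a] <- sum(tt * f) / sum(tt * tt)
    p <- drop(crossprod(E, tt)) / sum(tt * tt)
    E <- E - outer(tt, p)
    f <- f - q[a] * tt
    W[, a] <- w; P[, a] <- p
  }
  list(W = W, P = P, q = q, xm = xm, ym = ym, A = A)
}

oracle_nipals_predict <- function(m, Xnew) {
  Xnew <- as.matrix(Xnew)
  out <- numeric(nrow(Xnew))
  for (i in seq_len(nrow(Xnew))) {
    e <- Xnew[i, ] - m$xm
    yhat <- m$ym
    for (a in seq_len(m$A)) {
      t_a <- sum(e * m$W[, a])
      yhat <- yhat + t_a * m$q[a]
      e <- e - t_a * m$P[, a]
    }
    out[i] <- yhat
  }
  out
}

# Dual objective of linear eps-SVR in beta form (minimization).
svr_dual_objective <- function(beta, K, y, epsilon) {
  0.5 * drop(beta %*% K %*% beta) - sum(y * beta) + epsilon * sum(abs(beta))
}

# Brute-force solution of the 3-sample eps-SVR dual: grid over (b1, b2)
# with b3 = -b1 - b2, two-stage refinement.
oracle_svr3_bruteforce <- function(K, y, epsilon, cost, n_grid = 161) {
  best <- c(0, 0); half <- cost
  for (stage in 1:4) {
    g1 <- seq(best[1] - half, best[1] + half, length.out = n_grid)
    g2 <- seq(best[2] - half, best[2] + half, length.out = n_grid)
    gg <- expand.grid(b1 = g1, b2 = g2)
    b3 <- -gg$b1 - gg$b2
    ok <- abs(gg$b1) <= cost & abs(gg$b2) <= cost & abs(b3) <= cost
    B <- cbind(gg$b1, gg$b2, b3)[ok, , drop = FALSE]
    quad <- 0.5 * rowSums((B %*% K) * B)
    lin <- -(B %*% y)[, 1]
    l1 <- epsilon * rowSums(abs(B))
    vals <- quad + lin + l1
    ix <- which.min(vals)
    best <- B[ix, 1:2]
    val <- vals[ix]
    half <- half * 6 / n_grid   # shrink window to a few grid steps around best
  }
  list(beta = c(best, -sum(best)), objective = val)
}

# Small synthetic problems on a short grid, for oracle comparisons.
random_spectra_problem <- function(I, J, seed) {
  set.seed(seed)
  X <- matrix(abs(rnorm(I * J, 0.5, 0.2)), I, J)
  y <- rowSums(X[, seq_len(min(3, J)), drop = FALSE]) + rnorm(I, 0, 0.05)
  list(X = spectra_matrix(X, wavelengths = 210 + seq_len(J)), y = y)
}

# Minimal JCAMP-DX writer for reader tests.
write_jcamp_fixture <- function(path, ys, firstx = 210, lastx = NULL,
                                yfactor = 1, xydata = "(X++(Y..Y))",
                                npoints = length(ys)) {
  if (is.null(lastx)) lastx <- firstx + length(ys) - 1
  lines <- c("##TITLE=fixture", "##JCAMP-DX=4.24", "##DATA TYPE=UV/VIS SPECTRUM",
             sprintf("##FIRSTX=%g", firstx), sprintf("##LASTX=%g", lastx),
             sprintf("##NPOINTS=%d", npoints), sprintf("##YFACTOR=%g", yfactor),
             sprintf("##XYDATA=%s", xydata),
             paste(firstx, paste(ys, collapse = " ")),
             "##END=")
  writeLines(lines, path)
}
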