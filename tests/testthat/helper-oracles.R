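# Independent reference implementations used only to check the package.

# Projection residual ||s - B B^+ s||^2 via QR, independent of the package's
# normal-equation solver. B's columns are exp((i2pi psi - r2s) te) and the
# fat-weighted copy.
brute_residual <- function(psi, r2s, s, te, cfat) {
  e <- exp((2i * pi * psi - r2s) * te)
  B <- cbind(e, cfat * e)
  qrB <- qr(B)
  Q <- qr.Q(qrB)
  sum(Mod(s)^2) - sum(Mod(Conj(t(Q)) %*% s)^2)
}

# Exhaustive grid search over psi x r2s; returns the minimum residual.
# Shares the QR projector across voxels of the signal matrix S (nE x N).
brute_grid_min <- function(S, te, cfat, psi_grid, r2s_grid) {
  ss <- colSums(Mod(S)^2)
  best <- rep(Inf, ncol(S))
  for (r2s in r2s_grid) {
    for (psi in psi_grid) {
      e <- exp((2i * pi * psi - r2s) * te)
      B <- cbind(e, cfat * e)
      Q <- qr.Q(qr(B))
      res <- ss - colSums(Mod(Conj(t(Q)) %*% S)^2)
      best <- pmin(best, res)
    }
  }
  best
}

# Forward signal for a single voxel, written directly from the model.
forward_signal <- function(W, F, psi, r2s, phi0, theta, te, freqs, amps,
                           parity) {
  cfat <- vapply(te, function(t) sum(amps * exp(2i * pi * freqs * t)),
                 complex(1))
  (W + F * cfat) * exp(2i * pi * psi * te) * exp(-r2s * te) *
    exp(1i * phi0) * exp(1i * parity * theta)
}

## -- brute-force statistics -------------------------------------------------

brute_one_sample_t <- function(x, mu0 = 0) {
  n <- length(x)
  m <- sum(x) / n
  s2 <- sum((x - m)^2) / (n - 1)
  tt <- (m - mu0) / sqrt(s2 / n)
  list(t = tt, df = n - 1, p = 2 * pt(-abs(tt), n - 1))
}

brute_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  m1 <- sum(x) / n1; m2 <- sum(y) / n2
  s1 <- sum((x - m1)^2); s2 <- sum((y - m2)^2)
  sp2 <- (s1 + s2) / (n1 + n2 - 2)
  tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, df = n1 + n2 - 2, p = 2 * pt(-abs(tt), n1 + n2 - 2))
}

brute_anova <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  k <- length(groups); N <- length(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = F, df1 = k - 1, df2 = N - k, p = pf(F, k - 1, N - k, lower.tail = FALSE))
}

brute_pearson_r <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Mid-ranks computed by explicit tie averaging (no rank()).
brute_midranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n))
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  r
}

brute_partial_r <- function(x, y, z) {
  rx <- residuals(lm(x ~ z))
  ry <- residuals(lm(y ~ z))
  brute_pearson_r(rx, ry)
}

## -- mask utilities ---------------------------------------------------------

# Is the TRUE set of a 3D logical array one 6-connected component?
is_single_component6 <- function(v) {
  d <- dim(v)
  idx <- which(v)
  if (length(idx) == 0) return(FALSE)
  lab <- array(0L, d)
  queue <- idx[1]
  lab[queue] <- 1L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    z <- (cur - 1) %/% (d[1] * d[2])
    rem <- (cur - 1) %% (d[1] * d[2])
    y <- rem %/% d[1]; x <- rem %% d[1]
    for (k in 1:6) {
      xx <- x + offs[k, 1]; yy <- y + offs[k, 2]; zz <- z + offs[k, 3]
      if (xx < 0 || xx >= d[1] || yy < 0 || yy >= d[2] || zz < 0 || zz >= d[3])
        next
      lin <- xx + yy * d[1] + zz * d[1] * d[2] + 1
      if (v[lin] && lab[lin] == 0L) {
        lab[lin] <- 1L
        queue <- c(queue, lin)
      }
    }
  }
  all(lab[v] == 1L)
}

# Random tube-like mask along axis 3 spanning >= 3 slices.
random_mask <- function(shape = c(12, 12, sample(3:14, 1)),
                        spacing = c(3, 3, 6)) {
  v <- array(FALSE, shape)
  z0 <- 1
  z1 <- shape[3]
  cx <- sample(3:(shape[1] - 2), 1)
  cy <- sample(3:(shape[2] - 2), 1)
  r <- sample(1:3, 1)
  for (z in z0:z1) {
    for (x in seq_len(shape[1])) for (y in seq_len(shape[2]))
      if ((x - cx)^2 + (y - cy)^2 <= r^2) v[x, y, z] <- TRUE
  }
  muscle_mask(v, spacing, axis = 3L,
              proximal_end = sample(c("first", "last"), 1))
}

small_protocol <- function() acquisition_protocol()
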