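## Complex-based water-fat separation.
##
## Per voxel the signal model is linear in the complex amplitudes (W, F) once
## the field map psi and the decay rate R2* are fixed, so the fit uses
## variable projection: for each (psi, R2*) candidate the complex least-squares
## solution for (W, F) is closed-form and the candidate misfit is the
## projection residual. A coarse grid locates the global basin; an iterative
## zoom (or a bounded quasi-Newton polish for single voxels) refines it. A
## shared initial phase phi0 is absorbed into the complex amplitudes.

# Basis e_n(psi, r2s) = exp((i 2 pi psi - r2s) TE_n); columns of the design
# matrix are (e, cfat * e).
wf_basis <- function(psi, r2s, te, cfat) {
  e <- exp((2i * pi * psi - r2s) * te)
  cbind(e, cfat * e)
}

# Projection residual ||s - P s||^2 for one (psi, r2s) over a matrix of
# signals S (n_echoes x n_voxels). Returns the residual vector; if solve=TRUE
# also the complex amplitudes W, F.
wf_candidate_fit <- function(psi, r2s, te, cfat, S, ss, solve = FALSE) {
  e2 <- exp(-2 * r2s * te)
  g11 <- sum(e2)
  g22 <- sum(Mod(cfat)^2 * e2)
  g12 <- sum(cfat * e2)              # <e, c e> = sum c_n exp(-2 r2s te_n)
  e <- exp((2i * pi * psi - r2s) * te)
  b1 <- Conj(e)
  b2 <- Conj(cfat * e)
  h1 <- as.vector(b1 %*% S)
  h2 <- as.vector(b2 %*% S)
  det <- g11 * g22 - Mod(g12)^2
  if (det <= .Machine$double.eps * g11 * g22) {
    # water and fat columns collinear (degenerate spectrum): fit water only
    W <- h1 / g11
    res <- pmax(0, ss - Mod(h1)^2 / g11)
    return(if (solve) list(res = res, W = W, F = rep(0i, length(W))) else res)
  }
  q <- (g22 * Mod(h1)^2 + g11 * Mod(h2)^2 -
          2 * Re(g12 * Conj(h1) * h2)) / det
  res <- pmax(0, ss - q)
  if (!solve) return(res)
  W <- (g22 * h1 - g12 * h2) / det
  F <- (g11 * h2 - Conj(g12) * h1) / det
  list(res = res, W = W, F = F)
}

# Coarse grid search over psi x r2s candidates for all voxels at once.
# Returns per-voxel best residual and best (psi, r2s).
wf_grid_search <- function(S, te, cfat, psi_grid, r2s_grid) {
  n <- ncol(S)
  ss <- colSums(Mod(S)^2)
  best_res <- rep(Inf, n)
  best_psi <- numeric(n)
  best_r2s <- numeric(n)
  for (r2s in r2s_grid) {
    for (psi in psi_grid) {
      res <- wf_candidate_fit(psi, r2s, te, cfat, S, ss)
      upd <- res < best_res
      if (any(upd)) {
        best_res[upd] <- res[upd]
        best_psi[upd] <- psi
        best_r2s[upd] <- r2s
      }
    }
  }
  list(res = best_res, psi = best_psi, r2s = best_r2s, ss = ss)
}

# Iterative zoom refinement: voxels sharing a centre are refined together on
# a 9 x 9 offset grid whose spacing shrinks by 4x per level.
wf_zoom_refine <- function(S, te, cfat, psi0, r2s0, psi_step, r2s_step,
                           n_levels = 3L, r2s_bounds = c(0, Inf)) {
  n <- ncol(S)
  ss <- colSums(Mod(S)^2)
  offs <- seq(-1, 1, by = 0.25)
  psi <- psi0
  r2s <- r2s0
  best <- rep(Inf, n)
  for (lev in seq_len(n_levels)) {
    key <- paste(psi, r2s)
    groups <- split(seq_len(n), key)
    for (idx in groups) {
      p0 <- psi[idx[1]]; r0 <- r2s[idx[1]]
      pg <- p0 + offs * psi_step
      rg <- pmin(pmax(r0 + offs * r2s_step, r2s_bounds[1]), r2s_bounds[2])
      rg <- unique(rg)
      Sg <- S[, idx, drop = FALSE]
      ssg <- ss[idx]
      bres <- rep(Inf, length(idx))
      bp <- rep(p0, length(idx)); br <- rep(r0, length(idx))
      for (r in rg) for (p in pg) {
        res <- wf_candidate_fit(p, r, te, cfat, Sg, ssg)
        upd <- res < bres
        if (any(upd)) { bres[upd] <- res[upd]; bp[upd] <- p; br[upd] <- r }
      }
      psi[idx] <- bp; r2s[idx] <- br; best[idx] <- bres
    }
    psi_step <- psi_step / 4
    r2s_step <- r2s_step / 4
  }
  list(psi = psi, r2s = r2s, res = best)
}

# Final amplitude solve at per-voxel (psi, r2s); grouped by unique parameters.
wf_solve_amplitudes <- function(S, te, cfat, psi, r2s) {
  n <- ncol(S)
  ss <- colSums(Mod(S)^2)
  W <- complex(n); F <- complex(n); res <- numeric(n)
  key <- paste(psi, r2s)
  groups <- split(seq_len(n), key)
  for (idx in groups) {
    fit <- wf_candidate_fit(psi[idx[1]], r2s[idx[1]], te, cfat,
                            S[, idx, drop = FALSE], ss[idx], solve = TRUE)
    W[idx] <- fit$W; F[idx] <- fit$F; res[idx] <- fit$res
  }
  list(W = W, F = F, res = res)
}

#' Fit the water-fat model to a single voxel
#'
#' Variable-projection least squares: the complex water and fat amplitudes are
#' solved linearly for each candidate field-map/R2* pair on a search grid, and
#' the best candidate is polished with a bounded quasi-Newton step. The
#' returned misfit is never worse than the best grid candidate.
#'
#' @param signal Complex vector, one value per echo.
#' @param protocol An [acquisition_protocol()] with at least 4 echoes (6
#'   echoes give a comfortably overdetermined fit for the 6 real unknowns:
#'   Re/Im of W and F, psi, and R2*).
#' @param spectrum A [fat_spectrum()].
#' @param psi_search Field-map search range in Hz, `c(lo, hi)`.
#' @param r2s_search R2* search range in 1/s, `c(lo, hi)` with `lo >= 0`.
#' @param psi_step,r2s_step Grid spacing for the coarse search.
#' @return A list of class `voxel_fit` with elements `water` and `fat`
#'   (complex amplitudes), `fieldmap` (Hz), `r2star` (1/s), `residual` (sum of
#'   squared residuals), `pdff` (%) and `converged`.
#' @examples
#' p <- acquisition_protocol()
#' sp <- default_fat_spectrum()
#' te <- echo_times(p)
#' cf <- musclepdff:::fat_coefficients(sp, p)
#' s <- (0.8 + 0.2 * cf) * exp((2i * pi * 40 - 30) * te)
#' fit_voxel(s, p, sp)
#' @export
fit_voxel <- function(signal, protocol, spectrum = default_fat_spectrum(),
                      psi_search = c(-200, 200), r2s_search = c(0, 300),
                      psi_step = 2, r2s_step = 5) {
  stopifnot(inherits(protocol, "acquisition_protocol"),
            inherits(spectrum, "fat_spectrum"))
  signal <- as.complex(signal)
  if (length(signal) != protocol$n_echoes)
    stop("'signal' length must equal the protocol echo count")
  if (protocol$n_echoes < 4L)
    stop("at least 4 echoes are required to fit W, F, psi and R2*")
  if (anyNA(signal) || any(!is.finite(Re(signal))) || any(!is.finite(Im(signal))))
    stop("'signal' must be finite and non-missing")
  if (length(psi_search) != 2L || diff(psi_search) <= 0)
    stop("'psi_search' must be an increasing range (Hz)")
  if (length(r2s_search) != 2L || diff(r2s_search) <= 0 || r2s_search[1] < 0)
    stop("'r2s_search' must be an increasing nonnegative range (1/s)")

  if (all(signal == 0)) {
    return(structure(
      list(water = 0i, fat = 0i, fieldmap = 0, r2star = 0, residual = 0,
           pdff = 0, converged = FALSE),
      class = "voxel_fit"))
  }

  te <- echo_times(protocol)
  cfat <- fat_coefficients(spectrum, protocol)
  S <- matrix(signal, ncol = 1)
  ss <- sum(Mod(signal)^2)

  psi_grid <- seq(psi_search[1], psi_search[2], by = psi_step)
  r2s_grid <- seq(r2s_search[1], r2s_search[2], by = r2s_step)
  g <- wf_grid_search(S, te, cfat, psi_grid, r2s_grid)

  obj <- function(par) wf_candidate_fit(par[1], par[2], te, cfat, S, ss)
  opt <- tryCatch(
    stats::optim(c(g$psi, g$r2s), obj, method = "L-BFGS-B",
                 lower = c(psi_search[1], r2s_search[1]),
                 upper = c(psi_search[2], r2s_search[2]),
                 control = list(factr = 10)),
    error = function(e) NULL)
  if (!is.null(opt) && opt$value <= g$res) {
    psi_hat <- opt$par[1]; r2s_hat <- opt$par[2]; res_hat <- opt$value
    converged <- is.null(opt$convergence) || opt$convergence == 0
  } else {
    psi_hat <- g$psi; r2s_hat <- g$r2s; res_hat <- g$res
    converged <- TRUE
  }

  amp <- wf_candidate_fit(psi_hat, r2s_hat, te, cfat, S, ss, solve = TRUE)
  W <- amp$W[1]; F <- amp$F[1]
  denom <- Mod(W) + Mod(F)
  structure(
    list(water = W, fat = F, fieldmap = psi_hat, r2star = r2s_hat,
         residual = min(res_hat, amp$res[1]),
         pdff = if (denom > 0) 100 * Mod(F) / denom else 0,
         converged = converged),
    class = "voxel_fit")
}

#' @export
print.voxel_fit <- function(x, ...) {
  cat(sprintf(
    "<voxel_fit> PDFF %.2f%%, psi %.2f Hz, R2* %.2f 1/s, residual %.3g\n",
    x$pdff, x$fieldmap, x$r2star, x$residual))
  invisible(x)
}

# 3D median filter over fitted voxels (26-neighbourhood box), NA outside.
median_filter3 <- function(vol, fitted) {
  d <- dim(vol)
  vals <- vol
  vals[!fitted] <- NA_real_
  idx <- which(fitted, arr.ind = TRUE)
  stack <- matrix(NA_real_, nrow(idx), 27)
  k <- 0
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    k <- k + 1
    xi <- idx[, 1] + dx; yi <- idx[, 2] + dy; zi <- idx[, 3] + dz
    ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
    lin <- rep(NA_integer_, nrow(idx))
    lin[ok] <- xi[ok] + (yi[ok] - 1) * d[1] + (zi[ok] - 1) * d[1] * d[2]
    stack[ok, k] <- vals[lin[ok]]
  }
  med <- apply(stack, 1, stats::median, na.rm = TRUE)
  out <- vol
  out[fitted] <- med
  out
}

#' Quantitative maps from water-fat separation
#'
#' @param pdff PDFF volume in %.
#' @param t2star T2* volume in ms (`NA` where invalid).
#' @param t2star_valid Logical volume: `TRUE` where R2* was strictly inside
#'   the search range (so T2* = 1000/R2* is trustworthy).
#' @param fieldmap Field-map volume, Hz.
#' @param r2star R2* volume, 1/s.
#' @param residual Fit misfit volume.
#' @param voxel_spacing Numeric length-3, mm.
#' @return An object of class `quant_maps`.
#' @export
quant_maps <- function(pdff, t2star, t2star_valid, fieldmap, r2star, residual,
                       voxel_spacing) {
  structure(
    list(pdff = pdff, t2star = t2star, t2star_valid = t2star_valid,
         fieldmap = fieldmap, r2star = r2star, residual = residual,
         voxel_spacing = as.numeric(voxel_spacing)),
    class = "quant_maps")
}

#' Separate water and fat over a whole volume
#'
#' Runs the variable-projection fit at every voxel with nonzero signal:
#' a coarse field-map x R2* grid, an iterative zoom refinement, then a
#' spatial field-map consistency pass (3D median filter; voxels whose field
#' estimate deviates from the filtered value by more than `swap_tol` Hz are
#' re-fit around the filtered value) to suppress water-fat swaps. PDFF is the
#' magnitude ratio `100 |F| / (|W| + |F|)` (0 where both are 0); T2* is
#' `1000 / R2*` ms and is flagged invalid where R2* ended on a search bound.
#'
#' @param series An [echo_series()].
#' @param spectrum A [fat_spectrum()].
#' @param psi_range,psi_step Field-map search range (Hz) and coarse step.
#' @param r2s_range,r2s_step R2* search range (1/s) and coarse step.
#' @param eddy `"off"` (default), `"estimate"` (calls
#'   [estimate_eddy_phase()]), or a numeric theta (radians) to correct with.
#' @param swap_filter Logical; run the field-map consistency pass.
#' @param swap_tol Deviation from the median-filtered field map (Hz) that
#'   triggers a re-fit.
#' @param mask Optional logical array: fit only these voxels (plus any voxel
#'   is skipped when its signal is all zero).
#' @return A [quant_maps()] object; the estimated eddy phase (if any) is in
#'   attribute `"eddy_phase"`.
#' @export
separate <- function(series, spectrum = default_fat_spectrum(),
                     psi_range = c(-150, 150), psi_step = 4,
                     r2s_range = c(0, 250), r2s_step = 10,
                     eddy = "off", swap_filter = TRUE, swap_tol = 30,
                     mask = NULL) {
  stopifnot(inherits(series, "echo_series"))
  protocol <- series$protocol
  d <- dim(series$signal)[1:3]
  te <- echo_times(protocol)
  cfat <- fat_coefficients(spectrum, protocol)
  nE <- protocol$n_echoes

  sig <- series$signal
  theta <- 0
  if (identical(eddy, "estimate")) {
    theta <- estimate_eddy_phase(series, spectrum,
                                 psi_range = psi_range, r2s_range = r2s_range)
  } else if (is.numeric(eddy)) {
    theta <- eddy
  } else if (!identical(eddy, "off")) {
    stop("'eddy' must be \"off\", \"estimate\" or a numeric phase")
  }
  if (theta != 0) {
    parity <- echo_parity(protocol)
    for (n in seq_len(nE))
      sig[, , , n] <- sig[, , , n] * exp(-1i * parity[n] * theta)
  }

  Smat <- matrix(sig, nrow = prod(d), ncol = nE)
  nonzero <- rowSums(Mod(Smat)) > 0
  if (!is.null(mask)) nonzero <- nonzero & as.logical(mask)
  fit_idx <- which(nonzero)

  pdff <- array(0, d)
  r2star <- array(0, d)
  fieldmap <- array(0, d)
  residual <- array(0, d)
  t2star <- array(NA_real_, d)
  valid <- array(FALSE, d)

  if (length(fit_idx) > 0) {
    S <- t(Smat[fit_idx, , drop = FALSE])  # nE x N
    psi_grid <- seq(psi_range[1], psi_range[2], by = psi_step)
    r2s_grid <- seq(r2s_range[1], r2s_range[2], by = r2s_step)
    g <- wf_grid_search(S, te, cfat, psi_grid, r2s_grid)
    z <- wf_zoom_refine(S, te, cfat, g$psi, g$r2s,
                        psi_step = psi_step, r2s_step = r2s_step,
                        n_levels = 3L, r2s_bounds = r2s_range)
    psi_hat <- z$psi; r2s_hat <- z$r2s

    if (swap_filter) {
      fitted <- array(FALSE, d); fitted[fit_idx] <- TRUE
      pm <- array(0, d); pm[fit_idx] <- psi_hat
      pf <- median_filter3(pm, fitted)
      dev <- abs(psi_hat - pf[fit_idx])
      bad <- which(dev > swap_tol)
      if (length(bad) > 0) {
        Sb <- S[, bad, drop = FALSE]
        zb <- wf_zoom_refine(Sb, te, cfat,
                             psi0 = pf[fit_idx][bad], r2s0 = r2s_hat[bad],
                             psi_step = psi_step, r2s_step = r2s_step,
                             n_levels = 3L, r2s_bounds = r2s_range)
        psi_hat[bad] <- zb$psi
        r2s_hat[bad] <- zb$r2s
      }
    }

    amp <- wf_solve_amplitudes(S, te, cfat, psi_hat, r2s_hat)
    denom <- Mod(amp$W) + Mod(amp$F)
    pd <- ifelse(denom > 0, 100 * Mod(amp$F) / denom, 0)

    pdff[fit_idx] <- pd
    r2star[fit_idx] <- r2s_hat
    fieldmap[fit_idx] <- psi_hat
    residual[fit_idx] <- amp$res
    eps_b <- 1e-9
    on_bound <- r2s_hat <= r2s_range[1] + eps_b | r2s_hat >= r2s_range[2] - eps_b
    ok <- !on_bound & r2s_hat > 0
    valid[fit_idx] <- ok
    t2s <- rep(NA_real_, length(fit_idx))
    t2s[r2s_hat > 0] <- 1000 / r2s_hat[r2s_hat > 0]
    t2star[fit_idx] <- t2s
  }

  out <- quant_maps(pdff, t2star, valid, fieldmap, r2star, residual,
                    protocol$voxel_spacing)
  attr(out, "eddy_phase") <- theta
  out
}

#' Estimate the bipolar eddy-current phase
#'
#' Finds the global alternating-echo phase theta that minimises the pooled
#' water-fat fit residual over a subsample of high-signal voxels: the signal
#' is corrected by `exp(-i (-1)^n theta)` and refit for each candidate theta,
#' a coarse scan bracketing the optimum before a golden-section polish.
#'
#' @param series An [echo_series()] acquired with a bipolar protocol.
#' @param spectrum A [fat_spectrum()].
#' @param psi_range,r2s_range Search ranges passed to the inner fits.
#' @param theta_range Search interval for theta, radians.
#' @param n_sample Number of voxels used for the pooled residual.
#' @return Estimated theta (radians), following the simulation convention
#'   that echo n carries phase `(-1)^n * theta`. For a monopolar protocol
#'   returns 0 with a message and attribute `notice`.
#' @export
estimate_eddy_phase <- function(series, spectrum = default_fat_spectrum(),
                                psi_range = c(-150, 150),
                                r2s_range = c(0, 250),
                                theta_range = c(-0.75, 0.75),
                                n_sample = 120L) {
  stopifnot(inherits(series, "echo_series"))
  protocol <- series$protocol
  if (!protocol$bipolar) {
    message("monopolar protocol: no alternating eddy-current phase to estimate")
    return(structure(0, notice = "monopolar protocol"))
  }
  te <- echo_times(protocol)
  cfat <- fat_coefficients(spectrum, protocol)
  parity <- echo_parity(protocol)
  nE <- protocol$n_echoes
  d <- dim(series$signal)[1:3]

  Smat <- matrix(series$signal, nrow = prod(d), ncol = nE)
  mag <- rowSums(Mod(Smat))
  cand <- which(mag > 0)
  if (length(cand) == 0) stop("no nonzero voxels to estimate from")
  # deterministic subsample: strongest voxels, thinned evenly
  ord <- cand[order(mag[cand], decreasing = TRUE)]
  keep <- ord[unique(round(seq(1, length(ord) / 2 + 0.5,
                               length.out = min(n_sample, length(ord)))))]
  S0 <- t(Smat[keep, , drop = FALSE])

  psi_grid <- seq(psi_range[1], psi_range[2], by = 8)
  r2s_grid <- seq(r2s_range[1], r2s_range[2], by = 20)

  pooled <- function(theta) {
    Sc <- S0 * exp(-1i * parity * theta)
    g <- wf_grid_search(Sc, te, cfat, psi_grid, r2s_grid)
    z <- wf_zoom_refine(Sc, te, cfat, g$psi, g$r2s,
                        psi_step = 8, r2s_step = 20, n_levels = 3L,
                        r2s_bounds = r2s_range)
    sum(z$res)
  }

  scan <- seq(theta_range[1], theta_range[2], by = 0.05)
  vals <- vapply(scan, pooled, numeric(1))
  i0 <- which.min(vals)
  lo <- scan[max(1, i0 - 1)]
  hi <- scan[min(length(scan), i0 + 1)]
  opt <- stats::optimize(pooled, c(lo, hi), tol = 1e-5)
  if (opt$objective <= vals[i0]) opt$minimum else scan[i0]
}
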