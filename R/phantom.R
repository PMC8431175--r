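## Digital muscle phantoms and forward signal simulation.
##
## The phantom holds per-voxel ground truth for the chemical-shift signal
## model: water and fat magnitudes W, F (arbitrary units), an off-resonance
## field map psi (Hz), an effective decay rate R2* (1/s), an initial phase
## phi0 (rad) and a global bipolar eddy-current phase theta (rad) applied with
## alternating sign across echoes.

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Ground-truth phantom maps
#'
#' Container for the per-voxel truth underlying a simulated acquisition.
#' Created by [generate_phantom()]; not usually constructed by hand.
#'
#' @param water_mag,fat_mag Nonnegative 3D arrays of water/fat magnitude.
#' @param fieldmap 3D array, off-resonance psi in Hz.
#' @param r2star 3D array, R2* in 1/s (>= 0).
#' @param init_phase 3D array, initial phase phi0 in radians.
#' @param eddy_phase Scalar theta in radians (alternating-sign bipolar phase).
#' @param masks Named list of [muscle_mask()] objects.
#' @param voxel_spacing Numeric length-3, mm.
#' @return An object of class `ground_truth` with a `pdff` element
#'   (true PDFF in %, `NA` where `W + F = 0`).
#' @export
ground_truth <- function(water_mag, fat_mag, fieldmap, r2star, init_phase,
                         eddy_phase, masks, voxel_spacing) {
  d <- dim(water_mag)
  if (length(d) != 3L) stop("maps must be 3D arrays")
  for (m in list(fat_mag, fieldmap, r2star, init_phase))
    if (!identical(dim(m), d)) stop("all ground-truth maps must share one shape")
  if (any(water_mag < 0) || any(fat_mag < 0)) stop("W and F must be >= 0")
  if (any(r2star < 0)) stop("R2* must be >= 0")
  tot <- water_mag + fat_mag
  pdff <- array(NA_real_, d)
  pdff[tot > 0] <- 100 * fat_mag[tot > 0] / tot[tot > 0]
  structure(
    list(water_mag = water_mag, fat_mag = fat_mag, fieldmap = fieldmap,
         r2star = r2star, init_phase = init_phase,
         eddy_phase = as.numeric(eddy_phase), masks = masks,
         voxel_spacing = as.numeric(voxel_spacing), pdff = pdff),
    class = "ground_truth"
  )
}

# Partition an inclusive slice span into proximal/middle/distal thirds.
# Remainder rule: r = 1 -> extra slice to middle; r = 2 -> extra to proximal
# and distal ("symmetric"); alternatives give the extras to proximal or
# distal ends.
third_lengths <- function(span, rule = c("symmetric", "proximal", "distal")) {
  rule <- match.arg(rule)
  q <- span %/% 3L
  r <- span %% 3L
  len <- c(q, q, q)
  if (r == 1L) {
    len <- switch(rule,
                  symmetric = c(q, q + 1L, q),
                  proximal = c(q + 1L, q, q),
                  distal = c(q, q, q + 1L))
  } else if (r == 2L) {
    len <- switch(rule,
                  symmetric = c(q + 1L, q, q + 1L),
                  proximal = c(q + 1L, q + 1L, q),
                  distal = c(q, q + 1L, q + 1L))
  }
  len
}

# Slice-index intervals (relative to the occupied span) for the three
# sections, ordered proximal, middle, distal in *array index* terms when
# proximal_end == "first"; the caller flips when proximal_end == "last".
span_thirds <- function(first, last, rule = "symmetric") {
  span <- last - first + 1L
  len <- third_lengths(span, rule)
  b1 <- first + len[1] - 1L
  b2 <- b1 + len[2]
  list(c(first, b1), c(b1 + 1L, b2), c(b2 + 1L, last))
}

# Smooth zero-mean in-mask PDFF texture so section means stay commanded while
# voxel values vary; amplitude in percentage points.
pdff_texture <- function(shape, amplitude) {
  x <- (seq_len(shape[1]) - 0.5) / shape[1]
  y <- (seq_len(shape[2]) - 0.5) / shape[2]
  z <- (seq_len(shape[3]) - 0.5) / shape[3]
  gx <- array(rep(sin(2 * pi * x * 1.3), times = shape[2] * shape[3]), shape)
  gy <- array(rep(rep(cos(2 * pi * y * 1.7), each = shape[1]), times = shape[3]), shape)
  gz <- array(rep(sin(2 * pi * z * 2.1 + 0.4), each = shape[1] * shape[2]), shape)
  amplitude * (gx + gy + gz) / 3
}

#' Generate a two-muscle digital phantom
#'
#' Builds a psoas-like muscle (one roughly cylindrical strand) and an erector
#' spinae-like muscle (two adjacent strands joined by an intermuscular fat
#' streak) running along the slice axis, with a depth-varying fat fraction:
#' each muscle's occupied slice span is divided lengthwise into
#' proximal/middle/distal thirds and the mask-mean PDFF of each third is set
#' to the commanded profile value exactly, with smooth within-section
#' variation on top. The off-resonance field map is a smooth low-order
#' polynomial, R2* is physiological for muscle at 3 T, and the initial phase
#' varies smoothly.
#'
#' @param shape Integer length-3 grid dimensions; at least `c(16, 16, 9)`.
#' @param protocol An [acquisition_protocol()] (supplies voxel spacing).
#' @param pdff_profile Target mean PDFF (%) per lengthwise third, proximal to
#'   distal. Either a numeric length-3 vector applied to both muscles, or a
#'   named list with elements `psoas` and `erector`.
#' @param seed Integer seed; output is bit-identical for a fixed seed.
#' @param fieldmap_amplitude Approximate peak |psi| of the smooth field map, Hz.
#' @param eddy_phase Global bipolar eddy-current phase theta (radians).
#' @return A [ground_truth()] object with `masks$psoas` and `masks$erector`.
#' @examples
#' p <- acquisition_protocol()
#' gt <- generate_phantom(c(16, 16, 9), p, c(14.1, 15.2, 22.5), seed = 1)
#' @export
generate_phantom <- function(shape, protocol,
                             pdff_profile = c(10, 10, 10),
                             seed = 1L,
                             fieldmap_amplitude = 60,
                             eddy_phase = 0) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) ||
      shape[1] < 16L || shape[2] < 16L || shape[3] < 9L)
    stop("'shape' must be at least c(16, 16, 9)")
  stopifnot(inherits(protocol, "acquisition_protocol"))
  if (is.numeric(pdff_profile)) {
    if (length(pdff_profile) != 3L)
      stop("'pdff_profile' must have one value per third (proximal, middle, distal)")
    pdff_profile <- list(psoas = pdff_profile, erector = pdff_profile)
  }
  if (!all(c("psoas", "erector") %in% names(pdff_profile)))
    stop("'pdff_profile' list must have elements 'psoas' and 'erector'")
  for (pr in pdff_profile) {
    if (length(pr) != 3L || any(!is.finite(pr)) || any(pr < 0) || any(pr > 100))
      stop("'pdff_profile' values must lie in [0, 100]")
  }

  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  spacing <- protocol$voxel_spacing

  # masks: strands along z (axis 3), slice 1 = proximal (superior origin)
  xs <- matrix(rep(seq_len(nx), ny), nx, ny)
  ys <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  disk <- function(cx, cy, r) (xs - cx)^2 + (ys - cy)^2 <= r^2

  r_psoas <- max(2, round(min(nx, ny) / 8))
  psoas2d <- disk(nx * 0.30, ny * 0.50, r_psoas)

  r_er <- max(2, round(min(nx, ny) / 9))
  cy1 <- ny * 0.35; cy2 <- ny * 0.65; cx_er <- nx * 0.72
  er_a <- disk(cx_er, cy1, r_er)
  er_b <- disk(cx_er, cy2, r_er)
  # inter-strand bridge: one-voxel-wide band joining the strand centres
  bridge <- abs(xs - cx_er) <= 1 & ys >= cy1 & ys <= cy2
  er2d <- er_a | er_b | bridge
  streak2d <- bridge & !(er_a | er_b)  # intermuscular fat streak voxels

  rep_slices <- function(m2d) array(rep(m2d, nz), c(nx, ny, nz))
  psoas_vox <- rep_slices(psoas2d)
  er_vox <- rep_slices(er2d)
  streak <- rep_slices(streak2d)

  masks <- list(
    psoas = muscle_mask(psoas_vox, spacing, axis = 3L, proximal_end = "first",
                        label = "psoas"),
    erector = muscle_mask(er_vox, spacing, axis = 3L, proximal_end = "first",
                          label = "erector")
  )

  with_seed(seed, {
    # smooth field map: low-order polynomial in normalised coordinates
    u <- (array(rep(xs, nz), shape) / nx) - 0.5
    v <- (array(rep(ys, nz), shape) / ny) - 0.5
    w <- (array(rep(seq_len(nz), each = nx * ny), shape) / nz) - 0.5
    coef <- stats::runif(6, -1, 1)
    psi_raw <- coef[1] + coef[2] * u + coef[3] * v + coef[4] * w +
      coef[5] * u * v + coef[6] * (u^2 - v^2)
    fieldmap <- fieldmap_amplitude * psi_raw / max(abs(psi_raw))

    init_phase <- 0.5 * (coef[2] * v - coef[3] * u + coef[6] * w)

    pdff <- array(0, shape)
    for (mname in c("psoas", "erector")) {
      mvox <- masks[[mname]]$voxels
      profile <- pdff_profile[[mname]]
      thirds <- span_thirds(1L, nz)
      tex <- pdff_texture(shape, amplitude = 0.4)
      for (k in 1:3) {
        zr <- thirds[[k]]
        sel <- mvox
        sel[, , -(zr[1]:zr[2])] <- FALSE
        if (profile[k] == 0) { pdff[sel] <- 0; next }
        amp_scale <- min(1, profile[k] / 2)
        vals <- profile[k] + amp_scale * tex[sel]
        # streak voxels carry concentrated intermuscular fat
        if (mname == "erector") {
          st <- streak[sel]
          vals[st] <- vals[st] + 25
        }
        # recentre so the commanded section mean holds exactly
        vals <- vals - mean(vals) + profile[k]
        pdff[sel] <- pmin(100, pmax(0, vals))
      }
    }

    in_any <- masks$psoas$voxels | masks$erector$voxels
    total_mag <- array(0, shape)
    total_mag[in_any] <- 1 + 0.05 * tanh(u[in_any] + v[in_any])
    fat_mag <- total_mag * pdff / 100
    water_mag <- total_mag - fat_mag

    r2star <- array(0, shape)
    r2star[in_any] <- 30 + 8 * (pdff[in_any] / 20) + 3 * w[in_any]

    ground_truth(water_mag, fat_mag, fieldmap, r2star, init_phase,
                 eddy_phase, masks, spacing)
  })
}

#' Multi-echo complex signal series
#'
#' @param signal Complex 4D array `(x, y, z, echo)`.
#' @param protocol An [acquisition_protocol()]; `protocol$n_echoes` must match
#'   the fourth array dimension.
#' @return An object of class `echo_series`.
#' @export
echo_series <- function(signal, protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  d <- dim(signal)
  if (length(d) != 4L || d[4] != protocol$n_echoes)
    stop("'signal' must be a 4D array with one volume per protocol echo")
  if (any(!is.finite(Re(signal))) || any(!is.finite(Im(signal))))
    stop("'signal' must be finite")
  structure(list(signal = signal, protocol = protocol), class = "echo_series")
}

#' Forward-simulate a multi-echo acquisition
#'
#' Evaluates the chemical-shift signal model per voxel and echo:
#' `s_n = (W + F * sum_p a_p exp(i 2 pi f_p TE_n)) * exp(i 2 pi psi TE_n) *
#' exp(-R2* TE_n) * exp(i phi0) * exp(i (-1)^n theta)`,
#' with the alternating eddy-current term present only for bipolar protocols.
#' Optionally adds circular complex Gaussian noise whose complex standard
#' deviation (sqrt of E|n|^2) equals the mean in-mask first-echo magnitude
#' divided by `snr`.
#'
#' @param truth A [ground_truth()] phantom.
#' @param protocol An [acquisition_protocol()].
#' @param spectrum A [fat_spectrum()].
#' @param snr Positive scalar signal-to-noise ratio, or `NULL` for a noiseless
#'   simulation.
#' @param seed Integer seed used for the noise draw.
#' @return An [echo_series()].
#' @export
simulate_signal <- function(truth, protocol, spectrum = default_fat_spectrum(),
                            snr = NULL, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(protocol, "acquisition_protocol"),
            inherits(spectrum, "fat_spectrum"))
  d <- dim(truth$water_mag)
  te <- echo_times(protocol)
  if (any(diff(te) <= 0)) stop("echo times must be increasing")
  cfat <- fat_coefficients(spectrum, protocol)
  parity <- echo_parity(protocol)

  base <- truth$water_mag * exp(1i * truth$init_phase)
  fatc <- truth$fat_mag * exp(1i * truth$init_phase)

  sig <- array(0i, c(d, protocol$n_echoes))
  for (n in seq_len(protocol$n_echoes)) {
    sn <- (base + fatc * cfat[n]) *
      exp((2i * pi * truth$fieldmap - truth$r2star) * te[n]) *
      exp(1i * parity[n] * truth$eddy_phase)
    sig[, , , n] <- sn
  }

  if (!is.null(snr)) {
    if (!is.numeric(snr) || snr <= 0) stop("'snr' must be positive or NULL")
    in_mask <- Reduce(`|`, lapply(truth$masks, function(m) m$voxels))
    s1 <- abs(sig[, , , 1, drop = FALSE])
    sigma <- mean(s1[in_mask]) / snr
    sig <- sig + with_seed(seed, {
      n_tot <- length(sig)
      (stats::rnorm(n_tot, sd = sigma / sqrt(2)) +
         1i * stats::rnorm(n_tot, sd = sigma / sqrt(2)))
    })
  }

  echo_series(sig, protocol)
}
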