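#' Acquisition protocol for a multi-echo gradient-echo sequence
#'
#' Describes the chemical-shift-encoded acquisition: number of echoes, first
#' echo time, echo spacing, field strength, voxel size and readout polarity.
#' Echo times are `TE_n = te1 + (n - 1) * delta_te`.
#'
#' @param n_echoes Number of echoes (>= 3).
#' @param te1 First echo time in seconds.
#' @param delta_te Echo spacing in seconds.
#' @param field_strength Main field strength in tesla.
#' @param voxel_spacing Numeric length-3 voxel size in millimetres (dx, dy, dz).
#' @param bipolar Logical; `TRUE` for a bipolar (alternating readout polarity)
#'   acquisition, in which eddy currents add a phase of alternating sign on
#'   even/odd echoes.
#'
#' @return An object of class `acquisition_protocol`.
#' @examples
#' p <- acquisition_protocol()
#' echo_times(p) * 1000  # ms
#' @export
acquisition_protocol <- function(n_echoes = 6L,
                                 te1 = 1.14e-3,
                                 delta_te = 0.8e-3,
                                 field_strength = 3,
                                 voxel_spacing = c(3, 3, 6),
                                 bipolar = TRUE) {
  n_echoes <- as.integer(n_echoes)
  if (is.na(n_echoes) || n_echoes < 3L)
    stop("'n_echoes' must be an integer >= 3")
  if (!is.numeric(te1) || te1 <= 0) stop("'te1' must be > 0 (seconds)")
  if (!is.numeric(delta_te) || delta_te <= 0) stop("'delta_te' must be > 0 (seconds)")
  if (!is.numeric(field_strength) || field_strength <= 0)
    stop("'field_strength' must be > 0 (tesla)")
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) != 3L || any(!is.finite(voxel_spacing)) ||
      any(voxel_spacing <= 0))
    stop("'voxel_spacing' must be three positive values (mm)")
  structure(
    list(n_echoes = n_echoes, te1 = te1, delta_te = delta_te,
         field_strength = field_strength, voxel_spacing = voxel_spacing,
         bipolar = isTRUE(bipolar)),
    class = "acquisition_protocol"
  )
}

#' Echo times of a protocol
#'
#' @param protocol An [acquisition_protocol()].
#' @return Numeric vector of echo times in seconds.
#' @export
echo_times <- function(protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  protocol$te1 + (seq_len(protocol$n_echoes) - 1) * protocol$delta_te
}

#' Per-echo eddy-current phase signs
#'
#' For a bipolar readout, echo `n` (1-based) carries an eddy-current phase
#' `(-1)^n * theta`; odd echoes get `-theta`, even echoes `+theta`. For a
#' monopolar protocol all signs are zero.
#'
#' @param protocol An [acquisition_protocol()].
#' @return Integer vector of +1/-1 signs (or zeros when monopolar).
#' @export
echo_parity <- function(protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  if (!protocol$bipolar) return(rep(0L, protocol$n_echoes))
  as.integer((-1)^seq_len(protocol$n_echoes))
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat(sprintf(
    "<acquisition_protocol> %d echoes, TE1 = %.3f ms, dTE = %.3f ms, %.1f T, %s readout\n",
    x$n_echoes, x$te1 * 1e3, x$delta_te * 1e3, x$field_strength,
    if (x$bipolar) "bipolar" else "monopolar"))
  cat(sprintf("  voxel spacing: %g x %g x %g mm\n",
              x$voxel_spacing[1], x$voxel_spacing[2], x$voxel_spacing[3]))
  invisible(x)
}

# Gyromagnetic ratio of 1H, MHz/T (so ppm * GAMMA_MHZ_PER_T * B0 gives Hz).
GAMMA_MHZ_PER_T <- 42.577

#' Multi-peak fat spectrum
#'
#' Chemical shifts of the fat resonances relative to water (ppm, signed;
#' methylene is downfield of water so its shift is negative) with relative
#' amplitudes normalised to sum to one.
#'
#' @param shifts_ppm Numeric chemical shifts relative to water (ppm).
#' @param amplitudes Nonnegative relative amplitudes; normalised internally.
#' @return An object of class `fat_spectrum`.
#' @seealso [default_fat_spectrum()]
#' @export
fat_spectrum <- function(shifts_ppm, amplitudes) {
  shifts_ppm <- as.numeric(shifts_ppm)
  amplitudes <- as.numeric(amplitudes)
  if (length(shifts_ppm) != length(amplitudes) || length(shifts_ppm) == 0)
    stop("'shifts_ppm' and 'amplitudes' must be nonempty and of equal length")
  if (any(!is.finite(shifts_ppm)) || any(!is.finite(amplitudes)))
    stop("fat spectrum values must be finite")
  if (any(amplitudes < 0)) stop("'amplitudes' must be >= 0")
  s <- sum(amplitudes)
  if (s <= 0) stop("'amplitudes' must not all be zero")
  structure(
    list(shifts_ppm = shifts_ppm, amplitudes = amplitudes / s),
    class = "fat_spectrum"
  )
}

#' Default six-peak fat spectrum
#'
#' The widely used six-peak triglyceride model for PDFF quantification at 3 T:
#' olefinic +0.60 ppm, water-adjacent -0.39 ppm (relative to water at 4.7 ppm),
#' alpha-carboxyl -1.94 ppm, alpha-olefinic -2.60 ppm, methylene -3.40 ppm
#' (dominant), methyl -3.80 ppm, with relative amplitudes
#' 0.048/0.039/0.004/0.128/0.693/0.087.
#'
#' @return A [fat_spectrum()] with six peaks; amplitudes sum to 1.
#' @examples
#' sp <- default_fat_spectrum()
#' sum(sp$amplitudes)
#' @export
default_fat_spectrum <- function() {
  fat_spectrum(
    shifts_ppm = c(0.60, -0.39, -1.94, -2.60, -3.40, -3.80),
    amplitudes = c(0.048, 0.039, 0.004, 0.128, 0.693, 0.087)
  )
}

#' Fat peak frequencies in Hz
#'
#' Converts the spectrum's ppm shifts into frequency offsets at the protocol's
#' field strength: `f_p = shift_ppm * 42.577 MHz/T * B0`.
#'
#' @param spectrum A [fat_spectrum()].
#' @param field_strength Field strength in tesla.
#' @return Numeric vector of frequencies (Hz), one per peak.
#' @export
fat_peak_frequencies <- function(spectrum, field_strength) {
  stopifnot(inherits(spectrum, "fat_spectrum"))
  spectrum$shifts_ppm * GAMMA_MHZ_PER_T * field_strength
}

# Complex fat dephasing coefficients c_n = sum_p a_p exp(i 2 pi f_p TE_n),
# one per echo. The water coefficient is identically 1.
fat_coefficients <- function(spectrum, protocol) {
  te <- echo_times(protocol)
  f <- fat_peak_frequencies(spectrum, protocol$field_strength)
  a <- spectrum$amplitudes
  vapply(te, function(t) sum(a * exp(2i * pi * f * t)), complex(1))
}
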