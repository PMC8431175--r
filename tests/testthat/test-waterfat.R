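protocol <- acquisition_protocol()
spectrum <- default_fat_spectrum()
te <- echo_times(protocol)
freqs <- fat_peak_frequencies(spectrum, 3)
parity <- echo_parity(protocol)

voxel_signal <- function(W, F, psi, r2s, phi0 = 0, theta = 0)
  forward_signal(W, F, psi, r2s, phi0, theta, te, freqs,
                 spectrum$amplitudes, parity)

test_that("fit_voxel recovers noiseless parameters", {
  s <- voxel_signal(0.8, 0.2, 40, 30)
  f <- fit_voxel(s, protocol, spectrum)
  expect_equal(Mod(f$water), 0.8, tolerance = 1e-3)
  expect_equal(Mod(f$fat), 0.2, tolerance = 1e-3)
  expect_equal(f$fieldmap, 40, tolerance = 40 * 1e-3)
  expect_equal(f$r2star, 30, tolerance = 30 * 1e-3)
  expect_equal(f$pdff, 20, tolerance = 1e-3)
})

test_that("pure water fits to PDFF 0 and degenerate inputs are handled", {
  f <- fit_voxel(voxel_signal(1, 0, 0, 0), protocol, spectrum)
  expect_equal(f$pdff, 0, tolerance = 1e-6)
  z <- fit_voxel(rep(0 + 0i, 6), protocol, spectrum)
  expect_equal(Mod(z$water) + Mod(z$fat), 0)
  expect_false(z$converged)
  expect_error(fit_voxel(c(NaN, rep(1 + 0i, 5)), protocol, spectrum), "finite")
  expect_error(fit_voxel(rep(1 + 0i, 4),
                         acquisition_protocol(n_echoes = 4), spectrum,
                         psi_search = c(50, -50)), "psi_search")
})

test_that("returned misfit is an argmin over the search grid", {
  set.seed(21)
  for (i in 1:5) {
    s <- voxel_signal(runif(1), runif(1), runif(1, -150, 150),
                      runif(1, 5, 200), runif(1, -pi, pi)) +
      0.02 * (rnorm(6) + 1i * rnorm(6))
    f <- fit_voxel(s, protocol, spectrum, psi_step = 5, r2s_step = 20)
    cfat <- musclepdff:::fat_coefficients(spectrum, protocol)
    for (psi in seq(-200, 200, by = 25)) for (r2s in seq(0, 300, by = 60))
      expect_lte(f$residual, brute_residual(psi, r2s, s, te, cfat) + 1e-10)
  }
})

test_that("estimated PDFF is nondecreasing in true fat fraction", {
  pd <- seq(0, 100, by = 10)
  est <- vapply(pd, function(p) {
    s <- voxel_signal(1 - p / 100, p / 100, 20, 40)
    fit_voxel(s, protocol, spectrum)$pdff
  }, 1)
  expect_true(all(diff(est) >= -1e-6))
})

test_that("PDFF is invariant to global scaling and initial phase", {
  s <- voxel_signal(0.7, 0.3, -25, 60)
  f0 <- fit_voxel(s, protocol, spectrum)
  f_scaled <- fit_voxel(5.3 * s, protocol, spectrum)
  f_phase <- fit_voxel(s * exp(1i * 1.1), protocol, spectrum)
  expect_equal(f_scaled$pdff, f0$pdff, tolerance = 1e-6)
  expect_equal(f_phase$pdff, f0$pdff, tolerance = 1e-6)
})

test_that("whole-volume separation round-trips a noiseless phantom", {
  gt <- generate_phantom(c(16, 16, 9), protocol, c(14.1, 15.2, 22.5), seed = 1)
  ser <- simulate_signal(gt, protocol, spectrum)
  qm <- separate(ser, spectrum)
  inm <- gt$masks$psoas$voxels | gt$masks$erector$voxels
  expect_lt(max(abs(qm$pdff[inm] - gt$pdff[inm])), 0.1)
  expect_lt(max(abs(qm$fieldmap[inm] - gt$fieldmap[inm])), 1)
  expect_lt(max(abs(qm$t2star[inm] - 1000 / gt$r2star[inm])), 1)
  expect_true(all(qm$t2star_valid[inm]))
  # background voxels are untouched zeros flagged invalid
  expect_true(all(qm$pdff[!inm] == 0))
  expect_true(all(!qm$t2star_valid[!inm]))
})

test_that("a uniform pure-fat phantom separates to PDFF 100", {
  d <- c(16, 16, 9)
  msk <- muscle_mask(array(TRUE, d), protocol$voxel_spacing)
  gt <- ground_truth(array(0, d), array(1, d), array(10, d), array(40, d),
                     array(0.2, d), 0, list(m = msk), protocol$voxel_spacing)
  qm <- separate(simulate_signal(gt, protocol, spectrum), spectrum)
  expect_equal(as.vector(qm$pdff), rep(100, prod(d)), tolerance = 1e-4)
})

test_that("separation is robust to noise at SNR 50", {
  gt <- generate_phantom(c(16, 16, 9), protocol, c(5, 15, 30), seed = 6)
  ser <- simulate_signal(gt, protocol, spectrum, snr = 50, seed = 8)
  inm <- gt$masks$psoas$voxels | gt$masks$erector$voxels
  qm <- separate(ser, spectrum, mask = inm)
  rmse <- sqrt(mean((qm$pdff[inm] - gt$pdff[inm])^2))
  expect_lt(rmse, 1.5)
})

test_that("eddy phase estimation finds zero and nonzero phases", {
  gt0 <- generate_phantom(c(16, 16, 9), protocol, c(10, 10, 10), seed = 2,
                          eddy_phase = 0)
  th0 <- estimate_eddy_phase(simulate_signal(gt0, protocol, spectrum), spectrum)
  expect_lt(abs(th0), 0.02)

  gt3 <- generate_phantom(c(16, 16, 9), protocol, c(10, 10, 10), seed = 2,
                          eddy_phase = 0.3)
  ser3 <- simulate_signal(gt3, protocol, spectrum)
  th3 <- estimate_eddy_phase(ser3, spectrum)
  expect_equal(th3, 0.3, tolerance = 0.01 / 0.3)

  # invariant to a global initial-phase shift
  ser_shift <- echo_series(ser3$signal * exp(1i * 0.9), protocol)
  th_shift <- estimate_eddy_phase(ser_shift, spectrum)
  expect_equal(th_shift, th3, tolerance = 0.05)

  # correcting with the estimate reduces the pooled misfit
  qm_raw <- separate(ser3, spectrum, mask = gt3$masks$psoas$voxels)
  qm_cor <- separate(ser3, spectrum, eddy = th3,
                     mask = gt3$masks$psoas$voxels)
  inm <- gt3$masks$psoas$voxels
  expect_lt(mean(qm_cor$residual[inm]), mean(qm_raw$residual[inm]))

  # monopolar: returns zero with a notice
  mono <- acquisition_protocol(bipolar = FALSE)
  gtm <- generate_phantom(c(16, 16, 9), mono, c(10, 10, 10), seed = 2)
  expect_message(
    thm <- estimate_eddy_phase(simulate_signal(gtm, mono, spectrum), spectrum),
    "monopolar")
  expect_equal(as.numeric(thm), 0)
})

test_that("eddy-corrected separation recovers PDFF under bipolar phase error", {
  gt <- generate_phantom(c(16, 16, 9), protocol, c(10, 15, 20), seed = 7,
                         eddy_phase = 0.25)
  ser <- simulate_signal(gt, protocol, spectrum)
  qm <- separate(ser, spectrum, eddy = "estimate")
  expect_equal(attr(qm, "eddy_phase"), 0.25, tolerance = 0.05)
  inm <- gt$masks$psoas$voxels | gt$masks$erector$voxels
  expect_lt(max(abs(qm$pdff[inm] - gt$pdff[inm])), 0.2)
})
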