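protocol <- acquisition_protocol()
spectrum <- default_fat_spectrum()

test_that("phantom section means match the commanded profile", {
  gt <- generate_phantom(c(16, 16, 9), protocol, c(14.1, 15.2, 22.5), seed = 4)
  for (m in gt$masks) {
    split <- split_thirds(m)
    means <- vapply(c("proximal", "middle", "distal"), function(s)
      mean(gt$pdff[split[[s]]$voxels]), 1)
    expect_equal(unname(means), c(14.1, 15.2, 22.5), tolerance = 0.5 / 14)
    expect_gt(means["distal"], means["proximal"])
  }
})

test_that("phantom orders sections as commanded in both directions", {
  gt <- generate_phantom(c(16, 16, 12), protocol, c(22.5, 15.2, 14.1), seed = 5)
  split <- split_thirds(gt$masks$psoas)
  expect_gt(mean(gt$pdff[split$proximal$voxels]),
            mean(gt$pdff[split$distal$voxels]))
})

test_that("pure-water profile yields zero fat inside the masks", {
  gt <- generate_phantom(c(16, 16, 9), protocol, c(0, 0, 0), seed = 1)
  inm <- gt$masks$psoas$voxels | gt$masks$erector$voxels
  expect_true(all(gt$fat_mag[inm] == 0))
  expect_true(all(gt$pdff[inm] == 0))
})

test_that("phantom generation is deterministic and validates input", {
  a <- generate_phantom(c(16, 16, 9), protocol, c(5, 10, 15), seed = 9)
  b <- generate_phantom(c(16, 16, 9), protocol, c(5, 10, 15), seed = 9)
  expect_identical(a, b)
  expect_error(generate_phantom(c(8, 8, 9), protocol, c(5, 10, 15)),
               "at least")
  expect_error(generate_phantom(c(16, 16, 9), protocol, c(5, 10, 150)),
               "0, 100")
})

test_that("masks are single 6-connected components", {
  gt <- generate_phantom(c(20, 20, 10), protocol, c(10, 10, 10), seed = 2)
  expect_true(is_single_component6(gt$masks$psoas$voxels))
  expect_true(is_single_component6(gt$masks$erector$voxels))
})

test_that("simulated signal matches the model closed forms", {
  # uniform phantoms built by hand
  mk_truth <- function(W, F, psi = 0, r2s = 0, phi0 = 0, theta = 0) {
    d <- c(4, 4, 4)
    msk <- muscle_mask(array(TRUE, d), protocol$voxel_spacing)
    ground_truth(array(W, d), array(F, d), array(psi, d), array(r2s, d),
                 array(phi0, d), theta, list(m = msk),
                 protocol$voxel_spacing)
  }
  # pure water, no confounders: s_n = 1
  s <- simulate_signal(mk_truth(1, 0), protocol, spectrum)$signal
  expect_equal(as.vector(s), rep(1 + 0i, length(s)))
  # pure fat with a degenerate single peak at 0 ppm: s_n = 1
  sp0 <- fat_spectrum(0, 1)
  s <- simulate_signal(mk_truth(0, 1), protocol, sp0)$signal
  expect_equal(as.vector(s), rep(1 + 0i, length(s)))
  # W = F = 1, R2* = 50: |s_n| = 2 exp(-50 TE_n)
  s <- simulate_signal(mk_truth(1, 1, r2s = 50), protocol, sp0)$signal
  te <- echo_times(protocol)
  for (n in seq_along(te))
    expect_equal(as.vector(Mod(s[, , , n])),
                 rep(2 * exp(-50 * te[n]), 64), tolerance = 1e-12)
  # full model at one voxel against an independently coded forward model
  gt <- mk_truth(0.7, 0.3, psi = 35, r2s = 40, phi0 = 0.5, theta = 0.2)
  s <- simulate_signal(gt, protocol, spectrum)$signal
  ref <- forward_signal(0.7, 0.3, 35, 40, 0.5, 0.2, te,
                        fat_peak_frequencies(spectrum, 3),
                        spectrum$amplitudes, echo_parity(protocol))
  expect_equal(s[1, 1, 1, ], ref, tolerance = 1e-12)
})

test_that("noise magnitude matches the requested SNR", {
  gt <- generate_phantom(c(16, 16, 9), protocol, c(10, 10, 10), seed = 3)
  clean <- simulate_signal(gt, protocol, spectrum)$signal
  noisy <- simulate_signal(gt, protocol, spectrum, snr = 30, seed = 11)$signal
  dn <- noisy - clean
  inm <- gt$masks$psoas$voxels | gt$masks$erector$voxels
  sigma_target <- mean(Mod(clean[, , , 1])[inm]) / 30
  sigma_emp <- sqrt(mean(Mod(dn)^2))  # > 10^4 voxel-echoes
  expect_equal(sigma_emp, sigma_target, tolerance = 0.05)
  # deterministic per seed
  noisy2 <- simulate_signal(gt, protocol, spectrum, snr = 30, seed = 11)$signal
  expect_identical(noisy, noisy2)
})
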