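test_that("normality gate labels normal, lognormal and neither", {
  set.seed(101)
  x <- rnorm(200)
  expect_equal(as.character(normality_gate(x)), "normal")
  expect_equal(as.character(normality_gate(exp(x))), "lognormal")
  y <- c(rep(0.01, 80), rexp(120)^3)  # heavily non-normal, log fails too
  expect_equal(as.character(normality_gate(y)), "neither")
  expect_error(normality_gate(rep(5, 20)), "degenerate")
  expect_error(normality_gate(rnorm(4)), "n >= 5")
  set.seed(202)
  expect_message(normality_gate(c(rnorm(100)^2 * -1)), "nonpositive")
})

test_that("one-sample t matches the closed form and handles edge cases", {
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(sample(5:50, 1), mean = runif(1, -1, 1))
    ref <- brute_one_sample_t(x)
    got <- one_sample_t(x)
    expect_equal(got$statistic, ref$t, tolerance = 1e-10)
    expect_equal(got$df, ref$df)
    expect_equal(got$p_value, ref$p, tolerance = 1e-10)
  }
  # exactly symmetric sample: t = 0, p = 1
  s0 <- one_sample_t(c(-1, 1))
  expect_equal(s0$statistic, 0)
  expect_equal(s0$p_value, 1)
  # zero variance away from the null: infinite t, p -> 0
  sz <- one_sample_t(c(5, 5, 5))
  expect_true(is.infinite(sz$statistic))
  expect_equal(sz$p_value, 0)
})

test_that("pooled t and ANOVA match brute-force sums of squares", {
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(sample(5:30, 1), 0.3)
    ref <- brute_pooled_t(x, y)
    got <- independent_t(x, y)
    expect_equal(got$statistic, ref$t, tolerance = 1e-10)
    expect_equal(got$p_value, ref$p, tolerance = 1e-10)

    g <- list(rnorm(sample(5:20, 1)), rnorm(sample(5:20, 1), 0.5),
              rnorm(sample(5:20, 1), -0.5))
    refa <- brute_anova(g)
    gota <- one_way_anova(g)
    expect_equal(gota$statistic, refa$F, tolerance = 1e-10)
    expect_equal(unname(gota$df), c(refa$df1, refa$df2))
    expect_equal(gota$p_value, refa$p, tolerance = 1e-10)
  }
  # identical samples: t = 0; equal-mean equal-n groups: tiny F
  expect_equal(independent_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
})

test_that("two-group ANOVA reproduces t squared", {
  set.seed(13)
  x <- rnorm(12); y <- rnorm(15, 0.4)
  tt <- independent_t(x, y)
  ff <- one_way_anova(list(x, y))
  expect_equal(ff$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(ff$p_value, tt$p_value, tolerance = 1e-10)
})

test_that("correlations match brute-force references including ties", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    expect_equal(pearson(x, y)$estimate, brute_pearson_r(x, y),
                 tolerance = 1e-10)
    # perfect linear relation
    expect_equal(pearson(x, 2 * x + 3)$estimate, 1, tolerance = 1e-12)
    # spearman equals pearson on rank vectors (no ties here, a.s.)
    expect_equal(spearman(x, y)$estimate,
                 brute_pearson_r(brute_midranks(x), brute_midranks(y)),
                 tolerance = 1e-10)
    # tied data against explicit mid-rank computation
    xt <- sample(1:5, n, replace = TRUE)
    yt <- sample(1:4, n, replace = TRUE)
    expect_equal(spearman(xt, yt)$estimate,
                 brute_pearson_r(brute_midranks(xt), brute_midranks(yt)),
                 tolerance = 1e-10)
  }
})

test_that("pearson with gate log-transforms lognormal inputs", {
  set.seed(16)
  lx <- rnorm(300); y <- 0.6 * lx + 0.8 * rnorm(300)
  res <- pearson(exp(lx), y, gate = TRUE)
  expect_match(res$transform, "log_x")
  expect_equal(res$estimate, brute_pearson_r(lx, y), tolerance = 1e-10)
})

test_that("partial correlation matches the residual-regression oracle", {
  set.seed(16)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -0.3 * z + rnorm(n)
    got <- partial_correlation(x, y, z)
    expect_equal(got$estimate, brute_partial_r(x, y, z), tolerance = 1e-10)
    expect_equal(got$df, n - 3)
  }
  # independent control reduces to the plain correlation
  n <- 2000
  x <- rnorm(n); y <- 0.4 * x + rnorm(n); z <- rnorm(n)
  expect_equal(partial_correlation(x, y, z)$estimate,
               brute_partial_r(x, y, z), tolerance = 1e-12)
  # x == z is degenerate
  expect_error(partial_correlation(x, y, x), "collinear")
})

test_that("partial correlation is invariant to affine transforms of z", {
  set.seed(17)
  z <- rnorm(40); x <- 0.7 * z + rnorm(40); y <- 0.2 * z + rnorm(40)
  r0 <- partial_correlation(x, y, z)$estimate
  expect_equal(partial_correlation(x, y, 3.2 * z - 17)$estimate, r0,
               tolerance = 1e-12)
  expect_equal(partial_correlation(x, y, -z)$estimate, r0, tolerance = 1e-12)
})

test_that("one-sample t holds its nominal type-I error", {
  set.seed(18)
  n <- 20; reps <- 10000
  x <- matrix(rnorm(n * reps), n, reps)
  p <- vapply(seq_len(reps), function(j) one_sample_t(x[, j])$p_value, 1)
  # cross-check the package p values against a vectorised closed form
  m <- colMeans(x)
  s <- sqrt((colSums(x^2) - n * m^2) / (n - 1))
  p_ref <- 2 * pt(-abs(m / (s / sqrt(n))), n - 1)
  expect_equal(p, p_ref, tolerance = 1e-10)
  expect_gte(mean(p < 0.05), 0.04)
  expect_lte(mean(p < 0.05), 0.06)
})
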