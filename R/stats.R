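## The study's statistical battery.
##
## All p values are two-sided and no multiple-testing correction is applied
## (the analysis is explorative). Normality is screened with a Lilliefors-
## corrected Kolmogorov-Smirnov test (parameters estimated from the sample);
## variables that fail but whose logs pass are analysed on the log scale;
## variables failing both are handled by rank methods (Spearman).

new_test_result <- function(statistic, df, p_value, n, method,
                            estimate = NA_real_, transform = "none") {
  structure(
    list(statistic = statistic, df = df, p_value = p_value, n = n,
         method = method, estimate = estimate, transform = transform),
    class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  est <- if (!is.na(x$estimate)) sprintf(", estimate %.4f", x$estimate) else ""
  cat(sprintf("<test_result> %s: stat %.4f, df %s, p %.4g, n %d%s%s\n",
              x$method, x$statistic, paste(signif(x$df, 6), collapse = "/"),
              x$p_value, x$n, est,
              if (x$transform != "none") paste0(" [", x$transform, "]") else ""))
  invisible(x)
}

#' Normality gate with log fallback
#'
#' Tests a sample for normality with the Lilliefors-corrected
#' Kolmogorov-Smirnov test (mean and SD estimated from the sample). If
#' normality is rejected at `alpha` and all values are positive, the log of
#' the sample is tested; the first non-rejected label is returned.
#'
#' @param x Numeric sample, n >= 5.
#' @param alpha Rejection level for the KS test.
#' @return `"normal"`, `"lognormal"` or `"neither"`, with the KS p values in
#'   attribute `"p_values"`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 5) stop("need n >= 5 for the normality gate")
  if (stats::sd(x) == 0) stop("degenerate (constant) sample")
  p1 <- nortest::lillie.test(x)$p.value
  if (p1 >= alpha)
    return(structure("normal", p_values = c(normal = p1)))
  if (any(x <= 0)) {
    message("nonpositive values: log branch unavailable")
    return(structure("neither", p_values = c(normal = p1, lognormal = NA)))
  }
  p2 <- nortest::lillie.test(log(x))$p.value
  if (p2 >= alpha)
    return(structure("lognormal", p_values = c(normal = p1, lognormal = p2)))
  structure("neither", p_values = c(normal = p1, lognormal = p2))
}

#' One-sample t test
#'
#' `t = (mean(x) - mu0) / (sd(x)/sqrt(n))` with `df = n - 1`, two-sided p.
#' The default null value of 0 tests whether an observed change differs from
#' no change.
#'
#' @param x Numeric sample.
#' @param mu0 Null value (default 0).
#' @return A `test_result` (statistic, df, p_value, n, estimate = mean).
#' @export
one_sample_t <- function(x, mu0 = 0) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) stop("need n >= 2")
  if (stats::sd(x) == 0) {
    # zero variance: t is infinite unless the mean equals mu0 exactly
    if (mean(x) == mu0)
      return(new_test_result(0, n - 1, 1, n, "one_sample_t", mean(x)))
    return(new_test_result(sign(mean(x) - mu0) * Inf, n - 1, 0, n,
                           "one_sample_t", mean(x)))
  }
  tt <- stats::t.test(x, mu = mu0)
  new_test_result(unname(tt$statistic), unname(tt$parameter),
                  tt$p.value, n, "one_sample_t", mean(x))
}

#' Independent-samples t test
#'
#' Classical pooled-variance two-sample t test by default (`var_equal =
#' TRUE`); Welch's unequal-variance form is available.
#'
#' @param x,y Numeric samples.
#' @param var_equal Logical; pooled (TRUE, default) or Welch.
#' @return A `test_result`; `estimate` is `mean(x) - mean(y)`.
#' @export
independent_t <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group")
  tt <- stats::t.test(x, y, var.equal = var_equal)
  new_test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
                  length(x) + length(y),
                  if (var_equal) "independent_t" else "welch_t",
                  mean(x) - mean(y))
}

#' One-way ANOVA
#'
#' Classical fixed-effects one-way analysis of variance: F with
#' `(k - 1, N - k)` degrees of freedom.
#'
#' @param groups List of numeric samples (k >= 2).
#' @return A `test_result` with `df = c(k - 1, N - k)`.
#' @export
one_way_anova <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  k <- length(groups)
  if (k < 2) stop("need >= 2 groups")
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs n >= 2")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_len(k), vapply(groups, length, 1L)))
  ow <- stats::oneway.test(y ~ g, var.equal = TRUE)
  new_test_result(unname(ow$statistic), unname(ow$parameter), ow$p.value,
                  length(y), "one_way_anova")
}

# two-sided p for a correlation via the t approximation with df = n - 2
cor_p_value <- function(r, n, df = n - 2) {
  if (df < 1) return(NA_real_)
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(tstat), df)
}

#' Pearson correlation (with optional log transform)
#'
#' Pearson's product-moment correlation with a two-sided p from the t
#' approximation (`df = n - 2`). With `gate = TRUE` each variable is passed
#' through [normality_gate()] and log-transformed when it is lognormal; if
#' either variable is neither normal nor lognormal the computation falls back
#' to [spearman()].
#'
#' @param x,y Numeric vectors; pairwise-complete observations are used.
#' @param gate Logical; apply the normality gate / log / rank routing.
#' @return A `test_result` with `estimate = r` and `transform` recording any
#'   log or rank transform applied.
#' @export
pearson <- function(x, y, gate = FALSE) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need n >= 3 pairs")
  transform <- "none"
  if (gate) {
    gx <- normality_gate(x)
    gy <- normality_gate(y)
    if (gx == "neither" || gy == "neither")
      return(spearman(x, y))
    if (gx == "lognormal") { x <- log(x); transform <- "log_x" }
    if (gy == "lognormal") {
      y <- log(y)
      transform <- if (transform == "none") "log_y" else "log_xy"
    }
  }
  r <- stats::cor(x, y)
  res <- new_test_result(r * sqrt((n - 2) / (1 - r^2)), n - 2,
                         cor_p_value(r, n), n, "pearson", r, transform)
  res
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties) with the
#' two-sided t-approximation p on `df = n - 2`.
#'
#' @param x,y Numeric vectors; pairwise-complete observations are used.
#' @return A `test_result` with `estimate = rho`.
#' @export
spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need n >= 3 pairs")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  new_test_result(rho * sqrt((n - 2) / (1 - rho^2)), n - 2,
                  cor_p_value(rho, n), n, "spearman", rho, "rank")
}

#' Partial correlation controlling for one covariate
#'
#' First-order partial correlation
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`
#' with a two-sided p from the t approximation on `df = n - 3`. With
#' `method = "spearman"` all three variables are rank-transformed first.
#'
#' @param x,y Variables to correlate.
#' @param z Control variable.
#' @param method `"pearson"` or `"spearman"` (rank-based).
#' @return A `test_result` with `estimate = r_xy.z` and `df = n - 3`.
#' @export
partial_correlation <- function(x, y, z, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 4) stop("need n >= 4 triples")
  if (method == "spearman") {
    x <- rank(x, ties.method = "average")
    y <- rank(y, ties.method = "average")
    z <- rank(z, ties.method = "average")
  }
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("control variable collinear with x or y: partial correlation undefined")
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  df <- n - 3
  tstat <- r * sqrt(df / (1 - r^2))
  new_test_result(tstat, df, 2 * stats::pt(-abs(tstat), df), n,
                  paste0("partial_", method), r,
                  if (method == "spearman") "rank" else "none")
}

#' Run the cohort correlation battery
#'
#' For every muscle x section (total + proximal/middle/distal) x metric
#' (mean PDFF, total/fat/contractile volume), correlates the baseline value
#' with each subject's maximum BMI change, plain and age-controlled. Method
#' routing follows the normality gate: Pearson when both variables pass
#' (possibly after log transform), Spearman otherwise. No multiple-testing
#' correction is applied.
#'
#' @param baseline `data.frame` with one row per subject x muscle x section:
#'   columns `subject_id`, `muscle`, `section`, `mean_pdff_pct`, `total_ml`,
#'   `fat_ml`, `contractile_ml`.
#' @param subjects `data.frame` with one row per subject: `subject_id`,
#'   `age`, `max_bmi_change` (and optionally `cachectic`).
#' @param gate Logical; apply normality-gate method routing (default TRUE).
#' @return `data.frame` with one row per muscle x section x metric:
#'   `muscle`, `section`, `metric`, `n`, `method`, `r`, `p`,
#'   `r_age_controlled`, `p_age_controlled`. Rows with fewer than 4 complete
#'   cases are kept with `NA` results.
#' @export
run_study_battery <- function(baseline, subjects, gate = TRUE) {
  need_b <- c("subject_id", "muscle", "section", "mean_pdff_pct", "total_ml",
              "fat_ml", "contractile_ml")
  if (!all(need_b %in% names(baseline)))
    stop("baseline table must have columns: ", paste(need_b, collapse = ", "))
  need_s <- c("subject_id", "age", "max_bmi_change")
  if (!all(need_s %in% names(subjects)))
    stop("subjects table must have columns: ", paste(need_s, collapse = ", "))
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject ids in 'subjects'")

  metrics <- c(mean_pdff_pct = "pdff_pct", total_ml = "total_volume_ml",
               fat_ml = "fat_volume_ml", contractile_ml = "contractile_volume_ml")
  sections <- c("total", "proximal", "middle", "distal")
  out <- list()
  for (mus in unique(baseline$muscle)) {
    for (sec in sections) {
      sub <- baseline[baseline$muscle == mus & baseline$section == sec, ]
      sub <- merge(sub, subjects, by = "subject_id")
      for (mcol in names(metrics)) {
        x <- sub[[mcol]]
        y <- sub$max_bmi_change
        z <- sub$age
        row <- data.frame(muscle = mus, section = sec,
                          metric = metrics[[mcol]],
                          n = sum(stats::complete.cases(x, y)),
                          method = NA_character_, r = NA_real_, p = NA_real_,
                          r_age_controlled = NA_real_,
                          p_age_controlled = NA_real_)
        if (row$n >= 4) {
          plain <- tryCatch(pearson(x, y, gate = gate), error = function(e) NULL)
          if (!is.null(plain)) {
            rank_based <- plain$method == "spearman"
            part <- tryCatch(
              partial_correlation(
                if (plain$transform %in% c("log_x", "log_xy")) log(x) else x,
                if (plain$transform %in% c("log_y", "log_xy")) log(y) else y,
                z, method = if (rank_based) "spearman" else "pearson"),
              error = function(e) NULL)
            row$method <- plain$method
            if (plain$transform != "none" && plain$method == "pearson")
              row$method <- "pearson_log"
            row$r <- plain$estimate
            row$p <- plain$p_value
            if (!is.null(part)) {
              row$r_age_controlled <- part$estimate
              row$p_age_controlled <- part$p_value
            }
          }
        }
        out[[length(out) + 1]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
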