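## Synthetic longitudinal cohort with the statistical structure the analysis
## assumes: anthropometrics drawn from the study-population distributions, a
## controllable correlation between baseline psoas fat volume and subsequent
## maximum BMI change (optionally loaded on age so the age-controlled partial
## correlation differs from the marginal one), and per-muscle, per-section
## metric trajectories with progressive volume loss.

#' Specification of a synthetic cohort
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param age_mean,age_sd Age distribution, years.
#' @param bmi_mean,bmi_sd Baseline BMI distribution, kg/m^2.
#' @param true_corr_fatvol_bmichange Target marginal Pearson correlation (on
#'   the log fat-volume scale) between baseline psoas fat volume and maximum
#'   BMI change; in [-1, 1].
#' @param age_effect_fatvol,age_effect_bmichange Standardised loadings of age
#'   on (log) fat volume and on BMI change. With nonzero loadings the
#'   age-controlled partial correlation (reported in attribute
#'   `"true_partial_corr"` of the generated cohort) differs from the marginal
#'   target.
#' @param bmi_change_mean,bmi_change_sd Distribution of the maximum BMI
#'   change, kg/m^2 (negative mean = net loss).
#' @param followup_range_days Range of days after baseline in which
#'   follow-ups fall.
#' @param max_followups Upper bound on follow-ups per subject (>= 1).
#' @param volume_loss_per100d_mean,volume_loss_per100d_sd Relative muscle
#'   volume loss in % per 100 days.
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 56L,
                        age_mean = 63.0, age_sd = 11.8,
                        bmi_mean = 25.4, bmi_sd = 4.4,
                        true_corr_fatvol_bmichange = -0.5,
                        age_effect_fatvol = 0.3,
                        age_effect_bmichange = 0.2,
                        bmi_change_mean = -2.11, bmi_change_sd = 1.99,
                        followup_range_days = c(44, 239),
                        max_followups = 3L,
                        volume_loss_per100d_mean = 7.5,
                        volume_loss_per100d_sd = 4,
                        seed = 1L) {
  if (n_subjects < 3) stop("'n_subjects' must be >= 3")
  r <- true_corr_fatvol_bmichange
  if (!is.finite(r) || abs(r) > 1)
    stop("'true_corr_fatvol_bmichange' must lie in [-1, 1]")
  a <- age_effect_fatvol; b <- age_effect_bmichange
  if (abs(a) >= 1 || abs(b) >= 1) stop("age effects must lie in (-1, 1)")
  rho <- (r - a * b) / sqrt((1 - a^2) * (1 - b^2))
  if (abs(rho) > 1)
    stop("infeasible correlation: |partial| > 1 given the age effects")
  structure(
    list(n_subjects = as.integer(n_subjects), age_mean = age_mean,
         age_sd = age_sd, bmi_mean = bmi_mean, bmi_sd = bmi_sd,
         true_corr_fatvol_bmichange = r,
         age_effect_fatvol = a, age_effect_bmichange = b,
         true_partial_corr = rho,
         bmi_change_mean = bmi_change_mean, bmi_change_sd = bmi_change_sd,
         followup_range_days = followup_range_days,
         max_followups = as.integer(max_followups),
         volume_loss_per100d_mean = volume_loss_per100d_mean,
         volume_loss_per100d_sd = volume_loss_per100d_sd,
         seed = as.integer(seed)),
    class = "cohort_spec")
}

# Table-2-like baseline distributions (mean, CV) and section fractions.
cohort_baseline_params <- function() {
  list(
    psoas = list(pdff_meanlog = log(9.7), pdff_sdlog = 0.33,
                 fat_mean = 28.5, fat_sdlog = 0.38,
                 section_frac = c(proximal = 0.255, middle = 0.567,
                                  distal = 0.178),
                 section_pdff_shift = c(proximal = 1.5, middle = 0.3,
                                        distal = -0.2)),
    erector = list(pdff_meanlog = log(15.5), pdff_sdlog = 0.35,
                   total_meanlog = log(804.7), total_sdlog = 0.30,
                   section_frac = c(proximal = 0.266, middle = 0.520,
                                    distal = 0.264),
                   section_pdff_shift = c(proximal = -1.4, middle = -0.3,
                                          distal = 7.0))
  )
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws subject anthropometrics, baseline muscle metrics and follow-up
#' trajectories per the [cohort_spec()]. Baseline psoas fat volume is
#' lognormal with a commanded correlation structure: on the log scale it and
#' the maximum BMI change are jointly Gaussian with age loadings, so the
#' induced marginal correlation converges to
#' `spec$true_corr_fatvol_bmichange` and the age-controlled partial
#' correlation to `spec$true_partial_corr` as n grows. Each subject's BMI
#' trajectory reaches its drawn maximum change at the last follow-up; muscle
#' volumes decay by a per-subject relative rate.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `cohort` with
#' \describe{
#'   \item{subjects}{one row per subject: `subject_id`, `age`, `sex`,
#'     `height_m`, `weight_kg`, `bmi`, `self_reported_weight_loss_kg`,
#'     `n_followups`, `max_bmi_change`.}
#'   \item{visits}{one row per scan: `subject_id`, `scan_date_offset_days`,
#'     `weight_kg`, `bmi`.}
#'   \item{baseline}{one row per subject x muscle x section with the
#'     [run_study_battery()] baseline columns.}
#'   \item{metrics}{long table (`subject_id`, `day_offset`, `muscle`,
#'     `section`, `metric`, `value`) across all timepoints, for
#'     [max_change_table()].}
#' }
#' The spec's derived true partial correlation is attached as attribute
#' `"true_partial_corr"`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  pars <- cohort_baseline_params()

  with_seed(spec$seed, {
    age <- stats::rnorm(n, spec$age_mean, spec$age_sd)
    age <- pmin(pmax(age, 30), 95)
    z_age <- (age - mean(age)) / stats::sd(age)
    sex <- sample(c("m", "f"), n, replace = TRUE, prob = c(37, 21) / 58)
    height <- ifelse(sex == "m", stats::rnorm(n, 1.76, 0.07),
                     stats::rnorm(n, 1.63, 0.06))
    bmi0 <- pmax(stats::rnorm(n, spec$bmi_mean, spec$bmi_sd), 14)
    weight0 <- bmi0 * height^2

    a <- spec$age_effect_fatvol; b <- spec$age_effect_bmichange
    rho <- spec$true_partial_corr
    u <- stats::rnorm(n)
    v <- rho * u + sqrt(1 - rho^2) * stats::rnorm(n)
    fz <- a * z_age + sqrt(1 - a^2) * u        # std score of log psoas fat vol
    bz <- b * z_age + sqrt(1 - b^2) * v        # std score of max BMI change

    p_ps <- pars$psoas
    fat_ps <- p_ps$fat_mean * exp(p_ps$fat_sdlog * fz - p_ps$fat_sdlog^2 / 2)
    pdff_ps <- exp(p_ps$pdff_meanlog + p_ps$pdff_sdlog *
                     (0.4 * fz + sqrt(1 - 0.4^2) * stats::rnorm(n)))
    pdff_ps <- pmin(pmax(pdff_ps, 3), 45)
    total_ps <- fat_ps * 100 / pdff_ps

    p_er <- pars$erector
    total_er <- exp(p_er$total_meanlog + p_er$total_sdlog * stats::rnorm(n))
    pdff_er <- pmin(pmax(exp(p_er$pdff_meanlog + p_er$pdff_sdlog *
                               (0.3 * z_age + 0.95 * stats::rnorm(n))), 4), 50)
    fat_er <- pdff_er / 100 * total_er

    max_bmi_change <- spec$bmi_change_mean + spec$bmi_change_sd * bz

    n_fup <- sample(seq_len(spec$max_followups), n, replace = TRUE,
                    prob = rev(seq_len(spec$max_followups)))
    loss_rate <- stats::rnorm(n, spec$volume_loss_per100d_mean,
                              spec$volume_loss_per100d_sd)

    self_loss <- pmax(0, stats::rnorm(n, 4.3, 5.5))

    muscles <- list(
      psoas = list(total = total_ps, pdff = pdff_ps,
                   frac = p_ps$section_frac, shift = p_ps$section_pdff_shift),
      erector = list(total = total_er, pdff = pdff_er,
                     frac = p_er$section_frac, shift = p_er$section_pdff_shift))
    sections <- c("total", "proximal", "middle", "distal")
    metrics4 <- c("mean_pdff_pct", "total_ml", "fat_ml", "contractile_ml")
    sids <- sprintf("S%03d", seq_len(n))

    # accumulate plain vectors per subject; one data.frame at the end
    v_sid <- m_sid <- m_mus <- vector("list", n)
    v_day <- v_w <- v_bmi <- vector("list", n)
    m_day <- m_sec <- m_met <- m_val <- vector("list", n)
    b_sid <- b_mus <- b_sec <- b_pdff <- b_tot <- b_fat <- vector("list", n)

    for (i in seq_len(n)) {
      fdays <- unique(sort(round(stats::runif(
        n_fup[i], spec$followup_range_days[1], spec$followup_range_days[2]))))
      days <- c(0, fdays)
      nT <- length(days)
      # BMI approaches its maximum change linearly over the follow-ups
      bmi_t <- bmi0[i] + max_bmi_change[i] * days / max(days)
      v_sid[[i]] <- rep(sids[i], nT)
      v_day[[i]] <- days
      v_w[[i]] <- bmi_t * height[i]^2
      v_bmi[[i]] <- bmi_t

      sec_i <- met_i <- day_i <- mus_i <- val_i <- list()
      bs_mus <- bs_sec <- bs_pdff <- bs_tot <- bs_fat <- list()
      for (mus in names(muscles)) {
        mm <- muscles[[mus]]
        frac_i <- mm$frac * exp(stats::rnorm(3, 0, 0.08))
        frac_i <- frac_i / sum(frac_i)
        sec_total0 <- c(mm$total[i], mm$total[i] * frac_i)
        sec_pdff0 <- c(mm$pdff[i],
                       pmin(pmax(mm$pdff[i] + mm$shift +
                                   stats::rnorm(3, 0, 0.8), 1), 60))
        shrink <- pmax(0.4, 1 - loss_rate[i] / 100 * days / 100)
        total_m <- outer(sec_total0, shrink)            # 4 sections x nT
        noise <- cbind(0, matrix(stats::rnorm(4 * (nT - 1), 0, 0.4), 4))
        pdff_m <- pmin(pmax(sec_pdff0 + noise, 1), 60)
        fat_m <- pdff_m / 100 * total_m
        vals <- rbind(as.vector(pdff_m), as.vector(total_m),
                      as.vector(fat_m), as.vector(total_m - fat_m))
        k <- length(sec_i) + 1
        sec_i[[k]] <- rep(rep(sections, each = 4), nT)
        met_i[[k]] <- rep(metrics4, 4 * nT)
        day_i[[k]] <- rep(days, each = 16)
        mus_i[[k]] <- rep(mus, 16 * nT)
        val_i[[k]] <- as.vector(vals)                   # metric-major per cell
        bs_mus[[k]] <- rep(mus, 4); bs_sec[[k]] <- sections
        bs_pdff[[k]] <- pdff_m[, 1]; bs_tot[[k]] <- total_m[, 1]
        bs_fat[[k]] <- fat_m[, 1]
      }
      m_sid[[i]] <- rep(sids[i], 32 * nT)
      m_mus[[i]] <- unlist(mus_i); m_day[[i]] <- unlist(day_i)
      m_sec[[i]] <- unlist(sec_i); m_met[[i]] <- unlist(met_i)
      m_val[[i]] <- unlist(val_i)
      b_sid[[i]] <- rep(sids[i], 8)
      b_mus[[i]] <- unlist(bs_mus); b_sec[[i]] <- unlist(bs_sec)
      b_pdff[[i]] <- unlist(bs_pdff); b_tot[[i]] <- unlist(bs_tot)
      b_fat[[i]] <- unlist(bs_fat)
    }

    baseline <- data.frame(
      subject_id = unlist(b_sid), muscle = unlist(b_mus),
      section = unlist(b_sec), mean_pdff_pct = unlist(b_pdff),
      total_ml = unlist(b_tot), fat_ml = unlist(b_fat),
      contractile_ml = unlist(b_tot) - unlist(b_fat))
    # commanded psoas total fat volume overrides the per-section draw noise
    sel <- baseline$muscle == "psoas" & baseline$section == "total"
    baseline$fat_ml[sel] <- fat_ps
    baseline$contractile_ml[sel] <- baseline$total_ml[sel] - fat_ps

    subjects <- data.frame(
      subject_id = sids, age = age, sex = sex,
      height_m = height, weight_kg = weight0, bmi = bmi0,
      self_reported_weight_loss_kg = self_loss,
      n_followups = n_fup, max_bmi_change = max_bmi_change)

    visits <- data.frame(
      subject_id = unlist(v_sid),
      scan_date_offset_days = unlist(v_day),
      weight_kg = unlist(v_w), bmi = unlist(v_bmi))
    metrics_long <- data.frame(
      subject_id = unlist(m_sid), day_offset = unlist(m_day),
      muscle = unlist(m_mus), section = unlist(m_sec),
      metric = unlist(m_met), value = unlist(m_val))

    out <- list(subjects = subjects, visits = visits,
                baseline = baseline, metrics = metrics_long)
    attr(out, "true_partial_corr") <- spec$true_partial_corr
    class(out) <- "cohort"
    out
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects, %d visits, %d baseline metric rows\n",
              nrow(x$subjects), nrow(x$visits), nrow(x$baseline)))
  invisible(x)
}
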