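test_that("cohort spec validates its inputs", {
  expect_error(cohort_spec(n_subjects = 2), ">= 3")
  expect_error(cohort_spec(true_corr_fatvol_bmichange = -1.2), "\\[-1, 1\\]")
  expect_error(cohort_spec(true_corr_fatvol_bmichange = -0.99,
                           age_effect_fatvol = 0.9,
                           age_effect_bmichange = 0.9),
               "infeasible")
})

test_that("cohort generation is deterministic and well-formed", {
  sp <- cohort_spec(n_subjects = 3, seed = 42)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a, b)
  expect_equal(nrow(a$subjects), 3)
  expect_false(anyDuplicated(a$subjects$subject_id) > 0)
  # baseline: 2 muscles x 4 sections per subject
  expect_equal(nrow(a$baseline), 3 * 2 * 4)
  # every subject has a baseline visit at day 0 and >= 1 follow-up
  for (sid in a$subjects$subject_id) {
    d <- a$visits$scan_date_offset_days[a$visits$subject_id == sid]
    expect_true(0 %in% d)
    expect_gte(sum(d > 0), 1)
    expect_true(all(diff(sort(d)) > 0))
  }
  # section volumes sum to the whole-muscle volume
  ps <- a$baseline[a$baseline$muscle == "psoas", ]
  for (sid in unique(ps$subject_id)) {
    s <- ps[ps$subject_id == sid, ]
    expect_equal(sum(s$total_ml[s$section != "total"]),
                 s$total_ml[s$section == "total"], tolerance = 1e-9)
  }
})

test_that("anthropometrics follow the commanded distributions", {
  co <- generate_cohort(cohort_spec(n_subjects = 4000, seed = 2))
  expect_equal(mean(co$subjects$age), 63.0, tolerance = 0.02)
  expect_equal(sd(co$subjects$age), 11.8, tolerance = 0.05)
  expect_equal(mean(co$subjects$bmi), 25.4, tolerance = 0.02)
  expect_equal(mean(co$subjects$max_bmi_change), -2.11, tolerance = 0.1)
})

test_that("an uncorrelated cohort shows near-zero sample correlation", {
  co <- generate_cohort(cohort_spec(n_subjects = 5000,
                                    true_corr_fatvol_bmichange = 0,
                                    age_effect_fatvol = 0,
                                    age_effect_bmichange = 0, seed = 3))
  fat <- co$baseline$fat_ml[co$baseline$muscle == "psoas" &
                              co$baseline$section == "total"]
  r <- cor(log(fat), co$subjects$max_bmi_change)
  expect_lt(abs(r), 0.05)
})

test_that("commanded correlation is recovered within the Fisher-z interval", {
  co <- generate_cohort(cohort_spec(n_subjects = 5000,
                                    true_corr_fatvol_bmichange = -0.5,
                                    seed = 4))
  fat <- co$baseline$fat_ml[co$baseline$muscle == "psoas" &
                              co$baseline$section == "total"]
  r <- cor(log(fat), co$subjects$max_bmi_change)
  expect_gt(r, -0.55)
  expect_lt(r, -0.45)
  # coverage across seeds: the 95% Fisher interval contains the target
  hits <- vapply(1:60, function(s) {
    c2 <- generate_cohort(cohort_spec(n_subjects = 300,
                                      true_corr_fatvol_bmichange = -0.5,
                                      seed = s))
    f <- c2$baseline$fat_ml[c2$baseline$muscle == "psoas" &
                              c2$baseline$section == "total"]
    rr <- cor(log(f), c2$subjects$max_bmi_change)
    ci <- tanh(atanh(rr) + c(-1, 1) * 1.96 / sqrt(300 - 3))
    ci[1] <= -0.5 && -0.5 <= ci[2]
  }, TRUE)
  expect_gte(mean(hits), 0.85)
})

test_that("study battery emits the full grid and recovers the structure", {
  co <- generate_cohort(cohort_spec(n_subjects = 2000, seed = 5))
  bat <- run_study_battery(co$baseline, co$subjects)
  # 2 muscles x 4 sections x 4 metrics
  expect_equal(nrow(bat), 32)
  expect_equal(sort(unique(bat$section)),
               sort(c("total", "proximal", "middle", "distal")))
  row <- bat[bat$muscle == "psoas" & bat$section == "total" &
               bat$metric == "fat_volume_ml", ]
  expect_equal(row$r, -0.5, tolerance = 0.1)
  expect_lt(row$p, 1e-6)
  # age-controlled partial is the generator's derived value
  expect_equal(row$r_age_controlled, attr(co, "true_partial_corr"),
               tolerance = 0.1)
})

test_that("battery keeps rows with insufficient data as NA, no crash", {
  co <- generate_cohort(cohort_spec(n_subjects = 10, seed = 6))
  bl <- co$baseline
  bl$fat_ml[bl$muscle == "erector" & bl$section == "distal"] <- NA
  bat <- run_study_battery(bl, co$subjects)
  row <- bat[bat$muscle == "erector" & bat$section == "distal" &
               bat$metric == "fat_volume_ml", ]
  expect_true(is.na(row$r))
  expect_equal(nrow(bat), 32)
})

test_that("cachexia prevalence from generated weight histories is sane", {
  co <- generate_cohort(cohort_spec(n_subjects = 200, seed = 7))
  calls <- vapply(seq_len(200), function(i) {
    sid <- co$subjects$subject_id[i]
    v <- co$visits[co$visits$subject_id == sid, ]
    classify_cachexia(v$weight_kg, v$scan_date_offset_days,
                      height_m = co$subjects$height_m[i],
                      self_reported_loss_kg =
                        co$subjects$self_reported_weight_loss_kg[i])$cachectic
  }, TRUE)
  expect_gt(mean(calls), 0.1)
  expect_lt(mean(calls), 0.95)
})
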