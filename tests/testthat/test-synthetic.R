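test_that("latent trajectories are bounded and regime-consistent", {
  cfg <- sim_config()
  tr <- latent_trajectory(120, onset_day = 90, cfg, seed = 3)
  expect_true(all(tr$severity >= 0 & tr$severity <= 1))
  expect_true(all(tr$regime[tr$day >= 90] == "relapse"))
  expect_true(all(tr$severity[tr$regime == "relapse"] >= 0.9))
  pro <- which(tr$regime == "prodrome")
  expect_true(length(pro) >= cfg$prodrome_days[1] - 1)
  expect_true(all(diff(pro) == 1))                   # contiguous ramp
  expect_true(max(pro) == which(tr$day == 90) - 1)   # ends at onset
  trh <- latent_trajectory(120, NULL, cfg, seed = 3)
  expect_true(all(trh$severity == 0))
  expect_true(all(trh$regime == "healthy"))
})

test_that("simulated counts are reproducible, non-negative, day-shaped", {
  cfg <- sim_config()
  tr <- latent_trajectory(3, NULL, cfg, seed = 1)
  a <- simulate_minute_counts(tr, cfg, seed = 9)
  b <- simulate_minute_counts(tr, cfg, seed = 9)
  expect_identical(a$counts, b$counts)
  expect_equal(dim(a$counts), c(3L, 1440L))
  expect_true(all(a$counts >= 0, na.rm = TRUE))
  # circadian gating: afternoon activity dwarfs night activity
  expect_gt(mean(a$counts[, 721:1080], na.rm = TRUE),
            3 * mean(a$counts[, 1:360], na.rm = TRUE))
})

test_that("feature extraction recovers the generator's scaling target", {
  cfg <- sim_config()
  est <- vapply(1:20, function(s) {
    tr <- latent_trajectory(8, NULL, cfg, seed = s)
    ms <- simulate_minute_counts(tr, cfg, seed = 500 + s)
    ft <- feature_table(ms, detect_gaps(ms), dates = ms$days[8])
    ft$alpha1
  }, numeric(1))
  expect_lt(abs(mean(est, na.rm = TRUE) - cfg$alpha_target_healthy), 0.07)
})

test_that("relapse regime lowers fractal scaling and afternoon entropy", {
  cfg <- sim_config()
  res <- t(vapply(1:20, function(s) {
    trH <- latent_trajectory(8, NULL, cfg, seed = s)
    trR <- trH; trR$severity <- 1; trR$regime <- "relapse"
    mh <- simulate_minute_counts(trH, cfg, seed = 1000 + s)
    mr <- simulate_minute_counts(trR, cfg, seed = 1000 + s)
    fh <- feature_table(mh, detect_gaps(mh), dates = mh$days[8])
    fr <- feature_table(mr, detect_gaps(mr), dates = mr$days[8])
    c(fh$alpha1 - fr$alpha1, fh$saen_afternoon - fr$saen_afternoon)
  }, numeric(2)))
  # paired sign test at n = 20: 15+ successes rejects "no effect" (p < 0.05)
  expect_gte(sum(res[, 1] > 0, na.rm = TRUE), 15)
  expect_gte(sum(res[, 2] > 0, na.rm = TRUE), 15)
})

test_that("surveys track severity and respect instrument ranges", {
  cfg <- sim_config(survey_noise_sd = 0)
  lowT <- latent_trajectory(28, NULL, cfg, seed = 1)
  hiT <- lowT; hiT$severity <- 1
  lo <- simulate_surveys(lowT, cfg, seed = 2)
  hi <- simulate_surveys(hiT, cfg, seed = 2)
  expect_true(all(lo$vqids_sr5 < 5) && all(lo$gad7 < 5))
  expect_true(all(hi$vqids_sr5 >= 6) && all(hi$gad7 >= 10))
  # stochastic upward shift with noise on
  cfgN <- sim_config(survey_noise_sd = 1)
  mid <- latent_trajectory(700, NULL, cfgN, seed = 1)
  mid$severity <- 0.6
  sv0 <- simulate_surveys(latent_trajectory(700, NULL, cfgN, seed = 1),
                          cfgN, seed = 5)
  sv1 <- simulate_surveys(mid, cfgN, seed = 6)
  wt <- wilcox.test(sv1$vqids_sr5, sv0$vqids_sr5, alternative = "greater",
                    exact = FALSE)
  expect_lt(wt$p.value, 1e-6)
  expect_true(all(sv1$vqids_sr5 <= 15) && all(sv1$gad7 <= 21))
})

test_that("cohorts respect labels, truncation and the relapse fraction", {
  cfg0 <- sim_config(n_patients = 3, follow_up_days = 180,
                     relapse_fraction = 0, seed = 8)
  coh0 <- simulate_cohort(cfg0)
  for (rec in coh0)
    expect_true(all(rec$visits$label == "non_relapse"))

  cfg1 <- sim_config(n_patients = 4, follow_up_days = 240,
                     relapse_fraction = 1, seed = 9)
  coh1 <- simulate_cohort(cfg1)
  for (rec in coh1) {
    expect_equal(sum(rec$visits$label == "relapse"), 1L)
    expect_equal(rec$visits$label[nrow(rec$visits)], "relapse")  # truncated
    # clean lead-in: first visit is never the relapse
    expect_gte(as.numeric(rec$visits$date[nrow(rec$visits)] - rec$enrollment),
               cfg1$lead_in_clean_days + cfg1$visit_interval_days)
  }
  expect_identical(simulate_cohort(cfg1)[[2]]$minutes$counts,
                   coh1[[2]]$minutes$counts)     # whole-cohort reproducibility

  cfg40 <- sim_config(n_patients = 40, follow_up_days = 180,
                      relapse_fraction = 0.3, seed = 21)
  n_rel <- sum(attr(simulate_cohort(cfg40), "truth")$relapse)
  expect_gte(n_rel, qbinom(0.001, 40, 0.3))
  expect_lte(n_rel, qbinom(0.999, 40, 0.3))

  expect_error(simulate_cohort(sim_config(follow_up_days = 130)),
               "infeasible")
})
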