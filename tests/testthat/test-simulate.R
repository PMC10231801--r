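test_that("default configuration reproduces the study group sizes", {
  sim <- simulate_cohort(sim_config(seed = 21))
  grp <- table(sim$cohort$subjects$genotype_group)
  expect_equal(unname(grp[["positive_symptomatic"]]), 29)
  expect_equal(unname(grp[["positive_presymptomatic"]]), 7)
  expect_equal(unname(grp[["negative"]]), 51)
  expect_equal(max(sim$cohort$visits$visit_index), 3)
})

test_that("generation is reproducible from the seed", {
  a <- simulate_cohort(sim_config(seed = 5))
  b <- simulate_cohort(sim_config(seed = 5))
  c <- simulate_cohort(sim_config(seed = 6))
  expect_identical(a$cohort$observations, b$cohort$observations)
  expect_identical(a$truth$latents, b$truth$latents)
  expect_false(identical(a$cohort$observations, c$cohort$observations))
})

test_that("generated values respect the catalogue invariants", {
  # xdp_cohort() validates ordinal level sets, positivity and integer counts
  # on construction; reaching here means every generated value passed
  sim <- simulate_cohort(sim_config(seed = 31))
  expect_s3_class(sim$cohort, "xdp_cohort")
  # spot-check latents
  lat <- sim$truth$latents
  pos <- lat$genotype_group != "negative"
  expect_true(all(lat$rate[pos] > 0))
  expect_true(all(is.finite(lat$true_onset[pos])))
})

test_that("realized missingness is close to the configured fraction", {
  big <- simulate_cohort(sim_config(n_symptomatic = 150, n_negative = 150,
                                    seed = 41))
  expect_lt(abs(missing_fraction(big$cohort) - 0.09), 0.01)
  none <- simulate_cohort(sim_config(n_symptomatic = 10,
                                     n_presymptomatic = 0, n_negative = 0,
                                     missing_fraction = 0, seed = 42))
  expect_equal(missing_fraction(none$cohort), 0)
})

test_that("reported onset lags true onset non-negatively, by years", {
  sim <- simulate_cohort(sim_config(seed = 51))
  sub <- dplyr::filter(sim$cohort$subjects,
                       genotype_group == "positive_symptomatic")
  lat <- sim$truth$latents[match(sub$subject_id,
                                 sim$truth$latents$subject_id), ]
  lags <- sub$reported_onset - lat$true_onset
  expect_true(all(lags >= -0.01))  # rounding of the stored reported onset
  expect_gt(mean(lags), 4)
  expect_lt(mean(lags), 11)
})

test_that("onset correlates negatively with repeat size at magnitude >= 0.5", {
  big <- simulate_cohort(sim_config(n_symptomatic = 300, seed = 61))
  r <- empirical_onset_repeat_correlation(big$cohort)
  expect_lt(r, -0.5)
})

test_that("onset-repeat correlation vanishes when the slope is zero", {
  cfg <- sim_config(n_symptomatic = 300,
                    onset_model = c(intercept = 32, slope = 0, sd = 5),
                    seed = 62)
  r <- empirical_onset_repeat_correlation(simulate_cohort(cfg)$cohort)
  expect_lt(abs(r), 0.2)
})

test_that("degenerate repeat sizes make the correlation an error", {
  cfg <- sim_config(n_symptomatic = 10, repeat_size_range = c(45L, 45L),
                    seed = 63)
  expect_error(empirical_onset_repeat_correlation(simulate_cohort(cfg)$cohort),
               "zero variance")
  few <- simulate_cohort(sim_config(n_symptomatic = 2, n_presymptomatic = 0,
                                    n_negative = 0, seed = 64))
  expect_error(empirical_onset_repeat_correlation(few$cohort), "at least 3")
})

test_that("severity-increasing ordinal measures worsen after onset on the
           noise-free predictor", {
  sim <- simulate_cohort(sim_config(seed = 71))
  par <- sim$truth$measure_params
  ord <- dplyr::filter(par, value_kind == "ordinal")
  cat <- xdp_catalogue()
  dir <- cat$severity_direction[match(ord$measure_id, cat$measure_id)]
  # expected category value must be non-decreasing (direction +1) or
  # non-increasing (direction -1) in time since onset
  for (j in seq_len(nrow(ord))) {
    ev <- vapply(c(0, 2, 5, 10), function(tau) {
      p <- ordinal_category_probs(ord$alpha[[j]], 0, ord$beta2[j],
                                  ord$ordinal_levels[[j]], age = 40 + tau,
                                  rate = 1, onset = 40)
      sum(p * ord$ordinal_levels[[j]])
    }, numeric(1))
    if (dir[j] == 1) expect_true(all(diff(ev) >= -1e-12))
    else expect_true(all(diff(ev) <= 1e-12))
  }
})

test_that("pre-symptomatic and gene-negative dynamics coincide before onset", {
  # with the onset term inactive, both groups share the same generative law:
  # compare large samples at matched ages for one continuous measure
  cfg <- sim_config(n_symptomatic = 0, n_presymptomatic = 200,
                    n_negative = 200, n_visits = 1, missing_fraction = 0,
                    seed = 81)
  sim <- simulate_cohort(cfg)
  # force matched ages by regenerating observations on a common age grid
  vis <- sim$cohort$visits
  vis$age <- 30
  obs <- simulate_observations(sim$cohort$subjects, vis, sim$truth,
                               sim$cohort$catalogue)
  grp <- sim$cohort$subjects$genotype_group[
    match(obs$subject_id, sim$cohort$subjects$subject_id)]
  x <- log(obs$value[obs$measure_id == "mpt" & grp == "positive_presymptomatic"])
  y <- log(obs$value[obs$measure_id == "mpt" & grp == "negative"])
  expect_gt(stats::ks.test(x, y)$p.value, 0.01)
})

test_that("DDK counts are masked whenever their paired duration is masked", {
  sim <- simulate_cohort(sim_config(missing_fraction = 0.25, seed = 91))
  obs <- sim$cohort$observations
  for (task in c("ba", "da", "ka", "amr")) {
    cnt <- obs[obs$measure_id == paste0("ddk_", task, "_count"), ]
    dur <- obs[obs$measure_id == paste0("ddk_", task, "_secs"), ]
    # every present count has a present duration at the same visit
    expect_true(all(paste(cnt$subject_id, cnt$visit_index) %in%
                      paste(dur$subject_id, dur$visit_index)))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(missing_fraction = 1))
  expect_error(sim_config(n_visits = 0))
  expect_error(sim_config(visit_spacing = -1))
})
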