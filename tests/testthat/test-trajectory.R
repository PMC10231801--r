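test_that("time since onset is the positive part of age minus onset", {
  expect_equal(time_since_onset(45, 40), 5)
  expect_equal(time_since_onset(35, 40), 0)
  expect_equal(time_since_onset(40, 40), 0)
  expect_equal(time_since_onset(c(30, 50), 40), c(0, 10))
})

test_that("ordinal probabilities are a proper distribution", {
  withr::with_seed(41, {
    for (rep in 1:20) {
      K <- sample(3:10, 1)
      alpha <- sort(stats::rnorm(K - 1, 0, 2))
      if (any(diff(alpha) <= 0)) next
      p <- ordinal_category_probs(alpha, stats::rnorm(1, 0, 0.05),
                                  stats::rnorm(1), 0:(K - 1),
                                  age = stats::runif(1, 20, 70),
                                  rate = stats::rlnorm(1),
                                  onset = stats::runif(1, 20, 70))
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p >= -1e-15))
    }
  })
  p0 <- ordinal_category_probs(0, 0, 0, 0:1, age = 50, rate = 1, onset = 40)
  expect_equal(unname(p0), c(0.5, 0.5))
  expect_error(ordinal_category_probs(c(1, 0), 0, 0, 0:2, 50, 1, 40),
               "increasing")
})

test_that("a worsening ordinal measure accumulates mass in the top category", {
  alpha <- c(-1, 0, 1, 2)
  top <- vapply(c(0, 2, 5, 10), function(tau) {
    p <- ordinal_category_probs(alpha, 0, -0.5, 0:4, age = 40 + tau,
                                rate = 1, onset = 40)
    p[5]
  }, numeric(1))
  expect_false(is.unsorted(top))
})

test_that("likelihood families match direct density oracles", {
  withr::with_seed(42, {
    for (rep in 1:30) {
      age <- stats::runif(1, 20, 70)
      rate <- stats::rlnorm(1)
      onset <- stats::runif(1, 20, 70)
      tau <- max(age - onset, 0)
      a <- stats::rnorm(1); b1 <- stats::rnorm(1, 0, 0.05)
      b2 <- stats::rnorm(1); sg <- stats::runif(1, 0.1, 1)
      y <- stats::rlnorm(1, 2, 1)
      # log-normal: density of log(y) with Jacobian, straight from dnorm
      direct <- stats::dnorm(log(y), a + b1 * age + b2 * rate * tau, sg,
                             log = TRUE) - log(y)
      expect_equal(continuous_loglik(a, b1, b2, sg, y, age, rate, onset),
                   direct, tolerance = 1e-10)
      # softplus Poisson mean from plain log1p(exp(.))
      off <- stats::runif(1, 0.5, 3)
      eta <- a + b1 * age + b2 * rate * tau
      expect_equal(count_mean(a, b1, b2, off, age, rate, onset),
                   off * log1p(exp(eta)), tolerance = 1e-10)
    }
  })
})

test_that("count mean handles extreme linear predictors safely", {
  expect_equal(count_mean(0, 0, 0, 1, 40, 1, 50), log(2))
  expect_equal(count_mean(0, 0, 0, 2, 40, 1, 50), 2 * log(2))
  tiny <- count_mean(-50, 0, 0, 1, 40, 1, 50)
  expect_gt(tiny, 0)
  expect_lt(tiny, 1e-20)
  big <- count_mean(800, 0, 0, 1, 40, 1, 50)
  expect_equal(big, 800)  # softplus(x) ~ x without overflow
  expect_error(count_mean(0, 0, 0, 0, 40, 1, 50), "offset")
  expect_error(continuous_loglik(0, 0, 0, 1, -2, 40, 1, 50), "> 0")
})

test_that("progression score is zero before onset and linear after", {
  expect_equal(progression_score(39, 40, 2), 0)
  expect_equal(progression_score(40, 40, 2), 0)
  expect_equal(progression_score(42, 40, 1.5), 3)
  ages <- seq(20, 70, by = 0.5)
  expect_false(is.unsorted(progression_score(ages, 43, 0.8)))
})

test_that("the hierarchical fit recovers latents and satisfies contracts", {
  sim <- recovery_cohort(seed = 2)
  fit <- suppressWarnings(
    fit_trajectory(sim$cohort, measures = small_measure_set(),
                   n_chains = 2, n_adapt = 300, n_burn = 300, n_draws = 300,
                   seed = 1))
  lat <- dplyr::inner_join(fit$latents, sim$truth$latents, by = "subject_id")
  sym <- lat$genotype_group.x == "positive_symptomatic"
  expect_gt(stats::cor(lat$true_onset[sym], lat$onset_mean[sym]), 0.6)
  expect_gt(stats::cor(lat$rate[sym], lat$rate_mean[sym]), 0.3)
  # intervals contain their means
  expect_true(all(fit$latents$onset_lo <= fit$latents$onset_mean &
                    fit$latents$onset_mean <= fit$latents$onset_hi))
  expect_true(all(fit$latents$rate_lo <= fit$latents$rate_mean &
                    fit$latents$rate_mean <= fit$latents$rate_hi))
  expect_true(all(fit$latents$rate_mean > 0))
  # rate scale anchored: geometric mean within a factor of 2 of 1
  gm <- exp(mean(log(fit$latents$rate_mean[sym])))
  expect_gt(gm, 0.5)
  expect_lt(gm, 2)

  # tidy/glance accessors
  td <- tidy(fit)
  expect_setequal(unique(td$term), c("onset", "rate"))
  expect_equal(nrow(td), 2 * nrow(fit$latents))
  gl <- glance(fit)
  expect_equal(gl$n_measures, length(small_measure_set()))

  # progression summary and measure trajectory predictions
  ps <- progression_summary(fit, sim$cohort)
  expect_true(all(ps$progression >= 0))
  tr <- predict_measure_trajectory(fit, "bfm_dis_feeding",
                                   ages = seq(30, 60, by = 1),
                                   onset = 40, rate = 1)
  post <- tr$expected[tr$age >= 40]
  expect_false(is.unsorted(post))  # worsening after onset
  neg <- predict_measure_trajectory(fit, "bfm_dis_feeding",
                                    ages = c(30, 45, 60))
  expect_equal(nrow(neg), 3)
  expect_error(predict_measure_trajectory(fit, "not_fitted", 40), "fitted")

  # association checks run and include the onset-repeat correlation
  at <- association_tests(fit, sim$cohort)
  expect_true("onset_vs_repeat_size" %in% at$check)
  r_onset <- at$estimate[at$check == "onset_vs_repeat_size"]
  expect_lt(r_onset, 0)
})

test_that("fixing onsets leaves them untouched in the output", {
  sim <- simulate_cohort(sim_config(n_symptomatic = 8, n_presymptomatic = 0,
                                    n_negative = 4, seed = 3))
  lat <- sim$truth$latents
  pos <- lat$genotype_group != "negative"
  onsets <- stats::setNames(lat$true_onset[pos], lat$subject_id[pos])
  fit <- suppressWarnings(
    fit_trajectory(sim$cohort, measures = c("updrs1_01", "updrs1_02", "mpt"),
                   n_chains = 1, n_adapt = 150, n_burn = 150, n_draws = 150,
                   fixed_onsets = onsets, seed = 4))
  expect_equal(stats::setNames(fit$latents$onset_mean,
                               fit$latents$subject_id),
               onsets[fit$latents$subject_id], tolerance = 1e-12)
  expect_equal(fit$latents$onset_sd, rep(0, nrow(fit$latents)))
})
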