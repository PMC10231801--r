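test_that("severity orientation negates exactly the direction -1 variables", {
  x <- c(1.5, -2, 0)
  expect_equal(orient_severity(x, -1L), -x)
  expect_equal(orient_severity(x, 1L), x)
  expect_equal(orient_severity(orient_severity(x, -1L), -1L), x)  # involution
})

test_that("the correlation data matrix has 102 oriented columns", {
  sim <- simulate_cohort(sim_config(seed = 22))
  cd <- correlation_data(sim$cohort)
  expect_equal(ncol(cd$X), 102)
  expect_equal(nrow(cd$X), 29 * 4)
  # subject-level constants replicated across visits
  rs <- cd$X[, "repeat_size"]
  per_sub <- split(rs, cd$rows$subject_id)
  expect_true(all(vapply(per_sub, function(v) length(unique(v)) == 1,
                         logical(1))))
  # flip set: CPIB total, the DDK measures, lip/tongue, MPT, weight, height
  expect_true(all(c("cpib_total", "lip_strength", "tongue_strength", "mpt",
                    "weight", "height") %in% cd$flipped))
  expect_false("repeat_size" %in% cd$flipped)
})

test_that("duplicated variables are estimated as near-perfectly correlated", {
  withr::with_seed(23, {
    x <- stats::rnorm(120)
    X <- cbind(a = x, b = x + stats::rnorm(120, sd = 1e-3),
               c = stats::rnorm(120))
  })
  est <- estimate_correlation_matrix(X, n_draws = 300, n_warmup = 100,
                                     transform = "none", seed = 1)
  expect_gte(est$mean["a", "b"], 0.99)
  expect_lt(abs(est$mean["a", "c"]), 0.3)
})

test_that("known correlation structure is recovered under MCAR missingness", {
  withr::with_seed(24, {
    p <- 12; n <- 250
    R <- random_correlation(p, seed = 24)
    X <- matrix(stats::rnorm(n * p), n) %*% chol(R)
    colnames(X) <- paste0("v", seq_len(p))
    X[stats::runif(n * p) < 0.09] <- NA
  })
  est <- estimate_correlation_matrix(X, n_draws = 400, n_warmup = 150,
                                     transform = "none", seed = 2)
  err <- abs(est$mean - R)[upper.tri(R)]
  expect_gt(mean(err < 0.15), 0.9)
  expect_lt(mean(err), 0.08)
})

test_that("returned matrices are valid correlation matrices", {
  sim <- simulate_cohort(sim_config(n_symptomatic = 12,
                                    n_presymptomatic = 0, n_negative = 0,
                                    missing_fraction = 0.25, seed = 25))
  est <- suppressWarnings(
    estimate_correlation(sim$cohort, n_draws = 150, n_warmup = 80,
                         n_chains = 1, seed = 3))
  R <- est$mean
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, nrow(R)))
  expect_true(all(R >= -1 - 1e-12 & R <= 1 + 1e-12))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
})

test_that("zero-variance variables are dropped with a warning", {
  withr::with_seed(26, {
    X <- cbind(a = stats::rnorm(80), b = rep(2, 80), c = stats::rnorm(80))
  })
  expect_warning(
    est <- estimate_correlation_matrix(X, n_draws = 100, n_warmup = 50,
                                       transform = "none", seed = 4),
    "zero-variance")
  expect_equal(est$dropped, "b")
  expect_equal(est$variables, c("a", "c"))
})

test_that("independent variables give small correlations covering zero", {
  covs <- vapply(1:3, function(s) {
    withr::with_seed(200 + s, {
      X <- matrix(stats::rnorm(200 * 8), 200)
      colnames(X) <- paste0("v", 1:8)
    })
    est <- estimate_correlation_matrix(X, n_draws = 300, n_warmup = 100,
                                       transform = "none", seed = s)
    ut <- upper.tri(est$mean)
    expect_lt(mean(abs(est$mean[ut])), 0.12)
    mean(abs(est$mean[ut]) <= est$half_width[ut])
  }, numeric(1))
  expect_gte(mean(covs), 0.85)  # nominal 95%, Monte-Carlo slack
})

test_that("hierarchical clustering merges correlated blocks first", {
  # planted block-diagonal structure
  R <- diag(6)
  R[1:3, 1:3] <- 0.9; R[4:6, 4:6] <- 0.85; diag(R) <- 1
  dimnames(R) <- list(paste0("v", 1:6), paste0("v", 1:6))
  est <- structure(list(mean = R, half_width = R * 0,
                        variables = rownames(R), flipped = character(0),
                        dropped = character(0),
                        diagnostics = list(max_rhat = 1, n_draws = 0,
                                           n_chains = 0, n_rows = 0)),
                   class = "xdp_correlation")
  cl <- cluster_variables(est)
  grp <- cutree(cl$hclust, k = 2)
  expect_equal(length(unique(grp[1:3])), 1)
  expect_equal(length(unique(grp[4:6])), 1)
  expect_false(grp[1] == grp[4])
  # single variable: trivial tree
  est1 <- est; est1$mean <- R[1, 1, drop = FALSE]
  expect_equal(cluster_variables(est1)$order, "v1")
})

test_that("rank inverse-normal transform is monotone and handles ties", {
  x <- c(3, 1, 4, 1, 5, NA, 9)
  z <- xdprogress:::inverse_normal_transform(x)
  expect_true(is.na(z[6]))
  ok <- !is.na(x)
  expect_equal(order(z[ok]), order(rank(x[ok], ties.method = "first")))
  expect_equal(z[2], z[4])  # tied inputs share the average-rank score
})
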