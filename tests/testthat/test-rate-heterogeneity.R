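# helper: build an xdp_rate_profiles object directly from a rate matrix
profiles_from_matrix <- function(m, categories = colnames(m)) {
  rates <- tidyr::pivot_longer(
    tibble::as_tibble(m, rownames = "subject_id"),
    cols = -dplyr::all_of("subject_id"),
    names_to = "category", values_to = "rate_mean") |>
    dplyr::mutate(rate_lo = .data$rate_mean * 0.8,
                  rate_hi = .data$rate_mean * 1.2,
                  rate_sd = .data$rate_mean * 0.1)
  structure(list(rates = rates, categories = categories,
                 onsets = NULL),
            class = "xdp_rate_profiles")
}

test_that("rate distances match hand-computed Euclidean values", {
  m <- rbind(a = rep(1, 13), b = c(rep(1, 12), 3))
  colnames(m) <- paste0("cat", 1:13)
  d <- rate_distance_matrix(profiles_from_matrix(m))
  expect_equal(d["a", "b"], 2)
  expect_equal(unname(diag(d)), c(0, 0))
  expect_equal(d, t(d))
})

test_that("rate distances satisfy the metric axioms", {
  withr::with_seed(55, {
    m <- matrix(stats::rlnorm(5 * 13), 5,
                dimnames = list(paste0("s", 1:5), paste0("c", 1:13)))
  })
  d <- rate_distance_matrix(profiles_from_matrix(m))
  expect_true(all(d >= 0))
  expect_equal(unname(diag(d)), rep(0, 5))
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("clustering recovers a planted two-group structure", {
  withr::with_seed(56, {
    grp1 <- matrix(stats::rnorm(6 * 13, mean = 1, sd = 0.05), 6)
    grp2 <- matrix(stats::rnorm(6 * 13, mean = 3, sd = 0.05), 6)
    m <- rbind(grp1, grp2)
    dimnames(m) <- list(paste0("s", 1:12), paste0("c", 1:13))
  })
  prof <- profiles_from_matrix(m)
  cl <- cluster_subjects(rate_distance_matrix(prof), prof)
  groups <- stats::cutree(cl$hclust, k = 2)
  expect_equal(length(unique(groups[1:6])), 1)
  expect_equal(length(unique(groups[7:12])), 1)
  expect_false(groups[1] == groups[7])
  # group 2 subjects have the higher average rates
  expect_true(all(cl$by_average_rate$subject_id[1:6] %in% paste0("s", 7:12)))
})

test_that("an extreme outlier joins the dendrogram last", {
  withr::with_seed(57, {
    m <- matrix(stats::rnorm(6 * 4, mean = 1, sd = 0.05), 6,
                dimnames = list(paste0("s", 1:6), paste0("c", 1:4)))
    m[6, ] <- 10
  })
  prof <- profiles_from_matrix(m)
  cl <- cluster_subjects(rate_distance_matrix(prof), prof)
  # the outlier is merged at the final (tallest) join
  expect_equal(cl$hclust$merge[nrow(cl$hclust$merge), ][1], -6)
})

test_that("average-rate ties break deterministically by subject id", {
  m <- matrix(1, 3, 4, dimnames = list(c("b", "a", "c"), paste0("k", 1:4)))
  prof <- profiles_from_matrix(m)
  cl <- cluster_subjects(rate_distance_matrix(prof), prof)
  expect_equal(cl$by_average_rate$subject_id, c("a", "b", "c"))
  expect_error(cluster_subjects(matrix(0, 1, 1)), "at least 2")
})

test_that("scheme validation enforces disjoint categories", {
  sim <- simulate_cohort(sim_config(n_symptomatic = 4, n_presymptomatic = 0,
                                    n_negative = 0, seed = 58))
  on <- stats::setNames(sim$truth$latents$true_onset,
                        sim$truth$latents$subject_id)
  bad <- tibble::tibble(measure_id = c("mpt", "mpt"),
                        category = c("a", "b"))
  expect_error(fit_category_rates(sim$cohort, on, scheme = bad),
               "at most one category")
  one <- tibble::tibble(measure_id = "mpt", category = "a")
  expect_error(fit_category_rates(sim$cohort, on, scheme = one),
               "at least 2")
})

test_that("per-category refits keep onsets fixed and recover planted
           heterogeneity", {
  # four small categories; one subject's rate doubled in one category
  cfg <- sim_config(n_symptomatic = 12, n_presymptomatic = 0,
                    n_negative = 6, missing_fraction = 0, seed = 59)
  sim <- simulate_cohort(cfg)
  scheme <- tibble::tibble(
    measure_id = c(sprintf("updrs1_%02d", 1:4),
                   sprintf("updrs2_%02d", 1:4),
                   c("bfm_dis_speech", "bfm_dis_feeding", "bfm_dis_dressing",
                     "bfm_dis_hygiene"),
                   c("mpt", "tongue_strength", "swallow_duration",
                     "lip_strength")),
    category = rep(c("nonmotor", "daily", "disability", "oromotor"),
                   each = 4))
  # plant: first symptomatic subject progresses twice as fast in "oromotor"
  target <- sim$truth$latents$subject_id[1]
  truth <- sim$truth
  cat_map <- stats::setNames(scheme$category, scheme$measure_id)
  # rebuild category_rates on the scheme's categories
  lat_pos <- dplyr::filter(truth$latents, genotype_group != "negative")
  truth$category_rates <- tidyr::crossing(
    subject_id = lat_pos$subject_id,
    category = unique(scheme$category)) |>
    dplyr::left_join(dplyr::select(lat_pos, "subject_id", rate0 = "rate"),
                     by = "subject_id") |>
    dplyr::mutate(rate = ifelse(.data$subject_id == target &
                                  .data$category == "oromotor",
                                2 * .data$rate0, .data$rate0)) |>
    dplyr::select("subject_id", "category", "rate")
  cat2 <- sim$cohort$catalogue
  cat2$category <- unname(cat_map[cat2$measure_id])
  truth$measure_params <- dplyr::filter(
    truth$measure_params, .data$measure_id %in% scheme$measure_id)
  obs <- simulate_observations(sim$cohort$subjects, sim$cohort$visits,
                               truth, cat2)
  co <- xdp_cohort(sim$cohort$subjects, sim$cohort$visits, obs,
                   sim$cohort$catalogue)
  onsets <- stats::setNames(lat_pos$true_onset, lat_pos$subject_id)
  prof <- suppressWarnings(
    fit_category_rates(co, onsets, scheme = scheme, n_chains = 1,
                       n_adapt = 200, n_burn = 200, n_draws = 300,
                       seed = 60))
  expect_setequal(prof$categories,
                  c("nonmotor", "daily", "disability", "oromotor"))
  # onsets never altered
  expect_identical(prof$onsets, onsets)
  # the planted category ranks highest within the planted subject
  mine <- dplyr::filter(prof$rates, .data$subject_id == target)
  expect_equal(mine$category[which.max(mine$rate_mean)], "oromotor")
})
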