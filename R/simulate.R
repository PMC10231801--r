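#' Simulation configuration for synthetic XDP cohorts
#'
#' Collects every knob of the synthetic-cohort generator. The defaults emulate
#' the study cohort: 29 symptomatic gene-positive, 7 pre-symptomatic
#' gene-positive and 51 gene-negative men, 4 visits at 6-month intervals,
#' roughly 9 percent of entries missing completely at random, reported onset
#' lagging true onset by about 5-10 years, and true onset negatively
#' correlated with SVA repeat size.
#'
#' @param n_symptomatic,n_presymptomatic,n_negative group sizes.
#' @param n_visits number of visits per subject (first visit = enrollment).
#' @param visit_spacing years between consecutive visits.
#' @param onset_model `c(intercept, slope, sd)` of the true-onset law
#'   `Onset ~ Normal(intercept + slope * repeat_size, sd)` (years). The
#'   default gives reported onsets centred near age 39 and an onset versus
#'   repeat-size correlation of about -0.7.
#' @param repeat_size_range inclusive integer range of SVA hexamer counts.
#' @param report_lag_model `c(mean, sd)` of the non-negative (truncated
#'   normal) lag of reported onset behind true onset, in years.
#' @param rate_model log-scale standard deviation of the per-subject rate of
#'   progression `Rate_i ~ LogNormal(0, rate_model)`.
#' @param category_rate_sd log-scale standard deviation of per-category rates
#'   around the subject's global rate; 0 (the default) gives every category
#'   the subject's global rate, matching the global trajectory model's
#'   single-rate assumption.
#' @param beta2_scale multiplier applied to every measure's progression
#'   coefficient; set to 0 to generate null cohorts with no progression
#'   signal anywhere.
#' @param missing_fraction proportion of observation entries masked missing
#'   completely at random (in `[0, 1)`).
#' @param seed integer seed; every stochastic draw of the generator flows
#'   from it.
#' @return A list of class `xdp_sim_config`.
#' @export
sim_config <- function(n_symptomatic = 29, n_presymptomatic = 7,
                       n_negative = 51, n_visits = 4, visit_spacing = 0.5,
                       onset_model = c(intercept = 98, slope = -1.5, sd = 5),
                       repeat_size_range = c(36L, 52L),
                       report_lag_model = c(mean = 7.5, sd = 3),
                       rate_model = 0.5, category_rate_sd = 0,
                       beta2_scale = 1, missing_fraction = 0.09, seed = 1L) {
  cfg <- list(
    n_symptomatic = n_symptomatic, n_presymptomatic = n_presymptomatic,
    n_negative = n_negative, n_visits = n_visits,
    visit_spacing = visit_spacing, onset_model = onset_model,
    repeat_size_range = repeat_size_range,
    report_lag_model = report_lag_model, rate_model = rate_model,
    category_rate_sd = category_rate_sd, beta2_scale = beta2_scale,
    missing_fraction = missing_fraction, seed = seed
  )
  stopifnot(
    n_symptomatic >= 0, n_presymptomatic >= 0, n_negative >= 0,
    n_visits >= 1, visit_spacing > 0,
    missing_fraction >= 0, missing_fraction < 1,
    length(onset_model) == 3, length(repeat_size_range) == 2,
    rate_model >= 0, category_rate_sd >= 0
  )
  structure(cfg, class = "xdp_sim_config")
}

rtnorm_pos <- function(n, mean, sd) {
  # draw-by-rejection truncated normal on [0, Inf); vectorized, exact
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
  }
  out
}

softplus <- function(x) {
  # overflow-safe log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

draw_measure_params <- function(catalogue, beta2_scale) {
  core <- dplyr::filter(catalogue, !.data$auxiliary | .data$measure_id %in%
                          c("weight", "bmi"))
  n <- nrow(core)
  params <- vector("list", n)
  for (i in seq_len(n)) {
    kind <- core$value_kind[i]
    dir <- core$severity_direction[i]
    id <- core$measure_id[i]
    if (kind == "ordinal") {
      K <- length(core$ordinal_levels[[i]])
      beta1 <- stats::rnorm(1, -0.01, 0.01)
      beta2 <- -dir * stats::rlnorm(1, log(0.4), 0.7) * beta2_scale
      a1 <- stats::rnorm(1, 2, 0.8)
      alpha_c <- a1 + c(0, cumsum(0.3 + abs(stats::rnorm(K - 2, 0.6, 0.3))))
      alpha <- alpha_c - beta1 * 40
      params[[i]] <- list(alpha = alpha, beta1 = beta1, beta2 = beta2,
                          sigma = NA_real_)
    } else if (kind == "positive_real") {
      if (id == "weight") {
        alpha_c <- log(60) + stats::rnorm(1, 0, 0.05)
        beta1 <- stats::rnorm(1, -0.002, 0.001)
        beta2 <- -abs(stats::rnorm(1, 0.05, 0.01)) * beta2_scale
        sigma <- 0.12
      } else {
        alpha_c <- stats::runif(1, 1.0, 3.5)
        beta1 <- stats::rnorm(1, -0.003, 0.003)
        beta2 <- dir * stats::rlnorm(1, log(0.04), 0.8) * beta2_scale
        sigma <- stats::runif(1, 0.15, 0.35)
      }
      params[[i]] <- list(alpha = alpha_c - beta1 * 40, beta1 = beta1,
                          beta2 = beta2, sigma = sigma)
    } else { # count
      if (id == "lip_strength") {
        alpha_c <- stats::runif(1, 15, 25)
        beta1 <- stats::rnorm(1, -0.05, 0.03)
        beta2 <- dir * stats::rlnorm(1, log(0.8), 0.5) * beta2_scale
      } else {
        alpha_c <- stats::runif(1, 2, 6)
        beta1 <- stats::rnorm(1, -0.01, 0.01)
        beta2 <- dir * stats::rlnorm(1, log(0.12), 0.6) * beta2_scale
      }
      params[[i]] <- list(alpha = alpha_c - beta1 * 40, beta1 = beta1,
                          beta2 = beta2, sigma = NA_real_)
    }
  }
  tibble::tibble(
    measure_id = core$measure_id,
    value_kind = core$value_kind,
    alpha = purrr::map(params, "alpha"),
    beta1 = purrr::map_dbl(params, "beta1"),
    beta2 = purrr::map_dbl(params, "beta2"),
    sigma = purrr::map_dbl(params, "sigma"),
    offset_link = core$offset_link,
    ordinal_levels = core$ordinal_levels
  )
}

#' Generate observation records from ground truth
#'
#' Draws one observation per subject-visit-measure from the generative law of
#' the trajectory model: cumulative-logit for ordinal measures, log-normal for
#' positive reals, Poisson with a softplus mean (and the paired DDK duration
#' as exposure offset) for counts. The linear predictor for measure j is
#' `alpha_j(+k) + beta_j1 * Age + beta_j2 * Rate_ig * max(Age - Onset, 0)`;
#' gene-negative subjects and pre-onset visits contribute through the age
#' term only. BMI is derived from the realized weight and the subject's
#' height. Missing-completely-at-random masking is then applied at
#' `missing_fraction`; a DDK count is masked whenever its paired duration is
#' masked (the offset is unavailable), and BMI whenever weight is.
#'
#' @param subjects,visits cohort tables ([xdp_cohort()]).
#' @param truth a ground-truth list as produced by [simulate_cohort()]
#'   (`latents`, `category_rates`, `measure_params`).
#' @param catalogue a catalogue tibble.
#' @param missing_fraction MCAR masking proportion.
#' @return An observations tibble (masked rows are absent).
#' @export
simulate_observations <- function(subjects, visits, truth, catalogue,
                                  missing_fraction = 0) {
  params <- truth$measure_params
  lat <- truth$latents
  crates <- truth$category_rates
  scheme <- dplyr::select(catalogue, "measure_id", "category")

  df <- tidyr::crossing(
    dplyr::select(visits, "subject_id", "visit_index", "age"),
    measure_id = params$measure_id
  ) |>
    dplyr::left_join(scheme, by = "measure_id") |>
    dplyr::left_join(dplyr::select(lat, "subject_id", "true_onset"),
                     by = "subject_id") |>
    dplyr::left_join(crates, by = c("subject_id", "category"))
  # gene-negative subjects carry no rate; their progression term is zero
  df$rate[is.na(df$rate)] <- 0
  df$tau <- pmax(df$age - df$true_onset, 0)
  df$tau[is.na(df$tau)] <- 0

  pidx <- match(df$measure_id, params$measure_id)
  df$kind <- params$value_kind[pidx]
  df$beta1 <- params$beta1[pidx]
  df$beta2 <- params$beta2[pidx]
  df$sigma <- params$sigma[pidx]
  df$prog <- df$beta2 * df$rate * df$tau

  value <- numeric(nrow(df))
  for (j in seq_len(nrow(params))) {
    rows <- which(pidx == j)
    if (length(rows) == 0) next
    kind <- params$value_kind[j]
    eta0 <- params$beta1[j] * df$age[rows] + df$prog[rows]
    if (kind == "ordinal") {
      alpha <- params$alpha[[j]]
      levels <- params$ordinal_levels[[j]]
      K <- length(levels)
      q <- stats::plogis(outer(eta0, alpha, "+"))  # n x (K-1) cumulative
      p <- cbind(q, 1) - cbind(0, q)
      u <- stats::runif(length(rows))
      ck <- max.col(u < t(apply(p, 1, cumsum)), ties.method = "first")
      value[rows] <- levels[ck]
    } else if (kind == "positive_real") {
      mu <- params$alpha[[j]] + eta0
      value[rows] <- stats::rlnorm(length(rows), mu, params$sigma[j])
    } else {
      value[rows] <- NA_real_  # filled after durations exist
    }
  }
  df$value <- value

  # counts need their offsets: unit for lip strength, paired DDK duration
  for (j in which(params$value_kind == "count")) {
    rows <- which(pidx == j)
    link <- params$offset_link[j]
    if (is.na(link) || link == "unit") {
      off <- rep(1, length(rows))
    } else {
      dur <- df[df$measure_id == link, c("subject_id", "visit_index", "value")]
      key <- paste(df$subject_id[rows], df$visit_index[rows])
      off <- dur$value[match(key, paste(dur$subject_id, dur$visit_index))]
    }
    eta <- params$alpha[[j]] + params$beta1[j] * df$age[rows] + df$prog[rows]
    df$value[rows] <- stats::rpois(length(rows), off * softplus(eta))
  }

  # BMI derives from weight and height
  if ("bmi" %in% params$measure_id) {
    w <- df[df$measure_id == "weight", c("subject_id", "visit_index", "value")]
    rows <- which(df$measure_id == "bmi")
    key <- paste(df$subject_id[rows], df$visit_index[rows])
    wv <- w$value[match(key, paste(w$subject_id, w$visit_index))]
    hv <- subjects$height[match(df$subject_id[rows], subjects$subject_id)]
    df$value[rows] <- wv / (hv / 100)^2
  }

  if (missing_fraction > 0) {
    df$masked <- stats::runif(nrow(df)) < missing_fraction
    # propagate: DDK count masked when its duration is; BMI when weight is
    mkey <- function(ids) paste(df$subject_id, df$visit_index, ids)
    for (j in which(params$value_kind == "count")) {
      link <- params$offset_link[j]
      if (!is.na(link) && link != "unit") {
        here <- df$measure_id == params$measure_id[j]
        dur_masked <- df$masked[match(
          paste(df$subject_id[here], df$visit_index[here], link),
          paste(df$subject_id, df$visit_index, df$measure_id))]
        df$masked[here] <- df$masked[here] | dur_masked
      }
    }
    if (all(c("bmi", "weight") %in% params$measure_id)) {
      here <- df$measure_id == "bmi"
      w_masked <- df$masked[match(
        paste(df$subject_id[here], df$visit_index[here], "weight"),
        paste(df$subject_id, df$visit_index, df$measure_id))]
      df$masked[here] <- df$masked[here] | w_masked
    }
    df <- dplyr::filter(df, !.data$masked)
  }
  dplyr::select(df, "subject_id", "visit_index", "measure_id", "value") |>
    dplyr::arrange(.data$subject_id, .data$visit_index, .data$measure_id)
}

#' Simulate a synthetic XDP cohort with ground truth
#'
#' Draws a full synthetic cohort from the generative version of the symptom
#' trajectory model: SVA repeat sizes; true onsets decreasing in repeat size;
#' reported onsets lagging true onsets by a non-negative truncated-normal lag;
#' log-normal per-subject rates of progression (optionally perturbed per
#' category); enrollment ages anchored so that symptomatic subjects have
#' a plausible disease duration at entry; and every measure generated from
#' its likelihood family. Missing-completely-at-random masking is applied at
#' the configured fraction. The returned ground truth carries every latent
#' the downstream analyses try to recover.
#'
#' @param config an [sim_config()] object.
#' @param catalogue a catalogue tibble ([xdp_catalogue()]).
#' @return A list with elements `cohort` (an [xdp_cohort()]) and `truth`
#'   (list: `latents`, `category_rates`, `measure_params`).
#' @examples
#' sim <- simulate_cohort(sim_config(seed = 7))
#' sim$cohort
#' @export
simulate_cohort <- function(config = sim_config(), catalogue = xdp_catalogue()) {
  stopifnot(inherits(config, "xdp_sim_config"))
  withr::with_seed(config$seed, {
    n_sym <- config$n_symptomatic
    n_pre <- config$n_presymptomatic
    n_neg <- config$n_negative
    n_pos <- n_sym + n_pre
    n_all <- n_pos + n_neg

    group <- rep(c("positive_symptomatic", "positive_presymptomatic",
                   "negative"), c(n_sym, n_pre, n_neg))
    # family letters: positives drawn from a smaller pool so siblings occur
    fam_pool <- make.unique(c(LETTERS, paste0(LETTERS, "A")))
    n_fam <- max(1, ceiling(n_pos * 0.7))
    fam_pos <- if (n_pos > 0) sample(fam_pool[seq_len(n_fam)], n_pos,
                                     replace = TRUE) else character(0)
    fam_neg <- if (n_neg > 0) paste0("N", seq_len(n_neg)) else character(0)
    family_id <- c(fam_pos, fam_neg)
    subject_id <- paste0(seq_len(n_all),
                         c(fam_pos, rep("N", n_neg)))

    rep_vals <- seq(config$repeat_size_range[1], config$repeat_size_range[2])
    repeat_size <- c(
      rep_vals[sample.int(length(rep_vals), n_pos, replace = TRUE)],
      rep(NA_integer_, n_neg))
    om <- config$onset_model
    true_onset <- c(
      stats::rnorm(n_pos, om[1] + om[2] * repeat_size[seq_len(n_pos)], om[3]),
      rep(NA_real_, n_neg))
    lag <- rtnorm_pos(n_pos, config$report_lag_model[1],
                      config$report_lag_model[2])
    reported_all <- true_onset[seq_len(n_pos)] + lag

    age0 <- numeric(n_all)
    is_sym <- group == "positive_symptomatic"
    is_pre <- group == "positive_presymptomatic"
    # symptomatic: enrolled some years after reported onset (duration ~ 4 y)
    age0[is_sym] <- reported_all[which(is_sym)] +
      stats::rgamma(n_sym, shape = 4, rate = 1)
    # pre-symptomatic: enrolled young, before their (future) true onset
    a_pre <- pmax(stats::rnorm(n_pre, 29, 5), 18)
    age0[is_pre] <- a_pre
    pre_idx <- which(is_pre)
    true_onset[pre_idx] <- pmax(true_onset[pre_idx],
                                a_pre + stats::rexp(n_pre, 1 / 4) + 0.5)
    age0[group == "negative"] <- pmax(stats::rnorm(n_neg, 36, 12.5), 18)

    reported_onset <- rep(NA_real_, n_all)
    reported_onset[is_sym] <- reported_all[which(is_sym)]

    rate <- c(stats::rlnorm(n_pos, 0, config$rate_model), rep(NA_real_, n_neg))
    height <- stats::rnorm(n_all, 162, 7)
    initial_symptom <- ifelse(
      is_sym, sample(c("dystonia", "parkinsonism"), n_all, replace = TRUE,
                     prob = c(23, 6)), "none")

    subjects <- tibble::tibble(
      subject_id = subject_id, genotype_group = group,
      reported_onset = round(reported_onset, 2),
      repeat_size = as.numeric(repeat_size), family_id = family_id,
      initial_symptom = initial_symptom, height = round(height, 1)
    )
    visits <- tidyr::crossing(subject_id = subject_id,
                              visit_index = seq_len(config$n_visits) - 1L) |>
      dplyr::left_join(tibble::tibble(subject_id = subject_id, age0 = age0),
                       by = "subject_id") |>
      dplyr::mutate(age = round(.data$age0 + .data$visit_index *
                                  config$visit_spacing +
                                  stats::runif(dplyr::n(), 0, 0.06), 3)) |>
      dplyr::select("subject_id", "visit_index", "age")

    categories <- unique(stats::na.omit(catalogue$category))
    pos_ids <- subject_id[seq_len(n_pos)]
    category_rates <- tidyr::crossing(subject_id = pos_ids,
                                      category = categories) |>
      dplyr::left_join(tibble::tibble(subject_id = pos_ids,
                                      global = rate[seq_len(n_pos)]),
                       by = "subject_id") |>
      dplyr::mutate(rate = .data$global *
                      exp(stats::rnorm(dplyr::n(), 0,
                                       config$category_rate_sd))) |>
      dplyr::select("subject_id", "category", "rate")

    measure_params <- draw_measure_params(catalogue, config$beta2_scale)
    latents <- tibble::tibble(
      subject_id = subject_id, genotype_group = group,
      true_onset = true_onset, rate = rate, enrollment_age = age0
    )
    truth <- list(latents = latents, category_rates = category_rates,
                  measure_params = measure_params)

    observations <- simulate_observations(subjects, visits, truth, catalogue,
                                          config$missing_fraction)
    cohort <- xdp_cohort(subjects, visits, observations, catalogue)
    list(cohort = cohort, truth = truth)
  })
}

#' Realized missing fraction of a cohort
#'
#' Fraction of the full subject x visit x measure grid (the 107 modelled
#' measures plus weight and BMI) with no recorded value.
#'
#' @param cohort an `xdp_cohort`.
#' @return A proportion in `[0, 1]`.
#' @export
missing_fraction <- function(cohort) {
  ids <- cohort$catalogue$measure_id
  ids <- setdiff(ids, "height")
  total <- nrow(cohort$visits) * length(ids)
  seen <- sum(cohort$observations$measure_id %in% ids &
                !is.na(cohort$observations$value))
  1 - seen / total
}

#' Correlation between reported onset and SVA repeat size
#'
#' Diagnostic for generator calibration and a basic association check:
#' the sample (Pearson) correlation between reported age at onset and repeat
#' size over symptomatic gene-positive subjects with both fields present.
#'
#' @param cohort an `xdp_cohort`.
#' @return A single correlation coefficient.
#' @export
empirical_onset_repeat_correlation <- function(cohort) {
  sub <- dplyr::filter(cohort$subjects,
                       .data$genotype_group == "positive_symptomatic",
                       !is.na(.data$reported_onset), !is.na(.data$repeat_size))
  if (nrow(sub) < 3) {
    stop("need at least 3 symptomatic subjects with onset and repeat size")
  }
  if (stats::sd(sub$repeat_size) == 0 || stats::sd(sub$reported_onset) == 0) {
    stop("zero variance in onset or repeat size; correlation undefined")
  }
  stats::cor(sub$reported_onset, sub$repeat_size)
}
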