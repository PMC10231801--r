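#' Per-category rates of progression with onsets held fixed
#'
#' Refits the symptom-trajectory model independently to each pre-defined
#' category of measures, holding every gene-positive subject's age at onset
#' fixed at the value estimated by the global fit (a common time realignment
#' across categories). Each refit yields a per-subject, per-category rate of
#' progression `Rate_ig`; together these form each subject's rate profile.
#' BMI is included as its own category (modelled, like the other positive
#' reals, with log-normal regression) even though it is excluded from the
#' global model. A category with no observed data leaves its rates at the
#' prior, with a warning.
#'
#' @param cohort an `xdp_cohort`.
#' @param fixed_onsets named numeric vector of onset ages for every
#'   gene-positive subject (typically `fit$latents$onset_mean` from the
#'   global [fit_trajectory()], named by subject id).
#' @param scheme a `measure_id` / `category` tibble
#'   ([default_category_scheme()]); needs at least two categories.
#' @param priors a [trajectory_priors()] list.
#' @param n_chains,n_adapt,n_burn,n_draws MCMC settings per category refit.
#' @param seed integer seed; category g uses `seed + g`.
#' @param quiet suppress JAGS output.
#' @return An object of class `xdp_rate_profiles`: `rates` (tibble
#'   `subject_id`, `category`, `rate_mean`, `rate_lo`, `rate_hi`, `rate_sd`),
#'   `categories`, `onsets` (the fixed onsets used).
#' @export
fit_category_rates <- function(cohort, fixed_onsets,
                               scheme = default_category_scheme(cohort$catalogue),
                               priors = trajectory_priors(), n_chains = 2,
                               n_adapt = 300, n_burn = 300, n_draws = 400,
                               seed = 1L, quiet = TRUE) {
  validate_cohort(cohort)
  categories <- sort(unique(scheme$category))
  if (length(categories) < 2) stop("scheme must define at least 2 categories")
  if (anyDuplicated(scheme$measure_id)) {
    stop("each measure may belong to at most one category")
  }
  rates <- vector("list", length(categories))
  for (g in seq_along(categories)) {
    cat_measures <- scheme$measure_id[scheme$category == categories[g]]
    n_obs <- sum(cohort$observations$measure_id %in% cat_measures &
                   !is.na(cohort$observations$value))
    if (n_obs == 0) {
      warning("category '", categories[g],
              "' has no observed data; rates revert to the prior")
    }
    fit_g <- fit_trajectory(
      cohort, measures = cat_measures, priors = priors,
      n_chains = n_chains, n_adapt = n_adapt, n_burn = n_burn,
      n_draws = n_draws, fixed_onsets = fixed_onsets,
      seed = seed + g, quiet = quiet)
    rates[[g]] <- fit_g$latents |>
      dplyr::transmute(.data$subject_id, category = categories[g],
                       .data$rate_mean, .data$rate_lo, .data$rate_hi,
                       .data$rate_sd)
  }
  structure(
    list(rates = dplyr::bind_rows(rates), categories = categories,
         onsets = fixed_onsets),
    class = "xdp_rate_profiles")
}

#' @export
print.xdp_rate_profiles <- function(x, ...) {
  cat("<xdp_rate_profiles>\n")
  cat(sprintf("  %d subjects x %d categories\n",
              length(unique(x$rates$subject_id)), length(x$categories)))
  invisible(x)
}

rate_profile_matrix <- function(profiles) {
  wide <- tidyr::pivot_wider(
    dplyr::select(profiles$rates, "subject_id", "category", "rate_mean"),
    names_from = "category", values_from = "rate_mean")
  m <- as.matrix(wide[, profiles$categories, drop = FALSE])
  rownames(m) <- wide$subject_id
  m
}

#' Euclidean distances between subjects' rate profiles
#'
#' The pairwise Euclidean distance between the per-category posterior-mean
#' rate vectors of every pair of subjects; symmetric with zero diagonal.
#'
#' @param profiles an `xdp_rate_profiles` (all subjects must share the same
#'   category set).
#' @return A symmetric distance matrix with subject ids as dimnames.
#' @export
rate_distance_matrix <- function(profiles) {
  stopifnot(inherits(profiles, "xdp_rate_profiles"))
  m <- rate_profile_matrix(profiles)
  if (anyNA(m)) stop("profiles do not share a complete category set")
  as.matrix(stats::dist(m, method = "euclidean"))
}

#' Cluster subjects by their progression profiles
#'
#' Agglomerative (average linkage) hierarchical clustering of subjects on
#' the Euclidean distances between their per-category rate profiles, plus a
#' table of subjects ordered from highest to lowest average rate across
#' categories (ties broken by subject id, deterministically).
#'
#' @param distances a symmetric distance matrix ([rate_distance_matrix()]).
#' @param profiles optional `xdp_rate_profiles`, used for the average-rate
#'   ordering; if omitted the ordering column is dropped.
#' @return A list: `hclust` (the tree), `order` (subject ids in leaf order),
#'   `by_average_rate` (tibble `subject_id`, `average_rate`, sorted
#'   descending).
#' @export
cluster_subjects <- function(distances, profiles = NULL) {
  stopifnot(is.matrix(distances), nrow(distances) == ncol(distances))
  if (nrow(distances) < 2) stop("need at least 2 subjects to cluster")
  hc <- stats::hclust(stats::as.dist(distances), method = "average")
  out <- list(hclust = hc, order = rownames(distances)[hc$order])
  if (!is.null(profiles)) {
    m <- rate_profile_matrix(profiles)
    avg <- rowMeans(m)
    ord <- order(-avg, names(avg))
    out$by_average_rate <- tibble::tibble(
      subject_id = names(avg)[ord], average_rate = unname(avg[ord]))
  }
  out
}
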