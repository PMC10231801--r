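#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the latents of a trajectory fit
#'
#' One row per gene-positive subject and latent parameter (onset, rate),
#' broom style.
#'
#' @param x an `xdp_trajectory_fit`.
#' @param ... unused.
#' @return A tibble `subject_id`, `genotype_group`, `term`, `estimate`,
#'   `conf.low`, `conf.high`, `std.error`.
#' @method tidy xdp_trajectory_fit
#' @export
tidy.xdp_trajectory_fit <- function(x, ...) {
  lat <- x$latents
  dplyr::bind_rows(
    tibble::tibble(subject_id = lat$subject_id,
                   genotype_group = lat$genotype_group, term = "onset",
                   estimate = lat$onset_mean, conf.low = lat$onset_lo,
                   conf.high = lat$onset_hi, std.error = lat$onset_sd),
    tibble::tibble(subject_id = lat$subject_id,
                   genotype_group = lat$genotype_group, term = "rate",
                   estimate = lat$rate_mean, conf.low = lat$rate_lo,
                   conf.high = lat$rate_hi, std.error = lat$rate_sd)
  )
}

#' One-row summary of a trajectory fit
#'
#' @param x an `xdp_trajectory_fit`.
#' @param ... unused.
#' @return A tibble with subject / measure counts, MCMC settings and
#'   convergence diagnostics.
#' @method glance xdp_trajectory_fit
#' @export
glance.xdp_trajectory_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$latents),
    n_measures = length(x$settings$measures),
    n_chains = x$diagnostics$n_chains,
    n_draws = x$diagnostics$n_draws,
    max_rhat = x$diagnostics$max_rhat_latents,
    min_ess = x$diagnostics$min_ess,
    converged = x$diagnostics$converged
  )
}

#' Tidy a correlation estimate into variable pairs
#'
#' @param x an `xdp_correlation`.
#' @param ... unused.
#' @return A long tibble of distinct pairs: `var1`, `var2`, `estimate`
#'   (posterior-mean correlation) and `half_width` (95% credible half-width).
#' @method tidy xdp_correlation
#' @export
tidy.xdp_correlation <- function(x, ...) {
  R <- x$mean
  ut <- which(upper.tri(R), arr.ind = TRUE)
  tibble::tibble(
    var1 = rownames(R)[ut[, 1]],
    var2 = colnames(R)[ut[, 2]],
    estimate = R[ut],
    half_width = x$half_width[ut]
  )
}

#' One-row summary of a correlation estimate
#'
#' @param x an `xdp_correlation`.
#' @param ... unused.
#' @return A tibble with dimensions, draw counts, the minimum eigenvalue of
#'   the posterior-mean matrix and the maximum split-Rhat.
#' @method glance xdp_correlation
#' @export
glance.xdp_correlation <- function(x, ...) {
  tibble::tibble(
    n_variables = length(x$variables),
    n_rows = x$diagnostics$n_rows,
    n_chains = x$diagnostics$n_chains,
    n_draws = x$diagnostics$n_draws,
    min_eigenvalue = min(eigen(x$mean, symmetric = TRUE,
                               only.values = TRUE)$values),
    max_rhat = x$diagnostics$max_rhat
  )
}

#' Tidy rate profiles
#'
#' @param x an `xdp_rate_profiles`.
#' @param ... unused.
#' @return The long rates tibble (`subject_id`, `category`, `rate_mean`,
#'   interval bounds, sd).
#' @method tidy xdp_rate_profiles
#' @export
tidy.xdp_rate_profiles <- function(x, ...) {
  x$rates
}
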