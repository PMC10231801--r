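#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the progression summary against age
#'
#' The piecewise-linear progression summary of every gene-positive subject:
#' flat at zero until the estimated onset, then rising at the estimated rate,
#' with the per-visit scores overplotted as points.
#'
#' @param object an `xdp_trajectory_fit`.
#' @param cohort the fitted cohort (for visit ages).
#' @param age_range age axis limits (years).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot xdp_trajectory_fit
#' @export
autoplot.xdp_trajectory_fit <- function(object, cohort,
                                        age_range = c(20, 70), ...) {
  lat <- object$latents
  grid <- tidyr::crossing(subject_id = lat$subject_id,
                          age = seq(age_range[1], age_range[2],
                                    length.out = 120)) |>
    dplyr::left_join(lat, by = "subject_id") |>
    dplyr::mutate(progression = progression_score(.data$age,
                                                  .data$onset_mean,
                                                  .data$rate_mean))
  pts <- progression_summary(object, cohort)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$age, y = .data$progression,
                                     group = .data$subject_id)) +
    ggplot2::geom_line(alpha = 0.35, linewidth = 0.3) +
    ggplot2::geom_point(data = pts, size = 1, alpha = 0.7,
                        ggplot2::aes(colour = .data$genotype_group)) +
    ggplot2::labs(x = "Age (years)", y = "Progression summary",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of the estimated correlation matrix
#'
#' Posterior-mean correlations on the severity-oriented scale, with
#' variables ordered by hierarchical clustering.
#'
#' @param object an `xdp_correlation`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot xdp_correlation
#' @export
autoplot.xdp_correlation <- function(object, ...) {
  ord <- cluster_variables(object)$order
  df <- tidy(object)
  df2 <- dplyr::bind_rows(
    df,
    dplyr::rename(df, var1 = "var2", var2 = "var1"),
    tibble::tibble(var1 = object$variables, var2 = object$variables,
                   estimate = 1, half_width = 0)
  )
  df2$var1 <- factor(df2$var1, levels = ord)
  df2$var2 <- factor(df2$var2, levels = ord)
  ggplot2::ggplot(df2, ggplot2::aes(x = .data$var1, y = .data$var2,
                                    fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Heatmap of per-category progression rates
#'
#' Subjects (ordered highest to lowest average rate) by category, filled by
#' the posterior-mean rate of progression.
#'
#' @param object an `xdp_rate_profiles`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot xdp_rate_profiles
#' @export
autoplot.xdp_rate_profiles <- function(object, ...) {
  dm <- rate_distance_matrix(object)
  ord <- cluster_subjects(dm, object)$by_average_rate$subject_id
  df <- object$rates
  df$subject_id <- factor(df$subject_id, levels = rev(ord))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$subject_id,
                                   fill = .data$rate_mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Rate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
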