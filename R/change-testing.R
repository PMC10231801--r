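#' First and last observed values of a per-visit series
#'
#' Implements the single-imputation rule used by the change-over-study tests:
#' the value at the final visit, imputed by last observation carried forward
#' when missing, and the value at enrollment, imputed by next observation
#' carried backward when missing. A subject contributes only if at least two
#' timepoints were observed for the measure; otherwise the pair is excluded.
#'
#' @param series numeric vector of per-visit values indexed by visit
#'   (enrollment first), `NA` for missing.
#' @return A list with `first`, `last` and `excluded` (logical). When
#'   `excluded` is `TRUE` the values are `NA`.
#' @examples
#' first_last_pair(c(5, NA, NA, 7))   # (5, 7)
#' first_last_pair(c(NA, 3, 4, NA))   # (3, 4) by NOCB then LOCF
#' first_last_pair(c(NA, 6, NA, NA))  # excluded: one observed timepoint
#' @export
first_last_pair <- function(series) {
  obs <- which(!is.na(series))
  if (length(obs) < 2) {
    return(list(first = NA_real_, last = NA_real_, excluded = TRUE))
  }
  list(first = series[obs[1]], last = series[obs[length(obs)]],
       excluded = FALSE)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' The signed-rank statistic is reported as the sum of signed ranks, W
#' (which can be negative). Zero differences are removed first (the reduced
#' sample procedure) and tied absolute differences receive average ranks.
#' The two-sided p-value is exact, `P(|W| >= |w|)` under the sign-flip null,
#' when the effective sample size is at most 25 and there are no ties among
#' the non-zero absolute differences; otherwise it uses the normal
#' approximation with tie-corrected variance and no continuity correction.
#'
#' @param differences numeric vector of paired differences.
#' @param exact_max largest tie-free effective n for which the exact null
#'   distribution is used (default 25).
#' @return A list: `W` (sum of signed ranks), `p_value`, `n_effective`
#'   (differences remaining after zero removal), `method` (`"exact"`,
#'   `"normal"` or `"untestable"`). All differences equal to zero yields an
#'   untestable result with `p_value = NA`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3))   # W = 6, exact p = 0.25
#' @export
wilcoxon_signed_rank <- function(differences, exact_max = 25) {
  stopifnot(length(differences) >= 1)
  d <- differences[!is.na(differences)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(W = NA_real_, p_value = NA_real_, n_effective = 0L,
                method = "untestable"))
  }
  r <- rank(abs(d))  # average ranks for ties
  W <- sum(sign(d) * r)
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= exact_max) {
    # W = 2V - n(n+1)/2 with V the positive-rank sum; the null law of W is
    # symmetric, so P(|W| >= |w|) = 2 P(V >= v_hi), capped at 1
    M <- n * (n + 1) / 2
    v_hi <- (abs(W) + M) / 2
    p <- min(1, 2 * stats::psignrank(v_hi - 1, n, lower.tail = FALSE))
    method <- "exact"
  } else {
    tie_counts <- table(abs(d))
    var_w <- n * (n + 1) * (2 * n + 1) / 6 -
      sum(tie_counts^3 - tie_counts) / 12
    if (var_w <= 0) {
      return(list(W = W, p_value = NA_real_, n_effective = as.integer(n),
                  method = "untestable"))
    }
    z <- W / sqrt(var_w)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(W = W, p_value = p, n_effective = as.integer(n), method = method)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' The monotone step-up adjustment: with the m p-values sorted ascending,
#' the k-th adjusted value is `min over j >= k of min(1, p_(j) * m / j)`,
#' mapped back to the input order. `NA` entries (untestable units) are
#' passed through and do not count toward m.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values in the input order.
#' @examples
#' bh_adjust(c(0.001, 0.5))        # 0.002, 0.5
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  out <- rep(NA_real_, length(p_values))
  if (m > 0) {
    o <- order(p)
    adj <- pmin(1, p[o] * m / seq_len(m))
    adj <- rev(cummin(rev(adj)))
    out[ok][o] <- adj
  }
  out
}

#' First-versus-last change tests across all test units
#'
#' Applies the full change-testing pipeline to every test unit derived from
#' the cohort's catalogue ([change_testing_variables()]): restrict to
#' symptomatic gene-positive subjects, form first/last pairs with LOCF/NOCB
#' imputation, exclude subjects with fewer than two observed timepoints,
#' run the Wilcoxon signed-rank test on the last-minus-first differences and
#' control the false discovery rate across units with the Benjamini-Hochberg
#' procedure.
#'
#' @param cohort an `xdp_cohort` containing symptomatic gene-positive
#'   subjects.
#' @param fdr_level FDR level for the significance flag (default 0.05).
#' @return A tibble of class `xdp_change_tests`, sorted by adjusted p-value,
#'   with columns `unit_id`, `label`, `n_subjects`, `mean_diff`, `stderr`,
#'   `W`, `p_value`, `p_adjusted`, `significant`, `method`.
#' @export
run_change_tests <- function(cohort, fdr_level = 0.05) {
  validate_cohort(cohort)
  sym <- cohort$subjects$subject_id[
    cohort$subjects$genotype_group == "positive_symptomatic"]
  if (length(sym) == 0) stop("no symptomatic gene-positive subjects in cohort")
  units <- change_testing_variables(cohort$catalogue)

  # one subject x visit x measure array, filled once
  vis <- dplyr::filter(cohort$visits, .data$subject_id %in% sym)
  visit_levels <- sort(unique(vis$visit_index))
  all_members <- unique(unlist(units$members))
  arr <- array(NA_real_, c(length(sym), length(visit_levels),
                           length(all_members)),
               dimnames = list(sym, visit_levels, all_members))
  obs <- dplyr::filter(cohort$observations,
                       .data$subject_id %in% sym,
                       .data$measure_id %in% all_members)
  arr[cbind(match(obs$subject_id, sym),
            match(obs$visit_index, visit_levels),
            match(obs$measure_id, all_members))] <- obs$value

  res <- purrr::pmap(units, function(unit_id, label, members, ...) {
    vals <- if (length(members) == 1) {
      arr[, , members, drop = FALSE][, , 1, drop = FALSE][, , 1]
    } else {
      # summed unit: missing if any member is missing at that visit
      apply(arr[, , members, drop = FALSE], c(1, 2), function(v) sum(v))
    }
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(sym))
    pairs <- apply(vals, 1, first_last_pair, simplify = FALSE)
    keep <- !purrr::map_lgl(pairs, "excluded")
    diffs <- purrr::map_dbl(pairs[keep], "last") -
      purrr::map_dbl(pairs[keep], "first")
    if (length(diffs) == 0) {
      return(tibble::tibble(
        unit_id = unit_id, label = label, n_subjects = 0L,
        mean_diff = NA_real_, stderr = NA_real_, W = NA_real_,
        p_value = NA_real_, method = "untestable"))
    }
    wt <- wilcoxon_signed_rank(diffs)
    tibble::tibble(
      unit_id = unit_id, label = label, n_subjects = length(diffs),
      mean_diff = mean(diffs),
      stderr = stats::sd(diffs) / sqrt(length(diffs)),
      W = wt$W, p_value = wt$p_value, method = wt$method)
  }) |>
    dplyr::bind_rows()

  res$p_adjusted <- bh_adjust(res$p_value)
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted < fdr_level
  res <- dplyr::arrange(res, is.na(.data$p_adjusted), .data$p_adjusted)
  attr(res, "fdr_level") <- fdr_level
  class(res) <- c("xdp_change_tests", class(res))
  res
}
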