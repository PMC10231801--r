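#' Orient a measure so that higher values mean worse disease
#'
#' Measures that improve with disease severity (the CPIB and BaDaKa/DDK
#' measures, lip strength, tongue strength, maximum phonation time, height,
#' weight and BMI) are multiplied by -1 before entering the correlation
#' analysis, so that every variable points in the same clinical direction.
#'
#' @param values numeric vector.
#' @param severity_direction `+1` (higher = worse; values returned unchanged)
#'   or `-1` (higher = better; values negated).
#' @return The oriented values.
#' @export
orient_severity <- function(values, severity_direction) {
  stopifnot(severity_direction %in% c(-1L, 1L))
  if (severity_direction == -1L) -values else values
}

# rank-based inverse-normal transform (Blom offsets, average ranks for ties);
# NA entries stay NA
inverse_normal_transform <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  if (n > 0) {
    r <- rank(x[ok], ties.method = "average")
    out[ok] <- stats::qnorm((r - 0.375) / (n + 0.25))
  }
  out
}

split_rhat <- function(draws) {
  # draws: iterations x chains; split each chain in half
  n <- nrow(draws)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  segs <- cbind(draws[seq_len(half), , drop = FALSE],
                draws[seq(n - half + 1, n), , drop = FALSE])
  m <- ncol(segs)
  means <- colMeans(segs)
  vars <- apply(segs, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Assemble the subject-visit data matrix for the correlation analysis
#'
#' One row per symptomatic gene-positive subject-visit, one column per
#' correlation variable ([correlation_variables()]): the 99 change-testing
#' units plus SVA repeat size, reported age at onset and height. Subject-level
#' constants are replicated across the subject's visits. Severity orientation
#' is applied (direction -1 variables are negated).
#'
#' @param cohort an `xdp_cohort`.
#' @return A list: `X` (numeric matrix with NAs), `variables` (the variable
#'   table), `flipped` (ids of negated variables), `rows` (subject-visit key).
#' @export
correlation_data <- function(cohort) {
  validate_cohort(cohort)
  vars <- correlation_variables(cohort$catalogue)
  sym <- cohort$subjects$subject_id[
    cohort$subjects$genotype_group == "positive_symptomatic"]
  if (length(sym) < 3) stop("need at least 3 symptomatic subjects")
  rows <- cohort$visits |>
    dplyr::filter(.data$subject_id %in% sym) |>
    dplyr::arrange(.data$subject_id, .data$visit_index)
  X <- matrix(NA_real_, nrow(rows), nrow(vars),
              dimnames = list(NULL, vars$unit_id))
  sub_idx <- match(rows$subject_id, cohort$subjects$subject_id)
  for (k in seq_len(nrow(vars))) {
    id <- vars$unit_id[k]
    if (vars$subject_constant[k]) {
      v <- cohort$subjects[[id]][sub_idx]
    } else {
      uv <- unit_values(cohort, vars$members[[k]], subjects = sym)
      v <- uv$value[match(paste(rows$subject_id, rows$visit_index),
                          paste(uv$subject_id, uv$visit_index))]
    }
    X[, k] <- orient_severity(v, vars$severity_direction[k])
  }
  list(X = X, variables = vars,
       flipped = vars$unit_id[vars$severity_direction == -1L],
       rows = dplyr::select(rows, "subject_id", "visit_index"))
}

#' Bayesian correlation matrix of a data matrix under missingness
#'
#' Fits a multivariate normal model to a data matrix with missing entries and
#' returns the posterior-mean correlation matrix with 95% credible
#' half-widths. The model is conjugate: a normal prior on the mean vector and
#' an inverse-Wishart prior on the covariance, centred at the identity (a mild
#' shrinkage towards uncorrelated variables). Missing entries are treated as
#' unknowns and sampled by coordinate-wise Gibbs updates from their
#' univariate full conditionals; the mean and covariance are then drawn from
#' their closed-form conditionals. Because every draw's correlation matrix is
#' symmetric positive semidefinite with unit diagonal, so is their average:
#' the returned point estimate is always a valid correlation matrix.
#'
#' Columns can optionally be passed through a rank-based inverse-normal
#' transform first (the default for cohort data, where ordinal scales and
#' skewed positive measures are far from Gaussian); the transform is monotone,
#' so it preserves rank dependence.
#'
#' @param X numeric matrix (rows = observations, columns = variables), NAs
#'   for missing entries.
#' @param n_draws post-warmup Gibbs draws per chain (default 500).
#' @param n_warmup warmup draws discarded per chain (default 200).
#' @param n_chains independent chains (default 2).
#' @param prior_extra_df inverse-Wishart degrees of freedom above `p + 1`
#'   (default 1); larger values shrink harder towards the identity.
#' @param transform `"int"` for the rank inverse-normal transform, `"none"`
#'   to use the columns as given.
#' @param seed integer seed.
#' @return An object of class `xdp_correlation`: `mean` (posterior-mean
#'   correlation matrix), `half_width` (95% credible half-widths), `variables`,
#'   `flipped`, `dropped` (zero-variance columns removed), and `diagnostics`
#'   (max split-Rhat over matrix entries, draws, chains).
#' @export
estimate_correlation_matrix <- function(X, n_draws = 500, n_warmup = 200,
                                        n_chains = 2, prior_extra_df = 1,
                                        transform = c("int", "none"),
                                        seed = 1L) {
  transform <- match.arg(transform)
  stopifnot(is.matrix(X), ncol(X) >= 2)
  vars <- colnames(X)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  dropped <- vars[is.na(sds) | sds == 0]
  if (length(dropped) > 0) {
    warning("dropping zero-variance variable(s): ",
            paste(dropped, collapse = ", "))
    keep <- !(vars %in% dropped)
    X <- X[, keep, drop = FALSE]
    vars <- vars[keep]
  }
  if (transform == "int") X <- apply(X, 2, inverse_normal_transform)
  # centre and scale so the identity-centred prior is on the right scale
  X <- scale(X)[, , drop = FALSE]

  n <- nrow(X)
  p <- ncol(X)
  nu0 <- p + 1 + prior_extra_df
  S0 <- diag(prior_extra_df, p)   # prior mean of Sigma = S0/(nu0 - p - 1) = I
  mu_prior_prec <- 1 / 100
  miss <- which(is.na(X), arr.ind = TRUE)
  ut <- upper.tri(matrix(0, p, p), diag = FALSE)
  n_entries <- sum(ut)

  run_chain <- function(chain_seed) {
    withr::with_seed(chain_seed, {
      Xc <- X
      mu <- colMeans(Xc, na.rm = TRUE)
      mu[is.na(mu)] <- 0
      for (j in seq_len(p)) Xc[is.na(X[, j]), j] <- mu[j]
      Sigma <- stats::cov(Xc) + diag(1e-6, p)
      keep_draws <- matrix(NA_real_, n_draws, n_entries)
      total <- n_warmup + n_draws
      for (it in seq_len(total)) {
        Omega <- chol2inv(chol(Sigma))
        # impute missing entries from univariate full conditionals
        if (nrow(miss) > 0) {
          for (j in unique(miss[, 2])) {
            rows_j <- miss[miss[, 2] == j, 1]
            dev <- sweep(Xc[rows_j, , drop = FALSE], 2, mu)
            # conditional of coordinate j given the rest, via the precision
            cond_var <- 1 / Omega[j, j]
            cond_mean <- mu[j] -
              cond_var * (dev %*% Omega[, j] - Omega[j, j] * dev[, j])
            Xc[rows_j, j] <- stats::rnorm(length(rows_j), cond_mean,
                                          sqrt(cond_var))
          }
        }
        # mean vector
        prec <- n * Omega + diag(mu_prior_prec, p)
        ch <- chol(prec)
        b <- Omega %*% colSums(Xc)
        mu_hat <- backsolve(ch, forwardsolve(t(ch), b))
        mu <- drop(mu_hat + backsolve(ch, stats::rnorm(p)))
        # covariance
        dev <- sweep(Xc, 2, mu)
        Spost <- S0 + crossprod(dev)
        W <- stats::rWishart(1, nu0 + n, chol2inv(chol(Spost)))[, , 1]
        Sigma <- chol2inv(chol(W))
        if (it > n_warmup) {
          R <- stats::cov2cor(Sigma)
          keep_draws[it - n_warmup, ] <- R[ut]
        }
      }
      keep_draws
    })
  }

  chain_seeds <- seed + seq_len(n_chains) - 1L
  draws <- lapply(chain_seeds, run_chain)
  all_draws <- do.call(rbind, draws)

  mean_vec <- colMeans(all_draws)
  qs <- apply(all_draws, 2, stats::quantile, probs = c(0.025, 0.975))
  hw_vec <- (qs[2, ] - qs[1, ]) / 2
  Rbar <- diag(1, p)
  Rbar[ut] <- mean_vec
  Rbar <- Rbar + t(Rbar) - diag(1, p)
  HW <- matrix(0, p, p)
  HW[ut] <- hw_vec
  HW <- HW + t(HW)
  dimnames(Rbar) <- dimnames(HW) <- list(vars, vars)

  # split-Rhat over (a subsample of) matrix entries
  ent <- if (n_entries > 500) {
    withr::with_seed(seed, sample.int(n_entries, 500))
  } else seq_len(n_entries)
  rhats <- vapply(ent, function(e) {
    split_rhat(vapply(draws, function(d) d[, e], numeric(n_draws)))
  }, numeric(1))
  max_rhat <- max(rhats, na.rm = TRUE)
  if (is.finite(max_rhat) && max_rhat > 1.1) {
    warning(sprintf("possible MCMC non-convergence: max split-Rhat = %.3f",
                    max_rhat))
  }

  structure(
    list(mean = Rbar, half_width = HW, variables = vars,
         flipped = character(0), dropped = dropped,
         diagnostics = list(max_rhat = max_rhat, n_draws = n_draws,
                            n_chains = n_chains, n_rows = n)),
    class = "xdp_correlation")
}

#' Bayesian correlation matrix of the cohort's analysis variables
#'
#' Builds the symptomatic subject-visit matrix over the 102 correlation
#' variables ([correlation_data()]), applies the severity orientation and the
#' rank inverse-normal transform, and estimates the correlation matrix with
#' [estimate_correlation_matrix()].
#'
#' @param cohort an `xdp_cohort`.
#' @inheritParams estimate_correlation_matrix
#' @return An `xdp_correlation` object (see [estimate_correlation_matrix()]),
#'   with `flipped` recording the severity-negated variables.
#' @export
estimate_correlation <- function(cohort, n_draws = 500, n_warmup = 200,
                                 n_chains = 2, prior_extra_df = 1, seed = 1L) {
  cd <- correlation_data(cohort)
  est <- estimate_correlation_matrix(
    cd$X, n_draws = n_draws, n_warmup = n_warmup, n_chains = n_chains,
    prior_extra_df = prior_extra_df, transform = "int", seed = seed)
  est$flipped <- cd$flipped
  est
}

#' @export
print.xdp_correlation <- function(x, ...) {
  cat("<xdp_correlation>\n")
  cat(sprintf("  %d variables, %d rows; %d chains x %d draws; max Rhat %.3f\n",
              length(x$variables), x$diagnostics$n_rows,
              x$diagnostics$n_chains, x$diagnostics$n_draws,
              x$diagnostics$max_rhat))
  invisible(x)
}

#' Hierarchical clustering of correlation variables
#'
#' Agglomerative (average linkage) clustering of the variables on the
#' distance `1 - r`, where `r` is the posterior-mean correlation on the
#' severity-oriented scale. Leaf order is deterministic given the estimate.
#'
#' @param estimate an `xdp_correlation`.
#' @return A list: `hclust` (the tree) and `order` (variable ids in leaf
#'   order).
#' @export
cluster_variables <- function(estimate) {
  stopifnot(inherits(estimate, "xdp_correlation"))
  R <- estimate$mean
  if (nrow(R) == 1) {
    return(list(hclust = NULL, order = rownames(R)))
  }
  hc <- stats::hclust(stats::as.dist(1 - R), method = "average")
  list(hclust = hc, order = rownames(R)[hc$order])
}
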