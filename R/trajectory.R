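#' Time since disease onset
#'
#' The positive-part realignment covariate `[age - onset]+`: years since
#' onset when age exceeds onset, zero otherwise (including at the boundary).
#'
#' @param age,onset ages in years (vectorized).
#' @return Non-negative years.
#' @examples
#' time_since_onset(45, 40)  # 5
#' time_since_onset(35, 40)  # 0
#' @export
time_since_onset <- function(age, onset) {
  pmax(age - onset, 0)
}

#' Category probabilities of the cumulative-logit measure model
#'
#' For an ordinal measure with levels `c_1 < ... < c_K`, the model puts
#' `logit(P(Y <= c_k)) = alpha_k + beta1 * age + beta2 * rate * [age - onset]+`
#' for the K-1 free thresholds `alpha_1 < ... < alpha_{K-1}` (the K-th
#' cumulative probability is 1 by construction). Per-category probabilities
#' are successive differences of the cumulative probabilities.
#'
#' @param alpha increasing numeric vector of K-1 thresholds (logit scale).
#' @param beta1 age coefficient (per year).
#' @param beta2 progression coefficient (per realigned year times rate unit).
#' @param levels the K ordinal level values.
#' @param age,rate,onset scalars; for gene-negative dynamics pass `rate = 0`
#'   (or `onset = Inf`).
#' @return Numeric vector of K probabilities summing to 1.
#' @export
ordinal_category_probs <- function(alpha, beta1, beta2, levels, age, rate,
                                   onset) {
  K <- length(levels)
  stopifnot(length(alpha) == K - 1)
  if (any(diff(alpha) <= 0)) stop("thresholds must be strictly increasing")
  eta <- beta1 * age + beta2 * rate * time_since_onset(age, onset)
  q <- stats::plogis(alpha + eta)
  p <- c(q, 1) - c(0, q)
  stats::setNames(p, levels)
}

#' Log-likelihood of the log-normal measure model
#'
#' `log(Y) ~ Normal(alpha + beta1 * age + beta2 * rate * [age - onset]+,
#' sigma)`; returns the log density of the positive value `value` (including
#' the 1/value Jacobian of the log transform).
#'
#' @param alpha intercept (log scale).
#' @inheritParams ordinal_category_probs
#' @param sigma positive scale (log scale).
#' @param value observed positive value.
#' @return Log density.
#' @export
continuous_loglik <- function(alpha, beta1, beta2, sigma, value, age, rate,
                              onset) {
  if (any(value <= 0)) stop("positive_real values must be > 0")
  mu <- alpha + beta1 * age + beta2 * rate * time_since_onset(age, onset)
  stats::dlnorm(value, meanlog = mu, sdlog = sigma, log = TRUE)
}

#' Mean of the Poisson measure model
#'
#' `Y ~ Poisson(offset * softplus(alpha + beta1 * age + beta2 * rate *
#' [age - onset]+))` with the overflow-safe softplus `log(1 + exp(x))`. The
#' offset is 1 for lip strength and the paired DDK duration (seconds) for the
#' DDK syllable counts.
#'
#' @inheritParams continuous_loglik
#' @param offset positive exposure offset.
#' @return Strictly positive Poisson mean.
#' @examples
#' count_mean(0, 0, 0, offset = 1, age = 40, rate = 1, onset = 50)  # log(2)
#' @export
count_mean <- function(alpha, beta1, beta2, offset, age, rate, onset) {
  if (any(offset <= 0)) stop("offset must be > 0")
  eta <- alpha + beta1 * age + beta2 * rate * time_since_onset(age, onset)
  offset * softplus(eta)
}

#' Prior settings for the trajectory model
#'
#' All hyperparameters of the hierarchical fit in one auditable list.
#' Scales are standard deviations (the model file converts to precisions).
#' `rate_sdlog = 0.5` fixes the scale of the multiplicatively non-identified
#' rate (`Rate_i ~ LogNormal(0, 0.5)` anchors the geometric mean of the rates
#' near 1 while `beta_j2` is unconstrained). The onset prior couples the
#' latent onset to SVA repeat size (`Onset_i ~ Normal(a + b * repeat_c, tau)`)
#' and to the reported onset through a shared non-negative reporting lag
#' (`Reported_i ~ Normal(Onset_i + lag, s)`).
#'
#' @param rate_sdlog log-scale sd of the per-subject rate prior.
#' @param lag_mean,lag_sd truncated-normal prior (>= 0) for the shared
#'   reporting lag, years.
#' @param report_sd_scale half-normal scale for the reported-onset noise sd.
#' @param onset_loc_mean,onset_loc_sd normal prior for the onset intercept.
#' @param onset_slope_sd normal scale for the onset slope on centred repeat
#'   size.
#' @param onset_tau_scale half-normal scale for the onset residual sd.
#' @param b1_sd,b2_sd normal scales for the age and progression coefficients.
#' @param cut_sd,alpha_cont_sd,alpha_count_sd normal scales for intercepts /
#'   first thresholds (centred-age scale).
#' @param dcut_sd half-normal scale for threshold increments.
#' @param sigma_scale half-normal scale for log-normal residual sds.
#' @param age_center years subtracted from age inside linear predictors for
#'   sampler conditioning (reported parameters are de-centred); about the
#'   cohort mean onset.
#' @return A named list.
#' @export
trajectory_priors <- function(rate_sdlog = 0.5, lag_mean = 7.5, lag_sd = 5,
                              report_sd_scale = 5, onset_loc_mean = 40,
                              onset_loc_sd = 20, onset_slope_sd = 2,
                              onset_tau_scale = 10, b1_sd = 0.5, b2_sd = 2,
                              cut_sd = 5, alpha_cont_sd = 10,
                              alpha_count_sd = 30, dcut_sd = 2,
                              sigma_scale = 1, age_center = 40) {
  as.list(environment())
}

trajectory_model_string <- function(priors) {
  pr <- function(sd) sprintf("%.8g", 1 / sd^2)
  paste0("
model {
  for (k in 1:Npos) {
    rep_c[k] ~ dnorm(0, rep_prec)
    Onset[k] ~ dnorm(a_on + b_on * rep_c[k], tau_on_prec)
    report[k] ~ dnorm(Onset[k] + lag, report_prec)
    Rate[k] ~ dlnorm(0, ", pr(priors$rate_sdlog), ")
  }
  a_on ~ dnorm(", priors$onset_loc_mean, ", ", pr(priors$onset_loc_sd), ")
  b_on ~ dnorm(0, ", pr(priors$onset_slope_sd), ")
  tau_on ~ dnorm(0, ", pr(priors$onset_tau_scale), ") T(0,)
  tau_on_prec <- 1 / (tau_on * tau_on + 1e-4)
  lag ~ dnorm(", priors$lag_mean, ", ", pr(priors$lag_sd), ") T(0,)
  s_report ~ dnorm(0, ", pr(priors$report_sd_scale), ") T(0,)
  report_prec <- 1 / (s_report * s_report + 1e-4)

  for (i in 1:Nsub) {
    OnsetAll[i] <- ifelse(ispos[i] == 1, Onset[posmap[i]], 1000)
    RateAll[i] <- ifelse(ispos[i] == 1, Rate[posmap[i]], 0)
  }

  for (n in 1:No) {
    etao[n] <- b1o[om[n]] * agec_o[n] +
      b2o[om[n]] * RateAll[so[n]] * max(age_o[n] - OnsetAll[so[n]], 0)
    for (k in 1:(Ko[om[n]] - 1)) {
      qo[n, k] <- ilogit(cut[om[n], k] + etao[n])
    }
    po[n, 1] <- qo[n, 1]
    for (k in 2:(Ko[om[n]] - 1)) {
      po[n, k] <- qo[n, k] - qo[n, k - 1]
    }
    po[n, Ko[om[n]]] <- 1 - qo[n, Ko[om[n]] - 1]
    yo[n] ~ dcat(po[n, 1:Ko[om[n]]])
  }
  for (j in 1:Jo) {
    cut[j, 1] ~ dnorm(0, ", pr(priors$cut_sd), ")
    for (k in 2:(Ko[j] - 1)) {
      cut[j, k] <- cut[j, k - 1] + dcut[j, k - 1]
    }
    for (k in 1:(Ko[j] - 2)) {
      dcut[j, k] ~ dnorm(0, ", pr(priors$dcut_sd), ") T(0,)
    }
    b1o[j] ~ dnorm(0, ", pr(priors$b1_sd), ")
    b2o[j] ~ dnorm(0, ", pr(priors$b2_sd), ")
  }

  for (n in 1:Nc) {
    muc[n] <- ac[cm[n]] + b1c[cm[n]] * agec_c[n] +
      b2c[cm[n]] * RateAll[sc[n]] * max(age_c[n] - OnsetAll[sc[n]], 0)
    lyc[n] ~ dnorm(muc[n], prec_c[cm[n]])
  }
  for (j in 1:Jc) {
    ac[j] ~ dnorm(0, ", pr(priors$alpha_cont_sd), ")
    b1c[j] ~ dnorm(0, ", pr(priors$b1_sd), ")
    b2c[j] ~ dnorm(0, ", pr(priors$b2_sd), ")
    sig_c[j] ~ dnorm(0, ", pr(priors$sigma_scale), ") T(0,)
    prec_c[j] <- 1 / (sig_c[j] * sig_c[j] + 1e-6)
  }

  for (n in 1:Nk) {
    etak[n] <- ak[km[n]] + b1k[km[n]] * agec_k[n] +
      b2k[km[n]] * RateAll[sk[n]] * max(age_k[n] - OnsetAll[sk[n]], 0)
    muk[n] <- offk[n] * (max(etak[n], 0) + log(1 + exp(-abs(etak[n])))) + 1e-10
    yk[n] ~ dpois(muk[n])
  }
  for (j in 1:Jk) {
    ak[j] ~ dnorm(0, ", pr(priors$alpha_count_sd), ")
    b1k[j] ~ dnorm(0, ", pr(priors$b1_sd), ")
    b2k[j] ~ dnorm(0, ", pr(priors$b2_sd), ")
  }
}
")
}

# assemble the per-family observation blocks and subject-level data for JAGS
trajectory_data <- function(cohort, measures, priors, fixed_onsets = NULL) {
  catalogue <- cohort$catalogue
  spec <- dplyr::filter(catalogue, .data$measure_id %in% measures)
  if (nrow(spec) == 0) stop("no catalogue entries match `measures`")
  bad_K <- spec$measure_id[spec$value_kind == "ordinal" &
                             lengths(spec$ordinal_levels) < 3]
  if (length(bad_K) > 0) {
    stop("ordinal measures need K >= 3 levels for the threshold ",
         "parameterization: ", paste(bad_K, collapse = ", "))
  }

  sub <- cohort$subjects
  ispos <- as.integer(sub$genotype_group != "negative")
  pos_ids <- sub$subject_id[ispos == 1]
  Npos <- length(pos_ids)
  if (Npos == 0) stop("cohort contains no gene-positive subjects")
  posmap <- match(sub$subject_id, pos_ids)
  posmap[is.na(posmap)] <- 1L  # dummy; masked by the ispos switch

  rep_sz <- sub$repeat_size[ispos == 1]
  rep_center <- mean(rep_sz, na.rm = TRUE)
  if (is.nan(rep_center)) rep_center <- 0
  rep_sd <- stats::sd(rep_sz, na.rm = TRUE)
  if (is.na(rep_sd) || rep_sd == 0) rep_sd <- 1
  report <- sub$reported_onset[ispos == 1]

  obs <- cohort$observations |>
    dplyr::filter(.data$measure_id %in% spec$measure_id,
                  !is.na(.data$value)) |>
    dplyr::left_join(cohort$visits, by = c("subject_id", "visit_index"))
  obs$sub_idx <- match(obs$subject_id, sub$subject_id)
  obs$kind <- spec$value_kind[match(obs$measure_id, spec$measure_id)]

  ord_spec <- dplyr::filter(spec, .data$value_kind == "ordinal")
  con_spec <- dplyr::filter(spec, .data$value_kind == "positive_real")
  cnt_spec <- dplyr::filter(spec, .data$value_kind == "count")

  oo <- dplyr::filter(obs, .data$kind == "ordinal")
  oc <- dplyr::filter(obs, .data$kind == "positive_real")
  ok <- dplyr::filter(obs, .data$kind == "count")

  # ordinal values -> category index within the measure's level set
  yo <- integer(nrow(oo))
  om <- match(oo$measure_id, ord_spec$measure_id)
  for (j in seq_len(nrow(ord_spec))) {
    rows <- which(om == j)
    yo[rows] <- match(oo$value[rows], ord_spec$ordinal_levels[[j]])
  }

  # count offsets: unit, or the paired duration observed at the same visit
  offk <- rep(1, nrow(ok))
  km <- match(ok$measure_id, cnt_spec$measure_id)
  drop_k <- rep(FALSE, nrow(ok))
  for (j in seq_len(nrow(cnt_spec))) {
    link <- cnt_spec$offset_link[j]
    rows <- which(km == j)
    if (!is.na(link) && link != "unit") {
      dur <- cohort$observations |>
        dplyr::filter(.data$measure_id == link, !is.na(.data$value))
      mt <- match(paste(ok$subject_id[rows], ok$visit_index[rows]),
                  paste(dur$subject_id, dur$visit_index))
      offk[rows] <- dur$value[mt]
      drop_k[rows] <- is.na(mt)
    }
  }
  if (any(drop_k)) {
    ok <- ok[!drop_k, , drop = FALSE]
    km <- km[!drop_k]
    offk <- offk[!drop_k]
  }

  dat <- list(
    Nsub = nrow(sub), Npos = Npos, ispos = ispos, posmap = posmap,
    rep_c = (rep_sz - rep_center) / 1, rep_prec = 1 / rep_sd^2,
    report = report,
    No = nrow(oo), Jo = nrow(ord_spec),
    Nc = nrow(oc), Jc = nrow(con_spec),
    Nk = nrow(ok), Jk = nrow(cnt_spec)
  )
  if (nrow(oo) > 0) {
    dat$yo <- yo
    dat$om <- om
    dat$so <- oo$sub_idx
    dat$age_o <- oo$age
    dat$agec_o <- oo$age - priors$age_center
    dat$Ko <- lengths(ord_spec$ordinal_levels)
  } else {
    dat$Jo <- 0L
  }
  if (nrow(oc) > 0) {
    dat$lyc <- log(oc$value)
    dat$cm <- match(oc$measure_id, con_spec$measure_id)
    dat$sc <- oc$sub_idx
    dat$age_c <- oc$age
    dat$agec_c <- oc$age - priors$age_center
  } else {
    dat$Jc <- 0L
  }
  if (nrow(ok) > 0) {
    dat$yk <- as.integer(ok$value)
    dat$km <- km
    dat$sk <- ok$sub_idx
    dat$age_k <- ok$age
    dat$agec_k <- ok$age - priors$age_center
    dat$offk <- offk
  } else {
    dat$Jk <- 0L
  }

  if (!is.null(fixed_onsets)) {
    on <- fixed_onsets[pos_ids]
    if (anyNA(on)) {
      stop("fixed_onsets must name every gene-positive subject")
    }
    dat$Onset <- unname(on)
  }

  list(data = dat, pos_ids = pos_ids, rep_center = rep_center,
       ord_spec = ord_spec, con_spec = con_spec, cnt_spec = cnt_spec)
}

strip_empty_blocks <- function(model_string, dat) {
  # JAGS rejects zero-length loops; drop unused likelihood blocks wholesale
  drop_block <- function(txt, pattern_from, pattern_to) {
    lines <- strsplit(txt, "\n")[[1]]
    from <- grep(pattern_from, lines)
    to <- grep(pattern_to, lines)
    keep <- rep(TRUE, length(lines))
    for (f in from) {
      t_ <- to[to >= f][1]
      keep[f:t_] <- FALSE
    }
    paste(lines[keep], collapse = "\n")
  }
  if (dat$No == 0) {
    model_string <- drop_block(model_string, "for \\(n in 1:No\\)|for \\(j in 1:Jo\\)",
                               "^  \\}$")
  }
  if (dat$Nc == 0) {
    model_string <- drop_block(model_string, "for \\(n in 1:Nc\\)|for \\(j in 1:Jc\\)",
                               "^  \\}$")
  }
  if (dat$Nk == 0) {
    model_string <- drop_block(model_string, "for \\(n in 1:Nk\\)|for \\(j in 1:Jk\\)",
                               "^  \\}$")
  }
  model_string
}

#' Fit the hierarchical Bayesian symptom-trajectory model
#'
#' Jointly fits, by MCMC, the three measure likelihood families (cumulative
#' logit for ordinal measures, log-normal for positive reals, Poisson with a
#' softplus mean and exposure offset for counts) over the selected measures,
#' together with the per-subject latent age at onset and rate of progression
#' of every gene-positive subject. The covariates are age and the entry-time
#' realigned `rate * [age - onset]+`, so gene-negative and pre-symptomatic
#' subjects inform the age trends while symptomatic subjects identify the
#' progression coefficients. The latent onset is informed by the reported
#' onset (through a shared non-negative reporting lag), the SVA repeat size
#' (through a linear onset-on-repeat-size prior) and all observed measures.
#' Missing observations are simply absent from the likelihood (the model's
#' conditional independences make dropping those factors equivalent to
#' marginalizing the missing values). Posterior means are the point
#' estimates.
#'
#' @param cohort an `xdp_cohort` with at least one gene-positive subject.
#' @param measures measure ids to fit (default: all non-auxiliary catalogue
#'   measures).
#' @param priors a [trajectory_priors()] list.
#' @param n_chains,n_adapt,n_burn,n_draws MCMC settings (defaults 2 chains,
#'   500 adaptation + 500 burn-in + 500 kept draws per chain).
#' @param fixed_onsets optional named numeric vector (by subject id) of onset
#'   ages for every gene-positive subject; when supplied the onsets are held
#'   fixed as data (used by the per-category rate-heterogeneity refits).
#' @param seed integer seed driving all chains.
#' @param quiet suppress JAGS progress output (default `TRUE`).
#' @return An object of class `xdp_trajectory_fit`: `latents` (per-subject
#'   posterior mean / 95% interval / sd for onset and rate), `params`
#'   (per-measure posterior-mean parameters, de-centred so intercepts and
#'   thresholds refer to raw age), `hyper` (reporting lag, onset regression),
#'   `diagnostics` (split-Rhat over latents, effective sample sizes),
#'   `settings`.
#' @export
fit_trajectory <- function(cohort, measures = NULL,
                           priors = trajectory_priors(), n_chains = 2,
                           n_adapt = 500, n_burn = 500, n_draws = 500,
                           fixed_onsets = NULL, seed = 1L, quiet = TRUE) {
  validate_cohort(cohort)
  if (is.null(measures)) {
    measures <- cohort$catalogue$measure_id[!cohort$catalogue$auxiliary]
  }
  td <- trajectory_data(cohort, measures, priors, fixed_onsets)
  dat <- td$data
  model_string <- strip_empty_blocks(trajectory_model_string(priors), dat)
  has_o <- dat$No > 0
  has_c <- dat$Nc > 0
  has_k <- dat$Nk > 0
  if (dat$No == 0) dat <- dat[!names(dat) %in% c("No", "Jo")]
  if (!is.null(dat$Nc) && dat$Nc == 0) dat <- dat[!names(dat) %in% c("Nc", "Jc")]
  if (!is.null(dat$Nk) && dat$Nk == 0) dat <- dat[!names(dat) %in% c("Nk", "Jk")]

  sub <- cohort$subjects
  pos_ids <- td$pos_ids
  onset_free <- is.null(fixed_onsets)

  inits <- lapply(seq_len(n_chains), function(ch) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = as.integer(seed + ch - 1))
    if (onset_free) {
      rep_on <- sub$reported_onset[match(pos_ids, sub$subject_id)]
      max_age <- vapply(pos_ids, function(id) {
        max(cohort$visits$age[cohort$visits$subject_id == id])
      }, numeric(1))
      ini$Onset <- ifelse(is.na(rep_on), max_age + 5,
                          pmax(rep_on - priors$lag_mean, 18))
      ini$Rate <- rep(1, length(pos_ids))
    }
    ini
  })

  monitors <- c("Onset", "Rate", "lag", "a_on", "b_on", "tau_on", "s_report")
  if (has_o) monitors <- c(monitors, "cut", "b1o", "b2o")
  if (has_c) monitors <- c(monitors, "ac", "b1c", "b2c", "sig_c")
  if (has_k) monitors <- c(monitors, "ak", "b1k", "b2k")

  mf <- tempfile(fileext = ".jags")
  writeLines(model_string, mf)
  on.exit(unlink(mf), add = TRUE)
  model <- rjags::jags.model(mf, data = dat, inits = inits,
                             n.chains = n_chains, n.adapt = n_adapt,
                             quiet = quiet)
  stats::update(model, n_burn, progress.bar = "none")
  samples <- rjags::coda.samples(model, monitors, n.iter = n_draws,
                                 progress.bar = "none")

  all_draws <- do.call(rbind, lapply(samples, as.matrix))
  cn <- colnames(all_draws)
  # coda drops brackets on length-1 nodes ("ac" instead of "ac[1]"); try the
  # plausible spellings in order
  draw_col <- function(prefix, i = NULL, j = NULL) {
    cands <- if (is.null(i)) {
      prefix
    } else if (is.null(j)) {
      c(sprintf("%s[%d]", prefix, i), if (i == 1) prefix)
    } else {
      c(sprintf("%s[%d,%d]", prefix, i, j),
        if (i == 1) sprintf("%s[%d]", prefix, j),
        if (j == 1) sprintf("%s[%d]", prefix, i),
        if (i == 1 && j == 1) prefix)
    }
    nm <- cands[cands %in% cn]
    if (length(nm) == 0) stop("monitor column not found: ", cands[1])
    all_draws[, nm[1]]
  }
  summ <- function(prefix, idx) {
    x <- draw_col(prefix, idx)
    c(mean = mean(x), lo = unname(stats::quantile(x, 0.025)),
      hi = unname(stats::quantile(x, 0.975)), sd = stats::sd(x))
  }

  onset_s <- t(vapply(seq_along(pos_ids), function(k) summ("Onset", k),
                      numeric(4)))
  rate_s <- t(vapply(seq_along(pos_ids), function(k) summ("Rate", k),
                     numeric(4)))
  latents <- tibble::tibble(
    subject_id = pos_ids,
    genotype_group = sub$genotype_group[match(pos_ids, sub$subject_id)],
    onset_mean = onset_s[, 1], onset_lo = onset_s[, 2],
    onset_hi = onset_s[, 3], onset_sd = onset_s[, 4],
    rate_mean = rate_s[, 1], rate_lo = rate_s[, 2],
    rate_hi = rate_s[, 3], rate_sd = rate_s[, 4]
  )

  decenter <- priors$age_center
  params <- list()
  if (has_o) {
    os <- td$ord_spec
    params$ordinal <- tibble::tibble(
      measure_id = os$measure_id,
      levels = os$ordinal_levels,
      alpha = purrr::map(seq_len(nrow(os)), function(j) {
        K <- length(os$ordinal_levels[[j]])
        b1 <- draw_col("b1o", j)
        vapply(seq_len(K - 1), function(k) {
          mean(draw_col("cut", j, k) - decenter * b1)
        }, numeric(1))
      }),
      beta1 = vapply(seq_len(nrow(os)), function(j)
        mean(draw_col("b1o", j)), numeric(1)),
      beta2 = vapply(seq_len(nrow(os)), function(j)
        mean(draw_col("b2o", j)), numeric(1))
    )
  }
  if (has_c) {
    cs <- td$con_spec
    params$continuous <- tibble::tibble(
      measure_id = cs$measure_id,
      alpha = vapply(seq_len(nrow(cs)), function(j)
        mean(draw_col("ac", j) - decenter * draw_col("b1c", j)), numeric(1)),
      beta1 = vapply(seq_len(nrow(cs)), function(j)
        mean(draw_col("b1c", j)), numeric(1)),
      beta2 = vapply(seq_len(nrow(cs)), function(j)
        mean(draw_col("b2c", j)), numeric(1)),
      sigma = vapply(seq_len(nrow(cs)), function(j)
        mean(draw_col("sig_c", j)), numeric(1))
    )
  }
  if (has_k) {
    ks <- td$cnt_spec
    params$count <- tibble::tibble(
      measure_id = ks$measure_id,
      offset_link = ks$offset_link,
      alpha = vapply(seq_len(nrow(ks)), function(j)
        mean(draw_col("ak", j) - decenter * draw_col("b1k", j)), numeric(1)),
      beta1 = vapply(seq_len(nrow(ks)), function(j)
        mean(draw_col("b1k", j)), numeric(1)),
      beta2 = vapply(seq_len(nrow(ks)), function(j)
        mean(draw_col("b2k", j)), numeric(1))
    )
  }

  hyper <- tibble::tibble(
    parameter = c("lag", "a_on", "b_on", "tau_on", "s_report"),
    mean = vapply(c("lag", "a_on", "b_on", "tau_on", "s_report"),
                  function(nm) mean(all_draws[, nm]), numeric(1))
  )

  # convergence on the latents (split-Rhat across chains)
  lat_cols <- cn[grepl("^Onset(\\[|$)|^Rate(\\[|$)", cn)]
  rhats <- vapply(lat_cols, function(nm) {
    split_rhat(vapply(samples, function(s) as.matrix(s)[, nm],
                      numeric(n_draws)))
  }, numeric(1))
  rhats <- rhats[is.finite(rhats)]
  max_rhat <- if (length(rhats) > 0) max(rhats) else NA_real_
  ess <- tryCatch(min(coda::effectiveSize(samples[, lat_cols, drop = FALSE])),
                  error = function(e) NA_real_)
  converged <- is.na(max_rhat) || max_rhat < 1.1
  if (!converged) {
    warning(sprintf("possible non-convergence: max split-Rhat on latents = %.3f",
                    max_rhat))
  }

  structure(
    list(latents = latents, params = params, hyper = hyper,
         diagnostics = list(max_rhat_latents = max_rhat, min_ess = ess,
                            converged = converged, n_chains = n_chains,
                            n_draws = n_draws),
         settings = list(measures = measures, priors = priors, seed = seed,
                         fixed_onsets = !onset_free,
                         rep_center = td$rep_center),
         draws = all_draws),
    class = "xdp_trajectory_fit")
}

#' @export
print.xdp_trajectory_fit <- function(x, ...) {
  cat("<xdp_trajectory_fit>\n")
  cat(sprintf("  %d gene-positive subjects, %d measures; %d chains x %d draws\n",
              nrow(x$latents), length(x$settings$measures),
              x$diagnostics$n_chains, x$diagnostics$n_draws))
  cat(sprintf("  max split-Rhat (latents): %.3f; min ESS: %.0f\n",
              x$diagnostics$max_rhat_latents, x$diagnostics$min_ess))
  invisible(x)
}

#' Progression score at a given age
#'
#' The per-subject quantitative progression summary: zero until the
#' estimated age at onset, then increasing linearly at the estimated rate of
#' progression: `rate * [age - onset]+`.
#'
#' @param age age in years (vectorized).
#' @param onset estimated age at onset.
#' @param rate estimated (positive) rate of progression.
#' @return Non-negative score.
#' @export
progression_score <- function(age, onset, rate) {
  rate * time_since_onset(age, onset)
}

#' Per-visit progression summary for a fitted trajectory model
#'
#' Evaluates the progression score at every recorded visit age of each
#' gene-positive subject, using the posterior-mean onset and rate.
#'
#' @param fit an `xdp_trajectory_fit`.
#' @param cohort the cohort the model was fitted to.
#' @return A tibble `subject_id`, `genotype_group`, `visit_index`, `age`,
#'   `progression`.
#' @export
progression_summary <- function(fit, cohort) {
  stopifnot(inherits(fit, "xdp_trajectory_fit"))
  lat <- fit$latents
  cohort$visits |>
    dplyr::inner_join(lat, by = "subject_id") |>
    dplyr::mutate(progression = progression_score(.data$age,
                                                  .data$onset_mean,
                                                  .data$rate_mean)) |>
    dplyr::select("subject_id", "genotype_group", "visit_index", "age",
                  "progression")
}

#' Expected measure value along an age grid
#'
#' The posterior-mean expected trajectory of one measure for given latents:
#' ordinal measures return the expected category value, positive reals the
#' model median `exp(mean)`, counts the softplus Poisson mean (for DDK
#' counts, against the reference offset supplied). With `rate = 0` or
#' `onset = Inf` this is the gene-negative age-only dynamic.
#'
#' @param fit an `xdp_trajectory_fit`.
#' @param measure_id one fitted measure id.
#' @param ages numeric age grid (non-empty).
#' @param onset,rate subject latents (e.g. posterior means from
#'   `fit$latents`); defaults give the gene-negative trajectory.
#' @param offset exposure offset for count measures (default 1).
#' @return A tibble `age`, `expected`.
#' @export
predict_measure_trajectory <- function(fit, measure_id, ages, onset = Inf,
                                       rate = 0, offset = 1) {
  stopifnot(inherits(fit, "xdp_trajectory_fit"), length(ages) > 0)
  for (fam in names(fit$params)) {
    tab <- fit$params[[fam]]
    j <- match(measure_id, tab$measure_id)
    if (!is.na(j)) {
      expected <- vapply(ages, function(a) {
        if (fam == "ordinal") {
          p <- ordinal_category_probs(tab$alpha[[j]], tab$beta1[j],
                                      tab$beta2[j], tab$levels[[j]], a,
                                      rate, onset)
          sum(p * tab$levels[[j]])
        } else if (fam == "continuous") {
          exp(tab$alpha[j] + tab$beta1[j] * a +
                tab$beta2[j] * rate * time_since_onset(a, onset))
        } else {
          count_mean(tab$alpha[j], tab$beta1[j], tab$beta2[j], offset, a,
                     rate, onset)
        }
      }, numeric(1))
      return(tibble::tibble(age = ages, expected = expected))
    }
  }
  stop("measure ", measure_id, " was not fitted")
}

#' Associations of the estimated latents with baseline factors
#'
#' Descriptive association checks on the fitted latents: Pearson correlation
#' of the estimated rate with SVA repeat size, of the estimated onset with
#' repeat size, and rank-based (Kruskal-Wallis) comparisons of the rate
#' across initial-symptom groups and family IDs (families with at least two
#' symptomatic members). Groupings with fewer than two levels are skipped
#' with a note.
#'
#' @param fit an `xdp_trajectory_fit`.
#' @param cohort the fitted cohort.
#' @return A tibble `check`, `statistic`, `estimate`, `p_value`, `n`, `note`.
#' @export
association_tests <- function(fit, cohort) {
  lat <- dplyr::inner_join(
    fit$latents,
    dplyr::select(cohort$subjects, "subject_id", "repeat_size", "family_id",
                  "initial_symptom"),
    by = "subject_id") |>
    dplyr::filter(.data$genotype_group == "positive_symptomatic")
  out <- list()
  corrow <- function(check, x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
      ct <- stats::cor.test(x[ok], y[ok])
      tibble::tibble(check = check, statistic = "pearson_r",
                     estimate = unname(ct$estimate), p_value = ct$p.value,
                     n = sum(ok), note = NA_character_)
    } else {
      tibble::tibble(check = check, statistic = "pearson_r",
                     estimate = NA_real_, p_value = NA_real_, n = sum(ok),
                     note = "insufficient data")
    }
  }
  out$rate_rep <- corrow("rate_vs_repeat_size", lat$rate_mean,
                         lat$repeat_size)
  out$onset_rep <- corrow("onset_vs_repeat_size", lat$onset_mean,
                          lat$repeat_size)
  kwrow <- function(check, value, group) {
    tab <- table(group[!is.na(value)])
    tab <- tab[tab >= 2]
    if (length(tab) >= 2) {
      keep <- group %in% names(tab) & !is.na(value)
      kt <- stats::kruskal.test(value[keep], factor(group[keep]))
      tibble::tibble(check = check, statistic = "kruskal_wallis",
                     estimate = unname(kt$statistic), p_value = kt$p.value,
                     n = sum(keep), note = NA_character_)
    } else {
      tibble::tibble(check = check, statistic = "kruskal_wallis",
                     estimate = NA_real_, p_value = NA_real_,
                     n = sum(!is.na(value)),
                     note = "fewer than two groups; skipped")
    }
  }
  out$sym <- kwrow("rate_by_initial_symptom", lat$rate_mean,
                   lat$initial_symptom)
  out$fam <- kwrow("rate_by_family", lat$rate_mean, lat$family_id)
  dplyr::bind_rows(out)
}
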