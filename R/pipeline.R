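#' Run the full natural-history analysis pipeline
#'
#' Wires all stages end to end: simulate (or ingest) a cohort, test each
#' measure for change over the study, estimate the correlation matrix,
#' select a minimal battery, fit the symptom-trajectory model, fit
#' per-category rates, and write every stage's output as delimited text into
#' `out_dir` together with a manifest of file hashes and seeds. Rerunning
#' with an identical configuration reproduces identical outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param cohort an existing `xdp_cohort`, or `NULL` to simulate one.
#' @param sim a [sim_config()] used when `cohort` is `NULL`.
#' @param fdr_level FDR level for change testing.
#' @param k number of battery blocks to select.
#' @param mcmc list of MCMC settings: `n_chains`, `n_adapt`, `n_burn`,
#'   `n_draws` (applied to the correlation, trajectory and rate stages).
#' @param seed integer master seed for the stochastic stages.
#' @param stages character vector of stages to run, in pipeline order.
#' @param trajectory_measures optional subset of measure ids for the
#'   trajectory fit (default: all 107).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the stage results and the manifest tibble.
#' @export
run_pipeline <- function(out_dir, cohort = NULL, sim = sim_config(),
                         fdr_level = 0.05, k = 15,
                         mcmc = list(n_chains = 2, n_adapt = 300,
                                     n_burn = 300, n_draws = 400),
                         seed = 1L,
                         stages = c("cohort", "change", "correlation",
                                    "battery", "trajectory", "rates"),
                         trajectory_measures = NULL, quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  log_msg <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s: %s",
                                format(Sys.time(), "%H:%M:%S"), stage,
                                paste0(...)))
  }
  results <- list()
  files <- character(0)
  save_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path, na = "")
    files <<- c(files, path)
    path
  }

  if ("cohort" %in% stages) {
    if (is.null(cohort)) {
      log_msg("cohort", "simulating (seed ", sim$seed, ")")
      simres <- simulate_cohort(sim)
      cohort <- simres$cohort
      results$truth <- simres$truth
      save_csv(simres$truth$latents, "truth_latents.csv")
    } else {
      log_msg("cohort", "using supplied cohort")
      validate_cohort(cohort)
    }
    write_cohort(cohort, file.path(out_dir, "cohort"))
    files <- c(files, file.path(out_dir, "cohort",
                                c("subjects.csv", "visits.csv",
                                  "measurements.csv")))
    results$cohort <- cohort
  }
  stopifnot(!is.null(cohort))

  if ("change" %in% stages) {
    log_msg("change", "first-versus-last tests at FDR ", fdr_level)
    ct <- run_change_tests(cohort, fdr_level = fdr_level)
    results$change <- ct
    save_csv(dplyr::select(ct, -dplyr::any_of("members")),
             "results_change.csv")
    log_msg("change", sum(ct$significant), " significant unit(s)")
  }

  if ("correlation" %in% stages) {
    log_msg("correlation", "Bayesian correlation matrix (seed ", seed, ")")
    est <- estimate_correlation(cohort, n_draws = mcmc$n_draws,
                                n_warmup = mcmc$n_burn,
                                n_chains = mcmc$n_chains, seed = seed)
    results$correlation <- est
    rmat <- tibble::as_tibble(est$mean, rownames = "variable")
    save_csv(rmat, "corr_mean.csv")
    hmat <- tibble::as_tibble(est$half_width, rownames = "variable")
    save_csv(hmat, "corr_halfwidth.csv")
  }

  if ("battery" %in% stages && !is.null(results$correlation)) {
    log_msg("battery", "principal-variables selection, k = ", k)
    blocks <- default_battery_blocks(cohort$catalogue)
    present <- purrr::map_lgl(
      blocks$members, ~ all(.x %in% rownames(results$correlation$mean)))
    if (any(!present)) {
      log_msg("battery", sum(!present),
              " block(s) dropped (variables absent from the estimate)")
      blocks <- blocks[present, ]
    }
    k <- min(k, nrow(blocks))
    sel <- select_battery(results$correlation$mean, blocks, k = k,
                          significance = results$change,
                          fdr_level = fdr_level)
    results$battery <- sel
    save_csv(dplyr::mutate(sel, members = purrr::map_chr(
      .data$members, paste, collapse = "+")), "battery.csv")
  }

  if ("trajectory" %in% stages) {
    log_msg("trajectory", "hierarchical fit (seed ", seed, ")")
    fit <- fit_trajectory(cohort, measures = trajectory_measures,
                          n_chains = mcmc$n_chains, n_adapt = mcmc$n_adapt,
                          n_burn = mcmc$n_burn, n_draws = mcmc$n_draws,
                          seed = seed, quiet = TRUE)
    results$trajectory <- fit
    save_csv(fit$latents, "latents.csv")
    save_csv(progression_summary(fit, cohort), "progression.csv")
    save_csv(association_tests(fit, cohort), "associations.csv")
  }

  if ("rates" %in% stages && !is.null(results$trajectory)) {
    log_msg("rates", "per-category refits with fixed onsets")
    on <- stats::setNames(results$trajectory$latents$onset_mean,
                          results$trajectory$latents$subject_id)
    prof <- fit_category_rates(cohort, on,
                               n_chains = mcmc$n_chains,
                               n_adapt = mcmc$n_adapt, n_burn = mcmc$n_burn,
                               n_draws = mcmc$n_draws, seed = seed)
    results$rates <- prof
    save_csv(prof$rates, "category_rates.csv")
    dm <- rate_distance_matrix(prof)
    save_csv(tibble::as_tibble(dm, rownames = "subject_id"),
             "rate_distances.csv")
    cl <- cluster_subjects(dm, prof)
    save_csv(cl$by_average_rate, "subjects_by_average_rate.csv")
  }

  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    seed = seed,
    generated = format(t_start, "%Y-%m-%d %H:%M:%S")
  )
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  log_msg("done", length(files), " artifact(s) in ", out_dir)
  invisible(c(results, list(manifest = manifest)))
}
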