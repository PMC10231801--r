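#' Percent of total variance explained by a variable subset
#'
#' The principal-variables criterion: given a correlation matrix R over p
#' variables and a subset S, the percent of total variance explained is
#' `100 * trace(R[,S] %*% solve(R[S,S]) %*% R[S,]) / p`, the average squared
#' multiple correlation of every variable regressed on the subset, scaled to
#' percent. A Moore-Penrose pseudo-inverse is used when `R[S,S]` is singular.
#'
#' @param R correlation matrix (dimnames give variable ids).
#' @param subset character vector of variable ids (or integer indices).
#' @return A percentage in `[0, 100]`.
#' @examples
#' R <- diag(4)
#' pve(R, 1)         # 25: one of four orthogonal variables
#' pve(R, 1:4)       # 100
#' pve(R, integer()) # 0
#' @export
pve <- function(R, subset) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R), nrow(R) >= 1)
  p <- nrow(R)
  if (length(subset) == 0) return(0)
  if (is.character(subset)) {
    idx <- match(subset, rownames(R))
    if (anyNA(idx)) stop("unknown variable(s): ",
                         paste(subset[is.na(idx)], collapse = ", "))
  } else idx <- as.integer(subset)
  Rss <- R[idx, idx, drop = FALSE]
  Rxs <- R[, idx, drop = FALSE]
  inv <- tryCatch(solve(Rss), error = function(e) MASS::ginv(Rss))
  100 * sum(diag(Rxs %*% inv %*% t(Rxs))) / p
}

#' Default battery blocks for principal-variables selection
#'
#' Groups the correlation variables into selection blocks: measures naturally
#' taken in pairs enter as one block (left/right analogues of the bilateral
#' UPDRS Part 3 items and the BFM movement limb items, and each DDK count
#' with its paired duration); every other variable is its own block. The
#' three subject-level constants (repeat size, reported onset, height) are
#' excluded from selection by default since they are not progression
#' measures.
#'
#' @param catalogue a catalogue tibble ([xdp_catalogue()]).
#' @param include_constants keep repeat size / reported onset / height as
#'   selectable singleton blocks (default `FALSE`).
#' @return A tibble with columns `block_id`, `members` (list of variable
#'   ids).
#' @export
default_battery_blocks <- function(catalogue = xdp_catalogue(),
                                   include_constants = FALSE) {
  vars <- correlation_variables(catalogue)
  if (!include_constants) {
    vars <- dplyr::filter(vars, !.data$subject_constant)
  }
  pair_sets <- list(
    c("updrs3_3_3b", "updrs3_3_3c"),  # rigidity upper extremities
    c("updrs3_3_3d", "updrs3_3_3e"),  # rigidity lower extremities
    c("updrs3_3_4a", "updrs3_3_4b"),  # finger tapping
    c("updrs3_3_5a", "updrs3_3_5b"),  # hand movements
    c("updrs3_3_6a", "updrs3_3_6b"),  # pronation-supination
    c("updrs3_3_7a", "updrs3_3_7b"),  # toe tapping
    c("updrs3_3_8a", "updrs3_3_8b"),  # leg agility
    c("updrs3_3_15a", "updrs3_3_15b"), # postural tremor
    c("updrs3_3_16a", "updrs3_3_16b"), # kinetic tremor
    c("updrs3_3_17a", "updrs3_3_17b"), # rest tremor arms
    c("updrs3_3_17c", "updrs3_3_17d"), # rest tremor legs
    c("bfm_mov_rarm", "bfm_mov_larm"),
    c("bfm_mov_rleg", "bfm_mov_lleg"),
    c("ddk_ba_count", "ddk_ba_secs"),
    c("ddk_da_count", "ddk_da_secs"),
    c("ddk_ka_count", "ddk_ka_secs"),
    c("ddk_amr_count", "ddk_amr_secs")
  )
  pair_sets <- purrr::keep(pair_sets,
                           ~ all(.x %in% vars$unit_id))
  paired <- unlist(pair_sets)
  singles <- setdiff(vars$unit_id, paired)
  tibble::tibble(
    block_id = c(purrr::map_chr(pair_sets, 1), singles),
    members = c(pair_sets, as.list(singles))
  ) |>
    dplyr::arrange(match(.data$block_id, vars$unit_id))
}

#' Greedy principal-variables battery selection
#'
#' Forward selection over blocks of variables: at each step the block with
#' the largest incremental percent of variance explained is added. Among
#' candidates whose incremental PVE ties within `tol`, a block containing a
#' measure that changed significantly over the study (adjusted p below
#' `fdr_level`) is preferred; remaining ties break on block id. Significance
#' is a preference, never a hard filter. For each selected block the output
#' reports PVE alone (the block by itself) and PVE jointly (the leave-one-out
#' increment within the final selected set), plus the cumulative PVE after
#' each step.
#'
#' @param R correlation matrix with variable dimnames.
#' @param blocks block tibble ([default_battery_blocks()]).
#' @param k number of blocks to select.
#' @param significance optional tibble with columns `unit_id`, `p_adjusted`
#'   (e.g. a [run_change_tests()] result); used for the tie-break.
#' @param fdr_level significance level on adjusted p-values (default 0.05).
#' @param tol tie tolerance on incremental PVE (default 1e-6).
#' @return A tibble of class `xdp_battery`, one row per selected block in
#'   selection order: `block_id`, `members`, `pve_alone`, `pve_joint`,
#'   `cumulative_pve`.
#' @export
select_battery <- function(R, blocks, k, significance = NULL,
                           fdr_level = 0.05, tol = 1e-6) {
  stopifnot(k >= 1)
  if (k > nrow(blocks)) {
    stop("k = ", k, " exceeds the ", nrow(blocks), " available blocks")
  }
  sig_ids <- character(0)
  if (!is.null(significance)) {
    sig_ids <- significance$unit_id[
      !is.na(significance$p_adjusted) & significance$p_adjusted < fdr_level]
  }
  block_sig <- purrr::map_lgl(blocks$members, ~ any(.x %in% sig_ids))

  selected <- integer(0)
  sel_vars <- character(0)
  cumulative <- numeric(0)
  current <- 0
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(nrow(blocks)), selected)
    inc <- vapply(cand, function(b) {
      pve(R, c(sel_vars, blocks$members[[b]])) - current
    }, numeric(1))
    best <- max(inc)
    tied <- cand[inc >= best - tol]
    if (length(tied) > 1) {
      tied_sig <- tied[block_sig[tied]]
      if (length(tied_sig) > 0) tied <- tied_sig
      # residual ties: keep greedy-optimal first, then block id order
      tied <- tied[order(-inc[match(tied, cand)], blocks$block_id[tied])]
    }
    pick <- tied[1]
    selected <- c(selected, pick)
    sel_vars <- c(sel_vars, blocks$members[[pick]])
    current <- pve(R, sel_vars)
    cumulative <- c(cumulative, current)
  }

  pve_alone <- vapply(selected, function(b) pve(R, blocks$members[[b]]),
                      numeric(1))
  pve_joint <- vapply(selected, function(b) {
    others <- setdiff(sel_vars, blocks$members[[b]])
    current - pve(R, others)
  }, numeric(1))

  out <- tibble::tibble(
    block_id = blocks$block_id[selected],
    members = blocks$members[selected],
    pve_alone = pve_alone,
    pve_joint = pve_joint,
    cumulative_pve = cumulative
  )
  attr(out, "total_pve") <- current
  class(out) <- c("xdp_battery", class(out))
  out
}

#' The proposed minimal battery of progression measures
#'
#' The published minimal battery: 15 groups containing 21 measures, each with
#' its reported percent of variance explained alone and jointly. Serves as
#' the reference for comparing data-driven selections.
#'
#' @return A tibble with columns `block_id`, `label`, `members` (list of
#'   measure ids), `pve_alone`, `pve_joint` (percent).
#' @export
reference_battery <- function() {
  tibble::tribble(
    ~block_id, ~label, ~members, ~pve_alone, ~pve_joint,
    "weight", "Weight", list("weight"), 10.3, 3.0,
    "bfm_dis_speech", "BFM disability: speech", list("bfm_dis_speech"), 9.9, 3.2,
    "bfm_dis_feeding", "BFM disability: feeding", list("bfm_dis_feeding"), 18.2, 4.5,
    "bfm_dis_dressing", "BFM disability: dressing", list("bfm_dis_dressing"), 16.0, 4.8,
    "bfm_mov_rarm", "BFM movement: arms",
    list(c("bfm_mov_rarm", "bfm_mov_larm")), 14.9, 5.5,
    "bfm_mov_rleg", "BFM movement: legs",
    list(c("bfm_mov_rleg", "bfm_mov_lleg")), 12.8, 4.9,
    "updrs3_3_2", "UPDRS 3.2: facial expression", list("updrs3_3_2"), 12.1, 3.5,
    "updrs3_3_3b", "UPDRS 3.3: rigidity - upper extremities",
    list(c("updrs3_3_3b", "updrs3_3_3c")), 8.2, 4.7,
    "updrs3_3_7a", "UPDRS 3.7: toe tapping",
    list(c("updrs3_3_7a", "updrs3_3_7b")), 12.9, 5.5,
    "updrs3_3_11", "UPDRS 3.11: freezing of gait", list("updrs3_3_11"), 9.0, 3.0,
    "updrs3_3_15a", "UPDRS 3.15: postural tremor of the hands",
    list(c("updrs3_3_15a", "updrs3_3_15b")), 9.9, 4.6,
    "updrs3_3_18", "UPDRS 3.18: constancy of rest tremor",
    list("updrs3_3_18"), 8.1, 4.4,
    "eat10_q01", "EAT-10: Q1 - weight loss", list("eat10_q01"), 17.1, 4.8,
    "eat10_q08", "EAT-10: Q8 - food sticks in throat", list("eat10_q08"), 9.1, 2.7,
    "ddk_ka_count", "DDK: Ka",
    list(c("ddk_ka_count", "ddk_ka_secs")), 8.7, 6.5
  )
}

#' Compare a selected battery against a reference battery
#'
#' Tabulates the selected blocks beside a reference battery (by default the
#' published 15-group / 21-measure battery) and counts agreement at the level
#' of member measures.
#'
#' @param selection an `xdp_battery` from [select_battery()].
#' @param reference a reference battery tibble ([reference_battery()]).
#' @return A list: `table` (one row per reference or selected block with an
#'   `in_selection` / `in_reference` flag), `n_agree` (measures in both),
#'   `agreement` (share of reference measures selected).
#' @export
report_battery <- function(selection, reference = reference_battery()) {
  sel_members <- unique(unlist(selection$members))
  ref_members <- unique(unlist(reference$members))
  agree <- intersect(sel_members, ref_members)
  tab <- dplyr::bind_rows(
    tibble::tibble(source = "reference", block_id = reference$block_id,
                   members = purrr::map_chr(reference$members, paste,
                                            collapse = "+"),
                   in_other = purrr::map_lgl(reference$members,
                                             ~ all(.x %in% sel_members))),
    tibble::tibble(source = "selection", block_id = selection$block_id,
                   members = purrr::map_chr(selection$members, paste,
                                            collapse = "+"),
                   in_other = purrr::map_lgl(selection$members,
                                             ~ all(.x %in% ref_members)))
  )
  list(table = tab, n_agree = length(agree),
       agreement = length(agree) / length(ref_members))
}
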