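#' Construct a longitudinal XDP cohort object
#'
#' Bundles the three tables of the cohort data model with a measure catalogue
#' and validates them jointly:
#'
#' * `subjects`: one row per participant with `subject_id`, `genotype_group`
#'   (`"positive_symptomatic"`, `"positive_presymptomatic"`, `"negative"`),
#'   `reported_onset` (years; present iff symptomatic gene-positive),
#'   `repeat_size` (SVA hexamer count, possibly missing), `family_id`,
#'   `initial_symptom` (`"dystonia"`, `"parkinsonism"`, `"none"`) and
#'   `height` (cm, possibly missing).
#' * `visits`: one row per subject visit with `subject_id`, `visit_index`
#'   (0-based, 0 = enrollment) and `age` in decimal years, strictly
#'   increasing within subject.
#' * `observations`: long-format records `subject_id`, `visit_index`,
#'   `measure_id`, `value`; at most one row per (subject, visit, measure);
#'   values must respect the catalogue (ordinal values in the level set,
#'   positive reals > 0, counts non-negative integers). Missing values are
#'   represented by absent rows or `NA`, never by sentinel numbers.
#'
#' @param subjects,visits,observations tibbles as described above.
#' @param catalogue a catalogue tibble ([xdp_catalogue()]).
#' @return An object of class `xdp_cohort` (a named list of the four parts).
#' @export
xdp_cohort <- function(subjects, visits, observations,
                       catalogue = xdp_catalogue()) {
  cohort <- structure(
    list(catalogue = catalogue,
         subjects = tibble::as_tibble(subjects),
         visits = tibble::as_tibble(visits),
         observations = tibble::as_tibble(observations)),
    class = "xdp_cohort"
  )
  validate_cohort(cohort)
  cohort
}

#' @export
print.xdp_cohort <- function(x, ...) {
  grp <- table(factor(x$subjects$genotype_group,
                      c("positive_symptomatic", "positive_presymptomatic",
                        "negative")))
  cat("<xdp_cohort>\n")
  cat(sprintf("  subjects: %d (%d symptomatic+, %d pre-symptomatic+, %d negative)\n",
              nrow(x$subjects), grp[1], grp[2], grp[3]))
  cat(sprintf("  visits: %d rows; observations: %d rows; measures: %d\n",
              nrow(x$visits), nrow(x$observations),
              sum(!x$catalogue$auxiliary)))
  invisible(x)
}

#' Validate an XDP cohort
#'
#' Row-level checks with row-numbered diagnostics: every observation must
#' reference an existing subject, visit and catalogue measure; no duplicate
#' (subject, visit, measure) triples; ordinal values inside their level set;
#' positive reals strictly positive; counts non-negative integers; visit ages
#' strictly increasing within subject; reported onset present exactly for
#' symptomatic gene-positive subjects.
#'
#' @param cohort an `xdp_cohort`.
#' @return The cohort, invisibly. Errors collect up to 10 offending rows.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "xdp_cohort") || is.list(cohort))
  catalogue <- validate_catalogue(cohort$catalogue)
  sub <- cohort$subjects
  vis <- cohort$visits
  obs <- cohort$observations
  problems <- character(0)
  note <- function(rows, what, table) {
    if (length(rows) > 0) {
      shown <- utils::head(rows, 10)
      problems <<- c(problems, sprintf(
        "%s (%s rows %s%s)", what, table, paste(shown, collapse = ", "),
        if (length(rows) > 10) ", ..." else ""))
    }
  }

  good_groups <- c("positive_symptomatic", "positive_presymptomatic", "negative")
  note(which(!sub$genotype_group %in% good_groups),
       "unknown genotype_group", "subjects")
  note(which(duplicated(sub$subject_id)), "duplicate subject_id", "subjects")
  sym <- sub$genotype_group == "positive_symptomatic"
  note(which(sym & is.na(sub$reported_onset)),
       "symptomatic subject without reported_onset", "subjects")
  note(which(!sym & !is.na(sub$reported_onset)),
       "reported_onset on a non-symptomatic subject", "subjects")

  note(which(!vis$subject_id %in% sub$subject_id),
       "visit for unknown subject", "visits")
  bad_age <- vis |>
    dplyr::arrange(.data$subject_id, .data$visit_index) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(bad = c(FALSE, diff(.data$age) <= 0) |
                    duplicated(.data$visit_index)) |>
    dplyr::ungroup()
  note(which(bad_age$bad[order(order(vis$subject_id, vis$visit_index))]),
       "non-increasing visit ages or duplicate visit_index", "visits")

  if (nrow(obs) > 0) {
    key <- paste(obs$subject_id, obs$visit_index, obs$measure_id)
    note(which(duplicated(key)),
         "duplicate (subject, visit, measure) observation", "measurements")
    note(which(!obs$measure_id %in% catalogue$measure_id),
         "unknown measure_id", "measurements")
    vkey <- paste(vis$subject_id, vis$visit_index)
    note(which(!paste(obs$subject_id, obs$visit_index) %in% vkey),
         "observation at an unrecorded visit", "measurements")

    idx <- match(obs$measure_id, catalogue$measure_id)
    kind <- catalogue$value_kind[idx]
    v <- obs$value
    ok_level <- vapply(seq_along(v), function(i) {
      if (is.na(v[i]) || is.na(idx[i]) || kind[i] != "ordinal") return(TRUE)
      v[i] %in% catalogue$ordinal_levels[[idx[i]]]
    }, logical(1))
    note(which(!ok_level), "ordinal value outside level set", "measurements")
    note(which(!is.na(v) & kind == "positive_real" & v <= 0),
         "non-positive value for positive_real measure", "measurements")
    note(which(!is.na(v) & kind == "count" & (v < 0 | v != round(v))),
         "count value not a non-negative integer", "measurements")
  }

  if (length(problems) > 0) {
    stop("invalid cohort:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(cohort)
}

#' Write a cohort to delimited text files
#'
#' Writes `subjects.csv`, `visits.csv` and `measurements.csv` (comma
#' delimited, UTF-8, header row; missing values as empty fields) into `dir`.
#'
#' @param cohort an `xdp_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  validate_cohort(cohort)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$subjects, file.path(dir, "subjects.csv"), na = "")
  readr::write_csv(cohort$visits, file.path(dir, "visits.csv"), na = "")
  readr::write_csv(cohort$observations, file.path(dir, "measurements.csv"),
                   na = "")
  invisible(dir)
}

#' Read a cohort from delimited text files
#'
#' Inverse of [write_cohort()]: reads `subjects.csv`, `visits.csv` and
#' `measurements.csv` from `dir`, coerces column types, and validates against
#' the catalogue. Invalid rows are reported with row numbers. Values for count
#' measures that arrive fractional (e.g. averaged lip-strength trials) are
#' rounded half-up, with a message recording how many rows were rounded.
#'
#' @param dir directory containing the three files.
#' @param catalogue a catalogue tibble ([xdp_catalogue()]).
#' @return An `xdp_cohort`.
#' @export
read_cohort <- function(dir, catalogue = xdp_catalogue()) {
  rd <- function(name, types) {
    path <- file.path(dir, name)
    if (!file.exists(path)) stop("missing cohort file: ", path, call. = FALSE)
    readr::read_csv(path, col_types = types, na = c("", "NA"),
                    progress = FALSE)
  }
  subjects <- rd("subjects.csv", readr::cols(
    subject_id = "c", genotype_group = "c", reported_onset = "d",
    repeat_size = "d", family_id = "c", initial_symptom = "c", height = "d"))
  visits <- rd("visits.csv", readr::cols(
    subject_id = "c", visit_index = "i", age = "d"))
  observations <- rd("measurements.csv", readr::cols(
    subject_id = "c", visit_index = "i", measure_id = "c", value = "d"))

  idx <- match(observations$measure_id, catalogue$measure_id)
  is_count <- !is.na(idx) & catalogue$value_kind[idx] == "count"
  frac <- is_count & !is.na(observations$value) &
    observations$value != round(observations$value)
  if (any(frac)) {
    # round half-up, not banker's rounding
    observations$value[frac] <- floor(observations$value[frac] + 0.5)
    message(sum(frac), " count value(s) rounded half-up on read")
  }
  xdp_cohort(subjects, visits, observations, catalogue)
}

#' Per-visit values of an analysis test unit
#'
#' Resolves a test unit (from [change_testing_variables()]) to one value per
#' subject-visit: single-measure units take the observation value; the summed
#' CPIB unit takes the per-visit sum of its items (missing if any item is
#' missing at that visit).
#'
#' @param cohort an `xdp_cohort`.
#' @param members character vector of constituent measure ids.
#' @param subjects optional character vector restricting subjects.
#' @return A tibble `subject_id`, `visit_index`, `value` (NA when missing).
#' @export
unit_values <- function(cohort, members, subjects = NULL) {
  vis <- cohort$visits
  if (!is.null(subjects)) vis <- dplyr::filter(vis, .data$subject_id %in% subjects)
  obs <- dplyr::filter(cohort$observations, .data$measure_id %in% members)
  grid <- tidyr::crossing(
    dplyr::select(vis, "subject_id", "visit_index"),
    measure_id = members
  )
  full <- dplyr::left_join(grid, obs,
                           by = c("subject_id", "visit_index", "measure_id"))
  full |>
    dplyr::group_by(.data$subject_id, .data$visit_index) |>
    dplyr::summarise(value = if (length(members) == 1) .data$value[1] else
      sum(.data$value), .groups = "drop")
}
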