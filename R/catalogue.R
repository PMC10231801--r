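#' The default XDP measure catalogue
#'
#' Builds the full inventory of the 107 clinical measures collected in the
#' XDP natural-history protocol, one row per individual measure. Each row
#' records the measure's group (e.g. MDS-UPDRS Part 3, BFM movement scale),
#' its value kind (`"ordinal"`, `"positive_real"` or `"count"`), the ordinal
#' level set where applicable, the clinical severity direction (+1 when higher
#' values mean worse disease, -1 when higher values mean better function),
#' the Poisson offset link for count measures (`"unit"` for lip strength, the
#' paired diadochokinetic (DDK) duration measure for the DDK syllable counts),
#' and the rate-heterogeneity category the measure belongs to.
#'
#' Group inventory: MDS-UPDRS Parts 1/2/3 (13 + 13 + 33 items, ordinal 0-4),
#' BFM disability scale (6 items ordinal 0-4 plus walking with levels
#' 0-4 and 6), BFM movement scale (9 items with the irregular level set
#' 0,1,2,3,4,6,8,9,12,16), EAT-10 (10 items, 0-4), CPIB short form
#' (10 items, 0-3), lip strength (rounded kPa count), tongue strength,
#' maximum phonation time, 4 DDK syllable counts with 4 paired DDK durations,
#' and swallow duration; 107 measures in total.
#'
#' Auxiliary variables (participant weight, height and BMI) are carried in a
#' companion block flagged `auxiliary = TRUE`; they are not part of the 107
#' modelled measures but enter specific analyses (weight in change testing,
#' height in the correlation set, BMI as its own rate-heterogeneity category).
#'
#' @param include_auxiliary logical; append the auxiliary weight/height/BMI
#'   rows (flagged by the `auxiliary` column). Default `TRUE`.
#' @return A tibble with columns `measure_id`, `label`, `group`, `value_kind`,
#'   `ordinal_levels` (list column of numeric level sets), `severity_direction`,
#'   `offset_link`, `category`, `auxiliary`.
#' @examples
#' cat107 <- xdp_catalogue(include_auxiliary = FALSE)
#' nrow(cat107)            # 107
#' dplyr::count(cat107, group)
#' @export
xdp_catalogue <- function(include_auxiliary = TRUE) {
  lev04 <- list(0:4)
  row <- function(id, label, group, kind, levels, dir, offset, category) {
    tibble::tibble(
      measure_id = id, label = label, group = group, value_kind = kind,
      ordinal_levels = lapply(levels, as.numeric),
      severity_direction = as.integer(dir),
      offset_link = offset, category = category, auxiliary = FALSE
    )
  }
  ord <- function(ids, labels, group, category, levels = lev04, dir = 1L) {
    row(ids, labels, group, "ordinal", rep(levels, length(ids)), dir,
        NA_character_, category)
  }

  updrs1_items <- c(
    "cognitive impairment", "hallucinations and psychosis", "depressed mood",
    "anxious mood", "apathy", "dopamine dysregulation syndrome",
    "sleep problems", "daytime sleepiness", "pain and other sensations",
    "urinary problems", "constipation problems", "light headedness on standing",
    "fatigue"
  )
  updrs2_items <- c(
    "speech", "saliva and drooling", "chewing and swallowing", "eating tasks",
    "dressing", "hygiene", "handwriting", "doing hobbies", "turning in bed",
    "tremor", "getting out of bed", "walking and balance", "freezing"
  )
  updrs3 <- tibble::tribble(
    ~stem,          ~item,                            ~category,
    "3.1",  "speech",                                 "speech",
    "3.2",  "facial expression",                      "bradykinesia",
    "3.3a", "rigidity - neck",                        "rigidity",
    "3.3b", "rigidity - RUE",                         "rigidity",
    "3.3c", "rigidity - LUE",                         "rigidity",
    "3.3d", "rigidity - RLE",                         "rigidity",
    "3.3e", "rigidity - LLE",                         "rigidity",
    "3.4a", "finger tapping - right hand",            "bradykinesia",
    "3.4b", "finger tapping - left hand",             "bradykinesia",
    "3.5a", "hand movements - right hand",            "bradykinesia",
    "3.5b", "hand movements - left hand",             "bradykinesia",
    "3.6a", "pronation-supination - right hand",      "bradykinesia",
    "3.6b", "pronation-supination - left hand",       "bradykinesia",
    "3.7a", "toe tapping - right foot",               "bradykinesia",
    "3.7b", "toe tapping - left foot",                "bradykinesia",
    "3.8a", "leg agility - right leg",                "bradykinesia",
    "3.8b", "leg agility - left leg",                 "bradykinesia",
    "3.9",  "arising from chair",                     "gait",
    "3.10", "gait",                                   "gait",
    "3.11", "freezing of gait",                       "gait",
    "3.12", "postural stability",                     "gait",
    "3.13", "posture",                                "gait",
    "3.14", "global spontaneity of movement",         "bradykinesia",
    "3.15a", "postural tremor of the hands - right",  "tremor_other",
    "3.15b", "postural tremor of the hands - left",   "tremor_other",
    "3.16a", "kinetic tremor of the hands - right",   "tremor_other",
    "3.16b", "kinetic tremor of the hands - left",    "tremor_other",
    "3.17a", "rest tremor amplitude - RUE",           "tremor_rest",
    "3.17b", "rest tremor amplitude - LUE",           "tremor_rest",
    "3.17c", "rest tremor amplitude - RLE",           "tremor_rest",
    "3.17d", "rest tremor amplitude - LLE",           "tremor_rest",
    "3.17e", "rest tremor amplitude - lip/jaw",       "tremor_rest",
    "3.18", "constancy of rest tremor",               "tremor_rest"
  )
  bfm_dis <- tibble::tribble(
    ~id,                 ~item,        ~category,
    "bfm_dis_speech",    "speech",     "speech",
    "bfm_dis_handwriting", "handwriting", "daily_living_motor",
    "bfm_dis_feeding",   "feeding",    "daily_living_motor",
    "bfm_dis_eating",    "eating and swallowing", "swallowing",
    "bfm_dis_hygiene",   "hygiene",    "daily_living_motor",
    "bfm_dis_dressing",  "dressing",   "daily_living_motor"
  )
  bfm_mov <- tibble::tribble(
    ~id,              ~item,                  ~category,
    "bfm_mov_eyes",   "eyes",                 "dystonia_axial",
    "bfm_mov_mouth",  "mouth",                "dystonia_axial",
    "bfm_mov_speech", "speech and swallowing", "speech",
    "bfm_mov_neck",   "neck",                 "dystonia_axial",
    "bfm_mov_rarm",   "right arm",            "dystonia_limbs",
    "bfm_mov_larm",   "left arm",             "dystonia_limbs",
    "bfm_mov_trunk",  "trunk",                "dystonia_axial",
    "bfm_mov_rleg",   "right leg",            "dystonia_limbs",
    "bfm_mov_lleg",   "left leg",             "dystonia_limbs"
  )
  eat10_items <- c(
    "my swallowing problem has caused me to lose weight",
    "my swallowing problem interferes with going out for meals",
    "swallowing liquids takes extra effort",
    "swallowing solids takes extra effort",
    "swallowing pills takes extra effort",
    "swallowing is painful",
    "the pleasure of eating is affected by my swallowing",
    "when I swallow food sticks in my throat",
    "I cough when I eat",
    "swallowing is stressful"
  )
  ddk <- tibble::tribble(
    ~task, ~label,
    "ba",  "SMR Ba",
    "da",  "SMR Da",
    "ka",  "SMR Ka",
    "amr", "AMR"
  )

  core <- dplyr::bind_rows(
    ord(sprintf("updrs1_%02d", seq_len(13)),
        paste0("UPDRS 1.", seq_len(13), ": ", updrs1_items),
        "MDS-UPDRS Part 1", "non_motor"),
    ord(sprintf("updrs2_%02d", seq_len(13)),
        paste0("UPDRS 2.", seq_len(13), ": ", updrs2_items),
        "MDS-UPDRS Part 2", "daily_living_motor"),
    ord(paste0("updrs3_", gsub("\\.", "_", updrs3$stem)),
        paste0("UPDRS ", sub("[a-e]$", "", updrs3$stem), ": ", updrs3$item),
        "MDS-UPDRS Part 3", updrs3$category),
    ord(bfm_dis$id, paste0("BFM disability: ", bfm_dis$item),
        "BFM disability scale", bfm_dis$category),
    ord("bfm_dis_walking", "BFM disability: walking",
        "BFM disability scale: walking", "gait",
        levels = list(c(0, 1, 2, 3, 4, 6))),
    ord(bfm_mov$id, paste0("BFM movement: ", bfm_mov$item),
        "BFM movement scale", bfm_mov$category,
        levels = list(c(0, 1, 2, 3, 4, 6, 8, 9, 12, 16))),
    ord(sprintf("eat10_q%02d", seq_len(10)),
        paste0("EAT-10: Q", seq_len(10), " - ", eat10_items),
        "EAT-10 survey", "swallowing"),
    ord(sprintf("cpib_q%02d", seq_len(10)),
        paste0("CPIB: Q", seq_len(10)),
        "CPIB survey", "speech", levels = list(0:3), dir = -1L),
    row("lip_strength", "Lip strength (kPa)", "Lip strength", "count",
        list(numeric(0)), -1L, "unit", "oromotor_quantitative"),
    row("tongue_strength", "Tongue strength (kPa)", "Tongue strength",
        "positive_real", list(numeric(0)), -1L, NA_character_,
        "oromotor_quantitative"),
    row("mpt", "Maximum phonation time (s)", "Maximum phonation time",
        "positive_real", list(numeric(0)), -1L, NA_character_,
        "oromotor_quantitative"),
    row(paste0("ddk_", ddk$task, "_count"),
        paste0("DDK: ", ddk$label, " count"),
        "DDK counts", "count", rep(list(numeric(0)), 4), -1L,
        paste0("ddk_", ddk$task, "_secs"), "oromotor_quantitative"),
    row(paste0("ddk_", ddk$task, "_secs"),
        paste0("DDK: ", ddk$label, " secs"),
        "DDK durations", "positive_real", rep(list(numeric(0)), 4), -1L,
        NA_character_, "oromotor_quantitative"),
    row("swallow_duration", "Swallow duration (s)", "Swallow duration",
        "positive_real", list(numeric(0)), 1L, NA_character_, "swallowing")
  )

  if (include_auxiliary) {
    aux <- tibble::tibble(
      measure_id = c("weight", "height", "bmi"),
      label = c("Weight (kg)", "Height (cm)", "Body mass index"),
      group = "Auxiliary",
      value_kind = "positive_real",
      ordinal_levels = rep(list(numeric(0)), 3),
      severity_direction = -1L,
      offset_link = NA_character_,
      category = c(NA_character_, NA_character_, "bmi"),
      auxiliary = TRUE
    )
    core <- dplyr::bind_rows(core, aux)
  }
  validate_catalogue(core)
  core
}

#' Validate a measure catalogue
#'
#' Checks the structural invariants of a catalogue tibble: unique measure ids,
#' known value kinds, strictly increasing ordinal level sets with at least two
#' levels, offset links only on count measures and resolving to an existing
#' positive-real measure (or `"unit"`), and severity directions in {-1, +1}.
#'
#' @param catalogue a catalogue tibble as returned by [xdp_catalogue()].
#' @return The catalogue, invisibly; errors describe the first violation found.
#' @export
validate_catalogue <- function(catalogue) {
  req <- c("measure_id", "label", "group", "value_kind", "ordinal_levels",
           "severity_direction", "offset_link", "category", "auxiliary")
  missing_cols <- setdiff(req, names(catalogue))
  if (length(missing_cols) > 0) {
    stop("catalogue is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(catalogue$measure_id)) {
    dup <- unique(catalogue$measure_id[duplicated(catalogue$measure_id)])
    stop("duplicate measure_id: ", paste(dup, collapse = ", "))
  }
  bad_kind <- setdiff(unique(catalogue$value_kind),
                      c("ordinal", "positive_real", "count"))
  if (length(bad_kind) > 0) {
    stop("unknown value_kind: ", paste(bad_kind, collapse = ", "))
  }
  if (!all(catalogue$severity_direction %in% c(-1L, 1L))) {
    stop("severity_direction must be +1 or -1")
  }
  for (i in seq_len(nrow(catalogue))) {
    lv <- catalogue$ordinal_levels[[i]]
    if (catalogue$value_kind[i] == "ordinal") {
      if (length(lv) < 2 || any(diff(lv) <= 0)) {
        stop("measure ", catalogue$measure_id[i],
             ": ordinal_levels must be strictly increasing with K >= 2")
      }
    } else if (length(lv) > 0) {
      stop("measure ", catalogue$measure_id[i],
           ": non-ordinal measures must have empty ordinal_levels")
    }
    ol <- catalogue$offset_link[i]
    if (!is.na(ol)) {
      if (catalogue$value_kind[i] != "count") {
        stop("measure ", catalogue$measure_id[i],
             ": offset_link is only valid for count measures")
      }
      if (ol != "unit" && !ol %in% catalogue$measure_id) {
        stop("measure ", catalogue$measure_id[i],
             ": offset_link '", ol, "' does not name a catalogue measure")
      }
    } else if (catalogue$value_kind[i] == "count") {
      stop("measure ", catalogue$measure_id[i],
           ": count measures need an offset_link ('unit' or a duration id)")
    }
  }
  invisible(catalogue)
}

core_measures <- function(catalogue) {
  dplyr::filter(catalogue, !.data$auxiliary)
}

cpib_ids <- function(catalogue) {
  catalogue$measure_id[catalogue$group == "CPIB survey" & !catalogue$auxiliary]
}

#' Variable set for first-versus-last change testing
#'
#' Derives the ordered list of test units from a catalogue: every
#' non-auxiliary measure, with the 10 CPIB items collapsed into a single
#' summed unit (`cpib_total`, the per-visit sum of the ten item scores, which
#' are very strongly correlated), and participant weight appended as an extra
#' unit. With the default catalogue this yields 99 test units.
#'
#' @param catalogue a catalogue tibble ([xdp_catalogue()]).
#' @return A tibble with columns `unit_id`, `label`, `members` (list column of
#'   constituent measure ids) and `severity_direction`.
#' @export
change_testing_variables <- function(catalogue) {
  validate_catalogue(catalogue)
  core <- core_measures(catalogue)
  cpib <- cpib_ids(catalogue)
  units <- tibble::tibble(
    unit_id = core$measure_id,
    label = core$label,
    members = as.list(core$measure_id),
    severity_direction = core$severity_direction
  )
  if (length(cpib) > 0) {
    first_cpib <- match(cpib[1], units$unit_id)
    units$unit_id[first_cpib] <- "cpib_total"
    units$label[first_cpib] <- "CPIB total"
    units$members[[first_cpib]] <- cpib
    units$severity_direction[first_cpib] <- -1L
    units <- dplyr::filter(units, !.data$unit_id %in% cpib)
  }
  dplyr::bind_rows(
    units,
    tibble::tibble(unit_id = "weight", label = "Weight (kg)",
                   members = list("weight"), severity_direction = -1L)
  )
}

#' Variable set for the correlation analysis
#'
#' The change-testing units plus three subject-level constants: SVA repeat
#' size, reported age at onset and height. With the default catalogue this
#' yields 102 variables. The constants carry no visit index; when assembling
#' the subject-visit data matrix they are replicated across a subject's
#' visits.
#'
#' @param catalogue a catalogue tibble ([xdp_catalogue()]).
#' @return A tibble like [change_testing_variables()] with an extra logical
#'   column `subject_constant`.
#' @export
correlation_variables <- function(catalogue) {
  units <- change_testing_variables(catalogue)
  units$subject_constant <- FALSE
  extras <- tibble::tibble(
    unit_id = c("repeat_size", "reported_onset", "height"),
    label = c("SVA repeat size", "Reported age at onset", "Height (cm)"),
    members = list("repeat_size", "reported_onset", "height"),
    severity_direction = c(1L, 1L, -1L),
    subject_constant = TRUE
  )
  out <- dplyr::bind_rows(units, extras)
  stopifnot(!anyDuplicated(out$unit_id))
  out
}

#' Default rate-heterogeneity category scheme
#'
#' The 13 pre-defined categories of measures used by the rate-heterogeneity
#' analysis, assembled from the catalogue's `category` column: rigidity,
#' rest tremor, other (postural/kinetic) tremor, bradykinesia, limb dystonia,
#' axial dystonia, speech, swallowing, gait, non-motor symptoms, motor aspects
#' of daily living, quantitative oromotor measures, and BMI (BMI is its own
#' category here even though it is excluded from the global trajectory model).
#' The exact clinical grouping is a package default and can be overridden by
#' supplying any `measure_id -> category` mapping of at least two categories.
#'
#' @param catalogue a catalogue tibble ([xdp_catalogue()]).
#' @return A tibble with columns `measure_id`, `category`.
#' @export
default_category_scheme <- function(catalogue = xdp_catalogue()) {
  validate_catalogue(catalogue)
  out <- dplyr::filter(catalogue, !is.na(.data$category))
  tibble::tibble(measure_id = out$measure_id, category = out$category)
}
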