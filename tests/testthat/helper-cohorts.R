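# Shared fixture builders (generated in code, no stored data).

# small catalogue subset spanning all three value kinds
small_measure_set <- function() {
  c(sprintf("updrs1_%02d", 1:6), sprintf("updrs2_%02d", 1:4),
    "bfm_mov_rarm", "bfm_mov_larm", "bfm_dis_speech", "bfm_dis_feeding",
    "tongue_strength", "mpt", "swallow_duration",
    "lip_strength", "ddk_ka_count", "ddk_ka_secs")
}

# the reduced cohort used by the MCMC-heavy checks: 40 subjects, 20 measures
recovery_cohort <- function(seed = 2) {
  simulate_cohort(sim_config(n_symptomatic = 25, n_presymptomatic = 5,
                             n_negative = 10, seed = seed))
}

# tiny hand-built cohort for validation / I/O tests
tiny_cohort <- function() {
  catalogue <- xdp_catalogue()
  subjects <- tibble::tibble(
    subject_id = c("1A", "2B", "3N"),
    genotype_group = c("positive_symptomatic", "positive_presymptomatic",
                       "negative"),
    reported_onset = c(40, NA, NA),
    repeat_size = c(45, 42, NA),
    family_id = c("A", "B", "N1"),
    initial_symptom = c("dystonia", "none", "none"),
    height = c(160, 165, 158)
  )
  visits <- tidyr::crossing(subject_id = subjects$subject_id,
                            visit_index = 0:1) |>
    dplyr::mutate(age = 30 + dplyr::row_number() * 0.5)
  observations <- tibble::tibble(
    subject_id = c("1A", "1A", "2B"),
    visit_index = c(0L, 1L, 0L),
    measure_id = c("updrs1_01", "mpt", "bfm_mov_eyes"),
    value = c(3, 12.5, 4)
  )
  xdp_cohort(subjects, visits, observations, catalogue)
}
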