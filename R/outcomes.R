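#' Analysis-variant windows
#'
#' The primary analysis uses a 120-day time-at-risk window with confirmation
#' 30--90 days after adverse-event onset; the sensitivity analysis uses a
#' 90-day time-at-risk with confirmation 30--60 days after onset. The two
#' settings are linked: since onsets fall in days 1--30, the latest possible
#' confirmatory visit always coincides with the end of the time-at-risk
#' window.
#'
#' @param variant `"primary"` or `"sensitivity"`.
#' @return A list with `tar_days` and `confirm_window` (length-2 integer).
#' @export
analysis_variant <- function(variant = c("primary", "sensitivity")) {
  variant <- match.arg(variant)
  if (variant == "primary") {
    list(variant = "primary", tar_days = 120L, confirm_window = c(30L, 90L))
  } else {
    list(variant = "sensitivity", tar_days = 90L, confirm_window = c(30L, 60L))
  }
}

#' Find incident adverse events
#'
#' An incident AE is an adverse-event-mapped diagnosis first observed in
#' days 1--30 after the index date with no occurrence of the same code in
#' the 183-day lookback (ending on the index date); "incident" is assessed
#' at diagnosis-code level.
#'
#' @param cohort Cohort entries (tibble with `person_id`, `index_date`).
#' @param bundle The claims bundle.
#' @param vocab A loaded vocabulary.
#' @return Tibble of incident AEs: `person_id`, `condition_code`, `soc`,
#'   `onset_date`, `days_from_index`.
#' @export
find_incident_aes <- function(cohort, bundle, vocab) {
  empty <- tibble::tibble(person_id = integer(), condition_code = character(),
                          soc = character(), onset_date = as.Date(character()),
                          days_from_index = integer())
  if (nrow(cohort) == 0) return(empty)
  ae <- bundle$condition_occurrence |>
    dplyr::inner_join(vocab$soc_map, by = "condition_code") |>
    dplyr::inner_join(dplyr::select(cohort, "person_id", "index_date"),
                      by = "person_id", relationship = "many-to-many") |>
    dplyr::mutate(days_from_index =
                    as.integer(.data$event_date - .data$index_date))
  if (nrow(ae) == 0) return(empty)
  in_window <- ae |>
    dplyr::filter(.data$days_from_index >= 1L, .data$days_from_index <= 30L) |>
    dplyr::group_by(.data$person_id, .data$condition_code) |>
    dplyr::slice_min(.data$event_date, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  dirty <- ae |>
    dplyr::filter(.data$days_from_index >= -LOOKBACK_GENERAL,
                  .data$days_from_index <= 0L) |>
    dplyr::distinct(.data$person_id, .data$condition_code)
  in_window |>
    dplyr::anti_join(dirty, by = c("person_id", "condition_code")) |>
    dplyr::transmute(person_id = .data$person_id,
                     condition_code = .data$condition_code, soc = .data$soc,
                     onset_date = .data$event_date,
                     days_from_index = .data$days_from_index) |>
    dplyr::arrange(.data$person_id, .data$onset_date, .data$condition_code)
}

#' Confirm incident adverse events
#'
#' An incident AE is confirmed when the same diagnosis code recurs within
#' the confirmation window after onset (30--90 days for the primary
#' analysis, 30--60 for the sensitivity analysis; endpoints inclusive, with
#' the onset day as day 0 of the confirmation clock).
#'
#' @param incident_aes Output of [find_incident_aes()].
#' @param bundle The claims bundle.
#' @param window Length-2 integer confirmation window in days after onset.
#' @return The confirmed subset with `confirmation_date` and
#'   `days_to_confirmation` (earliest confirming visit).
#' @export
confirm_aes <- function(incident_aes, bundle, window = c(30L, 90L)) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  if (nrow(incident_aes) == 0) {
    return(dplyr::mutate(incident_aes,
                         confirmation_date = as.Date(character()),
                         days_to_confirmation = integer()))
  }
  repeats <- bundle$condition_occurrence |>
    dplyr::semi_join(incident_aes, by = c("person_id", "condition_code")) |>
    dplyr::select("person_id", "condition_code", rep_date = "event_date")
  incident_aes |>
    dplyr::inner_join(repeats, by = c("person_id", "condition_code"),
                      relationship = "many-to-many") |>
    dplyr::mutate(gap = as.integer(.data$rep_date - .data$onset_date)) |>
    dplyr::filter(.data$gap >= window[1], .data$gap <= window[2]) |>
    dplyr::group_by(.data$person_id, .data$condition_code) |>
    dplyr::slice_min(.data$rep_date, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(person_id = .data$person_id,
                     condition_code = .data$condition_code, soc = .data$soc,
                     onset_date = .data$onset_date,
                     days_from_index = .data$days_from_index,
                     confirmation_date = .data$rep_date,
                     days_to_confirmation = .data$gap)
}

#' Find incident short-term disability claims
#'
#' True for a person when a disability claim starts within the time-at-risk
#' window (`[index, index + tar_days]`), is not flagged as the continuation
#' of a claim initiated before index, and no claim overlaps the 183-day
#' pre-index lookback.
#'
#' @param cohort Cohort entries.
#' @param bundle The claims bundle.
#' @param tar_days Time-at-risk length in days (120 primary, 90
#'   sensitivity).
#' @return Tibble `person_id`, `disability` (flag), `disability_start`
#'   (earliest qualifying claim start, `NA` when none).
#' @export
find_incident_disability <- function(cohort, bundle, tar_days = 120L) {
  base <- dplyr::select(cohort, "person_id", "index_date")
  if (nrow(cohort) == 0 || nrow(bundle$disability_claim) == 0) {
    return(dplyr::transmute(base, person_id = .data$person_id,
                            disability = logical(nrow(base)),
                            disability_start = as.Date(NA)[seq_len(nrow(base))]))
  }
  claims <- bundle$disability_claim |>
    dplyr::inner_join(base, by = "person_id",
                      relationship = "many-to-many")
  # continuation flags referencing a claim that started before index
  pre_start <- claims |>
    dplyr::filter(.data$claim_start < .data$index_date) |>
    dplyr::pull(.data$claim_id)
  qualifying <- claims |>
    dplyr::filter(.data$claim_start >= .data$index_date,
                  .data$claim_start <= .data$index_date + tar_days,
                  is.na(.data$continuation_of) |
                    !.data$continuation_of %in% pre_start)
  blocked <- claims |>
    dplyr::filter(.data$claim_start <= .data$index_date - 1L,
                  .data$claim_end >= .data$index_date - LOOKBACK_GENERAL) |>
    dplyr::distinct(.data$person_id)
  first_claim <- qualifying |>
    dplyr::anti_join(blocked, by = "person_id") |>
    dplyr::group_by(.data$person_id) |>
    dplyr::slice_min(.data$claim_start, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("person_id", disability_start = "claim_start")
  base |>
    dplyr::left_join(first_claim, by = "person_id") |>
    dplyr::transmute(person_id = .data$person_id,
                     disability = !is.na(.data$disability_start),
                     disability_start = .data$disability_start)
}

#' Classify the composite outcome
#'
#' The composite outcome requires confirmed incident AEs in at least two of
#' the six collapsed SOC categories (ear and eye codes both count once as
#' `sensory`) together with an incident short-term disability claim inside
#' the time-at-risk window.
#'
#' @param cohort Cohort entries.
#' @param confirmed_aes Output of [confirm_aes()].
#' @param disability Output of [find_incident_disability()].
#' @param tar_days Time-at-risk used (recorded, and re-checked against the
#'   disability start).
#' @return Tibble with one row per cohort entry: `person_id`,
#'   `n_confirmed_socs`, per-SOC flags (`soc_*`), `disability`,
#'   `disability_start`, `outcome`, `days_to_ae_onset` (earliest incident
#'   AE) and `days_to_confirmation` (earliest confirming visit).
#' @export
classify_outcomes <- function(cohort, confirmed_aes, disability,
                              tar_days = 120L) {
  soc_levels <- c("peripheral_nervous", "neuropsychiatric", "musculoskeletal",
                  "sensory", "cardiovascular", "skin")
  per_person <- if (nrow(confirmed_aes) == 0) {
    tibble::tibble(person_id = integer(), n_confirmed_socs = integer(),
                   days_to_ae_onset = integer(),
                   days_to_confirmation = integer())
  } else {
    confirmed_aes |>
      dplyr::group_by(.data$person_id) |>
      dplyr::summarise(
        n_confirmed_socs = dplyr::n_distinct(.data$soc),
        days_to_ae_onset = min(.data$days_from_index),
        days_to_confirmation = min(.data$days_to_confirmation),
        .groups = "drop")
  }
  soc_flags <- confirmed_aes |>
    dplyr::distinct(.data$person_id, .data$soc) |>
    dplyr::mutate(flag = TRUE, soc = factor(.data$soc, levels = soc_levels)) |>
    tidyr::pivot_wider(names_from = "soc", values_from = "flag",
                       names_prefix = "soc_", values_fill = FALSE,
                       names_expand = TRUE)
  out <- dplyr::select(cohort, "person_id", "arm", "index_date") |>
    dplyr::left_join(per_person, by = "person_id") |>
    dplyr::left_join(soc_flags, by = "person_id") |>
    dplyr::left_join(disability, by = "person_id") |>
    dplyr::mutate(
      n_confirmed_socs = dplyr::coalesce(.data$n_confirmed_socs, 0L),
      dplyr::across(dplyr::starts_with("soc_"),
                    \(x) dplyr::coalesce(x, FALSE)),
      disability = dplyr::coalesce(.data$disability, FALSE) &
        !is.na(.data$disability_start) &
        .data$disability_start <= .data$index_date + tar_days,
      outcome = .data$n_confirmed_socs >= 2L & .data$disability,
      tar_days = tar_days)
  dplyr::arrange(out, .data$person_id)
}

#' Phenotype the composite outcome for a cohort
#'
#' Convenience wrapper running [find_incident_aes()], [confirm_aes()],
#' [find_incident_disability()] and [classify_outcomes()] for one analysis
#' variant.
#'
#' @param cohort Cohort entries tibble (or an `fqad_cohort`).
#' @param bundle The claims bundle.
#' @param vocab A loaded vocabulary.
#' @param variant `"primary"` (120-day time-at-risk, 30--90-day
#'   confirmation) or `"sensitivity"` (90-day, 30--60).
#' @return A list of class `fqad_outcomes`: `outcomes` (one row per
#'   entry), `case_detail` (confirmed AEs of outcome cases) and the variant
#'   windows.
#' @export
phenotype_outcomes <- function(cohort, bundle, vocab,
                               variant = c("primary", "sensitivity")) {
  if (inherits(cohort, "fqad_cohort")) cohort <- cohort$cohort
  win <- analysis_variant(match.arg(variant))
  incident <- find_incident_aes(cohort, bundle, vocab)
  confirmed <- confirm_aes(incident, bundle, win$confirm_window)
  disability <- find_incident_disability(cohort, bundle, win$tar_days)
  outcomes <- classify_outcomes(cohort, confirmed, disability, win$tar_days)
  case_ids <- outcomes$person_id[outcomes$outcome]
  case_detail <- confirmed |>
    dplyr::filter(.data$person_id %in% case_ids) |>
    dplyr::left_join(dplyr::select(cohort, "person_id", "arm", "indication",
                                   "drug_code", "age_at_index", "sex"),
                     by = "person_id")
  structure(list(outcomes = outcomes, case_detail = case_detail,
                 variant = win$variant, tar_days = win$tar_days,
                 confirm_window = win$confirm_window),
            class = "fqad_outcomes")
}

#' @export
print.fqad_outcomes <- function(x, ...) {
  cat("<fqad_outcomes> variant:", x$variant,
      sprintf("(TAR %d days, confirmation %d-%d days)\n", x$tar_days,
              x$confirm_window[1], x$confirm_window[2]))
  print(dplyr::count(x$outcomes, .data$arm, .data$outcome))
  invisible(x)
}
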