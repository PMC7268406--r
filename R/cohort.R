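# windows, in days: the study's "6 months" / "3 months" / "1 year" are fixed
# globally as 183 / 92 / 365 days
LOOKBACK_GENERAL <- 183L
LOOKBACK_SPECIFIC <- 92L
LOOKBACK_YEAR <- 365L
FOLLOWUP_MIN <- 120L
IND_TO_EXPOSURE_MAX <- 30L
CO_DISPENSE_TAIL <- 7L

#' Find candidate index events
#'
#' Scans the raw claims tables for qualifying indication-exposure
#' combinations: an outpatient diagnosis of sinusitis, bronchitis or
#' uncomplicated UTI followed within 0--30 days (inclusive) by a dispensing
#' of a study antibiotic, with the arm-indication pairing enforced
#' (fluoroquinolones for any of the three indications; azithromycin only for
#' sinusitis/bronchitis; sulfamethoxazole-trimethoprim only for UTI).
#' Episodes in which both an FQ and the comparator drug were dispensed
#' (other-arm dispensing between the indication date and 7 days after the
#' index dispensing) are discarded. The earliest remaining qualifying
#' dispensing per person becomes the candidate index event; same-day ties
#' are broken by the lexicographically lowest drug code.
#'
#' @param bundle A claims bundle ([simulate_claims()] or
#'   [read_claims_bundle()]).
#' @param vocab A loaded vocabulary.
#' @return A tibble of candidate entries: `person_id`, `arm` (`fq`/`azst`),
#'   `index_date`, `indication` (`+`-joined when several indications map to
#'   the same dispensing), `drug_code`, `age_at_index`, `sex`.
#' @export
find_index_events <- function(bundle, vocab) {
  ind_map <- purrr::imap_dfr(vocab$indications, function(codes, ind) {
    tibble::tibble(condition_code = codes, indication = ind)
  })
  ind_events <- bundle$condition_occurrence |>
    dplyr::filter(.data$setting == "outpatient") |>
    dplyr::inner_join(ind_map, by = "condition_code",
                      relationship = "many-to-many") |>
    dplyr::select("person_id", "indication", ind_date = "event_date")

  drug_map <- dplyr::bind_rows(
    tibble::tibble(drug_code = vocab$exposures$fq, arm = "fq", drug_class = "fq"),
    tibble::tibble(drug_code = vocab$exposures$az, arm = "azst", drug_class = "az"),
    tibble::tibble(drug_code = vocab$exposures$st, arm = "azst", drug_class = "st"))
  disp <- bundle$drug_exposure |>
    dplyr::inner_join(drug_map, by = "drug_code") |>
    dplyr::select("person_id", "drug_code", "arm", "drug_class",
                  "dispense_date")

  if (nrow(ind_events) == 0 || nrow(disp) == 0) {
    return(tibble::tibble(person_id = integer(), arm = character(),
                          index_date = as.Date(character()),
                          indication = character(), drug_code = character(),
                          age_at_index = integer(), sex = character()))
  }

  pairs <- dplyr::inner_join(ind_events, disp, by = "person_id",
                             relationship = "many-to-many") |>
    dplyr::filter(.data$dispense_date >= .data$ind_date,
                  .data$dispense_date <= .data$ind_date + IND_TO_EXPOSURE_MAX) |>
    # arm-indication pairing: AZ is not used for UTI, ST only for UTI
    dplyr::filter(.data$drug_class == "fq" |
                    (.data$drug_class == "az" &
                       .data$indication %in% c("sinusitis", "bronchitis")) |
                    (.data$drug_class == "st" & .data$indication == "uti"))
  if (nrow(pairs) == 0) {
    return(tibble::tibble(person_id = integer(), arm = character(),
                          index_date = as.Date(character()),
                          indication = character(), drug_code = character(),
                          age_at_index = integer(), sex = character()))
  }

  # drop episodes where the other arm's drug was co-dispensed
  other_disp <- dplyr::select(disp, "person_id", other_arm = "arm",
                              other_date = "dispense_date")
  viol <- pairs |>
    dplyr::mutate(.pair = dplyr::row_number()) |>
    dplyr::inner_join(other_disp, by = "person_id",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$other_arm != .data$arm,
                  .data$other_date >= .data$ind_date,
                  .data$other_date <= .data$dispense_date + CO_DISPENSE_TAIL) |>
    dplyr::pull(.data$.pair) |>
    unique()
  if (length(viol) > 0) pairs <- pairs[-viol, ]
  if (nrow(pairs) == 0) {
    return(tibble::tibble(person_id = integer(), arm = character(),
                          index_date = as.Date(character()),
                          indication = character(), drug_code = character(),
                          age_at_index = integer(), sex = character()))
  }

  # earliest qualifying dispensing per person; deterministic tie-break
  chosen <- pairs |>
    dplyr::group_by(.data$person_id) |>
    dplyr::filter(.data$dispense_date == min(.data$dispense_date)) |>
    dplyr::filter(.data$drug_code == min(.data$drug_code)) |>
    dplyr::summarise(
      arm = .data$arm[1], index_date = .data$dispense_date[1],
      drug_code = .data$drug_code[1],
      indication = paste(sort(unique(.data$indication)), collapse = "+"),
      .groups = "drop")

  chosen |>
    dplyr::left_join(bundle$person, by = "person_id") |>
    dplyr::mutate(
      age_at_index = as.integer(format(.data$index_date, "%Y")) -
        .data$birth_year) |>
    dplyr::select("person_id", "arm", "index_date", "indication",
                  "drug_code", "age_at_index", "sex") |>
    dplyr::arrange(.data$person_id)
}

#' Apply the continuous-observation eligibility rule
#'
#' Retains candidates with at least 183 days of continuous observation
#' before the index date and at least 120 days of observation with
#' short-term-disability insurance afterward (both inside a single
#' observation period containing the index date).
#'
#' @param candidates Output of [find_index_events()].
#' @param bundle The claims bundle.
#' @param require_insured_lookback Also require the disability-insurance
#'   flag for the pre-index period (stricter than the study's literal
#'   wording; default `FALSE`).
#' @return The retained entries; removed `person_id`s are attached as the
#'   `"removed"` attribute.
#' @export
apply_eligibility <- function(candidates, bundle,
                              require_insured_lookback = FALSE) {
  if (nrow(candidates) == 0) {
    out <- candidates
    attr(out, "removed") <- integer()
    return(out)
  }
  obs <- bundle$observation_period
  joined <- candidates |>
    dplyr::inner_join(obs, by = "person_id",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$index_date >= .data$start_date,
                  .data$index_date <= .data$end_date) |>
    dplyr::mutate(
      pre_ok = .data$start_date <= .data$index_date - LOOKBACK_GENERAL,
      post_ok = .data$end_date >= .data$index_date + FOLLOWUP_MIN,
      # insurance is a period-level flag, so the stricter lookback variant
      # coincides with the post-window requirement unless periods differ
      ok = .data$pre_ok & .data$post_ok & .data$disability_insured)
  keep_ids <- unique(joined$person_id[joined$ok])
  out <- dplyr::filter(candidates, .data$person_id %in% keep_ids)
  attr(out, "removed") <- setdiff(candidates$person_id, keep_ids)
  out
}

#' @keywords internal
exclusion_hits <- function(entries, bundle, vocab) {
  if (nrow(entries) == 0) {
    return(tibble::tibble(person_id = integer(), rule = character(),
                          priority = integer()))
  }
  ex <- vocab$exclusions
  conds <- bundle$condition_occurrence |>
    dplyr::inner_join(dplyr::select(entries, "person_id", "index_date",
                                    "indication"),
                      by = "person_id", relationship = "many-to-many")

  hits <- list()
  # general conditions, 183-day lookback, in listed (priority) order
  gen <- conds |>
    dplyr::filter(.data$condition_code %in% ex$general_conditions,
                  .data$event_date >= .data$index_date - LOOKBACK_GENERAL,
                  .data$event_date <= .data$index_date - 1L) |>
    dplyr::mutate(rule = paste0("general:", .data$condition_code),
                  priority = match(.data$condition_code,
                                   ex$general_conditions))
  hits$general <- dplyr::select(gen, "person_id", "rule", "priority")

  drugs <- bundle$drug_exposure |>
    dplyr::inner_join(dplyr::select(entries, "person_id", "index_date"),
                      by = "person_id", relationship = "many-to-many") |>
    dplyr::filter(.data$dispense_date >= .data$index_date - LOOKBACK_GENERAL,
                  .data$dispense_date <= .data$index_date - 1L)
  n_gen <- length(ex$general_conditions)
  ster <- drugs |>
    dplyr::filter(.data$drug_code %in% ex$steroid_drugs) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(total = sum(.data$days_supplied), .groups = "drop") |>
    dplyr::filter(.data$total >= (ex$steroid_min_days %||% 30)) |>
    dplyr::transmute(person_id = .data$person_id,
                     rule = "general:long_term_steroids",
                     priority = n_gen + 1L)
  hits$steroids <- ster
  chemo <- drugs |>
    dplyr::filter(.data$drug_code %in% ex$chemotherapy_drugs) |>
    dplyr::transmute(person_id = .data$person_id,
                     rule = "general:chemotherapy", priority = n_gen + 2L)
  hits$chemo <- chemo
  claims <- bundle$disability_claim |>
    dplyr::inner_join(dplyr::select(entries, "person_id", "index_date"),
                      by = "person_id", relationship = "many-to-many") |>
    dplyr::filter(.data$claim_start <= .data$index_date - 1L,
                  .data$claim_end >= .data$index_date - LOOKBACK_GENERAL) |>
    dplyr::transmute(person_id = .data$person_id,
                     rule = "general:prior_disability_claim",
                     priority = n_gen + 3L)
  hits$claims <- claims

  # indication-specific exclusions, 92-day lookback
  spec_rules <- purrr::imap_dfr(ex$condition_specific, function(rules, ind) {
    dplyr::bind_rows(
      tibble::tibble(indication = ind,
                     condition_code = as.character(rules$inpatient),
                     setting_req = "inpatient"),
      tibble::tibble(indication = ind,
                     condition_code = as.character(rules$any_setting),
                     setting_req = "any"))
  })
  spec <- conds |>
    tidyr::separate_rows("indication", sep = "\\+") |>
    dplyr::inner_join(spec_rules, by = c("indication", "condition_code"),
                      relationship = "many-to-many") |>
    dplyr::filter(.data$setting_req == "any" |
                    .data$setting == "inpatient",
                  .data$event_date >= .data$index_date - LOOKBACK_SPECIFIC,
                  .data$event_date <= .data$index_date - 1L) |>
    dplyr::transmute(person_id = .data$person_id,
                     rule = paste0("specific:", .data$indication, ":",
                                   .data$condition_code),
                     priority = n_gen + 4L)
  hits$specific <- spec

  dplyr::bind_rows(hits)
}

#' Apply the general and indication-specific exclusions
#'
#' Removes entries with any general-exclusion condition, long-term oral
#' steroid use (cumulative days supplied >= 30), chemotherapy, or disability
#' claim in the 183-day pre-index lookback, or any indication-matched
#' specific exclusion (e.g. hospitalization for pneumonia before a
#' bronchitis index) in the 92-day lookback. Each removal is attributed to
#' its first matching rule.
#'
#' @inheritParams apply_eligibility
#' @param entries Eligible entries.
#' @param vocab A loaded vocabulary.
#' @return Retained entries; a tibble of removals (`person_id`, `rule`) is
#'   attached as the `"removals"` attribute.
#' @export
apply_exclusions <- function(entries, bundle, vocab) {
  hits <- exclusion_hits(entries, bundle, vocab)
  removals <- hits |>
    dplyr::arrange(.data$person_id, .data$priority, .data$rule) |>
    dplyr::distinct(.data$person_id, .keep_all = TRUE) |>
    dplyr::select("person_id", "rule")
  out <- dplyr::filter(entries, !.data$person_id %in% removals$person_id)
  attr(out, "removals") <- removals
  out
}

#' Enforce mutually exclusive new-user cohorts
#'
#' Removes fluoroquinolone entries with any comparator (AZ/ST) dispensing in
#' the 183 days before index, and vice versa, so that each person qualifies
#' only for the first cohort for which they were eligible and the two arms
#' share no recent cross-exposure.
#'
#' @inheritParams apply_exclusions
#' @return Retained entries; removed `person_id`s attached as `"removed"`.
#' @export
enforce_mutual_exclusivity <- function(entries, bundle, vocab) {
  if (nrow(entries) == 0) {
    attr(entries, "removed") <- integer()
    return(entries)
  }
  arm_of_drug <- dplyr::bind_rows(
    tibble::tibble(drug_code = vocab$exposures$fq, drug_arm = "fq"),
    tibble::tibble(drug_code = c(vocab$exposures$az, vocab$exposures$st),
                   drug_arm = "azst"))
  cross <- bundle$drug_exposure |>
    dplyr::inner_join(arm_of_drug, by = "drug_code") |>
    dplyr::inner_join(dplyr::select(entries, "person_id", "arm",
                                    "index_date"),
                      by = "person_id", relationship = "many-to-many") |>
    dplyr::filter(.data$drug_arm != .data$arm,
                  .data$dispense_date >= .data$index_date - LOOKBACK_GENERAL,
                  .data$dispense_date <= .data$index_date - 1L)
  removed <- unique(cross$person_id)
  out <- dplyr::filter(entries, !.data$person_id %in% removed)
  attr(out, "removed") <- removed
  out
}

#' Build the matched-analysis-ready study cohorts
#'
#' Runs the full cohort construction chain: candidate index events,
#' continuous-observation eligibility, general and indication-specific
#' exclusions, and mutual exclusivity of the two new-user arms, recording an
#' attrition table along the way.
#'
#' @inheritParams apply_eligibility
#' @param vocab A loaded vocabulary.
#' @return An object of class `fqad_cohort`: a list with `cohort` (one row
#'   per retained person), `attrition` (long tibble of `step`, `arm`,
#'   `n_remaining`) and `exclusion_detail` (`person_id`, `rule`).
#' @examples
#' bundle <- simulate_claims(sim_config(n_persons = 2000, seed = 7))
#' ch <- build_cohort(bundle, load_vocabulary())
#' ch$attrition
#' @export
build_cohort <- function(bundle, vocab, require_insured_lookback = FALSE) {
  steps <- list()
  tally <- function(entries, step) {
    dplyr::bind_rows(
      tibble::tibble(step = step, arm = "fq",
                     n_remaining = sum(entries$arm == "fq")),
      tibble::tibble(step = step, arm = "azst",
                     n_remaining = sum(entries$arm == "azst")))
  }
  candidates <- find_index_events(bundle, vocab)
  steps[[1]] <- tally(candidates, "index_event_candidates")
  eligible <- apply_eligibility(candidates, bundle, require_insured_lookback)
  steps[[2]] <- tally(eligible, "full_observation")
  excluded <- apply_exclusions(eligible, bundle, vocab)
  steps[[3]] <- tally(excluded, "exclusions_applied")
  final <- enforce_mutual_exclusivity(excluded, bundle, vocab)
  steps[[4]] <- tally(final, "mutually_exclusive_new_users")

  attrition <- dplyr::bind_rows(steps) |>
    dplyr::mutate(step = factor(.data$step, levels = unique(.data$step)))
  out <- list(cohort = tibble::as_tibble(final),
              attrition = attrition,
              exclusion_detail = attr(excluded, "removals"))
  attr(out$cohort, "removed") <- NULL
  attr(out$cohort, "removals") <- NULL
  class(out) <- "fqad_cohort"
  out
}

#' @export
print.fqad_cohort <- function(x, ...) {
  cat("<fqad_cohort>\n")
  print(tidyr::pivot_wider(x$attrition, names_from = "arm",
                           values_from = "n_remaining"))
  invisible(x)
}
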