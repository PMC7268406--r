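#' Study run configuration
#'
#' Bundles every stage's settings for a reproducible end-to-end run. The
#' analysis variant fixes the time-at-risk and confirmation windows as a
#' linked pair: primary = 120-day TAR with 30--90-day confirmation,
#' sensitivity = 90-day TAR with 30--60-day confirmation.
#'
#' @param sim A [sim_config()] for the synthetic claims source.
#' @param variant `"primary"` or `"sensitivity"`.
#' @param caliper_mult Matching caliper as a multiple of the pooled score
#'   SD.
#' @param trim Lower/upper pooled-percentile trimming bounds.
#' @param nfolds Propensity cross-validation folds.
#' @return An `fqad_run_config`.
#' @export
study_config <- function(sim = sim_config(), variant = c("primary",
                                                         "sensitivity"),
                         caliper_mult = 0.25, trim = c(0.05, 0.95),
                         nfolds = 10) {
  structure(list(sim = sim, variant = match.arg(variant),
                 caliper_mult = caliper_mult, trim = trim, nfolds = nfolds),
            class = "fqad_run_config")
}

#' Run the full comparative-cohort analysis
#'
#' Orchestrates simulate -> build cohorts -> phenotype -> propensity match
#' -> estimate -> calibrate -> report as one reproducible run. Re-running
#' with the same configuration reproduces every result exactly. Any stage
#' failure aborts with the stage name; completed stage outputs up to that
#' point are attached to the error condition.
#'
#' @param config An [study_config()] object.
#' @param bundle Optionally, an existing claims bundle to analyse instead
#'   of simulating one (the `sim` settings then only supply the vocabulary
#'   and seed).
#' @return An `fqad_study` with elements `bundle`, `cohort`, `outcomes`,
#'   `covariates`, `ps_model`, `matched`, `balance`, `estimates`
#'   (incidence, crude OR/RR, matched OR, nominal and calibrated p),
#'   `controls`, `null`, and `report` (attrition, utilization, drug, case,
#'   outcome and SOC tables).
#' @examples
#' \donttest{
#' study <- run_study(study_config(sim_config(n_persons = 5000, seed = 7)))
#' glance(study)
#' }
#' @export
run_study <- function(config, bundle = NULL) {
  stopifnot(inherits(config, "fqad_run_config"))
  done <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(structure(class = c("fqad_stage_error", "error", "condition"),
                     list(message = paste0("stage '", name, "' failed: ",
                                           conditionMessage(e)),
                          call = NULL, partial = done)))
    })
  }
  vocab <- config$sim$vocab
  win <- analysis_variant(config$variant)

  if (is.null(bundle)) {
    bundle <- stage("simulate", simulate_claims(config$sim))
  }
  done$bundle <- bundle
  cohort <- stage("build-cohorts", build_cohort(bundle, vocab))
  done$cohort <- cohort
  outcomes <- stage("phenotype",
                    phenotype_outcomes(cohort, bundle, vocab,
                                       config$variant))
  done$outcomes <- outcomes

  covariates <- stage("match", build_covariates(cohort, bundle))
  entries <- cohort$cohort
  covariates <- stage("match",
                      covariates[match(entries$person_id,
                                       covariates$person_id), ])
  ps_model <- stage("match", fit_ps(covariates, entries$arm,
                                    nfolds = config$nfolds,
                                    seed = config$sim$seed))
  trimmed <- stage("match", trim_ps(ps_model$scores, config$trim[1],
                                    config$trim[2]))
  matched <- stage("match", greedy_match(trimmed, config$caliper_mult))
  done$matched <- matched
  balance <- stage("match", balance_report(matched, covariates))
  done$balance <- balance

  estimates <- stage("estimate", {
    if (nrow(matched$pairs) == 0) {
      stop("estimation refused: zero matched pairs", call. = FALSE)
    }
    matched_ids <- c(matched$pairs$target_id, matched$pairs$comparator_id)
    oc_m <- dplyr::filter(outcomes$outcomes,
                          .data$person_id %in% matched_ids)
    inc <- crude_incidence(oc_m, win$tar_days)
    t22 <- two_by_two(inc$events[inc$arm == "fq"], inc$n[inc$arm == "fq"],
                      inc$events[inc$arm == "azst"],
                      inc$n[inc$arm == "azst"])
    d <- discordant_pairs(matched, oc_m)
    list(incidence = inc, twobytwo = t22, discordant = d,
         table = dplyr::bind_rows(crude_or(t22), crude_rr(t22),
                                  matched_or(d)))
  })
  done$estimates <- estimates

  calib <- stage("calibrate", {
    controls <- estimate_controls(matched, bundle, vocab, cohort,
                                  win$tar_days)
    null <- fit_empirical_null(controls)
    est <- estimates$table
    est$calibrated_p <- calibrate_p(null, est$log_estimate, est$se_log)
    list(controls = controls, null = null, table = est)
  })
  done$controls <- calib$controls
  done$null <- calib$null

  report <- stage("report", {
    matched_ids <- c(matched$pairs$target_id, matched$pairs$comparator_id)
    entries_m <- dplyr::filter(entries, .data$person_id %in% matched_ids)
    list(attrition = cohort$attrition,
         utilization = report_utilization_table(entries_m),
         drug = report_drug_table(entries_m, outcomes),
         case = report_case_table(outcomes),
         outcome = calib$table,
         soc = report_soc_table(outcomes$case_detail))
  })

  structure(list(config = config, bundle = bundle, cohort = cohort,
                 outcomes = outcomes, covariates = covariates,
                 ps_model = ps_model, trimmed = trimmed, matched = matched,
                 balance = balance,
                 estimates = calib$table,
                 incidence = estimates$incidence,
                 twobytwo = estimates$twobytwo,
                 discordant = estimates$discordant,
                 controls = calib$controls, null = calib$null,
                 report = report, variant = win),
            class = "fqad_study")
}

#' Antibiotic utilization by indication (Table-2 analogue)
#'
#' @param entries Cohort entries (matched or unmatched).
#' @return Tibble: drug by indication counts with arm totals.
#' @export
report_utilization_table <- function(entries) {
  entries |>
    tidyr::separate_rows("indication", sep = "\\+") |>
    dplyr::count(.data$arm, .data$drug_code, .data$indication) |>
    tidyr::pivot_wider(names_from = "indication", values_from = "n",
                       values_fill = 0L) |>
    dplyr::arrange(.data$arm, .data$drug_code)
}

#' Adverse-event and disability counts per drug (Table-3 analogue)
#'
#' Per drug in the target arm: persons used, and counts (with row
#' percentages) of persons with at least one confirmed qualifying AE, one
#' or more AEs plus disability, confirmed AEs in two or more SOCs, and the
#' full composite (2+ SOCs plus disability). A drug with zero users yields
#' a zero row.
#'
#' @param entries Cohort entries.
#' @param outcomes An `fqad_outcomes` (or its `outcomes` tibble).
#' @return Tibble with count and percentage columns per drug.
#' @export
report_drug_table <- function(entries, outcomes) {
  if (inherits(outcomes, "fqad_outcomes")) outcomes <- outcomes$outcomes
  pct <- function(num, den) ifelse(den > 0, round(100 * num / den, 1), 0)
  entries |>
    dplyr::filter(.data$arm == "fq") |>
    dplyr::left_join(dplyr::select(outcomes, "person_id",
                                   "n_confirmed_socs", "disability",
                                   "outcome"),
                     by = "person_id") |>
    dplyr::group_by(.data$drug_code) |>
    dplyr::summarise(
      n = dplyr::n(),
      ae1 = sum(.data$n_confirmed_socs >= 1),
      ae1_disability = sum(.data$n_confirmed_socs >= 1 & .data$disability),
      ae2 = sum(.data$n_confirmed_socs >= 2),
      ae2_disability = sum(.data$outcome),
      .groups = "drop") |>
    dplyr::mutate(ae1_pct = pct(.data$ae1, .data$n),
                  ae1_disability_pct = pct(.data$ae1_disability, .data$n),
                  ae2_pct = pct(.data$ae2, .data$n),
                  ae2_disability_pct = pct(.data$ae2_disability, .data$n)) |>
    dplyr::arrange(dplyr::desc(.data$n))
}

#' Case descriptive statistics (Table-4 analogue)
#'
#' Age, sex, indication mix, days-to-onset distribution (bins 1--2, 3--4,
#' 5--10, >10 days) and days-to-confirmation summaries for the composite
#' outcome cases in each arm.
#'
#' @param outcomes An `fqad_outcomes` object.
#' @return A long tibble (`section`, `statistic`, one column per arm).
#' @export
report_case_table <- function(outcomes) {
  cases <- outcomes$outcomes |>
    dplyr::filter(.data$outcome)
  demo <- outcomes$case_detail |>
    dplyr::distinct(.data$person_id, .data$arm, .data$age_at_index,
                    .data$sex, .data$indication)
  cases <- dplyr::left_join(dplyr::select(cases, "person_id", "arm",
                                          "days_to_ae_onset",
                                          "days_to_confirmation"),
                            dplyr::select(demo, -"arm"), by = "person_id")
  one_arm <- function(df) {
    if (nrow(df) == 0) {
      return(tibble::tibble(section = character(), statistic = character(),
                            value = double()))
    }
    bins <- cut(df$days_to_ae_onset, c(0, 2, 4, 10, 30),
                labels = c("1-2 days", "3-4 days", "5-10 days", "> 10 days"))
    dplyr::bind_rows(
      tibble::tibble(section = "n", statistic = "cases",
                     value = nrow(df)),
      tibble::tibble(section = "age",
                     statistic = c("mean", "sd", "median"),
                     value = c(mean(df$age_at_index),
                               stats::sd(df$age_at_index),
                               stats::median(df$age_at_index))),
      tibble::tibble(section = "sex", statistic = "female_pct",
                     value = 100 * mean(df$sex == "F")),
      df |>
        dplyr::count(.data$indication) |>
        dplyr::transmute(section = "indication",
                         statistic = .data$indication,
                         value = 100 * .data$n / nrow(df)),
      tibble::tibble(section = "days_to_onset",
                     statistic = levels(bins),
                     value = 100 * as.numeric(table(bins)) / nrow(df)),
      tibble::tibble(section = "days_to_onset",
                     statistic = "median",
                     value = stats::median(df$days_to_ae_onset)),
      tibble::tibble(section = "days_to_confirmation",
                     statistic = c("mean", "median"),
                     value = c(mean(df$days_to_confirmation),
                               stats::median(df$days_to_confirmation))))
  }
  fq <- one_arm(dplyr::filter(cases, .data$arm == "fq"))
  az <- one_arm(dplyr::filter(cases, .data$arm == "azst"))
  dplyr::full_join(fq, az, by = c("section", "statistic"),
                   suffix = c("_fq", "_azst")) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric), \(x) round(x, 2)))
}

#' SOC distribution among cases (Table-6 analogue)
#'
#' Per-SOC case counts by arm, total confirmed SOC-AE count, and the mean
#' number of affected SOCs per case (2 d.p.). Zero cases yield an empty
#' table.
#'
#' @param case_detail Confirmed-AE detail of outcome cases
#'   (`fqad_outcomes$case_detail`).
#' @return Tibble with one row per SOC plus `total` and
#'   `average_per_case` rows.
#' @export
report_soc_table <- function(case_detail) {
  if (nrow(case_detail) == 0) {
    return(tibble::tibble(soc = character(), fq = double(),
                          azst = double()))
  }
  per_soc <- case_detail |>
    dplyr::distinct(.data$person_id, .data$arm, .data$soc) |>
    dplyr::count(.data$soc, .data$arm) |>
    tidyr::pivot_wider(names_from = "arm", values_from = "n",
                       values_fill = 0L)
  for (a in c("fq", "azst")) if (!a %in% names(per_soc)) per_soc[[a]] <- 0L
  n_cases <- case_detail |>
    dplyr::distinct(.data$person_id, .data$arm) |>
    dplyr::count(.data$arm)
  totals <- per_soc |>
    dplyr::summarise(fq = sum(.data$fq), azst = sum(.data$azst))
  cases_fq <- sum(n_cases$n[n_cases$arm == "fq"])
  cases_az <- sum(n_cases$n[n_cases$arm == "azst"])
  dplyr::bind_rows(
    dplyr::mutate(per_soc, fq = as.double(.data$fq),
                  azst = as.double(.data$azst)),
    tibble::tibble(soc = "total", fq = as.double(totals$fq),
                   azst = as.double(totals$azst)),
    tibble::tibble(soc = "average_per_case",
                   fq = if (cases_fq > 0) round(totals$fq / cases_fq, 2) else NA_real_,
                   azst = if (cases_az > 0) round(totals$azst / cases_az, 2) else NA_real_))
}

#' @export
print.fqad_study <- function(x, ...) {
  cat("<fqad_study> variant:", x$variant$variant, "\n")
  cat(sprintf("  cohort: %d fq / %d azst; matched pairs: %d\n",
              sum(x$cohort$cohort$arm == "fq"),
              sum(x$cohort$cohort$arm == "azst"), nrow(x$matched$pairs)))
  print(dplyr::select(x$estimates, "estimate_type", "estimate", "ci_low",
                      "ci_high", "nominal_p", "calibrated_p"))
  invisible(x)
}

#' @rdname run_study
#' @param x An `fqad_study`.
#' @param ... Unused.
#' @method tidy fqad_study
#' @export
tidy.fqad_study <- function(x, ...) x$estimates

#' @rdname run_study
#' @method glance fqad_study
#' @export
glance.fqad_study <- function(x, ...) {
  m <- dplyr::filter(x$estimates, .data$estimate_type == "matched_or")
  tibble::tibble(
    variant = x$variant$variant,
    n_pairs = nrow(x$matched$pairs),
    events_target = x$twobytwo$a,
    events_comparator = x$twobytwo$c,
    matched_or = m$estimate, ci_low = m$ci_low, ci_high = m$ci_high,
    nominal_p = m$nominal_p, calibrated_p = m$calibrated_p,
    null_mu = x$null$mu, null_sigma = x$null$sigma)
}

#' @rdname run_study
#' @param object An `fqad_study`.
#' @method autoplot fqad_study
#' @export
autoplot.fqad_study <- function(object, ...) {
  autoplot(object$balance)
}
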