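#' Two-by-two outcome table
#'
#' @param events_target,n_target Outcome count and cohort size, target arm.
#' @param events_comparator,n_comparator Same for the comparator arm.
#' @return A one-row tibble with cells `a` (target events), `b` (target
#'   non-events), `c`, `d`.
#' @export
two_by_two <- function(events_target, n_target, events_comparator,
                       n_comparator) {
  stopifnot(events_target >= 0, events_comparator >= 0,
            events_target <= n_target, events_comparator <= n_comparator)
  tibble::tibble(a = events_target, b = n_target - events_target,
                 c = events_comparator, d = n_comparator - events_comparator)
}

#' @keywords internal
wald_estimate <- function(type, log_est, se, corrected = FALSE) {
  z <- log_est / se
  tibble::tibble(
    estimate_type = type,
    estimate = exp(log_est),
    log_estimate = log_est,
    se_log = se,
    ci_low = exp(log_est - stats::qnorm(0.975) * se),
    ci_high = exp(log_est + stats::qnorm(0.975) * se),
    nominal_p = 2 * stats::pnorm(-abs(z)),
    continuity_corrected = corrected)
}

#' Crude incidence
#'
#' Both the simple proportion (events / persons) and the person-time rate
#' (events / person-days at risk) per arm. Time at risk per person is the
#' full window for non-cases and the days to the qualifying disability
#' claim for cases (there are no other censoring events inside the cohort
#' by eligibility).
#'
#' @param outcomes Outcome tibble from [phenotype_outcomes()] (or the
#'   `outcomes` element).
#' @param tar_days The time-at-risk window length in days.
#' @return Tibble per arm: `n`, `events`, `proportion`, `person_days`,
#'   `rate_per_person_day`.
#' @export
crude_incidence <- function(outcomes, tar_days = 120L) {
  if (inherits(outcomes, "fqad_outcomes")) outcomes <- outcomes$outcomes
  out <- outcomes |>
    dplyr::mutate(days_at_risk = dplyr::if_else(
      .data$outcome, as.integer(.data$disability_start - .data$index_date),
      as.integer(tar_days))) |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(n = dplyr::n(), events = sum(.data$outcome),
                     proportion = mean(.data$outcome),
                     person_days = sum(pmin(.data$days_at_risk, tar_days)),
                     .groups = "drop")
  if (any(out$person_days == 0)) {
    stop("undefined incidence rate: zero person-time at risk", call. = FALSE)
  }
  dplyr::mutate(out, rate_per_person_day = .data$events / .data$person_days)
}

#' Crude odds ratio
#'
#' `OR = (a/b) / (c/d)` with `SE(log OR) = sqrt(1/a + 1/b + 1/c + 1/d)`,
#' Wald 95% CI and a two-sided normal p-value. Any zero cell triggers the
#' Haldane-Anscombe 0.5 continuity correction (flagged in the output).
#'
#' @param t A [two_by_two()] row.
#' @return A one-row estimate tibble.
#' @examples
#' crude_or(two_by_two(264, 119653, 243, 119653)) # OR 1.09
#' @export
crude_or <- function(t) {
  cells <- c(t$a, t$b, t$c, t$d)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  log_or <- log(cells[1] / cells[2]) - log(cells[3] / cells[4])
  se <- sqrt(sum(1 / cells))
  wald_estimate("crude_or", log_or, se, corrected)
}

#' Crude relative risk
#'
#' `RR = (a/(a+b)) / (c/(c+d))` with the log-scale Wald CI
#' (`SE = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`).
#'
#' @inheritParams crude_or
#' @return A one-row estimate tibble.
#' @export
crude_rr <- function(t) {
  if (t$a == 0 && t$c == 0) {
    stop("relative risk undefined: zero events in both arms", call. = FALSE)
  }
  cells <- c(t$a, t$b, t$c, t$d)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  r1 <- cells[1] / (cells[1] + cells[2])
  r0 <- cells[3] / (cells[3] + cells[4])
  log_rr <- log(r1) - log(r0)
  se <- sqrt(1 / cells[1] - 1 / (cells[1] + cells[2]) +
               1 / cells[3] - 1 / (cells[3] + cells[4]))
  wald_estimate("crude_rr", log_rr, se, corrected)
}

#' Count outcome discordance across matched pairs
#'
#' @param matched An `fqad_matched` object.
#' @param outcomes Outcome tibble covering the matched persons.
#' @return A one-row tibble `n10` (target case, comparator not), `n01`,
#'   `n11`, `n00`.
#' @export
discordant_pairs <- function(matched, outcomes) {
  if (inherits(outcomes, "fqad_outcomes")) outcomes <- outcomes$outcomes
  oc <- dplyr::select(outcomes, "person_id", "outcome")
  tab <- matched$pairs |>
    dplyr::left_join(oc, by = c(target_id = "person_id")) |>
    dplyr::left_join(oc, by = c(comparator_id = "person_id"),
                     suffix = c("_t", "_c")) |>
    dplyr::mutate(outcome_t = dplyr::coalesce(.data$outcome_t, FALSE),
                  outcome_c = dplyr::coalesce(.data$outcome_c, FALSE))
  tibble::tibble(n10 = sum(tab$outcome_t & !tab$outcome_c),
                 n01 = sum(!tab$outcome_t & tab$outcome_c),
                 n11 = sum(tab$outcome_t & tab$outcome_c),
                 n00 = sum(!tab$outcome_t & !tab$outcome_c))
}

#' Matched-pair conditional odds ratio
#'
#' The conditional-likelihood (conditional logistic / McNemar) odds ratio
#' for 1:1 matched binary outcomes is `n10 / n01` -- concordant pairs carry
#' no information -- with `SE(log OR) = sqrt(1/n10 + 1/n01)`, Wald 95% CI
#' and a two-sided normal p-value. A zero discordant cell triggers the 0.5
#' continuity correction (flagged).
#'
#' @param pairs A [discordant_pairs()] row, or `n10` directly.
#' @param n01 Discordant count when `pairs` is given as `n10`.
#' @return A one-row estimate tibble.
#' @examples
#' matched_or(20, 10) # OR 2.0
#' @export
matched_or <- function(pairs, n01 = NULL) {
  if (is.data.frame(pairs)) {
    n10 <- pairs$n10
    n01 <- pairs$n01
  } else {
    n10 <- pairs
  }
  if (n10 + n01 == 0) {
    stop("matched odds ratio undefined: no discordant pairs", call. = FALSE)
  }
  corrected <- n10 == 0 || n01 == 0
  if (corrected) {
    n10 <- n10 + 0.5
    n01 <- n01 + 0.5
  }
  wald_estimate("matched_or", log(n10 / n01), sqrt(1 / n10 + 1 / n01),
                corrected)
}

#' Power for comparing two proportions
#'
#' Normal-approximation power to detect an alternative defined by an odds
#' ratio: `p1` is obtained from `p0` and `or_alt` on the odds scale, the
#' effect z-value is `|p1 - p0| / sqrt((p0(1-p0) + p1(1-p1)) / n)` and
#' power is `Phi(z_effect - z_alpha)`.
#'
#' @param n_per_arm Sample size per arm.
#' @param p0 Baseline outcome proportion.
#' @param or_alt Alternative-hypothesis odds ratio.
#' @param alpha Significance level.
#' @param sided 1 (default) or 2.
#' @return Power as a proportion in (0,1).
#' @examples
#' power_two_proportions(119653, 0.002, 1.25) # >= 0.80
#' @export
power_two_proportions <- function(n_per_arm, p0, or_alt, alpha = 0.05,
                                  sided = 1) {
  stopifnot(p0 > 0, p0 < 1, or_alt > 0, sided %in% c(1, 2))
  odds1 <- or_alt * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  z_eff <- abs(p1 - p0) /
    sqrt((p0 * (1 - p0) + p1 * (1 - p1)) / n_per_arm)
  z_crit <- stats::qnorm(1 - alpha / sided)
  stats::pnorm(z_eff - z_crit)
}
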