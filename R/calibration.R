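#' Estimate negative-control outcome effects on the matched cohort
#'
#' Applies the matched-pair analysis to each negative-control condition:
#' the control outcome for an entry is the first occurrence of the control
#' code within the time-at-risk window (with a clean 183-day pre-index
#' window), and the effect is the matched-pair conditional odds ratio.
#' Controls are single conditions, so no multi-SOC or confirmation logic
#' applies. Controls with no discordant pairs are excluded (and listed in
#' the `"excluded"` attribute).
#'
#' @param matched An `fqad_matched` object.
#' @param bundle The claims bundle.
#' @param vocab A loaded vocabulary (supplies the 45 control codes).
#' @param cohort Cohort entries (for index dates).
#' @param tar_days Time-at-risk window (same as the study outcome).
#' @return Tibble of `NegativeControlEstimate`s: `control_id`, `log_or`,
#'   `se_log_or`, `n10`, `n01`.
#' @export
estimate_controls <- function(matched, bundle, vocab, cohort,
                              tar_days = 120L) {
  if (inherits(cohort, "fqad_cohort")) cohort <- cohort$cohort
  matched_ids <- c(matched$pairs$target_id, matched$pairs$comparator_id)
  entries <- dplyr::filter(cohort, .data$person_id %in% matched_ids)
  events <- bundle$condition_occurrence |>
    dplyr::filter(.data$condition_code %in% vocab$negative_controls) |>
    dplyr::inner_join(dplyr::select(entries, "person_id", "index_date"),
                      by = "person_id", relationship = "many-to-many") |>
    dplyr::mutate(days = as.integer(.data$event_date - .data$index_date))
  in_tar <- events |>
    dplyr::filter(.data$days >= 1L, .data$days <= tar_days) |>
    dplyr::distinct(.data$person_id, .data$condition_code)
  dirty <- events |>
    dplyr::filter(.data$days >= -LOOKBACK_GENERAL, .data$days <= 0L) |>
    dplyr::distinct(.data$person_id, .data$condition_code)
  hits <- dplyr::anti_join(in_tar, dirty,
                           by = c("person_id", "condition_code"))

  ests <- purrr::map_dfr(vocab$negative_controls, function(code) {
    pos <- hits$person_id[hits$condition_code == code]
    oc <- tibble::tibble(person_id = entries$person_id,
                         outcome = entries$person_id %in% pos)
    d <- discordant_pairs(matched, oc)
    if (d$n10 + d$n01 == 0) {
      return(tibble::tibble(control_id = code, log_or = NA_real_,
                            se_log_or = NA_real_, n10 = d$n10, n01 = d$n01))
    }
    est <- matched_or(d)
    tibble::tibble(control_id = code, log_or = est$log_estimate,
                   se_log_or = est$se_log, n10 = d$n10, n01 = d$n01)
  })
  usable <- dplyr::filter(ests, is.finite(.data$log_or))
  if (nrow(usable) < 5) {
    stop("calibration refused: only ", nrow(usable),
         " usable negative controls (need >= 5)", call. = FALSE)
  }
  attr(usable, "excluded") <- ests$control_id[!is.finite(ests$log_or)]
  usable
}

#' @keywords internal
null_loglik <- function(mu, sigma, log_or, se) {
  sum(stats::dnorm(log_or, mean = mu, sd = sqrt(sigma^2 + se^2), log = TRUE))
}

#' Fit the empirical null distribution
#'
#' Maximum-likelihood fit of the systematic-error distribution
#' `Normal(mu, sigma)` to negative-control estimates: each control log-OR
#' `theta_i` with sampling SE `tau_i` contributes
#' `Normal(theta_i; mu, sqrt(sigma^2 + tau_i^2))`. Optimized by bounded
#' quasi-Newton on `(mu, log sigma)` with multi-start over
#' `sigma = 0.01, 0.1, 0.5` (best likelihood wins); a vanishing-`sigma`
#' profile is also evaluated so the degenerate `sigma = 0` solution is
#' found exactly.
#'
#' @param controls Tibble with `log_or` and `se_log_or` (e.g.
#'   [estimate_controls()]).
#' @return An `fqad_null`: `mu`, `sigma`, `n_controls`, `loglik`,
#'   `convergence`.
#' @examples
#' fit_empirical_null(tibble::tibble(log_or = c(0.1, -0.1),
#'                                   se_log_or = c(0.01, 0.01)))
#' @export
fit_empirical_null <- function(controls) {
  theta <- controls$log_or
  tau <- controls$se_log_or
  ok <- is.finite(theta) & is.finite(tau) & tau > 0
  theta <- theta[ok]; tau <- tau[ok]
  if (length(theta) < 2) {
    stop("empirical null needs at least 2 finite control estimates",
         call. = FALSE)
  }
  negll <- function(par) -null_loglik(par[1], exp(par[2]), theta, tau)
  starts <- lapply(c(0.01, 0.1, 0.5),
                   function(s0) c(mean(theta), log(s0)))
  fits <- lapply(starts, function(p0) {
    tryCatch(stats::optim(p0, negll, method = "L-BFGS-B",
                          lower = c(-10, -20), upper = c(10, 3),
                          control = list(factr = 1e5)),
             error = function(e) list(convergence = 99L,
                                      message = conditionMessage(e),
                                      value = Inf, par = p0))
  })
  converged <- vapply(fits, function(f) f$convergence == 0, logical(1))
  if (!any(converged)) {
    msgs <- vapply(fits, function(f) paste0(f$convergence, ": ",
                                            f$message %||% ""), "")
    stop("empirical-null optimizer failed to converge from every start (",
         paste(unique(msgs), collapse = "; "), ")", call. = FALSE)
  }
  fits <- fits[converged]
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  mu <- best$par[1]; sigma <- exp(best$par[2]); ll <- -best$value
  # exact degenerate boundary: sigma = 0 reduces to a weighted mean
  mu0 <- sum(theta / tau^2) / sum(1 / tau^2)
  ll0 <- null_loglik(mu0, 0, theta, tau)
  if (ll0 >= ll || sigma < 1e-6) {
    if (ll0 >= ll) {
      mu <- mu0; sigma <- 0; ll <- ll0
    } else {
      sigma <- 0
      ll <- null_loglik(mu, 0, theta, tau)
    }
  }
  structure(list(mu = mu, sigma = sigma, n_controls = length(theta),
                 loglik = ll, convergence = best$convergence),
            class = "fqad_null")
}

#' @export
print.fqad_null <- function(x, ...) {
  cat(sprintf(
    "<fqad_null> empirical null: mu = %.4f, sigma = %.4f (%d controls)\n",
    x$mu, x$sigma, x$n_controls))
  invisible(x)
}

#' @rdname fit_empirical_null
#' @param x An `fqad_null`.
#' @param ... Unused.
#' @method tidy fqad_null
#' @export
tidy.fqad_null <- function(x, ...) {
  tibble::tibble(term = c("mu", "sigma"), estimate = c(x$mu, x$sigma))
}

#' @rdname fit_empirical_null
#' @method glance fqad_null
#' @export
glance.fqad_null <- function(x, ...) {
  tibble::tibble(mu = x$mu, sigma = x$sigma, n_controls = x$n_controls,
                 loglik = x$loglik)
}

#' Calibrated p-value
#'
#' Two-sided tail probability of an estimate under the fitted empirical
#' null: `z = (log_or - mu) / sqrt(sigma^2 + se^2)` and
#' `p = 2 * min(Phi(z), 1 - Phi(z))`. With a degenerate null
#' (`mu = 0, sigma = 0`) this equals the nominal two-sided p-value.
#'
#' @param null An `fqad_null`.
#' @param log_or Log odds ratio of the estimate to calibrate.
#' @param se Its standard error.
#' @return Calibrated p-value in (0, 1].
#' @export
calibrate_p <- function(null, log_or, se) {
  stopifnot(inherits(null, "fqad_null"))
  z <- (log_or - null$mu) / sqrt(null$sigma^2 + se^2)
  2 * pmin(stats::pnorm(z), 1 - stats::pnorm(z))
}

#' Calibration diagnostics plot
#'
#' Negative-control estimates (log OR vs standard error) with the
#' conventional nominal-significance funnel and the band implied by the
#' fitted empirical null.
#'
#' @param controls Tibble from [estimate_controls()].
#' @param null An `fqad_null`.
#' @return A ggplot object.
#' @export
plot_calibration <- function(controls, null) {
  se_grid <- seq(1e-3, max(controls$se_log_or) * 1.1, length.out = 100)
  bands <- tibble::tibble(
    se = se_grid,
    nominal_low = -1.96 * se_grid, nominal_high = 1.96 * se_grid,
    cal_low = null$mu - 1.96 * sqrt(null$sigma^2 + se_grid^2),
    cal_high = null$mu + 1.96 * sqrt(null$sigma^2 + se_grid^2))
  ggplot2::ggplot(controls, ggplot2::aes(x = .data$se_log_or,
                                         y = .data$log_or)) +
    ggplot2::geom_ribbon(data = bands,
                         ggplot2::aes(x = .data$se, y = NULL,
                                      ymin = .data$cal_low,
                                      ymax = .data$cal_high),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line(data = bands,
                       ggplot2::aes(x = .data$se, y = .data$nominal_low),
                       linetype = 2) +
    ggplot2::geom_line(data = bands,
                       ggplot2::aes(x = .data$se, y = .data$nominal_high),
                       linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "standard error of log OR",
                  y = "negative-control log OR",
                  title = "Empirical calibration of negative controls") +
    ggplot2::theme_minimal()
}
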