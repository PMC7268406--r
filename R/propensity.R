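#' Build the baseline covariate table
#'
#' Constructs strictly pre-index features for the propensity model:
#' demographics (five-year age bands, sex) plus indicator flags for every
#' diagnosis code and drug code observed in the 30-day, 183-day and 365-day
#' windows before the index date (windows end the day before index, so the
#' index dispensing itself is never a feature). Entries whose observation
#' period does not span the full 365-day lookback keep window-truncated
#' features and are flagged, not dropped.
#'
#' @param cohort Cohort entries tibble (or `fqad_cohort`).
#' @param bundle The claims bundle.
#' @return A wide tibble: `person_id`, demographic indicators, and
#'   `dx_<code>_w<window>` / `rx_<code>_w<window>` flags (0/1). The feature
#'   dictionary (feature, kind, code, window) is attached as the
#'   `"dictionary"` attribute, truncated-lookback persons as `"truncated"`.
#' @export
build_covariates <- function(cohort, bundle) {
  if (inherits(cohort, "fqad_cohort")) cohort <- cohort$cohort
  base <- dplyr::select(cohort, "person_id", "index_date", "age_at_index",
                        "sex")

  bands <- seq(15L, 70L, 5L)
  demo <- base |>
    dplyr::mutate(
      age_band = cut(.data$age_at_index, breaks = bands, right = FALSE,
                     labels = paste0("age_", head(bands, -1), "_",
                                     head(bands, -1) + 4L)),
      flag = 1L) |>
    tidyr::pivot_wider(id_cols = "person_id", names_from = "age_band",
                       values_from = "flag", values_fill = 0L,
                       names_expand = TRUE) |>
    dplyr::left_join(dplyr::transmute(base, person_id = .data$person_id,
                                      female = as.integer(.data$sex == "F")),
                     by = "person_id")

  window_flags <- function(events, date_col, kind) {
    long <- events |>
      dplyr::inner_join(dplyr::select(base, "person_id", "index_date"),
                        by = "person_id", relationship = "many-to-many") |>
      dplyr::mutate(days_before =
                      as.integer(.data$index_date - .data[[date_col]])) |>
      dplyr::filter(.data$days_before >= 1L,
                    .data$days_before <= LOOKBACK_YEAR)
    purrr::map_dfr(c(30L, 183L, 365L), function(w) {
      long |>
        dplyr::filter(.data$days_before <= w) |>
        dplyr::distinct(.data$person_id, .data$code) |>
        dplyr::mutate(feature = paste0(kind, "_", .data$code, "_w", w))
    })
  }
  dx <- window_flags(dplyr::select(bundle$condition_occurrence, "person_id",
                                   code = "condition_code",
                                   event_date = "event_date"),
                     "event_date", "dx")
  rx <- window_flags(dplyr::select(bundle$drug_exposure, "person_id",
                                   code = "drug_code",
                                   dispense_date = "dispense_date"),
                     "dispense_date", "rx")
  flags <- dplyr::bind_rows(dx, rx)
  wide <- if (nrow(flags) > 0) {
    flags |>
      dplyr::mutate(value = 1L) |>
      tidyr::pivot_wider(id_cols = "person_id", names_from = "feature",
                         values_from = "value", values_fill = 0L,
                         names_sort = TRUE)
  } else {
    tibble::tibble(person_id = base$person_id)
  }
  out <- demo |>
    dplyr::left_join(wide, by = "person_id") |>
    dplyr::mutate(dplyr::across(-"person_id", \(x) dplyr::coalesce(x, 0L)))

  feats <- setdiff(names(out), "person_id")
  dict <- tibble::tibble(
    feature = feats,
    kind = dplyr::case_when(stringr::str_starts(feats, "dx_") ~ "diagnosis",
                            stringr::str_starts(feats, "rx_") ~ "drug",
                            TRUE ~ "demographic"),
    window = dplyr::if_else(stringr::str_detect(feats, "_w\\d+$"),
                            stringr::str_extract(feats, "\\d+$"), NA_character_))
  obs <- bundle$observation_period |>
    dplyr::inner_join(dplyr::select(base, "person_id", "index_date"),
                      by = "person_id", relationship = "many-to-many") |>
    dplyr::filter(.data$index_date >= .data$start_date,
                  .data$index_date <= .data$end_date)
  truncated <- obs$person_id[obs$start_date > obs$index_date - LOOKBACK_YEAR]
  attr(out, "dictionary") <- dict
  attr(out, "truncated") <- truncated
  out
}

#' Fit the LASSO propensity-score model
#'
#' Estimates the probability of membership in the fluoroquinolone arm by
#' L1-penalized (lasso / Laplace-prior) logistic regression, with the
#' penalty chosen by 10-fold cross-validated likelihood at convergence
#' tolerance 2e-7. Constant feature columns are dropped (and logged); fold
#' assignment is seeded, so refits are reproducible.
#'
#' @param covariates Output of [build_covariates()].
#' @param arms Character vector aligned with `covariates` rows (`"fq"` /
#'   `"azst"`).
#' @param nfolds Cross-validation folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return An `fqad_ps_model`: the glmnet cv fit, the selected penalty,
#'   coefficients, dropped columns, and a `scores` tibble (`person_id`,
#'   `arm`, `score`).
#' @export
fit_ps <- function(covariates, arms, nfolds = 10, seed = 1) {
  stopifnot(nrow(covariates) == length(arms))
  if (sum(arms == "fq") < 2 || sum(arms == "azst") < 2) {
    stop("propensity model needs at least 2 entries per arm", call. = FALSE)
  }
  x <- as.matrix(covariates[, setdiff(names(covariates), "person_id")])
  storage.mode(x) <- "double"
  constant <- apply(x, 2, function(col) length(unique(col)) < 2)
  dropped <- colnames(x)[constant]
  x <- x[, !constant, drop = FALSE]
  y <- as.integer(arms == "fq")

  set.seed(seed)
  if (ncol(x) >= 2) {
    xs <- Matrix::Matrix(x, sparse = TRUE)
    foldid <- sample(rep_len(seq_len(nfolds), nrow(x)))
    cv <- glmnet::cv.glmnet(xs, y, family = "binomial", alpha = 1,
                            foldid = foldid, thresh = 2e-7)
    score <- as.numeric(stats::predict(cv, newx = xs, s = "lambda.min",
                                       type = "response"))
    beta <- as.matrix(stats::coef(cv, s = "lambda.min"))
    coefs <- tibble::tibble(term = rownames(beta), estimate = beta[, 1])
    lambda <- cv$lambda.min
    cv_trace <- tibble::tibble(lambda = cv$lambda, cvm = cv$cvm,
                               cvsd = cv$cvsd, nzero = as.integer(cv$nzero))
  } else {
    # too few informative columns for a penalized path; plain logistic fit
    df <- data.frame(y = y, x)
    fit <- stats::glm(y ~ ., data = df, family = stats::binomial())
    score <- as.numeric(stats::fitted(fit))
    coefs <- tibble::tibble(term = names(stats::coef(fit)),
                            estimate = unname(stats::coef(fit)))
    cv <- fit
    lambda <- 0
    cv_trace <- tibble::tibble()
  }
  score <- pmin(pmax(score, 1e-12), 1 - 1e-12)
  structure(list(fit = cv, lambda = lambda, coefficients = coefs,
                 dropped = dropped, cv_trace = cv_trace, nfolds = nfolds,
                 seed = seed,
                 scores = tibble::tibble(person_id = covariates$person_id,
                                         arm = arms, score = score)),
            class = "fqad_ps_model")
}

#' @export
print.fqad_ps_model <- function(x, ...) {
  nz <- sum(x$coefficients$estimate != 0 &
              x$coefficients$term != "(Intercept)")
  cat("<fqad_ps_model> lasso propensity model\n")
  cat(sprintf("  n = %d, penalty (lambda) = %.3g, nonzero terms = %d\n",
              nrow(x$scores), x$lambda, nz))
  if (length(x$dropped) > 0) {
    cat("  dropped constant columns:", length(x$dropped), "\n")
  }
  invisible(x)
}

#' @rdname fit_ps
#' @param x An `fqad_ps_model`.
#' @param ... Unused.
#' @method tidy fqad_ps_model
#' @export
tidy.fqad_ps_model <- function(x, ...) x$coefficients

#' @rdname fit_ps
#' @method glance fqad_ps_model
#' @export
glance.fqad_ps_model <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$scores),
    n_target = sum(x$scores$arm == "fq"),
    n_comparator = sum(x$scores$arm == "azst"),
    lambda = x$lambda,
    n_nonzero = sum(x$coefficients$estimate != 0 &
                      x$coefficients$term != "(Intercept)"),
    n_dropped_constant = length(x$dropped))
}

#' Trim by pooled propensity-score percentiles
#'
#' Removes entries whose score falls strictly below the 5th or strictly
#' above the 95th percentile of the pooled (both-arm) score distribution;
#' boundary values are retained. Percentiles use linear-interpolation
#' quantiles, so identical scores yield degenerate bounds and nothing is
#' trimmed.
#'
#' @param scores Tibble with `person_id`, `arm`, `score` (e.g.
#'   `fit_ps(...)$scores`).
#' @param lower,upper Percentile bounds as proportions.
#' @return The retained rows; trimming bounds attached as `"bounds"`.
#' @export
trim_ps <- function(scores, lower = 0.05, upper = 0.95) {
  q <- stats::quantile(scores$score, c(lower, upper), type = 7, names = FALSE)
  out <- dplyr::filter(scores, .data$score >= q[1], .data$score <= q[2])
  attr(out, "bounds") <- q
  out
}

# lexicographic binary min-heap on (gap, target_id, comparator_id);
# used by the large-cohort path of greedy_match
heap_less <- function(h, a, b) {
  (h$gap[a] < h$gap[b]) ||
    (h$gap[a] == h$gap[b] &&
       (h$t[a] < h$t[b] || (h$t[a] == h$t[b] && h$c[a] < h$c[b])))
}

#' 1:1 greedy caliper matching on the propensity score
#'
#' Nearest-first greedy matching: all feasible cross-arm pairs are
#' considered in order of increasing score distance (ties broken by target
#' then comparator person id) and accepted when both members are still
#' unmatched and the distance does not exceed the caliper. The caliper is
#' `caliper_mult` times the sample standard deviation of the pooled
#' post-trim scores, applied on the probability scale by default.
#'
#' For large cohorts an equivalent pooled-sort formulation is used (the
#' globally nearest cross-arm pair is always adjacent in the pooled score
#' order), which gives the same nearest-first result in O(n log n).
#'
#' @param scores Post-trim score tibble (`person_id`, `arm`, `score`).
#' @param caliper_mult Caliper as a multiple of the pooled score SD
#'   (default 0.25).
#' @param logit_scale Match on the log-odds scale instead of the
#'   probability scale (off by default).
#' @return An `fqad_matched`: `pairs` tibble (`target_id`,
#'   `comparator_id`, `ps_target`, `ps_comparator`, `distance`), the
#'   caliper, pooled SD, and the full score table.
#' @export
greedy_match <- function(scores, caliper_mult = 0.25, logit_scale = FALSE) {
  s <- scores
  if (logit_scale) s$score <- stats::qlogis(s$score)
  tgt <- dplyr::filter(s, .data$arm == "fq")
  cmp <- dplyr::filter(s, .data$arm == "azst")
  sd_pooled <- stats::sd(s$score)
  caliper <- caliper_mult * sd_pooled
  if (!is.finite(caliper)) caliper <- Inf

  empty_pairs <- tibble::tibble(pair_id = integer(), target_id = integer(),
                                comparator_id = integer(),
                                ps_target = double(), ps_comparator = double(),
                                distance = double())
  if (nrow(tgt) == 0 || nrow(cmp) == 0) {
    return(structure(list(pairs = empty_pairs, caliper = caliper,
                          sd_pooled = sd_pooled, scores = scores,
                          caliper_mult = caliper_mult),
                     class = "fqad_matched"))
  }

  if (as.double(nrow(tgt)) * nrow(cmp) <= 250000) {
    pairs <- tidyr::expand_grid(i = seq_len(nrow(tgt)), j = seq_len(nrow(cmp)))
    pairs$d <- abs(tgt$score[pairs$i] - cmp$score[pairs$j])
    pairs <- pairs[pairs$d <= caliper, ]
    pairs <- pairs[order(pairs$d, tgt$person_id[pairs$i],
                         cmp$person_id[pairs$j]), ]
    used_t <- rep(FALSE, nrow(tgt)); used_c <- rep(FALSE, nrow(cmp))
    keep <- logical(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      if (!used_t[i] && !used_c[j]) {
        keep[k] <- TRUE; used_t[i] <- TRUE; used_c[j] <- TRUE
      }
    }
    sel <- pairs[keep, ]
    matched <- tibble::tibble(target_id = tgt$person_id[sel$i],
                              comparator_id = cmp$person_id[sel$j],
                              ps_target = tgt$score[sel$i],
                              ps_comparator = cmp$score[sel$j],
                              distance = sel$d)
  } else {
    matched <- greedy_match_pooled(tgt, cmp, caliper)
  }
  matched <- dplyr::arrange(matched, .data$target_id)
  matched$pair_id <- seq_len(nrow(matched))
  if (logit_scale) {
    matched$ps_target <- stats::plogis(matched$ps_target)
    matched$ps_comparator <- stats::plogis(matched$ps_comparator)
  }
  structure(list(pairs = dplyr::relocate(matched, "pair_id"),
                 caliper = caliper, sd_pooled = sd_pooled, scores = scores,
                 caliper_mult = caliper_mult),
            class = "fqad_matched")
}

#' @keywords internal
greedy_match_pooled <- function(tgt, cmp, caliper) {
  n_t <- nrow(tgt); n_c <- nrow(cmp)
  score <- c(tgt$score, cmp$score)
  pid <- c(tgt$person_id, cmp$person_id)
  is_t <- c(rep(TRUE, n_t), rep(FALSE, n_c))
  ord <- order(score, pid)
  score <- score[ord]; pid <- pid[ord]; is_t <- is_t[ord]
  n <- n_t + n_c
  nxt <- c(2:n, NA_integer_); prv <- c(NA_integer_, 1:(n - 1))
  alive <- rep(TRUE, n)

  # binary heap over candidate adjacent cross-arm pairs (preallocated)
  cap <- 4L * n + 8L
  h <- new.env(parent = emptyenv())
  h$gap <- numeric(cap); h$t <- numeric(cap); h$c <- numeric(cap)
  h$i <- integer(cap); h$j <- integer(cap); h$size <- 0L
  swap <- function(a, b) {
    tmp <- h$gap[a]; h$gap[a] <- h$gap[b]; h$gap[b] <- tmp
    tmp <- h$t[a]; h$t[a] <- h$t[b]; h$t[b] <- tmp
    tmp <- h$c[a]; h$c[a] <- h$c[b]; h$c[b] <- tmp
    tmp <- h$i[a]; h$i[a] <- h$i[b]; h$i[b] <- tmp
    tmp <- h$j[a]; h$j[a] <- h$j[b]; h$j[b] <- tmp
  }
  push <- function(i, j) {
    if (is_t[i] == is_t[j]) return(invisible())
    gap <- abs(score[i] - score[j])
    if (gap > caliper) return(invisible())
    ti <- if (is_t[i]) i else j; ci <- if (is_t[i]) j else i
    k <- h$size + 1L
    if (k > length(h$gap)) {  # doubling growth
      extra <- length(h$gap)
      h$gap <- c(h$gap, numeric(extra)); h$t <- c(h$t, numeric(extra))
      h$c <- c(h$c, numeric(extra)); h$i <- c(h$i, integer(extra))
      h$j <- c(h$j, integer(extra))
    }
    h$gap[k] <- gap; h$t[k] <- pid[ti]; h$c[k] <- pid[ci]
    h$i[k] <- i; h$j[k] <- j; h$size <- k
    while (k > 1L) {
      p <- k %/% 2L
      if (heap_less(h, k, p)) { swap(k, p); k <- p } else break
    }
    invisible()
  }
  pop <- function() {
    top <- c(h$i[1], h$j[1])
    h$gap[1] <- h$gap[h$size]; h$t[1] <- h$t[h$size]
    h$c[1] <- h$c[h$size]; h$i[1] <- h$i[h$size]; h$j[1] <- h$j[h$size]
    h$size <- h$size - 1L
    k <- 1L
    repeat {
      l <- 2L * k; r <- l + 1L; m <- k
      if (l <= h$size && heap_less(h, l, m)) m <- l
      if (r <= h$size && heap_less(h, r, m)) m <- r
      if (m == k) break
      swap(k, m)
      k <- m
    }
    top
  }

  for (i in seq_len(n - 1L)) push(i, i + 1L)
  max_pairs <- min(n_t, n_c)
  res_t <- integer(max_pairs); res_c <- integer(max_pairs); n_res <- 0L
  while (h$size > 0L) {
    ij <- pop()
    i <- ij[1]; j <- ij[2]
    if (!alive[i] || !alive[j]) next
    ti <- if (is_t[i]) i else j; ci <- if (is_t[i]) j else i
    n_res <- n_res + 1L
    res_t[n_res] <- ti; res_c[n_res] <- ci
    alive[i] <- FALSE; alive[j] <- FALSE
    a <- prv[min(i, j)]; b <- nxt[max(i, j)]
    if (!is.na(a)) nxt[a] <- b
    if (!is.na(b)) prv[b] <- a
    if (!is.na(a) && !is.na(b)) push(a, b)
  }
  res_t <- res_t[seq_len(n_res)]; res_c <- res_c[seq_len(n_res)]
  tibble::tibble(target_id = pid[res_t], comparator_id = pid[res_c],
                 ps_target = score[res_t], ps_comparator = score[res_c],
                 distance = abs(score[res_t] - score[res_c]))
}

#' @export
print.fqad_matched <- function(x, ...) {
  cat("<fqad_matched>\n")
  cat(sprintf("  pairs: %d (caliper %.4g = %.2f x pooled SD %.4g)\n",
              nrow(x$pairs), x$caliper, x$caliper_mult, x$sd_pooled))
  invisible(x)
}

#' Standardized mean difference
#'
#' `(m1 - m2) / sqrt((v1 + v2) / 2)`; for binary covariates supply
#' prevalences and the Bernoulli variances `p(1-p)` are used. When both
#' variances are zero the SMD is 0 for equal means and `Inf` otherwise.
#'
#' @param m1,m2 Means (or prevalences) in each arm.
#' @param v1,v2 Variances; defaults assume binary covariates.
#' @return Numeric SMD vector.
#' @examples
#' smd(0.032, 0.009) # 0.16 to 2 d.p.
#' @export
smd <- function(m1, m2, v1 = m1 * (1 - m1), v2 = m2 * (1 - m2)) {
  denom <- sqrt((v1 + v2) / 2)
  out <- (m1 - m2) / denom
  zero <- denom == 0
  out[zero & m1 == m2] <- 0
  out[zero & m1 != m2] <- Inf
  out
}

#' Preference score
#'
#' Transforms a propensity score `S` for treated fraction `P` via
#' `logit(F) = logit(S) - logit(P)`, so that with equal-sized arms the
#' preference score equals the propensity score. Used to visualize clinical
#' equipoise between arms.
#'
#' @param score Propensity scores in (0,1).
#' @param p_treated Fraction of the population in the target arm.
#' @return Preference scores in (0,1).
#' @export
preference_score <- function(score, p_treated) {
  stats::plogis(stats::qlogis(score) - stats::qlogis(p_treated))
}

#' Covariate balance diagnostics
#'
#' Per-covariate prevalence in each arm and standardized mean difference,
#' before matching (all scored entries) and after matching (matched persons
#' only), plus per-entry preference scores.
#'
#' @param matched An `fqad_matched` object.
#' @param covariates Output of [build_covariates()] covering the cohort.
#' @return An `fqad_balance`: `table` (one row per covariate) and
#'   `preference` (entry-level preference scores with matched flags).
#' @export
balance_report <- function(matched, covariates) {
  scores <- matched$scores
  cov <- dplyr::inner_join(dplyr::select(scores, "person_id", "arm"),
                           covariates, by = "person_id")
  matched_ids <- c(matched$pairs$target_id, matched$pairs$comparator_id)
  feats <- setdiff(names(covariates), "person_id")

  arm_means <- function(data) {
    data |>
      dplyr::group_by(.data$arm) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(feats), mean),
                       .groups = "drop") |>
      tidyr::pivot_longer(-"arm", names_to = "feature",
                          values_to = "mean") |>
      tidyr::pivot_wider(names_from = "arm", values_from = "mean")
  }
  before <- arm_means(cov)
  after <- arm_means(dplyr::filter(cov, .data$person_id %in% matched_ids))
  tab <- dplyr::full_join(before, after, by = "feature",
                          suffix = c("_before", "_after")) |>
    dplyr::mutate(
      smd_before = smd(.data$fq_before, .data$azst_before),
      smd_after = smd(.data$fq_after, .data$azst_after))

  p_treated <- mean(scores$arm == "fq")
  pref <- scores |>
    dplyr::mutate(preference = preference_score(.data$score, p_treated),
                  matched = .data$person_id %in% matched_ids)
  structure(list(table = tab, preference = pref, p_treated = p_treated),
            class = "fqad_balance")
}

#' @export
print.fqad_balance <- function(x, ...) {
  cat("<fqad_balance>\n")
  cat(sprintf("  covariates: %d | max |SMD| before %.3f -> after %.3f\n",
              nrow(x$table), max(abs(x$table$smd_before), na.rm = TRUE),
              max(abs(x$table$smd_after), na.rm = TRUE)))
  invisible(x)
}

#' Preference-score distribution plot
#'
#' Density of the preference score by arm, before and after matching; good
#' overlap indicates clinical equipoise between the exposure groups.
#'
#' @param object An `fqad_balance` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fqad_balance
#' @export
autoplot.fqad_balance <- function(object, ...) {
  pref <- object$preference |>
    dplyr::mutate(stage = "before matching") |>
    dplyr::bind_rows(object$preference |>
                       dplyr::filter(.data$matched) |>
                       dplyr::mutate(stage = "after matching")) |>
    dplyr::mutate(stage = factor(.data$stage, c("before matching",
                                                "after matching")),
                  arm = dplyr::recode(.data$arm, fq = "fluoroquinolone",
                                      azst = "azithromycin / SMX-TMP"))
  ggplot2::ggplot(pref, ggplot2::aes(x = .data$preference,
                                     fill = .data$arm)) +
    ggplot2::geom_density(alpha = 0.4, adjust = 1.5) +
    ggplot2::facet_wrap(~stage) +
    ggplot2::labs(x = "preference score", y = "density", fill = NULL) +
    ggplot2::theme_minimal()
}
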