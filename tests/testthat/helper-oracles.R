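# Independent brute-force oracles. Each re-derives a pipeline result by
# naive per-person scans or exhaustive search, sharing no code with the
# vectorized implementations they check.

# per-person scan re-deriving the final cohort (arm + index date)
oracle_cohort <- function(bundle, vocab) {
  ind_of <- function(code) {
    for (ind in names(vocab$indications)) {
      if (code %in% vocab$indications[[ind]]) return(ind)
    }
    NA_character_
  }
  arm_of <- function(code) {
    if (code %in% vocab$exposures$fq) return("fq")
    if (code %in% c(vocab$exposures$az, vocab$exposures$st)) return("azst")
    NA_character_
  }
  ex <- vocab$exclusions
  out <- list()
  for (pid in bundle$person$person_id) {
    conds <- bundle$condition_occurrence[
      bundle$condition_occurrence$person_id == pid, ]
    drugs <- bundle$drug_exposure[bundle$drug_exposure$person_id == pid, ]
    claims <- bundle$disability_claim[
      bundle$disability_claim$person_id == pid, ]
    obs <- bundle$observation_period[
      bundle$observation_period$person_id == pid, ]

    # qualifying (indication, dispensing) pairs
    cands <- list()
    for (i in seq_len(nrow(conds))) {
      ind <- ind_of(conds$condition_code[i])
      if (is.na(ind) || conds$setting[i] != "outpatient") next
      for (j in seq_len(nrow(drugs))) {
        arm <- arm_of(drugs$drug_code[j])
        if (is.na(arm)) next
        dc <- drugs$drug_code[j]
        pair_ok <- (dc %in% vocab$exposures$fq) ||
          (dc %in% vocab$exposures$az &&
             ind %in% c("sinusitis", "bronchitis")) ||
          (dc %in% vocab$exposures$st && ind == "uti")
        gap <- as.integer(drugs$dispense_date[j] - conds$event_date[i])
        if (!pair_ok || gap < 0 || gap > 30) next
        # both-drug co-dispensing in [indication, index + 7]
        both <- FALSE
        for (k in seq_len(nrow(drugs))) {
          oa <- arm_of(drugs$drug_code[k])
          if (is.na(oa) || oa == arm) next
          if (drugs$dispense_date[k] >= conds$event_date[i] &&
              drugs$dispense_date[k] <= drugs$dispense_date[j] + 7) {
            both <- TRUE
          }
        }
        if (!both) {
          cands[[length(cands) + 1]] <-
            list(date = drugs$dispense_date[j], arm = arm, drug = dc)
        }
      }
    }
    if (length(cands) == 0) next
    dates <- as.Date(vapply(cands, function(c) as.character(c$date), ""))
    first <- cands[dates == min(dates)]
    codes <- vapply(first, function(c) c$drug, "")
    pick <- first[[order(codes)[1]]]
    index <- pick$date
    arm <- pick$arm

    # eligibility
    ok <- FALSE
    for (i in seq_len(nrow(obs))) {
      if (obs$start_date[i] <= index - 183 &&
          obs$end_date[i] >= index + 120 &&
          index >= obs$start_date[i] && index <= obs$end_date[i] &&
          obs$disability_insured[i]) ok <- TRUE
    }
    if (!ok) next

    # general exclusions
    excluded <- FALSE
    for (i in seq_len(nrow(conds))) {
      if (conds$condition_code[i] %in% ex$general_conditions &&
          conds$event_date[i] >= index - 183 &&
          conds$event_date[i] <= index - 1) excluded <- TRUE
    }
    ster_days <- 0
    for (j in seq_len(nrow(drugs))) {
      if (drugs$dispense_date[j] >= index - 183 &&
          drugs$dispense_date[j] <= index - 1) {
        if (drugs$drug_code[j] %in% ex$steroid_drugs) {
          ster_days <- ster_days + drugs$days_supplied[j]
        }
        if (drugs$drug_code[j] %in% ex$chemotherapy_drugs) excluded <- TRUE
      }
    }
    if (ster_days >= 30) excluded <- TRUE
    for (i in seq_len(nrow(claims))) {
      if (claims$claim_start[i] <= index - 1 &&
          claims$claim_end[i] >= index - 183) excluded <- TRUE
    }
    # indication-specific exclusions (any indication tied to the index date)
    inds <- character()
    for (i in seq_len(nrow(conds))) {
      ind <- ind_of(conds$condition_code[i])
      if (is.na(ind) || conds$setting[i] != "outpatient") next
      gap <- as.integer(index - conds$event_date[i])
      if (gap >= 0 && gap <= 30) inds <- union(inds, ind)
    }
    for (ind in inds) {
      rules <- ex$condition_specific[[ind]]
      for (i in seq_len(nrow(conds))) {
        if (conds$event_date[i] < index - 92 ||
            conds$event_date[i] > index - 1) next
        code <- conds$condition_code[i]
        if (code %in% rules$any_setting) excluded <- TRUE
        if (code %in% rules$inpatient &&
            conds$setting[i] == "inpatient") excluded <- TRUE
      }
    }
    if (excluded) next

    # mutual exclusivity: other-arm dispensing in the 183-day lookback
    cross <- FALSE
    for (j in seq_len(nrow(drugs))) {
      oa <- arm_of(drugs$drug_code[j])
      if (is.na(oa) || oa == arm) next
      if (drugs$dispense_date[j] >= index - 183 &&
          drugs$dispense_date[j] <= index - 1) cross <- TRUE
    }
    if (cross) next

    out[[length(out) + 1]] <- tibble::tibble(person_id = pid, arm = arm,
                                             index_date = index)
  }
  if (length(out) == 0) {
    return(tibble::tibble(person_id = integer(), arm = character(),
                          index_date = as.Date(character())))
  }
  dplyr::bind_rows(out)
}

# per-person scan re-deriving the composite outcome
oracle_outcomes <- function(cohort, bundle, vocab, variant = "primary") {
  win <- if (variant == "primary") c(30, 90) else c(30, 60)
  tar <- if (variant == "primary") 120 else 90
  res <- list()
  for (r in seq_len(nrow(cohort))) {
    pid <- cohort$person_id[r]
    index <- cohort$index_date[r]
    conds <- bundle$condition_occurrence[
      bundle$condition_occurrence$person_id == pid, ]
    claims <- bundle$disability_claim[
      bundle$disability_claim$person_id == pid, ]
    socs <- character()
    onsets <- integer()
    confirm_gaps <- integer()
    for (code in unique(conds$condition_code)) {
      soc <- soc_of(code, vocab)
      if (is.na(soc)) next
      dts <- sort(conds$event_date[conds$condition_code == code])
      gaps <- as.integer(dts - index)
      if (any(gaps >= -183 & gaps <= 0)) next        # not incident
      in_win <- dts[gaps >= 1 & gaps <= 30]
      if (length(in_win) == 0) next
      onset <- min(in_win)
      rep_gaps <- as.integer(dts - onset)
      confirming <- rep_gaps[rep_gaps >= win[1] & rep_gaps <= win[2]]
      if (length(confirming) == 0) next
      socs <- c(socs, soc)
      onsets <- c(onsets, as.integer(onset - index))
      confirm_gaps <- c(confirm_gaps, min(confirming))
    }
    n_socs <- length(unique(socs))
    # disability
    blocked <- FALSE
    pre_ids <- claims$claim_id[claims$claim_start < index]
    dis_date <- as.Date(NA)
    for (i in seq_len(nrow(claims))) {
      if (claims$claim_start[i] <= index - 1 &&
          claims$claim_end[i] >= index - 183) blocked <- TRUE
    }
    if (!blocked) {
      for (i in seq_len(nrow(claims))) {
        if (claims$claim_start[i] >= index &&
            claims$claim_start[i] <= index + tar &&
            (is.na(claims$continuation_of[i]) ||
               !claims$continuation_of[i] %in% pre_ids)) {
          if (is.na(dis_date) || claims$claim_start[i] < dis_date) {
            dis_date <- claims$claim_start[i]
          }
        }
      }
    }
    res[[r]] <- tibble::tibble(
      person_id = pid, n_confirmed_socs = n_socs,
      disability = !is.na(dis_date),
      outcome = n_socs >= 2 && !is.na(dis_date),
      days_to_ae_onset = if (n_socs > 0) min(onsets) else NA_integer_,
      days_to_confirmation = if (n_socs > 0) min(confirm_gaps) else NA_integer_)
  }
  dplyr::bind_rows(res)
}

# exhaustive maximum caliper matching (pair count) for tiny instances
oracle_max_pairs <- function(t_scores, c_scores, caliper) {
  n_t <- length(t_scores)
  best <- 0L
  recurse <- function(i, used_c, count) {
    if (i > n_t) {
      best <<- max(best, count)
      return()
    }
    recurse(i + 1L, used_c, count)  # skip target i
    for (j in seq_along(c_scores)) {
      if (!used_c[j] && abs(t_scores[i] - c_scores[j]) <= caliper) {
        used_c[j] <- TRUE
        recurse(i + 1L, used_c, count + 1L)
        used_c[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, length(c_scores)), 0L)
  best
}

# numeric maximization of the matched-pair conditional likelihood
oracle_conditional_or <- function(n10, n01) {
  negll <- function(lpsi) {
    -(n10 * lpsi - (n10 + n01) * log(1 + exp(lpsi)))
  }
  stats::optimize(negll, c(-15, 15), tol = 1e-9)$minimum
}

# grid-search MLE for the empirical null
oracle_grid_null <- function(log_or, se, mu_range = c(-1, 1),
                             sigma_range = c(0, 1), n_grid = 200) {
  mus <- seq(mu_range[1], mu_range[2], length.out = n_grid)
  sigmas <- seq(sigma_range[1], sigma_range[2], length.out = n_grid)
  best <- c(NA, NA, -Inf)
  for (mu in mus) {
    for (sigma in sigmas) {
      ll <- sum(stats::dnorm(log_or, mu, sqrt(sigma^2 + se^2), log = TRUE))
      if (ll > best[3]) best <- c(mu, sigma, ll)
    }
  }
  list(mu = best[1], sigma = best[2], loglik = best[3])
}
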