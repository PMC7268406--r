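#' Simulation configuration for the synthetic claims generator
#'
#' Builds and validates the parameter set for [simulate_claims()]. Defaults
#' emulate the structure of a large US employer-sponsored claims database
#' linked to short-term disability records: roughly two-year enrollment
#' spans, indication-triggered antibiotic dispensings (fluoroquinolone vs
#' azithromycin / sulfamethoxazole-trimethoprim), baseline covariates that
#' confound treatment choice, a rare (~0.2%) composite
#' disability-plus-multi-SOC-adverse-event outcome, and negative-control
#' conditions whose rates do not depend on the exposure arm.
#'
#' @param n_persons Number of persons to simulate.
#' @param seed Integer seed; the same config and seed reproduce every table
#'   exactly. Per-table sub-streams are derived deterministically.
#' @param enrollment_start,enrollment_end Calendar window within which
#'   observation periods fall (ISO dates).
#' @param mean_enrollment_days Mean observation-period length in days
#'   (default 730, i.e. the ~2-year average dwell time typical of commercial
#'   claims databases).
#' @param indication_rates Named annual probabilities of an episode of each
#'   indication (`sinusitis`, `bronchitis`, `uti`).
#' @param confounder_spec Tibble with columns `name`, `code`, `prevalence`,
#'   `beta_treat` (effect on the fluoroquinolone log-odds) and `beta_outcome`
#'   (effect on the composite-case log-odds). Carriers receive the
#'   confounder's condition code in the pre-index window, so a claims-based
#'   propensity model can adjust for it.
#' @param treatment_model Named per-indication log-odds of receiving a
#'   fluoroquinolone rather than the comparator for that indication.
#' @param dispense_prob Probability that an indication episode is treated
#'   with a study antibiotic.
#' @param ae_model List controlling adverse events: `theta` (ground-truth
#'   exposure log-odds ratio on the composite outcome -- the estimand the
#'   downstream matched OR targets), `case_base_logodds` (baseline log-odds
#'   of being a true composite case), `extra_soc_mean` (mean number of
#'   affected SOCs beyond the defining two, Poisson), `soc_weights` (sampling
#'   weights over the six SOC categories for case AEs),
#'   `background_soc_prob` (arm-independent per-SOC probability of an
#'   incident AE episode unrelated to the composite process),
#'   `background_confirm_prob` (probability such an episode gets a
#'   confirmatory repeat diagnosis), `onset_geom_p` and `confirm_geom_p`
#'   (geometric shape parameters for days to onset in 1--30 and confirmation
#'   delay in 30--90), and `prior_ae_rate` (per-code probability of an
#'   AE-code occurrence in the pre-index history, exercising the
#'   incident-diagnosis clean-window rule).
#' @param disability_model List: `base_logodds` and `per_soc_logodds` give
#'   the probability of a background incident short-term disability claim as
#'   `plogis(base + per_soc * k)` for `k` confirmed background SOC AEs;
#'   `prior_claim_rate` is the probability of a historical disability claim
#'   (which triggers the general exclusion); `continuation_prob` is the
#'   chance a pre-index claim spawns a flagged continuation claim after
#'   index.
#' @param negative_control_rates Named vector of 45 per-person event
#'   probabilities for the negative-control outcome codes (uniform over the
#'   observation period, independent of arm by default).
#' @param nc_bias_logodds Shared systematic log-odds shift applied to
#'   negative-control event probabilities in the fluoroquinolone arm;
#'   default 0 (controls independent of treatment).
#' @param exclusion_condition_rates Per-code probability of each general /
#'   indication-specific exclusion condition over the observation period.
#' @param steroid_rate,chemo_rate Probabilities of steroid / chemotherapy
#'   dispensing histories.
#' @param insured_prob Probability the observation period carries
#'   short-term-disability insurance.
#' @param vocab Vocabulary used for code lists (defaults to the bundled
#'   dictionary).
#' @return An object of class `fqad_sim_config` (a validated list).
#' @export
sim_config <- function(n_persons = 20000,
                       seed = 1,
                       enrollment_start = as.Date("2007-01-01"),
                       enrollment_end = as.Date("2015-12-31"),
                       mean_enrollment_days = 730,
                       indication_rates = c(sinusitis = 0.20, bronchitis = 0.16,
                                            uti = 0.14),
                       confounder_spec = default_confounders(),
                       treatment_model = c(sinusitis = -0.21, bronchitis = -0.42,
                                           uti = 0.93),
                       dispense_prob = 0.85,
                       ae_model = list(theta = 0,
                                       case_base_logodds = -6.35,
                                       extra_soc_mean = 0.66,
                                       soc_weights = c(peripheral_nervous = 0.17,
                                                       neuropsychiatric = 0.15,
                                                       musculoskeletal = 0.16,
                                                       sensory = 0.27,
                                                       cardiovascular = 0.22,
                                                       skin = 0.03),
                                       background_soc_prob = 0.042,
                                       background_confirm_prob = 0.60,
                                       onset_geom_p = 0.08,
                                       confirm_geom_p = 0.055,
                                       prior_ae_rate = 0.004),
                       disability_model = list(base_logodds = -5.1,
                                               per_soc_logodds = 0.30,
                                               prior_claim_rate = 0.02,
                                               continuation_prob = 0.30),
                       negative_control_rates = NULL,
                       nc_bias_logodds = 0,
                       exclusion_condition_rates = 0.004,
                       steroid_rate = 0.02,
                       chemo_rate = 0.005,
                       insured_prob = 0.93,
                       vocab = load_vocabulary()) {
  if (is.null(negative_control_rates)) {
    negative_control_rates <- stats::setNames(
      rep(0.015, length(vocab$negative_controls)), vocab$negative_controls)
  }
  cfg <- list(n_persons = n_persons, seed = seed,
              enrollment_start = as.Date(enrollment_start),
              enrollment_end = as.Date(enrollment_end),
              mean_enrollment_days = mean_enrollment_days,
              indication_rates = indication_rates,
              confounder_spec = confounder_spec,
              treatment_model = treatment_model,
              dispense_prob = dispense_prob,
              ae_model = ae_model,
              disability_model = disability_model,
              negative_control_rates = negative_control_rates,
              nc_bias_logodds = nc_bias_logodds,
              exclusion_condition_rates = exclusion_condition_rates,
              steroid_rate = steroid_rate,
              chemo_rate = chemo_rate,
              insured_prob = insured_prob,
              vocab = vocab)
  validate_sim_config(cfg)
}

#' Default confounder specification
#'
#' Three baseline characteristics that shift both the treatment choice and
#' the composite-outcome risk, each surfaced as a pre-index diagnosis code so
#' the propensity model can recover it from claims.
#' @return A tibble with columns `name`, `code`, `prevalence`, `beta_treat`,
#'   `beta_outcome`.
#' @export
default_confounders <- function() {
  tibble::tribble(
    ~name,          ~code,              ~prevalence, ~beta_treat, ~beta_outcome,
    "dysuria",      "CONF_DYSURIA",      0.05,        1.3,         0.6,
    "hematuria",    "CONF_HEMATURIA",    0.02,        0.9,         0.4,
    "chronic_pain", "CONF_CHRONIC_PAIN", 0.10,       -0.6,         0.8
  )
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid simulation config [%s]: %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(cfg$n_persons) || length(cfg$n_persons) != 1 ||
      is.na(cfg$n_persons) || cfg$n_persons < 0 ||
      cfg$n_persons != floor(cfg$n_persons)) {
    fail("n_persons", "must be a single non-negative integer")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed)) {
    fail("seed", "must be a single integer")
  }
  if (is.na(cfg$enrollment_start) || is.na(cfg$enrollment_end) ||
      cfg$enrollment_start >= cfg$enrollment_end) {
    fail("enrollment window", "start must precede end")
  }
  if (!is.numeric(cfg$mean_enrollment_days) || cfg$mean_enrollment_days <= 0) {
    fail("mean_enrollment_days", "must be positive")
  }
  probs <- c(cfg$indication_rates, cfg$dispense_prob,
             cfg$negative_control_rates, cfg$exclusion_condition_rates,
             cfg$steroid_rate, cfg$chemo_rate, cfg$insured_prob,
             cfg$confounder_spec$prevalence,
             cfg$ae_model$background_soc_prob,
             cfg$ae_model$background_confirm_prob,
             cfg$ae_model$prior_ae_rate,
             cfg$disability_model$prior_claim_rate,
             cfg$disability_model$continuation_prob)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    fail("probabilities", "all probabilities must lie in [0, 1]")
  }
  if (!is.finite(cfg$ae_model$theta)) fail("ae_model$theta", "must be finite")
  if (length(cfg$negative_control_rates) !=
      length(cfg$vocab$negative_controls)) {
    fail("negative_control_rates",
         sprintf("must supply one rate per control code (%d)",
                 length(cfg$vocab$negative_controls)))
  }
  req_ind <- c("sinusitis", "bronchitis", "uti")
  if (!all(req_ind %in% names(cfg$indication_rates))) {
    fail("indication_rates", "must name sinusitis, bronchitis and uti")
  }
  class(cfg) <- "fqad_sim_config"
  cfg
}

# deterministic sub-stream seeds so each table is independently reproducible
subseed <- function(seed, k) {
  (abs(as.numeric(seed)) * 131 + k * 9973) %% 2147483647
}

rgeom_capped <- function(n, p, cap) pmin(stats::rgeom(n, p), cap)

# relative frequency of individual fluoroquinolones in the target arm
fq_drug_weights <- c(ciprofloxacin = 0.4747, levofloxacin = 0.4172,
                     moxifloxacin = 0.1013, gemifloxacin = 0.0066,
                     ofloxacin = 4e-04, norfloxacin = 1e-04,
                     gatifloxacin = 1e-04)

#' Generate a synthetic claims bundle
#'
#' Produces the five OMOP-lite claims tables (`person`,
#' `observation_period`, `drug_exposure`, `condition_occurrence`,
#' `disability_claim`) plus a ground-truth sidecar (`truth`). The sidecar
#' records confounder carriage, the anticipated exposure arm and whether the
#' person is a true composite-outcome case; it exists for testing only and
#' is never consumed by the analysis pipeline.
#'
#' The generative story: persons enroll for ~2 years; indication episodes
#' (sinusitis / bronchitis / UTI) arise at configured annual rates and are
#' treated within days with a fluoroquinolone or the indication-appropriate
#' comparator, with the arm choice confounded by baseline characteristics.
#' A small fraction of treated persons become true composite cases --
#' incident adverse events in two or more of the six SOC categories, each
#' confirmed by a repeat diagnosis 30--90 days after onset, plus an incident
#' short-term disability claim inside the 120-day time-at-risk window. The
#' exposure effect on this composite process is `exp(theta)` on the odds
#' scale. Arm-independent background AEs, disability claims, exclusion
#' conditions and negative-control events are layered on top.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `fqad_bundle`: a named list of tibbles
#'   (`person`, `observation_period`, `drug_exposure`,
#'   `condition_occurrence`, `disability_claim`, `truth`).
#' @examples
#' bundle <- simulate_claims(sim_config(n_persons = 500, seed = 42))
#' dplyr::count(bundle$condition_occurrence, setting)
#' @export
simulate_claims <- function(config) {
  stopifnot(inherits(config, "fqad_sim_config"))
  cfg <- config
  n <- cfg$n_persons
  vocab <- cfg$vocab

  if (n == 0) {
    return(empty_bundle(cfg))
  }

  ## --- persons and observation periods ----------------------------------
  set.seed(subseed(cfg$seed, 1))
  span_days <- as.integer(cfg$enrollment_end - cfg$enrollment_start)
  obs_start <- cfg$enrollment_start +
    sample.int(max(span_days - 365L, 1L), n, replace = TRUE) - 1L
  obs_len <- pmax(60L, as.integer(round(stats::rexp(n, 1 / cfg$mean_enrollment_days))))
  obs_end <- pmin(obs_start + obs_len, cfg$enrollment_end)
  age0 <- sample(19:63, n, replace = TRUE)
  person <- tibble::tibble(
    person_id = seq_len(n),
    birth_year = as.integer(format(obs_start, "%Y")) - age0,
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.55, 0.45))
  )
  observation_period <- tibble::tibble(
    person_id = seq_len(n),
    start_date = obs_start,
    end_date = obs_end,
    disability_insured = stats::runif(n) < cfg$insured_prob
  )

  ## --- confounders --------------------------------------------------------
  set.seed(subseed(cfg$seed, 2))
  conf <- cfg$confounder_spec
  conf_mat <- vapply(conf$prevalence,
                     function(p) as.integer(stats::runif(n) < p),
                     integer(n))
  if (is.null(dim(conf_mat))) conf_mat <- matrix(conf_mat, nrow = n)
  colnames(conf_mat) <- conf$name

  ## --- indication episodes and antibiotic dispensings ---------------------
  set.seed(subseed(cfg$seed, 3))
  obs_years <- as.numeric(obs_end - obs_start) / 365
  episodes <- purrr::map_dfr(names(cfg$indication_rates), function(ind) {
    p_ep <- 1 - exp(-cfg$indication_rates[[ind]] * obs_years)
    has <- stats::runif(n) < p_ep
    idx <- which(has)
    if (length(idx) == 0) return(NULL)
    # leave room for the 183-day lookback / 120-day follow-up most of the time
    len <- as.integer(obs_end[idx] - obs_start[idx])
    offset <- as.integer(floor(stats::runif(length(idx)) * pmax(len, 1L)))
    tibble::tibble(person_id = idx, indication = ind,
                   ind_date = obs_start[idx] + offset)
  })

  drug_exposure <- tibble::tibble(person_id = integer(), drug_code = character(),
                                  dispense_date = as.Date(character()),
                                  days_supplied = integer())
  condition_occurrence <- tibble::tibble(person_id = integer(),
                                         condition_code = character(),
                                         event_date = as.Date(character()),
                                         setting = character())
  anticipated <- tibble::tibble(person_id = integer(), arm = character(),
                                index_date = as.Date(character()))

  if (nrow(episodes) > 0) {
    episodes <- dplyr::arrange(episodes, .data$person_id, .data$ind_date)
    m <- nrow(episodes)
    # outpatient indication diagnoses
    ind_codes <- vapply(episodes$indication, function(ind) {
      codes <- vocab$indications[[ind]]
      codes[sample.int(length(codes), 1)]
    }, character(1))
    condition_occurrence <- dplyr::bind_rows(
      condition_occurrence,
      tibble::tibble(person_id = episodes$person_id, condition_code = ind_codes,
                     event_date = episodes$ind_date, setting = "outpatient"))

    treated <- stats::runif(m) < cfg$dispense_prob
    lp <- cfg$treatment_model[episodes$indication] +
      as.vector(conf_mat[episodes$person_id, , drop = FALSE] %*% conf$beta_treat)
    is_fq <- stats::runif(m) < stats::plogis(lp)
    drug <- ifelse(is_fq,
                   sample(names(fq_drug_weights), m, replace = TRUE,
                          prob = fq_drug_weights),
                   ifelse(episodes$indication == "uti",
                          vocab$exposures$st[1], vocab$exposures$az[1]))
    delay <- sample(0:7, m, replace = TRUE)
    disp <- tibble::tibble(person_id = episodes$person_id,
                           drug_code = drug,
                           dispense_date = episodes$ind_date + delay,
                           days_supplied = sample(5:14, m, replace = TRUE),
                           arm = ifelse(is_fq, "fq", "azst"))[treated, ]
    disp <- dplyr::filter(disp,
                          .data$dispense_date <= obs_end[.data$person_id])
    drug_exposure <- dplyr::bind_rows(
      drug_exposure, dplyr::select(disp, -"arm"))
    anticipated <- disp |>
      dplyr::arrange(.data$person_id, .data$dispense_date, .data$drug_code) |>
      dplyr::distinct(.data$person_id, .keep_all = TRUE) |>
      dplyr::transmute(person_id = .data$person_id, arm = .data$arm,
                       index_date = .data$dispense_date)
  }

  ## --- composite-outcome cases --------------------------------------------
  set.seed(subseed(cfg$seed, 4))
  am <- cfg$ae_model
  dm <- cfg$disability_model
  is_case <- rep(FALSE, n)
  case_rows <- NULL
  if (nrow(anticipated) > 0) {
    lp_case <- am$case_base_logodds +
      am$theta * (anticipated$arm == "fq") +
      as.vector(conf_mat[anticipated$person_id, , drop = FALSE] %*%
                  conf$beta_outcome)
    case <- stats::runif(nrow(anticipated)) < stats::plogis(lp_case)
    case_rows <- anticipated[case, ]
    is_case[case_rows$person_id] <- TRUE
  }

  ae_events <- NULL
  disability_claim <- tibble::tibble(person_id = integer(), claim_id = integer(),
                                     claim_start = as.Date(character()),
                                     claim_end = as.Date(character()),
                                     continuation_of = integer())

  socs <- unique(vocab$soc_map$soc)
  if (!is.null(case_rows) && nrow(case_rows) > 0) {
    nc_cases <- nrow(case_rows)
    k_soc <- 2L + pmin(stats::rpois(nc_cases, am$extra_soc_mean), 4L)
    per_case <- purrr::map_dfr(seq_len(nc_cases), function(i) {
      chosen <- sample(socs, k_soc[i], prob = am$soc_weights[socs])
      tibble::tibble(person_id = case_rows$person_id[i],
                     index_date = case_rows$index_date[i], soc = chosen)
    })
    kk <- nrow(per_case)
    code <- vapply(per_case$soc, function(s) {
      codes <- vocab$soc_map$condition_code[vocab$soc_map$soc == s]
      codes[sample.int(length(codes), 1)]
    }, character(1))
    onset <- 1L + rgeom_capped(kk, am$onset_geom_p, 29L)
    confirm_delay <- 30L + rgeom_capped(kk, am$confirm_geom_p, 60L)
    ae_events <- tibble::tibble(
      person_id = rep(per_case$person_id, 2),
      condition_code = rep(code, 2),
      event_date = c(per_case$index_date + onset,
                     per_case$index_date + onset + confirm_delay),
      setting = "outpatient")
    # incident disability claim inside the 120-day time-at-risk window
    dis_start <- case_rows$index_date +
      sample(30:120, nrow(case_rows), replace = TRUE)
    disability_claim <- dplyr::bind_rows(
      disability_claim,
      tibble::tibble(person_id = case_rows$person_id,
                     claim_id = NA_integer_,
                     claim_start = dis_start,
                     claim_end = dis_start + sample(30:120, nrow(case_rows),
                                                    replace = TRUE),
                     continuation_of = NA_integer_))
  }

  ## --- background AEs (arm-independent) -----------------------------------
  set.seed(subseed(cfg$seed, 5))
  n_conf_bg <- rep(0L, n)
  if (nrow(anticipated) > 0) {
    bg <- tidyr::expand_grid(i = seq_len(nrow(anticipated)), soc = socs)
    bg <- bg[stats::runif(nrow(bg)) < am$background_soc_prob, ]
    if (nrow(bg) > 0) {
      bg$person_id <- anticipated$person_id[bg$i]
      bg$index_date <- anticipated$index_date[bg$i]
      code <- vapply(bg$soc, function(s) {
        codes <- vocab$soc_map$condition_code[vocab$soc_map$soc == s]
        codes[sample.int(length(codes), 1)]
      }, character(1))
      onset <- 1L + rgeom_capped(nrow(bg), am$onset_geom_p, 29L)
      confirmed <- stats::runif(nrow(bg)) < am$background_confirm_prob
      confirm_delay <- 30L + rgeom_capped(nrow(bg), am$confirm_geom_p, 60L)
      bg_onset <- tibble::tibble(person_id = bg$person_id,
                                 condition_code = code,
                                 event_date = bg$index_date + onset,
                                 setting = "outpatient")
      bg_conf <- tibble::tibble(person_id = bg$person_id[confirmed],
                                condition_code = code[confirmed],
                                event_date = bg$index_date[confirmed] +
                                  onset[confirmed] + confirm_delay[confirmed],
                                setting = "outpatient")
      ae_events <- dplyr::bind_rows(ae_events, bg_onset, bg_conf)
      tab <- table(factor(bg$person_id[confirmed], levels = seq_len(n)))
      n_conf_bg <- as.integer(tab)
    }
    # background incident disability, risk increasing with confirmed SOC AEs
    ppl <- anticipated$person_id
    p_dis <- stats::plogis(dm$base_logodds + dm$per_soc_logodds * n_conf_bg[ppl])
    gets <- stats::runif(length(ppl)) < p_dis
    if (any(gets)) {
      ds <- anticipated$index_date[gets] + sample(1:120, sum(gets), replace = TRUE)
      disability_claim <- dplyr::bind_rows(
        disability_claim,
        tibble::tibble(person_id = ppl[gets], claim_id = NA_integer_,
                       claim_start = ds,
                       claim_end = ds + sample(20:90, sum(gets), replace = TRUE),
                       continuation_of = NA_integer_))
    }
  }

  # stray historical AE-code occurrences (violate the clean window)
  ae_codes <- vocab$soc_map$condition_code
  prior_ae <- tidyr::expand_grid(person_id = seq_len(n), condition_code = ae_codes)
  prior_ae <- prior_ae[stats::runif(nrow(prior_ae)) < am$prior_ae_rate, ]
  if (nrow(prior_ae) > 0) {
    len <- as.integer(obs_end[prior_ae$person_id] - obs_start[prior_ae$person_id])
    prior_ae$event_date <- obs_start[prior_ae$person_id] +
      as.integer(floor(stats::runif(nrow(prior_ae)) * pmax(len, 1L)))
    prior_ae$setting <- "outpatient"
    prior_ae <- dplyr::select(prior_ae, "person_id", "condition_code",
                              "event_date", "setting")
    ae_events <- dplyr::bind_rows(ae_events, prior_ae)
  }
  if (!is.null(ae_events)) {
    ae_events <- dplyr::filter(ae_events,
                               .data$event_date >= obs_start[.data$person_id],
                               .data$event_date <= obs_end[.data$person_id])
    condition_occurrence <- dplyr::bind_rows(condition_occurrence, ae_events)
  }

  ## --- confounder codes in the pre-index history ---------------------------
  set.seed(subseed(cfg$seed, 6))
  for (j in seq_len(nrow(conf))) {
    carriers <- which(conf_mat[, j] == 1L)
    if (length(carriers) == 0) next
    anchor <- obs_start[carriers] + 200L
    hit <- match(carriers, anticipated$person_id)
    anchor[!is.na(hit)] <- anticipated$index_date[hit[!is.na(hit)]]
    ev <- anchor - sample(10:170, length(carriers), replace = TRUE)
    keep <- ev >= obs_start[carriers] & ev <= obs_end[carriers]
    condition_occurrence <- dplyr::bind_rows(
      condition_occurrence,
      tibble::tibble(person_id = carriers[keep], condition_code = conf$code[j],
                     event_date = ev[keep], setting = "outpatient"))
  }

  ## --- exclusion conditions, steroids, chemotherapy ------------------------
  set.seed(subseed(cfg$seed, 7))
  excl_codes <- c(vocab$exclusions$general_conditions,
                  unique(unlist(purrr::map(vocab$exclusions$condition_specific,
                                           "any_setting"))))
  excl <- tidyr::expand_grid(person_id = seq_len(n), condition_code = excl_codes)
  excl <- excl[stats::runif(nrow(excl)) < cfg$exclusion_condition_rates, ]
  if (nrow(excl) > 0) {
    len <- as.integer(obs_end[excl$person_id] - obs_start[excl$person_id])
    excl$event_date <- obs_start[excl$person_id] +
      as.integer(floor(stats::runif(nrow(excl)) * pmax(len, 1L)))
    excl$setting <- sample(c("outpatient", "inpatient"), nrow(excl),
                           replace = TRUE, prob = c(0.8, 0.2))
    condition_occurrence <- dplyr::bind_rows(condition_occurrence, excl)
  }
  # occasional inpatient indication-code events (hospitalization exclusions)
  hosp <- which(stats::runif(n) < 0.002)
  if (length(hosp) > 0) {
    len <- as.integer(obs_end[hosp] - obs_start[hosp])
    condition_occurrence <- dplyr::bind_rows(
      condition_occurrence,
      tibble::tibble(person_id = hosp,
                     condition_code = sample(c("466.0", "461.0", "599.0"),
                                             length(hosp), replace = TRUE),
                     event_date = obs_start[hosp] +
                       as.integer(floor(stats::runif(length(hosp)) * pmax(len, 1L))),
                     setting = "inpatient"))
  }
  ster <- which(stats::runif(n) < cfg$steroid_rate)
  chemo <- which(stats::runif(n) < cfg$chemo_rate)
  extra_drugs <- NULL
  if (length(ster) > 0) {
    len <- as.integer(obs_end[ster] - obs_start[ster])
    extra_drugs <- tibble::tibble(
      person_id = ster,
      drug_code = vocab$exclusions$steroid_drugs[1],
      dispense_date = obs_start[ster] +
        as.integer(floor(stats::runif(length(ster)) * pmax(len, 1L))),
      days_supplied = sample(c(10L, 20L, 30L, 60L), length(ster),
                             replace = TRUE))
  }
  if (length(chemo) > 0) {
    len <- as.integer(obs_end[chemo] - obs_start[chemo])
    extra_drugs <- dplyr::bind_rows(extra_drugs, tibble::tibble(
      person_id = chemo,
      drug_code = vocab$exclusions$chemotherapy_drugs[1],
      dispense_date = obs_start[chemo] +
        as.integer(floor(stats::runif(length(chemo)) * pmax(len, 1L))),
      days_supplied = sample(5:30, length(chemo), replace = TRUE)))
  }
  # arm-independent non-study medication history (propensity-model noise)
  other <- tidyr::expand_grid(person_id = seq_len(n),
                              drug_code = c("amoxicillin_clavulanate",
                                            "nitrofurantoin",
                                            "phenazopyridine"))
  other <- other[stats::runif(nrow(other)) < 0.07, ]
  if (nrow(other) > 0) {
    len <- as.integer(obs_end[other$person_id] - obs_start[other$person_id])
    other$dispense_date <- obs_start[other$person_id] +
      as.integer(floor(stats::runif(nrow(other)) * pmax(len, 1L)))
    other$days_supplied <- sample(5:30, nrow(other), replace = TRUE)
    extra_drugs <- dplyr::bind_rows(extra_drugs, other)
  }
  if (!is.null(extra_drugs)) {
    drug_exposure <- dplyr::bind_rows(drug_exposure, extra_drugs)
  }

  ## --- historical disability claims + continuations ------------------------
  set.seed(subseed(cfg$seed, 8))
  prior <- which(stats::runif(n) < dm$prior_claim_rate)
  if (length(prior) > 0) {
    len <- as.integer(obs_end[prior] - obs_start[prior])
    ps <- obs_start[prior] +
      as.integer(floor(stats::runif(length(prior)) * pmax(len, 1L)))
    pe <- ps + sample(30:90, length(prior), replace = TRUE)
    prior_claims <- tibble::tibble(person_id = prior, claim_id = NA_integer_,
                                   claim_start = ps, claim_end = pe,
                                   continuation_of = NA_integer_)
    cont <- stats::runif(length(prior)) < dm$continuation_prob
    disability_claim <- dplyr::bind_rows(disability_claim, prior_claims)
    if (any(cont)) {
      cs <- pe[cont] + sample(1:14, sum(cont), replace = TRUE)
      disability_claim <- dplyr::bind_rows(
        disability_claim,
        tibble::tibble(person_id = prior[cont],
                       claim_id = NA_integer_,
                       claim_start = cs,
                       claim_end = cs + sample(20:60, sum(cont), replace = TRUE),
                       # resolved to real ids after claim ids are assigned
                       continuation_of = -seq_len(sum(cont))))
    }
  }
  # assign claim ids and resolve continuation references
  if (nrow(disability_claim) > 0) {
    disability_claim <- dplyr::arrange(disability_claim, .data$person_id,
                                       .data$claim_start)
    disability_claim$claim_id <- seq_len(nrow(disability_claim))
    pending <- which(!is.na(disability_claim$continuation_of) &
                       disability_claim$continuation_of < 0)
    for (i in pending) {
      pid <- disability_claim$person_id[i]
      prior_i <- which(disability_claim$person_id == pid &
                         disability_claim$claim_start <
                           disability_claim$claim_start[i])
      disability_claim$continuation_of[i] <-
        if (length(prior_i) > 0) disability_claim$claim_id[max(prior_i)] else NA_integer_
    }
  }

  truth <- tibble::tibble(person_id = seq_len(n)) |>
    dplyr::bind_cols(tibble::as_tibble(conf_mat)) |>
    dplyr::left_join(anticipated, by = "person_id") |>
    dplyr::mutate(is_true_case = is_case, theta = am$theta)

  bundle <- new_bundle(person, observation_period, drug_exposure,
                       condition_occurrence, disability_claim, truth)
  inject_negative_controls(bundle, cfg$negative_control_rates,
                           bias_logodds = cfg$nc_bias_logodds,
                           seed = subseed(cfg$seed, 9), vocab = vocab)
}

#' Add negative-control outcome events to a claims bundle
#'
#' Sprinkles occurrences of the negative-control condition codes uniformly
#' over each person's observation period. By default the event probability
#' is identical in both (future) exposure arms; a nonzero `bias_logodds`
#' shifts the fluoroquinolone-arm probability on the log-odds scale, which
#' emulates shared systematic error and is what empirical calibration is
#' designed to absorb.
#'
#' @param bundle A claims bundle.
#' @param rates Named per-person event probabilities, one per control code.
#' @param bias_logodds Log-odds shift applied in the fluoroquinolone arm
#'   (uses the truth sidecar's anticipated arm; 0 = fully independent).
#' @param seed Integer seed for this injection step.
#' @param vocab Vocabulary used to detect code collisions.
#' @return The bundle with control events appended to
#'   `condition_occurrence`.
#' @export
inject_negative_controls <- function(bundle, rates, bias_logodds = 0,
                                     seed = 1, vocab = load_vocabulary()) {
  stopifnot(inherits(bundle, "fqad_bundle"))
  codes <- names(rates)
  if (is.null(codes)) stop("negative-control rates must be named by code",
                           call. = FALSE)
  # collisions with AE/indication codes are configuration errors
  reserved <- c(vocab$soc_map$condition_code,
                unlist(vocab$indications, use.names = FALSE))
  collision <- intersect(codes, reserved)
  if (length(collision) > 0) {
    stop("negative-control code(s) collide with adverse-event/indication ",
         "codes: ", paste(collision, collapse = ", "), call. = FALSE)
  }
  if (all(rates == 0) || nrow(bundle$person) == 0) return(bundle)

  set.seed(seed)
  obs <- bundle$observation_period
  n <- nrow(obs)
  fq_arm <- rep(FALSE, n)
  if (!is.null(bundle$truth) && "arm" %in% names(bundle$truth)) {
    fq_arm[match(bundle$truth$person_id[!is.na(bundle$truth$arm) &
                                          bundle$truth$arm == "fq"],
                 obs$person_id)] <- TRUE
  }
  events <- purrr::map_dfr(codes, function(code) {
    p <- rep(rates[[code]], n)
    if (bias_logodds != 0) {
      p[fq_arm] <- stats::plogis(stats::qlogis(pmin(pmax(p[fq_arm], 1e-12),
                                                    1 - 1e-12)) + bias_logodds)
    }
    hit <- which(stats::runif(n) < p)
    if (length(hit) == 0) return(NULL)
    len <- as.integer(obs$end_date[hit] - obs$start_date[hit])
    tibble::tibble(person_id = obs$person_id[hit], condition_code = code,
                   event_date = obs$start_date[hit] +
                     as.integer(floor(stats::runif(length(hit)) * pmax(len, 1L))),
                   setting = "outpatient")
  })
  bundle$condition_occurrence <-
    dplyr::bind_rows(bundle$condition_occurrence, events) |>
    dplyr::arrange(.data$person_id, .data$event_date, .data$condition_code)
  bundle
}

#' @keywords internal
new_bundle <- function(person, observation_period, drug_exposure,
                       condition_occurrence, disability_claim, truth = NULL) {
  bundle <- list(person = person,
                 observation_period = observation_period,
                 drug_exposure = dplyr::arrange(drug_exposure, .data$person_id,
                                                .data$dispense_date,
                                                .data$drug_code),
                 condition_occurrence = dplyr::arrange(condition_occurrence,
                                                       .data$person_id,
                                                       .data$event_date,
                                                       .data$condition_code),
                 disability_claim = disability_claim,
                 truth = truth)
  class(bundle) <- "fqad_bundle"
  bundle
}

#' @keywords internal
empty_bundle <- function(cfg) {
  new_bundle(
    person = tibble::tibble(person_id = integer(), birth_year = integer(),
                            sex = character()),
    observation_period = tibble::tibble(person_id = integer(),
                                        start_date = as.Date(character()),
                                        end_date = as.Date(character()),
                                        disability_insured = logical()),
    drug_exposure = tibble::tibble(person_id = integer(),
                                   drug_code = character(),
                                   dispense_date = as.Date(character()),
                                   days_supplied = integer()),
    condition_occurrence = tibble::tibble(person_id = integer(),
                                          condition_code = character(),
                                          event_date = as.Date(character()),
                                          setting = character()),
    disability_claim = tibble::tibble(person_id = integer(),
                                      claim_id = integer(),
                                      claim_start = as.Date(character()),
                                      claim_end = as.Date(character()),
                                      continuation_of = integer()),
    truth = tibble::tibble(person_id = integer(), arm = character(),
                           index_date = as.Date(character()),
                           is_true_case = logical(), theta = double())
  )
}

#' @export
print.fqad_bundle <- function(x, ...) {
  cat("<fqad_bundle>\n")
  for (nm in c("person", "observation_period", "drug_exposure",
               "condition_occurrence", "disability_claim")) {
    cat(sprintf("  %-22s %8d rows\n", nm, nrow(x[[nm]])))
  }
  if (!is.null(x$truth)) cat("  (ground-truth sidecar attached)\n")
  invisible(x)
}

bundle_cols <- list(
  person = c("person_id", "birth_year", "sex"),
  observation_period = c("person_id", "start_date", "end_date",
                         "disability_insured"),
  drug_exposure = c("person_id", "drug_code", "dispense_date",
                    "days_supplied"),
  condition_occurrence = c("person_id", "condition_code", "event_date",
                           "setting"),
  disability_claim = c("person_id", "claim_id", "claim_start", "claim_end",
                       "continuation_of")
)

#' Write a claims bundle to CSV files
#'
#' Writes `person.csv`, `observation_period.csv`, `drug_exposure.csv`,
#' `condition_occurrence.csv` and `disability_claim.csv` (fixed column
#' order, ISO-8601 dates), plus a `truth.csv` sidecar when ground truth is
#' attached. The sidecar is for tests only: the analysis pipeline never
#' reads it.
#'
#' @param bundle A claims bundle.
#' @param dir Output directory (created if absent).
#' @param truth Write the ground-truth sidecar too?
#' @return `dir`, invisibly.
#' @export
write_claims_bundle <- function(bundle, dir, truth = TRUE) {
  stopifnot(inherits(bundle, "fqad_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(bundle_cols)) {
    readr::write_csv(bundle[[nm]][, bundle_cols[[nm]]],
                     file.path(dir, paste0(nm, ".csv")), na = "")
  }
  if (truth && !is.null(bundle$truth)) {
    readr::write_csv(bundle$truth, file.path(dir, "truth.csv"), na = "")
  }
  invisible(dir)
}

#' Read a claims bundle from CSV files
#'
#' @param dir Directory containing the five claims CSV files written by
#'   [write_claims_bundle()].
#' @return An `fqad_bundle`.
#' @export
read_claims_bundle <- function(dir) {
  specs <- list(
    person = readr::cols(person_id = readr::col_integer(),
                         birth_year = readr::col_integer(),
                         sex = readr::col_character()),
    observation_period = readr::cols(person_id = readr::col_integer(),
                                     start_date = readr::col_date(),
                                     end_date = readr::col_date(),
                                     disability_insured = readr::col_logical()),
    drug_exposure = readr::cols(person_id = readr::col_integer(),
                                drug_code = readr::col_character(),
                                dispense_date = readr::col_date(),
                                days_supplied = readr::col_integer()),
    condition_occurrence = readr::cols(person_id = readr::col_integer(),
                                       condition_code = readr::col_character(),
                                       event_date = readr::col_date(),
                                       setting = readr::col_character()),
    disability_claim = readr::cols(person_id = readr::col_integer(),
                                   claim_id = readr::col_integer(),
                                   claim_start = readr::col_date(),
                                   claim_end = readr::col_date(),
                                   continuation_of = readr::col_integer())
  )
  tabs <- purrr::imap(specs, function(spec, nm) {
    readr::read_csv(file.path(dir, paste0(nm, ".csv")), col_types = spec,
                    progress = FALSE)
  })
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) {
    readr::read_csv(truth_path, show_col_types = FALSE, progress = FALSE)
  } else NULL
  new_bundle(tabs$person, tabs$observation_period, tabs$drug_exposure,
             tabs$condition_occurrence, tabs$disability_claim, truth)
}
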