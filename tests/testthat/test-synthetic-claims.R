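test_that("n_persons = 0 yields five empty, schema-conforming tables", {
  b <- simulate_claims(sim_config(n_persons = 0, seed = 1))
  for (nm in names(fqad:::bundle_cols)) {
    expect_equal(nrow(b[[nm]]), 0)
    expect_true(all(fqad:::bundle_cols[[nm]] %in% names(b[[nm]])))
  }
})

test_that("the same config and seed reproduce every table exactly", {
  cfg <- sim_config(n_persons = 800, seed = 99)
  b1 <- simulate_claims(cfg)
  b2 <- simulate_claims(cfg)
  for (nm in c(names(fqad:::bundle_cols), "truth")) {
    expect_identical(b1[[nm]], b2[[nm]])
  }
  b3 <- simulate_claims(sim_config(n_persons = 800, seed = 100))
  expect_false(identical(b1$drug_exposure, b3$drug_exposure))
})

test_that("invalid configurations are rejected with named errors", {
  expect_error(sim_config(n_persons = -5), "n_persons")
  expect_error(sim_config(insured_prob = 1.4), "probabilities")
  expect_error(sim_config(enrollment_start = "2016-01-01",
                          enrollment_end = "2015-01-01"),
               "enrollment window")
  expect_error(sim_config(ae_model = utils::modifyList(
    sim_config()$ae_model, list(theta = Inf))), "theta")
  expect_error(sim_config(indication_rates = c(sinusitis = 0.1)),
               "indication_rates")
})

test_that("generated records respect structural invariants", {
  b <- simulate_claims(sim_config(n_persons = 2000, seed = 5))
  obs <- b$observation_period
  expect_true(all(obs$start_date <= obs$end_date))
  # events fall inside the person's observation period
  co <- dplyr::inner_join(b$condition_occurrence, obs, by = "person_id")
  expect_true(all(co$event_date >= co$start_date &
                    co$event_date <= co$end_date))
  rx <- dplyr::inner_join(b$drug_exposure, obs, by = "person_id")
  expect_true(all(rx$dispense_date >= rx$start_date &
                    rx$dispense_date <= rx$end_date))
  expect_true(all(b$drug_exposure$days_supplied >= 1))
  expect_true(all(b$disability_claim$claim_start <=
                    b$disability_claim$claim_end))
  # index ages within the working-age sampling frame
  idx <- dplyr::filter(b$truth, !is.na(.data$arm)) |>
    dplyr::inner_join(b$person, by = "person_id") |>
    dplyr::mutate(age = as.integer(format(.data$index_date, "%Y")) -
                    .data$birth_year)
  expect_true(all(idx$age >= 18 & idx$age <= 65))
})

test_that("CSV round trip reproduces the bundle exactly", {
  b <- simulate_claims(sim_config(n_persons = 300, seed = 21))
  dir <- withr::local_tempdir()
  write_claims_bundle(b, dir)
  b2 <- read_claims_bundle(dir)
  for (nm in names(fqad:::bundle_cols)) {
    expect_equal(as.data.frame(b[[nm]][, fqad:::bundle_cols[[nm]]]),
                 as.data.frame(b2[[nm]]))
  }
  # the empty bundle round-trips too
  dir0 <- withr::local_tempdir()
  write_claims_bundle(simulate_claims(sim_config(n_persons = 0, seed = 1)),
                      dir0)
  b0 <- read_claims_bundle(dir0)
  expect_equal(nrow(b0$person), 0)
})

test_that("marginal event frequencies match configured rates", {
  n <- 100000
  cfg <- sim_config(n_persons = n, seed = 17)
  b <- simulate_claims(cfg)
  # confounder prevalences within 3 binomial SDs
  for (j in seq_len(nrow(cfg$confounder_spec))) {
    p <- cfg$confounder_spec$prevalence[j]
    obs <- mean(b$truth[[cfg$confounder_spec$name[j]]])
    expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
  }
  # negative-control incidence within 3 binomial SDs of its rate
  r <- cfg$negative_control_rates[["NC_01"]]
  obs <- sum(b$condition_occurrence$condition_code == "NC_01") / n
  expect_lt(abs(obs - r), 3 * sqrt(r * (1 - r) / n))
  # insurance flag rate
  p <- cfg$insured_prob
  obs <- mean(b$observation_period$disability_insured)
  expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("negative-control injection is rate-faithful and collision-safe", {
  cfg <- sim_config(n_persons = 500, seed = 3)
  b <- simulate_claims(cfg)
  # all-zero rates leave the bundle unchanged
  rates0 <- stats::setNames(rep(0, 45), cfg$vocab$negative_controls)
  b0 <- inject_negative_controls(b, rates0, seed = 11)
  expect_identical(b0$condition_occurrence, b$condition_occurrence)
  # colliding code names are rejected
  expect_error(
    inject_negative_controls(b, c(AE_SKN_01 = 0.01), seed = 1),
    "collide")
  # a shared bias term raises the fluoroquinolone-arm control rate
  cfg_b <- sim_config(n_persons = 40000, seed = 13,
                      nc_bias_logodds = log(3))
  bb <- simulate_claims(cfg_b)
  arm_of <- dplyr::select(bb$truth, "person_id", "arm")
  counts <- bb$condition_occurrence |>
    dplyr::filter(.data$condition_code == "NC_05") |>
    dplyr::inner_join(arm_of, by = "person_id") |>
    dplyr::filter(!is.na(.data$arm)) |>
    dplyr::count(.data$arm)
  n_fq <- sum(!is.na(bb$truth$arm) & bb$truth$arm == "fq")
  n_az <- sum(!is.na(bb$truth$arm) & bb$truth$arm == "azst")
  rate_fq <- sum(counts$n[counts$arm == "fq"]) / n_fq
  rate_az <- sum(counts$n[counts$arm == "azst"]) / n_az
  expect_gt(rate_fq, 1.5 * rate_az)
})
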