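# a one-person cohort entry anchored at day 15
entry1 <- function() {
  tibble::tibble(person_id = 1L, arm = "fq", index_date = day(15),
                 indication = "bronchitis", drug_code = "levofloxacin",
                 age_at_index = 40L, sex = "F")
}

test_that("incident AEs need onset in days 1-30 and a clean lookback", {
  idx <- 15
  base <- dplyr::bind_rows(dx(1, "466.0", 10))
  # same code 100 days before index: not incident
  b <- mini_bundle(conds = dplyr::bind_rows(base,
                                            dx(1, "AE_CVD_01", idx - 100),
                                            dx(1, "AE_CVD_01", idx + 10)))
  expect_equal(nrow(find_incident_aes(entry1(), b, test_vocab)), 0)
  # first seen day 31: outside the incidence window
  b2 <- mini_bundle(conds = dplyr::bind_rows(base,
                                             dx(1, "AE_CVD_01", idx + 31)))
  expect_equal(nrow(find_incident_aes(entry1(), b2, test_vocab)), 0)
  # first seen day 5, never before: incident with days_from_index = 5
  b3 <- mini_bundle(conds = dplyr::bind_rows(base,
                                             dx(1, "AE_CVD_01", idx + 5)))
  got <- find_incident_aes(entry1(), b3, test_vocab)
  expect_equal(got$days_from_index, 5L)
  expect_equal(got$soc, "cardiovascular")
  # an occurrence on the index day itself blocks incidence
  b4 <- mini_bundle(conds = dplyr::bind_rows(base, dx(1, "AE_CVD_01", idx),
                                             dx(1, "AE_CVD_01", idx + 5)))
  expect_equal(nrow(find_incident_aes(entry1(), b4, test_vocab)), 0)
})

test_that("confirmation windows are inclusive and variant-dependent", {
  idx <- 15
  make <- function(rep_offset) {
    mini_bundle(conds = dplyr::bind_rows(
      dx(1, "466.0", 10), dx(1, "AE_CVD_01", idx + 5),
      dx(1, "AE_CVD_01", idx + 5 + rep_offset)))
  }
  inc <- function(b) find_incident_aes(entry1(), b, test_vocab)
  # repeat at onset + 42: confirmed with days_to_confirmation = 42
  got <- confirm_aes(inc(make(42)), make(42), c(30L, 90L))
  expect_equal(got$days_to_confirmation, 42L)
  # repeat at onset + 29: not confirmed (window starts at 30)
  expect_equal(nrow(confirm_aes(inc(make(29)), make(29), c(30L, 90L))), 0)
  # repeat at onset + 75: confirmed in primary, not in sensitivity
  expect_equal(nrow(confirm_aes(inc(make(75)), make(75), c(30L, 90L))), 1)
  expect_equal(nrow(confirm_aes(inc(make(75)), make(75), c(30L, 60L))), 0)
  # boundary: exactly 90 confirms in primary
  expect_equal(nrow(confirm_aes(inc(make(90)), make(90), c(30L, 90L))), 1)
})

test_that("incident disability respects continuations, lookback and TAR", {
  idx <- 15
  base <- dplyr::bind_rows(dx(1, "466.0", 10))
  dis <- function(claims, tar = 120L) {
    b <- mini_bundle(conds = base, claims = claims)
    find_incident_disability(entry1(), b, tar)
  }
  # claim starting day 60 post-index, no history: qualifies
  got <- dis(claim(1, idx + 60, idx + 90))
  expect_true(got$disability)
  expect_equal(got$disability_start, day(idx + 60))
  # continuation of a pre-index claim: does not qualify, and the earlier
  # claim also blocks via the lookback
  got2 <- dis(dplyr::bind_rows(
    claim(1, idx - 20, idx - 5, claim_id = 1L),
    claim(1, idx + 60, idx + 90, claim_id = 2L, continuation_of = 1L)))
  expect_false(got2$disability)
  # claim starting at day 121 exceeds the primary TAR
  expect_false(dis(claim(1, idx + 121, idx + 150))$disability)
  expect_true(dis(claim(1, idx + 120, idx + 150))$disability)
})

test_that("the composite outcome needs two collapsed SOCs plus disability", {
  idx <- 15
  conf <- function(codes) {
    conds <- dplyr::bind_rows(
      dx(1, "466.0", 10),
      purrr::map_dfr(codes, \(cc) dplyr::bind_rows(
        dx(1, cc, idx + 5), dx(1, cc, idx + 5 + 40))))
    conds
  }
  run <- function(codes, claims = NULL) {
    b <- mini_bundle(conds = conf(codes), claims = claims)
    phenotype_outcomes(entry1(), b, test_vocab, "primary")$outcomes
  }
  # cardiovascular + skin, disability day 80: outcome
  got <- run(c("AE_CVD_01", "AE_SKN_01"), claim(1, idx + 80, idx + 100))
  expect_true(got$outcome)
  expect_equal(got$n_confirmed_socs, 2L)
  # ear + eye codes both collapse to sensory: only 1 SOC, no outcome
  got2 <- run(c("AE_EAR_01", "AE_EYE_01"), claim(1, idx + 80, idx + 100))
  expect_equal(got2$n_confirmed_socs, 1L)
  expect_false(got2$outcome)
  expect_true(got2$disability)
  # three confirmed SOCs but no disability claim: no outcome
  got3 <- run(c("AE_CVD_01", "AE_SKN_01", "AE_MSK_01"))
  expect_equal(got3$n_confirmed_socs, 3L)
  expect_false(got3$outcome)
})

test_that("phenotyping matches a per-person brute-force scan", {
  b <- simulate_claims(sim_config(n_persons = 700, seed = 47))
  ch <- build_cohort(b, test_vocab)
  for (variant in c("primary", "sensitivity")) {
    got <- phenotype_outcomes(ch, b, test_vocab, variant)$outcomes
    want <- oracle_outcomes(ch$cohort, b, test_vocab, variant)
    cols <- c("n_confirmed_socs", "disability", "outcome")
    expect_equal(as.data.frame(got[, c("person_id", cols)]),
                 as.data.frame(want[, c("person_id", cols)]))
    cases <- want$outcome
    expect_equal(got$days_to_ae_onset[cases], want$days_to_ae_onset[cases])
    expect_equal(got$days_to_confirmation[cases],
                 want$days_to_confirmation[cases])
  }
})

test_that("sensitivity-analysis outcomes are a subset of primary outcomes", {
  b <- simulate_claims(sim_config(n_persons = 3000, seed = 53))
  ch <- build_cohort(b, test_vocab)
  prim <- phenotype_outcomes(ch, b, test_vocab, "primary")$outcomes
  sens <- phenotype_outcomes(ch, b, test_vocab, "sensitivity")$outcomes
  expect_true(all(prim$person_id == sens$person_id))
  expect_true(all(prim$outcome[sens$outcome]))
  expect_true(all(sens$n_confirmed_socs <= prim$n_confirmed_socs))
  # count structure: each composite column no larger than its parent
  n1 <- sum(prim$n_confirmed_socs >= 1)
  n1d <- sum(prim$n_confirmed_socs >= 1 & prim$disability)
  n2 <- sum(prim$n_confirmed_socs >= 2)
  n2d <- sum(prim$outcome)
  expect_true(n1d <= n1 && n2 <= n1 && n2d <= n2 && n2d <= n1d)
})
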