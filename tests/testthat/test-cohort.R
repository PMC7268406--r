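test_that("index events require a 0-30 day indication-to-exposure gap", {
  # indication day 10, dispensing day 15 -> index day 15, arm fq
  b <- mini_bundle(conds = dx(1, "466.0", 10),
                   drugs = rx(1, "levofloxacin", 15))
  cand <- find_index_events(b, test_vocab)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$index_date, day(15))
  expect_equal(cand$arm, "fq")
  expect_equal(cand$indication, "bronchitis")

  # 31-day gap does not qualify; the 30-day boundary does (inclusive)
  b31 <- mini_bundle(conds = dx(1, "466.0", 10),
                     drugs = rx(1, "levofloxacin", 41))
  expect_equal(nrow(find_index_events(b31, test_vocab)), 0)
  b30 <- mini_bundle(conds = dx(1, "466.0", 10),
                     drugs = rx(1, "levofloxacin", 40))
  expect_equal(nrow(find_index_events(b30, test_vocab)), 1)
  # same-day dispensing qualifies (day-0 convention)
  b0 <- mini_bundle(conds = dx(1, "466.0", 10),
                    drugs = rx(1, "levofloxacin", 10))
  expect_equal(find_index_events(b0, test_vocab)$index_date, day(10))
})

test_that("arm-indication pairing and co-dispensing rules are enforced", {
  # azithromycin after a UTI diagnosis only: no index
  b <- mini_bundle(conds = dx(1, "599.0", 10),
                   drugs = rx(1, "azithromycin", 12))
  expect_equal(nrow(find_index_events(b, test_vocab)), 0)
  # sulfamethoxazole/trimethoprim is UTI-only
  b2 <- mini_bundle(conds = dx(1, "461.0", 10), drugs = rx(1, "smx_tmp", 12))
  expect_equal(nrow(find_index_events(b2, test_vocab)), 0)
  # inpatient indication diagnoses do not start an episode
  b3 <- mini_bundle(conds = dx(1, "466.0", 10, setting = "inpatient"),
                    drugs = rx(1, "levofloxacin", 15))
  expect_equal(nrow(find_index_events(b3, test_vocab)), 0)
  # both an FQ and the comparator in the episode: person dropped
  b4 <- mini_bundle(conds = dx(1, "466.0", 10),
                    drugs = dplyr::bind_rows(rx(1, "levofloxacin", 15),
                                             rx(1, "azithromycin", 18)))
  expect_equal(nrow(find_index_events(b4, test_vocab)), 0)
  # same-day tie within an arm: lexicographically lowest drug code
  b5 <- mini_bundle(conds = dx(1, "466.0", 10),
                    drugs = dplyr::bind_rows(rx(1, "levofloxacin", 15),
                                             rx(1, "gemifloxacin", 15)))
  expect_equal(find_index_events(b5, test_vocab)$drug_code, "gemifloxacin")
})

test_that("eligibility enforces 183 days pre and 120 insured days post", {
  cand <- function(obs) {
    b <- mini_bundle(obs = obs, conds = dx(1, "466.0", 10),
                     drugs = rx(1, "levofloxacin", 15))
    apply_eligibility(find_index_events(b, test_vocab), b)
  }
  # observation starting 100 days before index: excluded
  expect_equal(nrow(cand(tibble::tibble(person_id = 1L,
                                        start_date = day(-85),
                                        end_date = day(400),
                                        disability_insured = TRUE))), 0)
  # observation ending 119 days after index: excluded (120 required)
  expect_equal(nrow(cand(tibble::tibble(person_id = 1L,
                                        start_date = day(-400),
                                        end_date = day(15 + 119),
                                        disability_insured = TRUE))), 0)
  # exactly 183 pre + 120 post: retained
  expect_equal(nrow(cand(tibble::tibble(person_id = 1L,
                                        start_date = day(15 - 183),
                                        end_date = day(15 + 120),
                                        disability_insured = TRUE))), 1)
  # uninsured observation period: excluded
  expect_equal(nrow(cand(tibble::tibble(person_id = 1L,
                                        start_date = day(-400),
                                        end_date = day(400),
                                        disability_insured = FALSE))), 0)
})

test_that("general and indication-specific exclusions apply in their windows", {
  run_excl <- function(conds = NULL, drugs = NULL, claims = NULL) {
    b <- mini_bundle(conds = dplyr::bind_rows(dx(1, "466.0", 10), conds),
                     drugs = dplyr::bind_rows(rx(1, "levofloxacin", 15),
                                              drugs),
                     claims = claims)
    entries <- apply_eligibility(find_index_events(b, test_vocab), b)
    apply_exclusions(entries, b, test_vocab)
  }
  # prior disability claim 30 days before index
  out <- run_excl(claims = claim(1, -15, 5))
  expect_equal(nrow(out), 0)
  expect_match(attr(out, "removals")$rule, "prior_disability_claim")
  # pneumonia hospitalization 60 days before a bronchitis index
  out <- run_excl(conds = dx(1, "EXCL_PNEUMONIA", -45, setting = "inpatient"))
  expect_equal(nrow(out), 0)
  expect_match(attr(out, "removals")$rule, "specific:bronchitis")
  # general condition inside the 183-day lookback
  expect_equal(nrow(run_excl(conds = dx(1, "EXCL_LUPUS", -100))), 0)
  # outside the lookback: retained
  expect_equal(nrow(run_excl(conds = dx(1, "EXCL_LUPUS", -200))), 1)
  # cumulative steroid days >= 30 in the lookback
  expect_equal(nrow(run_excl(drugs = dplyr::bind_rows(
    rx(1, "oral_steroid", -60, 20), rx(1, "oral_steroid", -30, 15)))), 0)
  expect_equal(nrow(run_excl(drugs = rx(1, "oral_steroid", -60, 20))), 1)

  # pyelonephritis 200 days before a UTI index: outside the 92-day window
  b <- mini_bundle(conds = dplyr::bind_rows(
    dx(1, "599.0", 10), dx(1, "EXCL_PYELONEPHRITIS", -185)),
    drugs = rx(1, "ciprofloxacin", 15))
  entries <- apply_eligibility(find_index_events(b, test_vocab), b)
  expect_equal(nrow(apply_exclusions(entries, b, test_vocab)), 1)
  # the same event 60 days before index excludes
  b2 <- mini_bundle(conds = dplyr::bind_rows(
    dx(1, "599.0", 10), dx(1, "EXCL_PYELONEPHRITIS", -45)),
    drugs = rx(1, "ciprofloxacin", 15))
  entries2 <- apply_eligibility(find_index_events(b2, test_vocab), b2)
  expect_equal(nrow(apply_exclusions(entries2, b2, test_vocab)), 0)
})

test_that("cohorts are mutually exclusive new users", {
  # FQ index with an ST dispensing 90 days prior: excluded
  b <- mini_bundle(conds = dx(1, "599.0", 10),
                   drugs = dplyr::bind_rows(rx(1, "ciprofloxacin", 15),
                                            rx(1, "smx_tmp", -75)))
  entries <- find_index_events(b, test_vocab)
  expect_equal(entries$arm, "fq")
  expect_equal(nrow(enforce_mutual_exclusivity(entries, b, test_vocab)), 0)
  # cross-arm history outside 183 days: retained
  b2 <- mini_bundle(conds = dx(1, "599.0", 10),
                    drugs = dplyr::bind_rows(rx(1, "ciprofloxacin", 15),
                                             rx(1, "smx_tmp", -200)))
  e2 <- find_index_events(b2, test_vocab)
  expect_equal(nrow(enforce_mutual_exclusivity(e2, b2, test_vocab)), 1)
  # first-cohort rule: FQ index earlier than a later AZ candidate
  b3 <- mini_bundle(conds = dplyr::bind_rows(dx(1, "599.0", 10),
                                             dx(1, "461.0", 100)),
                    drugs = dplyr::bind_rows(rx(1, "ciprofloxacin", 15),
                                             rx(1, "azithromycin", 105)))
  e3 <- find_index_events(b3, test_vocab)
  expect_equal(e3$arm, "fq")
  expect_equal(e3$index_date, day(15))
})

test_that("cohort construction matches a per-person brute-force scan", {
  b <- simulate_claims(sim_config(n_persons = 700, seed = 31))
  got <- build_cohort(b, test_vocab)
  want <- oracle_cohort(b, test_vocab)
  got_tab <- dplyr::arrange(
    dplyr::select(got$cohort, "person_id", "arm", "index_date"),
    .data$person_id)
  want_tab <- dplyr::arrange(want, .data$person_id)
  expect_equal(as.data.frame(got_tab), as.data.frame(want_tab))
  # arms are disjoint and one entry per person
  expect_equal(anyDuplicated(got$cohort$person_id), 0)
  # attrition counts are monotone non-increasing per arm
  att <- tidyr::pivot_wider(got$attrition, names_from = "arm",
                            values_from = "n_remaining")
  expect_true(all(diff(att$fq) <= 0))
  expect_true(all(diff(att$azst) <= 0))
  # final attrition row equals the delivered cohort sizes
  expect_equal(att$fq[nrow(att)], sum(got$cohort$arm == "fq"))
  expect_equal(att$azst[nrow(att)], sum(got$cohort$arm == "azst"))
})
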