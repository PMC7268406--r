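# Hand-built micro claims bundles for boundary tests. Day arithmetic is
# anchored at a fixed origin so tests can speak in day offsets.

D0 <- as.Date("2010-06-01")
day <- function(k) D0 + k

mini_bundle <- function(persons = NULL, obs = NULL, drugs = NULL,
                        conds = NULL, claims = NULL) {
  default_persons <- tibble::tibble(person_id = 1L, birth_year = 1970L,
                                    sex = "F")
  default_obs <- tibble::tibble(person_id = 1L, start_date = day(-400),
                                end_date = day(400),
                                disability_insured = TRUE)
  empty_drugs <- tibble::tibble(person_id = integer(),
                                drug_code = character(),
                                dispense_date = as.Date(character()),
                                days_supplied = integer())
  empty_conds <- tibble::tibble(person_id = integer(),
                                condition_code = character(),
                                event_date = as.Date(character()),
                                setting = character())
  empty_claims <- tibble::tibble(person_id = integer(), claim_id = integer(),
                                 claim_start = as.Date(character()),
                                 claim_end = as.Date(character()),
                                 continuation_of = integer())
  persons <- persons %||% default_persons
  obs <- obs %||% default_obs
  fqad:::new_bundle(persons, obs,
                    dplyr::bind_rows(empty_drugs, drugs),
                    dplyr::bind_rows(empty_conds, conds),
                    dplyr::bind_rows(empty_claims, claims))
}

rx <- function(person_id, drug_code, at, days_supplied = 10L) {
  tibble::tibble(person_id = as.integer(person_id), drug_code = drug_code,
                 dispense_date = day(at),
                 days_supplied = as.integer(days_supplied))
}

dx <- function(person_id, condition_code, at, setting = "outpatient") {
  tibble::tibble(person_id = as.integer(person_id),
                 condition_code = condition_code, event_date = day(at),
                 setting = setting)
}

claim <- function(person_id, from, to, claim_id = 1L,
                  continuation_of = NA_integer_) {
  tibble::tibble(person_id = as.integer(person_id),
                 claim_id = as.integer(claim_id), claim_start = day(from),
                 claim_end = day(to),
                 continuation_of = as.integer(continuation_of))
}

test_vocab <- load_vocabulary()

`%||%` <- rlang::`%||%`
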