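test_that("covariate windows nest and age bands follow five-year cuts", {
  entry <- tibble::tibble(person_id = 1L, arm = "fq", index_date = day(0),
                          indication = "uti", drug_code = "ciprofloxacin",
                          age_at_index = 52L, sex = "F")
  b <- mini_bundle(conds = dplyr::bind_rows(dx(1, "CONF_DYSURIA", -10),
                                            dx(1, "CONF_HEMATURIA", -200)))
  cov <- build_covariates(entry, b)
  # 10 days pre-index: flagged in all three windows
  expect_equal(cov$dx_CONF_DYSURIA_w30, 1L)
  expect_equal(cov$dx_CONF_DYSURIA_w183, 1L)
  expect_equal(cov$dx_CONF_DYSURIA_w365, 1L)
  # 200 days pre-index: only the 365-day window
  expect_false("dx_CONF_HEMATURIA_w30" %in% names(cov))
  expect_false("dx_CONF_HEMATURIA_w183" %in% names(cov))
  expect_equal(cov$dx_CONF_HEMATURIA_w365, 1L)
  # age 52 falls in the 50-54 band
  expect_equal(cov$age_50_54, 1L)
  expect_equal(sum(dplyr::select(cov, dplyr::starts_with("age_"))), 1L)
})

test_that("propensity scores are well-calibrated under random assignment", {
  aucs <- purrr::map_dbl(1:3, function(s) {
    set.seed(1000 + s)
    n <- 2000
    covs <- tibble::tibble(person_id = 1:n,
                           x1 = rbinom(n, 1, 0.3), x2 = rbinom(n, 1, 0.1),
                           x3 = rbinom(n, 1, 0.5))
    arms <- sample(c("fq", "azst"), n, replace = TRUE)
    ps <- fit_ps(covs, arms, seed = s)
    y <- ps$scores$arm == "fq"
    r <- rank(ps$scores$score)
    (mean(r[y]) - (sum(y) + 1) / 2) / sum(!y)  # AUC via rank statistic
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("a strongly arm-associated covariate is selected by the lasso", {
  set.seed(7)
  n <- 3000
  x1 <- rbinom(n, 1, 0.3)
  arms <- ifelse(runif(n) < plogis(-0.5 + 2.0 * x1), "fq", "azst")
  covs <- tibble::tibble(person_id = 1:n, x1 = x1,
                         x2 = rbinom(n, 1, 0.4), x3 = rbinom(n, 1, 0.2))
  ps <- fit_ps(covs, arms, seed = 7)
  beta1 <- ps$coefficients$estimate[ps$coefficients$term == "x1"]
  expect_gt(beta1, 0)  # same sign as the unpenalized truth
  # identical covariate rows receive identical scores
  expect_equal(dplyr::n_distinct(ps$scores$score[x1 == 1 & covs$x2 == 0 &
                                                   covs$x3 == 0]), 1)
})

test_that("trimming drops the outer pooled percentiles only", {
  # uniform scores: about 90% retained
  set.seed(42)
  sc <- tibble::tibble(person_id = 1:10000,
                       arm = rep(c("fq", "azst"), 5000),
                       score = runif(10000))
  kept <- trim_ps(sc)
  expect_lt(abs(nrow(kept) / nrow(sc) - 0.90), 0.01)
  # 100 pooled entries leave at most 90
  sc100 <- tibble::tibble(person_id = 1:100, arm = rep(c("fq", "azst"), 50),
                          score = seq(0.01, 1, length.out = 100))
  expect_lte(nrow(trim_ps(sc100)), 90)
  # identical scores: degenerate percentiles, nothing trimmed
  same <- tibble::tibble(person_id = 1:50, arm = rep(c("fq", "azst"), 25),
                         score = rep(0.4, 50))
  expect_equal(nrow(trim_ps(same)), 50)
})

test_that("greedy matching is nearest-first within the caliper", {
  sc <- tibble::tibble(person_id = 1:4,
                       arm = c("fq", "fq", "azst", "azst"),
                       score = c(0.20, 0.50, 0.21, 0.90))
  m <- greedy_match(sc)
  # caliper 0.25 * sd(0.20, 0.50, 0.21, 0.90) ~ 0.082 rejects (0.50, 0.90)
  expect_equal(m$caliper, 0.25 * sd(sc$score))
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$target_id, 1L)
  expect_equal(m$pairs$comparator_id, 3L)
  # identical score multisets match completely at zero distance
  sc2 <- tibble::tibble(person_id = 1:10,
                        arm = rep(c("fq", "azst"), each = 5),
                        score = c(1:5, 1:5) / 10)
  m2 <- greedy_match(sc2)
  expect_equal(nrow(m2$pairs), 5)
  expect_true(all(m2$pairs$distance == 0))
  # empty comparator pool: zero pairs
  sc3 <- dplyr::filter(sc, arm == "fq")
  expect_equal(nrow(greedy_match(sc3)$pairs), 0)
})

test_that("matching is caliper-safe, order-invariant, and near-optimal", {
  for (s in 1:20) {
    set.seed(200 + s)
    n_t <- sample(2:6, 1)
    n_c <- sample(2:6, 1)
    sc <- tibble::tibble(
      person_id = 1:(n_t + n_c),
      arm = c(rep("fq", n_t), rep("azst", n_c)),
      score = round(runif(n_t + n_c), 2))
    m <- greedy_match(sc)
    # no pair beyond the caliper (post-hoc scan)
    expect_true(all(m$pairs$distance <= m$caliper + 1e-12))
    # each person in at most one pair
    expect_equal(anyDuplicated(c(m$pairs$target_id, m$pairs$comparator_id)),
                 0)
    # row order of the input does not change the result
    perm <- sc[sample(nrow(sc)), ]
    m_perm <- greedy_match(perm)
    expect_equal(m$pairs, m_perm$pairs)
    # pair count within 1 of the exhaustive optimum
    opt <- oracle_max_pairs(sc$score[sc$arm == "fq"],
                            sc$score[sc$arm == "azst"], m$caliper)
    expect_gte(nrow(m$pairs), opt - 1)
  }
})

test_that("the pooled-order matcher agrees with the all-pairs formulation", {
  for (s in 1:10) {
    set.seed(300 + s)
    n <- 60
    sc <- tibble::tibble(person_id = 1:n,
                         arm = sample(c("fq", "azst"), n, replace = TRUE),
                         score = runif(n))
    if (sum(sc$arm == "fq") == 0 || sum(sc$arm == "azst") == 0) next
    m_small <- greedy_match(sc)  # all-pairs path
    tgt <- dplyr::filter(sc, arm == "fq")
    cmp <- dplyr::filter(sc, arm == "azst")
    m_pooled <- fqad:::greedy_match_pooled(tgt, cmp, m_small$caliper)
    expect_equal(
      dplyr::arrange(m_small$pairs, target_id)[
        , c("target_id", "comparator_id", "distance")],
      dplyr::arrange(m_pooled, target_id)[
        , c("target_id", "comparator_id", "distance")])
  }
})

test_that("SMD and preference-score formulas match their definitions", {
  # binary covariate 3.2% vs 0.9% gives SMD 0.16; 59.1% vs 49.3% gives 0.20
  expect_equal(round(smd(0.032, 0.009), 2), 0.16)
  expect_equal(round(smd(0.591, 0.493), 2), 0.20)
  # identical arms: SMD 0; zero variance with differing means: infinite
  expect_equal(smd(0.25, 0.25), 0)
  expect_equal(smd(0, 0), 0)
  expect_equal(smd(1, 0), Inf)
  # with a treated fraction of one half the transformation is the identity
  s <- c(0.1, 0.4, 0.9)
  expect_equal(preference_score(s, 0.5), s)
  expect_lt(preference_score(0.5, 0.75), 0.5)
})

test_that("balance reporting computes arm prevalences and SMDs", {
  set.seed(11)
  n <- 400
  covs <- tibble::tibble(person_id = 1:n, x1 = rbinom(n, 1, 0.5),
                         x2 = rbinom(n, 1, 0.2))
  scores <- tibble::tibble(person_id = 1:n,
                           arm = rep(c("fq", "azst"), each = n / 2),
                           score = runif(n, 0.3, 0.7))
  m <- greedy_match(scores, caliper_mult = 10)  # wide caliper: all matched
  rep <- balance_report(m, covs)
  expect_equal(nrow(m$pairs), n / 2)
  x1row <- dplyr::filter(rep$table, feature == "x1")
  expect_equal(x1row$smd_before,
               smd(mean(covs$x1[1:(n / 2)]), mean(covs$x1[(n / 2 + 1):n])))
  expect_true(all(c("preference", "matched") %in% names(rep$preference)))
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
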