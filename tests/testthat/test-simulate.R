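test_that("generated covariates match their targets at large n", {
  cov <- generate_covariates(generation_config(n_persons = 1e4, seed = 21))
  expect_equal(mean(cov$gender_female), 0.30, tolerance = 0.02)
  expect_equal(mean(cov$alcohol_no), 0.29, tolerance = 0.02)
  # identity correlation: personality scores uncorrelated
  r <- cor(cov[c("hopelessness", "impulsivity", "sensation_seeking",
                 "anxiety_sensitivity")])
  expect_true(all(abs(r[upper.tri(r)]) < 0.03))
  # standardized on the sample
  expect_equal(unname(colMeans(cov[4:7])), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(cov[4:7], 2, sd)), rep(1, 4), tolerance = 1e-10)
})

test_that("covariate missingness hits roughly its target rate", {
  cfg <- generation_config(n_persons = 606, seed = 22,
                           missing_covariate_rate = 33 / 606)
  cov <- generate_covariates(cfg)
  n_incomplete <- sum(!complete.cases(cov[sud_covariates()]))
  expect_gte(n_incomplete, 33 - 12)  # binomial 99% band
  expect_lte(n_incomplete, 33 + 12)
})

test_that("a non-PD personality correlation matrix is rejected", {
  bad <- matrix(0.99, 4, 4)
  bad[1, 2] <- bad[2, 1] <- -0.99
  diag(bad) <- 1
  expect_error(generation_config(personality_cor = bad),
               "positive-definite")
})

test_that("theta is the configured linear predictor plus noise", {
  # pure noise: sample SD tracks residual_sd
  cfg <- generation_config(n_persons = 1e4, seed = 23,
                           fixed_effects = numeric(0), residual_sd = 1.6)
  sim <- simulate_dataset(cfg)
  expect_equal(sd(sim$theta_true), 1.6, tolerance = 0.05)
  # noise-free limit: one binary effect gives exactly two values
  cfg0 <- generation_config(n_persons = 500, seed = 24,
                            fixed_effects = c(gender_female = -0.42),
                            residual_sd = 1e-12)
  sim0 <- simulate_dataset(cfg0)
  expect_equal(sim0$theta_true,
               -0.42 * sim0$covariates$gender_female, tolerance = 1e-9)
  # OLS on the generated sample recovers a continuous effect
  cfg1 <- generation_config(n_persons = 1e5, seed = 25,
                            fixed_effects = c(sensation_seeking = 0.55),
                            residual_sd = 1.5)
  sim1 <- simulate_dataset(cfg1)
  slope <- coef(lm(sim1$theta_true ~ sim1$covariates$sensation_seeking))[2]
  expect_lt(abs(unname(slope) - 0.55), 0.02)
  # unknown term
  expect_error(
    generate_theta(sim1$covariates,
                   generation_config(fixed_effects = c(nope = 1))),
    "unknown covariate")
})

test_that("responses follow the Rasch probabilities", {
  # theta == severity everywhere -> endorsement 0.5
  cfg <- generation_config(n_persons = 1000, seed = 26,
                           severities = setNames(rep(0.7, 11), sud_items()),
                           fixed_effects = numeric(0), residual_sd = 1e-12)
  set.seed(26)
  cov <- generate_covariates(cfg)
  resp <- generate_responses(rep(0.7, 1000), cov, cfg)
  expect_equal(mean(resp$response), 0.5, tolerance = 0.02)
  # saturation
  cfg_sat <- generation_config(n_persons = 30, seed = 27,
                               severities = setNames(rep(-10, 11), sud_items()),
                               fixed_effects = numeric(0), residual_sd = 0.5)
  expect_true(all(simulate_dataset(cfg_sat)$responses$response == 1))
})

test_that("simulated prevalence matches the quadrature-implied marginal", {
  cfg <- generation_config(n_persons = 2e4, seed = 28,
                           fixed_effects = numeric(0), residual_sd = 1.6)
  sim <- simulate_dataset(cfg)
  d <- describe_items(sim$responses)
  implied <- marginal_prevalence(-default_severities()[d$item_id], 1.6,
                                 gh_rule(201))
  expect_true(all(abs(d$mean - implied) < 0.015))
})

test_that("raising a severity strictly lowers that item's prevalence", {
  sev_lo <- default_severities()
  sev_hi <- sev_lo
  sev_hi["Craving"] <- sev_hi["Craving"] + 1
  p <- sapply(list(sev_lo, sev_hi), function(s) {
    sim <- simulate_dataset(generation_config(
      n_persons = 1e4, seed = 29, severities = s,
      fixed_effects = numeric(0), residual_sd = 1.6))
    mean(sim$responses$response[sim$responses$item_id == "Craving"])
  })
  expect_lt(p[2], p[1])
})

test_that("injected DIF shifts the group's conditional log-odds by its value", {
  d <- 1.0
  cfg <- generation_config(
    n_persons = 2e4, seed = 30, fixed_effects = numeric(0),
    residual_sd = 1.6,
    dif_map = list(list(item = "Withdrawal", covariate = "gender_female",
                        value = d)))
  sim <- simulate_dataset(cfg)
  wd <- sim$responses[sim$responses$item_id == "Withdrawal", ]
  idx <- match(wd$person_id, sim$covariates$person_id)
  # at fixed theta (entered as an offset) the group contrast is the shift
  g <- glm(wd$response ~ sim$covariates$gender_female[idx],
           offset = sim$theta_true[idx], family = binomial)
  expect_equal(unname(coef(g)[2]), d, tolerance = 0.12)
})

test_that("datasets are reproducible from the config and handle n = 0", {
  cfg <- generation_config(n_persons = 80, seed = 31,
                           dif_map = default_dif_map(),
                           missing_covariate_rate = 0.05)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$responses, b$responses)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$theta_true, b$theta_true)
  empty <- simulate_dataset(generation_config(n_persons = 0))
  expect_equal(nrow(empty$responses), 0)
  expect_equal(length(empty$theta_true), 0)
})

test_that("the default study-condition config runs end-to-end", {
  cfg <- generation_config(n_persons = 180, seed = 32,
                           dif_map = default_dif_map())
  sim <- simulate_dataset(cfg)
  specs <- canonical_specs()[c("null", "m1")]
  lad <- run_ladder(sim$responses, sim$covariates, specs,
                    gh_rule(21), se = FALSE)
  expect_named(lad$fits, c("null", "m1"))
  expect_true(all(vapply(lad$fits, function(f) f$converged, TRUE)))
})
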