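test_that("logistic is the stable inverse-logit", {
  expect_identical(logistic(0), 0.5)
  expect_equal(logistic(2.58) + logistic(-2.58), 1, tolerance = 1e-15)
  expect_equal(logistic(1.879), 1 / (1 + exp(-1.879)))
  expect_equal(logistic(1.879), 0.8675, tolerance = 5e-4)
  expect_equal(logistic(c(-700, 700)), c(0, 1), tolerance = 1e-15)
})

test_that("quadrature rule is symmetric with unit-mass weights", {
  for (k in c(5, 21, 41)) {
    r <- gh_rule(k)
    expect_equal(sum(r$weights), 1, tolerance = 1e-12)
    expect_equal(r$nodes, -rev(r$nodes), tolerance = 1e-9)
    # exact for low-order moments of the standard normal
    expect_equal(sum(r$weights * r$nodes^2), 1, tolerance = 1e-10)
    expect_equal(sum(r$weights * r$nodes^4), 3, tolerance = 1e-9)
  }
})

test_that("marginal loglik collapses, adds, and matches the dense oracle", {
  one <- response_table(data.frame(person_id = "a", item_id = "Larger",
                                   response = 1))
  e0 <- setNames(rep(0, 11), sud_items())
  # degenerate limit: nearly-point prior at 0 gives log 0.5
  expect_equal(marginal_loglik(one, e0, 1e-6), log(0.5), tolerance = 1e-9)
  # duplicating every person doubles the loglik
  df <- make_long(6, seed = 40)
  rt1 <- response_table(df)
  df2 <- df
  df2$person_id <- paste0(df2$person_id, "_copy")
  rt2 <- response_table(rbind(df, df2))
  e <- setNames(runif(11, -2, 2), sud_items())
  expect_equal(marginal_loglik(rt2, e, 1.4),
               2 * marginal_loglik(rt1, e, 1.4), tolerance = 1e-9)
  # oracle equivalence on an instance with missing cells
  df$response[c(4, 17)] <- NA
  rt <- response_table(df)
  expect_equal(marginal_loglik(rt, e, 1.6, gh_rule(201)),
               oracle_marginal_loglik(rt, e, 1.6), tolerance = 1e-6)
  expect_error(marginal_loglik(rt1[0, ], e, 1), "no observed")
})

test_that("the fit satisfies the score equations at its optimum", {
  sim <- small_sim(300, seed = 41, fixed_effects = numeric(0),
                   residual_sd = 1.6)
  fit <- fit_rasch(sim$responses)
  expect_true(fit$converged)
  expect_equal(fit$severity, -fit$easiness)
  expect_equal(fit$deviance, -2 * fit$loglik)
  expect_equal(fit$n_params, 12L)
  # numerical derivative of the public loglik is ~0 in every direction
  h <- 1e-5
  for (k in c(1, 6, 11)) {
    up <- fit$easiness; up[k] <- up[k] + h
    dn <- fit$easiness; dn[k] <- dn[k] - h
    g <- (marginal_loglik(sim$responses, up, fit$person_sd, fit$rule) -
            marginal_loglik(sim$responses, dn, fit$person_sd, fit$rule)) / (2 * h)
    expect_lt(abs(g), 1e-2)
  }
  # model-implied marginal prevalence tracks observed prevalence closely
  d <- describe_items(sim$responses)
  imp <- marginal_prevalence(as.numeric(fit$easiness[d$item_id]),
                             fit$person_sd, fit$rule)
  expect_true(all(abs(imp - d$mean) < 0.01))
})

test_that("degenerate items are refused with the item named", {
  df <- make_long(20, seed = 42)
  df$response[df$item_id == "Craving"] <- 1
  expect_error(fit_rasch(response_table(df)), "Craving")
})

test_that("item relabeling permutes the estimates identically", {
  sim <- small_sim(150, seed = 43)
  fit <- fit_rasch(sim$responses, gh_rule(21))
  perm <- setNames(sud_items()[c(2:11, 1)], sud_items())
  df <- as.data.frame(sim$responses)
  df$item_id <- unname(perm[df$item_id])
  fit_p <- fit_rasch(response_table(df), gh_rule(21))
  expect_equal(unname(fit_p$easiness[unname(perm)]), unname(fit$easiness),
               tolerance = 1e-4)
  expect_equal(fit_p$loglik, fit$loglik, tolerance = 1e-6)
})

test_that("fitted parameters are stable from 21 to 61 quadrature nodes", {
  sim <- small_sim(500, seed = 44, fixed_effects = numeric(0),
                   residual_sd = 1.6)
  f21 <- fit_rasch(sim$responses, gh_rule(21), se = FALSE)
  f61 <- fit_rasch(sim$responses, gh_rule(61), se = FALSE)
  expect_lt(max(abs(f21$easiness - f61$easiness)), 1e-3)
  expect_lt(abs(f21$person_sd - f61$person_sd), 1e-3)
})

test_that("loglik is invariant to person order and input layout", {
  sim <- small_sim(40, seed = 45)
  e <- -default_severities()
  base <- marginal_loglik(sim$responses, e, 1.5)
  shuf <- as.data.frame(sim$responses)
  shuf <- shuf[sample(nrow(shuf)), ]
  expect_equal(marginal_loglik(response_table(shuf), e, 1.5), base,
               tolerance = 1e-10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(sim$responses, path, "wide")
  expect_equal(marginal_loglik(load_responses(path, "wide"), e, 1.5), base,
               tolerance = 1e-10)
})

test_that("estimates agree with an adaptive-quadrature GLMM fit", {
  # independent route: the same marginal model fitted by lme4
  sim <- small_sim(300, seed = 46)
  fit <- fit_rasch(sim$responses, gh_rule(41))
  df <- as.data.frame(sim$responses)
  df$item_id <- factor(df$item_id, levels = sud_items())
  g <- suppressWarnings(lme4::glmer(
    response ~ 0 + item_id + (1 | person_id), data = df,
    family = binomial, nAGQ = 25))
  expect_equal(unname(fit$easiness), unname(lme4::fixef(g)),
               tolerance = 0.02)
  expect_equal(fit$person_sd,
               sqrt(unname(unlist(lme4::VarCorr(g)))), tolerance = 0.02)
  expect_equal(fit$loglik, as.numeric(stats::logLik(g)), tolerance = 0.05)
})

test_that("EAP scores shrink toward the prior mean", {
  sim <- small_sim(250, seed = 47, fixed_effects = numeric(0),
                   residual_sd = 1.6)
  df <- as.data.frame(sim$responses)
  extremes <- data.frame(
    person_id = rep(c("zz_all1", "zz_all0", "zz_none"), each = 11),
    item_id = rep(sud_items(), 3),
    response = c(rep(1, 11), rep(0, 11), rep(NA, 11)))
  rt <- response_table(rbind(df, extremes))
  fit <- fit_rasch(rt, gh_rule(41))
  sc <- eap_scores(rt, fit)
  rownames(sc) <- sc$person_id
  expect_gt(sc["zz_all1", "eap"], 0)
  expect_lt(sc["zz_all0", "eap"], 0)
  expect_equal(sc["zz_none", "eap"], 0, tolerance = 1e-10)
  expect_equal(sc["zz_none", "psd"], fit$person_sd, tolerance = 1e-8)
  expect_true(all(sc$psd > 0))
  expect_true(all(abs(sc$eap) <= max(abs(fit$rule$nodes)) * fit$person_sd))
  # shrinkage: EAP variance below the fitted person variance
  expect_lt(var(sc$eap[seq_len(250)]), fit$person_var)
})

test_that("marginal prevalence collapses, is antisymmetric, matches a grid", {
  expect_equal(marginal_prevalence(0.7, 0), logistic(0.7))
  expect_equal(marginal_prevalence(1.2, 1.5) + marginal_prevalence(-1.2, 1.5),
               1, tolerance = 1e-10)
  # dense-grid reference for the endorsement rate of an easy item
  th <- seq(-16, 16, length.out = 20001)
  ref <- pracma::trapz(th, dnorm(th, 0, 1.6) * plogis(th + 2.58))
  expect_equal(marginal_prevalence(2.58, 1.6, gh_rule(201)), ref,
               tolerance = 1e-8)
  expect_equal(marginal_prevalence(2.58, 1.6), 0.87, tolerance = 0.01)
})

test_that("ICC curves are monotone with 0.5 at the severity", {
  sim <- small_sim(120, seed = 48)
  fit <- fit_rasch(sim$responses, gh_rule(21))
  cc <- icc_curve("Larger", fit, grid = fit$severity[["Larger"]])
  expect_equal(cc$prob, 0.5)
  cc2 <- icc_curve("Larger", fit)
  expect_true(all(diff(cc2$prob) > 0))
  # a negative DIF shift puts the focal curve uniformly below
  focal <- icc_curve("Withdrawal", fit, dif = -1.23)
  refc <- icc_curve("Withdrawal", fit)
  expect_true(all(focal$prob < refc$prob))
  expect_error(icc_curve("Nope", fit), "unknown item")
})
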