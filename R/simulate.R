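#' Default generating severities
#'
#' Item severities (logit units) used as the generator's truth: the
#' Rasch severities of the 11 criteria in a severe clinical sample --
#' all negative, i.e. all criteria are endorsed by a majority.
#'
#' @return Named numeric vector over the 11 items.
#' @export
default_severities <- function() {
  stats::setNames(
    c(-1.18, -2.05, -1.72, -0.99, -2.11, -2.42, -2.58, -1.46, -2.49,
      -1.67, -1.69),
    sud_items())
}

#' Default generating covariate effects
#'
#' Latent-regression fixed effects (logit units) on the person side:
#' female and non-drinker main effects, their interaction, and per-SD
#' effects of the four personality scores, with sensation seeking the
#' dominant personality effect.
#'
#' @return Named numeric vector of effects.
#' @export
default_fixed_effects <- function() {
  c(gender_female = -0.42, alcohol_no = -0.76,
    "gender_female:alcohol_no" = 0.92,
    hopelessness = 0.17, impulsivity = 0.23,
    sensation_seeking = 0.55, anxiety_sensitivity = 0.06)
}

#' Default injected DIF map
#'
#' Uniform DIF shifts in the easiness convention: a positive value makes
#' the item easier to endorse for the indicator-1 group (or for higher
#' covariate values) at equal latent level.
#'
#' @return List of `list(item, covariate, value)` entries.
#' @export
default_dif_map <- function() {
  list(
    list(item = "Craving", covariate = "gender_female", value = -0.73),
    list(item = "Social", covariate = "alcohol_no", value = -1.65),
    list(item = "Social", covariate = "impulsivity", value = -0.89),
    list(item = "Give up", covariate = "gender_female", value = 1.00),
    list(item = "Give up", covariate = "alcohol_no", value = -0.73),
    list(item = "Give up", covariate = "sensation_seeking", value = -0.62),
    list(item = "Hazard", covariate = "gender_female", value = -0.74),
    list(item = "Consistent use", covariate = "gender_female", value = 1.01),
    list(item = "Tolerance", covariate = "gender_female", value = -1.09),
    list(item = "Tolerance", covariate = "sensation_seeking", value = 0.52),
    list(item = "Withdrawal", covariate = "gender_female", value = -1.23)
  )
}

#' Generator configuration
#'
#' Defines the generating truth for a synthetic dataset: sample size,
#' item severities, person-side fixed effects, residual latent SD, DIF
#' map, covariate model and covariate missingness. Defaults emulate the
#' study conditions the analysis targets: n = 573 persons, about 30%
#' female and 29% non-drinkers, the default severities and fixed
#' effects, residual SD sqrt(2.34) (the residual person variance after
#' the covariate effects), and no DIF or missingness unless requested.
#'
#' @param n_persons Number of persons.
#' @param severities Named severity vector over the 11 items.
#' @param fixed_effects Named vector of covariate/interaction effects
#'   (logit units); names may contain `:` products.
#' @param residual_sd SD of the residual person effect e_j, > 0.
#' @param dif_map List of `list(item, covariate, value)`; easiness
#'   convention (positive = easier for the group).
#' @param p_female,p_alcohol_no Bernoulli probabilities of the binary
#'   covariates.
#' @param personality_cor 4x4 correlation matrix of the personality
#'   scores (default identity).
#' @param missing_covariate_rate Per-person probability of an incomplete
#'   covariate row (a uniformly chosen field is blanked).
#' @param seed Integer seed; mandatory for reproducibility.
#' @return Object of class `generation_config`.
#' @export
generation_config <- function(n_persons = 573,
                              severities = default_severities(),
                              fixed_effects = default_fixed_effects(),
                              residual_sd = sqrt(2.34),
                              dif_map = list(),
                              p_female = 0.30,
                              p_alcohol_no = 0.29,
                              personality_cor = diag(4),
                              missing_covariate_rate = 0,
                              seed = 1L) {
  stopifnot(n_persons >= 0, residual_sd > 0,
            p_female >= 0, p_female <= 1,
            p_alcohol_no >= 0, p_alcohol_no <= 1,
            missing_covariate_rate >= 0, missing_covariate_rate <= 1)
  if (!all(sud_items() %in% names(severities))) {
    stop("severities must be named over all 11 items")
  }
  if (!all(is.finite(severities))) stop("severities must be finite")
  pc <- as.matrix(personality_cor)
  if (!isTRUE(all.equal(pc, t(pc))) || any(abs(diag(pc) - 1) > 1e-8) ||
      min(eigen(pc, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
    stop("personality_cor must be a symmetric positive-definite ",
         "correlation matrix")
  }
  for (d in dif_map) {
    if (!all(c("item", "covariate", "value") %in% names(d))) {
      stop("dif_map entries need item, covariate, value")
    }
    if (!d$item %in% sud_items()) stop("dif_map names unknown item: ", d$item)
  }
  structure(list(n_persons = as.integer(n_persons),
                 severities = severities[sud_items()],
                 fixed_effects = fixed_effects,
                 residual_sd = residual_sd, dif_map = dif_map,
                 p_female = p_female, p_alcohol_no = p_alcohol_no,
                 personality_cor = pc,
                 missing_covariate_rate = missing_covariate_rate,
                 seed = as.integer(seed)),
            class = "generation_config")
}

#' Generate a covariate table
#'
#' Gender ~ Bernoulli(p_female), non-drinking ~ Bernoulli(p_alcohol_no),
#' personality scores multivariate normal with the configured
#' correlations then z-standardized on the generated sample. If
#' `missing_covariate_rate > 0`, that fraction of persons (in
#' expectation) gets one uniformly chosen covariate field blanked.
#'
#' @param config A [generation_config()].
#' @return Covariate data frame (columns of [sud_covariates()]).
#' @export
generate_covariates <- function(config) {
  set.seed(config$seed)
  n <- config$n_persons
  ids <- sprintf("P%04d", seq_len(n))
  if (n == 0) {
    return(stats::setNames(
      data.frame(matrix(numeric(0), 0, 7)),
      c("person_id", sud_covariates())))
  }
  pers <- MASS::mvrnorm(n, mu = rep(0, 4), Sigma = config$personality_cor)
  if (n == 1) pers <- matrix(pers, 1)
  cov <- data.frame(
    person_id = ids,
    gender_female = stats::rbinom(n, 1, config$p_female),
    alcohol_no = stats::rbinom(n, 1, config$p_alcohol_no),
    hopelessness = pers[, 1], impulsivity = pers[, 2],
    sensation_seeking = pers[, 3], anxiety_sensitivity = pers[, 4]
  )
  if (n > 2) {
    cov <- standardize(cov)
  }
  if (config$missing_covariate_rate > 0 && n > 0) {
    hit <- stats::runif(n) < config$missing_covariate_rate
    fld <- sample(sud_covariates(), n, replace = TRUE)
    for (j in which(hit)) cov[j, fld[j]] <- NA
  }
  cov
}

#' Generate true latent levels
#'
#' theta_j = sum of configured fixed effects over the person's
#' covariates (product terms allowed via `:` in the effect name) plus
#' N(0, residual_sd^2) noise.
#'
#' @param covariates Covariate data frame (complete for modeled terms).
#' @param config A [generation_config()].
#' @return Numeric vector of latent levels, one per person.
#' @export
generate_theta <- function(covariates, config) {
  n <- nrow(covariates)
  mu <- rep(0, n)
  for (nm in names(config$fixed_effects)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    v <- rep(1, n)
    for (p in parts) {
      if (!p %in% names(covariates)) {
        stop("fixed effect references unknown covariate: ", p)
      }
      v <- v * covariates[[p]]
    }
    if (anyNA(v)) stop("missing covariate value in modeled term: ", nm)
    mu <- mu + config$fixed_effects[[nm]] * v
  }
  mu + stats::rnorm(n, 0, config$residual_sd)
}

#' Generate binary criterion responses
#'
#' Each observed cell is Bernoulli with
#' logit = theta_j - severity_i + sum(dif value x covariate) over the
#' DIF-map entries hitting the item: a positive DIF value makes the item
#' easier for the indicator-1 group at equal latent level.
#'
#' @param theta_true Latent levels, one per covariate row.
#' @param covariates Covariate data frame.
#' @param config A [generation_config()].
#' @return A [response_table()] with n_persons x 11 rows.
#' @export
generate_responses <- function(theta_true, covariates, config) {
  n <- nrow(covariates)
  stopifnot(length(theta_true) == n)
  items <- sud_items()
  if (n == 0) {
    return(response_table(data.frame(person_id = character(),
                                     item_id = character(),
                                     response = numeric())))
  }
  long <- data.frame(
    person_id = rep(covariates$person_id, each = length(items)),
    item_id = rep(items, times = n)
  )
  eta <- rep(theta_true, each = length(items)) -
    config$severities[long$item_id]
  for (d in config$dif_map) {
    z <- covariates[[d$covariate]][match(long$person_id, covariates$person_id)]
    hit <- long$item_id == d$item
    eta[hit] <- eta[hit] + d$value * z[hit]
  }
  long$response <- stats::rbinom(nrow(long), 1, logistic(eta))
  response_table(long)
}

#' Simulate a full dataset
#'
#' Composes [generate_covariates()], [generate_theta()] and
#' [generate_responses()] under one seed; bit-for-bit reproducible from
#' the config. Persons left incomplete by covariate missingness are
#' excluded from the latent/response generation of modeled terms only if
#' a modeled term is missing; by default missingness and modeled terms
#' do not collide because theta is generated before blanking.
#'
#' @param config A [generation_config()].
#' @return Object of class `simulated_dataset`: `responses`,
#'   `covariates` (with any injected missingness), `theta_true`,
#'   `config`.
#' @export
simulate_dataset <- function(config = generation_config()) {
  set.seed(config$seed)
  n <- config$n_persons
  ids <- sprintf("P%04d", seq_len(n))
  if (n == 0) {
    cov <- stats::setNames(data.frame(matrix(numeric(0), 0, 7)),
                           c("person_id", sud_covariates()))
    resp <- response_table(data.frame(person_id = character(),
                                      item_id = character(),
                                      response = numeric()))
    return(structure(list(responses = resp, covariates = cov,
                          theta_true = numeric(0), config = config),
                     class = "simulated_dataset"))
  }
  pers <- MASS::mvrnorm(n, mu = rep(0, 4), Sigma = config$personality_cor)
  if (n == 1) pers <- matrix(pers, 1)
  cov <- data.frame(
    person_id = ids,
    gender_female = stats::rbinom(n, 1, config$p_female),
    alcohol_no = stats::rbinom(n, 1, config$p_alcohol_no),
    hopelessness = pers[, 1], impulsivity = pers[, 2],
    sensation_seeking = pers[, 3], anxiety_sensitivity = pers[, 4]
  )
  if (n > 2) cov <- standardize(cov)
  theta <- generate_theta(cov, config)
  resp <- generate_responses(theta, cov, config)
  if (config$missing_covariate_rate > 0) {
    hit <- stats::runif(n) < config$missing_covariate_rate
    fld <- sample(sud_covariates(), n, replace = TRUE)
    for (j in which(hit)) cov[j, fld[j]] <- NA
  }
  structure(list(responses = resp, covariates = cov, theta_true = theta,
                 config = config),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "Simulated SUD dataset: %d persons, %d response cells, seed %d\n",
    x$config$n_persons, nrow(x$responses), x$config$seed))
  cat(sprintf("  %.0f%% female, %.0f%% non-drinkers, %d DIF entries, %s\n",
              100 * mean(x$covariates$gender_female, na.rm = TRUE),
              100 * mean(x$covariates$alcohol_no, na.rm = TRUE),
              length(x$config$dif_map),
              sprintf("residual SD %.2f", x$config$residual_sd)))
  invisible(x)
}
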