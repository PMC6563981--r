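#' Logistic response function
#'
#' \eqn{P(Y=1) = e^x / (1 + e^x)}, numerically stable over the full double
#' range. At \eqn{x = 0} -- a person whose latent level equals the item
#' severity -- the endorsement probability is exactly 0.5.
#'
#' @param x Numeric vector of logits.
#' @return Probabilities in (0, 1).
#' @export
logistic <- function(x) stats::plogis(x)

# internal: assemble (y, pid, n_persons, persons) from a response table
response_cells <- function(responses) {
  obs <- responses[!is.na(responses$response), , drop = FALSE]
  if (nrow(obs) == 0) stop("no observed responses")
  persons <- sort(unique(responses$person_id))
  list(y = obs$response,
       pid = match(obs$person_id, persons),
       item = obs$item_id,
       n_persons = length(persons),
       persons = persons)
}

# internal: cells x 11 item indicator matrix
item_indicator_matrix <- function(item_ids) {
  items <- sud_items()
  X <- matrix(0, length(item_ids), length(items),
              dimnames = list(NULL, items))
  X[cbind(seq_along(item_ids), match(item_ids, items))] <- 1
  X
}

#' Marginal log-likelihood of the Rasch model
#'
#' For easiness parameters \eqn{\epsilon_i} and person SD \eqn{\sigma},
#' computes \eqn{\sum_j \log \int \prod_{i \in obs(j)}
#' p_{ij}(\theta)^{y_{ij}} (1-p_{ij}(\theta))^{1-y_{ij}}\, dN(0,\sigma^2)}
#' with \eqn{\mathrm{logit}\, p_{ij} = \theta + \epsilon_i}, the integral
#' evaluated by the quadrature rule. Missing cells are simply absent from
#' the product.
#'
#' @param responses A [response_table()].
#' @param easiness Named numeric vector over the 11 items (easiness =
#'   -severity).
#' @param person_sd Positive scalar SD of the latent trait.
#' @param rule A [gh_rule()].
#' @return Scalar log-likelihood.
#' @export
marginal_loglik <- function(responses, easiness, person_sd, rule = gh_rule()) {
  stopifnot(person_sd > 0)
  cells <- response_cells(responses)
  X <- item_indicator_matrix(cells$item)
  easiness <- easiness[colnames(X)]
  if (anyNA(easiness)) stop("easiness must be named over all 11 items")
  mml_loglik(cells$y, cells$pid, cells$n_persons, X,
             as.numeric(easiness), log(person_sd), rule)
}

#' Fit the Rasch model by marginal maximum likelihood
#'
#' Estimates 11 item easiness parameters and the person SD by integrating
#' the person effect over a normal distribution (Gauss-Hermite
#' quadrature) and maximizing the marginal likelihood by BFGS with
#' analytic gradients. There is no global intercept: the 11 item
#' indicators plus one variance give 12 parameters. Severity is reported
#' as minus easiness, so higher severity means a higher latent level is
#' required to endorse.
#'
#' @param responses A [response_table()].
#' @param rule A [gh_rule()]; default 41 nodes.
#' @param tol Gradient tolerance for the convergence flag.
#' @param max_iter Maximum BFGS iterations.
#' @param se Compute standard errors from the observed information?
#' @return Object of class `rasch_fit`: easiness, severity, person_sd,
#'   person_var, loglik, deviance, n_params, n_obs, se, converged, n_iter.
#' @export
fit_rasch <- function(responses, rule = gh_rule(), tol = 1e-6,
                      max_iter = 300, se = TRUE) {
  cells <- response_cells(responses)
  for (it in sud_items()) {
    r <- cells$y[cells$item == it]
    if (length(r) == 0 || all(r == 0) || all(r == 1)) {
      stop("item '", it, "' lacks both 0 and 1 responses; ",
           "its parameter is not finite")
    }
  }
  X <- item_indicator_matrix(cells$item)
  fit <- mml_fit(cells$y, cells$pid, cells$n_persons, X, rule,
                 tol = tol, max_iter = max_iter, se = se)
  easiness <- stats::setNames(fit$beta, colnames(X))
  se_vec <- stats::setNames(fit$se_beta, colnames(X))
  structure(list(
    easiness = easiness,
    severity = -easiness,
    person_sd = fit$sigma,
    person_var = fit$sigma^2,
    loglik = fit$loglik,
    deviance = -2 * fit$loglik,
    n_params = length(easiness) + 1L,
    n_obs = length(cells$y),
    n_persons = cells$n_persons,
    se = se_vec,
    se_log_sigma = fit$se_log_sigma,
    converged = fit$converged,
    n_iter = fit$n_iter,
    rule = rule
  ), class = "rasch_fit")
}

#' @export
print.rasch_fit <- function(x, ...) {
  cat("Rasch model (MML,", x$rule$n_nodes, "GH nodes)\n")
  cat(sprintf("  persons %d, observed cells %d, loglik %.1f, deviance %.1f\n",
              x$n_persons, x$n_obs, x$loglik, x$deviance))
  cat(sprintf("  person variance %.2f (SD %.2f)%s\n", x$person_var,
              x$person_sd, if (x$converged) "" else "  [NOT CONVERGED]"))
  print(round(rbind(severity = x$severity), 2))
  invisible(x)
}

#' Model-implied marginal endorsement probability
#'
#' \eqn{\int \mathrm{logit}^{-1}(\theta + \epsilon)\, dN(0, \sigma^2)}:
#' the population endorsement rate implied by an item's easiness and the
#' latent SD. Links the severity column of a fit to the observed
#' prevalence column (the two agree at an MML optimum).
#'
#' @param easiness Scalar (or vector) easiness.
#' @param person_sd Latent SD, may be 0 (collapses to `logistic(easiness)`).
#' @param rule A [gh_rule()].
#' @return Probability (vectorized over `easiness`).
#' @export
marginal_prevalence <- function(easiness, person_sd, rule = gh_rule()) {
  stopifnot(person_sd >= 0)
  if (person_sd == 0) return(logistic(easiness))
  theta <- person_sd * rule$nodes
  sapply(easiness, function(e) sum(rule$weights * logistic(theta + e)))
}

#' EAP latent scores
#'
#' Posterior mean and SD of each person's latent level under a fitted
#' Rasch model, computed on the quadrature grid. A person with no
#' observed responses gets the prior: EAP 0 and posterior SD equal to the
#' fitted person SD. EAPs are shrunk toward 0, so their sample variance
#' is below the fitted person variance.
#'
#' @param responses A [response_table()].
#' @param fit A `rasch_fit`.
#' @param rule A [gh_rule()]; defaults to the fit's rule.
#' @return Data frame: `person_id`, `eap`, `psd`.
#' @export
eap_scores <- function(responses, fit, rule = fit$rule) {
  cells <- response_cells(responses)
  X <- item_indicator_matrix(cells$item)
  parts <- mml_parts(cells$y, cells$pid, cells$n_persons, X,
                     as.numeric(fit$easiness[colnames(X)]),
                     log(fit$person_sd), rule)
  W <- exp(parts$M - parts$ll_j)
  eap <- as.vector(W %*% parts$theta)
  m2 <- as.vector(W %*% parts$theta^2)
  data.frame(person_id = cells$persons, eap = eap,
             psd = sqrt(pmax(m2 - eap^2, 0)))
}

#' Item characteristic curve
#'
#' Endorsement probability of one criterion over a grid of latent levels,
#' \eqn{P(\theta) = \mathrm{logit}^{-1}(\theta - severity_i + dif)}. A
#' nonzero `dif` draws the curve of a group for which the item is easier
#' (positive) or harder (negative) by that many logits -- uniform DIF
#' shifts the whole curve horizontally.
#'
#' @param item Item short-code.
#' @param fit A `rasch_fit` (or `eirm_fit` with item estimates).
#' @param grid Latent levels at which to evaluate.
#' @param dif Uniform easiness shift in logits, default 0.
#' @return Data frame `theta`, `prob`.
#' @export
icc_curve <- function(item, fit, grid = seq(-4, 4, by = 0.1), dif = 0) {
  if (!item %in% names(fit$severity)) stop("unknown item: ", item)
  data.frame(theta = grid,
             prob = logistic(grid - fit$severity[[item]] + dif))
}
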