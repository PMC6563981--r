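# Shared fixtures and the independent dense-grid oracle.

# long response data frame for n persons x all 11 items
make_long <- function(n, fill = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  df <- expand.grid(person_id = sprintf("p%03d", seq_len(n)),
                    item_id = sud_items(),
                    stringsAsFactors = FALSE)
  df$response <- if (is.null(fill)) rbinom(nrow(df), 1, 0.6) else fill
  df
}

# Independent dense-trapezoid oracle for the marginal log-likelihood:
# per person, integrate the Bernoulli product against N(0, sd^2) on a
# 20001-point grid over [-10 sd, 10 sd]. Shares no code with the
# quadrature path.
oracle_marginal_loglik <- function(responses, easiness, sd,
                                   n_grid = 20001) {
  m <- as_response_matrix(responses)
  th <- seq(-10 * sd, 10 * sd, length.out = n_grid)
  dens <- dnorm(th, 0, sd)
  e <- easiness[colnames(m)]
  total <- 0
  for (j in seq_len(nrow(m))) {
    y <- m[j, ]
    obs <- which(!is.na(y))
    eta <- outer(th, e[obs], "+")                     # grid x items
    lf <- eta %*% y[obs] - rowSums(log1p(exp(eta)))
    total <- total + log(pracma::trapz(th, dens * exp(lf)))
  }
  total
}

# a small complete simulated dataset reused across files
small_sim <- function(n = 200, seed = 1, ...) {
  simulate_dataset(generation_config(n_persons = n, seed = seed, ...))
}
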