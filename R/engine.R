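# Internal marginal-ML engine for random-intercept logistic models.
#
# Model for observed cell (j, i):  logit P(Y=1) = x' beta + theta_j,
# theta_j ~ N(0, sigma^2) integrated out by Gauss-Hermite quadrature.
# Parameters: beta (all fixed effects, including the 11 item easiness
# indicators) and log sigma. Objective and analytic gradient are fully
# vectorized over cells x nodes.

# log(1 + exp(x)) without overflow
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# Per-person log marginal likelihood contributions.
# y: 0/1 vector over cells; pid: integer person index (1..n) per cell;
# X: design matrix (cells x p); returns list used by loglik and gradient.
mml_parts <- function(y, pid, n_persons, X, beta, log_sigma, rule) {
  sigma <- exp(log_sigma)
  theta <- sigma * rule$nodes                      # K node values
  v <- as.vector(X %*% beta)                       # fixed part per cell
  E <- outer(v, theta, "+")                        # cells x K linear predictor
  LP <- y * E - softplus(E)                        # cell log-density per node
  lf <- rowsum(LP, pid, reorder = FALSE)           # persons-with-data x K
  # persons with zero observed cells contribute log f = 0 (prior only)
  if (nrow(lf) < n_persons) {
    full <- matrix(0, n_persons, ncol(lf))
    full[as.integer(rownames(lf)), ] <- lf
    lf <- full
  } else {
    lf <- lf[order(as.integer(rownames(lf))), , drop = FALSE]
  }
  M <- sweep(lf, 2, log(rule$weights), "+")
  m <- do.call(pmax, c(as.data.frame(M), list(na.rm = FALSE)))
  ll_j <- m + log(rowSums(exp(M - m)))
  list(E = E, lf = lf, M = M, ll_j = ll_j, theta = theta, v = v)
}

mml_loglik <- function(y, pid, n_persons, X, beta, log_sigma, rule) {
  sum(mml_parts(y, pid, n_persons, X, beta, log_sigma, rule)$ll_j)
}

mml_grad <- function(y, pid, n_persons, X, beta, log_sigma, rule) {
  parts <- mml_parts(y, pid, n_persons, X, beta, log_sigma, rule)
  W <- exp(parts$M - parts$ll_j)                   # posterior node weights, rows sum 1
  R <- y - stats::plogis(parts$E)                  # cells x K residuals
  r_cell <- rowSums(R * W[pid, , drop = FALSE])    # posterior-averaged residual
  g_beta <- as.vector(crossprod(X, r_cell))
  S <- rowsum(R, pid, reorder = FALSE)             # person score sums per node
  if (nrow(S) < n_persons) {
    full <- matrix(0, n_persons, ncol(S))
    full[as.integer(rownames(S)), ] <- S
    S <- full
  } else {
    S <- S[order(as.integer(rownames(S))), , drop = FALSE]
  }
  g_ls <- sum(W * S * matrix(parts$theta, nrow(S), ncol(S), byrow = TRUE))
  c(g_beta, g_ls)
}

# Quasi-Newton maximization of the marginal log-likelihood.
# start: optional c(beta, log_sigma). Returns estimates, loglik, gradient,
# convergence flag, iteration count, and (optionally) the observed-information
# covariance via a central-difference Hessian of the gradient.
mml_fit <- function(y, pid, n_persons, X, rule, start = NULL,
                    tol = 1e-6, max_iter = 300, se = TRUE) {
  p <- ncol(X)
  if (qr(X)$rank < p) {
    stop("design matrix is rank deficient: term set is not identifiable ",
         "(e.g. a full item-by-covariate interaction set together with the ",
         "covariate main effect)")
  }
  if (is.null(start)) {
    # easiness-style start: logit of column-wise endorsement for indicator
    # columns, 0 elsewhere; sigma = 1
    start_beta <- rep(0, p)
    ind <- which(colSums(X == 0 | X == 1) == nrow(X) & colSums(X) > 0)
    for (k in ind) {
      pk <- mean(y[X[, k] == 1])
      start_beta[k] <- stats::qlogis(min(max(pk, 0.02), 0.98))
    }
    start <- c(start_beta, 0)
  }
  negll <- function(par) -mml_loglik(y, pid, n_persons, X,
                                     par[seq_len(p)], par[p + 1], rule)
  neggr <- function(par) -mml_grad(y, pid, n_persons, X,
                                   par[seq_len(p)], par[p + 1], rule)
  opt <- stats::optim(start, negll, neggr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  g <- neggr(opt$par)
  loglik <- -opt$value
  # scale-invariant convergence check on the gradient
  converged <- max(abs(g)) < max(tol, 1e-6 * (1 + abs(loglik)))
  if (!converged) {
    opt2 <- stats::optim(opt$par, negll, neggr, method = "BFGS",
                         control = list(maxit = max_iter, reltol = 1e-12))
    if (opt2$value <= opt$value) opt <- opt2
    g <- neggr(opt$par)
    loglik <- -opt$value
    converged <- max(abs(g)) < max(tol, 1e-6 * (1 + abs(loglik)))
  }
  par <- opt$par
  vcov <- NULL
  se_vec <- rep(NA_real_, p + 1)
  if (se) {
    H <- matrix(0, p + 1, p + 1)
    for (k in seq_len(p + 1)) {
      h <- 1e-4 * max(1, abs(par[k]))
      up <- par; up[k] <- up[k] + h
      dn <- par; dn[k] <- dn[k] - h
      H[, k] <- (neggr(up) - neggr(dn)) / (2 * h)
    }
    H <- (H + t(H)) / 2
    vcov <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(vcov)) {
      d <- diag(vcov)
      se_vec <- ifelse(d > 0, sqrt(pmax(d, 0)), NA_real_)
    }
  }
  list(beta = par[seq_len(p)], log_sigma = par[p + 1],
       sigma = exp(par[p + 1]), loglik = loglik,
       gradient = -g, converged = converged,
       n_iter = opt$counts[["function"]],
       se_beta = se_vec[seq_len(p)], se_log_sigma = se_vec[p + 1],
       vcov = vcov)
}
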