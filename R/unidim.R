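#' Eigenvalues of the item correlation matrix
#'
#' Pearson (phi) correlations between the binary items, eigenvalues in
#' descending order. Items with zero variance are excluded with a
#' warning. Pairwise-complete observations are used.
#'
#' @param responses A [response_table()].
#' @return Numeric vector of eigenvalues (sum = number of retained items).
#' @export
correlation_eigenvalues <- function(responses) {
  R <- item_correlation(responses)
  sort(eigen(R, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

# internal: phi correlation matrix of the 11 items
item_correlation <- function(responses) {
  m <- as_response_matrix(responses)
  v <- apply(m, 2, stats::var, na.rm = TRUE)
  drop <- !is.finite(v) | v == 0
  if (any(drop)) {
    warning("constant or empty item(s) excluded: ",
            paste(colnames(m)[drop], collapse = ", "))
    m <- m[, !drop, drop = FALSE]
  }
  if (ncol(m) < 2) stop("need at least 2 items with variance")
  stats::cor(m, use = "pairwise.complete.obs")
}

#' Single-factor loadings by principal-axis factoring
#'
#' Iterates communalities on the reduced correlation matrix (squared
#' loadings on the diagonal) until the largest change is below `tol`,
#' taking the loading vector from the leading eigenpair at each step.
#' Loadings above 1 (Heywood cases) are clipped with a warning. The
#' overall sign is fixed so the loading sum is positive.
#'
#' @param responses A [response_table()].
#' @param max_iter,tol Iteration controls (defaults 100, 1e-6).
#' @return Named numeric vector of loadings.
#' @export
one_factor_loadings <- function(responses, max_iter = 100, tol = 1e-6) {
  R <- item_correlation(responses)
  k <- ncol(R)
  if (k < 3) stop("single-factor model is under-identified with fewer than 3 items")
  h2 <- 1 - 1 / diag(solve(R))  # SMC start
  for (i in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    lambda <- e$vectors[, 1] * sqrt(max(e$values[1], 0))
    h2_new <- pmin(lambda^2, 1)
    if (max(abs(h2_new - h2)) < tol) {
      h2 <- h2_new
      break
    }
    h2 <- h2_new
  }
  if (sum(lambda) < 0) lambda <- -lambda
  if (any(abs(lambda) > 1)) {
    warning("Heywood case: loading(s) clipped to [-1, 1]")
    lambda <- pmin(pmax(lambda, -1), 1)
  }
  stats::setNames(lambda, colnames(R))
}

#' Coefficient omega from single-factor loadings
#'
#' \eqn{\omega = (\sum\lambda)^2 / ((\sum\lambda)^2 + \sum(1 - \lambda^2))}:
#' the proportion of total-score variance attributable to the common
#' factor under a one-factor model with unit item variances.
#'
#' @param loadings Numeric vector of loadings in (-1, 1).
#' @return Scalar omega in [0, 1].
#' @export
coefficient_omega <- function(loadings) {
  if (length(loadings) == 0) stop("empty loadings")
  s <- sum(loadings)^2
  s / (s + sum(1 - loadings^2))
}

#' Unidimensionality and reliability summary
#'
#' Raw correlation-matrix eigenvalues, reduced-matrix (communality-
#' adjusted, principal-axis) eigenvalues, the proportion of variance
#' carried by the first factor, single-factor loadings and coefficient
#' omega. Both eigenvalue conventions are reported because trailing
#' factor-analysis eigenvalues are near zero where raw PCA eigenvalues
#' are not.
#'
#' @param responses A [response_table()].
#' @return Object of class `unidim_summary`.
#' @export
unidim_summary <- function(responses) {
  ev <- correlation_eigenvalues(responses)
  lambda <- one_factor_loadings(responses)
  R <- item_correlation(responses)
  Rr <- R
  diag(Rr) <- pmin(lambda^2, 1)
  ev_reduced <- sort(eigen(Rr, symmetric = TRUE, only.values = TRUE)$values,
                     decreasing = TRUE)
  structure(list(eigenvalues = ev,
                 eigenvalues_reduced = ev_reduced,
                 prop_var_first = ev[1] / sum(ev),
                 loadings = lambda,
                 omega = coefficient_omega(lambda)),
            class = "unidim_summary")
}

#' @export
print.unidim_summary <- function(x, ...) {
  cat("Unidimensionality summary\n")
  cat("  leading eigenvalues (raw):    ",
      paste(sprintf("%.2f", utils::head(x$eigenvalues, 5)), collapse = ", "), "\n")
  cat("  leading eigenvalues (reduced):",
      paste(sprintf("%.2f", utils::head(x$eigenvalues_reduced, 5)), collapse = ", "), "\n")
  cat(sprintf("  first factor carries %.0f%% of variance\n",
              100 * x$prop_var_first))
  cat(sprintf("  loadings in [%.2f, %.2f], omega %.2f\n",
              min(x$loadings), max(x$loadings), x$omega))
  invisible(x)
}
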