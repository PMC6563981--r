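#' Explanatory model specification
#'
#' A model spec names the fixed-effect structure added on top of the 11
#' item indicators (which are always present, with no global intercept):
#' person covariate main effects, person-by-person interactions, optional
#' item-property (LLTM-style) terms, and item-by-covariate (uniform DIF)
#' terms.
#'
#' @param name Label, e.g. `"model3"`.
#' @param person Character vector of covariate main effects.
#' @param interactions Character vector of `"a:b"` covariate products.
#' @param dif List of `c(item_id, covariate)` pairs; each adds one column
#'   `covariate x 1[item]`, the uniform-DIF contrast of Eq.-style
#'   item-person interaction terms.
#' @param item_properties Optional data frame (`item_id` + numeric
#'   property columns) replacing the 11 indicators by a linear item-side
#'   model; unused in the replication ladder.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(name, person = character(), interactions = character(),
                       dif = list(), item_properties = NULL) {
  person <- as.character(person)
  interactions <- as.character(interactions)
  if (anyDuplicated(c(person, interactions))) stop("duplicated terms in spec")
  for (d in dif) {
    if (length(d) != 2) stop("each dif term is c(item, covariate)")
    if (!d[1] %in% sud_items()) stop("dif term names unknown item: ", d[1])
  }
  if (anyDuplicated(vapply(dif, paste, "", collapse = ":"))) {
    stop("duplicated dif terms")
  }
  structure(list(name = name, person = person, interactions = interactions,
                 dif = dif, item_properties = item_properties),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec '", x$name, "': 11 item indicators", sep = "")
  if (length(x$person)) cat(" + ", paste(x$person, collapse = " + "))
  if (length(x$interactions)) cat(" + ", paste(x$interactions, collapse = " + "))
  if (length(x$dif)) {
    cat(" + ", paste(vapply(x$dif, paste, "", collapse = ":"), collapse = " + "))
  }
  cat(" + person variance\n")
  invisible(x)
}

#' The shipped model ladder
#'
#' The canonical nested sequence: a covariate-free null model; gender and
#' alcohol-use main effects (model 1); their interaction (model 2); the
#' four personality scores (model 3); gender-by-personality interactions
#' (model 4); alcohol-by-personality interactions (model 5, nested in
#' model 3, not model 4).
#'
#' @return Named list of [model_spec()] objects
#'   (`null`, `m1`, ..., `m5`).
#' @export
canonical_specs <- function() {
  pers <- c("hopelessness", "impulsivity", "sensation_seeking",
            "anxiety_sensitivity")
  list(
    null = model_spec("null"),
    m1 = model_spec("m1", person = c("gender_female", "alcohol_no")),
    m2 = model_spec("m2", person = c("gender_female", "alcohol_no"),
                    interactions = "gender_female:alcohol_no"),
    m3 = model_spec("m3", person = c("gender_female", "alcohol_no", pers),
                    interactions = "gender_female:alcohol_no"),
    m4 = model_spec("m4", person = c("gender_female", "alcohol_no", pers),
                    interactions = c("gender_female:alcohol_no",
                                     paste0("gender_female:", pers))),
    m5 = model_spec("m5", person = c("gender_female", "alcohol_no", pers),
                    interactions = c("gender_female:alcohol_no",
                                     paste0("alcohol_no:", pers)))
  )
}

#' Model degrees of freedom (parameter count)
#'
#' 11 item parameters + one per non-item fixed-effect term + 1 for the
#' person variance. The shipped ladder gives 12, 14, 15, 19, 23, 23.
#'
#' @param spec A [model_spec()].
#' @return Integer parameter count.
#' @export
model_df <- function(spec) {
  n_item <- if (is.null(spec$item_properties)) 11L else
    ncol(spec$item_properties) - 1L
  n_item + length(spec$person) + length(spec$interactions) +
    length(spec$dif) + 1L
}

# internal: is `small` nested in `large` (term-set inclusion)?
spec_nested <- function(small, large) {
  all(small$person %in% large$person) &&
    all(small$interactions %in% large$interactions) &&
    all(vapply(small$dif, paste, "", collapse = ":") %in%
          vapply(large$dif, paste, "", collapse = ":"))
}

#' Build the long design matrix for an explanatory model
#'
#' One row per observed (person, item) cell: 11 item indicator columns
#' (or item-property columns), then person covariates replicated over the
#' person's rows, covariate products, and item-by-covariate DIF columns,
#' in deterministic order.
#'
#' @param responses A [response_table()].
#' @param covariates Complete covariate data frame.
#' @param spec A [model_spec()].
#' @return List: `X` (cells x p matrix), `y`, `pid`, `n_persons`,
#'   `persons`, `term_type` (character tag per column).
#' @export
build_design <- function(responses, covariates, spec) {
  cells <- response_cells(responses)
  if (!all(cells$persons %in% covariates$person_id)) {
    stop("covariates missing for some persons in the response table")
  }
  cov <- covariates[match(cells$persons, covariates$person_id), , drop = FALSE]
  if (is.null(spec$item_properties)) {
    Xi <- item_indicator_matrix(cells$item)
    type <- rep("item", ncol(Xi))
  } else {
    ip <- spec$item_properties
    Xi <- as.matrix(ip[match(cells$item, ip$item_id),
                       setdiff(names(ip), "item_id"), drop = FALSE])
    type <- rep("item_property", ncol(Xi))
  }
  covcol <- function(nm) {
    if (!nm %in% names(cov)) stop("unknown covariate in spec: ", nm)
    v <- cov[[nm]][cells$pid]
    if (anyNA(v)) stop("missing values in modeled covariate '", nm,
                       "'; run filter_complete_cases first")
    v
  }
  Xp <- list()
  for (nm in spec$person) Xp[[nm]] <- covcol(nm)
  for (nm in spec$interactions) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("interaction must be 'a:b': ", nm)
    Xp[[nm]] <- covcol(parts[1]) * covcol(parts[2])
  }
  for (d in spec$dif) {
    Xp[[paste0(d[1], ":", d[2])]] <-
      covcol(d[2]) * as.numeric(cells$item == d[1])
  }
  X <- if (length(Xp) == 0) Xi else
    cbind(Xi, do.call(cbind, Xp))
  type <- c(type, rep("person", length(spec$person)),
            rep("interaction", length(spec$interactions)),
            rep("dif", length(spec$dif)))
  list(X = X, y = cells$y, pid = cells$pid, n_persons = cells$n_persons,
       persons = cells$persons, term_type = type)
}

#' Fit an explanatory item response model
#'
#' Marginal ML for the latent-regression Rasch model: all fixed effects
#' of the spec plus a residual person effect \eqn{\theta_j \sim
#' N(0, \sigma^2)} integrated by quadrature. The person variance is
#' re-estimated in every model; in covariate models it is the residual
#' variance after the covariate effects. Wald z and two-sided normal
#' p-values are attached per term.
#'
#' @param responses A [response_table()].
#' @param covariates Complete covariate data frame.
#' @param spec A [model_spec()].
#' @param rule A [gh_rule()].
#' @param tol,max_iter Optimizer controls.
#' @param se Compute standard errors?
#' @param start Optional warm-start `c(beta, log_sigma)` (extra terms
#'   padded with 0), e.g. from a nested fit.
#' @return Object of class `eirm_fit`.
#' @export
fit_eirm <- function(responses, covariates, spec, rule = gh_rule(),
                     tol = 1e-6, max_iter = 300, se = TRUE, start = NULL) {
  d <- build_design(responses, covariates, spec)
  fit <- mml_fit(d$y, d$pid, d$n_persons, d$X, rule, start = start,
                 tol = tol, max_iter = max_iter, se = se)
  est <- stats::setNames(fit$beta, colnames(d$X))
  sev <- stats::setNames(fit$se_beta, colnames(d$X))
  z <- est / sev
  item_ix <- d$term_type == "item"
  structure(list(
    spec = spec,
    estimates = est,
    se = sev,
    z = z,
    p = 2 * stats::pnorm(-abs(z)),
    term_type = stats::setNames(d$term_type, colnames(d$X)),
    easiness = est[item_ix],
    severity = -est[item_ix],
    person_sd = fit$sigma,
    person_var = fit$sigma^2,
    loglik = fit$loglik,
    deviance = -2 * fit$loglik,
    n_params = ncol(d$X) + 1L,
    n_obs = length(d$y),
    n_persons = d$n_persons,
    aic = -2 * fit$loglik + 2 * (ncol(d$X) + 1L),
    bic = -2 * fit$loglik + log(length(d$y)) * (ncol(d$X) + 1L),
    converged = fit$converged,
    n_iter = fit$n_iter,
    par = c(fit$beta, fit$log_sigma),
    rule = rule
  ), class = "eirm_fit")
}

#' @export
print.eirm_fit <- function(x, ...) {
  cat("EIRM fit '", x$spec$name, "' (MML, ", x$rule$n_nodes, " GH nodes)\n",
      sep = "")
  cat(sprintf("  persons %d, cells %d, df %d, deviance %.1f, AIC %.1f, BIC %.1f\n",
              x$n_persons, x$n_obs, x$n_params, x$deviance, x$aic, x$bic))
  cat(sprintf("  person variance %.2f (SD %.2f)%s\n", x$person_var, x$person_sd,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  nonitem <- names(x$estimates)[x$term_type != "item"]
  if (length(nonitem)) print(wald_table(x)[nonitem, ], digits = 3)
  invisible(x)
}

#' Wald inference table
#'
#' Estimate, SE, z, two-sided normal p and star coding (`***` p < .001,
#' `**` p < .01, `*` p < .05; a p exactly at a boundary is not starred at
#' that level) for every fixed effect of a fit, in the "estimate(SE)"
#' style of a fixed-effects report table.
#'
#' @param fit An `eirm_fit` (or `rasch_fit` restricted to items).
#' @param terms Which terms; default all non-item terms, or all items if
#'   there are none.
#' @return Data frame with `estimate`, `se`, `z`, `p`, `stars`,
#'   `formatted`.
#' @export
wald_table <- function(fit, terms = NULL) {
  if (is.null(terms)) {
    terms <- names(fit$estimates)
  }
  est <- fit$estimates[terms]
  se <- fit$se[terms]
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  stars <- ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                  ifelse(p < 0.05, "*", "")))
  data.frame(term = terms, estimate = est, se = se, z = z, p = p,
             stars = stars,
             formatted = sprintf("%.2f%s(%.2f)", est, stars, se),
             row.names = terms)
}
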