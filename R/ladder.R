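#' Likelihood-ratio test for nested explanatory models
#'
#' Statistic = deviance(small) - deviance(large), referred to a
#' chi-square with df equal to the difference in parameter counts.
#'
#' @param fit_small,fit_large Nested `eirm_fit` objects (small in large).
#' @return List `stat`, `delta_df`, `p`.
#' @export
lr_test <- function(fit_small, fit_large) {
  if (!spec_nested(fit_small$spec, fit_large$spec)) {
    stop("'", fit_small$spec$name, "' is not nested in '",
         fit_large$spec$name, "'")
  }
  stat <- fit_small$deviance - fit_large$deviance
  if (stat < -1e-6) {
    warning("negative LR statistic (", format(stat),
            "): one of the fits has not converged")
  }
  stat <- max(stat, 0)
  delta_df <- fit_large$n_params - fit_small$n_params
  if (delta_df <= 0) stop("larger model must add parameters")
  list(stat = stat, delta_df = delta_df,
       p = stats::pchisq(stat, delta_df, lower.tail = FALSE))
}

#' Akaike information criterion from deviance
#'
#' `aic = deviance + 2 k`.
#'
#' @param deviance Model deviance (-2 log-likelihood).
#' @param n_params Parameter count k.
#' @return Scalar AIC.
#' @export
aic <- function(deviance, n_params) {
  if (n_params < 1) warning("n_params < 1: criterion equals the deviance")
  deviance + 2 * max(n_params, 0)
}

#' Bayesian information criterion from deviance
#'
#' `bic = deviance + log(n_obs) k`, where `n_obs` is the number of
#' observed response cells (persons x items minus missing) -- the sample
#' size under which the reported criteria are internally consistent.
#'
#' @param deviance Model deviance.
#' @param n_params Parameter count k.
#' @param n_obs Number of observed response cells.
#' @return Scalar BIC.
#' @export
bic <- function(deviance, n_params, n_obs) {
  stopifnot(n_obs >= 1)
  if (n_params < 1) warning("n_params < 1: criterion equals the deviance")
  deviance + log(n_obs) * max(n_params, 0)
}

#' Fit the nested model ladder
#'
#' Fits an ordered list of specs and runs the comparison plan
#' null-m1, m1-m2, m2-m3, m3-m4, m3-m5 (model 5 is compared against
#' model 3, in which it is nested, not against model 4). Each fit warm-
#' starts from the previous nested fit.
#'
#' @param responses A [response_table()].
#' @param covariates Complete covariate data frame.
#' @param specs Named list of [model_spec()]s, default [canonical_specs()].
#' @param rule A [gh_rule()].
#' @param comparisons List of `c(small, large)` name pairs; default the
#'   canonical plan restricted to the specs supplied.
#' @param se Compute standard errors (needed for the Wald columns)?
#' @return Object of class `ladder_result`: `fits` (named list),
#'   `comparisons` (data frame small, large, lr_stat, delta_df, p).
#' @export
run_ladder <- function(responses, covariates, specs = canonical_specs(),
                       rule = gh_rule(), comparisons = NULL, se = TRUE) {
  if (is.null(comparisons)) {
    plan <- list(c("null", "m1"), c("m1", "m2"), c("m2", "m3"),
                 c("m3", "m4"), c("m3", "m5"))
    comparisons <- Filter(function(p) all(p %in% names(specs)), plan)
  }
  for (p in comparisons) {
    if (!spec_nested(specs[[p[1]]], specs[[p[2]]])) {
      stop("comparison plan violates nesting: '", p[1],
           "' is not nested in '", p[2], "'")
    }
  }
  fits <- list()
  for (nm in names(specs)) {
    start <- NULL
    # warm start from the largest already-fitted nested spec
    for (prev in rev(names(fits))) {
      if (spec_nested(fits[[prev]]$spec, specs[[nm]])) {
        start <- pad_start(fits[[prev]], responses, covariates, specs[[nm]])
        break
      }
    }
    fits[[nm]] <- fit_eirm(responses, covariates, specs[[nm]], rule,
                           se = se, start = start)
    if (!fits[[nm]]$converged) {
      warning("fit '", nm, "' did not converge; ladder aborted with ",
              "partial results")
      break
    }
  }
  comp <- do.call(rbind, lapply(comparisons, function(p) {
    if (!all(p %in% names(fits))) return(NULL)
    t <- lr_test(fits[[p[1]]], fits[[p[2]]])
    data.frame(smaller = p[1], larger = p[2], lr_stat = t$stat,
               delta_df = t$delta_df, p = t$p)
  }))
  structure(list(fits = fits, comparisons = comp), class = "ladder_result")
}

# internal: map a nested fit's parameters onto a larger spec's columns
pad_start <- function(fit, responses, covariates, spec) {
  cols <- colnames(build_design(responses[seq_len(min(nrow(responses), 22)), ,
                                          drop = FALSE],
                                covariates, spec)$X)
  beta <- stats::setNames(rep(0, length(cols)), cols)
  shared <- intersect(names(fit$estimates), cols)
  beta[shared] <- fit$estimates[shared]
  c(as.numeric(beta), log(fit$person_sd))
}

#' @export
print.ladder_result <- function(x, ...) {
  cat("Model ladder:", paste(names(x$fits), collapse = " -> "), "\n")
  tab <- ladder_table(x)
  print(tab[c("deviance", "df", "aic", "bic"), ], digits = 1)
  cat("\nLR comparisons:\n")
  print(x$comparisons, digits = 3)
  invisible(x)
}

#' Fixed-effects and comparison report table for a ladder
#'
#' Assembles the familiar report layout: one column per model, rows for
#' the person variance ("var(sd)"), every covariate term as
#' "estimate(SE)" with stars, then AIC, BIC, deviance, df, delta-df and
#' the LR statistic of each planned comparison.
#'
#' @param ladder A `ladder_result`.
#' @return Character matrix (rows = report lines, columns = models).
#' @export
ladder_table <- function(ladder) {
  fits <- ladder$fits
  terms <- unique(unlist(lapply(fits, function(f)
    names(f$estimates)[f$term_type != "item"])))
  rows <- c("variance", terms, "aic", "bic", "deviance", "df",
            "delta_df", "lr_stat")
  tab <- matrix("", length(rows), length(fits),
                dimnames = list(rows, names(fits)))
  for (nm in names(fits)) {
    f <- fits[[nm]]
    tab["variance", nm] <- sprintf("%.2f(%.2f)", f$person_var, f$person_sd)
    wt <- wald_table(f)
    for (tm in intersect(terms, rownames(wt))) {
      tab[tm, nm] <- wt[tm, "formatted"]
    }
    tab["aic", nm] <- sprintf("%.1f", f$aic)
    tab["bic", nm] <- sprintf("%.1f", f$bic)
    tab["deviance", nm] <- sprintf("%.1f", f$deviance)
    tab["df", nm] <- sprintf("%d", f$n_params)
  }
  if (!is.null(ladder$comparisons)) {
    for (k in seq_len(nrow(ladder$comparisons))) {
      cmp <- ladder$comparisons[k, ]
      stars <- ifelse(cmp$p < 0.001, "***",
                      ifelse(cmp$p < 0.01, "**", ifelse(cmp$p < 0.05, "*", "")))
      tab["delta_df", cmp$larger] <- sprintf("%d", cmp$delta_df)
      tab["lr_stat", cmp$larger] <- sprintf("%.2f%s", cmp$lr_stat, stars)
    }
  }
  tab
}

#' Scan all items for uniform DIF against person covariates
#'
#' For each (item, covariate) pair, refits the base model augmented with
#' the single item-by-covariate interaction (all other items anchor the
#' scale) and records the interaction's Wald test. A positive estimate
#' means the item is easier to endorse for the indicator-1 group (or for
#' higher covariate values), the convention of the DIF report table.
#'
#' @param responses A [response_table()].
#' @param covariates Complete covariate data frame.
#' @param base_spec Base [model_spec()]; the scanned covariate's main
#'   effect should normally be in it.
#' @param scan_covariates Covariate names to scan.
#' @param items Items to scan, default all 11.
#' @param alpha Flagging level, default 0.05.
#' @param correction `"none"` or `"BH"` (Benjamini-Hochberg within the
#'   scan).
#' @param rule A [gh_rule()].
#' @return Object of class `dif_result`: data frame `table` with
#'   `item_id`, `covariate`, `estimate`, `se`, `z`, `p`, `p_adj`, `flag`,
#'   plus `alpha`, `correction`, `base` metadata.
#' @export
dif_scan <- function(responses, covariates, base_spec = canonical_specs()$m3,
                     scan_covariates = sud_covariates(),
                     items = sud_items(), alpha = 0.05,
                     correction = c("none", "BH"), rule = gh_rule()) {
  correction <- match.arg(correction)
  missing_cov <- setdiff(scan_covariates, names(covariates))
  if (length(missing_cov) > 0) {
    stop("covariate(s) absent from data: ", paste(missing_cov, collapse = ", "))
  }
  base <- fit_eirm(responses, covariates, base_spec, rule, se = FALSE)
  if (!base$converged) stop("base model did not converge")
  rows <- list()
  for (cv in scan_covariates) {
    for (it in items) {
      spec_aug <- model_spec(paste0(base_spec$name, "+", it, ":", cv),
                             person = base_spec$person,
                             interactions = base_spec$interactions,
                             dif = c(base_spec$dif, list(c(it, cv))))
      start <- pad_start(base, responses, covariates, spec_aug)
      fit <- tryCatch(
        fit_eirm(responses, covariates, spec_aug, rule, start = start),
        error = function(e) NULL)
      nm <- paste0(it, ":", cv)
      if (is.null(fit) || !fit$converged || !is.finite(fit$se[nm])) {
        rows[[nm]] <- data.frame(item_id = it, covariate = cv,
                                 estimate = NA_real_, se = NA_real_,
                                 z = NA_real_, p = NA_real_)
        next
      }
      rows[[nm]] <- data.frame(item_id = it, covariate = cv,
                               estimate = unname(fit$estimates[nm]),
                               se = unname(fit$se[nm]),
                               z = unname(fit$z[nm]),
                               p = unname(fit$p[nm]))
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$p_adj <- if (correction == "BH") stats::p.adjust(tab$p, "BH") else tab$p
  tab$flag <- !is.na(tab$p_adj) & tab$p_adj < alpha
  structure(list(table = tab, alpha = alpha, correction = correction,
                 base = base_spec$name, anchor = "all-other-items"),
            class = "dif_result")
}

#' @export
print.dif_result <- function(x, ...) {
  cat(sprintf("Uniform DIF scan (base '%s', alpha %.3g, correction %s)\n",
              x$base, x$alpha, x$correction))
  flagged <- x$table[x$table$flag %in% TRUE, ]
  if (nrow(flagged) == 0) {
    cat("no items flagged\n")
  } else {
    print(flagged, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' DIF results as an items-by-covariates report table
#'
#' Flagged cells show "estimate*(SE)" with stars; unflagged cells are
#' empty, matching the layout of a DIF summary table.
#'
#' @param dif A `dif_result`.
#' @return Character matrix items x covariates.
#' @export
dif_table <- function(dif) {
  tab <- dif$table
  items <- unique(tab$item_id)
  covs <- unique(tab$covariate)
  out <- matrix("", length(items), length(covs),
                dimnames = list(items, covs))
  for (k in seq_len(nrow(tab))) {
    if (isTRUE(tab$flag[k])) {
      p <- tab$p_adj[k]
      stars <- ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", "*"))
      out[tab$item_id[k], tab$covariate[k]] <-
        sprintf("%.2f%s(%.2f)", tab$estimate[k], stars, tab$se[k])
    }
  }
  out
}
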