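#' Run configuration for the report pipeline
#'
#' Bundles everything a pipeline step needs: either input CSV paths or a
#' generator config, the model specs, quadrature size, DIF settings and
#' the seed. The config is echoed as JSON into every output directory so
#' a run can be regenerated exactly.
#'
#' @param responses Path to a responses CSV, or `NULL` to simulate.
#' @param covariates Path to a covariates CSV, or `NULL` to simulate.
#' @param layout Layout of the responses CSV.
#' @param generator A [generation_config()] used when no input paths are
#'   given.
#' @param specs Named list of [model_spec()]s.
#' @param n_nodes Quadrature size.
#' @param alpha DIF flagging level.
#' @param correction `"none"` or `"BH"`.
#' @param seed Integer seed for any stochastic step.
#' @return Object of class `run_config`.
#' @export
run_config <- function(responses = NULL, covariates = NULL,
                       layout = "wide", generator = generation_config(),
                       specs = canonical_specs(), n_nodes = 41,
                       alpha = 0.05, correction = "none", seed = 1L) {
  structure(list(responses = responses, covariates = covariates,
                 layout = layout, generator = generator, specs = specs,
                 n_nodes = n_nodes, alpha = alpha, correction = correction,
                 seed = as.integer(seed)),
            class = "run_config")
}

# internal: serialize the run config next to the outputs
echo_config <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ser <- config
  ser$generator$severities <- as.list(ser$generator$severities)
  ser$generator$fixed_effects <- as.list(ser$generator$fixed_effects)
  ser$generator$personality_cor <-
    apply(ser$generator$personality_cor, 1, as.list)
  ser$specs <- lapply(ser$specs, unclass)
  jsonlite::write_json(lapply(unclass(ser), function(x)
    if (inherits(x, "generation_config")) unclass(x) else x),
    file.path(out_dir, "run_config.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

# internal: load or simulate the analysis inputs
resolve_inputs <- function(config) {
  if (!is.null(config$responses) && !is.null(config$covariates)) {
    list(responses = load_responses(config$responses, config$layout),
         covariates = load_covariates(config$covariates),
         theta_true = NULL)
  } else {
    gen <- config$generator
    gen$seed <- config$seed
    sim <- simulate_dataset(gen)
    list(responses = sim$responses, covariates = sim$covariates,
         theta_true = sim$theta_true)
  }
}

#' Simulate and write a dataset to disk
#'
#' Writes `responses.csv` (wide), `covariates.csv`, `theta_true.csv` and
#' the echoed `run_config.json`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
pipeline_simulate <- function(config = run_config(), out_dir) {
  echo_config(config, out_dir)
  gen <- config$generator
  gen$seed <- config$seed
  sim <- simulate_dataset(gen)
  write_responses(sim$responses, file.path(out_dir, "responses.csv"), "wide")
  utils::write.csv(sim$covariates, file.path(out_dir, "covariates.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(data.frame(person_id = sim$covariates$person_id,
                              theta_true = sim$theta_true),
                   file.path(out_dir, "theta_true.csv"), row.names = FALSE)
  invisible(file.path(out_dir, c("responses.csv", "covariates.csv",
                                 "theta_true.csv", "run_config.json")))
}

#' Covariate-free Rasch fit with descriptives and scores
#'
#' Writes `table3.csv` (item descriptives with fitted severities),
#' `fig1_eap.csv` (per-person EAP scores for the latent-score histogram)
#' and `unidim.csv` (eigenvalues in both conventions, loadings, omega).
#'
#' @inheritParams pipeline_simulate
#' @return The `rasch_fit`, invisibly.
#' @export
pipeline_fit <- function(config = run_config(), out_dir) {
  echo_config(config, out_dir)
  inp <- resolve_inputs(config)
  cc <- filter_complete_cases(inp$responses, inp$covariates)
  fit <- fit_rasch(cc$responses, gh_rule(config$n_nodes))
  desc <- describe_items(cc$responses)
  desc$severity <- as.numeric(fit$severity[desc$item_id])
  utils::write.csv(desc, file.path(out_dir, "table3.csv"), row.names = FALSE)
  utils::write.csv(eap_scores(cc$responses, fit),
                   file.path(out_dir, "fig1_eap.csv"), row.names = FALSE)
  uni <- unidim_summary(cc$responses)
  k <- length(uni$eigenvalues)
  utils::write.csv(
    data.frame(rank = seq_len(k),
               eigenvalue_raw = uni$eigenvalues,
               eigenvalue_reduced = uni$eigenvalues_reduced,
               loading = as.numeric(uni$loadings),
               item_id = names(uni$loadings),
               omega = rep(uni$omega, k),
               prop_var_first = rep(uni$prop_var_first, k)),
    file.path(out_dir, "unidim.csv"), row.names = FALSE)
  invisible(fit)
}

#' Run the model ladder and write the comparison table
#'
#' Writes `table4.csv` (the report-shaped character table) and
#' `table4.json` (full-precision fits and comparisons).
#'
#' @inheritParams pipeline_simulate
#' @return The `ladder_result`, invisibly.
#' @export
pipeline_ladder <- function(config = run_config(), out_dir) {
  echo_config(config, out_dir)
  inp <- resolve_inputs(config)
  cc <- filter_complete_cases(inp$responses, inp$covariates)
  ladder <- run_ladder(cc$responses, cc$covariates, config$specs,
                       gh_rule(config$n_nodes))
  tab <- ladder_table(ladder)
  utils::write.csv(data.frame(row = rownames(tab), tab,
                              check.names = FALSE),
                   file.path(out_dir, "table4.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(fits = lapply(ladder$fits, function(f) list(
      name = f$spec$name, estimates = as.list(f$estimates),
      se = as.list(f$se), person_var = f$person_var,
      loglik = f$loglik, deviance = f$deviance, df = f$n_params,
      aic = f$aic, bic = f$bic, converged = f$converged)),
      comparisons = ladder$comparisons),
    file.path(out_dir, "table4.json"), auto_unbox = TRUE, digits = NA)
  invisible(ladder)
}

#' Run the DIF scan and write the DIF table and ICC series
#'
#' Writes `table5.csv` (long scan results), `table5_matrix.csv`
#' (items-by-covariates report shape) and, for every flagged
#' (item, binary covariate) pair, a `fig2_icc_<item>.csv` with the
#' reference and focal ICC series.
#'
#' @inheritParams pipeline_simulate
#' @param base_spec Base model for the scan.
#' @param scan_covariates Covariates to scan.
#' @return The `dif_result`, invisibly.
#' @export
pipeline_dif <- function(config = run_config(), out_dir,
                         base_spec = config$specs$m3,
                         scan_covariates = sud_covariates()) {
  echo_config(config, out_dir)
  inp <- resolve_inputs(config)
  cc <- filter_complete_cases(inp$responses, inp$covariates)
  dif <- dif_scan(cc$responses, cc$covariates, base_spec, scan_covariates,
                  alpha = config$alpha, correction = config$correction,
                  rule = gh_rule(config$n_nodes))
  utils::write.csv(dif$table, file.path(out_dir, "table5.csv"),
                   row.names = FALSE)
  m <- dif_table(dif)
  utils::write.csv(data.frame(item_id = rownames(m), m, check.names = FALSE),
                   file.path(out_dir, "table5_matrix.csv"), row.names = FALSE)
  fit0 <- fit_rasch(cc$responses, gh_rule(config$n_nodes))
  flagged <- dif$table[dif$table$flag %in% TRUE &
                         dif$table$covariate %in% c("gender_female",
                                                    "alcohol_no"), ]
  for (k in seq_len(nrow(flagged))) {
    it <- flagged$item_id[k]
    ref <- icc_curve(it, fit0)
    foc <- icc_curve(it, fit0, dif = flagged$estimate[k])
    utils::write.csv(
      data.frame(theta = ref$theta, prob_reference = ref$prob,
                 prob_focal = foc$prob,
                 covariate = flagged$covariate[k]),
      file.path(out_dir, sprintf("fig2_icc_%s.csv", gsub(" ", "_", it))),
      row.names = FALSE)
  }
  invisible(dif)
}

#' Full report pipeline
#'
#' Runs simulate (when no input paths are given), fit, ladder and DIF
#' into one output directory and writes a short run log.
#'
#' @inheritParams pipeline_simulate
#' @return List with the fit, ladder and DIF results, invisibly.
#' @export
pipeline_report <- function(config = run_config(), out_dir) {
  t0 <- Sys.time()
  echo_config(config, out_dir)
  if (is.null(config$responses)) pipeline_simulate(config, out_dir)
  fit <- pipeline_fit(config, out_dir)
  ladder <- pipeline_ladder(config, out_dir)
  dif <- pipeline_dif(config, out_dir)
  writeLines(c(
    sprintf("sudirt %s | R %s", as.character(utils::packageVersion("sudirt")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed %d, %d GH nodes, alpha %.3g (%s)", config$seed,
            config$n_nodes, config$alpha, config$correction),
    sprintf("elapsed %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))),
    file.path(out_dir, "run_log.txt"))
  invisible(list(fit = fit, ladder = ladder, dif = dif))
}
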