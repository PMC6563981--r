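#' The 11 DSM-5 SUD criterion short-codes
#'
#' Fixed item set and order used throughout the package. The order follows
#' the conventional presentation of the criteria (larger amounts, cut down,
#' time spent, craving, major role, social, give up, hazard, consistent use,
#' tolerance, withdrawal) so that every report table is deterministic.
#'
#' @return Character vector of length 11.
#' @export
sud_items <- function() {
  c("Larger", "Cut down", "Time spent", "Craving", "Major role", "Social",
    "Give up", "Hazard", "Consistent use", "Tolerance", "Withdrawal")
}

#' Names of the person covariates
#'
#' Binary indicators are coded female = 1 (reference male) and
#' non-drinker = 1 (reference drinker); the four personality scores are
#' continuous and are z-standardized before modeling.
#'
#' @return Character vector of the six covariate column names.
#' @export
sud_covariates <- function() {
  c("gender_female", "alcohol_no", "hopelessness", "impulsivity",
    "sensation_seeking", "anxiety_sensitivity")
}

#' Construct and validate a response table
#'
#' A response table is a long data frame with columns `person_id`,
#' `item_id` and `response`, one row per observed (person, item) cell.
#' Responses are 0/1; missing responses may be kept as `NA` rows or
#' dropped -- the likelihood only ever sums over observed cells.
#'
#' @param df Data frame with columns `person_id`, `item_id`, `response`.
#' @param drop_missing Drop rows with `NA` response? Default `FALSE`.
#' @return Validated `response_table` (a data frame).
#' @export
response_table <- function(df, drop_missing = FALSE) {
  need <- c("person_id", "item_id", "response")
  if (!all(need %in% names(df))) {
    stop("response table needs columns: ", paste(need, collapse = ", "))
  }
  df <- df[need]
  df$person_id <- as.character(df$person_id)
  df$item_id <- as.character(df$item_id)
  bad_item <- setdiff(unique(df$item_id), sud_items())
  if (length(bad_item) > 0) {
    stop("unknown item_id: ", paste(bad_item, collapse = ", "))
  }
  ok <- df$response %in% c(0, 1) | is.na(df$response)
  if (!all(ok)) {
    i <- which(!ok)[1]
    stop(sprintf("response outside {0,1,NA} for person '%s', item '%s'",
                 df$person_id[i], df$item_id[i]))
  }
  key <- paste(df$person_id, df$item_id, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop(sprintf("duplicated (person,item) pair: person '%s', item '%s'",
                 df$person_id[i], df$item_id[i]))
  }
  if (drop_missing) df <- df[!is.na(df$response), , drop = FALSE]
  # canonical ordering: person, then the fixed item order
  df <- df[order(df$person_id, match(df$item_id, sud_items())), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("response_table", "data.frame")
  df
}

#' Read a response table from CSV
#'
#' @param path CSV file. Wide layout: `person_id` plus one column per
#'   criterion short-code. Long layout: `person_id,item_id,response`.
#' @param layout `"wide"` or `"long"`.
#' @param drop_missing Drop `NA` cells after reading? Default `TRUE` for
#'   wide input (unobserved cells carry no information), `FALSE` for long.
#' @return A [response_table()].
#' @export
load_responses <- function(path, layout = c("wide", "long"),
                           drop_missing = (layout == "wide")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (layout == "wide") {
    if (!"person_id" %in% names(df)) stop("wide layout needs a person_id column")
    item_cols <- setdiff(names(df), "person_id")
    bad <- setdiff(item_cols, sud_items())
    if (length(bad) > 0) stop("unknown item columns: ", paste(bad, collapse = ", "))
    long <- data.frame(
      person_id = rep(as.character(df$person_id), times = length(item_cols)),
      item_id = rep(item_cols, each = nrow(df)),
      response = unlist(df[item_cols], use.names = FALSE)
    )
    response_table(long, drop_missing = drop_missing)
  } else {
    response_table(df, drop_missing = drop_missing)
  }
}

#' Write a response table to CSV
#'
#' Inverse of [load_responses()]: `load_responses(write_responses(x))`
#' reproduces `x` record for record.
#'
#' @param x A [response_table()].
#' @param path Output CSV path.
#' @param layout `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_responses <- function(x, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (layout == "long") {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  } else {
    wide <- as_response_matrix(x)
    out <- data.frame(person_id = rownames(wide), wide, check.names = FALSE)
    utils::write.csv(out, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Response table as persons-by-items matrix
#'
#' @param x A [response_table()].
#' @return Numeric matrix, rows = persons (sorted ids), columns = the 11
#'   items in fixed order; unobserved cells are `NA`.
#' @export
as_response_matrix <- function(x) {
  persons <- sort(unique(x$person_id))
  m <- matrix(NA_real_, length(persons), length(sud_items()),
              dimnames = list(persons, sud_items()))
  m[cbind(match(x$person_id, persons), match(x$item_id, sud_items()))] <-
    x$response
  m
}

#' Read a covariate table from CSV
#'
#' Expected columns: `person_id`, then any of the six covariates
#' (see [sud_covariates()]). Empty fields and `NA` are missing.
#'
#' @param path CSV file.
#' @return Data frame, one row per person.
#' @export
load_covariates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (!"person_id" %in% names(df)) stop("covariate table needs person_id")
  df$person_id <- as.character(df$person_id)
  if (anyDuplicated(df$person_id)) stop("duplicated person_id in covariates")
  for (b in intersect(c("gender_female", "alcohol_no"), names(df))) {
    ok <- df[[b]] %in% c(0, 1) | is.na(df[[b]])
    if (!all(ok)) stop("binary covariate '", b, "' has values outside {0,1,NA}")
  }
  df
}

#' Complete-case filtering on covariates
#'
#' Removes every person with at least one missing covariate value and
#' restricts the response table to the retained persons; missing
#' *responses* are kept (the marginal likelihood sums over observed cells
#' only).
#'
#' @param responses A [response_table()].
#' @param covariates Covariate data frame with `person_id`.
#' @param fields Covariate columns to require complete; default all
#'   non-id columns present.
#' @return List with `responses`, `covariates`, `n_removed`.
#' @export
filter_complete_cases <- function(responses, covariates,
                                  fields = setdiff(names(covariates), "person_id")) {
  common <- intersect(unique(responses$person_id), covariates$person_id)
  if (length(common) == 0) stop("no persons shared by responses and covariates")
  cov <- covariates[covariates$person_id %in% common, , drop = FALSE]
  complete <- stats::complete.cases(cov[, fields, drop = FALSE])
  keep <- cov$person_id[complete]
  n_removed <- length(common) - length(keep)
  if (length(keep) == 0) {
    warning("all persons have missing covariates; nothing retained")
  }
  resp <- responses[responses$person_id %in% keep, , drop = FALSE]
  rownames(resp) <- NULL
  class(resp) <- c("response_table", "data.frame")
  cov <- cov[complete, , drop = FALSE]
  rownames(cov) <- NULL
  list(responses = resp, covariates = cov, n_removed = n_removed)
}

#' Per-item descriptive statistics
#'
#' Endorsement mean, sample SD (n - 1 denominator) and prevalence percent
#' per criterion, in the fixed item order. The `severity` column is `NA`
#' until filled from a Rasch fit (see [fit_rasch()]).
#'
#' @param responses A [response_table()].
#' @return Data frame with columns `item_id`, `n`, `mean`, `sd`,
#'   `prevalence_pct`, `severity`.
#' @export
describe_items <- function(responses) {
  if (nrow(responses) == 0) stop("empty response table")
  out <- do.call(rbind, lapply(sud_items(), function(it) {
    r <- responses$response[responses$item_id == it]
    r <- r[!is.na(r)]
    n <- length(r)
    if (n == 0) {
      warning("item '", it, "' has no observed responses")
      return(data.frame(item_id = it, n = 0L, mean = NA_real_, sd = NA_real_,
                        prevalence_pct = NA_real_, severity = NA_real_))
    }
    data.frame(item_id = it, n = n, mean = mean(r),
               sd = if (n > 1) stats::sd(r) else NA_real_,
               prevalence_pct = 100 * mean(r), severity = NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Z-standardize continuous covariates
#'
#' Rescales each named field to sample mean 0 and SD 1 (n - 1 denominator),
#' leaving other columns untouched. Missing values are ignored in the
#' moments and preserved in place.
#'
#' @param covariates Covariate data frame.
#' @param fields Columns to standardize; default the four personality
#'   scores present in the table.
#' @return The covariate data frame with the named fields rescaled.
#' @export
standardize <- function(covariates,
                        fields = intersect(c("hopelessness", "impulsivity",
                                             "sensation_seeking",
                                             "anxiety_sensitivity"),
                                           names(covariates))) {
  for (f in fields) {
    if (!f %in% names(covariates)) stop("unknown field: ", f)
    v <- covariates[[f]]
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("constant field cannot be standardized: ", f)
    covariates[[f]] <- (v - mean(v, na.rm = TRUE)) / s
  }
  covariates
}
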