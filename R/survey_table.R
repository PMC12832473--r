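# Data model: one row per household/respondent with a binary no-hunger
# outcome, an SES measure, covariates, and a probability weight.

#' Closed categorical level sets of the survey data model
#'
#' Reference level first in every set; regression reference categories are
#' not economically active, Black African, poorest quintile, formal dwelling,
#' no electricity, no piped water, no education, male.
#'
#' @format A named list of character vectors.
#' @export
survey_levels <- list(
  sex         = c("male", "female"),
  employment  = c("not_economically_active", "unemployed", "employed"),
  race        = c("black_african", "people_of_colour", "asian_indian", "white"),
  education   = c("none", "primary", "secondary", "tertiary"),
  dwelling    = c("formal", "traditional", "informal"),
  electricity = c("no", "yes"),
  piped_water = c("no", "yes"),
  ses_quintile = c("1", "2", "3", "4", "5")
)

#' Construct a survey table
#'
#' Builds the canonical household-survey container used throughout the
#' package: a `data.frame` of class `survey_table` with a binary
#' `no_hunger` outcome (1 = no household hunger in the past 7 days), an
#' optional continuous SES score, an SES quintile (1 = poorest), categorical
#' covariates with fixed level sets, and a positive probability weight.
#'
#' @param df A data.frame with (a subset of) the canonical columns:
#'   `no_hunger`, `ses_score`, `ses_quintile`, `weight`, `sex`, `age`,
#'   `household_size`, `employment`, `race`, `education`, `dwelling`,
#'   `electricity`, `piped_water`, `province`, `wave_id`.
#' @param validate Check invariants (positive weights, closed level sets)?
#' @return A `survey_table`. Values outside a column's closed level set are
#'   converted to `NA` and counted in `attr(x, "n_flagged")`.
#' @export
survey_table <- function(df, validate = TRUE) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"weight" %in% names(df)) stop("mandatory column 'weight' is missing")
  if (!"no_hunger" %in% names(df)) stop("mandatory column 'no_hunger' is missing")

  bad_w <- which(!is.finite(df$weight) | df$weight <= 0)
  if (length(bad_w) > 0)
    stop("non-positive or missing weight in row(s): ",
         paste(utils::head(bad_w, 5L), collapse = ", "))

  y <- df$no_hunger
  if (!all(y %in% c(0, 1) | is.na(y)))
    stop("no_hunger must be 0, 1 or missing")
  df$no_hunger <- as.integer(y)

  n_flagged <- 0L
  for (col in names(survey_levels)) {
    if (!col %in% names(df)) next
    lev <- survey_levels[[col]]
    v <- as.character(df[[col]])
    out_of_set <- !is.na(v) & !(v %in% lev)
    if (any(out_of_set)) {
      n_flagged <- n_flagged + sum(out_of_set)
      v[out_of_set] <- NA_character_
    }
    df[[col]] <- factor(v, levels = lev)
  }
  for (col in intersect(c("age", "household_size", "ses_score"), names(df)))
    df[[col]] <- as.numeric(df[[col]])
  if ("province" %in% names(df)) df$province <- factor(df$province)
  if ("wave_id" %in% names(df)) df$wave_id <- as.character(df$wave_id)

  if (validate && n_flagged > 0)
    warning(n_flagged, " value(s) outside the declared level sets were flagged as missing")

  structure(df,
            class = c("survey_table", "data.frame"),
            n_flagged = n_flagged)
}

#' @export
print.survey_table <- function(x, ...) {
  cat("<survey_table> ", nrow(x), " rows, ", ncol(x), " columns",
      if (isTRUE(attr(x, "n_flagged") > 0))
        paste0(" (", attr(x, "n_flagged"), " flagged values)"),
      "\n", sep = "")
  NextMethod()
}

# Missing codes used by the external CSV interface.
.missing_codes <- c("", "NA", "-9")

#' Load a household survey from CSV
#'
#' Reads a UTF-8 CSV with a header row, renames columns according to
#' `schema`, converts the missing codes `""`, `"NA"` and `-9` to `NA`, and
#' validates the result via [survey_table()]. Rows with categorical values
#' outside the closed level sets are flagged (value set to missing) with a
#' warning; the load still succeeds.
#'
#' @param path Path to the CSV file.
#' @param schema Named character vector or list mapping canonical column
#'   names (see [survey_table()]) to CSV column names. Defaults to the
#'   identity mapping for every canonical column present in the file.
#' @return A `survey_table`.
#' @export
load_survey <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = .missing_codes,
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (is.null(schema)) {
    canonical <- c("no_hunger", "ses_score", "ses_quintile", "weight", "sex",
                   "age", "household_size", "employment", "race", "education",
                   "dwelling", "electricity", "piped_water", "province",
                   "wave_id")
    schema <- stats::setNames(intersect(canonical, names(raw)),
                              intersect(canonical, names(raw)))
  }
  schema <- unlist(schema)
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols) > 0)
    stop("mapped column(s) absent from file: ",
         paste(missing_cols, collapse = ", "))
  for (col in c("no_hunger", "weight"))
    if (!col %in% names(schema))
      stop("mandatory column '", col, "' is not mapped")
  df <- raw[, unname(schema), drop = FALSE]
  names(df) <- names(schema)
  # the numeric missing code -9 survives read.csv's na.strings in numeric cols
  for (col in names(df))
    if (is.numeric(df[[col]])) df[[col]][df[[col]] == -9] <- NA
  survey_table(df)
}

#' Harmonize a raw 7-day hunger item into the no-hunger outcome
#'
#' The two source surveys code the household-hunger item in opposite
#' directions. Under `"nids_hunger"` the raw item is 1 when someone in the
#' household went hungry in the past 7 days, so no-hunger = 1 - raw. Under
#' `"nfnss_reversed"` the raw item is already 1 = no episode of not having
#' enough food, so it passes through unchanged. Missing values propagate.
#'
#' @param raw Integer/numeric vector in \{0, 1, NA\}.
#' @param convention `"nids_hunger"` or `"nfnss_reversed"`.
#' @return Integer vector in \{0, 1, NA\}: 1 = no household hunger.
#' @export
harmonize_no_hunger <- function(raw,
                                convention = c("nids_hunger", "nfnss_reversed")) {
  convention <- match.arg(convention)
  if (!all(raw %in% c(0, 1) | is.na(raw)))
    stop("raw hunger indicator must be 0, 1 or missing")
  raw <- as.integer(raw)
  switch(convention,
         nids_hunger    = 1L - raw,
         nfnss_reversed = raw)
}
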