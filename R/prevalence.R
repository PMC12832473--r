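# Survey-weighted prevalence with logit-scale confidence intervals.

#' Weighted prevalence of the no-hunger outcome, by group
#'
#' For each level of the grouping column, computes the weighted proportion
#' `100 * sum(w*y) / sum(w)` of the binary outcome among rows with a
#' non-missing outcome. The standard error uses the weighted binomial
#' variance with the effective sample size `n_eff = (sum w)^2 / sum(w^2)`;
#' the 95% interval is computed on the logit scale and back-transformed, so
#' its bounds stay inside [0, 100]. A group whose weighted proportion is
#' exactly 0 or 100 gets a degenerate interval at the bound and is flagged
#' in the `degenerate` column.
#'
#' @param data A [survey_table()].
#' @param by Name of a grouping column, or `NULL` for a single overall row.
#' @param outcome Name of the binary outcome column (default `"no_hunger"`).
#' @param conf_level Confidence level (default 0.95).
#' @return A data.frame of class `prevalence_table` with columns
#'   `group`, `n`, `proportion`, `std_err`, `ci_low`, `ci_high`,
#'   `degenerate` (percent scale throughout; `std_err` on the proportion
#'   scale, matching survey-software output).
#' @export
prevalence_table <- function(data, by = NULL, outcome = "no_hunger",
                             conf_level = 0.95) {
  stopifnot(is.data.frame(data), outcome %in% names(data))
  y <- data[[outcome]]
  w <- data$weight
  g <- if (is.null(by)) factor(rep("all", nrow(data))) else factor(data[[by]])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  rows <- lapply(levels(g), function(lv) {
    idx <- which(g == lv & !is.na(y))
    if (length(idx) == 0L) {
      warning("group '", lv, "' has no non-missing outcome; omitted")
      return(NULL)
    }
    yi <- y[idx]; wi <- w[idx]
    p <- sum(wi * yi) / sum(wi)
    n_eff <- sum(wi)^2 / sum(wi^2)
    se <- sqrt(p * (1 - p) / n_eff)
    if (p <= 0 || p >= 1) {
      lo <- hi <- p
      degenerate <- TRUE
    } else {
      # delta-method SE on the logit scale, back-transformed
      se_logit <- se / (p * (1 - p))
      lg <- stats::qlogis(p)
      lo <- stats::plogis(lg - z * se_logit)
      hi <- stats::plogis(lg + z * se_logit)
      degenerate <- FALSE
    }
    data.frame(group = lv, n = length(idx), proportion = 100 * p,
               std_err = se, ci_low = 100 * lo, ci_high = 100 * hi,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no group has a non-missing outcome")
  rownames(out) <- NULL
  class(out) <- c("prevalence_table", "data.frame")
  out
}

#' Write / read a prevalence table as CSV
#'
#' @param x A `prevalence_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly (`write_prevalence`); the re-loaded table
#'   (`read_prevalence`).
#' @export
write_prevalence <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prevalence
#' @export
read_prevalence <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("prevalence_table", "data.frame")
  out
}
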