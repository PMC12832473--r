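# Weighted fractional ranks and weighted quintiles of an SES measure.
# The fractional rank of a unit is the midpoint of its cumulative-weight
# interval in the SES ordering; tied units share the weight-averaged rank of
# their tie group (equivalently, the midpoint of the group's interval).

#' Weighted fractional ranks of a socio-economic measure
#'
#' Sorts by `ses` ascending and assigns each unit the midpoint of its
#' cumulative normalized-weight interval, `r_i = (cw_before_i + w_i/2) / W`.
#' Units tied on `ses` form a tie group and all receive the weight-averaged
#' rank of the group. The weighted mean of the ranks is exactly 0.5 and ranks
#' are invariant to positive rescaling of the weights and to strictly
#' monotone transforms of `ses`.
#'
#' @param ses Numeric SES measure (no missing values).
#' @param weight Positive weights, same length.
#' @return A `rank_vector`: data.frame with columns `rank` (in (0,1)) and
#'   `tie_group` (integer id, increasing in `ses`), aligned to the input
#'   row order.
#' @export
weighted_fractional_rank <- function(ses, weight) {
  n <- length(ses)
  if (n < 2L) stop("need at least 2 rows to rank")
  if (length(weight) != n) stop("ses and weight lengths differ")
  if (anyNA(ses) || anyNA(weight)) stop("missing values in ses or weight")
  if (any(weight <= 0)) stop("weights must be positive")

  grp <- match(ses, sort(unique(ses)))          # tie group id, ascending in ses
  if (length(unique(ses)) == 1L)
    warning("all ses values identical: single tie group, all ranks 0.5")

  W <- sum(weight)
  gw <- unname(vapply(split(weight, grp), sum, numeric(1)))  # group weights, in id order
  cum_hi <- cumsum(gw) / W
  mid <- cum_hi - gw / (2 * W)                           # group interval midpoint
  structure(data.frame(rank = mid[grp], tie_group = grp),
            class = c("rank_vector", "data.frame"))
}

#' Weighted quintiles of a socio-economic measure
#'
#' Cuts `ses` at its weighted 20/40/60/80th percentiles into quintiles 1
#' (poorest) to 5 (richest). Units tied on `ses` are treated as one block of
#' probability mass; a block whose mass spans a cut point is assigned the
#' lowest quintile it touches, so assignment is deterministic and
#' order-independent. When `ses` carries no mass points each quintile's
#' weight share is within one percentage point of 20%.
#'
#' @inheritParams weighted_fractional_rank
#' @return Integer vector in 1..5.
#' @export
weighted_quintiles <- function(ses, weight) {
  n <- length(ses)
  if (n < 2L) stop("need at least 2 rows")
  if (length(weight) != n) stop("ses and weight lengths differ")
  if (anyNA(ses) || anyNA(weight)) stop("missing values in ses or weight")
  if (any(weight <= 0)) stop("weights must be positive")

  vals <- sort(unique(ses))
  if (length(vals) < 5L)
    warning("fewer than 5 distinct ses values: quintiles will be unbalanced")
  grp <- match(ses, vals)
  W <- sum(weight)
  gw <- unname(vapply(split(weight, grp), sum, numeric(1)))
  lo <- (cumsum(gw) - gw) / W                  # mass interval start per block
  eps <- 1e-12
  cuts <- c(0.2, 0.4, 0.6, 0.8)
  q_block <- vapply(lo, function(s) 1L + sum(s >= cuts - eps), integer(1))
  q <- q_block[grp]
  share <- vapply(1:5, function(k) sum(weight[q == k]) / W, numeric(1))
  if (length(vals) >= 5L && any(share == 0))
    warning("mass point spans quintile cut points; empty quintile(s): ",
            paste(which(share == 0), collapse = ", "))
  q
}
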