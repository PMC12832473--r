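# Rank-dependent socio-economic inequality indices.
#
# All three indices are functionals of the weighted covariance between the
# health variable h and the weighted fractional SES rank r:
#   standard   C = 2 cov_w(h, r) / mu
#   Erreygers  E = 4 mu C / (b - a)    (binary bounds (0,1): E = 8 cov_w)
#   Wagstaff   W = C mu (b - a) / ((b - mu)(mu - a))   (binary: C / (1 - mu))
# Positive values mean the outcome is concentrated among the rich.

weighted_mean <- function(x, w) sum(w * x) / sum(w)

# population-style weighted covariance (normalized by total weight);
# normalization cancels in every index, ratio and regression slope below.
weighted_cov <- function(x, y, w) {
  W <- sum(w)
  xb <- sum(w * x) / W
  yb <- sum(w * y) / W
  sum(w * (x - xb) * (y - yb)) / W
}

index_estimate <- function(type, value, mu, n, bounds,
                           std_err = NA_real_, p_value = NA_real_) {
  structure(list(index_type = type, value = value, std_err = std_err,
                 p_value = p_value, mean_outcome = mu, n = n,
                 bounds = bounds),
            class = "index_estimate")
}

#' @export
print.index_estimate <- function(x, ...) {
  cat(sprintf("<index_estimate> %s = %.4f", x$index_type, x$value))
  if (!is.na(x$std_err))
    cat(sprintf(" (robust SE %.4f, p %s)", x$std_err,
                format.pval(x$p_value, digits = 3)))
  cat(sprintf("; mean outcome %.4f, n = %d\n", x$mean_outcome, x$n))
  cat(" ", interpret_index(x), "\n")
  invisible(x)
}

rank_values <- function(ranks) {
  if (inherits(ranks, "rank_vector") || is.data.frame(ranks)) ranks$rank
  else as.numeric(ranks)
}

#' Standard concentration index
#'
#' `C = 2 cov_w(h, r) / mu`, where `r` is the weighted fractional SES rank
#' and `mu` the weighted mean of `h`. Undefined when `mu = 0`.
#'
#' @param h Outcome/factor column (numeric).
#' @param ranks A [weighted_fractional_rank()] result (or numeric ranks).
#' @param weight Positive weights.
#' @return An `index_estimate` (no standard error; see [index_se()]).
#' @export
standard_ci <- function(h, ranks, weight) {
  r <- rank_values(ranks)
  mu <- weighted_mean(h, weight)
  if (abs(mu) < .Machine$double.eps)
    stop("mean outcome is zero; standard concentration index undefined")
  C <- 2 * weighted_cov(h, r, weight) / mu
  index_estimate("standard", C, mu, length(h), c(NA_real_, NA_real_))
}

#' Erreygers concentration index
#'
#' Bounded-variable correction `E = 4 mu C / (b - a)`; for a binary outcome
#' with bounds (0, 1), `E = 8 cov_w(h, r)`. `E` lies in [-1, 1] and
#' satisfies the mirror property `E(1 - h) = -E(h)`.
#'
#' @inheritParams standard_ci
#' @param bounds Numeric `c(a, b)` with `a < b` and all `h` inside.
#' @return An `index_estimate`.
#' @export
erreygers_index <- function(h, ranks, weight, bounds = c(0, 1)) {
  a <- bounds[1]; b <- bounds[2]
  if (!(a < b)) stop("bounds must satisfy a < b")
  if (any(h < a | h > b)) stop("outcome outside the declared bounds")
  r <- rank_values(ranks)
  mu <- weighted_mean(h, weight)
  E <- 8 * weighted_cov(h, r, weight) / (b - a)
  index_estimate("erreygers", E, mu, length(h), bounds)
}

#' Wagstaff normalized concentration index
#'
#' `W = C mu (b - a) / ((b - mu)(mu - a))`; for a binary outcome,
#' `W = C / (1 - mu)`. Requires the mean strictly inside the bounds.
#'
#' @inheritParams erreygers_index
#' @return An `index_estimate`.
#' @export
wagstaff_index <- function(h, ranks, weight, bounds = c(0, 1)) {
  a <- bounds[1]; b <- bounds[2]
  if (!(a < b)) stop("bounds must satisfy a < b")
  if (any(h < a | h > b)) stop("outcome outside the declared bounds")
  r <- rank_values(ranks)
  mu <- weighted_mean(h, weight)
  if (mu <= a || mu >= b)
    stop("mean outcome at a bound; Wagstaff index undefined")
  Wv <- 2 * weighted_cov(h, r, weight) * (b - a) / ((b - mu) * (mu - a))
  index_estimate("wagstaff", Wv, mu, length(h), bounds)
}

# transformed outcome whose WLS-on-rank slope equals the requested index
convenient_transform <- function(h, r, weight, index_type, bounds) {
  mu <- weighted_mean(h, weight)
  s2r <- weighted_cov(r, r, weight)
  a <- bounds[1]; b <- bounds[2]
  switch(index_type,
         standard  = 2 * s2r * h / mu,
         erreygers = 8 * s2r * h / (b - a),
         wagstaff  = 2 * s2r * h * (b - a) / ((b - mu) * (mu - a)),
         stop("unknown index type: ", index_type))
}

#' Concentration index with a standard error
#'
#' Computes the requested index together with a standard error and a
#' two-sided normal p-value. `method = "convenient_regression"` (default)
#' regresses the appropriately transformed outcome on the fractional rank by
#' weighted least squares — the slope equals the covariance-formula index —
#' and takes the heteroskedasticity-robust (sandwich) slope SE, matching the
#' "robust std. error" convention of survey software. `method = "bootstrap"`
#' resamples rows with replacement (recomputing ranks in every resample) and
#' uses the bootstrap standard deviation.
#'
#' @inheritParams erreygers_index
#' @param index_type `"erreygers"` (default), `"standard"` or `"wagstaff"`.
#' @param method `"convenient_regression"` or `"bootstrap"`.
#' @param B Bootstrap replicates (default 1000; a warning is emitted
#'   below 100).
#' @param seed Seed for the bootstrap resampling.
#' @param cluster Optional cluster ids for a cluster bootstrap.
#' @return An `index_estimate` with `std_err` and `p_value` filled in.
#' @export
index_se <- function(h, ranks, weight, index_type = "erreygers",
                     method = c("convenient_regression", "bootstrap"),
                     bounds = c(0, 1), B = 1000L, seed = 1L, cluster = NULL) {
  method <- match.arg(method)
  r <- rank_values(ranks)
  if (length(h) < 10L) stop("need at least 10 observations for an SE")
  point <- switch(index_type,
                  standard  = standard_ci(h, r, weight),
                  erreygers = erreygers_index(h, r, weight, bounds),
                  wagstaff  = wagstaff_index(h, r, weight, bounds))

  if (method == "convenient_regression") {
    g <- convenient_transform(h, r, weight, index_type, bounds)
    X <- cbind(1, r)
    fit <- stats::lm.wfit(X, g, weight)
    slope <- fit$coefficients[2]
    e <- g - drop(X %*% fit$coefficients)
    A_inv <- solve(crossprod(X, X * weight))
    score <- X * (weight * e)
    if (!is.null(cluster)) score <- rowsum(score, cluster)
    V <- A_inv %*% crossprod(score) %*% A_inv
    se <- sqrt(V[2, 2])
    stopifnot(abs(slope - point$value) < 1e-6 * max(1, abs(point$value)))
  } else {
    if (B < 100L) warning("bootstrap with B < 100 replicates is unreliable")
    n <- length(h)
    ids <- if (is.null(cluster)) seq_len(n) else cluster
    uid <- unique(ids)
    set.seed(seed)
    vals <- vapply(seq_len(B), function(b) {
      take <- sample(uid, length(uid), replace = TRUE)
      idx <- unlist(lapply(take, function(u) which(ids == u)), use.names = FALSE)
      hb <- h[idx]; wb <- weight[idx]
      # ranks must be recomputed on the resampled SES ordering; the stored
      # rank is a monotone image of ses, so re-ranking it is equivalent
      rb <- weighted_fractional_rank(r[idx], wb)$rank
      switch(index_type,
             standard  = standard_ci(hb, rb, wb)$value,
             erreygers = erreygers_index(hb, rb, wb, bounds)$value,
             wagstaff  = wagstaff_index(hb, rb, wb, bounds)$value)
    }, numeric(1))
    se <- stats::sd(vals)
  }
  point$std_err <- unname(se)
  point$p_value <- unname(2 * stats::pnorm(-abs(point$value / se)))
  point
}

#' Interpretation label for an inequality index
#'
#' Positive values indicate that the desirable outcome is concentrated among
#' richer households ("pro-rich inequality"), negative values among poorer
#' households ("pro-poor inequality"); zero denotes absence of
#' socio-economic-related inequality. The magnitude is rendered as a percent
#' with one decimal.
#'
#' @param e An `index_estimate` or a bare numeric value.
#' @return A label string, e.g. `"Pro-rich inequality (20.3%)"`.
#' @export
interpret_index <- function(e) {
  v <- if (inherits(e, "index_estimate")) e$value else as.numeric(e)
  pct <- sprintf("%.1f%%", abs(v) * 100)
  if (v > 0) paste0("Pro-rich inequality (", pct, ")")
  else if (v < 0) paste0("Pro-poor inequality (", pct, ")")
  else "No socio-economic-related inequality (0.0%)"
}
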