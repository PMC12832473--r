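# Model diagnostics for the weighted regressions: Hosmer-Lemeshow
# calibration, ROC/AUC discrimination, variance inflation factors, and the
# Pregibon-style link test.

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups observations into (by default) deciles of fitted risk and compares
#' observed and expected outcome counts with a chi-squared statistic on
#' `groups - 2` degrees of freedom. Following common practice for weighted
#' logistic models the test is computed on the unweighted observations.
#'
#' @param fit A `wfit` with `link = "logit"`.
#' @param groups Number of risk groups (default 10).
#' @return List with `statistic`, `p_value`, `df`, `groups`.
#' @export
hosmer_lemeshow <- function(fit, groups = 10L) {
  stopifnot(inherits(fit, "wfit"))
  p <- fit$fitted_probabilities
  y <- fit$y
  n_distinct <- length(unique(p))
  if (n_distinct < groups) {
    groups <- max(2L, n_distinct)
    warning("too few distinct fitted probabilities; using ", groups, " groups")
  }
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = groups + 1),
                               type = 7, names = FALSE))
  g <- cut(p, breaks = br, include.lowest = TRUE)
  obs <- tapply(y, g, sum)
  exp_ <- tapply(p, g, sum)
  n_g <- tapply(rep(1, length(y)), g, sum)
  pbar <- exp_ / n_g
  denom <- pmax(n_g * pbar * (1 - pbar), .Machine$double.eps)
  statistic <- sum((obs - exp_)^2 / denom)
  df <- length(obs) - 2L
  list(statistic = statistic,
       p_value = stats::pchisq(statistic, df = df, lower.tail = FALSE),
       df = df, groups = length(obs))
}

#' Weighted area under the ROC curve
#'
#' Weighted Mann-Whitney statistic: the weighted probability that a randomly
#' drawn positive outcome has a higher fitted score than a randomly drawn
#' negative one, ties counting one half.
#'
#' @param fit A `wfit`, or `NULL` if `scores`/`y`/`w` are given directly.
#' @param scores,y,w Optional explicit scores, binary outcome and weights
#'   (used when `fit` is `NULL`).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(fit = NULL, scores = NULL, y = NULL, w = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "wfit"))
    scores <- fit$fitted_probabilities; y <- fit$y; w <- fit$weights
  }
  if (is.null(w)) w <- rep(1, length(y))
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  # weighted midrank formulation: O(n log n), ties contribute 1/2
  o <- order(scores)
  s <- scores[o]; ys <- y[o]; ws <- w[o]
  cw <- cumsum(ws)
  # weighted midrank of each observation among all observations
  grp <- match(s, unique(s))
  gw <- vapply(split(ws, grp), sum, numeric(1))
  ghi <- cumsum(gw)
  mid <- (ghi - gw / 2)[grp]
  w1 <- sum(ws[ys == 1]); w0 <- sum(ws[ys == 0])
  # sum over positives of weighted "rank" = W0*U + within-positive mass
  r1 <- sum(ws[ys == 1] * mid[ys == 1])
  (r1 - w1^2 / 2) / (w1 * w0)
}

#' Variance inflation factors
#'
#' For each non-intercept design column, `VIF_k = 1 / (1 - R^2_k)` from the
#' weighted least-squares regression of that column on all other columns
#' (including the intercept). Exactly aliased columns are reported as `Inf`
#' and flagged.
#'
#' @param data A [survey_table()].
#' @param formula Model formula (response ignored for the VIFs themselves).
#' @param weight_col Weight column name.
#' @return data.frame `term`, `vif`, `aliased`; the mean VIF is attached as
#'   `attr(x, "mean_vif")`.
#' @export
vif <- function(data, formula, weight_col = "weight") {
  d <- build_design(formula, data, weight_col)
  X <- d$X; w <- d$w
  cols <- setdiff(seq_len(ncol(X)), which(colnames(X) == "(Intercept)"))
  res <- lapply(cols, function(j) {
    xj <- X[, j]
    Z <- X[, -j, drop = FALSE]
    fit <- stats::lm.wfit(Z, xj, w)
    cf <- fit$coefficients; cf[is.na(cf)] <- 0
    e <- xj - drop(Z %*% cf)
    xbar <- sum(w * xj) / sum(w)
    sst <- sum(w * (xj - xbar)^2)
    sse <- sum(w * e^2)
    r2 <- if (sst <= 0) 1 else 1 - sse / sst
    v <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    data.frame(term = colnames(X)[j], vif = v, aliased = !is.finite(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "mean_vif") <- mean(out$vif[is.finite(out$vif)])
  out
}

#' Link (specification) test for a logistic fit
#'
#' Refits the outcome on the linear predictor and its square. In a
#' well-specified model the linear predictor is significant while its square
#' is not; a significant squared term signals functional-form
#' misspecification.
#'
#' @param fit A converged `wfit` with `link = "logit"`.
#' @return List with `coef_hat`, `coef_hatsq`, `p_hatsq`.
#' @export
link_test <- function(fit) {
  stopifnot(inherits(fit, "wfit"))
  if (!fit$converged) stop("fit did not converge")
  eta <- stats::qlogis(pmin(pmax(fit$fitted_probabilities, 1e-12), 1 - 1e-12))
  if (stats::sd(eta) < 1e-10)
    stop("linear predictor is constant; link test undefined")
  d <- data.frame(y = fit$y, hat = eta, hatsq = eta^2, weight = fit$weights)
  refit <- fit_weighted_logit(survey_minimal(d), y ~ hat + hatsq)
  list(coef_hat = unname(refit$coefficients["hat"]),
       coef_hatsq = unname(refit$coefficients["hatsq"]),
       p_hatsq = unname(refit$p_values["hatsq"]))
}

# Minimal data.frame wrapper so internal refits can reuse the fitters
# without the survey_table contract (used by link_test and index_se).
survey_minimal <- function(df) {
  stopifnot("weight" %in% names(df))
  df
}
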