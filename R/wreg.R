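# Probability-weighted logistic and linear-probability regression.
#
# Estimation is pseudo-maximum-likelihood: the weighted Bernoulli
# log-likelihood is maximized by IRLS (deterministic start at beta = 0,
# tolerance 1e-8 on max |delta beta|, at most 100 iterations) and inference
# uses the robust sandwich estimator treating the weights as probability
# weights, optionally clustered.

# Build outcome, design matrix and aligned weights from a formula.
# Complete-case within the model frame; returns the kept row indices.
build_design <- function(formula, data, weight_col = "weight") {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  omitted <- attr(mf, "na.action")
  kept <- setdiff(seq_len(nrow(data)), as.integer(omitted))
  tt <- attr(mf, "terms")
  y <- stats::model.response(mf)
  X <- stats::model.matrix(tt, mf)
  w <- data[[weight_col]][kept]
  list(y = as.numeric(y), X = X, w = w, terms = tt, kept = kept,
       assign = attr(X, "assign"))
}

#' Detect perfect predictors and exact collinearity
#'
#' Identifies design columns that must be omitted before a logistic fit:
#' dummy columns within whose cells the outcome is constant (perfect
#' prediction, which would send the coefficient to +/- infinity) and columns
#' that are exactly linearly dependent on earlier columns (collinearity,
#' detected by pivoted QR). Mirrors the blank "omitted" cells of standard
#' survey-regression output.
#'
#' @param data A [survey_table()].
#' @param formula Model formula, e.g. `no_hunger ~ ses_quintile + sex`.
#' @return List with `drop` (design column names to omit) and `report`
#'   (data.frame `term`, `reason`; zero rows when nothing is dropped).
#' @export
drop_perfect_predictors <- function(data, formula) {
  d <- build_design(formula, data)
  X <- d$X; y <- d$y
  nms <- colnames(X)
  drop <- character(0); reason <- character(0)

  for (j in seq_len(ncol(X))) {
    if (nms[j] == "(Intercept)") next
    xj <- X[, j]
    if (!all(xj %in% c(0, 1))) next
    inside <- y[xj == 1]
    if (length(inside) > 0 && length(unique(inside)) == 1L &&
        length(inside) < length(y)) {
      drop <- c(drop, nms[j]); reason <- c(reason, "perfect prediction")
    }
  }
  keep <- setdiff(nms, drop)
  Xk <- X[, keep, drop = FALSE]
  qr_x <- qr(Xk)
  if (qr_x$rank < ncol(Xk)) {
    aliased <- colnames(Xk)[qr_x$pivot[seq.int(qr_x$rank + 1L, ncol(Xk))]]
    drop <- c(drop, aliased)
    reason <- c(reason, rep("collinearity", length(aliased)))
  }
  list(drop = drop,
       report = data.frame(term = drop, reason = reason,
                           stringsAsFactors = FALSE))
}

# Shared sandwich machinery. score = per-row score contributions (n x p).
sandwich_vcov <- function(A_inv, score, cluster = NULL) {
  if (!is.null(cluster)) {
    score <- rowsum(score, group = cluster)
  }
  B <- crossprod(score)
  V <- A_inv %*% B %*% A_inv
  (V + t(V)) / 2
}

wfit_result <- function(beta, vcov, link, y, X, w, kept, dropped, converged,
                        fitted, formula, iterations, loglik = NA_real_) {
  se <- sqrt(pmax(diag(vcov), 0))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(coefficients = beta, vcov = vcov, se = se, z = z,
                 p_values = p, link = link, n_used = length(y),
                 dropped_terms = dropped, converged = converged,
                 fitted_probabilities = unname(fitted), y = y, X = X,
                 weights = w,
                 kept = kept, formula = formula, iterations = iterations,
                 loglik = loglik),
            class = "wfit")
}

#' @export
print.wfit <- function(x, ...) {
  cat("<wfit> link =", x$link, "| n =", x$n_used,
      "| converged =", x$converged, "\n")
  tab <- cbind(estimate = x$coefficients, se = x$se, p = x$p_values)
  print(round(tab, 4))
  if (length(x$dropped_terms$term))
    cat("dropped:", paste(x$dropped_terms$term, collapse = ", "), "\n")
  invisible(x)
}

#' Survey-weighted logistic regression
#'
#' Fits a logistic regression by probability-weighted IRLS with robust
#' sandwich variance. Perfectly predicting dummy cells and exactly collinear
#' columns are detected and dropped before fitting (see
#' [drop_perfect_predictors()]). Coefficients are invariant to positive
#' rescaling of the weights; with equal weights the fit equals unweighted
#' maximum likelihood.
#'
#' @param data A [survey_table()].
#' @param formula Model formula with a binary response.
#' @param weight_col Name of the weight column (default `"weight"`).
#' @param cluster Optional name of a cluster-id column for clustered robust
#'   variance; default is household-level (row-level) robust variance.
#' @param tol,max_iter IRLS convergence tolerance on `max |delta beta|`
#'   and iteration cap.
#' @return A `wfit` object: `coefficients`, `vcov` (sandwich), `se`,
#'   `p_values`, `link`, `n_used`, `dropped_terms`, `converged`,
#'   `fitted_probabilities`, plus the internal design for diagnostics.
#' @export
fit_weighted_logit <- function(data, formula, weight_col = "weight",
                               cluster = NULL, tol = 1e-8, max_iter = 100L) {
  d <- build_design(formula, data, weight_col)
  y <- d$y; X <- d$X; w <- d$w
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")

  dp <- drop_perfect_predictors(data, formula)
  if (length(dp$drop) > 0) {
    keep <- setdiff(colnames(X), dp$drop)
    asg <- d$assign[match(keep, colnames(X))]
    X <- X[, keep, drop = FALSE]
    attr(X, "assign") <- asg
  }
  if (qr(X)$rank < ncol(X))
    stop("design rank-deficient after drops; aliased terms remain")

  beta <- rep(0, ncol(X))
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    mu_w <- pmax(p * (1 - p), 1e-10)
    wirls <- w * mu_w
    z <- eta + (y - p) / mu_w
    fit <- stats::lm.wfit(X, z, wirls)
    delta <- fit$coefficients - beta
    beta <- fit$coefficients
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) warning("IRLS did not converge in ", max_iter, " iterations")

  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  A <- crossprod(X, X * (w * p * (1 - p)))
  A_inv <- solve(A)
  score <- X * (w * (y - p))
  cl <- if (is.null(cluster)) NULL else data[[cluster]][d$kept]
  V <- sandwich_vcov(A_inv, score, cl)
  ll <- sum(w * (y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300))))
  wfit_result(stats::setNames(beta, colnames(X)), V, "logit", y, X, w,
              d$kept, dp$report, converged, p, formula, iter, ll)
}

#' Weighted linear-probability model
#'
#' Weighted least squares of the binary outcome on the design, with
#' heteroskedasticity-robust (HC0) sandwich variance using the probability
#' weights. The linear first-stage model of the concentration-index
#' decomposition.
#'
#' @inheritParams fit_weighted_logit
#' @return A `wfit` with `link = "identity"`; `fitted_probabilities` are the
#'   linear predictions (not truncated to [0, 1]).
#' @export
fit_weighted_lpm <- function(data, formula, weight_col = "weight",
                             cluster = NULL) {
  d <- build_design(formula, data, weight_col)
  y <- d$y; X <- d$X; w <- d$w

  dp <- drop_perfect_predictors(data, formula)
  # only collinearity matters for least squares; perfect prediction is finite
  alias <- dp$report$term[dp$report$reason == "collinearity"]
  if (length(alias) > 0) {
    keep <- setdiff(colnames(X), alias)
    asg <- d$assign[match(keep, colnames(X))]
    X <- X[, keep, drop = FALSE]
    attr(X, "assign") <- asg
  }
  if (qr(X)$rank < ncol(X))
    stop("design rank-deficient after drops; aliased terms remain")

  fit <- stats::lm.wfit(X, y, w)
  beta <- fit$coefficients
  yhat <- drop(X %*% beta)
  e <- y - yhat
  A_inv <- solve(crossprod(X, X * w))
  score <- X * (w * e)
  cl <- if (is.null(cluster)) NULL else data[[cluster]][d$kept]
  V <- sandwich_vcov(A_inv, score, cl)
  rep_df <- dp$report[dp$report$reason == "collinearity", , drop = FALSE]
  wfit_result(stats::setNames(beta, colnames(X)), V, "identity", y, X, w,
              d$kept, rep_df, TRUE, yhat, formula, 1L)
}

#' Adjusted odds-ratio table from a logistic fit
#'
#' `aOR = exp(beta)`, Wald 95% interval `exp(beta +/- 1.96 se)`, and the
#' three-tier significance marks used in the source tables: `a` for
#' p < 0.01, `b` for p < 0.05, `c` for p < 0.1.
#'
#' @param fit A `wfit` with `link = "logit"`.
#' @param conf_level Confidence level (default 0.95).
#' @return data.frame `term`, `estimate`, `se`, `aOR`, `ci_low`, `ci_high`,
#'   `p`, `mark`.
#' @export
odds_ratio_table <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "wfit"))
  if (fit$link != "logit") stop("odds ratios require a logit-link fit")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  b <- fit$coefficients; se <- fit$se; p <- fit$p_values
  mark <- ifelse(p < 0.01, "a", ifelse(p < 0.05, "b", ifelse(p < 0.1, "c", "")))
  data.frame(term = names(b), estimate = unname(b), se = unname(se),
             aOR = exp(unname(b)),
             ci_low = exp(unname(b - z * se)),
             ci_high = exp(unname(b + z * se)),
             p = unname(p), mark = unname(mark),
             stringsAsFactors = FALSE)
}

# AME point estimates as a function of beta, for the delta method.
# Continuous columns: weighted mean of beta_k p(1-p). Dummy columns:
# weighted mean discrete difference of predicted probability setting the
# dummy to 1 vs 0 (sibling dummies of the same factor set to 0).
ame_point <- function(beta, X, w, assign) {
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  W <- sum(w)
  cols <- setdiff(seq_len(ncol(X)), which(colnames(X) == "(Intercept)"))
  vapply(cols, function(j) {
    xj <- X[, j]
    if (all(xj %in% c(0, 1))) {
      sib <- setdiff(which(assign == assign[j]), j)
      eta0 <- eta - xj * beta[j]
      if (length(sib) > 0)
        eta0 <- eta0 - drop(X[, sib, drop = FALSE] %*% beta[sib])
      sum(w * (stats::plogis(eta0 + beta[j]) - stats::plogis(eta0))) / W
    } else {
      sum(w * beta[j] * p * (1 - p)) / W
    }
  }, numeric(1))
}

#' Average marginal effects on the probability scale
#'
#' For a logit fit, continuous regressors get the weighted mean derivative
#' `beta_k p_i (1 - p_i)` and factor dummies the weighted mean discrete
#' difference in predicted probability between the dummy level and the
#' reference. Standard errors come from the delta method with a numerical
#' Jacobian against the sandwich vcov. For an identity-link fit the AMEs
#' equal the coefficients exactly.
#'
#' @param fit A converged `wfit`.
#' @return data.frame of class `marginal_effects` with `term`, `ame`, `se`.
#' @export
average_marginal_effects <- function(fit) {
  stopifnot(inherits(fit, "wfit"))
  if (!fit$converged) stop("fit did not converge")
  terms_out <- setdiff(names(fit$coefficients), "(Intercept)")
  if (fit$link == "identity") {
    out <- data.frame(term = terms_out,
                      ame = unname(fit$coefficients[terms_out]),
                      se = unname(fit$se[terms_out]),
                      stringsAsFactors = FALSE)
    class(out) <- c("marginal_effects", "data.frame")
    return(out)
  }
  X <- fit$X; w <- fit$weights
  assign <- attr(X, "assign")
  if (is.null(assign)) assign <- seq_len(ncol(X)) - 1L
  beta <- fit$coefficients
  point <- ame_point(beta, X, w, assign)
  # numerical Jacobian d ame / d beta for the delta method
  h <- 1e-6 * pmax(abs(beta), 1)
  J <- matrix(0, nrow = length(point), ncol = length(beta))
  for (k in seq_along(beta)) {
    bp <- beta; bp[k] <- bp[k] + h[k]
    bm <- beta; bm[k] <- bm[k] - h[k]
    J[, k] <- (ame_point(bp, X, w, assign) - ame_point(bm, X, w, assign)) /
      (2 * h[k])
  }
  V <- J %*% fit$vcov %*% t(J)
  out <- data.frame(term = terms_out, ame = point,
                    se = sqrt(pmax(diag(V), 0)), stringsAsFactors = FALSE)
  class(out) <- c("marginal_effects", "data.frame")
  out
}
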