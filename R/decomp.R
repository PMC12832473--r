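# Wagstaff-van Doorslaer regression-based decomposition of the
# concentration index into factor contributions plus a residual
# (generalized-concentration) term.
#
# With a linear first stage y = a + sum_k beta_k x_k + e, the standard
# index decomposes as C = sum_k (beta_k xbar_k / mu) C_k + GC_e / mu, where
# C_k is the concentration index of factor k over the same SES ranks. The
# Erreygers version scales every term by 4 mu (binary bounds), so percent
# shares are identical across the two scalings. For a logistic first stage
# the coefficients are replaced by average marginal effects.

#' Decompose a concentration index into factor contributions
#'
#' Fits the first-stage model (weighted LPM by default, or weighted logit
#' with average marginal effects), computes each design column's
#' concentration index against the supplied ranks, and forms the explained
#' contribution per column: `(beta_k * xbar_k / mu) * CI_k` for the
#' standard index, scaled by `4 mu` for the Erreygers index and by
#' `1/(1 - mu)` for the Wagstaff index (binary bounds). The residual is the
#' total index minus the sum of explained contributions and houses the
#' generalized concentration index of the error term. Dummy columns are
#' additionally aggregated by variable group (contributions summed; group
#' factor CI the mean-weighted average of the dummy CIs, an explicit
#' reporting assumption).
#'
#' @param data A [survey_table()].
#' @param formula First-stage model formula.
#' @param ranks A [weighted_fractional_rank()] result aligned to `data`.
#' @param index_type `"erreygers"` (default), `"standard"` or `"wagstaff"`.
#' @param model `"lpm"` (default) or `"logit_ame"`.
#' @param weight_col Weight column name.
#' @return A `decomposition` object: `detail` (per design column: `factor`,
#'   `beta`, `mean`, `factor_ci`, `contribution`, `percent`), `groups`
#'   (per variable group: `variable`, `factor_ci`, `contribution`,
#'   `percent`), `residual_gc`, `residual_percent`, `total_index`,
#'   `explained`, `mean_outcome`, `model`, `index_type`, `fit`.
#' @export
decompose_index <- function(data, formula, ranks,
                            index_type = c("erreygers", "standard", "wagstaff"),
                            model = c("lpm", "logit_ame"),
                            weight_col = "weight") {
  index_type <- match.arg(index_type)
  model <- match.arg(model)

  fit <- switch(model,
                lpm = fit_weighted_lpm(data, formula, weight_col),
                logit_ame = fit_weighted_logit(data, formula, weight_col))
  if (!fit$converged) stop("first-stage model did not converge")

  kept <- fit$kept
  r <- rank_values(ranks)[kept]
  w <- fit$weights
  y <- fit$y
  mu <- weighted_mean(y, w)
  if (abs(mu) < .Machine$double.eps) stop("mean outcome is zero")

  total <- switch(index_type,
                  standard  = standard_ci(y, r, w)$value,
                  erreygers = erreygers_index(y, r, w)$value,
                  wagstaff  = wagstaff_index(y, r, w)$value)
  scale_k <- switch(index_type,
                    standard  = 1 / mu,
                    erreygers = 4,
                    wagstaff  = 1 / (mu * (1 - mu)))

  if (model == "lpm") {
    betas <- fit$coefficients
  } else {
    am <- average_marginal_effects(fit)
    betas <- stats::setNames(am$ame, am$term)
  }
  X <- fit$X
  cols <- setdiff(colnames(X), "(Intercept)")
  assign <- attr(X, "assign")

  detail <- do.call(rbind, lapply(cols, function(nm) {
    xk <- X[, nm]
    xbar <- weighted_mean(xk, w)
    ck <- if (abs(xbar) < .Machine$double.eps) 0
          else standard_ci(xk, r, w)$value
    contrib <- scale_k * betas[[nm]] * xbar * ck
    data.frame(factor = nm, beta = unname(betas[[nm]]), mean = xbar,
               factor_ci = ck, contribution = contrib,
               stringsAsFactors = FALSE)
  }))
  rownames(detail) <- NULL
  explained <- sum(detail$contribution)
  residual <- total - explained

  # aggregate dummy columns by originating model term
  asg <- assign[match(cols, colnames(X))]
  lbl <- attr(stats::terms(formula), "term.labels")[asg]
  groups <- do.call(rbind, lapply(unique(lbl), function(g) {
    sel <- detail[lbl == g, , drop = FALSE]
    wsum <- sum(abs(sel$mean))
    gci <- if (wsum > 0) sum(abs(sel$mean) * sel$factor_ci) / wsum else 0
    data.frame(variable = g, factor_ci = gci,
               contribution = sum(sel$contribution),
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL

  out <- structure(list(detail = detail, groups = groups,
                        residual_gc = residual,
                        total_index = total, explained = explained,
                        mean_outcome = mu, model = model,
                        index_type = index_type, fit = fit,
                        residual_percent = NA_real_),
                   class = "decomposition")
  percent_contributions(out)
}

#' Percent shares of a decomposition
#'
#' Expresses each contribution as a share of the total index,
#' `percent_k = 100 * contribution_k / total`. Shares can be negative or
#' exceed 100 (the residual then takes the balancing sign); they always sum
#' to 100 including the residual share.
#'
#' @param t A `decomposition`.
#' @return The `decomposition` with `percent` columns and
#'   `residual_percent` filled in.
#' @export
percent_contributions <- function(t) {
  stopifnot(inherits(t, "decomposition"))
  if (abs(t$total_index) < .Machine$double.eps)
    stop("total index is zero; report absolute contributions instead")
  t$detail$percent <- 100 * t$detail$contribution / t$total_index
  t$groups$percent <- 100 * t$groups$contribution / t$total_index
  t$residual_percent <- 100 * t$residual_gc / t$total_index
  t
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> %s index = %.4f (%s model), explained %.4f\n",
              x$index_type, x$total_index, x$model, x$explained))
  print(transform(x$groups,
                  factor_ci = round(factor_ci, 4),
                  contribution = round(contribution, 4),
                  percent = round(percent, 2)))
  cat(sprintf("residual (GC of error): %.4f (%.2f%%)\n",
              x$residual_gc, x$residual_percent))
  invisible(x)
}

#' Sensitivity of the SES gradient to its functional form
#'
#' Refits the first-stage logit with SES entered as quintile categories and
#' as a single ordinal 1-5 term, reports the joint Wald significance of the
#' categorical SES block, the McFadden pseudo-R-squared difference between
#' the two specifications, and the SES decomposition share under each.
#'
#' @param data A [survey_table()] with a `ses_quintile` column.
#' @param formula_base Model formula *without* any SES term; `ses_quintile`
#'   (categorical) and `ses_ordinal` (numeric) are added internally.
#' @param ranks A [weighted_fractional_rank()] result aligned to `data`.
#' @param weight_col Weight column name.
#' @return List: `wald` (statistic, df, p_value for the categorical SES
#'   block), `pseudo_r2_categorical`, `pseudo_r2_ordinal`, `delta_pseudo_r2`,
#'   `ses_share_categorical`, `ses_share_ordinal`, `fit_categorical`,
#'   `fit_ordinal`.
#' @export
ses_sensitivity <- function(data, formula_base, ranks, weight_col = "weight") {
  stopifnot("ses_quintile" %in% names(data))
  data$ses_ordinal <- as.numeric(as.character(data$ses_quintile))
  f_cat <- stats::update(formula_base, . ~ . + ses_quintile)
  f_ord <- stats::update(formula_base, . ~ . + ses_ordinal)

  fit_cat <- fit_weighted_logit(data, f_cat, weight_col)
  fit_ord <- fit_weighted_logit(data, f_ord, weight_col)

  ses_terms <- grep("^ses_quintile", names(fit_cat$coefficients), value = TRUE)
  b <- fit_cat$coefficients[ses_terms]
  V <- fit_cat$vcov[ses_terms, ses_terms, drop = FALSE]
  stat <- drop(t(b) %*% solve(V, b))
  wald <- list(statistic = stat, df = length(b),
               p_value = stats::pchisq(stat, df = length(b),
                                       lower.tail = FALSE))

  pseudo_r2 <- function(fit, data) {
    null_fit <- fit_weighted_logit(data[fit$kept, , drop = FALSE],
                                   stats::update(fit$formula, . ~ 1),
                                   weight_col)
    1 - fit$loglik / null_fit$loglik
  }
  r2_cat <- pseudo_r2(fit_cat, data)
  r2_ord <- pseudo_r2(fit_ord, data)

  ses_share <- function(f, ses_label) {
    dd <- decompose_index(data, f, ranks, index_type = "erreygers",
                          model = "lpm", weight_col = weight_col)
    dd$groups$percent[dd$groups$variable == ses_label]
  }
  list(wald = wald,
       pseudo_r2_categorical = r2_cat,
       pseudo_r2_ordinal = r2_ord,
       delta_pseudo_r2 = r2_cat - r2_ord,
       ses_share_categorical = ses_share(f_cat, "ses_quintile"),
       ses_share_ordinal = ses_share(f_ord, "ses_ordinal"),
       fit_categorical = fit_cat,
       fit_ordinal = fit_ord)
}
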