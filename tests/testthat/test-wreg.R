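# Weighted logistic / linear-probability regression and its diagnostics.

make_logit_data <- function(n, beta = log(2), seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  y <- as.integer(runif(n) < plogis(-0.3 + beta * x))
  survey_table(data.frame(no_hunger = y, x = x,
                          weight = rgamma(n, 4, 4)))
}

test_that("weighted logit equals the glm oracle and is weight-scale invariant", {
  d <- make_logit_data(800, seed = 11)
  # equal weights: must match unweighted maximum likelihood
  d$weight <- rep(1, nrow(d))
  fit <- fit_weighted_logit(d, no_hunger ~ x)
  oracle <- glm(no_hunger ~ x, family = binomial(), data = d)
  expect_equal(unname(fit$coefficients), unname(coef(oracle)),
               tolerance = 1e-8)

  # heterogeneous weights: glm with prior weights gives the same PML point
  d2 <- make_logit_data(800, seed = 12)
  fit2 <- fit_weighted_logit(d2, no_hunger ~ x)
  oracle2 <- suppressWarnings(
    glm(no_hunger ~ x, family = quasibinomial(), data = d2,
        weights = d2$weight))
  expect_equal(unname(fit2$coefficients), unname(coef(oracle2)),
               tolerance = 1e-8)

  # positive rescaling of all weights changes nothing
  d3 <- d2
  d3$weight <- d3$weight * 10
  fit3 <- fit_weighted_logit(d3, no_hunger ~ x)
  expect_equal(fit3$coefficients, fit2$coefficients, tolerance = 1e-10)
  expect_equal(fit3$se, fit2$se, tolerance = 1e-10)
  expect_true(fit2$converged)
  # sandwich vcov is symmetric PSD
  ev <- eigen(fit2$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
})

test_that("null and signal slopes are recovered", {
  # outcome independent of the predictor: slope within 2 SE of zero
  set.seed(5)
  d <- survey_table(data.frame(no_hunger = rbinom(2000, 1, 0.7),
                               x = rnorm(2000), weight = rgamma(2000, 4, 4)))
  fit <- fit_weighted_logit(d, no_hunger ~ x)
  expect_lt(abs(fit$coefficients["x"]), 2 * fit$se["x"])

  # Monte-Carlo coverage of a log(2) slope: within 2 SE in >= 93/100 seeds
  hits <- vapply(1:100, function(s) {
    d <- make_logit_data(5000, beta = log(2), seed = 1000 + s)
    f <- fit_weighted_logit(d, no_hunger ~ x)
    abs(f$coefficients["x"] - log(2)) <= 2 * f$se["x"]
  }, logical(1))
  expect_gte(sum(hits), 93)
})

test_that("weighted LPM matches closed forms and the normal-equations oracle", {
  x <- c(0, 0, 1, 1, 0, 1)
  d <- survey_table(data.frame(no_hunger = as.integer(x), x = x,
                               weight = c(1, 2, 1, 3, 1, 1)))
  fit <- fit_weighted_lpm(d, no_hunger ~ x)
  expect_equal(unname(fit$coefficients), c(0, 1), tolerance = 1e-12)
  expect_equal(fit$fitted_probabilities, x, tolerance = 1e-12)

  # orthogonal predictor gets a zero slope
  d2 <- survey_table(data.frame(
    no_hunger = c(0L, 1L, 0L, 1L), z = c(1, 1, -1, -1), weight = rep(1, 4)))
  fit2 <- fit_weighted_lpm(d2, no_hunger ~ z)
  expect_lt(abs(fit2$coefficients["z"]), 1e-10)

  # direct normal-equations oracle on a 6-row instance
  set.seed(2)
  d3 <- survey_table(data.frame(no_hunger = c(1L, 0L, 1L, 1L, 0L, 1L),
                                a = rnorm(6), b = rnorm(6),
                                weight = rgamma(6, 2, 2)))
  fit3 <- fit_weighted_lpm(d3, no_hunger ~ a + b)
  X <- cbind(1, d3$a, d3$b)
  expect_equal(unname(fit3$coefficients),
               unname(wls_normal_eq(X, d3$no_hunger, d3$weight)),
               tolerance = 1e-10)
})

test_that("perfect predictors and aliased columns are detected and dropped", {
  set.seed(8)
  n <- 200
  g <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
  y <- rbinom(n, 1, 0.6)
  y[g == "c"] <- 1L                      # perfect prediction cell
  d <- survey_table(data.frame(no_hunger = y, g = g, x = rnorm(n),
                               weight = rep(1, n)))
  d$x_dup <- d$x                         # exact collinearity
  rep1 <- drop_perfect_predictors(d, no_hunger ~ g + x + x_dup)
  expect_setequal(rep1$report$term, c("gc", "x_dup"))
  expect_equal(rep1$report$reason[rep1$report$term == "gc"],
               "perfect prediction")
  expect_equal(rep1$report$reason[rep1$report$term == "x_dup"],
               "collinearity")
  # the fit silently proceeds on the reduced design
  fit <- fit_weighted_logit(d, no_hunger ~ g + x + x_dup)
  expect_false("gc" %in% names(fit$coefficients))
  expect_true(fit$converged)

  # well-conditioned design: empty report
  rep2 <- drop_perfect_predictors(d, no_hunger ~ x)
  expect_equal(nrow(rep2$report), 0L)
})

test_that("odds-ratio table applies exp, Wald CIs and the a/b/c marks", {
  d <- make_logit_data(600, seed = 31)
  fit <- fit_weighted_logit(d, no_hunger ~ x)
  tab <- odds_ratio_table(fit)
  expect_equal(tab$aOR, exp(tab$estimate), tolerance = 1e-12)
  expect_equal(tab$ci_low, exp(tab$estimate - qnorm(0.975) * tab$se),
               tolerance = 1e-12)

  # marks at the three thresholds, on a constructed fit
  fk <- fit
  fk$p_values <- c(0.005, 0.03)
  names(fk$p_values) <- names(fk$coefficients)
  tk <- odds_ratio_table(fk)
  expect_equal(tk$mark, c("a", "b"))
  fk$p_values[] <- c(0.07, 0.5)
  expect_equal(odds_ratio_table(fk)$mark, c("c", ""))

  lpm <- fit_weighted_lpm(d, no_hunger ~ x)
  expect_error(odds_ratio_table(lpm), "logit")
})

test_that("average marginal effects match identity coefficients and a finite-difference oracle", {
  d <- make_logit_data(300, seed = 17)
  lpm <- fit_weighted_lpm(d, no_hunger ~ x)
  am_lpm <- average_marginal_effects(lpm)
  expect_equal(am_lpm$ame, unname(lpm$coefficients["x"]))
  expect_equal(am_lpm$se, unname(lpm$se["x"]))

  fit <- fit_weighted_logit(d, no_hunger ~ x)
  am <- average_marginal_effects(fit)
  # finite-difference oracle: shift the covariate, re-predict
  eps <- 1e-6
  X <- fit$X; b <- fit$coefficients; w <- fit$weights
  p_hi <- plogis(drop(cbind(X[, 1], X[, 2] + eps) %*% b))
  p_lo <- plogis(drop(cbind(X[, 1], X[, 2] - eps) %*% b))
  fd <- sum(w * (p_hi - p_lo) / (2 * eps)) / sum(w)
  expect_equal(am$ame[am$term == "x"], fd, tolerance = 1e-6)

  # dummy terms: AME equals the weighted mean discrete difference
  set.seed(18)
  g <- factor(sample(c("lo", "hi"), 300, replace = TRUE), c("lo", "hi"))
  d2 <- survey_table(data.frame(
    no_hunger = rbinom(300, 1, ifelse(g == "hi", 0.8, 0.5)),
    g = g, weight = rgamma(300, 4, 4)))
  fit2 <- fit_weighted_logit(d2, no_hunger ~ g)
  am2 <- average_marginal_effects(fit2)
  b2 <- fit2$coefficients
  dd <- plogis(b2[1] + b2[2]) - plogis(b2[1])
  expect_equal(am2$ame, unname(dd), tolerance = 1e-10)
})

test_that("Hosmer-Lemeshow is zero under perfect calibration and rejects misspecification", {
  # groups where fitted probability equals the observed frequency exactly
  p_g <- seq(0.1, 0.9, by = 0.1)
  y <- unlist(lapply(p_g, function(p) rep(c(1L, 0L), c(round(10 * p),
                                                       10 - round(10 * p)))))
  fake <- structure(list(fitted_probabilities = rep(p_g, each = 10), y = y),
                    class = "wfit")
  hl <- hosmer_lemeshow(fake, groups = 9)
  expect_equal(hl$statistic, 0, tolerance = 1e-12)
  expect_equal(hl$p_value, 1)
  expect_equal(hl$df, hl$groups - 2L)

  # grossly misspecified model (quadratic truth): rejects in most replicates
  rejects <- vapply(1:20, function(s) {
    set.seed(400 + s)
    x <- rnorm(1500)
    y <- as.integer(runif(1500) < plogis(1.5 - 2 * x^2))
    d <- survey_table(data.frame(no_hunger = y, x = x,
                                 weight = rep(1, 1500)))
    hosmer_lemeshow(fit_weighted_logit(d, no_hunger ~ x))$p_value < 0.05
  }, logical(1))
  expect_gte(sum(rejects), 14)

  expect_warning(
    hosmer_lemeshow(structure(list(fitted_probabilities = rep(c(.2, .8), 10),
                                   y = rep(0:1, 10)), class = "wfit")),
    "too few distinct")
})

test_that("weighted AUC matches the exhaustive pair-count oracle", {
  # perfect separation
  expect_equal(roc_auc(scores = c(.1, .2, .8, .9), y = c(0, 0, 1, 1)), 1)
  # 4-row fixture with one tie
  s <- c(0.3, 0.5, 0.5, 0.7); y <- c(0, 0, 1, 1); w <- c(1, 2, 1.5, 0.5)
  expect_equal(roc_auc(scores = s, y = y, w = w),
               auc_pairs_oracle(s, y, w), tolerance = 1e-12)
  # random weighted fixtures
  set.seed(21)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    w <- rgamma(n, 3, 3)
    expect_equal(roc_auc(scores = s, y = y, w = w),
                 auc_pairs_oracle(s, y, w), tolerance = 1e-12)
  }
  # independence null at large n
  set.seed(22)
  expect_lt(abs(roc_auc(scores = runif(20000), y = rbinom(20000, 1, 0.5)) -
                  0.5), 0.02)
  expect_error(roc_auc(scores = 1:3, y = rep(1, 3)), "classes")
})

test_that("VIF matches closed forms and flags aliasing", {
  # orthogonal balanced predictors: VIF exactly 1
  x1 <- rep(c(-1, 1), 20); x2 <- rep(c(-1, 1), each = 20)
  d <- survey_table(data.frame(no_hunger = rbinom(40, 1, .5), x1 = x1,
                               x2 = x2, weight = rep(1, 40)))
  v <- vif(d, no_hunger ~ x1 + x2)
  expect_equal(v$vif, c(1, 1), tolerance = 1e-10)

  # exact sample correlation 0.8 gives VIF 1/(1-0.64) = 2.7778
  set.seed(9)
  z1 <- rnorm(200); z2 <- rnorm(200)
  z1 <- (z1 - mean(z1)) / sd(z1)
  z2 <- residuals(lm(z2 ~ z1)); z2 <- z2 / sd(z2)
  x2 <- 0.8 * z1 + sqrt(1 - 0.64) * z2
  d2 <- survey_table(data.frame(no_hunger = rbinom(200, 1, .5), z1 = z1,
                                x2 = x2, weight = rep(1, 200)))
  v2 <- vif(d2, no_hunger ~ z1 + x2)
  expect_equal(v2$vif, rep(1 / (1 - 0.64), 2), tolerance = 1e-6)

  d2$dup <- d2$z1
  v3 <- vif(d2, no_hunger ~ z1 + dup)
  expect_true(all(v3$aliased))
  expect_true(all(is.infinite(v3$vif)))
})

test_that("link test separates well-specified from quadratic truths", {
  # well-specified: squared prediction not significant in most seeds
  ok <- vapply(1:20, function(s) {
    d <- make_logit_data(1500, beta = 1, seed = 600 + s)
    link_test(fit_weighted_logit(d, no_hunger ~ x))$p_hatsq > 0.05
  }, logical(1))
  expect_gte(sum(ok), 15)

  # quadratic truth: squared prediction significant in most seeds
  bad <- vapply(1:20, function(s) {
    set.seed(700 + s)
    x <- rnorm(1500)
    y <- as.integer(runif(1500) < plogis(-1 + x + 1.5 * x^2))
    d <- survey_table(data.frame(no_hunger = y, x = x, weight = rep(1, 1500)))
    link_test(fit_weighted_logit(d, no_hunger ~ x))$p_hatsq < 0.05
  }, logical(1))
  expect_gte(sum(bad), 14)

  # constant predictor propagates an error
  d0 <- survey_table(data.frame(no_hunger = rbinom(50, 1, .5),
                                weight = rep(1, 50)))
  f0 <- fit_weighted_logit(d0, no_hunger ~ 1)
  expect_error(link_test(f0), "constant")
})
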