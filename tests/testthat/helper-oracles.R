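# Independent oracles used across the suite. Each re-derives a quantity by
# a route different from the implementation under test.

# Concentration index via the concentration curve: 1 - 2 * area under the
# weighted concentration curve, trapezoid rule over tie-group points.
trapezoid_ci_oracle <- function(h, ses, w) {
  o <- order(ses)
  h <- h[o]; s <- ses[o]; w <- w[o]
  grp <- match(s, unique(s))
  gw <- tapply(w, grp, sum)
  gh <- tapply(w * h, grp, sum)
  p <- c(0, cumsum(gw) / sum(gw))
  L <- c(0, cumsum(gh) / sum(w * h))
  1 - sum(diff(p) * (L[-1] + L[-length(L)]))
}

# AUC by exhaustive weighted pair counting, ties counting one half.
auc_pairs_oracle <- function(scores, y, w = rep(1, length(y))) {
  pos <- which(y == 1); neg <- which(y == 0)
  num <- 0
  for (i in pos) for (j in neg) {
    num <- num + w[i] * w[j] *
      (if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0)
  }
  num / (sum(w[pos]) * sum(w[neg]))
}

# Weighted least squares by direct normal equations.
wls_normal_eq <- function(X, y, w) {
  solve(t(X) %*% (X * w), t(X) %*% (y * w))[, 1]
}

# Brute-force weighted quintile: per row, total weight strictly below its
# ses value (O(n^2), no sorting) determines the block start.
quintile_brute_oracle <- function(ses, w) {
  vapply(seq_along(ses), function(i) {
    start <- sum(w[ses < ses[i]]) / sum(w)
    1L + sum(start >= c(0.2, 0.4, 0.6, 0.8) - 1e-12)
  }, integer(1))
}

# Small deterministic survey fixture built in code.
tiny_survey <- function() {
  survey_table(data.frame(
    no_hunger = c(1L, 0L, 1L, 1L),
    ses_score = c(0.5, 1.2, 2.5, 4.0),
    ses_quintile = c(1L, 2L, 4L, 5L),
    weight = c(1.0, 2.0, 1.5, 0.5),
    sex = c("male", "female", "female", "male"),
    age = c(30, 45, 60, 28),
    household_size = c(4, 6, 2, 3),
    employment = c("unemployed", "not_economically_active", "employed",
                   "employed"),
    race = c("black_african", "black_african", "white", "people_of_colour"),
    education = c("primary", "none", "tertiary", "secondary"),
    dwelling = c("informal", "traditional", "formal", "formal"),
    electricity = c("no", "yes", "yes", "yes"),
    piped_water = c("no", "no", "yes", "yes"),
    province = c("Gauteng", "Limpopo", "Gauteng", "Western Cape"),
    wave_id = "wave1",
    stringsAsFactors = FALSE))
}

write_tiny_csv <- function(path, mutate = identity) {
  df <- as.data.frame(tiny_survey())
  df[] <- lapply(df, function(v) if (is.factor(v)) as.character(v) else v)
  df <- mutate(df)
  utils::write.csv(df, path, row.names = FALSE)
  path
}
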