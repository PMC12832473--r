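# Data model, outcome harmonization, ranks, quintiles, prevalence.

test_that("load_survey round-trips a clean fixture and enforces its contract", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_tiny_csv(f)
  tab <- load_survey(f)
  expect_s3_class(tab, "survey_table")
  expect_equal(nrow(tab), 4L)
  expect_identical(attr(tab, "n_flagged"), 0L)
  expect_equal(tab$no_hunger, c(1L, 0L, 1L, 1L))
  expect_equal(levels(tab$race), survey_levels$race)

  # non-positive weight names the offending row
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_tiny_csv(f2, function(d) { d$weight[3] <- 0; d })
  expect_error(load_survey(f2), "row\\(s\\): 3")

  # out-of-set level: flagged, load succeeds with a warning
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_tiny_csv(f3, function(d) { d$race[2] <- "Other"; d })
  expect_warning(tab3 <- load_survey(f3), "flagged")
  expect_identical(attr(tab3, "n_flagged"), 1L)
  expect_true(is.na(tab3$race[2]))

  # missing mandatory column is a hard error
  f4 <- withr::local_tempfile(fileext = ".csv")
  write_tiny_csv(f4, function(d) { d$weight <- NULL; d })
  expect_error(load_survey(f4), "weight")

  # missing codes "", "NA", -9 become NA
  f5 <- withr::local_tempfile(fileext = ".csv")
  write_tiny_csv(f5, function(d) { d$age[1] <- -9; d$education[2] <- ""; d })
  tab5 <- load_survey(f5)
  expect_true(is.na(tab5$age[1]))
  expect_true(is.na(tab5$education[2]))
})

test_that("harmonize_no_hunger maps both survey conventions", {
  expect_equal(harmonize_no_hunger(c(1, 0, 1), "nids_hunger"), c(0L, 1L, 0L))
  expect_equal(harmonize_no_hunger(c(0, 1, NA), "nfnss_reversed"),
               c(0L, 1L, NA))
  expect_equal(harmonize_no_hunger(rep(0, 5), "nids_hunger"), rep(1L, 5))
  expect_error(harmonize_no_hunger(c(0, 1), "bogus"))
  expect_error(harmonize_no_hunger(c(0, 2), "nids_hunger"), "0, 1 or missing")
})

test_that("weighted fractional ranks match hand computations", {
  expect_equal(weighted_fractional_rank(c(1, 2, 3, 4), rep(1, 4))$rank,
               c(0.125, 0.375, 0.625, 0.875))
  # cumulative-weight midpoints for weights (2,1,1): (1, 2.5, 3.5)/4
  expect_equal(weighted_fractional_rank(c(1, 2, 3), c(2, 1, 1))$rank,
               c(0.25, 0.625, 0.875))
  # ties share the weight-averaged rank of the tie group
  r <- weighted_fractional_rank(c(1, 1, 2, 2), rep(1, 4))
  expect_equal(r$rank, c(0.25, 0.25, 0.75, 0.75))
  expect_equal(r$tie_group, c(1L, 1L, 2L, 2L))
  # original row order is restored
  expect_equal(weighted_fractional_rank(c(4, 1, 3, 2), rep(1, 4))$rank,
               c(0.875, 0.125, 0.625, 0.375))
  expect_warning(r0 <- weighted_fractional_rank(rep(7, 3), 1:3), "identical")
  expect_equal(r0$rank, rep(0.5, 3))
})

test_that("rank invariants hold over random instances", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(2:80, 1)
    ses <- sample(1:12, n, replace = TRUE)   # tie-prone
    w <- rgamma(n, 3, 2)
    r <- suppressWarnings(weighted_fractional_rank(ses, w))
    # weighted mean exactly 0.5
    expect_lt(abs(sum(w * r$rank) / sum(w) - 0.5), 1e-10)
    # invariant to positive weight rescaling
    expect_equal(weighted_fractional_rank(ses, w * pi)$rank, r$rank,
                 tolerance = 1e-12)
    # invariant to strictly monotone transform of ses
    expect_equal(weighted_fractional_rank(exp(ses / 3), w)$rank, r$rank,
                 tolerance = 1e-12)
    # non-decreasing in the ses ordering, constant within tie groups
    o <- order(ses)
    expect_true(all(diff(r$rank[o]) >= -1e-15))
    expect_true(all(tapply(r$rank, r$tie_group, function(v)
      diff(range(v))) == 0))
  }
})

test_that("weighted quintiles split evenly and agree with the brute-force oracle", {
  expect_equal(weighted_quintiles(1:10, rep(1, 10)),
               rep(1:5, each = 2))
  # dominant mass point spans cut points: lowest spanned quintile + warning
  expect_warning(q <- weighted_quintiles(1:5, c(0.6, 0.1, 0.1, 0.1, 0.1)),
                 "empty quintile")
  expect_equal(q[1], 1L)

  # exhaustive-style sweep against the O(n^2) oracle at n <= 12
  set.seed(99)
  for (i in 1:300) {
    n <- sample(2:12, 1)
    ses <- sample(1:6, n, replace = TRUE)
    w <- round(rgamma(n, 2, 2), 3) + 0.01
    expect_identical(suppressWarnings(weighted_quintiles(ses, w)),
                     quintile_brute_oracle(ses, w))
  }

  # weight share per quintile within 1 percentage point when ses is continuous
  set.seed(7)
  ses <- rnorm(20000); w <- rgamma(20000, 4, 4)
  q <- weighted_quintiles(ses, w)
  shares <- tapply(w, q, sum) / sum(w)
  expect_true(all(abs(shares - 0.2) < 0.01))

  expect_warning(weighted_quintiles(rep(c(1, 2), 5), rep(1, 10)),
                 "fewer than 5 distinct")
})

test_that("prevalence_table computes weighted proportions with logit CIs", {
  tab <- survey_table(data.frame(no_hunger = c(1L, 1L, 1L, 0L),
                                 weight = rep(1, 4)))
  p <- prevalence_table(tab)
  expect_equal(p$proportion, 75)
  expect_true(p$ci_low < 75 && 75 < p$ci_high)
  expect_true(p$ci_low >= 0 && p$ci_high <= 100)

  tab2 <- survey_table(data.frame(no_hunger = c(1L, 0L), weight = c(3, 1)))
  expect_equal(prevalence_table(tab2)$proportion, 75)

  # constant weights equal the unweighted proportion exactly
  set.seed(3)
  y <- rbinom(50, 1, 0.6)
  tab3 <- survey_table(data.frame(no_hunger = y, weight = rep(2.5, 50)))
  expect_equal(prevalence_table(tab3)$proportion, 100 * mean(y))

  # degenerate group at a bound is flagged with a collapsed interval
  tab4 <- survey_table(data.frame(no_hunger = rep(1L, 8), weight = rep(1, 8)))
  p4 <- prevalence_table(tab4)
  expect_true(p4$degenerate)
  expect_equal(c(p4$ci_low, p4$ci_high), c(100, 100))

  # group with all-missing outcome omitted with a warning
  tab5 <- survey_table(data.frame(
    no_hunger = c(1L, 0L, NA, NA),
    weight = rep(1, 4),
    province = c("a", "a", "b", "b")))
  expect_warning(p5 <- prevalence_table(tab5, by = "province"), "omitted")
  expect_equal(p5$group, "a")

  # CSV round trip of the external interface
  f <- withr::local_tempfile(fileext = ".csv")
  write_prevalence(p, f)
  expect_equal(read_prevalence(f)$proportion, p$proportion)
})
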