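make_clean_record <- function() {
  cfg <- generator_config(n_respondents = 1, seed = 21)
  generate_cohort(cfg)
}

test_that("exclusion rules flag the right records with the right reasons", {
  rec <- make_clean_record()
  expect_equal(nrow(apply_exclusions(rec)$excluded), 0)

  miss <- rec; miss$pcq7 <- NA_integer_
  ex <- apply_exclusions(miss)
  expect_equal(nrow(ex$retained), 0)
  expect_equal(ex$excluded$reason, "incomplete")

  straight <- rec
  straight[paste0("phq", 1:9)] <- 2L
  straight[paste0("is", 1:9)] <- 3L
  ex <- apply_exclusions(straight)
  expect_equal(ex$excluded$reason, "straight_line")

  patterned <- rec
  patterned[paste0("pcq", 1:24)] <- rep(c(2L, 5L), 12)
  ex <- apply_exclusions(patterned)
  expect_equal(ex$excluded$reason, "patterned")
})

test_that("a constant binary family-support response is not straight-lining", {
  rec <- make_clean_record()
  rec[paste0("fs", 1:20)] <- 1L      # all "yes": a common, legitimate answer
  expect_equal(nrow(apply_exclusions(rec)$excluded), 0)
})

test_that("apply_exclusions is idempotent and order-stable", {
  cfg <- generator_config(n_respondents = 400, seed = 22,
                          contamination = c(incomplete = 0.03,
                                            straight_line = 0.02,
                                            patterned = 0.01))
  coh <- generate_cohort(cfg)
  once <- apply_exclusions(coh)
  twice <- apply_exclusions(once$retained)
  expect_equal(nrow(twice$excluded), 0)
  expect_equal(as.data.frame(twice$retained), as.data.frame(once$retained))
  expect_equal(once$retained$id, sort(once$retained$id))
})

test_that("screening threshold keeps exactly the at-or-above rows", {
  scores <- data.frame(id = as.character(1:4), gender = "female",
                       dep = c(4, 5, 27, NA), is = 1, psycap = 50, fs = 10)
  kept <- screen_positive(scores)
  expect_equal(kept$dep, c(5, 27))
  expect_equal(nrow(screen_positive(scores, threshold = 28)), 0)
})

test_that("screening report reproduces the published arithmetic", {
  rep <- screening_report(study_fixture_cohort(seed = 31))
  expect_equal(rep$n_raw, 2359)
  expect_equal(rep$n_excluded, 112)
  expect_equal(rep$n_retained, 2247)
  expect_equal(round(rep$exclusion_pct, 2), 4.75)
  expect_equal(as.integer(rep$band_counts),
               c(1553L, 591L, 70L, 23L, 10L))
  expect_equal(rep$n_positive, 591 + 70 + 23 + 10)
  expect_equal(round(rep$prevalence_pct, 2), 30.89)
  # prevalence and band counts are invariant to row order
  shuffled <- study_fixture_cohort(seed = 31)
  shuffled <- shuffled[rev(seq_len(nrow(shuffled))), ]
  rep2 <- screening_report(shuffled)
  expect_equal(rep2$prevalence_pct, rep$prevalence_pct)
  expect_equal(rep2$band_counts, rep$band_counts)
})

test_that("pearson_matrix gives textbook correlations and cor.test p-values", {
  x <- data.frame(dep = c(1, 4, 2, 8, 5), is = c(1, 4, 2, 8, 5) * 2 + 3)
  pm <- pearson_matrix(x, vars = c("dep", "is"))
  expect_equal(pm$r["dep", "is"], 1)
  x$is <- -x$dep
  expect_equal(pearson_matrix(x, vars = c("dep", "is"))$r["dep", "is"], -1)
  set.seed(23)
  y <- data.frame(dep = rnorm(40), is = rnorm(40))
  pm <- pearson_matrix(y, vars = c("dep", "is"))
  ct <- cor.test(y$dep, y$is)
  expect_equal(pm$r["dep", "is"], unname(ct$estimate))
  expect_equal(pm$p["dep", "is"], ct$p.value)
  expect_error(pearson_matrix(data.frame(dep = rep(1, 5), is = rnorm(5)),
                              vars = c("dep", "is")),
               class = "modmod_degenerate_error")
})

test_that("pooled gender t-test matches the hand computation", {
  scores <- data.frame(gender = rep(c("male", "female"), each = 3),
                       dep = c(1, 2, 3, 4, 5, 6))
  ht <- gender_t_test(scores, "dep")
  expect_equal(ht$t, -3.674, tolerance = 1e-3)
  expect_equal(ht$df, 4)
  same <- data.frame(gender = rep(c("male", "female"), each = 3),
                     dep = rep(c(1, 2, 3), 2))
  ht0 <- gender_t_test(same, "dep")
  expect_equal(ht0$t, 0)
  expect_equal(ht0$p, 1)
  expect_error(gender_t_test(data.frame(gender = "male", dep = 1), "dep"),
               class = "modmod_validation_error")
})

test_that("gender t-test is calibrated when scores are gender-independent", {
  set.seed(24)
  reps <- 500
  pvals <- replicate(reps, {
    scores <- data.frame(gender = sample(c("male", "female"), 2000,
                                         replace = TRUE),
                         dep = rnorm(2000))
    gender_t_test(scores, "dep")$p
  })
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("Harman's single-factor share matches closed-form eigenstructure", {
  set.seed(25)
  base <- rnorm(500)
  copies <- matrix(base, 500, 8)
  expect_equal(harman_single_factor(copies +
                                      rnorm(4000, sd = 1e-8))$first_factor_pct,
               100, tolerance = 1e-4)
  # independent items: first share ~ 100/k
  k <- 62
  indep <- matrix(rnorm(10000 * k), ncol = k)
  expect_lt(abs(harman_single_factor(indep)$first_factor_pct - 100 / k), 1)
  # one-factor structure, loadings 0.7: share ~ 49% + 51/k %
  kf <- 20
  f <- rnorm(10000)
  items <- 0.7 * matrix(f, 10000, kf) +
    sqrt(1 - 0.49) * matrix(rnorm(10000 * kf), 10000, kf)
  h <- harman_single_factor(items)
  expect_lt(abs(h$first_factor_pct - (49 + 51 / kf)), 2)
  expect_false(h$acceptable)
  expect_error(harman_single_factor(cbind(rep(1, 10), rnorm(10))),
               class = "modmod_degenerate_error")
})

test_that("cohort-level Harman entry point pools all 62 items", {
  cfg <- generator_config(n_respondents = 600, seed = 26)
  h <- harman_single_factor_cohort(generate_cohort(cfg))
  expect_true(h$first_factor_pct > 0 && h$first_factor_pct < 100)
  expect_true(h$acceptable)
})
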