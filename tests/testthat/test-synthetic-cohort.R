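test_that("identical config and seed give byte-identical cohorts", {
  cfg <- generator_config(n_respondents = 300, seed = 11,
                          contamination = c(incomplete = 0.02,
                                            straight_line = 0.02,
                                            patterned = 0.01))
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  lat <- generate_latents(cfg, n = 100)
  expect_identical(lat, generate_latents(cfg, n = 100))
})

test_that("adding contamination does not perturb the clean records", {
  clean_cfg <- generator_config(n_respondents = 200, seed = 4)
  cont_cfg <- generator_config(n_respondents = 200, seed = 4,
                               contamination = c(incomplete = 0.05))
  a <- generate_cohort(clean_cfg)
  b <- generate_cohort(cont_cfg)
  n_clean <- sum(attr(b, "contamination") == "clean")
  expect_equal(as.data.frame(b)[seq_len(n_clean), ],
               as.data.frame(a)[seq_len(n_clean), ], ignore_attr = TRUE)
})

test_that("discretization hits boundaries and preserves totals", {
  expect_equal(unname(discretize_to_items(0, "dep", seed = 1)[1, ]),
               rep(0L, 9))
  expect_equal(unname(discretize_to_items(27, "dep", seed = 1)[1, ]),
               rep(3L, 9))
  fs <- discretize_to_items(13, "fs", seed = 2)
  expect_equal(sum(fs), 13)
  expect_true(all(fs %in% 0:1))
  # arbitrary totals: sums equal the rounded/clipped target, items in range
  set.seed(3)
  targets <- runif(50, -5, 150)
  m <- discretize_to_items(targets, "psycap", seed = 4)
  expect_equal(rowSums(m), pmin(pmax(round(targets), 24), 144))
  expect_true(all(m >= 1 & m <= 6))
  expect_identical(m, discretize_to_items(targets, "psycap", seed = 4))
})

test_that("latents follow the configured regression structure", {
  # near-noiseless limit with no interactions: Y is linear in (X, M, W)
  b_lin <- c(0.2, 0.5, -0.3, 0, 0.1, 0, 0, 0)
  cfg <- generator_config(n_respondents = 500, true_coefficients = b_lin,
                          noise_sd = 1e-10, seed = 5)
  lat <- generate_latents(cfg)
  fit <- stats::lm(Y ~ X + M + W, data = lat)
  expect_lt(max(abs(stats::residuals(fit))), 1e-8)
  expect_equal(unname(stats::coef(fit)), c(0.2, 0.5, -0.3, 0.1),
               tolerance = 1e-7)

  # identity correlations: predictors uncorrelated
  cfg_id <- generator_config(n_respondents = 10000,
                             latent_correlations = diag(3), seed = 6)
  lat_id <- generate_latents(cfg_id)
  cc <- cor(lat_id[, c("X", "M", "W")])
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.03)

  # moderate-n coefficient recovery on the generating scale
  cfg_big <- generator_config(n_respondents = 20000, seed = 7)
  fit3 <- fit_model(as_model_frame(generate_latents(cfg_big)),
                    model = 3, standardize = FALSE)
  expect_lt(max(abs(fit3$b - table3_b()) / fit3$coefficients$se), 3)
})

test_that("contamination class counts are exactly round(rate * n)", {
  cfg <- generator_config(n_respondents = 1000, seed = 12,
                          contamination = c(incomplete = 0.02,
                                            straight_line = 0.013,
                                            patterned = 0.005))
  coh <- generate_cohort(cfg)
  item_cols <- unlist(lapply(scale_definitions(), `[[`, "items"))
  n_missing <- sum(rowSums(is.na(coh[, item_cols])) > 0)
  expect_equal(n_missing, 20)          # exactly round(0.02 * 1000)
  ex <- apply_exclusions(coh)
  expect_equal(unname(ex$rule_counts),
               c(20L, 13L, 5L))
  expect_equal(nrow(ex$excluded), 38L)
  # each contaminated record violates exactly one rule
  expect_false(any(grepl("\\+", ex$excluded$reason)))
  # the generator's hidden truth agrees with detection
  truth <- attr(coh, "contamination")
  expect_equal(sort(ex$excluded$reason),
               sort(truth[truth != "clean"]))
})

test_that("clean cohorts recover the configured moments", {
  cfg <- generator_config(n_respondents = 5000, seed = 13)
  scores <- score_cohort(generate_cohort(cfg))
  mm <- study_scale_moments()
  n <- nrow(scores)
  for (v in c("dep", "is", "psycap")) {
    se_mean <- mm$sd[[v]] / sqrt(n)
    se_sd <- mm$sd[[v]] / sqrt(2 * n)
    expect_lt(abs(mean(scores[[v]]) - mm$mean[[v]]), 3 * se_mean)
    expect_lt(abs(sd(scores[[v]]) - mm$sd[[v]]), 3 * se_sd)
  }
  # family support is censored at its 20-point ceiling (+1.26 SD), so the
  # oracle is the censored-normal moment, not the configured latent moment
  cc <- (20 - mm$mean[["fs"]]) / mm$sd[["fs"]]
  ez <- -(dnorm(cc) - cc * pnorm(-cc))
  ez2 <- 1 - (pnorm(-cc) + cc * dnorm(cc)) + cc^2 * pnorm(-cc)
  mean_oracle <- mm$mean[["fs"]] + mm$sd[["fs"]] * ez
  sd_oracle <- mm$sd[["fs"]] * sqrt(ez2 - ez^2)
  expect_lt(abs(mean(scores$fs) - mean_oracle),
            3 * sd_oracle / sqrt(n))
  expect_lt(abs(sd(scores$fs) - sd_oracle),
            3 * sd_oracle / sqrt(2 * n) + 0.03)  # integer rounding of totals
})

test_that("discretizing to items preserves the latent correlations", {
  cfg <- generator_config(n_respondents = 5000, seed = 14)
  lat <- generate_latents(cfg)
  scores <- score_cohort(generate_cohort(cfg))
  r_lat <- cor(cbind(dep = lat$Y, is = lat$X, psycap = lat$M, fs = lat$W))
  r_coh <- cor(scores[, c("dep", "is", "psycap", "fs")])
  # rounding and range clipping may only attenuate mildly (the family
  # support ceiling is the worst case, correlation shrinkage ~2%)
  expect_lt(max(abs(r_coh - r_lat)), 0.02)
})

test_that("invalid generator configurations are rejected", {
  bad_R <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.99, -0.99, 0.99, 1), 3, 3)
  expect_error(generator_config(latent_correlations = bad_R),
               class = "modmod_validation_error")
  expect_error(generator_config(n_respondents = 10,
                                contamination = c(incomplete = 0.9,
                                                  straight_line = 0.2)),
               class = "modmod_validation_error")
  expect_error(generator_config(noise_sd = 0),
               class = "modmod_validation_error")
})

test_that("cohort CSV round-trips through write_cohort / read_cohort", {
  cfg <- generator_config(n_respondents = 50, seed = 15,
                          contamination = c(incomplete = 0.04))
  coh <- generate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(coh),
               ignore_attr = TRUE)
})
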