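test_that("standardize produces exact z-scores and is idempotent", {
  set.seed(31)
  x <- matrix(rnorm(200, mean = 5, sd = 3), 50, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  z <- standardize(x)
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-12)
  expect_equal(standardize(z), z)
  expect_equal(standardize(x + 17), z)         # location invariance
  expect_error(standardize(cbind(rep(2, 10), rnorm(10))),
               class = "modmod_degenerate_error")
})

test_that("noiseless data are fit exactly", {
  lat <- random_latents(n = 300, seed = 32, noise_sd = 1e-12)
  fit <- fit_model(as_model_frame(lat), model = 3, standardize = FALSE)
  expect_equal(unname(fit$b), unname(table3_b()), tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("the QR solver agrees with the normal-equations oracle", {
  set.seed(33)
  for (i in 1:20) {
    d <- data.frame(Y = rnorm(12), X = rnorm(12), M = rnorm(12),
                    W = rnorm(12))
    fit <- fit_model(d, model = 3, standardize = FALSE)
    D <- cbind(1, d$X, d$M, d$X * d$M, d$W, d$X * d$W, d$M * d$W,
               d$X * d$M * d$W)
    expect_equal(unname(fit$b), normal_equations_ols(D, d$Y),
                 tolerance = 1e-9)
  }
})

test_that("inference columns follow the stated formulas", {
  lat <- random_latents(n = 150, seed = 34)
  fit <- fit_model(as_model_frame(lat), model = 3)
  lmfit <- stats::lm(Y ~ X * M * W,
                     data = as.data.frame(standardize(as.matrix(lat))))
  sm <- summary(lmfit)
  co <- sm$coefficients[c("(Intercept)", "X", "M", "X:M", "W", "X:W",
                          "M:W", "X:M:W"), ]
  expect_equal(unname(fit$b), unname(co[, 1]), tolerance = 1e-10)
  expect_equal(fit$coefficients$se, unname(co[, 2]), tolerance = 1e-10)
  expect_equal(fit$coefficients$p, unname(co[, 4]), tolerance = 1e-10)
  expect_equal(fit$r_squared, sm$r.squared, tolerance = 1e-10)
  expect_equal(unname(fit$f), unname(sm$fstatistic[1]), tolerance = 1e-8)
  expect_equal(fit$df[["df2"]], fit$n - 8)
  ci <- stats::confint(lmfit)[rownames(co), ]
  expect_equal(fit$coefficients$llci, unname(ci[, 1]), tolerance = 1e-10)
  expect_equal(fit$coefficients$ulci, unname(ci[, 2]), tolerance = 1e-10)
})

test_that("standardized coefficients are invariant to scaling raw Y", {
  lat <- random_latents(n = 120, seed = 35)
  d <- as_model_frame(lat)
  d2 <- d; d2$Y <- d$Y * 37
  f1 <- fit_model(d, model = 3)
  f2 <- fit_model(d2, model = 3)
  expect_equal(f1$b, f2$b, tolerance = 1e-12)
})

test_that("the three-way model never fits worse than the two-way model", {
  for (s in 36:38) {
    d <- as_model_frame(random_latents(n = 100, seed = s))
    expect_gte(fit_model(d, model = 3)$r_squared,
               fit_model(d, model = 1)$r_squared)
  }
})

test_that("rank deficiency raises a collinearity error naming columns", {
  d <- as_model_frame(random_latents(n = 60, seed = 39))
  d$W <- d$M                          # second moderator duplicates the first
  err <- expect_error(fit_model(d, model = 3, standardize = FALSE),
                      class = "modmod_collinearity_error")
  expect_match(conditionMessage(err), "collinear")
})

test_that("conditional effects follow the contrast algebra", {
  fit <- model_fit_from_coefficients(table3_b())
  expect_equal(conditional_effect(fit, m = -1, w = -1)$effect, 0.557)
  expect_equal(conditional_effect(fit, m = 1, w = 1)$effect, 0.281)
  # no interactions: effect is b1 at every probe point
  flat <- model_fit_from_coefficients(c(0.1, 0.4, 0.2, 0, -0.1, 0, 0.3, 0))
  for (m in c(-2, 0, 1.5)) for (w in c(-1, 2))
    expect_equal(conditional_effect(flat, m, w)$effect, 0.4)
  # supplying w to a two-way fit is a specification error
  fit1 <- model_fit_from_coefficients(c(0, 0.3, 0.1, -0.2))
  expect_error(conditional_effect(fit1, m = 1, w = 1),
               class = "modmod_validation_error")
  expect_equal(conditional_effect(fit1, m = 2)$effect, 0.3 - 0.4)
})

test_that("published R2 and F are mutually consistent under our F formula", {
  f_from_r2 <- (0.193 / 3) / ((1 - 0.193) / (694 - 3 - 1))
  expect_lt(abs(f_from_r2 - 54.944) / 54.944, 0.005)
})
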