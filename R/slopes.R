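# Corner ordering follows the published convention:
# slope 1 = high M, high W; 2 = high M, low W; 3 = low M, high W;
# 4 = low M, low W.
slope_corners <- function(level = 1) {
  data.frame(slope = 1:4,
             m = c(level, level, -level, -level),
             w = c(level, -level, level, -level),
             label = c("high PsyCap, high FS", "high PsyCap, low FS",
                       "low PsyCap, high FS", "low PsyCap, low FS"),
             stringsAsFactors = FALSE)
}

#' Simple slopes at the four moderator corners
#'
#' Evaluates the conditional effect of X on Y at the four (+/-1 SD, +/-1 SD)
#' combinations of the two moderators of a three-way interaction model:
#' `slope(m, w) = b1 + b3 m + b5 w + b7 m w`, with standard errors from the
#' coefficient covariance via the contrast `c = (0, 1, 0, m, 0, w, 0, mw)`.
#'
#' @param fit A model-3 `modmod_fit`.
#' @param level Probe level in SD units (default 1, i.e. +/-1 SD on the
#'   standardized scale).
#' @return Data frame of class `slope_set`: `slope` (1--4), `label`, `m`,
#'   `w`, `estimate`, `se`.
#' @export
#' @examples
#' simple_slopes(model_fit_from_coefficients(study_coefficients()))
simple_slopes <- function(fit, level = 1) {
  stopifnot(inherits(fit, "modmod_fit"))
  if (fit$model != 3)
    validation_error("simple slopes over two moderators need a model-3 fit")
  corners <- slope_corners(level)
  eff <- lapply(seq_len(4), function(i)
    conditional_effect(fit, corners$m[i], corners$w[i]))
  corners$estimate <- vapply(eff, `[[`, numeric(1), "effect")
  corners$se <- vapply(eff, `[[`, numeric(1), "se")
  class(corners) <- c("slope_set", "data.frame")
  corners
}

#' Pairwise slope-difference tests
#'
#' Dawson-Richter tests for all six pairs of the four simple slopes of a
#' three-way interaction. Each difference is a linear contrast of the
#' coefficients (e.g. pair (1,2) = `2(b5 + b7)`, pair (2,4) =
#' `2(b3 - b7)`); its standard error is `sqrt(c' V c)` with the
#' coefficient covariance V, the test statistic is normal
#' (`z = diff / se`) and the confidence interval uses the 1.96 normal
#' multiplier, per the Dawson-Richter convention. With a coefficient-only
#' fit (no covariance), point estimates are returned and se/z/p are `NA`.
#'
#' @param fit A model-3 `modmod_fit`.
#' @param level Probe level in SD units (default 1).
#' @param ci_level Confidence level (default 0.95).
#' @return Data frame of class `slope_differences`: `pair`, `slope_a`,
#'   `slope_b`, `difference`, `se`, `z`, `llci`, `ulci`, `p`.
#' @export
#' @examples
#' slope_difference_tests(model_fit_from_coefficients(study_coefficients()))
slope_difference_tests <- function(fit, level = 1, ci_level = 0.95) {
  stopifnot(inherits(fit, "modmod_fit"))
  if (fit$model != 3)
    validation_error("slope-difference tests need a model-3 fit")
  corners <- slope_corners(level)
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  contrast <- function(i)
    effect_contrast(3, corners$m[i], corners$w[i])
  zcrit <- stats::qnorm(1 - (1 - ci_level) / 2)
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    cv <- contrast(a) - contrast(b)
    diff <- sum(cv * fit$b)
    if (is.null(fit$vcov)) {
      se <- NA_real_; z <- NA_real_; p <- NA_real_
      ll <- NA_real_; ul <- NA_real_
    } else {
      se <- sqrt(drop(t(cv) %*% fit$vcov %*% cv))
      if (se <= 0 || !is.finite(se))
        modmod_stop("singular coefficient covariance",
                    "modmod_numerical_error")
      z <- diff / se
      p <- 2 * stats::pnorm(-abs(z))
      ll <- diff - zcrit * se; ul <- diff + zcrit * se
    }
    data.frame(pair = sprintf("(%d) and (%d)", a, b), slope_a = a,
               slope_b = b, difference = diff, se = se, z = z,
               llci = ll, ulci = ul, p = p, stringsAsFactors = FALSE)
  }))
  class(out) <- c("slope_differences", "data.frame")
  out
}

#' Predicted values for the three-way interaction plot
#'
#' Model-3 predictions at X in {-1, +1} for each of the four moderator
#' corners: the data behind the classic two-panel three-way interaction
#' plot. Line slopes equal the [simple_slopes()] estimates exactly.
#'
#' @param fit A model-3 `modmod_fit`.
#' @param level Probe level in SD units (default 1).
#' @param x_values Predictor values to evaluate (default `c(-1, 1)`).
#' @return Tidy data frame: `slope`, `label`, `m`, `w`, `x`, `y_hat`.
#' @export
interaction_plot_data <- function(fit, level = 1, x_values = c(-1, 1)) {
  stopifnot(inherits(fit, "modmod_fit"))
  if (fit$model != 3)
    validation_error("interaction plot data needs a model-3 fit")
  corners <- slope_corners(level)
  b <- fit$b
  out <- do.call(rbind, lapply(seq_len(4), function(i) {
    m <- corners$m[i]; w <- corners$w[i]
    yhat <- b[["constant"]] + b[["X"]] * x_values + b[["M"]] * m +
      b[["XM"]] * x_values * m + b[["W"]] * w +
      b[["XW"]] * x_values * w + b[["MW"]] * m * w +
      b[["XMW"]] * x_values * m * w
    data.frame(slope = corners$slope[i], label = corners$label[i],
               m = m, w = w, x = x_values, y_hat = yhat,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
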