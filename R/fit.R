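#' Standardize variables
#'
#' Centres and scales each column to mean 0, SD 1 (sample SD, n-1
#' denominator). Product terms in the interaction designs are always formed
#' AFTER standardizing their components, which is what makes the +/-1 SD
#' simple-slope algebra exact.
#'
#' @param x Numeric vector, matrix or data frame.
#' @return Object of the same shape with standardized columns.
#' @export
standardize <- function(x) {
  if (is.null(dim(x))) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      degenerate_error("cannot standardize a zero-variance variable")
    return((x - mean(x)) / s)
  }
  out <- x
  for (j in seq_len(ncol(x))) {
    s <- stats::sd(x[, j])
    if (!is.finite(s) || s == 0)
      degenerate_error(sprintf("zero variance in column %s",
                               if (!is.null(colnames(x))) colnames(x)[j]
                               else j))
    out[, j] <- (x[, j] - mean(x[, j])) / s
  }
  out
}

model_terms <- function(model) {
  if (model == 1) c("constant", "X", "M", "XM")
  else c("constant", "X", "M", "XM", "W", "XW", "MW", "XMW")
}

# Build the design matrix from standardized (or raw) component columns.
build_design <- function(X, M, W = NULL, model = 3) {
  if (model == 1) {
    D <- cbind(1, X, M, X * M)
  } else {
    D <- cbind(1, X, M, X * M, W, X * W, M * W, X * M * W)
  }
  colnames(D) <- model_terms(model)
  D
}

# Map a score table (dep/is/psycap/fs) or generic (Y/X/M/W) data frame to
# the model variables.
extract_variables <- function(data, model) {
  nm <- names(data)
  if (all(c("dep", "is", "psycap") %in% nm)) {
    out <- list(Y = data$dep, X = data$is, M = data$psycap,
                W = if ("fs" %in% nm) data$fs else NULL)
  } else if (all(c("Y", "X", "M") %in% nm)) {
    out <- list(Y = data$Y, X = data$X, M = data$M,
                W = if ("W" %in% nm) data$W else NULL)
  } else {
    validation_error(paste(
      "data must contain either dep/is/psycap[/fs] or Y/X/M[/W] columns"))
  }
  if (model == 3 && is.null(out$W))
    validation_error("model 3 needs the second moderator (fs / W)")
  out
}

#' Fit a two- or three-way interaction model
#'
#' Ordinary least squares for the moderation (model 1) and moderated
#' moderation (model 3) designs:
#' \deqn{\textrm{model 1: } Y = b_0 + b_1 X + b_2 M + b_3 XM + e}
#' \deqn{\textrm{model 3: } Y = b_0 + b_1 X + b_2 M + b_3 XM + b_4 W +
#'   b_5 XW + b_6 MW + b_7 XMW + e}
#' By default all component variables (including Y) are standardized first
#' and products formed afterwards, replicating the standardized
#' PROCESS-style coefficient tables. Estimation uses a QR solve; standard
#' errors come from `sigma2 * (D'D)^{-1}` with `sigma2 = RSS / (n - k - 1)`,
#' t-based two-sided p-values and confidence intervals on `n - k - 1` df,
#' and `F = (R2/k) / ((1 - R2)/(n - k - 1))`.
#'
#' @param data Data frame with columns `dep`, `is`, `psycap`, `fs` (a score
#'   table) or `Y`, `X`, `M`, `W`. Rows with missing values are dropped
#'   (listwise) before standardization.
#' @param model 1 (two-way) or 3 (three-way).
#' @param ci_level Confidence level (default 0.95).
#' @param standardize Standardize components before forming products
#'   (default `TRUE`).
#' @return Object of class `modmod_fit`: coefficient table, coefficient
#'   vector `b`, covariance matrix `vcov`, `sigma2`, `r_squared`, `f`
#'   with `df`, and `n`.
#' @export
fit_model <- function(data, model = 3, ci_level = 0.95,
                      standardize = TRUE) {
  if (!model %in% c(1, 3)) validation_error("model must be 1 or 3")
  v <- extract_variables(data, model)
  mat <- cbind(Y = v$Y, X = v$X, M = v$M)
  if (!is.null(v$W)) mat <- cbind(mat, W = v$W)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  n <- nrow(mat)
  k <- if (model == 1) 3L else 7L
  if (n <= k + 1)
    validation_error(sprintf("need more than %d rows, got %d", k + 1, n))
  if (standardize) mat <- standardize(mat)
  D <- build_design(mat[, "X"], mat[, "M"],
                    if (model == 3) mat[, "W"] else NULL, model)
  y <- mat[, "Y"]

  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    dropped <- colnames(D)[qrD$pivot[seq.int(qrD$rank + 1L, ncol(D))]]
    modmod_stop(paste("design matrix is rank deficient; collinear columns:",
                      paste(dropped, collapse = ", ")),
                "modmod_collinearity_error")
  }
  b <- qr.coef(qrD, y)
  res <- y - drop(D %*% b)
  rss <- sum(res^2)
  df2 <- n - k - 1L
  sigma2 <- rss / df2
  Rmat <- qr.R(qrD)[, order(qrD$pivot), drop = FALSE]
  XtX_inv <- chol2inv(Rmat)
  V <- sigma2 * XtX_inv
  dimnames(V) <- list(colnames(D), colnames(D))
  se <- sqrt(diag(V))
  tstat <- b / se
  p <- 2 * stats::pt(-abs(tstat), df = df2)
  tcrit <- stats::qt(1 - (1 - ci_level) / 2, df = df2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  fstat <- (r2 / k) / ((1 - r2) / df2)

  coef_table <- data.frame(
    term = colnames(D), estimate = unname(b), se = unname(se),
    t = unname(tstat), p = unname(p),
    llci = unname(b - tcrit * se), ulci = unname(b + tcrit * se),
    stringsAsFactors = FALSE)
  structure(list(model = model, coefficients = coef_table,
                 b = stats::setNames(unname(b), colnames(D)), vcov = V,
                 sigma2 = sigma2, r_squared = r2,
                 f = fstat, df = c(df1 = k, df2 = df2), n = n,
                 ci_level = ci_level, standardized = standardize),
            class = "modmod_fit")
}

#' Build a fit object from a published coefficient table
#'
#' Desk-calculation constructor: wraps printed coefficients (and optionally
#' their covariance matrix) in a `modmod_fit` so the simple-slope and
#' slope-difference machinery can be applied to a published table. Without
#' a covariance matrix, contrast point estimates are exact and standard
#' errors are `NA`.
#'
#' @param b Coefficient vector, length 4 (model 1) or 8 (model 3), in
#'   design order `(constant, X, M, XM[, W, XW, MW, XMW])`.
#' @param vcov Optional coefficient covariance matrix.
#' @param n Sample size the table came from (optional, for labelling).
#' @return A `modmod_fit`.
#' @export
#' @examples
#' fit <- model_fit_from_coefficients(study_coefficients())
#' slope_difference_tests(fit)
model_fit_from_coefficients <- function(b, vcov = NULL, n = NA_integer_) {
  model <- if (length(b) == 4) 1 else if (length(b) == 8) 3 else
    validation_error("b must have length 4 (model 1) or 8 (model 3)")
  terms <- model_terms(model)
  b <- stats::setNames(as.numeric(b), terms)
  if (!is.null(vcov)) {
    if (!all(dim(vcov) == length(b)))
      validation_error("vcov dimensions do not match the coefficients")
    dimnames(vcov) <- list(terms, terms)
  }
  coef_table <- data.frame(term = terms, estimate = unname(b),
                           se = if (is.null(vcov)) NA_real_ else
                             sqrt(diag(vcov)),
                           t = NA_real_, p = NA_real_, llci = NA_real_,
                           ulci = NA_real_, stringsAsFactors = FALSE)
  structure(list(model = model, coefficients = coef_table, b = b,
                 vcov = vcov, sigma2 = NA_real_, r_squared = NA_real_,
                 f = NA_real_,
                 df = c(df1 = length(b) - 1, df2 = n - length(b)),
                 n = n, ci_level = 0.95, standardized = TRUE),
            class = "modmod_fit")
}

#' @export
print.modmod_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Interaction model %d (n = %s)\n", x$model,
              ifelse(is.na(x$n), "?", x$n)))
  tab <- x$coefficients
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  if (!is.na(x$r_squared))
    cat(sprintf("R-squared %.3f, F(%d, %d) = %.3f\n", x$r_squared,
                x$df[["df1"]], x$df[["df2"]], x$f))
  invisible(x)
}

# Contrast vector for the conditional effect of X at moderator values m, w.
effect_contrast <- function(model, m, w = NULL) {
  if (model == 1) c(0, 1, 0, m)
  else c(0, 1, 0, m, 0, w, 0, m * w)
}

#' Conditional (simple) effect of X on Y
#'
#' Evaluates the effect of the predictor at fixed moderator values:
#' model 3 effect `b1 + b3 m + b5 w + b7 m w` (model 1: `b1 + b3 m`), with
#' the standard error from the contrast form `sqrt(c' V c)`.
#'
#' @param fit A `modmod_fit`.
#' @param m Value of the first moderator (standardized scale; +/-1 are the
#'   conventional probe points).
#' @param w Value of the second moderator (model 3 only).
#' @return List with `effect`, `se`, `t`, `p` (t-based on the fit's
#'   residual df when available).
#' @export
conditional_effect <- function(fit, m, w = NULL) {
  stopifnot(inherits(fit, "modmod_fit"))
  if (fit$model == 1 && !is.null(w))
    validation_error("model 1 has no second moderator; drop w")
  if (fit$model == 3 && is.null(w))
    validation_error("model 3 needs both moderator values m and w")
  cv <- effect_contrast(fit$model, m, w)
  est <- sum(cv * fit$b)
  if (is.null(fit$vcov)) return(list(effect = est, se = NA_real_,
                                     t = NA_real_, p = NA_real_))
  se <- sqrt(drop(t(cv) %*% fit$vcov %*% cv))
  tstat <- est / se
  df2 <- fit$df[["df2"]]
  p <- if (is.finite(df2)) 2 * stats::pt(-abs(tstat), df2) else
    2 * stats::pnorm(-abs(tstat))
  list(effect = est, se = se, t = tstat, p = p)
}
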