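#' Apply data-quality exclusion rules
#'
#' Flags and removes records that violate any of three rules:
#' \describe{
#'   \item{incomplete}{at least one missing item on any instrument;}
#'   \item{straight_line}{identical answer on every item of at least two of
#'     the three polytomous instruments (PHQ-9, IS, PCQ-24; the binary
#'     family-support scale is not counted, since a constant binary response
#'     is legitimately common);}
#'   \item{patterned}{a strict two-value alternating cycle across all items
#'     of any instrument.}
#' }
#' The operation is idempotent and order-stable.
#'
#' @param cohort Cohort data frame.
#' @return List with `retained` (cohort subset), `excluded` (subset with a
#'   `reason` column listing all triggered rules, `+`-separated) and
#'   `rule_counts` (named vector of per-rule trigger counts).
#' @export
apply_exclusions <- function(cohort) {
  defs <- scale_definitions()
  item_cols <- unlist(lapply(defs, `[[`, "items"))
  m <- as.matrix(cohort[, item_cols, drop = FALSE])
  n <- nrow(m)

  incomplete <- rowSums(is.na(m)) > 0
  const_count <- rep(0L, n)
  for (nm in straightline_scales()) {
    sub <- as.matrix(cohort[, defs[[nm]]$items, drop = FALSE])
    const_count <- const_count +
      as.integer(apply(sub, 1, is_constant_row))
  }
  straight <- const_count >= 2
  patterned <- rep(FALSE, n)
  for (nm in names(defs)) {
    sub <- as.matrix(cohort[, defs[[nm]]$items, drop = FALSE])
    patterned <- patterned | apply(sub, 1, is_alternating_row)
  }

  flags <- cbind(incomplete = incomplete, straight_line = straight,
                 patterned = patterned)
  bad <- rowSums(flags) > 0
  reason <- apply(flags, 1, function(f)
    paste(colnames(flags)[f], collapse = "+"))
  excluded <- cohort[bad, , drop = FALSE]
  if (nrow(excluded) > 0) excluded$reason <- reason[bad]
  list(retained = cohort[!bad, , drop = FALSE],
       excluded = excluded,
       rule_counts = colSums(flags))
}

#' Screen for a positive depression result
#'
#' Keeps exactly the rows whose PHQ-9 total is at or above the screening
#' threshold (default 5, the conventional mild cut-off).
#'
#' @param scores Score table from [score_cohort()].
#' @param threshold PHQ-9 threshold (default 5).
#' @return Subset of `scores`.
#' @export
screen_positive <- function(scores, threshold = 5) {
  scores[!is.na(scores$dep) & scores$dep >= threshold, , drop = FALSE]
}

#' Full screening report
#'
#' Applies the exclusion rules, scores the retained records, counts
#' severity bands and computes the screening prevalence
#' `100 * n_positive / n_retained`.
#'
#' @param cohort Cohort data frame.
#' @param threshold PHQ-9 screening threshold.
#' @return Object of class `screening_report`.
#' @export
screening_report <- function(cohort, threshold = 5) {
  excl <- apply_exclusions(cohort)
  scores <- score_cohort(excl$retained)
  band_counts <- table(scores$band)
  n_retained <- nrow(scores)
  n_positive <- nrow(screen_positive(scores, threshold))
  out <- list(
    n_raw = nrow(cohort),
    n_excluded = nrow(excl$excluded),
    rule_counts = excl$rule_counts,
    n_retained = n_retained,
    exclusion_pct = 100 * nrow(excl$excluded) / nrow(cohort),
    n_positive = n_positive,
    prevalence_pct = 100 * n_positive / n_retained,
    band_counts = band_counts,
    threshold = threshold
  )
  class(out) <- "screening_report"
  out
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Screening report (PHQ-9 >= %g)\n", x$threshold))
  cat(sprintf("  raw records:      %d\n", x$n_raw))
  cat(sprintf("  excluded:         %d (%.2f%%)  [%s]\n", x$n_excluded,
              x$exclusion_pct,
              paste(names(x$rule_counts), x$rule_counts, sep = "=",
                    collapse = ", ")))
  cat(sprintf("  retained:         %d\n", x$n_retained))
  cat(sprintf("  screen positive:  %d (prevalence %.2f%%)\n",
              x$n_positive, x$prevalence_pct))
  bc <- x$band_counts
  cat("  severity bands:   ",
      paste(names(bc), as.integer(bc), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Descriptives and Pearson correlation matrix
#'
#' Means, SDs and the pairwise product-moment correlation matrix of the
#' four scale totals, with two-sided p-values from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df.
#'
#' @param scores Score table; rows with any missing total are dropped.
#' @param vars Columns to correlate (default the four scale totals).
#' @return List with `mean`, `sd`, `r`, `p` and `n`.
#' @export
pearson_matrix <- function(scores, vars = c("dep", "is", "psycap", "fs")) {
  x <- as.matrix(scores[, vars, drop = FALSE])
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 3) validation_error("need at least 3 complete rows")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    degenerate_error(paste("zero variance in:",
                           paste(vars[sds == 0], collapse = ", ")))
  r <- stats::cor(x)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA
  list(mean = colMeans(x), sd = sds, r = r, p = p, n = n)
}

#' Gender comparison t-test
#'
#' Two-sample Student's t-test (pooled variance by default, matching the
#' plain "independent samples t-test"; Welch available via `welch = TRUE`)
#' of a scale total between the two gender groups.
#'
#' @param scores Score table with a `gender` column.
#' @param variable Column to compare (e.g. `"dep"`).
#' @param welch Use the Welch unequal-variance test instead of pooled.
#' @return List with `t`, `df`, `p`, and the group means.
#' @export
gender_t_test <- function(scores, variable, welch = FALSE) {
  g <- scores$gender
  y <- scores[[variable]]
  keep <- !is.na(g) & !is.na(y) & g %in% c("male", "female")
  g <- factor(g[keep], levels = c("male", "female"))
  y <- y[keep]
  if (any(table(g) < 2))
    validation_error("both gender groups need at least 2 observations")
  ht <- stats::t.test(y ~ g, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, group_means = ht$estimate)
}

#' Harman's single-factor test
#'
#' Common-method-bias heuristic: the percentage of total variance carried
#' by the first unrotated principal component of the pooled standardized
#' item (or scale-score) matrix. Values below 40% are conventionally taken
#' as showing no serious common-method bias.
#'
#' @param x Item matrix (complete cases are used), e.g. all 62 items of a
#'   cohort; or a score table's four totals for the scale-level variant.
#' @return List with `first_factor_pct`, `threshold` (40) and `acceptable`.
#' @export
harman_single_factor <- function(x) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (ncol(x) < 2) validation_error("need at least 2 items")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    degenerate_error("constant item column; correlation undefined")
  ev <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
  pct <- 100 * ev[1] / ncol(x)
  list(first_factor_pct = pct, threshold = 40, acceptable = pct < 40)
}

#' @rdname harman_single_factor
#' @param cohort Cohort data frame; convenience entry point pooling all 62
#'   items.
#' @export
harman_single_factor_cohort <- function(cohort) {
  item_cols <- unlist(lapply(scale_definitions(), `[[`, "items"))
  harman_single_factor(cohort[, item_cols, drop = FALSE])
}
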