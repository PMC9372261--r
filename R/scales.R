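#' Instrument definitions
#'
#' The four self-report instruments the pipeline understands:
#' \describe{
#'   \item{dep}{PHQ-9 depression screener, 9 items scored 0--3, total 0--27,
#'     banded at 5/10/15/20 into mild / moderate / moderately severe /
#'     severe.}
#'   \item{is}{SCL-90 interpersonal-sensitivity subscale, 9 items scored
#'     0--4, total 0--36.}
#'   \item{psycap}{PCQ-24 psychological capital questionnaire, 24 items on a
#'     1--6 Likert scale, total 24--144.}
#'   \item{fs}{Perceived family support, 20 binary (0/1) items, total 0--20.}
#' }
#'
#' @return Named list of scale definitions. Each element has `name`,
#'   `items` (the cohort column names), `n_items`, `item_min`, `item_max`
#'   and, for `dep`, the severity thresholds.
#' @export
scale_definitions <- function() {
  list(
    dep = list(name = "dep", items = paste0("phq", 1:9), n_items = 9L,
               item_min = 0L, item_max = 3L,
               severity_thresholds = c(5L, 10L, 15L, 20L)),
    is = list(name = "is", items = paste0("is", 1:9), n_items = 9L,
              item_min = 0L, item_max = 4L),
    psycap = list(name = "psycap", items = paste0("pcq", 1:24),
                  n_items = 24L, item_min = 1L, item_max = 6L),
    fs = list(name = "fs", items = paste0("fs", 1:20), n_items = 20L,
              item_min = 0L, item_max = 1L)
  )
}

severity_levels <- function() {
  c("none", "mild", "moderate", "moderately_severe", "severe")
}

#' Score one instrument
#'
#' Sums the items of a single instrument for each respondent. Any missing
#' item voids the total for that respondent (listwise principle: no
#' prorating), mirroring the exclusion of incomplete questionnaires.
#'
#' @param items Numeric matrix or data frame, one row per respondent, one
#'   column per item.
#' @param scale One of the definitions returned by [scale_definitions()],
#'   or its name (`"dep"`, `"is"`, `"psycap"`, `"fs"`).
#' @return Numeric vector of totals, `NA` where any item is missing.
#' @export
#' @examples
#' score_scale(rbind(rep(0, 9), rep(3, 9)), "dep")
score_scale <- function(items, scale) {
  if (is.character(scale)) scale <- scale_definitions()[[match.arg(
    scale, names(scale_definitions()))]]
  items <- as.matrix(items)
  if (ncol(items) != scale$n_items)
    validation_error(sprintf("scale '%s' expects %d items, got %d",
                             scale$name, scale$n_items, ncol(items)))
  bad <- which(!is.na(items) &
                 (items < scale$item_min | items > scale$item_max |
                    items != round(items)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    validation_error(sprintf(
      "scale '%s': out-of-range value %s for respondent %s, item %d",
      scale$name, format(items[bad[1, 1], bad[1, 2]]),
      if (!is.null(rownames(items))) rownames(items)[bad[1, 1]] else
        as.character(bad[1, 1]),
      bad[1, 2]))
  }
  totals <- rowSums(items)           # NA propagates when any item missing
  unname(totals)
}

#' PHQ-9 severity band
#'
#' Maps PHQ-9 totals to severity bands using the conventional thresholds
#' 5, 10, 15 and 20: 0--4 none, 5--9 mild, 10--14 moderate, 15--19
#' moderately severe, 20--27 severe.
#'
#' @param dep_total Integer vector of PHQ-9 totals in 0--27 (`NA` allowed).
#' @return Factor with levels `none`, `mild`, `moderate`,
#'   `moderately_severe`, `severe`.
#' @export
#' @examples
#' severity_band(c(0, 4, 5, 14, 19, 20, 27))
severity_band <- function(dep_total) {
  ok <- is.na(dep_total) |
    (dep_total >= 0 & dep_total <= 27 & dep_total == round(dep_total))
  if (!all(ok))
    validation_error(sprintf("PHQ-9 total out of range [0, 27]: %s",
                             format(dep_total[!ok][1])))
  cut(dep_total, breaks = c(-Inf, 4.5, 9.5, 14.5, 19.5, Inf),
      labels = severity_levels())
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability
#' \deqn{\alpha = \frac{k}{k-1}\left(1 -
#'   \frac{\sum_i \sigma^2_i}{\sigma^2_{\mathrm{total}}}\right)}
#' with population (divide-by-n) variances throughout. Rows with any missing
#' item are dropped.
#'
#' @param items Numeric matrix/data frame of item responses (respondents in
#'   rows).
#' @return Alpha coefficient (scalar).
#' @export
#' @examples
#' cronbach_alpha(cbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  items <- items[stats::complete.cases(items), , drop = FALSE]
  k <- ncol(items)
  if (k < 2) validation_error("Cronbach's alpha needs at least 2 items")
  if (nrow(items) < 2)
    validation_error("Cronbach's alpha needs at least 2 complete respondents")
  total_var <- pop_var(rowSums(items))
  if (total_var <= 0)
    degenerate_error("total-score variance is zero; reliability undefined")
  k / (k - 1) * (1 - sum(apply(items, 2, pop_var)) / total_var)
}

#' Kuder-Richardson formula 21
#'
#' Reliability for binary items assuming equal item difficulty:
#' \deqn{KR_{21} = \frac{k}{k-1}\left(1 -
#'   \frac{M(k - M)}{k\,\sigma^2_{\mathrm{total}}}\right)}
#' where `M` is the mean total score and the total variance uses the
#' population (divide-by-n) convention, as for [cronbach_alpha()].
#'
#' @param items Matrix/data frame of strictly 0/1 item responses.
#' @return KR-21 coefficient (scalar).
#' @export
kr21 <- function(items) {
  items <- as.matrix(items)
  items <- items[stats::complete.cases(items), , drop = FALSE]
  if (!all(items %in% c(0, 1)))
    validation_error("KR-21 requires strictly binary (0/1) items")
  k <- ncol(items)
  if (k < 2) validation_error("KR-21 needs at least 2 items")
  totals <- rowSums(items)
  s2 <- pop_var(totals)
  if (s2 <= 0)
    degenerate_error("total-score variance is zero; reliability undefined")
  m <- mean(totals)
  k / (k - 1) * (1 - m * (k - m) / (k * s2))
}

#' Score a cohort on all four instruments
#'
#' @param cohort Cohort data frame as produced by [generate_cohort()] or
#'   [read_cohort()]: columns `id`, `gender`, `phq1..phq9`, `is1..is9`,
#'   `pcq1..pcq24`, `fs1..fs20`.
#' @return Score table: `id`, `gender`, `dep`, `is`, `psycap`, `fs`,
#'   `band` (PHQ-9 severity). Totals are `NA` where any item of that
#'   instrument is missing.
#' @export
score_cohort <- function(cohort) {
  defs <- scale_definitions()
  missing_cols <- setdiff(unlist(lapply(defs, `[[`, "items")),
                          names(cohort))
  if (length(missing_cols) > 0)
    validation_error(paste("cohort is missing item columns:",
                           paste(utils::head(missing_cols, 5),
                                 collapse = ", ")))
  out <- data.frame(
    id = if ("id" %in% names(cohort)) cohort$id else
      as.character(seq_len(nrow(cohort))),
    gender = if ("gender" %in% names(cohort)) cohort$gender else
      NA_character_,
    stringsAsFactors = FALSE
  )
  for (nm in names(defs)) {
    m <- as.matrix(cohort[, defs[[nm]]$items, drop = FALSE])
    rownames(m) <- out$id
    out[[nm]] <- score_scale(m, defs[[nm]])
  }
  out$band <- severity_band(out$dep)
  out
}

#' PCQ-24 component subtotals
#'
#' Optional extras: subtotals for the four six-item PCQ-24 components in
#' their standard order (self-efficacy 1--6, hope 7--12, resilience 13--18,
#' optimism 19--24). Not used by the downstream models.
#'
#' @param cohort Cohort data frame with `pcq1..pcq24` columns.
#' @return Data frame of four component subtotals.
#' @export
psycap_components <- function(cohort) {
  blocks <- list(self_efficacy = 1:6, hope = 7:12,
                 resilience = 13:18, optimism = 19:24)
  out <- lapply(blocks, function(ix)
    rowSums(as.matrix(cohort[, paste0("pcq", ix), drop = FALSE])))
  as.data.frame(out)
}
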