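#' Published study inputs
#'
#' Convenience accessors for the published summary statistics of the
#' freshman depression-screening study that this package's defaults
#' emulate. These are inputs to simulation and desk calculations, not
#' outputs of this package.
#'
#' @details
#' * `study_coefficients()` — the fitted three-way interaction model on the
#'   standardized scale, in design order
#'   `(constant, X, M, XM, W, XW, MW, XMW)` with X = interpersonal
#'   sensitivity, M = psychological capital, W = family support,
#'   Y = depression.
#' * `study_coefficient_ses()` — the published standard errors for the same
#'   eight coefficients (used to calibrate fixed-design power simulations,
#'   see [power_scenario()]).
#' * `study_correlations()` — the published 3x3 Pearson correlation matrix
#'   of (IS, PsyCap, FS).
#' * `study_scale_moments()` — the published means and SDs of the four
#'   scale totals.
#'
#' @return Numeric vector / matrix / list, see Details.
#' @export
study_coefficients <- function() {
  c(constant = -0.058, X = 0.343, M = -0.006, XM = -0.106,
    W = -0.033, XW = -0.032, MW = 0.011, XMW = 0.076)
}

#' @rdname study_coefficients
#' @export
study_coefficient_ses <- function() {
  c(constant = 0.036, X = 0.038, M = 0.039, XM = 0.036,
    W = 0.038, XW = 0.035, MW = 0.035, XMW = 0.027)
}

#' @rdname study_coefficients
#' @export
study_correlations <- function() {
  R <- matrix(c(1, -0.361, -0.286,
                -0.361, 1, 0.229,
                -0.286, 0.229, 1), 3, 3)
  dimnames(R) <- list(c("is", "psycap", "fs"), c("is", "psycap", "fs"))
  R
}

#' @rdname study_coefficients
#' @export
study_scale_moments <- function() {
  list(mean = c(dep = 7.909, is = 14.442, psycap = 102.107, fs = 13.895),
       sd = c(dep = 3.147, is = 6.148, psycap = 13.064, fs = 4.833))
}

#' Generator configuration
#'
#' Configuration for the synthetic item-level cohort generator. Defaults
#' are the published study conditions: n = 694 respondents (the analysed
#' screened sample), Table-style scale means/SDs, the published predictor
#' correlations, the fitted three-way model coefficients, residual SD 0.8
#' and 59.65% women.
#'
#' @param n_respondents Number of respondents.
#' @param latent_correlations 3x3 correlation matrix of the standardized
#'   latents (IS, PsyCap, FS); symmetric, unit diagonal, positive definite.
#' @param scale_means,scale_sds Named numeric vectors (`dep`, `is`,
#'   `psycap`, `fs`) giving the target raw-total moments.
#' @param true_coefficients Length-8 coefficient vector
#'   `(constant, X, M, XM, W, XW, MW, XMW)` generating the standardized
#'   depression latent.
#' @param noise_sd Residual SD of the generating equation (default 0.8).
#' @param female_fraction Fraction of respondents coded female.
#' @param contamination Named list/vector of rates for `incomplete`,
#'   `straight_line` and `patterned` records; each class receives exactly
#'   `round(rate * n)` records.
#' @param seed Root seed; every stage derives its own sub-stream from it.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_respondents = 694,
                             latent_correlations = study_correlations(),
                             scale_means = study_scale_moments()$mean,
                             scale_sds = study_scale_moments()$sd,
                             true_coefficients = study_coefficients(),
                             noise_sd = 0.8,
                             female_fraction = 0.5965,
                             contamination = c(incomplete = 0,
                                               straight_line = 0,
                                               patterned = 0),
                             seed = 1L) {
  if (!is_count(n_respondents))
    validation_error("n_respondents must be a positive count")
  check_symmetric_pd(latent_correlations)
  if (!(length(noise_sd) == 1 && is.finite(noise_sd) && noise_sd > 0))
    validation_error("noise_sd must be a positive scalar")
  if (!(female_fraction >= 0 && female_fraction <= 1))
    validation_error("female_fraction must lie in [0, 1]")
  cont <- c(incomplete = 0, straight_line = 0, patterned = 0)
  cont[names(contamination)] <- unlist(contamination)
  if (any(cont < 0) || sum(cont) >= 1)
    validation_error("contamination rates must be >= 0 and sum to < 1")
  nm <- c("dep", "is", "psycap", "fs")
  scale_means <- scale_means[nm]; scale_sds <- scale_sds[nm]
  if (anyNA(scale_means) || anyNA(scale_sds) || any(scale_sds <= 0))
    validation_error("scale_means/scale_sds must cover dep, is, psycap, fs with positive SDs")
  if (length(true_coefficients) != 8)
    validation_error("true_coefficients must have length 8")
  if (sum(round(cont * n_respondents)) >= n_respondents)
    validation_error("n_respondents too small for the requested contamination")
  structure(list(n_respondents = as.integer(n_respondents),
                 latent_correlations = latent_correlations,
                 scale_means = scale_means, scale_sds = scale_sds,
                 true_coefficients = as.numeric(true_coefficients),
                 noise_sd = noise_sd, female_fraction = female_fraction,
                 contamination = cont, seed = as.integer(seed)),
            class = "generator_config")
}

#' Draw standardized latents (X, M, W, Y)
#'
#' Draws (X, M, W) from a zero-mean unit-variance trivariate normal with
#' the configured correlations, then computes
#' `Y = b0 + b1 X + b2 M + b3 XM + b4 W + b5 XW + b6 MW + b7 XMW + e`,
#' `e ~ Normal(0, noise_sd)`.
#'
#' @param config A [generator_config()].
#' @param n Number of draws (defaults to `config$n_respondents`).
#' @param seed Seed (defaults to the latent sub-stream of `config$seed`).
#' @return Data frame with columns `X`, `M`, `W`, `Y`.
#' @export
generate_latents <- function(config, n = config$n_respondents,
                             seed = substream(config$seed, 1L)) {
  b <- config$true_coefficients
  withr::with_seed(seed, {
    XMW <- matrix(MASS::mvrnorm(n, mu = rep(0, 3),
                                Sigma = config$latent_correlations),
                  ncol = 3)
    X <- XMW[, 1]; M <- XMW[, 2]; W <- XMW[, 3]
    Y <- b[1] + b[2] * X + b[3] * M + b[4] * X * M + b[5] * W +
      b[6] * X * W + b[7] * M * W + b[8] * X * M * W +
      stats::rnorm(n, 0, config$noise_sd)
    data.frame(X = X, M = M, W = W, Y = Y)
  })
}

#' Distribute a scale total over bounded items
#'
#' Allocates each target total across `n_items` items bounded in
#' `[item_min, item_max]` so that the item sum equals the total after
#' rounding and clipping to the feasible range
#' `[n_items * item_min, n_items * item_max]`. Allocation places the excess
#' over the all-minimum configuration by sampling capacity slots uniformly
#' without replacement, so every feasible composition is reachable and the
#' result is deterministic given the seed.
#'
#' @param totals Numeric vector of target totals (finite).
#' @param scale Scale definition (see [scale_definitions()]) or its name.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return Integer matrix, one row per total, one column per item.
#' @export
#' @examples
#' rowSums(discretize_to_items(c(0, 13, 27), "dep", seed = 1))
discretize_to_items <- function(totals, scale, seed = NULL) {
  if (is.character(scale)) scale <- scale_definitions()[[match.arg(
    scale, names(scale_definitions()))]]
  if (any(!is.finite(totals)))
    validation_error("latent totals must be finite")
  k <- scale$n_items
  cap <- scale$item_max - scale$item_min
  lo <- k * scale$item_min; hi <- k * scale$item_max
  tgt <- pmin(pmax(round(totals), lo), hi)
  slots <- rep(seq_len(k), each = cap)
  draw <- function() {
    out <- matrix(scale$item_min, nrow = length(tgt), ncol = k)
    for (i in seq_along(tgt)) {
      rem <- tgt[i] - lo
      if (rem > 0) {
        idx <- sample(slots, rem)
        out[i, ] <- out[i, ] + tabulate(idx, nbins = k)
      }
    }
    out
  }
  m <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  colnames(m) <- scale$items
  storage.mode(m) <- "integer"
  m
}

# ---- contamination / data-quality internals ---------------------------------

# Instruments eligible for straight-line detection: the three polytomous
# ones. A constant binary family-support response (e.g. all "yes") is
# legitimately common and must not look like careless responding.
straightline_scales <- function() c("dep", "is", "psycap")

is_constant_row <- function(x) !anyNA(x) && length(unique(x)) == 1L

is_alternating_row <- function(x) {
  if (anyNA(x) || length(x) < 4) return(FALSE)
  a <- x[1]; b <- x[2]
  if (a == b) return(FALSE)
  all(x == rep_len(c(a, b), length(x)))
}

# Minimal, total-aware adjustments so that a clean record can never trigger
# an exclusion rule. Constancy: break all-but-one constant instruments among
# the polytomous three, preferring non-PHQ instruments so depression totals
# (and severity bands) are preserved. Patterned: swap two adjacent items.
detrigger_record <- function(items, defs) {
  const <- vapply(straightline_scales(), function(nm)
    is_constant_row(items[[nm]]), logical(1))
  if (sum(const) >= 2) {
    for (nm in c("is", "psycap", "dep")) {
      if (sum(const) < 2) break
      if (!const[[nm]]) next
      d <- defs[[nm]]
      v <- items[[nm]]
      if (v[1] > d$item_min && v[1] < d$item_max) {
        v[1] <- v[1] + 1L; v[2] <- v[2] - 1L       # total preserved
      } else if (v[1] == d$item_min) v[1] <- v[1] + 1L
      else v[1] <- v[1] - 1L
      items[[nm]] <- v
      const[[nm]] <- FALSE
    }
  }
  for (nm in names(defs)) {
    v <- items[[nm]]
    if (is_alternating_row(v)) {
      items[[nm]] <- c(v[1], v[3], v[2], v[-(1:3)])  # break strict cycle
    }
  }
  items
}

contaminate_records <- function(rows, classes, defs, seed) {
  withr::with_seed(seed, {
    for (i in seq_along(classes)) {
      cls <- classes[i]
      if (cls == "incomplete") {
        all_items <- unlist(lapply(defs, `[[`, "items"))
        n_miss <- sample(1:3, 1)
        rows[i, sample(all_items, n_miss)] <- NA_integer_
      } else if (cls == "straight_line") {
        for (nm in straightline_scales()) {
          d <- defs[[nm]]
          rows[i, d$items] <- sample(seq(d$item_min, d$item_max), 1)
        }
      } else if (cls == "patterned") {
        d <- defs[["psycap"]]
        ab <- sample(seq(d$item_min, d$item_max), 2)
        rows[i, d$items] <- rep_len(ab, d$n_items)
      }
    }
    rows
  })
}

# Build item columns for a matrix of raw totals (dep, is, psycap, fs),
# de-triggering each clean record.
totals_to_items <- function(totals, defs, seed) {
  withr::with_seed(seed, {
    mats <- lapply(names(defs), function(nm)
      discretize_to_items(totals[, nm], defs[[nm]]))
    names(mats) <- names(defs)
    for (i in seq_len(nrow(totals))) {
      rec <- lapply(mats, function(m) m[i, ])
      fixed <- detrigger_record(rec, defs)
      for (nm in names(defs)) mats[[nm]][i, ] <- fixed[[nm]]
    }
    do.call(cbind, unname(mats))
  })
}

#' Generate a synthetic item-level cohort
#'
#' Draws standardized latents from the configured trivariate-normal +
#' regression structure, rescales them to the configured raw-total means
#' and SDs (the depression latent is standardized by its sample moments
#' first, since the generating equation does not have unit variance),
#' rounds and clips the totals to each instrument's feasible range,
#' distributes them over items, and appends contaminated records that each
#' violate exactly one data-quality rule. Clean records are guaranteed to
#' pass [apply_exclusions()], so contamination-class counts are exact:
#' `round(rate * n)` per class.
#'
#' @param config A [generator_config()].
#' @return Data frame of class `modmod_cohort`: `id`, `gender`, 62 item
#'   columns. The true contamination class of each row is kept in
#'   `attr(, "contamination")` for testing; the screening code never reads
#'   it.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  defs <- scale_definitions()
  n <- config$n_respondents
  n_cont <- round(config$contamination * n)
  n_clean <- n - sum(n_cont)

  lat <- generate_latents(config, n = n)
  zy <- if (n > 1) (lat$Y - mean(lat$Y)) / stats::sd(lat$Y) else 0
  z <- cbind(dep = zy, is = lat$X, psycap = lat$M, fs = lat$W)
  totals <- sweep(sweep(z, 2, config$scale_sds[colnames(z)], `*`),
                  2, config$scale_means[colnames(z)], `+`)

  items <- totals_to_items(totals, defs, seed = substream(config$seed, 2L))
  cohort <- data.frame(id = sprintf("R%05d", seq_len(n)),
                       gender = NA_character_, items,
                       stringsAsFactors = FALSE)
  gender_seed <- substream(config$seed, 4L)
  cohort$gender <- withr::with_seed(gender_seed, ifelse(
    stats::runif(n) < config$female_fraction, "female", "male"))

  classes <- rep("clean", n)
  if (sum(n_cont) > 0) {
    idx <- seq.int(n_clean + 1L, n)
    cls <- rep(names(n_cont), times = n_cont)
    item_cols <- unlist(lapply(defs, `[[`, "items"))
    cohort[idx, item_cols] <- contaminate_records(
      cohort[idx, item_cols, drop = FALSE], cls, defs,
      seed = substream(config$seed, 3L))
    classes[idx] <- cls
  }
  structure(cohort, contamination = classes, class = c("modmod_cohort",
                                                       "data.frame"))
}

#' Fixture cohort reproducing the published screening arithmetic
#'
#' Builds a 2,359-record cohort whose retained records hit the published
#' severity-band counts exactly (1,553 none / 591 mild / 70 moderate /
#' 23 moderately severe / 10 severe) and which contains exactly 112
#' contaminated records (47 incomplete, 47 straight-line, 18 patterned).
#' Depression totals are assigned band-by-band (uniform within band); the
#' other instruments are drawn from the latent model. This fixture emulates
#' the screening arithmetic of the source survey, not its correlation
#' structure (the published correlations describe the post-screening
#' sample; use [generate_cohort()] for those).
#'
#' @param seed Root seed.
#' @return A `modmod_cohort` data frame with 2,359 rows.
#' @export
study_fixture_cohort <- function(seed = 20220729) {
  defs <- scale_definitions()
  band_counts <- c(none = 1553L, mild = 591L, moderate = 70L,
                   moderately_severe = 23L, severe = 10L)
  band_range <- list(none = 0:4, mild = 5:9, moderate = 10:14,
                     moderately_severe = 15:19, severe = 20:27)
  n_clean <- sum(band_counts)
  n_cont <- c(incomplete = 47L, straight_line = 47L, patterned = 18L)
  n <- n_clean + sum(n_cont)

  cfg <- generator_config(n_respondents = n, seed = seed)
  lat <- generate_latents(cfg, n = n)
  dep_totals <- withr::with_seed(substream(seed, 5L), {
    tot <- unlist(lapply(names(band_counts), function(bn)
      sample(band_range[[bn]], band_counts[[bn]], replace = TRUE)))
    # contaminated rows get band-agnostic totals; they are excluded anyway
    c(sample(tot), sample(0:27, sum(n_cont), replace = TRUE))
  })
  mm <- study_scale_moments()
  totals <- cbind(dep = dep_totals,
                  is = mm$mean["is"] + mm$sd["is"] * lat$X,
                  psycap = mm$mean["psycap"] + mm$sd["psycap"] * lat$M,
                  fs = mm$mean["fs"] + mm$sd["fs"] * lat$W)
  items <- totals_to_items(totals, defs, seed = substream(seed, 2L))
  cohort <- data.frame(id = sprintf("R%05d", seq_len(n)),
                       gender = withr::with_seed(
                         substream(seed, 4L),
                         ifelse(stats::runif(n) < 0.5965, "female", "male")),
                       items, stringsAsFactors = FALSE)
  classes <- rep("clean", n)
  idx <- seq.int(n_clean + 1L, n)
  cls <- rep(names(n_cont), times = n_cont)
  item_cols <- unlist(lapply(defs, `[[`, "items"))
  cohort[idx, item_cols] <- contaminate_records(
    cohort[idx, item_cols, drop = FALSE], cls, defs,
    seed = substream(seed, 3L))
  classes[idx] <- cls
  structure(cohort, contamination = classes,
            class = c("modmod_cohort", "data.frame"))
}

#' Read / write a cohort CSV
#'
#' One row per respondent; columns `id`, `gender`, `phq1..phq9`,
#' `is1..is9`, `pcq1..pcq24`, `fs1..fs20`; missing items as empty fields.
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   `modmod_cohort` data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(id = "character",
                                      gender = "character"))
  item_cols <- unlist(lapply(scale_definitions(), `[[`, "items"))
  missing_cols <- setdiff(item_cols, names(x))
  if (length(missing_cols) > 0)
    validation_error(paste("cohort CSV is missing columns:",
                           paste(utils::head(missing_cols, 5),
                                 collapse = ", ")))
  structure(x, class = c("modmod_cohort", "data.frame"))
}
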