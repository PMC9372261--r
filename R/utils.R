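# Internal helpers: error conditions, RNG sub-streams, small validators.

modmod_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "modmod_error", "error"),
                      call = call))
}

validation_error <- function(msg) modmod_stop(msg, "modmod_validation_error")
degenerate_error <- function(msg)
  modmod_stop(msg, c("modmod_degenerate_error", "modmod_validation_error"))
dependency_error <- function(msg) modmod_stop(msg, "modmod_dependency_error")

# Deterministic sub-stream seed derived from a root seed and a stage index.
# Keeps every stage on its own stream so, e.g., adding contamination does not
# perturb the clean records. Result always fits in a 32-bit integer.
substream <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  as.integer((as.double(seed) %% 2147483647 * 69621 + 1000003 * stage) %%
               2147483647)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

# Population (divide-by-n) variance, the convention used for the
# reliability coefficients.
pop_var <- function(x) mean((x - mean(x))^2)

check_symmetric_pd <- function(R, what = "latent_correlations") {
  if (!is.matrix(R) || nrow(R) != ncol(R))
    validation_error(sprintf("%s must be a square matrix", what))
  if (max(abs(R - t(R))) > 1e-8)
    validation_error(sprintf("%s must be symmetric", what))
  if (max(abs(diag(R) - 1)) > 1e-8)
    validation_error(sprintf("%s must have unit diagonal", what))
  ok <- tryCatch({ chol(R); TRUE }, error = function(e) FALSE)
  if (!ok)
    validation_error(sprintf("%s is not positive definite", what))
  invisible(R)
}
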