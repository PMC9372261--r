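# Shared fixtures built in code.

table3_b <- function() study_coefficients()

# A small random model-3 dataset on the latent scale.
random_latents <- function(n = 200, seed = 1, noise_sd = 0.8,
                           b = table3_b()) {
  cfg <- generator_config(n_respondents = n, true_coefficients = b,
                          noise_sd = noise_sd, seed = seed)
  generate_latents(cfg)
}

as_model_frame <- function(lat) {
  data.frame(Y = lat$Y, X = lat$X, M = lat$M, W = lat$W)
}

# Explicit normal-equations OLS: the independent oracle for the
# production QR-based solver.
normal_equations_ols <- function(D, y) {
  drop(solve(t(D) %*% D, t(D) %*% y))
}
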