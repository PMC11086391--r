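## Memoized full-size runs shared across test files, so the default
## experiment (10 subjects x 11 angles x 96 frames) is simulated and
## fitted once per test session.
.run_cache <- new.env(parent = emptyenv())

default_noisy_run <- function() {
  if (is.null(.run_cache$noisy)) {
    tab <- simulate_landmarks(simulation_plan())        # seed 42 defaults
    ft <- extract_feature_table(tab)
    sp <- split_features(ft, fraction_test = 0.2, seed = 7L, unit = "frame")
    .run_cache$noisy <- list(
      features = ft, split = sp,
      gbt = fit_model(model_spec("gbt", seed = 1L), sp$train),
      ols = fit_model(model_spec("ols", seed = 1L), sp$train)
    )
  }
  .run_cache$noisy
}

zero_noise_run <- function() {
  if (is.null(.run_cache$zero)) {
    tab <- simulate_landmarks(simulation_plan(landmark_noise_sd = 0))
    ft <- extract_feature_table(tab)
    sp <- split_features(ft, fraction_test = 0.2, seed = 7L, unit = "frame")
    .run_cache$zero <- list(
      features = ft, split = sp,
      gbt = fit_model(model_spec("gbt", seed = 1L), sp$train)
    )
  }
  .run_cache$zero
}
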