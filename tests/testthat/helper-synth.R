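# shared fixtures: everything is generated in code at test time

# small session: one short run, deterministic behavior available on demand
tiny_spec <- function(n_runs = 1, trials_per_run = 12, run_volumes = 700,
                      ...) {
  design_spec(n_runs = n_runs, trials_per_run = trials_per_run,
              run_volumes = run_volumes, ...)
}

det_stage_model <- function(mean_p = 0.3, mean_c = 0.6, mean_m = 0.15,
                            serial = TRUE) {
  stage_model(mean_p = mean_p, mean_c = mean_c, mean_m = mean_m,
              cv_p = 0, cv_c = 0, cv_m = 0, subject_sd = 0,
              accuracy = 1, serial = serial)
}

quiet_noise <- function(sigma = 0, ...) {
  noise_config(sigma = sigma, drift_sd = 0, n_nuisance = 0, ...)
}

# trials table with behavior, deterministic stages
det_trials <- function(spec = tiny_spec(), model = det_stage_model()) {
  simulate_behavior(make_design(spec), model, c_scale = 1)
}

# linearly separable patterns: one orthogonal direction per mapping
separable_patterns <- function(n_per_class = 4, n_classes = 8,
                               n_features = 16, noise = 0.01) {
  labels <- rep(seq_len(n_classes), each = n_per_class)
  X <- matrix(stats::rnorm(length(labels) * n_features, 0, noise),
              length(labels), n_features)
  for (i in seq_along(labels)) X[i, labels[i]] <- X[i, labels[i]] + 1
  list(X = X, labels = labels,
       runs = rep_len(seq_len(n_per_class), length(labels)))
}
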