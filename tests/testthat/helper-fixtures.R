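# Shared fixtures, built once per test run and cached.  Heavy experiment
# objects are reused across test files (testthat keeps one session).

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env, inherits = FALSE)
}

grf_channels <- function() synth_channels(angles = FALSE)

# the scaled training schedule used by the cross-validated experiments in
# this suite: same staged learning rates, stages of 2500 iterations
test_train_config <- function(seed = 11) {
  train_config(max_iterations = 7500, stage_iterations = 2500,
               eval_every = 250, patience = 4, seed = seed)
}

# small full-channel dataset for preprocessing / io tests
small_dataset <- function() {
  fixture("ds_small", function() {
    generate_dataset(synth_config(n_subjects = 3, n_trials_per_subject = 4,
                                  seed = 7))
  })
}

small_samples <- function() {
  fixture("smp_small", function() build_samples(small_dataset(), "grf"))
}

# 20-subject x 20-trial GRF dataset: the subject-classification study
class20 <- function() {
  fixture("class20", function() {
    cfg <- synth_config(n_subjects = 20, n_trials_per_subject = 20,
                        channels = grf_channels(), seed = 20)
    ds <- generate_dataset(cfg)
    plan <- make_folds(ds, k = 10, seed = 20)
    core <- preprocess_trials(ds, "grf")
    list(ds = ds, plan = plan, core = core)
  })
}

svm_experiment20 <- function() {
  fixture("exp_svm20", function() {
    s <- class20()
    run_experiment(s$ds, model_spec("linear_svm", 20, 6), s$plan,
                   test_train_config(20), core = s$core)
  })
}

mlp256_experiment20 <- function() {
  fixture("exp_mlp256_20", function() {
    s <- class20()
    run_experiment(s$ds, model_spec("mlp", 20, 6, n_layers = 3, width = 256),
                   s$plan, test_train_config(20), core = s$core)
  })
}

# 30-subject x 20-trial GRF dataset: the robustness / reliability study
robust30 <- function() {
  fixture("robust30", function() {
    cfg <- synth_config(n_subjects = 30, n_trials_per_subject = 20,
                        channels = grf_channels(), seed = 11)
    ds <- generate_dataset(cfg)
    plan <- make_folds(ds, k = 10, seed = 11)
    core <- preprocess_trials(ds, "grf")
    list(ds = ds, plan = plan, core = core)
  })
}

sgd_experiment30 <- function() {
  fixture("exp_sgd30", function() {
    s <- robust30()
    run_experiment(s$ds, model_spec("linear_sgd", 30, 6), s$plan,
                   test_train_config(11), core = s$core)
  })
}

mlp1024_experiment30 <- function() {
  fixture("exp_mlp1024_30", function() {
    s <- robust30()
    run_experiment(s$ds, model_spec("mlp", 30, 6, n_layers = 3, width = 1024),
                   s$plan, test_train_config(11), core = s$core)
  })
}
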