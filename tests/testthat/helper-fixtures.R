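# Shared fixtures, built once per test run and memoized in-session.
.fixture_env <- new.env()

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env, inherits = FALSE)
}

clean_record <- function() memo("clean_record", generate_record(
  sim_config(duration_s = 30, hr_bpm = 72, sbp = 120, dbp = 80,
             noise_sd = 0, drift_amp = 0, powerline_amp = 0, jitter = 0,
             seed = 42)))

# moderately noisy default-condition record
default_record <- function() memo("default_record", generate_record(
  sim_config(duration_s = 30, seed = 7)))

# small screened dataset for training smoke tests (~90 segments)
tiny_dataset <- function() memo("tiny_dataset", {
  recs <- generate_dataset(10, "uniform", sim_config(duration_s = 30),
                           seed = 301)
  segs <- preprocess_records(recs)
  build_model_inputs(segs[segs$passed, ])
})

tiny_model_cfg <- function() model_config(width_multiplier = 0.25)
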