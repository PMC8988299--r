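# Session cache: the 20-session recovery set is expensive, so generate and
# score it once per test run and share it between test files.
.session_cache <- new.env(parent = emptyenv())

recovery_sessions <- function(n = 20) {
  key <- paste0("rec", n)
  if (is.null(.session_cache[[key]])) {
    .session_cache[[key]] <- lapply(seq_len(n), function(i) {
      plan <- random_state_plan(seed = 5000 + i)
      ses <- generate_session(plan, seed = 6000 + i)
      sc_hpc <- score_session(ses$cortical, ses$speed, hpc = ses$hpc)
      sc_cort <- score_session(ses$cortical, ses$speed)
      list(truth = ses$truth, duration = max(ses$truth$end),
           hpc = sc_hpc, cortical = sc_cort)
    })
  }
  .session_cache[[key]]
}

# short two-state session for detector unit tests (cached too)
freeze_sleep_session <- function() {
  if (is.null(.session_cache$fs)) {
    plan <- state_plan(c("freezing", "sws"), c(300, 300))
    ses <- generate_session(plan, seed = 11)
    .session_cache$fs <- ses
  }
  .session_cache$fs
}

default_test_params <- function() {
  p <- scoring_params()
  p$speed_threshold <- synth_params()$speed_threshold
  p
}
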