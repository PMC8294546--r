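# Shared fixtures: small simulated trials built once per test run.

quiet_noise <- function(seed = 1L) noise_params(0, 0, seed = seed)

# default-condition trial, cached across tests
sim_cache <- new.env()

cached_trial <- function(key, expr) {
  if (is.null(sim_cache[[key]])) sim_cache[[key]] <- force(expr)
  sim_cache[[key]]
}

default_trial_quiet <- function() cached_trial("quiet", {
  simulate_trial(gait_params(n_strides = 14, timing_jitter_sd = 0),
                 noise = quiet_noise(11))
})

default_trial_noisy <- function() cached_trial("noisy", {
  simulate_trial(gait_params(n_strides = 14), noise = noise_params(seed = 11))
})

detected_events <- function(sim, config = load_config()) {
  lapply(sim$trial$streams[c("LF", "RF", "LH", "RH")],
         detect_claw_events, config = config)
}

# Maximum |detected - true| over all events; true events within 0.25 s of
# the recording end are not required (not detectable without lookahead).
max_event_error <- function(truth, detected, t_end = NULL) {
  if (is.null(t_end))
    t_end <- max(unlist(lapply(detected, function(e) c(e$claw_on, e$claw_off))))
  err <- function(a, b) {
    a <- a[a <= t_end - 0.25]
    if (!length(a)) return(0)
    if (!length(b)) return(Inf)
    max(vapply(a, function(x) min(abs(b - x)), numeric(1)))
  }
  max(vapply(names(truth), function(l)
    max(err(truth[[l]]$claw_on, detected[[l]]$claw_on),
        err(truth[[l]]$claw_off, detected[[l]]$claw_off)), numeric(1)))
}
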