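# deterministic performer: all noise sources switched off
noiseless_params <- function(...) {
  performer_params(rt_scale = 0, extent_cv = 0, angle_sd = 0,
                   dwell_scale = 0, ...)
}

# frame period of a params object, ms
frame_ms <- function(params) 1000 / params$frame_rate

# small simulated two-context session (fast; n_cycles cycles per block)
small_exp1 <- function(seed = 42, n_cycles = 5, params = performer_params()) {
  simulate_experiment1(params, seed = seed, n_cycles = n_cycles)
}
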