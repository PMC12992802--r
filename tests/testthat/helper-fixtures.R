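# Shared fixtures, all generated in code at test time.

# a clean two-step trace: base -> TTX -> GBZ
make_staircase <- function(s1 = 5, s2 = 5, noise = 0, rate = 100,
                           duration = 450, seed = 1, ipsc_times = numeric(0),
                           ipsc_amp = 30) {
  gen_tonic_trace(
    c("TTX", "GBZ"),
    trace_ground_truth(-200, c("base->TTX" = s1, "TTX->GBZ" = s2),
                       ipsc_times = ipsc_times,
                       ipsc_amplitudes = ipsc_amp, noise_sd = noise),
    duration = duration, rate = rate, seed = seed)
}

# small cached network run shared across netsim tests
gl_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_gl_experiment("adult-wt", seed = 7, duration = 2)
    cache
  }
})
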