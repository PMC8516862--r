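# Shared fixtures: everything is generated in code at test time.

# Coarse integration settings for fast structural tests: 250 ms at 4096
# points keeps the default step size and a 4 Hz resolution, so 20 and 40 Hz
# stay on exact bins.
quick_params <- function(..., n_trials = 3L) {
  model_parameters(duration = 250, n_steps = 4096L, n_trials = n_trials, ...)
}

# A drive-only stimulus object for beat-index unit tests.
fake_drive <- function(freq = 40, duration = 600) {
  structure(list(drive_freq = freq,
                 drive_spike_times = make_click_train(freq, duration),
                 duration = duration),
            class = "assr_stimulus")
}

# An isolated theta neuron under constant input I0: a one-cell network with
# all synapses silenced and applied current b = I0.
isolated_neuron_params <- function(I0, duration = 100, n_steps = 10000L) {
  model_parameters(n_E = 1L, n_I = 0L, g_ee = 0, g_ei = 0, g_ie = 0,
                   g_ii = 0, g_de = 0, g_di = 0, b = I0, noise_rate = 0,
                   duration = duration, n_steps = as.integer(n_steps),
                   n_trials = 1L)
}
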