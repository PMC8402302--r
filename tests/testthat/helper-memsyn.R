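# shared builders for the test suite; everything is generated in code

fast_spec <- function(n_spikes = 3, ...) {
  stimulus_spec(spike_rate = 40, spike_duration = 25, n_spikes = n_spikes,
                shape = "biphasic_template", ...)
}

# short coupled run used where only structure, not asymptotics, matters
quick_config <- function(t_end = 300, noise = noise_off(), ...) {
  coupled_config(pre = fhn_params(), post = fhn_params(epsilon = 0.09),
                 device = memristor_params(S = 0.02, d = 10),
                 noise = noise, t_end = t_end, dt = 5e-3,
                 record_every = 4L, resample_period = 28, ...)
}

# strictly periodic train of n spikes with period T starting at t0
periodic_train <- function(n, T, t0 = 0) new_spike_train(t0 + (0:(n - 1)) * T)
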