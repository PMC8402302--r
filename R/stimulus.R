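#' Specification of the neuron-like stimulus waveform
#'
#' Describes the asymmetric neuron-like pulse train used to drive the
#' memristive device: periodic spikes that traverse
#' `0 -> peak_negative -> 0 -> peak_positive -> 0` within each period. The
#' defaults give the -5 V / +4 V asymmetric pulse sampled at 5 kHz.
#'
#' @param spike_rate Spiking frequency in Hz, in \[10, 150\].
#' @param spike_duration Duration of the biphasic excursion in ms, in
#'   \[10, 25\]; the remainder of each period is held at 0 V. Must not exceed
#'   the period `1000 / spike_rate`.
#' @param peak_positive Positive peak voltage (default 4 V).
#' @param peak_negative Negative peak voltage (default -5 V).
#' @param n_spikes Number of spikes in the generated train.
#' @param sample_rate Sampling frequency in Hz (default 5000).
#' @param shape `"fhn_recorded"` (default) replays one steady-state period of
#'   a simulated FHN neuron, rescaled to the requested peaks;
#'   `"biphasic_template"` is a closed-form pair of half-sine lobes, useful
#'   as a fast analytic fixture.
#' @return An object of class `stimulus_spec`.
#' @examples
#' stimulus_spec(spike_rate = 40, n_spikes = 5)
#' @export
stimulus_spec <- function(spike_rate = 40, spike_duration = 25,
                          peak_positive = 4, peak_negative = -5,
                          n_spikes = 10, sample_rate = 5000,
                          shape = c("fhn_recorded", "biphasic_template")) {
  shape <- match.arg(shape)
  check_that(spike_rate >= 10 && spike_rate <= 150,
             "`spike_rate` must lie in [10, 150] Hz")
  check_that(spike_duration >= 10 && spike_duration <= 25,
             "`spike_duration` must lie in [10, 25] ms")
  check_that(spike_duration <= 1000 / spike_rate,
             "`spike_duration` must not exceed the period 1000/spike_rate ms")
  check_that(peak_negative < 0 && peak_positive > 0,
             "peaks must satisfy peak_negative < 0 < peak_positive")
  check_that(n_spikes >= 0 && n_spikes == round(n_spikes),
             "`n_spikes` must be a non-negative integer")
  check_that(sample_rate * spike_duration / 1000 >= 10,
             "`sample_rate` x `spike_duration` must give >= 10 samples per spike")
  structure(list(spike_rate = spike_rate, spike_duration = spike_duration,
                 peak_positive = peak_positive, peak_negative = peak_negative,
                 n_spikes = n_spikes, sample_rate = sample_rate,
                 shape = shape),
            class = "stimulus_spec")
}

# one steady-state FHN period cut at a downward zero crossing, so the cycle
# runs 0 -> min -> 0 -> max -> 0, matching the four-segment pulse anatomy
fhn_template_cycle <- function() {
  tr <- simulate_fhn(fhn_params(), t_end = 400, dt = 5e-3, record_every = 2L)
  tr <- tr[tr$t >= 200, ]
  u <- tr$u
  down <- which(u[-length(u)] >= 0 & u[-1] < 0)
  check_that(length(down) >= 3, "template neuron failed to oscillate")
  i0 <- down[length(down) - 2]
  i1 <- down[length(down) - 1]
  u[i0:i1]
}

#' Generate the neuron-like stimulus
#'
#' Produces the periodic asymmetric spike train described by a
#' [stimulus_spec()]: each period traverses four monotone-trend segments
#' `0 -> peak_negative -> 0 -> peak_positive -> 0`. The negative and positive
#' half-waves are rescaled independently so the extrema match the requested
#' peaks. The result is exactly periodic (identical samples in every period).
#'
#' @param spec A [stimulus_spec()].
#' @param seed Integer seed; the generator is deterministic for a fixed seed.
#' @return A tibble of class `memsyn_ts` with columns `t` (seconds, uniform)
#'   and `x` (volts).
#' @examples
#' ts <- generate_neuron_like_signal(stimulus_spec(n_spikes = 3))
#' c(min(ts$x), max(ts$x))
#' @export
generate_neuron_like_signal <- function(spec, seed = 1L) {
  check_that(inherits(spec, "stimulus_spec"), "`spec` must be a stimulus_spec")
  set.seed(seed)
  period_s <- 1 / spec$spike_rate
  n_per <- round(spec$sample_rate * period_s)
  n_act <- round(spec$sample_rate * spec$spike_duration / 1000)
  if (spec$n_spikes == 0) {
    n <- n_per
    return(new_memsyn_tbl(
      list(t = (seq_len(n) - 1) / spec$sample_rate, x = rep(0, n)),
      "memsyn_ts", stimulus_spec = spec))
  }
  phase <- (seq_len(n_act) - 0.5) / n_act  # in (0, 1)
  if (spec$shape == "biphasic_template") {
    cyc <- ifelse(phase < 0.5,
                  spec$peak_negative * sin(2 * pi * phase),
                  spec$peak_positive * sin(2 * pi * (phase - 0.5)))
  } else {
    u <- fhn_template_cycle()
    cyc <- approx(seq(0, 1, length.out = length(u)), u, xout = phase)$y
    cyc <- ifelse(cyc < 0,
                  cyc * abs(spec$peak_negative) / abs(min(cyc)),
                  cyc * spec$peak_positive / max(cyc))
  }
  one <- c(cyc, rep(0, n_per - n_act))
  x <- rep(one, spec$n_spikes)
  n <- length(x)
  new_memsyn_tbl(list(t = (seq_len(n) - 1) / spec$sample_rate, x = x),
                 "memsyn_ts", stimulus_spec = spec)
}

#' Rescale a stimulus to a target positive peak
#'
#' Applies one linear gain so that `max(x)` equals `target_peak`; the
#' negative peak scales proportionally, preserving the waveform's asymmetry
#' ratio (e.g. -5:4).
#'
#' @param ts A time-series tibble with columns `t` and `x`.
#' @param target_peak Desired positive peak (V).
#' @return The rescaled series.
#' @examples
#' ts <- generate_neuron_like_signal(stimulus_spec(n_spikes = 2))
#' max(scale_peak_amplitude(ts, 2)$x)
#' @export
scale_peak_amplitude <- function(ts, target_peak) {
  check_that(is.data.frame(ts) && all(c("t", "x") %in% names(ts)),
             "`ts` must have columns `t` and `x`")
  rng <- range(ts$x)
  check_that(diff(rng) > 0, "`ts` is constant: peak amplitude is undefined")
  out <- ts
  out$x <- ts$x * (target_peak / max(ts$x))
  out
}

#' Read / write two-column time-series files
#'
#' Plain delimited text with columns time (seconds) and value. A header line
#' is optional on read. The round trip preserves `t` and `x` to better than
#' 1e-9.
#'
#' @param path File path.
#' @param delim Field delimiter (default tab).
#' @return `read_timeseries()` returns a `memsyn_ts` tibble with columns
#'   `t`, `x`.
#' @export
read_timeseries <- function(path, delim = "\t") {
  first <- readLines(path, n = 1)
  has_header <- !grepl("^\\s*[-+0-9.]", first)
  df <- readr::read_delim(path, delim = delim, col_names = has_header,
                          show_col_types = FALSE, progress = FALSE)
  check_that(ncol(df) == 2,
             sprintf("expected 2 columns (time, value), found %d", ncol(df)))
  names(df) <- c("t", "x")
  check_that(all(is.finite(df$t)) && all(is.finite(df$x)),
             "non-numeric or missing entries in time-series file")
  bad <- which(diff(df$t) <= 0)
  if (length(bad) > 0) {
    line <- bad[1] + 1 + has_header
    abort(sprintf("time column is not strictly increasing at line %d", line),
          class = "memsyn_parse_error")
  }
  new_memsyn_tbl(df, "memsyn_ts")
}

#' @param ts Time-series tibble with columns `t` and `x`.
#' @rdname read_timeseries
#' @export
write_timeseries <- function(ts, path, delim = "\t") {
  check_that(all(c("t", "x") %in% names(ts)), "`ts` must have columns t, x")
  readr::write_delim(ts[c("t", "x")], path, delim = delim)
  invisible(path)
}
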