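#' Configuration of the one-way coupled neuron-memristor-neuron system
#'
#' The presynaptic FHN neuron drives the memristive device; the device
#' current feeds the postsynaptic neuron's membrane equation as
#' `du2/dt = f(u2) - v2 + j(u1) * S * d`. There is no feedback from the
#' postsynaptic pair to the presynaptic one. The device sees the
#' presynaptic potential scaled by `amplitude_gain` (volts per model unit),
#' representing the experimenter's drive-level potentiometer; the FHN
#' internal dynamics are not rescaled.
#'
#' @param pre,post [fhn_params()] for the two neurons.
#' @param device [memristor_params()].
#' @param noise [noise_spec()]; stochasticity enters only through device
#'   parameter resampling (no additive dynamical noise).
#' @param dt Integration step in model-time units (default 5e-3).
#' @param t_end Run length in model-time units.
#' @param transient_discard Fraction of the run treated as transient.
#' @param amplitude_gain Volts at the device input per unit of `u1`.
#' @param record_every Record every this many steps.
#' @param resample_period Model-time between per-cycle noise redraws;
#'   default is the presynaptic neuron's limit-cycle period (measured once
#'   at construction).
#' @return An object of class `coupled_config`.
#' @export
coupled_config <- function(pre = fhn_params(), post = fhn_params(),
                           device = memristor_params(),
                           noise = noise_spec(), dt = 5e-3, t_end = 2000,
                           transient_discard = 0.5, amplitude_gain = 1,
                           record_every = 4L, resample_period = NULL) {
  check_that(inherits(pre, "fhn_params") && inherits(post, "fhn_params"),
             "`pre` and `post` must be fhn_params")
  check_that(inherits(device, "memristor_params"),
             "`device` must be memristor_params")
  check_that(inherits(noise, "noise_spec"), "`noise` must be a noise_spec")
  check_that(dt > 0, "`dt` must be > 0")
  check_that(t_end > dt, "`t_end` must exceed `dt`")
  check_that(transient_discard >= 0 && transient_discard < 1,
             "`transient_discard` must lie in [0, 1)")
  check_that(amplitude_gain >= 0, "`amplitude_gain` must be >= 0")
  if (is.null(resample_period)) resample_period <- fhn_period(pre)
  structure(list(pre = pre, post = post, device = device, noise = noise,
                 dt = dt, t_end = t_end,
                 transient_discard = transient_discard,
                 amplitude_gain = amplitude_gain,
                 record_every = as.integer(record_every),
                 resample_period = resample_period),
            class = "coupled_config")
}

#' Vector field of the coupled system
#'
#' Evaluates the right-hand side of the coupled equations at one or more
#' states. The presynaptic terms are exactly the uncoupled FHN vector
#' field; the postsynaptic membrane equation adds the memristive forcing
#' `c = j(amplitude_gain * u1) * S * d`.
#'
#' @param state Data frame with columns `u1`, `v1`, `u2`, `v2` (and `w` in
#'   relaxation mode).
#' @param config A [coupled_config()].
#' @param device_params Optional stochastic realisation (row of
#'   [sample_params()]); defaults to the nominal device parameters.
#' @return A tibble with columns `du1`, `dv1`, `du2`, `dv2` (plus `dw` in
#'   relaxation mode) and the forcing `c`.
#' @export
coupled_derivative <- function(state, config, device_params = NULL) {
  check_that(all(c("u1", "v1", "u2", "v2") %in% names(state)),
             "`state` must have columns u1, v1, u2, v2")
  dev <- config$device
  if (!is.null(device_params)) {
    dev$E_m <- device_params$E_m
    dev$E_b <- device_params$E_b
    dev$rho <- device_params$rho
  }
  udev <- config$amplitude_gain * state$u1
  relax <- dev$mode == "relaxation"
  w <- if (relax) state$w else filament_fraction(udev, dev)
  j <- current_density(udev, w, dev)
  cc <- j * dev$S * dev$d
  pre_d <- fhn_derivative(data.frame(u = state$u1, v = state$v1), config$pre)
  post_d <- fhn_derivative(data.frame(u = state$u2, v = state$v2),
                           config$post)
  out <- tibble::tibble(du1 = pre_d$du, dv1 = pre_d$dv,
                        du2 = post_d$du + cc, dv2 = post_d$dv, c = cc)
  if (relax) out$dw <- (filament_fraction(udev, dev) - w) / dev$tau_w
  out
}

#' Simulate the coupled system
#'
#' Fixed-step RK4 integration of the coupled equations with device
#' parameters held piecewise-constant between noise resamplings. All random
#' draws are made up front from the R RNG, so a fixed seed reproduces the
#' trace exactly; with the noise policy `"off"` the run is fully
#' deterministic.
#'
#' @param config A [coupled_config()].
#' @param init Numeric vector `c(u1, v1, u2, v2)` (a fifth element
#'   initialises `w` in relaxation mode). The default starts the two
#'   neurons at distinct phases of their cycles.
#' @param seed Integer seed for the device-parameter draws.
#' @return A tibble of class `memsyn_trace` with columns `t`, `u1`, `v1`,
#'   `u2`, `v2`, `j` (device current density), `w` (filament fraction) and
#'   `c` (postsynaptic forcing `j*S*d`), plus the config as an attribute.
#' @examples
#' cfg <- coupled_config(t_end = 200, resample_period = 25)
#' tr <- simulate_coupled(cfg, seed = 1)
#' names(tr)
#' @export
simulate_coupled <- function(config, init = c(-1, 0.5, 1.5, -0.3),
                             seed = 1L) {
  check_that(inherits(config, "coupled_config"),
             "`config` must be a coupled_config")
  set.seed(seed)
  n_steps <- as.integer(round(config$t_end / config$dt))
  noise <- config$noise
  if (noise$resample == "off") {
    resample_every <- 0L
    draws <- matrix(numeric(0), nrow = 0, ncol = 3)
  } else {
    resample_every <- if (noise$resample == "per_step") 1L else
      max(1L, as.integer(round(config$resample_period / config$dt)))
    n_blocks <- n_steps %/% resample_every + 1L
    f <- draw_noise_factors(noise, n_blocks)
    draws <- cbind(f$f_Em, f$f_Eb, f$f_rho)
  }
  dev <- config$device
  out <- simulate_coupled_cpp(
    as_fhn_vector(config$pre), as_fhn_vector(config$post),
    as_device_vector(dev), draws, resample_every, as.numeric(init),
    config$amplitude_gain, dev$S, dev$d, config$dt, n_steps,
    config$record_every, as.integer(dev$mode == "relaxation"), dev$tau_w)
  new_memsyn_tbl(out, "memsyn_trace", config = config, seed = seed)
}

#' Coupling strength of a trace
#'
#' The dimensionless coupling strength `z` is the steady-state peak of the
#' magnitude of the postsynaptic forcing term `|j(u1) * S * d|`.
#'
#' @param trace A `memsyn_trace`.
#' @param transient_discard Fraction of the run discarded first (default
#'   from the trace's config).
#' @return The scalar `z`.
#' @export
coupling_strength <- function(trace, transient_discard = NULL) {
  cfg <- attr(trace, "config")
  if (is.null(transient_discard))
    transient_discard <- if (!is.null(cfg)) cfg$transient_discard else 0.5
  t_cut <- min(trace$t) + transient_discard * diff(range(trace$t))
  cc <- trace$c[trace$t >= t_cut]
  check_that(length(cc) > 0, "empty steady-state window")
  max(abs(cc))
}

# noise-off reference run used to convert between load resistance and z,
# and to read off the presynaptic amplitude
reference_run <- function(config) {
  cfg <- config
  cfg$noise <- noise_off()
  tr <- simulate_coupled(cfg, seed = 1L)
  t_cut <- min(tr$t) + cfg$transient_discard * diff(range(tr$t))
  st <- tr[tr$t >= t_cut, ]
  list(peak_jS = max(abs(st$j)) * config$device$S,
       u1_max = max(st$u1))
}

majority_vote <- function(reports) {
  regimes <- vapply(reports, function(r) r$regime, character(1))
  ratios <- vapply(reports, function(r)
    if (is.na(r$ratio_p)) NA_character_ else
      paste0(r$ratio_p, ":", r$ratio_q), character(1))
  reg_tab <- sort(table(regimes), decreasing = TRUE)
  regime <- names(reg_tab)[1]
  in_reg <- which(regimes == regime)
  rat_tab <- sort(table(ratios[in_reg]), decreasing = TRUE)
  ratio <- if (length(rat_tab)) names(rat_tab)[1] else NA_character_
  conf <- mean(vapply(reports[in_reg], function(r) r$confidence, numeric(1)))
  zs <- vapply(reports, function(r) r$z, numeric(1))
  list(regime = regime, ratio = ratio, confidence = conf,
       z_measured = median(zs, na.rm = TRUE),
       votes = sum(regimes == regime))
}

sweep_engine <- function(config, values, value_name, apply_value, n_reps,
                         seed, ...) {
  check_that(length(values) >= 2, "need at least 2 sweep points")
  rows <- purrr::imap(values, function(val, i) {
    cfg <- apply_value(config, val)
    reports <- lapply(seq_len(n_reps), function(r) {
      tr <- simulate_coupled(cfg, seed = seed + 1000L * (i - 1L) + r)
      classify_regime(tr, ...)
    })
    mv <- majority_vote(reports)
    tibble::tibble("{value_name}" := val, regime = mv$regime,
                   ratio = mv$ratio, confidence = mv$confidence,
                   z_measured = mv$z_measured, votes = mv$votes,
                   n_reps = n_reps)
  })
  new_memsyn_tbl(dplyr::bind_rows(rows), "memsyn_map",
                 value_name = value_name, config = config, seed = seed)
}

#' Sweep the coupling strength and map synchronization regimes
#'
#' For each requested coupling strength `z`, scales the equivalent load
#' resistance `d` so the noise-off steady-state peak of `|j * S * d|`
#' equals `z` (the device current is independent of `d` because the
#' coupling is one-way), runs `n_reps` stochastic replicates, classifies
#' each with the locking detector, and reports the majority regime.
#'
#' @param config A [coupled_config()].
#' @param z_values Coupling strengths to visit.
#' @param n_reps Replicate seeds per point (default 5).
#' @param seed Base seed.
#' @param ... Passed to [classify_regime()].
#' @return A tibble of class `memsyn_map` with one row per sweep point:
#'   the sweep value, majority `regime`, modal `ratio`, mean `confidence`,
#'   median measured `z`, and vote counts.
#' @export
sweep_coupling <- function(config, z_values, n_reps = 5, seed = 1L, ...) {
  ref <- reference_run(config)
  check_that(ref$peak_jS > 0, "reference device current is zero; cannot set z")
  sweep_engine(config, z_values, "z", function(cfg, z) {
    cfg$device$d <- z / ref$peak_jS
    cfg
  }, n_reps, seed, ...)
}

#' Sweep the presynaptic drive amplitude
#'
#' For each requested device drive peak (volts), sets `amplitude_gain` so
#' the steady-state positive peak of the device input `amplitude_gain * u1`
#' equals that value, then classifies the regime as in [sweep_coupling()].
#'
#' In the hardware experiment the drive level is set by the presynaptic
#' generator's potentiometer, which changes the oscillator's operating
#' point (its spiking rate rises with the dial) as well as the voltage
#' reaching the device. Passing a `potentiometer` function (drive peak in
#' volts -> presynaptic `epsilon`) emulates that dial: at each sweep point
#' the presynaptic neuron's recovery rate is set from the curve (holding
#' its `I/epsilon` ratio and `alpha`, `beta` fixed) before the gain is
#' normalised. With `potentiometer = NULL` only the gain is swept.
#'
#' @param peak_values Device drive peaks (V) to visit.
#' @param potentiometer Optional function mapping drive peak to presynaptic
#'   `epsilon`, e.g. [paper2021_potentiometer()].
#' @inheritParams sweep_coupling
#' @return A `memsyn_map` tibble with value column `amplitude`.
#' @export
sweep_amplitude <- function(config, peak_values, n_reps = 5, seed = 1L,
                            potentiometer = NULL, ...) {
  if (is.null(potentiometer)) {
    ref <- reference_run(config)
    check_that(ref$u1_max > 0, "presynaptic amplitude is zero")
    return(sweep_engine(config, peak_values, "amplitude",
                        function(cfg, pk) {
                          cfg$amplitude_gain <- pk / ref$u1_max
                          cfg
                        }, n_reps, seed, ...))
  }
  i_ratio <- config$pre$I / config$pre$epsilon
  sweep_engine(config, peak_values, "amplitude", function(cfg, pk) {
    e1 <- potentiometer(pk)
    cfg$pre <- suppressWarnings(
      fhn_params(epsilon = e1, I = i_ratio * e1,
                 alpha = config$pre$alpha, beta = config$pre$beta))
    cfg$resample_period <- fhn_period(cfg$pre)
    ref <- reference_run(cfg)
    cfg$amplitude_gain <- pk / ref$u1_max
    cfg
  }, n_reps, seed, ...)
}

#' Contiguous regime regions of a sweep map
#'
#' Groups consecutive sweep points with the same regime (and, for locked
#' points, the same ratio) into regions. Region edges are the midpoints
#' between the last point inside and the first point outside (the grid
#' endpoints at the boundaries), i.e. the sweep's resolution limit.
#'
#' @param map A `memsyn_map` from [sweep_coupling()] or [sweep_amplitude()].
#' @return A tibble with columns `regime`, `ratio`, `lo`, `hi`, `n_points`.
#' @export
regime_regions <- function(map) {
  value_name <- attr(map, "value_name")
  if (is.null(value_name))
    value_name <- setdiff(names(map), c("regime", "ratio", "confidence",
                                        "z_measured", "votes", "n_reps"))[1]
  v <- map[[value_name]]
  key <- paste(map$regime, ifelse(map$regime == "locked", map$ratio, ""))
  run <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  purrr::map_dfr(split(seq_along(v), run), function(idx) {
    i0 <- min(idx); i1 <- max(idx)
    lo <- if (i0 == 1) v[1] else (v[i0 - 1] + v[i0]) / 2
    hi <- if (i1 == length(v)) v[i1] else (v[i1] + v[i1 + 1]) / 2
    tibble::tibble(regime = map$regime[i0], ratio = map$ratio[i0],
                   lo = lo, hi = hi, n_points = length(idx))
  })
}
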