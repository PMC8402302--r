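#' Memristive device parameters
#'
#' Parameters of the filament-fraction memristor model. The current density
#' through the device is a state-weighted mix of ohmic and Poole-Frenkel
#' conduction,
#' \deqn{j = w\,u/\rho + (1 - w)\,u\,e^{b u - E_b},}
#' where the filament fraction
#' \deqn{w(u) = \mathrm{clamp}\{A\,e^{-(E_m - \alpha_1 u)/kT},\ 0,\ 1\}}
#' is the fraction of the insulator occupied by conductive filaments. `E_m`
#' is the ion-migration barrier, `E_b` the effective Poole-Frenkel
#' conduction barrier, `rho` the resistivity of the filamentary path, `b`
#' the field coefficient, `kT` a lumped thermal energy (no self-consistent
#' Joule heating), `alpha1` the field-barrier coupling whose sign sets the
#' SET polarity (negative by default so the device SETs at negative
#' voltage), `A` the filament-fraction prefactor, `S` the conductive
#' filament area (device current `i = j * S`), and `d` the equivalent load
#' resistance through which the device couples into the postsynaptic neuron.
#'
#' Voltages are in volts; `j` is a model current density, so absolute
#' calibration to amperes is an external scale factor.
#'
#' @param rho Filament resistivity (> 0).
#' @param b Poole-Frenkel field coefficient (1/V).
#' @param E_b Conduction barrier (same units as `b * u`).
#' @param E_m Ion-migration barrier.
#' @param alpha1 Field-barrier coupling; negative means SET at negative bias.
#' @param A Filament-fraction prefactor (> 0).
#' @param kT Lumped thermal energy (> 0).
#' @param S Conductive filament area (>= 0).
#' @param d Equivalent load resistance (>= 0).
#' @param mode `"quasi_static"` (default): `w` is an instantaneous function
#'   of the applied voltage, the literal first-order model.
#'   `"relaxation"`: `w` relaxes towards `w_inf(u)` with time constant
#'   `tau_w`, giving the state memory that opens the I-V loop.
#' @param tau_w Relaxation time constant (seconds of stimulus time), used in
#'   `"relaxation"` mode only.
#' @return An object of class `memristor_params`.
#' @examples
#' memristor_params()
#' @export
memristor_params <- function(rho = 1, b = 1, E_b = 5, E_m = 2.3,
                             alpha1 = -1, A = 1, kT = 0.2, S = 0.02, d = 1,
                             mode = c("quasi_static", "relaxation"),
                             tau_w = 5e-3) {
  mode <- match.arg(mode)
  check_that(rho > 0, "`rho` must be > 0")
  check_that(kT > 0, "`kT` must be > 0")
  check_that(A > 0, "`A` must be > 0")
  check_that(S >= 0, "`S` must be >= 0")
  check_that(d >= 0, "`d` must be >= 0")
  check_that(tau_w > 0, "`tau_w` must be > 0")
  structure(list(rho = rho, b = b, E_b = E_b, E_m = E_m, alpha1 = alpha1,
                 A = A, kT = kT, S = S, d = d, mode = mode, tau_w = tau_w),
            class = "memristor_params")
}

#' @export
print.memristor_params <- function(x, ...) {
  cat(sprintf(paste0("<memristor_params> rho = %g, b = %g, E_b = %g, ",
                     "E_m = %g, alpha1 = %g, A = %g, kT = %g, S = %g, ",
                     "d = %g, mode = %s\n"),
              x$rho, x$b, x$E_b, x$E_m, x$alpha1, x$A, x$kT, x$S, x$d,
              x$mode))
  invisible(x)
}

as_device_vector <- function(p) {
  c(p$rho, p$b, p$E_b, p$E_m, p$alpha1, p$A, p$kT)
}

#' Cycle-to-cycle parameter fluctuation specification
#'
#' Normally distributed relative fluctuations of the ion-migration barrier
#' `E_m` (default dispersion 10%), the Poole-Frenkel conduction barrier
#' `E_b` (1%) and the ohmic resistivity `rho` (10%). Draws are truncated at
#' 1e-6 of the nominal value so parameters stay positive.
#'
#' @param sigma_Em_rel Relative SD of `E_m` (default 0.10).
#' @param sigma_Eb_rel Relative SD of `E_b` (default 0.01).
#' @param sigma_rho_rel Relative SD of `rho` (default 0.10).
#' @param resample `"per_cycle"` (one draw per stimulus period, the default),
#'   `"per_step"` (one draw per sample), or `"off"` (no fluctuations).
#' @return An object of class `noise_spec`.
#' @examples
#' noise_spec()
#' noise_off()
#' @export
noise_spec <- function(sigma_Em_rel = 0.10, sigma_Eb_rel = 0.01,
                       sigma_rho_rel = 0.10,
                       resample = c("per_cycle", "per_step", "off")) {
  resample <- match.arg(resample)
  check_that(sigma_Em_rel >= 0 && sigma_Eb_rel >= 0 && sigma_rho_rel >= 0,
             "noise dispersions must be >= 0")
  structure(list(sigma_Em_rel = sigma_Em_rel, sigma_Eb_rel = sigma_Eb_rel,
                 sigma_rho_rel = sigma_rho_rel, resample = resample),
            class = "noise_spec")
}

#' @rdname noise_spec
#' @export
noise_off <- function() noise_spec(0, 0, 0, resample = "off")

#' Filament fraction as a function of applied voltage
#'
#' @param u Applied voltage (V), vectorised.
#' @param params A [memristor_params()] object.
#' @return `w` in \[0, 1\].
#' @examples
#' filament_fraction(c(-3, 0, 3), memristor_params())
#' @export
filament_fraction <- function(u, params) {
  w <- params$A * exp(-(params$E_m - params$alpha1 * u) / params$kT)
  pmin(pmax(w, 0), 1)
}

#' Memristor current density
#'
#' `j = w * u / rho + (1 - w) * u * exp(b * u - E_b)`: the ohmic filament
#' branch weighted by the filament fraction plus the Poole-Frenkel branch in
#' the remaining insulator. Both terms are proportional to `u`, so
#' `j(0) = 0` exactly — the pinched-hysteresis fingerprint.
#'
#' @param u Applied voltage (V), vectorised.
#' @param w Filament fraction in \[0, 1\] (vectorised, recycled against `u`).
#' @param params A [memristor_params()] object.
#' @return Current density `j` (model units); device current is `j * S`.
#' @examples
#' current_density(1, w = 1, memristor_params(rho = 2))
#' @export
current_density <- function(u, w, params) {
  check_that(all(w >= 0 & w <= 1), "`w` must lie in [0, 1]")
  w * u / params$rho + (1 - w) * u * exp(params$b * u - params$E_b)
}

# n x 3 tibble of multiplicative factors for (E_m, E_b, rho)
draw_noise_factors <- function(noise, n) {
  if (noise$resample == "off" || n == 0) {
    return(tibble::tibble(f_Em = rep(1, n), f_Eb = rep(1, n),
                          f_rho = rep(1, n)))
  }
  clamp <- function(x) pmax(x, 1e-6)
  tibble::tibble(
    f_Em = clamp(rnorm(n, 1, noise$sigma_Em_rel)),
    f_Eb = clamp(rnorm(n, 1, noise$sigma_Eb_rel)),
    f_rho = clamp(rnorm(n, 1, noise$sigma_rho_rel))
  )
}

#' Draw fluctuating device parameters
#'
#' Returns `n` stochastic realisations of the device parameters with
#' `E_m`, `E_b` and `rho` perturbed per the noise specification (all other
#' fields unchanged). With `resample = "off"` the nominal values are
#' returned. Draws consume the R RNG stream, so they are deterministic under
#' `set.seed()`.
#'
#' @param params A [memristor_params()] object.
#' @param noise A [noise_spec()] object.
#' @param n Number of realisations.
#' @return A tibble with `n` rows and columns `E_m`, `E_b`, `rho`.
#' @examples
#' set.seed(1)
#' sample_params(memristor_params(), noise_spec(), n = 3)
#' @export
sample_params <- function(params, noise, n = 1) {
  f <- draw_noise_factors(noise, n)
  tibble::tibble(E_m = params$E_m * f$f_Em,
                 E_b = params$E_b * f$f_Eb,
                 rho = params$rho * f$f_rho)
}

# label samples of a periodic loop by polarity and sweep direction
label_segments <- function(v) {
  dv <- c(diff(v), utils::tail(diff(v), 1))
  ifelse(v < 0,
         ifelse(dv <= 0, "neg_down", "neg_up"),
         ifelse(dv >= 0, "pos_up", "pos_down"))
}

#' Stochastic I-V sweep
#'
#' Replays the stimulus `n_cycles` times through the device. Cycles are
#' independent replicates: parameters are redrawn per the noise policy and,
#' in relaxation mode, the state is re-initialised at `w_inf` of the first
#' sample. With noise off all cycles are bit-identical.
#'
#' @param stimulus A time-series tibble (`t` seconds, `x` volts) spanning
#'   both polarities.
#' @param params A [memristor_params()] object.
#' @param noise A [noise_spec()] object.
#' @param n_cycles Number of replicate cycles.
#' @param mode Override of the device state-update mode.
#' @return A tibble of class `memsyn_iv` with columns `cycle`, `t`, `v`,
#'   `i`, `w`, `segment`.
#' @examples
#' stim <- generate_neuron_like_signal(stimulus_spec(n_spikes = 2))
#' iv <- iv_sweep(stim, memristor_params(), noise_off(), n_cycles = 2)
#' all(iv$i[iv$v == 0] == 0)
#' @export
iv_sweep <- function(stimulus, params, noise = noise_spec(), n_cycles = 10,
                     mode = params$mode) {
  check_that(all(c("t", "x") %in% names(stimulus)),
             "`stimulus` must have columns `t` and `x`")
  v <- stimulus$x
  if (min(v) >= 0 || max(v) <= 0)
    warn("stimulus does not span both polarities: no full switching loop")
  dt_s <- median(diff(stimulus$t))
  n <- length(v)
  seg <- label_segments(v)
  out <- vector("list", n_cycles)
  for (cy in seq_len(n_cycles)) {
    n_draw <- if (noise$resample == "per_step") n else 1L
    f <- draw_noise_factors(noise, n_draw)
    p <- params
    E_m <- p$E_m * f$f_Em
    E_b <- p$E_b * f$f_Eb
    rho <- p$rho * f$f_rho
    w_inf <- pmin(pmax(p$A * exp(-(E_m - p$alpha1 * v) / p$kT), 0), 1)
    if (mode == "quasi_static") {
      w <- w_inf
    } else {
      a <- exp(-dt_s / p$tau_w)
      # exact exponential step of dw/dt = (w_inf - w)/tau_w on each sample
      w <- stats::filter((1 - a) * w_inf, a, method = "recursive",
                         init = w_inf[1])
      w <- pmin(pmax(as.numeric(w), 0), 1)
    }
    j <- w * v / rho + (1 - w) * v * exp(p$b * v - E_b)
    out[[cy]] <- tibble::tibble(cycle = cy, t = stimulus$t, v = v,
                                i = j * p$S, w = w, segment = seg)
  }
  new_memsyn_tbl(dplyr::bind_rows(out), "memsyn_iv", params = params,
                 noise = noise, mode = mode)
}

# secant resistance |v/i| at the sample of a segment subset closest to v_read
read_resistance <- function(v, i, idx, v_read) {
  if (length(idx) == 0) return(NA_real_)
  k <- idx[which.min(abs(v[idx] - v_read))]
  if (i[k] == 0) return(Inf)
  abs(v[k] / i[k])
}

#' Extract resistive-switching metrics from I-V cycles
#'
#' For each cycle: `R_HRS` is the secant resistance `|v/i|` at the read
#' voltage on the entering negative branch (before SET), `R_LRS` the same on
#' the returning negative branch (after SET); `V_set` (negative) and
#' `V_reset` (positive) are the voltages of maximal `|d log|i| / dv|` on the
#' respective branches. A cycle counts as switched (SET observed) when
#' `R_HRS / R_LRS >= hrs_lrs_threshold_ratio`; otherwise a no-switch
#' sentinel row is returned (`switched = FALSE`, `V_set = NA`).
#'
#' @param iv A `memsyn_iv` tibble from [iv_sweep()] (or any tibble with
#'   columns `cycle`, `v`, `i`, `segment`).
#' @param read_frac Read voltage as a fraction of the smaller peak
#'   (default 0.5).
#' @param hrs_lrs_threshold_ratio Minimum `R_HRS / R_LRS` to call a switch
#'   (default 10; partial filament growth routinely gives small resistance
#'   contrasts without a genuine transition to the ohmic branch).
#' @return A tibble with one row per cycle: `cycle`, `V_set`, `V_reset`,
#'   `R_HRS`, `R_LRS`, `switched`.
#' @export
extract_switching <- function(iv, read_frac = 0.5,
                              hrs_lrs_threshold_ratio = 10) {
  check_that(all(c("cycle", "v", "i", "segment") %in% names(iv)),
             "`iv` must have columns cycle, v, i, segment")
  check_that(min(iv$v) < 0 && max(iv$v) > 0,
             "I-V loop must span both polarities")
  v_read <- read_frac * min(max(iv$v), abs(min(iv$v)))
  one_cycle <- function(d) {
    v <- d$v; i <- d$i; seg <- d$segment
    r_hrs <- read_resistance(v, i, which(seg == "neg_down"), -v_read)
    r_lrs <- read_resistance(v, i, which(seg == "neg_up"), -v_read)
    logi <- log(pmax(abs(i), 1e-300))
    slope_at <- function(idx) {
      # the log-current slope diverges near the pinch point v = 0; restrict
      # the knee search to beyond the read voltage
      idx <- idx[abs(v[idx]) >= v_read]
      idx <- idx[order(match(idx, seq_along(v)))]
      if (length(idx) < 3) return(NA_real_)
      dv <- diff(v[idx]); dl <- diff(logi[idx])
      ok <- which(abs(dv) > 1e-12)
      if (length(ok) == 0) return(NA_real_)
      sl <- abs(dl[ok] / dv[ok])
      mid <- (v[idx][ok] + v[idx][ok + 1]) / 2
      # |slope|-weighted centroid of the steepest intervals: sub-grid
      # localisation of the switching knee
      top <- order(sl, decreasing = TRUE)[seq_len(min(3, length(sl)))]
      sum(mid[top] * sl[top]) / sum(sl[top])
    }
    switched <- is.finite(r_hrs) && is.finite(r_lrs) &&
      r_lrs > 0 && (r_hrs / r_lrs) >= hrs_lrs_threshold_ratio
    tibble::tibble(
      V_set = if (switched) slope_at(which(seg == "neg_down")) else NA_real_,
      V_reset = if (switched)
        slope_at(which(seg %in% c("pos_up", "pos_down"))) else NA_real_,
      R_HRS = r_hrs, R_LRS = r_lrs, switched = switched)
  }
  out <- dplyr::group_modify(dplyr::group_by(tibble::as_tibble(iv),
                                             .data$cycle),
                             function(d, g) one_cycle(d))
  dplyr::ungroup(out)
}

#' Attribute switching variability to individual noise sources
#'
#' Runs [iv_sweep()] with exactly one noise source enabled at a time
#' (`E_m` only, `E_b` only, `rho` only) and reports the standard deviations
#' of the SET voltage and of the read resistances across cycles. Under the
#' shipped calibration the spread of the switching voltage is dominated by
#' the ion-migration barrier `E_m`, while the cycle-to-cycle spread of the
#' resistive states is dominated by the electron-transport parameters.
#'
#' @param params A [memristor_params()] object.
#' @param stimulus Stimulus time series for the sweep.
#' @param noise Baseline [noise_spec()] whose dispersions are used for the
#'   single-source runs.
#' @param n_cycles Cycles per run (>= 50 recommended).
#' @param read_frac Read point for the resistance states (default 0.65 of
#'   the smaller peak: deep enough that the returning branch is read with
#'   the filament fully formed, so the LRS attribution reflects the ohmic
#'   path rather than residual barrier fluctuations).
#' @param ... Passed on to [extract_switching()].
#' @return A tibble with columns `source`, `sd_V_set`, `sd_R_HRS`,
#'   `sd_R_LRS`, `n_switched`.
#' @export
variance_decomposition <- function(params, stimulus, noise = noise_spec(),
                                   n_cycles = 50, read_frac = 0.65, ...) {
  sources <- list(
    E_m = noise_spec(noise$sigma_Em_rel, 0, 0),
    E_b = noise_spec(0, noise$sigma_Eb_rel, 0),
    rho = noise_spec(0, 0, noise$sigma_rho_rel)
  )
  purrr::imap_dfr(sources, function(ns, nm) {
    iv <- iv_sweep(stimulus, params, ns, n_cycles = n_cycles)
    sw <- extract_switching(iv, read_frac = read_frac, ...)
    sd0 <- function(x) if (sum(is.finite(x)) >= 2) sd(x[is.finite(x)]) else 0
    tibble::tibble(source = nm,
                   sd_V_set = sd0(sw$V_set),
                   sd_R_HRS = sd0(sw$R_HRS),
                   sd_R_LRS = sd0(sw$R_LRS),
                   n_switched = sum(sw$switched))
  })
}
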