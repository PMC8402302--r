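#' The shipped `paper2021` calibration
#'
#' Named default parameter sets for the two neurons, the memristive device
#' and the fluctuation model. The neuron and device constants are not
#' published quantities: they were fitted (see the methods vignette) so
#' that (a) both neurons are self-oscillatory, (b) the device SET threshold
#' under the -5:4 asymmetric stimulus lies between the 1.558 V and 2 V
#' positive-peak drives, and (c) the coupled system reproduces the reported
#' regime boundaries: 1:1 frequency locking for coupling strength z in
#' (0.02, 0.06), intermittent synchronization for z in (0.06, 0.095), and
#' 2:1 / 3:1 locking across the 1.6-2 V drive range.
#'
#' @return Parameter objects ([fhn_params()], [memristor_params()],
#'   [noise_spec()]) or a [coupled_config()].
#' @name paper2021
NULL

#' @rdname paper2021
#' @export
paper2021_pre <- function() fhn_params(epsilon = 0.08, I = 0.02,
                                       alpha = 1, beta = 2)

#' @rdname paper2021
#' @export
paper2021_post <- function() fhn_params(epsilon = 0.0436, I = 0.12353,
                                        alpha = 1, beta = 4)

#' @rdname paper2021
#' @param ... For `paper2021_device()`, overrides of individual device
#'   fields (e.g. `tau_w` in stimulus seconds for I-V runs); for
#'   `paper2021_config()`, overrides passed to [coupled_config()].
#' @export
paper2021_device <- function(...) {
  args <- list(rho = 1, b = 1, E_b = 5, E_m = 2.3, alpha1 = -1, A = 1,
               kT = 0.2, S = 0.02, d = 25, mode = "relaxation", tau_w = 8)
  over <- list(...)
  args[names(over)] <- over
  do.call(memristor_params, args)
}

#' @rdname paper2021
#' @export
paper2021_noise <- function() noise_spec()

#' @rdname paper2021
#' @param t_end,dt Run length and step passed to [coupled_config()].
#' @export
paper2021_config <- function(t_end = 2000, dt = 5e-3, ...) {
  coupled_config(pre = paper2021_pre(), post = paper2021_post(),
                 device = paper2021_device(), noise = paper2021_noise(),
                 t_end = t_end, dt = dt, amplitude_gain = 0.85,
                 resample_period = 27.66, record_every = 4L, ...)
}

#' @rdname paper2021
#' @param peak Device drive peak(s) in volts.
#' @export
paper2021_potentiometer <- function(peak) {
  approx(c(1.60, 1.73, 1.87, 2.00), c(0.210, 0.235, 0.440, 0.480),
         xout = peak, rule = 2)$y
}

#' @rdname paper2021
#' @export
paper2021_amplitude_config <- function(t_end = 2500, dt = 5e-3, ...) {
  coupled_config(pre = paper2021_pre(), post = paper2021_post(),
                 device = paper2021_device(d = 30),
                 noise = paper2021_noise(), t_end = t_end, dt = dt,
                 amplitude_gain = 1, resample_period = 27.66,
                 record_every = 4L, ...)
}

preset_names <- c("fig2_iv_scatter", "fig3_locking", "fig4_amplitude_sweep")

#' Run a shipped experiment preset
#'
#' Presets reproduce the package's three headline scenarios:
#' `fig2_iv_scatter` (stochastic I-V loops of the device under the
#' neuron-like stimulus at increasing peak amplitudes),
#' `fig3_locking` (coupling-strength sweep with regime classification) and
#' `fig4_amplitude_sweep` (drive-amplitude sweep producing n:1 locking).
#' All outputs are written as delimited text together with a JSON manifest
#' recording the seed, integration step, noise policy and a hash of the
#' configuration; rerunning with the same manifest settings reproduces the
#' outputs exactly (bit-identically for noise-off variants).
#'
#' @param name One of `"fig2_iv_scatter"`, `"fig3_locking"`,
#'   `"fig4_amplitude_sweep"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param noise `"on"` (default) or `"off"`.
#' @param fast If `TRUE`, use reduced problem sizes (fewer cycles, coarser
#'   grids) suitable for smoke tests.
#' @return Invisibly, a list with the result tibbles and the manifest.
#' @export
run_preset <- function(name, out_dir = tempfile("memsyn_"), seed = 1L,
                       noise = c("on", "off"), fast = FALSE) {
  noise <- match.arg(noise)
  if (!name %in% preset_names)
    abort(sprintf("unknown preset '%s'; available: %s", name,
                  paste(preset_names, collapse = ", ")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  ns <- if (noise == "on") paper2021_noise() else noise_off()
  results <- list()
  if (name == "fig2_iv_scatter") {
    peaks <- if (fast) c(2, 4) else c(1.558, 2, 2.5, 3, 3.5, 4)
    n_cycles <- if (fast) 3 else 10
    stim <- generate_neuron_like_signal(stimulus_spec(n_spikes = 1),
                                        seed = seed)
    dev <- paper2021_device(tau_w = 4e-3)  # stimulus time is in seconds
    curves <- purrr::map_dfr(peaks, function(pk) {
      iv <- iv_sweep(scale_peak_amplitude(stim, pk), dev, ns,
                     n_cycles = n_cycles)
      dplyr::mutate(tibble::as_tibble(iv), peak = pk)
    })
    sw <- dplyr::group_modify(
      dplyr::group_by(curves, .data$peak),
      function(d, g) extract_switching(d))
    results$curves <- curves
    results$switching <- dplyr::ungroup(sw)
    readr::write_csv(results$curves, file.path(out_dir, "iv_curves.csv"))
    readr::write_csv(results$switching, file.path(out_dir, "switching.csv"))
  } else if (name == "fig3_locking") {
    cfg <- paper2021_config(t_end = if (fast) 600 else 2000)
    cfg$noise <- ns
    zs <- if (fast) c(0.01, 0.04, 0.08) else
      seq(0.005, 0.12, length.out = 10)
    map <- sweep_coupling(cfg, zs, n_reps = if (fast) 2 else 5, seed = seed)
    results$map <- map
    results$regions <- regime_regions(map)
    readr::write_csv(tibble::as_tibble(map),
                     file.path(out_dir, "regime_map.csv"))
    readr::write_csv(results$regions, file.path(out_dir, "regions.csv"))
  } else {
    cfg <- paper2021_amplitude_config(t_end = if (fast) 800 else 2500)
    cfg$noise <- ns
    pks <- if (fast) c(1.65, 1.95) else seq(1.6, 2, length.out = 10)
    map <- sweep_amplitude(cfg, pks, n_reps = if (fast) 2 else 5,
                           seed = seed,
                           potentiometer = paper2021_potentiometer)
    results$map <- map
    results$regions <- regime_regions(map)
    readr::write_csv(tibble::as_tibble(map),
                     file.path(out_dir, "amplitude_map.csv"))
    readr::write_csv(results$regions, file.path(out_dir, "regions.csv"))
  }
  manifest <- list(preset = name, seed = seed, noise = noise, fast = fast,
                   package_version = as.character(utils::packageVersion("memsyn")),
                   config_hash = config_hash(results))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

config_hash <- function(x) {
  # dependency-free stable fingerprint of the serialised results
  raw <- serialize(x, NULL, version = 2)
  sum(as.integer(raw) * (seq_along(raw) %% 251 + 1)) %% 1e9
}

#' Write the deterministic test fixtures
#'
#' Generates the small plain-text fixtures used by the test suite:
#' constructed spike-train pairs with known locking ratios, a synthetic
#' two-branch I-V loop with a known SET jump, and a short FHN trace. A
#' checksum manifest allows corruption to be detected on reload.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return Invisibly, the manifest tibble (file, checksum).
#' @export
generate_fixtures <- function(dir = tempfile("fixtures_"), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  # spike trains with exact 2:1 and 3:1 ratios
  readr::write_tsv(tibble::tibble(time = seq(0, 60, by = 1)),
                   file.path(dir, "train_pre.tsv"))
  readr::write_tsv(tibble::tibble(time = seq(0, 60, by = 2)),
                   file.path(dir, "train_post_2to1.tsv"))
  readr::write_tsv(tibble::tibble(time = seq(0, 60, by = 3)),
                   file.path(dir, "train_post_3to1.tsv"))
  # synthetic loop with SET jump at -2 V
  v <- c(seq(0, -4, by = -0.1), seq(-4, 0, by = 0.1),
         seq(0, 4, by = 0.1), seq(4, 0, by = -0.1))
  w <- ifelse(seq_along(v) <= which.min(v) & v > -2, 0, 1)
  w[v > 0 & seq_along(v) > which.max(v)] <- 0
  i <- w * v + (1 - w) * v * exp(abs(v) - 6)
  readr::write_csv(tibble::tibble(cycle = 1, v = v, i = i,
                                  segment = label_segments(v)),
                   file.path(dir, "iv_synthetic_jump.csv"))
  tr <- simulate_fhn(fhn_params(), t_end = 100, dt = 5e-3, record_every = 20L)
  write_timeseries(tibble::tibble(t = tr$t, x = tr$u),
                   file.path(dir, "fhn_short.tsv"))
  files <- list.files(dir)
  files <- files[files != "manifest.csv"]
  manifest <- tibble::tibble(
    file = files,
    checksum = vapply(files, function(f)
      file_checksum(file.path(dir, f)), numeric(1)))
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

file_checksum <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  sum(as.integer(raw) * (seq_along(raw) %% 251 + 1)) %% 1e9
}

#' Verify fixtures against their checksum manifest
#'
#' @param dir Fixture directory written by [generate_fixtures()].
#' @return A tibble with columns `file`, `ok`.
#' @export
verify_fixtures <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE, progress = FALSE)
  dplyr::mutate(manifest,
                ok = vapply(.data$file, function(f)
                  isTRUE(all.equal(file_checksum(file.path(dir, f)),
                                   manifest$checksum[manifest$file == f])),
                  logical(1)),
                checksum = NULL)
}
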