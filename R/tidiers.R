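#' Tidy a locking report
#'
#' Returns the per-window local ratios as a tibble, one row per sliding
#' window.
#'
#' @param x A `locking_report` from [locking_ratio()] or
#'   [classify_regime()].
#' @param ... Unused.
#' @return A tibble with columns `t_start`, `t_end`, `label`.
#' @export
tidy.locking_report <- function(x, ...) {
  tibble::as_tibble(x$window_ratios)
}

#' Glance at a locking report
#'
#' @inheritParams tidy.locking_report
#' @return A one-row tibble with `regime`, `ratio_p`, `ratio_q`, `ratio`,
#'   `confidence`, `z`, `n_windows`.
#' @export
glance.locking_report <- function(x, ...) {
  tibble::tibble(
    regime = x$regime,
    ratio_p = x$ratio_p,
    ratio_q = x$ratio_q,
    ratio = if (is.na(x$ratio_p)) NA_character_ else
      paste0(x$ratio_p, ":", x$ratio_q),
    confidence = x$confidence,
    z = x$z,
    n_windows = nrow(x$window_ratios)
  )
}

#' Glance at a regime map
#'
#' One-row summary of a sweep: the number of points per regime and the
#' extent of the largest locked region.
#'
#' @param x A `memsyn_map` from [sweep_coupling()] or [sweep_amplitude()].
#' @param ... Unused.
#' @export
glance.memsyn_map <- function(x, ...) {
  regions <- regime_regions(x)
  locked <- regions[regions$regime == "locked", ]
  main <- if (nrow(locked)) locked[which.max(locked$n_points), ] else NULL
  tibble::tibble(
    n_points = nrow(x),
    n_locked = sum(x$regime == "locked"),
    n_intermittent = sum(x$regime == "intermittent"),
    n_unlocked = sum(x$regime == "unlocked"),
    main_locked_ratio = if (is.null(main)) NA_character_ else main$ratio,
    main_locked_lo = if (is.null(main)) NA_real_ else main$lo,
    main_locked_hi = if (is.null(main)) NA_real_ else main$hi
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
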