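#' Detect spikes by threshold crossing
#'
#' Finds upward crossings of a threshold separated by at least a refractory
#' interval; onset times are refined by linear interpolation between the
#' samples bracketing the crossing.
#'
#' @param ts A uniformly sampled time-series data frame.
#' @param x Name of the signal column (default `"x"`, or `"u"` if present).
#' @param t Name of the time column (default `"t"`).
#' @param threshold Crossing level; default is the midpoint between the
#'   signal's minimum and maximum.
#' @param refractory Minimum spacing between onsets; default is half the
#'   median inter-spike interval of a pilot pass without refractoriness.
#' @return A tibble of class `spike_train` with column `time`; attributes
#'   `threshold` and `refractory`.
#' @examples
#' tr <- simulate_fhn(fhn_params(), t_end = 200, dt = 5e-3)
#' nrow(detect_spikes(tr, x = "u"))
#' @export
detect_spikes <- function(ts, x = NULL, t = "t", threshold = NULL,
                          refractory = NULL) {
  if (is.null(x)) x <- if ("x" %in% names(ts)) "x" else "u"
  check_that(all(c(t, x) %in% names(ts)),
             sprintf("`ts` must have columns `%s` and `%s`", t, x))
  tt <- ts[[t]]
  xx <- ts[[x]]
  if (is.null(threshold)) threshold <- (min(xx) + max(xx)) / 2
  cross <- which(xx[-length(xx)] < threshold & xx[-1] >= threshold)
  onset <- function(k) {
    tt[k] + (threshold - xx[k]) / (xx[k + 1] - xx[k]) * (tt[k + 1] - tt[k])
  }
  times <- if (length(cross)) vapply(cross, onset, numeric(1)) else numeric(0)
  if (is.null(refractory)) {
    refractory <- if (length(times) >= 3) median(diff(times)) / 2 else 0
  }
  if (length(times) > 1 && refractory > 0) {
    keep <- times[1]
    for (s in times[-1]) if (s - keep[length(keep)] >= refractory)
      keep <- c(keep, s)
    times <- keep
  }
  new_memsyn_tbl(list(time = times), "spike_train", threshold = threshold,
                 refractory = refractory)
}

# simplest p/q with p, q in 1..max_den closest to ratio r (ties -> smaller q)
round_to_rational <- function(r, max_den = 8) {
  if (!is.finite(r) || r <= 0) return(c(NA_integer_, NA_integer_))
  best <- c(NA_integer_, NA_integer_)
  best_err <- Inf
  for (q in 1:max_den) {
    p <- max(1L, min(as.integer(max_den), as.integer(round(r * q))))
    g <- gcd_int(p, q)
    err <- abs(p / q - r)
    if (err < best_err - 1e-12) {
      best_err <- err
      best <- c(p %/% g, q %/% g)
    }
  }
  best
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Locking ratio of two spike trains
#'
#' Slides a window of `window_spikes` presynaptic spikes along the trains;
#' in each window the local ratio is the simplest rational `p:q`
#' (denominator and numerator at most 8) approximating the ratio of pre- to
#' postsynaptic spike counts. The modal ratio is reported together with the
#' fraction of windows agreeing with it (`confidence`). The regime is
#' `locked` when confidence >= `locked_conf`, `intermittent` when at least
#' two distinct ratios each occupy >= `intermittent_occ` of the windows,
#' and `unlocked` otherwise.
#'
#' @param pre,post Spike trains (tibbles with a `time` column) of the pre-
#'   and postsynaptic neurons.
#' @param window_spikes Presynaptic spikes per sliding window (default 12,
#'   divisible by 1:4 so small integer ratios give exact counts).
#' @param locked_conf Confidence cutoff for `locked` (default 0.95).
#' @param intermittent_occ Minimum occupancy of each of two ratios for
#'   `intermittent` (default 0.20).
#' @param direction `"pre_post"` (default): `p:q` is pre:post spike counts,
#'   so 2:1 means two presynaptic spikes per postsynaptic spike;
#'   `"post_pre"` inverts the convention.
#' @param drift_tol Maximum cumulative drift (in presynaptic cycles) of the
#'   postsynaptic spike phase over the analysed span for a `locked` call.
#'   Window counts cannot distinguish true locking from a slow phase slip;
#'   this stroboscopic-phase check can (default 0.5).
#' @param min_run Minimum mean run length of identical window labels for an
#'   `intermittent` call (default 3). Genuine intermittency consists of
#'   epochs that persist over several windows; quasi-periodic drift between
#'   two unlocked ratios alternates labels almost every window.
#' @return An object of class `locking_report`: a list with `ratio_p`,
#'   `ratio_q`, `regime`, `confidence`, a tibble `window_ratios`, and
#'   diagnostics `phase_drift` and `mean_run`.
#' @examples
#' pre <- new_spike_train(0:40)
#' post <- new_spike_train(seq(0, 40, by = 2))
#' locking_ratio(pre, post)$regime
#' @export
locking_ratio <- function(pre, post, window_spikes = 12, locked_conf = 0.95,
                          intermittent_occ = 0.20,
                          direction = c("pre_post", "post_pre"),
                          drift_tol = 0.5, min_run = 3) {
  direction <- match.arg(direction)
  tp <- pre$time
  tq <- post$time
  if (length(tq) == 0 || length(tp) == 0) {
    return(new_locking_report(NA_integer_, NA_integer_, "unlocked", 0,
                              tibble::tibble(t_start = numeric(0),
                                             t_end = numeric(0),
                                             label = character(0))))
  }
  check_that(length(tp) > window_spikes,
             "presynaptic train shorter than one window")
  n_win <- length(tp) - window_spikes
  labs <- character(n_win)
  t0s <- t1s <- numeric(n_win)
  for (k in seq_len(n_win)) {
    t0 <- tp[k]
    t1 <- tp[k + window_spikes]
    n_post <- sum(tq >= t0 & tq < t1)
    r <- if (n_post == 0) Inf else window_spikes / n_post
    if (direction == "post_pre" && is.finite(r)) r <- 1 / r
    pq <- round_to_rational(r)
    labs[k] <- if (any(is.na(pq))) NA_character_ else
      paste0(pq[1], ":", pq[2])
    t0s[k] <- t0
    t1s[k] <- t1
  }
  windows <- tibble::tibble(t_start = t0s, t_end = t1s, label = labs)
  tab <- table(labs[!is.na(labs)])
  if (length(tab) == 0) {
    return(new_locking_report(NA_integer_, NA_integer_, "unlocked", 0,
                              windows))
  }
  occ <- as.numeric(tab) / n_win
  modal <- names(tab)[which.max(tab)]
  confidence <- max(occ)
  pq <- as.integer(strsplit(modal, ":")[[1]])
  runs <- rle(labs)
  mean_run <- mean(runs$lengths)
  drift <- phase_drift(tp, tq, pq[1], pq[2])
  # genuine intermittency = alternation of epochs that are themselves
  # locked; a strictly drifting pair alternates labels without any epoch
  # holding a fixed phase relation
  epochs_locked <- modal_epochs_locked(tp, tq, labs, modal, pq,
                                       window_spikes, min_run, drift_tol)
  regime <- if (confidence >= locked_conf &&
                (!is.finite(drift) || abs(drift) <= drift_tol)) "locked"
  else if (sum(occ >= intermittent_occ) >= 2 && mean_run >= min_run &&
           isTRUE(epochs_locked)) "intermittent"
  else "unlocked"
  out <- new_locking_report(pq[1], pq[2], regime, confidence, windows)
  out$phase_drift <- drift
  out$mean_run <- mean_run
  out
}

# do the maximal runs of modal-label windows hold their phase (drift within
# tolerance)? TRUE when at least half of the qualifying epochs are locked
modal_epochs_locked <- function(tp, tq, labs, modal, pq, window_spikes,
                                min_run, drift_tol) {
  if (any(is.na(pq))) return(FALSE)
  runs <- rle(labs)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values == modal & runs$lengths >= min_run)
  if (length(keep) == 0) return(FALSE)
  ok <- vapply(keep, function(r) {
    k0 <- starts[r]
    k1 <- min(ends[r] + window_spikes, length(tp))
    d <- phase_drift(tp[k0:k1], tq, pq[1], pq[2])
    # epochs are shorter than the full span, so hold them to a tighter
    # drift bound than the global locked call
    !is.finite(d) || abs(d) <= 0.7 * drift_tol
  }, logical(1))
  mean(ok) >= 0.5
}

# cumulative deviation (in presynaptic cycles) of the postsynaptic spike
# phase from perfect p:q locking over the analysed span
phase_drift <- function(tp, tq, p, q) {
  if (is.na(p) || length(tp) < 2) return(NA_real_)
  s <- tq[tq >= tp[1] & tq < tp[length(tp)]]
  if (length(s) < q + 1) return(NA_real_)
  k <- findInterval(s, tp)
  psi <- k + (s - tp[k]) / (tp[k + 1] - tp[k])
  (psi[length(psi)] - psi[1]) - (p / q) * (length(psi) - 1)
}

new_locking_report <- function(p, q, regime, confidence, windows, z = NA_real_) {
  structure(list(ratio_p = p, ratio_q = q, regime = regime,
                 confidence = confidence, window_ratios = windows, z = z),
            class = "locking_report")
}

#' Construct a spike train from raw times
#'
#' @param times Strictly increasing spike times.
#' @return A `spike_train` tibble.
#' @export
new_spike_train <- function(times) {
  times <- as.numeric(times)
  check_that(all(diff(times) > 0), "spike times must be strictly increasing")
  new_memsyn_tbl(list(time = times), "spike_train", threshold = NA_real_,
                 refractory = 0)
}

#' @export
print.locking_report <- function(x, ...) {
  rat <- if (is.na(x$ratio_p)) "-" else paste0(x$ratio_p, ":", x$ratio_q)
  cat(sprintf("<locking_report> regime = %s, ratio = %s, confidence = %.3f",
              x$regime, rat, x$confidence))
  if (is.finite(x$z)) cat(sprintf(", z = %.4f", x$z))
  cat("\n")
  invisible(x)
}

#' Dominant oscillation frequency
#'
#' Primary estimator: reciprocal of the median inter-spike interval of a
#' spike train. `method = "acf"` instead locates the first non-trivial peak
#' of the autocorrelation of a time series, as an independent cross-check.
#'
#' @param x A `spike_train` (for `"isi"`) or a time-series data frame with
#'   columns `t` and a signal column (for `"acf"`).
#' @param method `"isi"` or `"acf"`.
#' @param signal Signal column name for `"acf"` (default `"u"` or `"x"`).
#' @return Frequency in reciprocal time units of the input.
#' @export
dominant_frequency <- function(x, method = c("isi", "acf"), signal = NULL) {
  method <- match.arg(method)
  if (method == "isi") {
    check_that(inherits(x, "spike_train") || "time" %in% names(x),
               "`x` must be a spike train for method = 'isi'")
    check_that(nrow(x) >= 3, "need at least 3 spikes to estimate a frequency")
    return(1 / median(diff(x$time)))
  }
  if (is.null(signal)) signal <- if ("x" %in% names(x)) "x" else "u"
  s <- x[[signal]]
  dt <- median(diff(x$t))
  a <- acf(s, lag.max = min(length(s) - 2, round(length(s) / 2)),
           plot = FALSE)$acf[, 1, 1]
  # first local maximum after the initial decay
  above <- which(diff(sign(diff(a))) == -2) + 1
  check_that(length(above) > 0, "no autocorrelation peak found")
  k <- above[which.max(a[above])]
  1 / ((k - 1) * dt)
}

#' Classify the synchronization regime of a coupled trace
#'
#' Detects spikes on `u1` and `u2` after discarding the transient, computes
#' the pre:post locking ratio, and attaches the coupling strength `z`.
#'
#' @param trace A `memsyn_trace` from [simulate_coupled()].
#' @param transient_discard Fraction of the run discarded as transient
#'   (default from the trace's config, else 0.5).
#' @param window_spikes See [locking_ratio()].
#' @param ... Further detector settings passed to [locking_ratio()].
#' @return A `locking_report` with `z` filled in.
#' @export
classify_regime <- function(trace, transient_discard = NULL,
                            window_spikes = 12, ...) {
  cfg <- attr(trace, "config")
  if (is.null(transient_discard))
    transient_discard <- if (!is.null(cfg)) cfg$transient_discard else 0.5
  t_cut <- min(trace$t) + transient_discard * diff(range(trace$t))
  tr <- trace[trace$t >= t_cut, ]
  pre <- detect_spikes(tr, x = "u1")
  post <- detect_spikes(tr, x = "u2")
  rep <- if (nrow(pre) > window_spikes)
    locking_ratio(pre, post, window_spikes = window_spikes, ...)
  else new_locking_report(NA_integer_, NA_integer_, "unlocked", 0,
                          tibble::tibble(t_start = numeric(0),
                                         t_end = numeric(0),
                                         label = character(0)))
  rep$z <- tryCatch(coupling_strength(trace, transient_discard),
                    error = function(e) NA_real_)
  rep
}

#' Phase-portrait samples of a coupled trace
#'
#' Returns paired `(u1, u2)` samples after transient discard, for
#' Lissajous-style synchronization plots.
#'
#' @param trace A `memsyn_trace`.
#' @param transient_discard Fraction of the run discarded (default 0.5).
#' @return A tibble with columns `t`, `u1`, `u2`.
#' @export
phase_portrait <- function(trace, transient_discard = 0.5) {
  t_cut <- min(trace$t) + transient_discard * diff(range(trace$t))
  tr <- trace[trace$t >= t_cut, c("t", "u1", "u2")]
  tibble::as_tibble(tr)
}
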