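#' FitzHugh-Nagumo neuron parameters
#'
#' Parameters of the two-variable FitzHugh-Nagumo (FHN) neuron
#' \deqn{du/dt = f(u) - v, \qquad dv/dt = \epsilon(g(u) - v) - I}
#' with cubic nonlinearity \eqn{f(u) = u - u^3/3} and piecewise-linear
#' recovery term \eqn{g(u) = \alpha u} for \eqn{u < 0}, \eqn{g(u) = \beta u}
#' for \eqn{u \ge 0}. `u` is the (dimensionless) membrane potential, `v` the
#' recovery variable, `I` the depolarization parameter setting the excitation
#' threshold and `epsilon` the small time-scale separation between the fast
#' membrane and the slow recovery dynamics. `alpha` and `beta` control the
#' shape and location of the v-nullcline on either side of `u = 0`.
#'
#' @param epsilon Small recovery-rate parameter (> 0). Values of 0.5 or more
#'   leave the relaxation-oscillation regime; a warning is raised.
#' @param I Depolarization parameter.
#' @param alpha Slope of `g` for negative `u`.
#' @param beta Slope of `g` for non-negative `u`.
#' @return An object of class `fhn_params`.
#' @examples
#' fhn_params(epsilon = 0.08, I = 0.02, alpha = 1, beta = 2)
#' @export
fhn_params <- function(epsilon = 0.08, I = 0.02, alpha = 1, beta = 2) {
  check_that(is.numeric(epsilon) && length(epsilon) == 1 && epsilon > 0,
             "`epsilon` must be a single positive number (epsilon > 0)")
  for (nm in c("I", "alpha", "beta")) {
    val <- get(nm)
    check_that(is.numeric(val) && length(val) == 1 && is.finite(val),
               paste0("`", nm, "` must be a single finite number"))
  }
  if (epsilon >= 0.5)
    warn("`epsilon` >= 0.5: the time-scale separation assumption is weak")
  structure(list(epsilon = epsilon, I = I, alpha = alpha, beta = beta),
            class = "fhn_params")
}

#' @export
print.fhn_params <- function(x, ...) {
  cat(sprintf("<fhn_params> epsilon = %g, I = %g, alpha = %g, beta = %g\n",
              x$epsilon, x$I, x$alpha, x$beta))
  invisible(x)
}

as_fhn_vector <- function(p) {
  c(p$epsilon, p$I, p$alpha, p$beta)
}

#' Cubic nonlinearity of the FHN neuron
#'
#' @param u Membrane potential (vectorised).
#' @return `u - u^3/3`.
#' @examples
#' f_cubic(c(0, 1, sqrt(3)))
#' @export
f_cubic <- function(u) u - u^3 / 3

#' Piecewise-linear recovery term of the FHN neuron
#'
#' `g(u) = alpha * u` for `u < 0` and `beta * u` for `u >= 0`; continuous at
#' zero since both branches vanish there.
#'
#' @param u Membrane potential (vectorised).
#' @param params An [fhn_params()] object.
#' @export
g_piecewise <- function(u, params) {
  ifelse(u < 0, params$alpha * u, params$beta * u)
}

#' FHN vector field
#'
#' Evaluates the right-hand side of the FHN equations at one or more states.
#'
#' @param state A data frame with columns `u` and `v` (one row per state).
#' @param params An [fhn_params()] object.
#' @return A tibble with columns `du` and `dv`.
#' @examples
#' fhn_derivative(data.frame(u = c(0, 1), v = 0), fhn_params(I = 0))
#' @export
fhn_derivative <- function(state, params) {
  check_that(is.data.frame(state) && all(c("u", "v") %in% names(state)),
             "`state` must be a data frame with columns `u` and `v`")
  check_that(all(is.finite(state$u)) && all(is.finite(state$v)),
             "`state` must be finite")
  tibble::tibble(
    du = f_cubic(state$u) - state$v,
    dv = params$epsilon * (g_piecewise(state$u, params) - state$v) - params$I
  )
}

#' Simulate a single FHN neuron
#'
#' Integrates the FHN equations with the classical fixed-step fourth-order
#' Runge-Kutta scheme. Time is in dimensionless model units.
#'
#' @param params An [fhn_params()] object.
#' @param init Numeric vector `c(u, v)` initial state.
#' @param t_end End time (model units).
#' @param dt Integration step (default 1e-3).
#' @param record_every Record every this many steps (thins the output).
#' @return A tibble of class `memsyn_ts` with columns `t`, `u`, `v`.
#' @examples
#' tr <- simulate_fhn(fhn_params(), t_end = 100)
#' range(tr$u)
#' @export
simulate_fhn <- function(params, init = c(u = -1, v = 0.5), t_end, dt = 1e-3,
                         record_every = 1L) {
  check_that(inherits(params, "fhn_params"), "`params` must be fhn_params")
  check_that(dt > 0, "`dt` must be > 0")
  check_that(t_end > dt, "`t_end` must exceed `dt`")
  n_steps <- as.integer(round(t_end / dt))
  out <- simulate_fhn_cpp(as_fhn_vector(params), init[[1]], init[[2]], dt,
                          n_steps, as.integer(record_every))
  new_memsyn_tbl(out, "memsyn_ts", params = params, dt = dt)
}

# period of the stable limit cycle, measured from upward threshold crossings
# after discarding the first half of the run
fhn_period <- function(params, t_end = 400, dt = 5e-3) {
  tr <- simulate_fhn(params, t_end = t_end, dt = dt, record_every = 4L)
  tr <- tr[tr$t >= t_end / 2, ]
  thr <- (min(tr$u) + max(tr$u)) / 2
  sp <- detect_spikes(tr, x = "u", threshold = thr)
  check_that(nrow(sp) >= 3, "neuron is not spiking; cannot measure a period")
  median(diff(sp$time))
}
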