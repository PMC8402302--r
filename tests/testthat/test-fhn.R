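test_that("cubic nonlinearity and piecewise recovery term evaluate exactly", {
  expect_equal(f_cubic(0), 0)
  expect_equal(f_cubic(sqrt(3)), 0)
  expect_equal(f_cubic(1), 2 / 3)
  p <- fhn_params(alpha = 2, beta = 0.5)
  expect_equal(g_piecewise(0, p), 0)
  expect_equal(g_piecewise(-1, p), -2)
  expect_equal(g_piecewise(1, p), 0.5)
  # continuity at zero from both sides
  expect_equal(g_piecewise(-1e-12, p), -2e-12)
})

test_that("vector field matches direct substitution and finds equilibria", {
  p <- fhn_params(epsilon = 0.01, I = 0, beta = 1)
  d0 <- fhn_derivative(data.frame(u = 0, v = 0), p)
  expect_equal(c(d0$du, d0$dv), c(0, 0))
  d1 <- fhn_derivative(data.frame(u = 1, v = 0), p)
  expect_equal(c(d1$du, d1$dv), c(2 / 3, 0.01))

  # brute-force grid oracle: the derivative-norm minimum over a dense grid
  # must coincide with the root of f(u) = v, eps*(g(u) - v) = I
  p2 <- fhn_params(epsilon = 0.08, I = 0.02, alpha = 1, beta = 2)
  grid <- expand.grid(u = seq(-2, 2, by = 0.002), v = 0)
  grid$v <- f_cubic(grid$u)  # on the u-nullcline
  dv <- fhn_derivative(grid, p2)$dv
  u_star_grid <- grid$u[which.min(abs(dv))]
  u_star_root <- uniroot(function(u) {
    p2$epsilon * (g_piecewise(u, p2) - f_cubic(u)) - p2$I
  }, c(0, 1))$root
  expect_lt(abs(u_star_grid - u_star_root), 0.005)
})

test_that("parameter validation names the violated bound", {
  expect_error(fhn_params(epsilon = -1), "epsilon > 0")
  expect_warning(fhn_params(epsilon = 0.6), "0.5")
})

test_that("integration stays at an equilibrium and on bounded orbits", {
  p <- fhn_params(epsilon = 0.05, I = 0, alpha = 1, beta = 2)
  tr <- simulate_fhn(p, init = c(u = 0, v = 0), t_end = 50)
  expect_lt(max(abs(tr$u)), 1e-6)
  expect_lt(max(abs(tr$v)), 1e-6)

  for (eps in c(0.05, 0.08, 0.2)) {
    trb <- simulate_fhn(fhn_params(epsilon = eps, I = 0.25 * eps),
                        t_end = 400, dt = 5e-3, record_every = 4L)
    expect_lt(max(abs(trb$u)), 5)
  }
})

test_that("default calibration is self-oscillatory with two period
           estimators agreeing", {
  tr <- simulate_fhn(paper2021_pre(), t_end = 600, dt = 5e-3,
                     record_every = 2L)
  st <- tr[tr$t >= 300, ]
  sp <- detect_spikes(st, x = "u")
  expect_gte(nrow(sp), 2)
  isi <- diff(sp$time)
  expect_lt(sd(isi) / mean(isi), 0.05)  # regular spiking
  f_isi <- dominant_frequency(sp)
  f_acf <- dominant_frequency(st, method = "acf", signal = "u")
  expect_lt(abs(f_isi - f_acf) / f_isi, 0.02)
})

test_that("relaxation structure: fast branches occupy a minority of the
           period", {
  tr <- simulate_fhn(paper2021_pre(), t_end = 400, dt = 5e-3,
                     record_every = 2L)
  st <- tr[tr$t >= 200, ]
  dudt <- abs(diff(st$u)) / diff(st$t)
  expect_lt(mean(dudt > quantile(dudt, 0.5) * 4), 0.5)
})

test_that("halving the step changes the end state consistently with RK4", {
  p <- paper2021_pre()
  end_state <- function(dt) {
    tr <- simulate_fhn(p, t_end = 100, dt = dt,
                       record_every = as.integer(round(100 / dt)))
    c(tail(tr$u, 1), tail(tr$v, 1))
  }
  e1 <- end_state(1e-3)
  e2 <- end_state(5e-4)
  expect_lt(max(abs(e1 - e2)), 1e-4)
})
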