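test_that("filament fraction follows the barrier law and stays clamped", {
  p <- memristor_params(E_m = 2, alpha1 = -1, A = 0.8, kT = 0.25)
  expect_equal(filament_fraction(p$E_m / p$alpha1, p), min(p$A, 1))
  expect_equal(filament_fraction(0, p),
               min(max(p$A * exp(-p$E_m / p$kT), 0), 1))
  u <- seq(-5, 5, length.out = 1000)
  w <- filament_fraction(u, p)
  expect_true(all(w >= 0 & w <= 1))
  # monotone with the sign of alpha1
  expect_true(all(diff(w) <= 1e-12))
  p_pos <- memristor_params(alpha1 = 1)
  expect_true(all(diff(filament_fraction(u, p_pos)) >= -1e-12))
})

test_that("current density mixes ohmic and Poole-Frenkel branches", {
  p <- memristor_params(rho = 2, b = 1.5, E_b = 3)
  expect_equal(current_density(0, 0.3, p), 0)   # pinched at the origin
  expect_equal(current_density(1.7, 1, p), 1.7 / 2)       # pure ohmic
  expect_equal(current_density(p$E_b / p$b, 0, p), p$E_b / p$b)  # exp = 1
  expect_error(current_density(1, 1.2, p), "\\[0, 1\\]")
})

test_that("parameter sampling reproduces the stated dispersions", {
  p <- memristor_params()
  expect_identical(sample_params(p, noise_off(), n = 5)$E_m, rep(p$E_m, 5))

  set.seed(99)
  draws <- sample_params(p, noise_spec(), n = 10000)
  expect_gt(sd(draws$E_m) / mean(draws$E_m), 0.095)
  expect_lt(sd(draws$E_m) / mean(draws$E_m), 0.105)
  expect_gt(sd(draws$E_b) / mean(draws$E_b), 0.0095)
  expect_lt(sd(draws$E_b) / mean(draws$E_b), 0.0105)
  expect_gt(sd(draws$rho) / mean(draws$rho), 0.095)
  expect_lt(sd(draws$rho) / mean(draws$rho), 0.105)
  expect_true(all(draws$rho > 0))

  set.seed(7)
  a <- sample_params(p, noise_spec(), n = 10)
  set.seed(7)
  b <- sample_params(p, noise_spec(), n = 10)
  expect_identical(a, b)
})

test_that("I-V sweeps are pinched, reproducible without noise and scattered
           with noise", {
  stim <- generate_neuron_like_signal(fast_spec(), seed = 1)
  dev <- paper2021_device(tau_w = 4e-3)

  iv0 <- iv_sweep(stim, dev, noise_off(), n_cycles = 5)
  expect_true(all(iv0$i[iv0$v == 0] == 0))
  by_cycle <- split(iv0$i, iv0$cycle)
  for (k in 2:5) expect_identical(by_cycle[[k]], by_cycle[[1]])

  set.seed(3)
  iv1 <- iv_sweep(stim, dev, noise_spec(), n_cycles = 10)
  expect_true(all(iv1$i[iv1$v == 0] == 0))
  cyc <- split(iv1$i, iv1$cycle)
  for (a in 1:9) for (b in (a + 1):10)
    expect_gt(max(abs(cyc[[a]] - cyc[[b]])), 0)

  pos_only <- tibble::tibble(t = (0:99) / 5000,
                             x = abs(sin(2 * pi * (0:99) / 100)))
  expect_warning(iv_sweep(pos_only, dev, noise_off(), n_cycles = 1),
                 "polarities")
})

test_that("switching extraction finds a constructed SET jump and returns a
           sentinel for ohmic loops", {
  v <- c(seq(0, -4, by = -0.05), seq(-4, 0, by = 0.05),
         seq(0, 4, by = 0.05), seq(4, 0, by = -0.05))
  seg <- memsyn:::label_segments(v)
  # HRS (tiny Poole-Frenkel-like) down to -2.5 V, LRS ohmic after the jump
  w <- as.numeric(!(seg == "neg_down" & v > -2.5))
  i <- w * v + (1 - w) * v * exp(abs(v) - 8)
  iv <- tibble::tibble(cycle = 1L, v = v, i = i, segment = seg)
  sw <- extract_switching(iv)
  expect_true(sw$switched)
  expect_lt(abs(sw$V_set - (-2.5)), 0.1)
  expect_gt(sw$R_HRS / sw$R_LRS, 10)

  ohmic <- tibble::tibble(cycle = 1L, v = v, i = v / 3, segment = seg)
  sw0 <- extract_switching(ohmic)
  expect_false(sw0$switched)
  expect_true(is.na(sw0$V_set))
})

test_that("stochastic switching has spread in the SET voltage", {
  stim <- generate_neuron_like_signal(fast_spec(n_spikes = 1), seed = 1)
  set.seed(11)
  iv <- iv_sweep(stim, paper2021_device(tau_w = 4e-3), noise_spec(),
                 n_cycles = 100)
  sw <- extract_switching(iv)
  expect_gt(sum(sw$switched), 50)
  expect_gt(sd(sw$V_set[sw$switched]), 0)
})

test_that("switching variability attributes to the expected noise sources", {
  stim <- generate_neuron_like_signal(fast_spec(n_spikes = 1), seed = 1)
  dev <- paper2021_device(tau_w = 4e-3)

  vd0 <- variance_decomposition(dev, stim, noise_spec(0, 0, 0),
                                n_cycles = 5)
  expect_true(all(vd0$sd_V_set == 0))
  expect_true(all(vd0$sd_R_LRS == 0))

  set.seed(21)
  vd <- variance_decomposition(dev, stim, noise_spec(), n_cycles = 60)
  sdv <- setNames(vd$sd_V_set, vd$source)
  sdr <- setNames(vd$sd_R_LRS, vd$source)
  expect_gt(sdv[["E_m"]], 0)
  expect_gt(sdv[["E_m"]], sdv[["E_b"]])
  expect_lt(sdv[["rho"]], 0.1 * sdv[["E_m"]])
  expect_gt(sdr[["rho"]], sdr[["E_m"]])
})
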