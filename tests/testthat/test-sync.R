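test_that("spike detection finds constructed onsets and ignores flat
           signals", {
  t <- seq(0, 10, by = 0.01)
  flat <- tibble::tibble(t = t, x = 0 * t)
  expect_identical(nrow(detect_spikes(flat, threshold = 0.5)), 0L)

  onsets <- seq(0.5, 9.5, length.out = 7)
  x <- rep(0, length(t))
  for (o in onsets) x[t >= o & t < o + 0.2] <- 1
  train <- detect_spikes(tibble::tibble(t = t, x = x), threshold = 0.5)
  expect_identical(nrow(train), 7L)
  expect_lt(max(abs(train$time - onsets)), 0.011)

  # doubling the sample rate moves onsets by less than one coarse sample
  t2 <- seq(0, 10, by = 0.005)
  x2 <- rep(0, length(t2))
  for (o in onsets) x2[t2 >= o & t2 < o + 0.2] <- 1
  train2 <- detect_spikes(tibble::tibble(t = t2, x = x2), threshold = 0.5)
  expect_lt(max(abs(train2$time - train$time)), 0.011)
})

test_that("locking ratio recovers constructed integer ratios exactly", {
  pre <- new_spike_train(0:40)
  post <- new_spike_train(seq(0, 40, by = 2))
  rep21 <- locking_ratio(pre, post)
  expect_identical(c(rep21$ratio_p, rep21$ratio_q), c(2L, 1L))
  expect_equal(rep21$confidence, 1)
  expect_identical(rep21$regime, "locked")

  same <- locking_ratio(pre, new_spike_train(0:40 + 0.1))
  expect_identical(c(same$ratio_p, same$ratio_q), c(1L, 1L))
  expect_identical(same$regime, "locked")

  # brute-force oracle over all small rationals
  for (p in 1:4) for (q in 1:4) {
    if (p == q && p > 1) next
    n_pre <- 48 * p
    pre_t <- new_spike_train((0:(n_pre - 1)))
    post_t <- new_spike_train(seq(0, n_pre - 1, by = p / q) + 0.25)
    rep <- locking_ratio(pre_t, post_t)
    g <- memsyn:::gcd_int(p, q)
    expect_identical(c(rep$ratio_p, rep$ratio_q), c(p %/% g, q %/% g) * 1L,
                     label = sprintf("ratio %d:%d", p, q))
    expect_identical(rep$regime, "locked")
    expect_equal(rep$confidence, 1)
  }
})

test_that("constructed epoch alternation is intermittent, drift is not", {
  # half the run 1:1, half 2:1, long epochs
  pre <- new_spike_train(0:120)
  post <- new_spike_train(c(0:60, seq(62, 120, by = 2)) + 0.25)
  rep <- locking_ratio(pre, post)
  expect_identical(rep$regime, "intermittent")

  # detuned periodic pair: labels alternate rapidly -> unlocked
  pre2 <- periodic_train(100, 1)
  post2 <- periodic_train(84, 1.19, t0 = 0.3)
  rep2 <- locking_ratio(pre2, post2)
  expect_identical(rep2$regime, "unlocked")

  # strictly periodic pairs never classify intermittent
  for (T2 in c(0.9, 1.07, 1.5, 2.3)) {
    repk <- locking_ratio(periodic_train(120, 1),
                          periodic_train(floor(119 / T2), T2, t0 = 0.2))
    expect_false(repk$regime == "intermittent",
                 label = sprintf("T2 = %g", T2))
  }
})

test_that("a slow phase slip is not reported as locked", {
  pre <- periodic_train(80, 1)
  post <- periodic_train(78, 80 / 78, t0 = 0.5)  # 2.6% detuning
  rep <- locking_ratio(pre, post)
  expect_false(rep$regime == "locked")
  expect_gt(abs(rep$phase_drift), 0.5)
})

test_that("classifier is invariant under uniform time rescaling", {
  pre <- new_spike_train(0:60)
  post <- new_spike_train(seq(0.25, 60, by = 3))
  a <- locking_ratio(pre, post)
  b <- locking_ratio(new_spike_train(pre$time * 7.3),
                     new_spike_train(post$time * 7.3))
  expect_identical(glance(a)$ratio, glance(b)$ratio)
  expect_identical(a$regime, b$regime)
  expect_equal(a$confidence, b$confidence)
})

test_that("empty postsynaptic trains give the unlocked sentinel", {
  pre <- new_spike_train(0:30)
  rep <- locking_ratio(pre, new_spike_train(numeric(0)))
  expect_identical(rep$regime, "unlocked")
  expect_true(is.na(rep$ratio_p))
})

test_that("dominant frequency estimators agree", {
  train <- periodic_train(50, 0.25)
  expect_equal(dominant_frequency(train), 4)
  expect_error(dominant_frequency(new_spike_train(c(0, 1))), "3 spikes")

  set.seed(1)
  jittered <- new_spike_train(cumsum(0.25 * (1 + rnorm(50, 0, 0.01))))
  expect_lt(abs(dominant_frequency(jittered) - 4) / 4, 0.02)

  tr <- simulate_fhn(paper2021_pre(), t_end = 600, dt = 5e-3,
                     record_every = 2L)
  st <- tr[tr$t > 300, ]
  f1 <- dominant_frequency(detect_spikes(st, x = "u"))
  f2 <- dominant_frequency(st, method = "acf", signal = "u")
  expect_lt(abs(f1 - f2) / f1, 0.02)
})

test_that("phase portraits separate synchronized from independent motion", {
  t <- seq(0, 100, by = 0.02)
  sync <- tibble::tibble(t = t, u1 = sin(t), u2 = sin(t))
  pp <- phase_portrait(sync)
  expect_lt(max(abs(pp$u2 - pp$u1)), 1e-12)

  fill_frac <- function(df) {
    gx <- cut(df$u1, 20)
    gy <- cut(df$u2, 20)
    length(unique(paste(gx, gy))) / 400
  }
  indep <- tibble::tibble(t = t, u1 = sin(t), u2 = sin(exp(1) / 2 * t + 1))
  expect_gt(fill_frac(phase_portrait(indep)), 2 * fill_frac(pp))
})

test_that("classify_regime composes detection, ratio and coupling
           strength", {
  cfg <- quick_config(t_end = 1500)
  cfg$device$S <- 0
  tr <- simulate_coupled(cfg, seed = 1)
  rep <- classify_regime(tr)
  expect_identical(rep$regime, "unlocked")
  expect_equal(rep$z, 0)
  gl <- glance(rep)
  expect_identical(gl$regime, "unlocked")
  td <- tidy(rep)
  expect_true(all(c("t_start", "t_end", "label") %in% names(td)))
})
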