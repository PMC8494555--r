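test_that("curve validation enforces the TIC contract", {
  expect_error(tic_curve(1:5, 1:5), "at least 8")
  expect_error(tic_curve(c(1:7, 7), rep(1, 8)), "strictly increasing")
  expect_error(tic_curve(1:8, c(-1, rep(1, 7))), "non-negative")
  expect_error(tic_curve(1:8, 1:7), "differ in length")
})

test_that("baseline estimation is a robust pre-arrival median", {
  flat <- tic_curve(seq(0, 120, 1), rep(5, 121))
  expect_equal(estimate_baseline(flat), 5)
  cur <- perfusion_curve(gv_fixture_params())  # t0 = 10 < 0.1 * 120
  expect_equal(estimate_baseline(cur), 10)
  shifted <- tic_curve(cur$times, cur$intensities + 3, window = cur$window)
  expect_equal(estimate_baseline(shifted), estimate_baseline(cur) + 3)
})

test_that("peak detection finds the analytic maximum with earliest-tie rule", {
  cur <- perfusion_curve(gv_fixture_params(dt = 0.1))
  pk <- detect_peak(cur)
  expect_lt(abs(pk$TTP - 20), 0.1 + 1e-9)
  flat <- tic_curve(seq(0, 120, 1), rep(4, 121))
  pkf <- detect_peak(flat)
  expect_equal(pkf$TTP, 0)
  expect_equal(pkf$I_max, 4)
  # two equal maxima: earlier time wins
  t <- seq(0, 120, 1)
  y <- rep(0, 121); y[c(40, 80)] <- 10
  pk2 <- detect_peak(tic_curve(t, y), tic_conventions(smooth_window = 1))
  expect_equal(pk2$TTP, t[40])
})

test_that("arrival time interpolates the 10% crossing", {
  # linear ramp 0 -> 100 over [0, 10]: 10% crossing of the line is at 1 s
  t <- seq(0, 10, 0.01)
  ramp <- tic_curve(t, 10 * t, window = 10)
  expect_equal(arrival_time(ramp, baseline = 0, I_max = 100), 1.0,
               tolerance = 0.02)
  # crossing exactly at a sample returns that sample's time
  y <- c(0, 0, 0, 0, 10, 20, 30, 40)
  cur <- tic_curve(0:7, y, window = 7)
  expect_equal(arrival_time(cur, baseline = 0, I_max = 40,
                            conventions = tic_conventions(smooth_window = 1,
                                                          arrival_frac = 0.25)),
               4)
  flat <- tic_curve(1:8, rep(2, 8), window = 8)
  expect_error(arrival_time(flat, baseline = 2, I_max = 2),
               class = "ceusflate_flat_curve")
})

test_that("rise time and mean transit time match triangle geometry", {
  tri <- triangle_curve(t_on = 12, rise_s = 10, fall_s = 20, height = 100)
  q <- quantify(tri)
  # arrival at 10% of peak = 1 s into the ramp; RT = 10 - 1 = 9 s
  expect_equal(q$RT, 9, tolerance = 0.02)
  # symmetric triangle: first moment sits at the peak, so mTT = TTP - arrival
  sym <- triangle_curve(t_on = 12, rise_s = 10, fall_s = 10, height = 100)
  qs <- quantify(sym)
  expect_equal(qs$mTT, qs$TTP - qs$arrival_time, tolerance = 0.05)
  # shifting the whole curve in time leaves RT and mTT unchanged
  tri2 <- triangle_curve(t_on = 30, rise_s = 10, fall_s = 20, height = 100)
  q2 <- quantify(tri2)
  expect_equal(q2$RT, q$RT, tolerance = 1e-6)
  expect_equal(q2$mTT, q$mTT, tolerance = 1e-6)
})

test_that("AUC is the clamped trapezoidal enhancement integral", {
  flat <- tic_curve(seq(0, 120, 1), rep(6, 121))
  expect_equal(auc_trapezoid(flat), 0)
  tri <- triangle_curve(t_on = 12, rise_s = 10, fall_s = 20, height = 100)
  expect_equal(auc_trapezoid(tri), 1500, tolerance = 0.01 * 1500)
  # quadrature convergence: halving dt changes AUC by < 0.5%
  a1 <- auc_trapezoid(perfusion_curve(gv_fixture_params(dt = 0.2)))
  a2 <- auc_trapezoid(perfusion_curve(gv_fixture_params(dt = 0.1)))
  expect_lt(rel_err(a1, a2), 0.005)
})

test_that("wash-in gradient is the steepest ascending slope", {
  t <- seq(0, 20, 0.01)
  y <- pmin(10 * t, 100)
  ramp <- tic_curve(t, y, window = 20)
  expect_equal(wash_in_gradient(ramp), 10, tolerance = 0.01)
  expect_error(wash_in_gradient(tic_curve(1:8, rep(3, 8), window = 8)),
               class = "ceusflate_flat_curve")
  # scaling intensities scales Grad linearly
  tri <- triangle_curve()
  tri3 <- tic_curve(tri$times, 3 * tri$intensities, window = tri$window)
  expect_equal(wash_in_gradient(tri3), 3 * wash_in_gradient(tri),
               tolerance = 1e-9)
})

test_that("chord slopes match triangle geometry with washout flagging", {
  tri <- triangle_curve(t_on = 12, rise_s = 10, fall_s = 20, height = 100)
  ks <- slopes_k(tri)
  expect_equal(ks$K_UP, 100 / 9, tolerance = 0.02 * 100 / 9)
  expect_equal(ks$K_DOWN, 5, tolerance = 0.02 * 5)
  expect_false(ks$missing_washout)
  expect_gte(ks$K_DOWN, 0)
  # monotone non-decreasing curve never reaches half-descent
  t <- seq(0, 120, 1)
  mono <- tic_curve(t, c(rep(0, 20), seq(0, 100, length.out = 101)))
  km <- slopes_k(mono)
  expect_true(km$missing_washout)
  expect_true(is.na(km$K_DOWN))
})

test_that("quantify recovers the closed-form oracle on noiseless fixtures", {
  params_set <- list(
    gv_fixture_params(dt = 0.1),
    perfusion_params(t0 = 8, alpha = 3, beta = 3, A = 4, baseline = 5,
                     dt = 0.1),
    perfusion_params(t0 = 15, alpha = 1.5, beta = 8, A = 0.5, baseline = 20,
                     dt = 0.1))
  for (pp in params_set) {
    an <- analytic_tic_parameters(pp)
    q <- quantify(perfusion_curve(pp))
    for (f in c("arrival_time", "RT", "TTP", "mTT", "I_max", "Grad", "AUC",
                "K_UP", "K_DOWN"))
      expect_lt(rel_err(q[[f]], an[[f]]), 0.02)
  }
})

test_that("quantify flags a constant curve instead of failing", {
  q <- quantify(tic_curve(seq(0, 120, 1), rep(9, 121)))
  expect_equal(q$baseline, 9)
  expect_true(q$flags[["flat"]])
  expect_true(is.na(q$TTP))
  expect_true(is.na(q$K_UP))
  expect_equal(q$AUC, 0)
})

test_that("indicators obey shift and scale equivariance", {
  pp <- gv_fixture_params(dt = 0.1)
  cur <- perfusion_curve(pp)
  q <- quantify(cur)
  # time shift: +5 s moves TTP/arrival, leaves durations and amplitudes
  shifted <- perfusion_curve(perfusion_params(t0 = 15, alpha = 2, beta = 5,
                                              A = 1, baseline = 10, dt = 0.1))
  qs <- quantify(shifted)
  expect_equal(qs$TTP, q$TTP + 5, tolerance = 0.2)
  for (f in c("RT", "mTT", "K_UP", "K_DOWN", "Grad"))
    expect_equal(qs[[f]], q[[f]], tolerance = 0.01 * abs(q[[f]]))
  expect_equal(qs$I_max - qs$baseline, q$I_max - q$baseline,
               tolerance = 0.01 * (q$I_max - q$baseline))
  # intensity scale: c * enhancement scales amplitude-type indicators by c
  scaled <- tic_curve(cur$times, 10 + 3 * (cur$intensities - 10),
                      window = cur$window)
  qc <- quantify(scaled)
  for (f in c("AUC", "Grad", "K_UP", "K_DOWN"))
    expect_equal(qc[[f]], 3 * q[[f]], tolerance = 0.01 * 3 * abs(q[[f]]))
  for (f in c("TTP", "RT", "mTT"))
    expect_equal(qc[[f]], q[[f]], tolerance = 0.01 * abs(q[[f]]))
})

test_that("slower washout never increases K_DOWN at matched enhancement", {
  # amplitude renormalised so every curve peaks at the same enhancement;
  # beta then only stretches the washout
  kd <- vapply(c(3, 4, 5, 6), function(b) {
    A <- 50 / ((2 * b)^2 * exp(-2))
    quantify(perfusion_curve(perfusion_params(t0 = 10, alpha = 2, beta = b,
                                              A = A, baseline = 10,
                                              dt = 0.1)))$K_DOWN
  }, numeric(1))
  expect_true(all(diff(kd) <= 1e-9))
})

test_that("noisy recovery keeps the median TTP error small", {
  pp <- gv_fixture_params(dt = 0.1)
  an <- analytic_tic_parameters(pp)
  cur <- perfusion_curve(pp)
  noise <- (an$I_max - pp$baseline) / 10   # 20 dB peak SNR
  errs <- vapply(1:50, function(k)
    rel_err(quantify(add_tic_noise(cur, noise, k))$TTP, an$TTP), numeric(1))
  expect_lt(median(errs), 0.05)
})
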