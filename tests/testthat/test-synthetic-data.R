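test_that("generator specs reject degenerate configurations", {
  expect_error(grass_wave_spec(length = 0), class = "ceusflate_invalid_spec")
  expect_error(grass_wave_spec(run_length_mean = 0.5),
               class = "ceusflate_invalid_spec")
  expect_error(grass_wave_spec(spike_rate = -1),
               class = "ceusflate_invalid_spec")
  expect_error(defect_wave_spec(length = 0), class = "ceusflate_invalid_spec")
  expect_error(defect_wave_spec(echo_amp_range = c(5, 5)),
               class = "ceusflate_invalid_spec")
})

test_that("signal generators are pure functions of (spec, seed)", {
  gs <- grass_wave_spec(length = 2000)
  ds <- defect_wave_spec(length = 2000)
  expect_identical(generate_grass_wave(gs, 11)$samples,
                   generate_grass_wave(gs, 11)$samples)
  expect_identical(generate_defect_wave(ds, 11)$samples,
                   generate_defect_wave(ds, 11)$samples)
  expect_false(identical(generate_grass_wave(gs, 11)$samples,
                         generate_grass_wave(gs, 12)$samples))
  # generators must not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_grass_wave(gs, 5)); after <- runif(1)
  expect_identical(before, after)
})

test_that("grass waves have RLE-compressible byte structure", {
  g <- generate_grass_wave(grass_wave_spec(run_length_mean = 20,
                                           spike_rate = 1), seed = 3)
  expect_equal(g$kind, "grass")
  blk <- rle_encode(signal_to_bytes(g))
  expect_lt(compression_ratio(length(blk$payload), blk$original_length), 100)
})

test_that("defect waves carry more symbol entropy than grass waves", {
  g <- generate_grass_wave(grass_wave_spec(), seed = 5)
  d <- generate_defect_wave(defect_wave_spec(), seed = 5)
  expect_equal(d$kind, "defect")
  expect_gt(information_entropy(d)$entropy_bits,
            information_entropy(g)$entropy_bits)
})

test_that("defect wave with no echoes and no noise is all-zero", {
  d <- generate_defect_wave(defect_wave_spec(n_echoes = 0, noise_sd = 0,
                                             length = 500), seed = 1)
  expect_true(all(d$samples == 0L))
})

test_that("perfusion curve follows the gamma-variate model", {
  pp <- perfusion_params(t0 = 10, alpha = 2, beta = 5, A = 1, baseline = 10,
                         dt = 0.1)
  cur <- perfusion_curve(pp)
  # baseline exactly up to arrival, non-negative everywhere
  expect_true(all(cur$intensities[cur$times <= pp$t0] == pp$baseline))
  expect_true(all(cur$intensities >= 0))
  # analytic argmax at t0 + alpha*beta = 20 s
  expect_equal(cur$times[which.max(cur$intensities)], 20, tolerance = 1e-8)
  # analytic peak value
  peak <- pp$baseline + pp$A * (pp$alpha * pp$beta)^pp$alpha * exp(-pp$alpha)
  expect_equal(max(cur$intensities), peak, tolerance = 1e-10)
  # A = 0 collapses to the baseline
  flat <- perfusion_curve(perfusion_params(A = 0, baseline = 7))
  expect_true(all(flat$intensities == 7))
})

test_that("TIC noise is zero-mean, clipped, and seed-deterministic", {
  cur <- perfusion_curve(gv_fixture_params())
  expect_identical(add_tic_noise(cur, 0, 1)$intensities, cur$intensities)
  expect_identical(add_tic_noise(cur, 3, 42)$intensities,
                   add_tic_noise(cur, 3, 42)$intensities)
  expect_error(add_tic_noise(cur, -1, 1), class = "ceusflate_invalid_spec")
  expect_true(all(add_tic_noise(cur, 50, 7)$intensities >= 0))
  # Monte-Carlo mean at a fixed time within 3 SE of the noiseless value
  idx <- which.min(abs(cur$times - 30))
  sd_n <- 2; n_rep <- 1000
  vals <- vapply(seq_len(n_rep), function(k)
    add_tic_noise(cur, sd_n, k)$intensities[idx], numeric(1))
  se <- sd_n / sqrt(n_rep)
  expect_lt(abs(mean(vals) - cur$intensities[idx]), 3 * se)
})

test_that("closed-form oracle matches brute-force evaluation of the model", {
  pp <- gv_fixture_params()
  an <- analytic_tic_parameters(pp)
  # TTP and peak in closed form
  expect_equal(an$TTP, 20)
  expect_equal(an$I_max, 10 + 100 * exp(-2), tolerance = 1e-12)
  # A = 0 gives zero enhancement indicators
  null <- analytic_tic_parameters(perfusion_params(A = 0))
  expect_equal(null$AUC, 0)
  expect_equal(null$Grad, 0)
  expect_equal(null$K_UP, 0)
  # quadrature convergence: 100x vs 1000x resolution within 0.1%
  a1 <- analytic_tic_parameters(pp, resolution_factor = 100)
  a2 <- analytic_tic_parameters(pp, resolution_factor = 1000)
  for (f in c("arrival_time", "RT", "mTT", "Grad", "AUC", "K_UP", "K_DOWN"))
    expect_lt(rel_err(a1[[f]], a2[[f]]), 0.001)
  # brute force on a 10x finer grid agrees within 0.1% for every indicator
  fine <- analytic_tic_parameters(perfusion_params(t0 = 10, alpha = 2,
                                                   beta = 5, A = 1,
                                                   baseline = 10,
                                                   dt = pp$dt / 10))
  for (f in c("arrival_time", "RT", "TTP", "mTT", "I_max", "Grad", "AUC",
              "K_UP", "K_DOWN"))
    expect_lt(rel_err(an[[f]], fine[[f]]), 0.001)
})

test_that("cohort generation is deterministic with configured group effects", {
  spec <- default_cohort_spec(seed = 21)
  coh1 <- generate_cohort(spec)
  coh2 <- generate_cohort(spec)
  expect_equal(length(coh1), 52 + 74)
  expect_identical(coh1[[5]]$curve$intensities, coh2[[5]]$curve$intensities)
  expect_identical(coh1[[100]]$true_params, coh2[[100]]$true_params)
  # population mean TTP lower in the malignant group
  ttp <- vapply(coh1, function(r)
    r$true_params$t0 + r$true_params$alpha * r$true_params$beta, numeric(1))
  grp <- vapply(coh1, function(r) r$group_label, character(1))
  expect_lt(mean(ttp[grp == "malignant"]), mean(ttp[grp == "benign"]))
})

test_that("cohort with zero variation shares parameters within groups", {
  spec <- cohort_spec(
    group_param_means = list(a = perfusion_params(),
                             b = perfusion_params(t0 = 8)),
    n_per_group = c(a = 2L, b = 2L),
    between_subject_cv = 0, noise_sd = 0, seed = 1)
  coh <- generate_cohort(spec)
  expect_identical(coh[[1]]$true_params, coh[[2]]$true_params)
  expect_identical(coh[[1]]$curve$intensities, coh[[2]]$curve$intensities)
})

test_that("mis-ordered group effects raise a configuration warning", {
  spec <- cohort_spec(
    group_param_means = list(
      benign = perfusion_params(t0 = 8, A = 12),
      malignant = perfusion_params(t0 = 12, A = 1)),
    n_per_group = c(benign = 2L, malignant = 2L),
    between_subject_cv = 0, noise_sd = 0, seed = 1)
  expect_warning(generate_cohort(spec), "effect directions")
})

test_that("noiseless zero-variation cohort matches the analytic oracle", {
  spec <- cohort_spec(
    group_param_means = list(a = gv_fixture_params()),
    n_per_group = c(a = 2L),
    between_subject_cv = 0, noise_sd = 0, seed = 1)
  coh <- generate_cohort(spec)
  q <- quantify(coh[[1]]$curve)
  an <- analytic_tic_parameters(coh[[1]]$true_params)
  for (f in c("RT", "TTP", "mTT", "I_max", "Grad", "AUC", "K_UP", "K_DOWN"))
    expect_lt(rel_err(q[[f]], an[[f]]), 0.02)
})
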