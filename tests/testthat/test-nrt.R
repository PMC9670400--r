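test_that("model construction validates the variant fraction", {
  wt <- variant_params("WT")
  gm <- build_gating_model(wt$act, wt$inact, wt$rec, label = "WT")
  expect_error(build_nrt_model(gm, f = -0.1), "\\[0, 1\\]")
  expect_error(build_nrt_model(gm, f = 1.2), "\\[0, 1\\]")
  m <- build_nrt_model(gm, f = 0.2)
  expect_s3_class(m, "nrt_model")
  # models without a parametric description are refused
  rm <- recording_model(wt$act, wt$inact, wt$rec)
  expect_error(build_nrt_model(rm), "parametric")
})

test_that("f = 0 reproduces the reference cell bit for bit, for any variant", {
  m_wt <- nrt_for("WT", f = 0)
  m_p <- nrt_for("P2280H", f = 0)
  r_wt <- run_current_clamp(m_wt, -0.3)
  r_p <- run_current_clamp(m_p, -0.3)
  expect_identical(r_wt$v_m, r_p$v_m)
  expect_identical(r_wt$spike_times, r_p$spike_times)
})

test_that("f = 1 with reference kinetics equals f = 0 (split consistency)", {
  m0 <- nrt_for("WT", f = 0)
  m1 <- build_nrt_model(reference_as_variant(), f = 1)
  r0 <- run_current_clamp(m0, -0.3)
  r1 <- run_current_clamp(m1, -0.3)
  expect_identical(r0$v_m, r1$v_m)
})

test_that("the solved bias holds the soma within 0.5 mV of -70 for 1 s", {
  for (lab in c("WT", "P2280H", "A802V")) {
    m <- nrt_for(lab)
    r <- run_current_clamp(m, 0, pre_ms = 200, pulse_ms = 200,
                           post_ms = 600)
    expect_lt(max(abs(r$v_m[, 1] + 70)), 0.5)
    expect_length(r$spike_times, 0)
  }
})

test_that("a strong depolarizing pulse evokes sustained tonic firing", {
  m <- nrt_for("WT")
  r <- run_current_clamp(m, 0.2)
  pulse_spikes <- r$spike_times[r$spike_times >= 200 &
                                  r$spike_times < 400]
  expect_gt(length(pulse_spikes), 10)
  # spikes span the pulse, not just its onset
  expect_gt(max(pulse_spikes), 350)
  expect_gt(firing_frequency(r, "pulse"), 50)
})

test_that("subthreshold hyperpolarization yields no rebound spikes", {
  m <- nrt_for("WT")
  r <- run_current_clamp(m, -0.02)
  expect_equal(sum(r$spike_times >= 400), 0)
})

test_that("rebound scan counts are non-decreasing with pulse magnitude", {
  m <- nrt_for("WT")
  sc <- rebound_scan(m, seq(-1.0, -0.05, by = 0.05), rebound_ms = 400)
  # amplitudes ascend from -1.0; counts must descend along that order
  counts_by_depth <- rev(sc$rebound_spikes)
  expect_true(all(diff(counts_by_depth) >= 0))
  expect_equal(counts_by_depth[1], 0)
  expect_gt(max(counts_by_depth), 3)
  expect_error(rebound_scan(m, c(0.1, 0.2)), "negative")
})

test_that("rheobase bisection is stable under bracket perturbation", {
  m <- nrt_for("WT")
  r1 <- find_rheobase(m, "rebound", resolution = 0.001,
                      bracket = c(0.02, 0.5), rebound_ms = 400)
  r2 <- find_rheobase(m, "rebound", resolution = 0.001,
                      bracket = c(0.013, 0.61), rebound_ms = 400)
  expect_lt(abs(r1 - r2), 2 * 0.001)
  expect_error(find_rheobase(m, "rebound", bracket = c(0.5, 1.0),
                             rebound_ms = 400), "bracket")
})

test_that("removing the T conductance abolishes rebound but not tonic firing", {
  ref <- nrt_reference()
  ref$pcat[] <- 0
  wt <- variant_params("WT")
  m <- build_nrt_model(build_gating_model(wt$act, wt$inact, wt$rec,
                                          label = "WT"), 0.2, ref)
  reb <- run_current_clamp(m, -0.65)
  expect_equal(sum(reb$spike_times >= 400), 0)
  ton <- run_current_clamp(m, 0.2)
  expect_gt(sum(ton$spike_times >= 200 & ton$spike_times < 400), 5)
})

test_that("a -10 mV synthetic activation shift lowers the rebound rheobase magnitude", {
  wt <- variant_params("WT")
  gm_wt <- build_gating_model(wt$act, wt$inact, wt$rec, label = "WT")
  act_shift <- activation_params(wt$act$g_max, wt$act$v_half - 10,
                                 wt$act$slope_k, wt$act$v_rev)
  gm_sh <- build_gating_model(act_shift, wt$inact, wt$rec,
                              label = "shifted")
  r_wt <- find_rheobase(build_nrt_model(gm_wt), "rebound",
                        resolution = 2e-4, rebound_ms = 400)
  r_sh <- find_rheobase(build_nrt_model(gm_sh), "rebound",
                        resolution = 2e-4, rebound_ms = 400)
  expect_lt(abs(r_sh), abs(r_wt))
})

test_that("halving the integration step leaves spike statistics unchanged", {
  m <- nrt_for("WT")
  for (a in c(-0.65, 0.2)) {
    r1 <- run_current_clamp(m, a, dt = 0.0125)
    r2 <- run_current_clamp(m, a, dt = 0.00625)
    expect_equal(length(r1$spike_times), length(r2$spike_times))
    expect_equal(r1$spike_times, r2$spike_times, tolerance = 0.02)
  }
})

test_that("firing_frequency uses the 200 ms convention", {
  r <- structure(list(spike_times = c(450, 500, 550),
                      phases = c(pre = 200, pulse = 200, post = 400)),
                 class = "current_clamp_result")
  expect_equal(firing_frequency(r, "rebound"), 15)  # 3 spikes -> 15 Hz
  expect_equal(firing_frequency(r, "pulse"), 0)
})

test_that("spike detection applies threshold and refractory period", {
  t <- seq(0, 20, by = 0.1)
  v <- rep(-70, length(t))
  v[t %in% c(5, 5.5)] <- 20   # two crossings 0.5 ms apart: one spike
  v[t %in% c(12)] <- 30       # second spike, > 2 ms later
  st <- detect_spikes(t, v)
  expect_length(st, 2)
  expect_equal(st, c(5, 12))
  expect_length(detect_spikes(t, rep(-70, length(t))), 0)
})
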