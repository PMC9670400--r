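test_that("forward gating equations match hand-evaluated values", {
  act <- wt_act()
  # zero driving force at the reversal potential
  expect_equal(eval_iv(40, act), 0)
  # half-activation point
  expect_equal(eval_iv(act$v_half, act),
               act$g_max * (act$v_half - act$v_rev) / 2)
  # hand evaluation at -30 mV with the published WT values
  expect_equal(eval_iv(-30, act), -46.0136936995, tolerance = 1e-10)

  expect_equal(eval_conductance(act$v_half, act), act$g_max / 2)
  expect_equal(eval_conductance(1e4, act), act$g_max, tolerance = 1e-12)
  expect_equal(eval_conductance(-1e4, act), 0, tolerance = 1e-12)

  inact <- wt_inact()
  expect_equal(eval_ssi(inact$v_half, inact), inact$i_max / 2)
  expect_equal(eval_ssi(-1e4, inact), inact$i_max, tolerance = 1e-12)
  expect_equal(eval_ssi(-50, inact), 0.0696863157, tolerance = 1e-9)

  rec <- wt_rec()
  expect_equal(eval_recovery(0, rec), 0)
  expect_equal(eval_recovery(644, recovery_params(tau = 644)),
               1 - exp(-1))
  expect_equal(eval_recovery(8000, rec), 0.9999959725, tolerance = 1e-9)
  expect_error(eval_recovery(-1, rec), "non-negative")
})

test_that("equations agree with independent scalar evaluation on random draws", {
  set.seed(42)
  for (i in 1:50) {
    g <- runif(1, 0.1, 2); vh <- runif(1, -60, -20)
    k <- runif(1, 2, 10); vr <- runif(1, 20, 60)
    p <- activation_params(g, vh, k, vr)
    v <- runif(5, -90, 30)
    expect_equal(eval_iv(v, p),
                 g * (v - vr) / (1 + exp((vh - v) / k)),
                 tolerance = 1e-12)
    # algebraic identity: G(V) * (V - Vrev) == I(V)
    expect_equal(eval_conductance(v, p) * (v - vr), eval_iv(v, p),
                 tolerance = 1e-12)
    pi2 <- inactivation_params(runif(1, -80, -50), runif(1, 2, 8))
    expect_equal(eval_ssi(v, pi2),
                 pi2$i_max / (1 + exp((v - pi2$v_half) / pi2$slope_k)),
                 tolerance = 1e-12)
    pr <- recovery_params(runif(1, 100, 1000), runif(1, 0.8, 1.05))
    t <- runif(5, 0, 8000)
    expect_equal(eval_recovery(t, pr),
                 pr$amplitude_A * (1 - exp(-t / pr$tau)),
                 tolerance = 1e-12)
  }
})

test_that("recovery curve is concave, increasing and bounded by A", {
  p <- recovery_params(tau = 300, amplitude_A = 0.97)
  t <- seq(0, 5000, by = 10)
  y <- eval_recovery(t, p)
  expect_true(all(diff(y) > 0))
  expect_true(all(diff(diff(y)) < 1e-12))  # concave
  expect_true(all(y <= p$amplitude_A + 1e-12))
})

test_that("parameter constructors enforce their invariants", {
  expect_error(activation_params(0.8, -40, -2), "slope_k")
  expect_error(activation_params(-0.1, -40, 5), "g_max")
  expect_error(activation_params(0.8, 50, 5, v_rev = 40), "v_rev")
  expect_error(inactivation_params(-60, 4, i_max = 1.2), "i_max")
  expect_error(recovery_params(-5), "tau")
  expect_error(recovery_params(100, amplitude_A = 1.2), "amplitude_A")
})

test_that("built gating models satisfy the gate invariants for all variants", {
  tab <- cav32_variants()
  grid <- seq(-120, 40, by = 0.1)
  for (lab in tab$label) {
    p <- variant_params(lab, tab)
    m <- build_gating_model(p$act, p$inact, p$rec, label = lab)
    expect_silent(validate_gating_model(m, grid))
    r <- recording_model(p$act, p$inact, p$rec, label = lab)
    expect_silent(validate_gating_model(r, grid))
  }
})

test_that("identity build reproduces the reference time constants", {
  ref <- reference_t_kinetics()
  act <- activation_params(1, -52, 7.4, v_rev = 40)
  inact <- inactivation_params(-80, 5)
  # a recovery tau equal to the reference tau_h at -110 mV gives unit
  # scaling and zero voltage shift
  rec <- recovery_params(tau = ref$tau_h(-110))
  m <- build_gating_model(act, inact, rec)
  v <- seq(-110, 30, by = 7)
  expect_equal(m$tau_m(v), ref$tau_m(v), tolerance = 1e-12)
  expect_equal(m$tau_h(v), ref$tau_h(v), tolerance = 1e-12)
  expect_equal(m$pars[["s_rec"]], 1, tolerance = 1e-12)
  expect_equal(m$pars[["dm"]], 0)
  expect_equal(m$pars[["dh"]], 0)
})

test_that("recovery limb of tau_h is anchored to the fitted recovery tau", {
  tab <- cav32_variants()
  wt <- variant_params("WT", tab)
  m_wt <- build_gating_model(wt$act, wt$inact, wt$rec, label = "WT")
  expect_equal(m_wt$tau_h(-110), 644, tolerance = 0.01)
  a8 <- variant_params("A802V", tab)
  m_a8 <- build_gating_model(a8$act, a8$inact, a8$rec, label = "A802V")
  expect_equal(m_a8$tau_h(-110), 241, tolerance = 0.01)
  # variant/WT recovery-limb ratio equals the ratio of fitted taus
  # (up to the ~3e-4 residual of the sigmoidal limb blend at -110 mV)
  expect_equal(m_a8$tau_h(-110) / m_wt$tau_h(-110), 0.3742236025,
               tolerance = 1e-3)
})

test_that("build_gating_model rejects missing or bad references", {
  expect_error(build_gating_model(wt_act(), wt_inact(), wt_rec(),
                                  reference = NULL),
               "reference")
  no_pars <- reference_t_kinetics()
  no_pars$pars <- NULL
  expect_error(build_gating_model(wt_act(), wt_inact(), wt_rec(),
                                  reference = no_pars),
               "reference")
})

test_that("gating parameters serialize to and from JSON losslessly", {
  path <- withr::local_tempfile(fileext = ".json")
  write_gating_json("WT", wt_act(), wt_inact(), wt_rec(), path,
                    provenance = "unit test")
  x <- read_gating_json(path)
  expect_equal(x$label, "WT")
  expect_equal(x$act, wt_act())
  expect_equal(x$inact, wt_inact())
  expect_equal(x$rec, wt_rec())
})

test_that("the bundled variant table carries the expected structure", {
  tab <- cav32_variants()
  expect_equal(nrow(tab), 14)
  expect_true(all(tab$k_inact > 0))  # re-signed on load
  expect_true(all(c("gmax", "vh_act", "k_act", "vh_inact", "k_inact",
                    "tau_rec", "n_act", "n_inact", "n_rec") %in%
                    names(tab)))
  expect_error(variant_params("NOPE", tab), "unknown")
})
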