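test_that("analytic AIF obeys pre-bolus zero, scaling and shape contracts", {
  t <- seq(0, 5, by = 0.05)
  expect_identical(analytic_aif(0, "parker"), 0)
  expect_identical(analytic_aif(t, "parker", dose_scale = 0),
                   numeric(length(t)))
  expect_error(analytic_aif(t, "gamma_variate"))
  expect_error(analytic_aif(-t), class = "dce_input_error")

  cp <- analytic_aif(t, "parker", bolus_arrival = 0.5)
  expect_true(all(cp[t <= 0.5] == 0))
  expect_true(all(cp >= 0))
  # single dominant peak then decay: tail is below half the peak
  expect_lt(cp[length(cp)], max(cp) / 2)
})

test_that("Parker curve matches the frozen dense-grid peak fixture", {
  # peak located once by argmax over a 1e-5 min grid and frozen
  t <- seq(0, 1, by = 1e-4)
  cp <- analytic_aif(t, "parker")
  expect_equal(t[which.max(cp)], 0.17257, tolerance = 1e-3)
  expect_equal(max(cp), 6.073208, tolerance = 1e-5)
})

test_that("extended Tofts forward model honours its limit cases", {
  t <- seq(0, 4, by = 0.02)
  cp <- analytic_aif(t, "parker")
  expect_identical(forward_tofts(tissue_kinetic_params(0, 0.3, 0), cp, t),
                   numeric(length(t)))
  expect_equal(forward_tofts(tissue_kinetic_params(0, 0.3, 1), cp, t), cp)
  # constant input closed form: Ct = ve ktrans/kep (1 - exp(-kep t)) reduces
  # to 0.2 (1 - exp(-0.5 t)) for ktrans 0.1, ve 0.2
  ct <- forward_tofts(tissue_kinetic_params(0.1, 0.2, 0), rep(1, length(t)), t)
  expect_equal(ct, 0.2 * (1 - exp(-0.5 * t)), tolerance = 1e-5)
  expect_equal(ct[t == 2], 0.2 * (1 - exp(-1)), tolerance = 1e-5)
})

test_that("two-compartment uptake model honours its limit cases", {
  t <- seq(0, 6, by = 0.02)
  # ps = 0: pure plasma transit, Fp * int cp exp(-(t-u)/Tp) du
  p <- uptake_kinetic_params(fp = 0.4, vp = 0.08, ps = 0)
  cp <- analytic_aif(t, "parker")
  ref <- p$fp * kernel_conv(cp, t, function(s) exp(-s / p$tp))
  expect_equal(forward_2cu(p, cp, t), ref, tolerance = 1e-12)
  # constant input with ps = 0 plateaus at Fp Tp = vp
  ct <- forward_2cu(p, rep(1, length(t)), t)
  expect_equal(ct[length(ct)], p$vp, tolerance = 1e-3)
})

test_that("discrete convolution matches adaptive quadrature", {
  # both models, checked at 10 probe times against stats::integrate on the
  # same smooth input
  cp_fun <- function(u) 5 * exp(-((u - 0.5) / 0.25)^2)
  n <- 12000
  t <- seq(0, 2, length.out = n)
  cp <- cp_fun(t)
  probes <- t[seq(n / 10, n, by = n / 10)]

  pt <- tissue_kinetic_params(0.25, 0.4, 0.05)
  ct <- forward_tofts(pt, cp, t)
  pu <- uptake_kinetic_params(0.6, 0.05, 0.05)
  cu <- forward_2cu(pu, cp, t)
  for (tp in probes) {
    ref_t <- pt$vp * cp_fun(tp) + pt$ktrans *
      stats::integrate(function(u) cp_fun(u) * exp(-pt$kep * (tp - u)),
                       0, tp, rel.tol = 1e-10)$value
    ref_u <- pu$fp *
      stats::integrate(function(u) cp_fun(u) *
                         (pu$e + (1 - pu$e) * exp(-(tp - u) / pu$tp)),
                       0, tp, rel.tol = 1e-10)$value
    expect_lt(abs(ct[t == tp] - ref_t) / max(ct), 1e-6)
    expect_lt(abs(cu[t == tp] - ref_u) / max(cu), 1e-6)
  }
})

test_that("kinetic parameter containers enforce their invariants", {
  p <- tissue_kinetic_params(0.25, 0.4, 0.05)
  expect_equal(p$kep * p$ve, p$ktrans, tolerance = 1e-9)
  expect_error(tissue_kinetic_params(0.1, 0, 0.05), class = "dce_input_error")
  expect_error(tissue_kinetic_params(-1, 0.4, 0.05), class = "dce_input_error")
  u <- uptake_kinetic_params(0.6, 0.05, 0.05)
  expect_true(u$e >= 0 && u$e < 1 && u$tp > 0)
  expect_error(uptake_kinetic_params(0, 0.05, 0.05), class = "dce_input_error")
})

test_that("phantom generation is deterministic and records ground truth", {
  cfg <- small_phantom_config()
  ph1 <- generate_phantom(cfg)
  ph2 <- generate_phantom(cfg)
  expect_identical(ph1$series$data, ph2$series$data)  # sigma = 0

  tum <- ph1$masks$tumour$data > 0
  expect_true(all(ph1$truth$ktrans$data[tum] == cfg$tumour_params$ktrans))
  expect_true(all(is.nan(ph1$truth$ktrans$data[ph1$masks$artery$data > 0])))

  # noisy generation is reproducible bit-for-bit given (config, seed)
  cfgn <- small_phantom_config(sigma = 0.05, seed = 99)
  expect_identical(generate_phantom(cfgn)$series$data,
                   generate_phantom(cfgn)$series$data)
  # and differs for a different seed
  cfgn2 <- small_phantom_config(sigma = 0.05, seed = 100)
  expect_false(identical(generate_phantom(cfgn)$series$data,
                         generate_phantom(cfgn2)$series$data))
})

test_that("overlapping phantom regions are rejected", {
  expect_error(phantom_config(dims = c(16, 16, 4),
                              tumour_centre = c(8, 8, 2), tumour_radius = 3,
                              artery_corner = c(8, 8, 1),
                              artery_size = c(2, 2, 4)),
               "overlap", class = "dce_input_error")
  expect_error(phantom_config(sigma = 0.1, seed = NULL),
               "seed", class = "dce_input_error")
})

test_that("concentration curves stay nonnegative for nonnegative inputs", {
  t <- seq(0, 5, by = 0.1)
  cp <- analytic_aif(t, "parker")
  set.seed(3)
  for (i in 1:20) {
    ve <- runif(1, 0.05, 1)
    ct <- forward_tofts(tissue_kinetic_params(runif(1, 0, 1), ve,
                                              runif(1, 0, 0.2)), cp, t)
    cu <- forward_2cu(uptake_kinetic_params(runif(1, 0.1, 2),
                                            runif(1, 0.01, 0.2),
                                            runif(1, 0, 0.5)), cp, t)
    expect_true(all(ct >= 0) && all(cu >= 0))
  }
})
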