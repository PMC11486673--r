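# Voxel-wise fitting: recovery oracles, degenerate handling, exclusion rule.

phantom_frame_grid <- function(n = 70, spacing = 5) (seq_len(n) - 1) * spacing / 60

test_that("extended Tofts fit recovers noiseless ground truth within 2%", {
  t <- phantom_frame_grid()
  cp <- analytic_aif(t, "parker", bolus_arrival = t[3])
  truth <- tissue_kinetic_params(0.25, 0.4, 0.05)
  ct <- forward_tofts(truth, cp, t)
  fit <- fit_extended_tofts(ct, cp, t, seed = 5)
  expect_false(fit$degenerate || fit$failed)
  expect_equal(fit$params$ktrans, truth$ktrans, tolerance = 0.02)
  expect_equal(fit$params$ve, truth$ve, tolerance = 0.02)
  expect_equal(fit$params$vp, truth$vp, tolerance = 0.02)
  expect_equal(fit$params$kep * fit$params$ve, fit$params$ktrans,
               tolerance = 1e-12)
  expect_gt(fit$rsq, 0.999)
  # optimizer sanity: never worse than the generating parameters
  expect_lte(fit$sse, sum((forward_tofts(truth, cp, t) - ct)^2) + 1e-12)
})

test_that("pure-plasma curves fit to vp with negligible leakage", {
  t <- phantom_frame_grid()
  cp <- analytic_aif(t, "parker", bolus_arrival = t[3])
  fit <- fit_extended_tofts(0.1 * cp, cp, t, seed = 2)
  expect_equal(fit$params$vp, 0.1, tolerance = 1e-3)
  expect_lt(fit$params$ktrans, 1e-3)
})

test_that("degenerate tissue curves are flagged, not fitted", {
  t <- phantom_frame_grid(40)
  cp <- analytic_aif(t, "parker")
  z <- fit_extended_tofts(rep(0, length(t)), cp, t)
  expect_true(z$degenerate)
  expect_identical(z$params$ktrans, 0)
  expect_identical(z$params$vp, 0)
  expect_true(fit_2cu(rep(0, length(t)), cp, t)$degenerate)
  expect_true(fit_extended_tofts(rep(NaN, length(t)), cp, t)$degenerate)
  expect_error(fit_extended_tofts(cp[1:4], cp[1:4], t[1:4]),
               class = "dce_input_error")
})

test_that("two-compartment uptake fit recovers Fp within 5%", {
  t <- phantom_frame_grid()
  cp <- analytic_aif(t, "parker", bolus_arrival = t[3])
  truth <- uptake_kinetic_params(0.6, 0.05, 0.05)
  ct <- forward_2cu(truth, cp, t)
  fit <- fit_2cu(ct, cp, t, seed = 5)
  expect_false(fit$degenerate || fit$failed)
  expect_equal(fit$params$fp, truth$fp, tolerance = 0.05)
  # data generated without extraction fit to e ~ 0
  ct0 <- forward_2cu(uptake_kinetic_params(0.6, 0.05, 0), cp, t)
  fit0 <- fit_2cu(ct0, cp, t, seed = 5)
  expect_lt(fit0$params$e, 0.01)
})

test_that("ktrans bias stays below 10% at 5% noise over 50 replicates", {
  t <- phantom_frame_grid()
  cp <- analytic_aif(t, "parker", bolus_arrival = t[3])
  truth <- tissue_kinetic_params(0.25, 0.4, 0.05)
  ct <- forward_tofts(truth, cp, t)
  set.seed(424)
  est <- vapply(1:50, function(i) {
    noisy <- ct + rnorm(length(ct), sd = 0.05 * max(ct))
    fit_extended_tofts(noisy, cp, t, n_starts = 3, seed = i)$params$ktrans
  }, numeric(1))
  expect_lt(abs(median(est) / truth$ktrans - 1), 0.10)
})

test_that("semiquantitative flow handles scaling, shifting and degeneracy", {
  # shift-scale construction: a pulse fully contained in the window
  t <- seq(0, 6, by = 0.005)
  pulse <- function(u, t0) exp(-((u - t0) / 0.3)^2)
  aif <- pulse(t, 1.0)
  ct <- 0.5 * pulse(t, 1.5)    # half the area, half a minute later
  sq <- semiquant_flow(ct, aif, t)
  expect_equal(sq$cbv, 0.5, tolerance = 1e-4)
  expect_equal(sq$mtt, 0.5, tolerance = 1e-4)
  expect_equal(sq$rbf_auc, 1.0, tolerance = 1e-4)
  expect_false(sq$flagged)

  ident <- semiquant_flow(aif, aif, t)
  expect_equal(ident$cbv, 1, tolerance = 1e-12)
  expect_true(ident$flagged)                 # moment difference 0 -> floored
  expect_equal(ident$mtt, 1 / 60)

  zero <- semiquant_flow(rep(0, length(t)), aif, t)
  expect_identical(zero$cbv, 0)
  expect_identical(zero$rbf_auc, 0)
  expect_error(semiquant_flow(ct, rep(0, length(t)), t),
               class = "dce_estimation_error")
})

test_that("parameter maps exclude zero-signal voxels and are deterministic", {
  cfg <- small_phantom_config()
  ph <- generate_phantom(cfg)
  # force one in-mask voxel to carry no dynamic signal at all
  dead <- which(ph$masks$tumour$data > 0)[1]
  nvox <- prod(dim(ph$series$data)[1:3])
  nt <- dim(ph$series$data)[4]
  ph$series$data[dead + (seq_len(nt) - 1) * nvox] <- 0

  maps <- compute_parameter_maps(ph$series, ph$t10, ph$aif, ph$masks$brain,
                                 seed = 3)
  expect_identical(maps$excluded$data[dead], 1)
  expect_true(is.nan(maps$ktrans$data[dead]))
  expect_true(is.nan(maps$fp_rbf$data[dead]))

  # excluded mask is exactly the zero-signal set here (all fits converge)
  expect_identical(which(maps$excluded$data > 0), dead)

  # kep * ve = ktrans identically across the fitted voxels
  fitted <- is.finite(maps$ktrans$data)
  expect_equal(maps$kep$data[fitted] * maps$ve$data[fitted],
               maps$ktrans$data[fitted], tolerance = 1e-12)
  expect_true(all(maps$rsq$data[fitted] >= 0 & maps$rsq$data[fitted] <= 1))

  maps2 <- compute_parameter_maps(ph$series, ph$t10, ph$aif, ph$masks$brain,
                                  seed = 3)
  expect_identical(maps$ktrans$data, maps2$ktrans$data)
  expect_identical(maps$fp_rbf$data, maps2$fp_rbf$data)
  expect_error(compute_parameter_maps(ph$series, ph$t10, ph$aif,
                                      mask_voi(array(0, dim(ph$t10$data)),
                                               label = "brain")),
               class = "dce_input_error")
})

test_that("noiseless phantom maps recover the regional ground truth", {
  cfg <- small_phantom_config()
  ph <- generate_phantom(cfg)
  maps <- compute_parameter_maps(ph$series, ph$t10, ph$aif, ph$masks$brain,
                                 seed = 1)
  tum <- ph$masks$tumour$data > 0
  expect_equal(median(maps$ktrans$data[tum]), cfg$tumour_params$ktrans,
               tolerance = 0.02)
  ctl <- ph$masks$control$data > 0
  expect_lt(median(maps$ktrans$data[ctl]), median(maps$ktrans$data[tum]))
})
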