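# VOI summarisation and the exact-test machinery.

test_that("VOI means honour the exclusion arithmetic", {
  aff <- diag(4)
  m <- volume_map(array(3, dim = c(4, 4, 2)), affine = aff)
  msk <- mask_voi(array(1, dim = c(4, 4, 2)), affine = aff, label = "tumour")
  out <- voi_mean(m, msk)
  expect_equal(out$mean, 3)
  expect_equal(out$n_used, 32)

  m2 <- volume_map(array(c(0, 4, rep(NaN, 30)), dim = c(4, 4, 2)), affine = aff)
  msk2 <- mask_voi(array(c(1, 1, rep(0, 30)), dim = c(4, 4, 2)),
                   affine = aff, label = "tumour")
  exc <- mask_voi(array(c(1, 0, rep(0, 30)), dim = c(4, 4, 2)),
                  affine = aff, label = "brain")
  out2 <- voi_mean(m2, msk2, exc)
  expect_equal(out2$mean, 4)
  expect_equal(out2$n_used, 1)
  expect_equal(out2$n_excluded, 1)

  exc_all <- mask_voi(array(c(1, 1, rep(0, 30)), dim = c(4, 4, 2)),
                      affine = aff, label = "brain")
  expect_warning(out3 <- voi_mean(m2, msk2, exc_all), "no usable")
  expect_true(is.nan(out3$mean))
})

test_that("mirrored control VOIs match tumour size on symmetric phantoms", {
  ph <- generate_phantom(small_phantom_config())
  ctl <- mirror_control_voi(ph$masks$tumour, ph$masks$brain)
  expect_identical(sum(ctl$data), sum(ph$masks$tumour$data))
  expect_identical(ctl$label, "control")
  # the mirror lands on the built-in control region
  expect_identical(ctl$data, ph$masks$control$data)
  # ground truth: control leakage below tumour leakage
  tmean <- voi_mean(ph$truth$ktrans, ph$masks$tumour)$mean
  cmean <- voi_mean(ph$truth$ktrans, ctl)$mean
  expect_lt(cmean, tmean)
})

test_that("midline-crossing tumours yield a warned, trimmed control", {
  d <- c(10, 8, 4)
  brain <- mask_voi(array(1, dim = d), label = "brain")
  tum <- array(0, dim = d)
  tum[5:8, 3:5, 2] <- 1       # crosses the x midline at 5.5
  tum <- mask_voi(tum, label = "tumour")
  expect_warning(ctl <- mirror_control_voi(tum, brain), "midline")
  expect_true(all(ctl$data + tum$data <= 1))   # disjoint from tumour
  expect_gt(sum(ctl$data), 0)

  # reflection entirely outside the brain is an error
  brain2 <- array(0, dim = d); brain2[1:5, , ] <- 0; brain2[8:10, 1:2, 1] <- 1
  tum3 <- array(0, dim = d); tum3[9, 7, 3] <- 1
  expect_error(mirror_control_voi(mask_voi(tum3, label = "tumour"),
                                  mask_voi(brain2, label = "brain")),
               "manual", class = "dce_input_error")
})

test_that("exact signed-rank test reproduces the cohort-table statistics", {
  tab <- canine_voi_table()
  men <- tab[tab$group == "meningioma", ]
  tum <- men[men$voi_label == "tumour", ]
  ctl <- men[men$voi_label == "control", ]
  ctl <- ctl[match(tum$subject, ctl$subject), ]

  wk <- wilcoxon_signed_rank_exact(ctl$mean_ktrans, tum$mean_ktrans)
  expect_equal(round_half_up(wk$estimate$median_of_differences, 3), -0.045)
  expect_identical(wk$p_num, 2)
  expect_identical(wk$p_den, 64)
  expect_identical(sprintf("%.4f", round_half_up(wk$p_value, 4)), "0.0313")

  wr <- wilcoxon_signed_rank_exact(ctl$mean_rbf, tum$mean_rbf)
  expect_equal(round_half_up(wr$estimate$median_of_differences, 3), -3.824)
  expect_equal(wr$p_value, 2 / 64)
})

test_that("exact Mann-Whitney reproduces the between-group statistics", {
  tab <- canine_voi_table()
  tum <- tab[tab$voi_label == "tumour", ]
  men <- tum[tum$group == "meningioma", ]
  oth <- tum[tum$group == "other", ]

  mw_rbf <- mann_whitney_exact(men$mean_rbf, oth$mean_rbf)
  expect_equal(mw_rbf$p_value, 2 / 84)
  expect_identical(sprintf("%.4f", round_half_up(mw_rbf$p_value, 4)), "0.0238")

  mw_kt <- mann_whitney_exact(men$mean_ktrans, oth$mean_ktrans)
  expect_equal(mw_kt$p_value, 14 / 84)
  expect_gt(mw_kt$p_value, 0.05)
})

test_that("tiny-sample exact tests match hand enumeration", {
  # three all-positive differences, one-sided: only 1 of 8 sign patterns
  # reaches W = 6
  w <- wilcoxon_signed_rank_exact(c(2, 3, 4), c(1, 1, 1), sidedness = "one")
  expect_equal(w$p_value, 1 / 8)
  # singleton groups: both arrangements are as extreme
  m <- mann_whitney_exact(1, 2)
  expect_equal(m$p_value, 1)
  expect_error(wilcoxon_signed_rank_exact(c(1, 2), c(1, 2)),
               class = "dce_estimation_error")
})

test_that("enumeration nulls match brute force across random fixtures", {
  set.seed(7319)
  for (rep in 1:100) {
    n <- sample(2:10, 1)
    x <- round(rnorm(n), sample(0:2, 1))   # coarse rounding induces ties
    y <- round(rnorm(n), 2)
    if (all(x - y == 0)) next
    for (side in c("two", "one")) {
      got <- wilcoxon_signed_rank_exact(x, y, sidedness = side)
      expect_equal(got$p_value, oracle_signrank_p(x, y, side),
                   tolerance = 1e-12)
      expect_identical(got$p_num %% 1, 0)
      expect_identical(got$p_den %% 1, 0)
    }
    # tie-free case: agree with the classical exact distribution
    xs <- rnorm(n); ys <- rnorm(n)
    ref <- stats::wilcox.test(xs, ys, paired = TRUE, exact = TRUE)$p.value
    expect_equal(wilcoxon_signed_rank_exact(xs, ys)$p_value, ref,
                 tolerance = 1e-12)
  }
  for (rep in 1:100) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    a <- round(rnorm(na), 1)
    b <- round(rnorm(nb), 1)
    for (side in c("two", "one")) {
      got <- mann_whitney_exact(a, b, sidedness = side)
      expect_equal(got$p_value, oracle_mw_p(a, b, side), tolerance = 1e-12)
    }
    au <- rnorm(na); bu <- rnorm(nb)
    ref <- stats::wilcox.test(au, bu, exact = TRUE)$p.value
    expect_equal(mann_whitney_exact(au, bu)$p_value, ref, tolerance = 1e-12)
  }
})

test_that("one-sided exact p never exceeds the two-sided p", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_lte(wilcoxon_signed_rank_exact(x, y, "one")$p_value,
               wilcoxon_signed_rank_exact(x, y, "two")$p_value)
    a <- rnorm(sample(2:5, 1)); b <- rnorm(sample(2:5, 1))
    expect_lte(mann_whitney_exact(a, b, "one")$p_value,
               mann_whitney_exact(a, b, "two")$p_value)
  }
})

test_that("signed-rank p is invariant to monotone transforms of |d| order", {
  x <- c(5, 1, 8, 2, 9, 4)
  y <- c(3, 2, 4, 5, 1, 4.5)
  d <- x - y
  base <- wilcoxon_signed_rank_exact(x, y)$p_value
  # any strictly monotone magnitude transform preserving signs
  d2 <- sign(d) * (abs(d)^3 + 1)
  expect_equal(wilcoxon_signed_rank_exact(d2, rep(0, length(d2)))$p_value,
               base, tolerance = 1e-12)
})

test_that("Pearson test matches perfect-linear cases and a permutation null", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1)$statistic[["r"]], 1)
  expect_equal(pearson_correlation(x, -x)$statistic[["r"]], -1)
  expect_error(pearson_correlation(x, rep(2, 5)),
               class = "dce_estimation_error")
  expect_error(pearson_correlation(1:2, 2:3), class = "dce_input_error")

  set.seed(15)
  xs <- rnorm(5); ys <- xs + rnorm(5, sd = 1.2)
  got <- pearson_correlation(xs, ys)$p_value
  # brute force: all 120 permutations of y
  perms <- matrix(unlist(combinat_perms(5)), ncol = 5, byrow = TRUE)
  r_obs <- abs(cor(xs, ys))
  r_null <- apply(perms, 1, function(ix) abs(cor(xs, ys[ix])))
  p_perm <- mean(r_null >= r_obs - 1e-12)
  expect_lt(abs(got - p_perm), 0.05)
})

test_that("enhancement curves normalise to the pre-bolus baseline", {
  arr <- array(100, dim = c(3, 3, 2, 6))
  sr <- dce_series(arr, frame_times = 0:5, tr = 4.83, flip_angle = 12)
  msk <- mask_voi(array(1, dim = c(3, 3, 2)), label = "tumour")
  flat <- enhancement_curve(sr, msk, baseline_frames = 2)
  expect_equal(flat$enhancement_pct, rep(0, 6))

  arr2 <- arr
  arr2[, , , 4:6] <- 200
  sr2 <- dce_series(arr2, frame_times = 0:5, tr = 4.83, flip_angle = 12)
  up <- enhancement_curve(sr2, msk, baseline_frames = 2)
  expect_equal(up$enhancement_pct[5], 100)

  # phantom: a leakage-dominated tumour enhances later and lower than the
  # artery (small vp so the first-pass spike does not set the peak)
  ph <- generate_phantom(small_phantom_config(
    tumour_params = tissue_kinetic_params(0.25, 0.4, 0.01)))
  tc <- enhancement_curve(ph$series, ph$masks$tumour, 2)
  ac <- enhancement_curve(ph$series, ph$masks$artery, 2)
  expect_gt(which.max(tc$enhancement_pct), which.max(ac$enhancement_pct))
  expect_lt(max(tc$enhancement_pct), max(ac$enhancement_pct))
})

test_that("the cohort report is complete, rendered, and order-invariant", {
  tab <- canine_voi_table()
  rep1 <- group_comparison_report(tab)
  expect_setequal(rownames(rep1$table), rownames(rep1$table))
  expect_identical(nrow(rep1$table), 4L)   # no volumes -> no Pearson rows
  wk <- rep1$table[rep1$table$test == "wilcoxon_signed_rank_exact" &
                     rep1$table$parameter == "ktrans", ]
  expect_identical(wk$p_rendered, "0.0313")
  expect_identical(wk$estimate_rendered, "-0.045")
  mwr <- rep1$table[rep1$table$test == "mann_whitney_exact" &
                      rep1$table$parameter == "rbf", ]
  expect_identical(mwr$p_rendered, "0.0238")

  set.seed(4)
  rep2 <- group_comparison_report(tab[sample(nrow(tab)), ])
  expect_identical(rep1$table, rep2$table)

  # single-subject other group: Mann-Whitney still runs
  small <- tab[tab$subject %in% c("m1", "m2", "m3", "o1"), ]
  rep3 <- group_comparison_report(small)
  expect_true("mann_whitney_ktrans" %in% names(rep3$comparisons))

  # with volumes present, Pearson rows appear for >= 3 subjects
  tabv <- tab
  set.seed(8)
  tabv$voi_volume <- runif(nrow(tabv), 500, 3000)
  repv <- group_comparison_report(tabv)
  expect_true("pearson_ktrans_volume" %in% names(repv$comparisons))
})
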