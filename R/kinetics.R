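# Voxel-wise pharmacokinetic model fitting and parametric map assembly.
#
# Two quantitative models are fitted per voxel: the extended Tofts model
# (Ktrans, ve, vp) and the two-compartment uptake model, whose plasma flow
# Fp is reported as the model-based rBF. A semiquantitative CBV/MTT flow
# estimate (central volume theorem, curve areas) is emitted alongside.
# Voxels with no usable dynamic signal are excluded rather than fitted, so
# VOI summaries never average model failures.

default_fit_bounds <- function() {
  list(tofts = list(lower = c(ktrans = 0, ve = 1e-4, vp = 0),
                    upper = c(ktrans = 5, ve = 1, vp = 1)),
       cu    = list(lower = c(fp = 1e-4, vp = 1e-4, ps = 0),
                    upper = c(fp = 20, vp = 1, ps = 5)))
}

# Deterministic multi-start grid: midpoint-ish base start plus seeded jitter.
multi_starts <- function(lower, upper, n_starts, seed) {
  base <- lower + 0.15 * (upper - lower)
  starts <- list(base)
  if (n_starts > 1) {
    rng <- local({ set.seed(seed); stats::runif((n_starts - 1) * length(lower)) })
    jit <- matrix(rng, ncol = length(lower))
    for (i in seq_len(n_starts - 1)) {
      starts[[i + 1]] <- lower + jit[i, ] * (upper - lower)
    }
  }
  starts
}

fit_quality <- function(ct, fitted) {
  ok <- is.finite(ct) & is.finite(fitted)
  sse <- sum((ct[ok] - fitted[ok])^2)
  sst <- sum((ct[ok] - mean(ct[ok]))^2)
  rsq <- if (sst > 0) max(0, min(1, 1 - sse / sst)) else NaN
  list(sse = sse, rsq = rsq)
}

# Shared bounded multi-start Levenberg-Marquardt driver.
fit_model_ls <- function(ct, cp, t, forward, lower, upper, n_starts, seed) {
  ok <- is.finite(ct)
  grid <- conv_grid(t)
  resid_fn <- function(p) {
    r <- forward(p, cp, grid) - ct
    r[ok]
  }
  best <- NULL
  sst <- sum((ct[ok] - mean(ct[ok]))^2)
  for (p0 in multi_starts(lower, upper, n_starts, seed)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(par = fit$par, sse = sse)
    if (sst > 0 && sse / sst < 1e-12) break  # noiseless early exit
  }
  best
}

#' Fit the extended Tofts model to one concentration curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt, multi-start with a
#' deterministic seed) minimising the sum of squared residuals of
#' [forward_tofts()] against the measured tissue curve.
#'
#' @param ct tissue concentration curve in mM (`NaN` frames are ignored).
#' @param aif an [aif_curve()] holding the plasma concentration on the same
#'   frame grid (or a plain numeric vector).
#' @param t time in minutes; >= 5 frames.
#' @param bounds list with `lower`/`upper` named vectors over
#'   `(ktrans, ve, vp)`; see `default_fit_bounds()$tofts` for the defaults
#'   (Ktrans up to 5/min, ve in (1e-4, 1], vp in [0, 1]).
#' @param n_starts number of optimiser starts (default 5).
#' @param seed seed for the deterministic start jitter.
#' @return list with `params` ([tissue_kinetic_params()]; `kep` is reported
#'   as `ktrans/ve`), `rsq`, `fitted`, `sse`, and flags `degenerate` (input
#'   curve carried no signal) / `failed` (no optimiser start converged).
#' @export
fit_extended_tofts <- function(ct, aif, t, bounds = default_fit_bounds()$tofts,
                               n_starts = 5, seed = 1) {
  cp <- if (inherits(aif, "aif_curve")) aif$cp else aif
  if (length(ct) != length(t) || length(cp) != length(t)) {
    stop_input("ct, aif and t must share one frame grid")
  }
  if (length(t) < 5) stop_input("need >= 5 frames to fit")
  ok <- is.finite(ct)
  if (!any(ok) || max(abs(ct[ok])) < 1e-12) {
    degen <- structure(list(ktrans = 0, ve = NaN, vp = 0, kep = NaN),
                       class = "tissue_kinetic_params")
    return(list(params = degen, rsq = NaN, fitted = rep(0, length(t)),
                sse = NaN, degenerate = TRUE, failed = FALSE))
  }
  fw <- function(p, cp, grid) forward_tofts_grid(p[1], p[2], p[3], cp, grid)
  best <- fit_model_ls(ct, cp, t, fw, bounds$lower, bounds$upper,
                       n_starts, seed)
  if (is.null(best)) {
    return(list(params = NULL, rsq = NaN, fitted = rep(NaN, length(t)),
                sse = NaN, degenerate = FALSE, failed = TRUE))
  }
  p <- best$par
  params <- tissue_kinetic_params(p[[1]], p[[2]], p[[3]])
  fitted <- forward_tofts(params, cp, t)
  q <- fit_quality(ct, fitted)
  list(params = params, rsq = q$rsq, fitted = fitted, sse = q$sse,
       degenerate = FALSE, failed = FALSE)
}

#' Fit the two-compartment uptake model to one concentration curve
#'
#' Same optimiser protocol as [fit_extended_tofts()], with forward model
#' [forward_2cu()]; the fitted plasma flow `fp` is the model-based rBF.
#'
#' @inheritParams fit_extended_tofts
#' @param bounds list with `lower`/`upper` over `(fp, vp, ps)`; defaults
#'   `fp` in (1e-4, 20]/min, `vp` in (1e-4, 1], `ps` in [0, 5]/min.
#' @return list as in [fit_extended_tofts()] but with `params` an
#'   [uptake_kinetic_params()].
#' @export
fit_2cu <- function(ct, aif, t, bounds = default_fit_bounds()$cu,
                    n_starts = 5, seed = 1) {
  cp <- if (inherits(aif, "aif_curve")) aif$cp else aif
  if (length(ct) != length(t) || length(cp) != length(t)) {
    stop_input("ct, aif and t must share one frame grid")
  }
  if (length(t) < 5) stop_input("need >= 5 frames to fit")
  ok <- is.finite(ct)
  if (!any(ok) || max(abs(ct[ok])) < 1e-12) {
    return(list(params = NULL, rsq = NaN, fitted = rep(0, length(t)),
                sse = NaN, degenerate = TRUE, failed = FALSE))
  }
  fw <- function(p, cp, grid) forward_2cu_grid(p[1], p[2], p[3], cp, grid)
  best <- fit_model_ls(ct, cp, t, fw, bounds$lower, bounds$upper,
                       n_starts, seed)
  if (is.null(best)) {
    return(list(params = NULL, rsq = NaN, fitted = rep(NaN, length(t)),
                sse = NaN, degenerate = FALSE, failed = TRUE))
  }
  p <- best$par
  params <- uptake_kinetic_params(p[[1]], p[[2]], p[[3]])
  fitted <- forward_2cu(params, cp, t)
  q <- fit_quality(ct, fitted)
  list(params = params, rsq = q$rsq, fitted = fitted, sse = q$sse,
       degenerate = FALSE, failed = FALSE)
}

#' Semiquantitative flow estimate (CBV / MTT)
#'
#' Central-volume-theorem estimator: relative CBV is the ratio of tissue to
#' arterial curve areas (trapezoidal), MTT the difference of their first
#' temporal moments, and flow their ratio. MTT is floored to avoid division
#' blow-ups; a floored MTT is flagged, never silently clipped.
#'
#' @param ct tissue concentration curve (mM).
#' @param aif an [aif_curve()] or numeric plasma curve.
#' @param t time in minutes.
#' @param mtt_floor_s MTT floor in seconds (default 1).
#' @return list with `cbv` (fraction), `mtt` (minutes), `rbf_auc` (/min) and
#'   `flagged` (`TRUE` when the MTT hit the floor).
#' @export
semiquant_flow <- function(ct, aif, t, mtt_floor_s = 1) {
  cp <- if (inherits(aif, "aif_curve")) aif$cp else aif
  if (!length(ct) || !length(cp)) stop_input("empty curve")
  ok <- is.finite(ct)
  ct0 <- ct; ct0[!ok] <- 0
  auc_a <- trapz(t, cp)
  if (auc_a <= 0) stop_estimation("AIF has nonpositive area; cannot normalise")
  auc_t <- trapz(t, ct0)
  cbv <- auc_t / auc_a
  if (auc_t <= 0) {
    return(list(cbv = max(cbv, 0), mtt = NaN, rbf_auc = 0, flagged = FALSE))
  }
  m_t <- trapz(t, t * ct0) / auc_t
  m_a <- trapz(t, t * cp) / auc_a
  floor_min <- mtt_floor_s / 60
  mtt <- m_t - m_a
  flagged <- mtt < floor_min
  mtt <- max(mtt, floor_min)
  list(cbv = cbv, mtt = mtt, rbf_auc = cbv / mtt, flagged = flagged)
}

#' Compute voxel-wise parametric maps over a brain mask
#'
#' For every voxel of the brain mask: convert the dynamic signal to
#' concentration (baseline-T1-corrected SPGR inversion using the voxel's
#' pre-contrast T1), fit the extended Tofts and two-compartment uptake
#' models, and evaluate the semiquantitative CBV/MTT estimator. Voxels whose
#' dynamic signal never rises above `zero_thresh` times the series maximum
#' ("zero-signal" voxels, where fitting is meaningless), and voxels whose
#' fits are degenerate or fail, enter the exclusion mask and are `NaN` in
#' every parameter map.
#'
#' @param series a [dce_series()].
#' @param t10_map pre-contrast T1 [volume_map()] in ms, same grid.
#' @param aif plasma [aif_curve()] on the series frame grid.
#' @param brain_mask [mask_voi()] selecting the voxels to fit.
#' @param r1 contrast relaxivity in /s/mM.
#' @param baseline_frames leading pre-bolus frames used for S0 (>= 1).
#' @param bounds list with `tofts` and `cu` bound sets; see
#'   `default_fit_bounds()`.
#' @param n_starts,seed optimiser protocol per voxel (the per-voxel seed is
#'   derived deterministically from `seed` and the voxel index).
#' @param zero_thresh zero-signal threshold as a fraction of the series
#'   maximum (default 1e-9).
#' @param mtt_floor_s MTT floor for the semiquantitative estimator.
#' @return Object of class `kinetic_maps`: [volume_map()]s `ktrans`, `kep`,
#'   `ve`, `vp`, `fp_rbf`, `rbf_auc`, `cbv`, `mtt`, `rsq` (extended Tofts
#'   goodness of fit) plus the `excluded` [mask_voi()].
#' @export
compute_parameter_maps <- function(series, t10_map, aif, brain_mask,
                                   r1 = 3.7, baseline_frames = 2,
                                   bounds = default_fit_bounds(),
                                   n_starts = 5, seed = 1,
                                   zero_thresh = 1e-9, mtt_floor_s = 1) {
  d <- dim(series$data)[1:3]
  if (!all(dim(brain_mask$data) == d) || !all(dim(t10_map$data) == d)) {
    stop_input("series, T1 map and brain mask must share one grid")
  }
  vox <- which(brain_mask$data > 0)
  if (!length(vox)) stop_input("brain mask is empty")
  t_min <- series$frame_times / 60
  nt <- length(t_min)
  nvox_total <- prod(d)
  smax <- max(series$data, na.rm = TRUE)

  blank <- array(NaN, dim = d)
  maps <- list(ktrans = blank, kep = blank, ve = blank, vp = blank,
               fp_rbf = blank, rbf_auc = blank, cbv = blank, mtt = blank,
               rsq = blank)
  excluded <- array(0, dim = d)

  for (ii in seq_along(vox)) {
    v <- vox[ii]
    s_t <- series$data[v + (seq_len(nt) - 1) * nvox_total]
    if (max(s_t, na.rm = TRUE) <= zero_thresh * smax) {
      excluded[v] <- 1
      next
    }
    t10 <- t10_map$data[v]
    if (!is.finite(t10) || t10 <= 0) {
      excluded[v] <- 1
      next
    }
    conv <- signal_to_concentration(
      s_t, baseline_frames, relaxation_state(t10, 1, r1),
      series$tr, series$flip_angle)
    if (conv$excluded) {
      excluded[v] <- 1
      next
    }
    vseed <- (seed + ii) %% .Machine$integer.max
    ft <- fit_extended_tofts(conv$conc, aif, t_min, bounds = bounds$tofts,
                             n_starts = n_starts, seed = vseed)
    fu <- fit_2cu(conv$conc, aif, t_min, bounds = bounds$cu,
                  n_starts = n_starts, seed = vseed)
    if (ft$degenerate || ft$failed || fu$degenerate || fu$failed) {
      excluded[v] <- 1
      next
    }
    sq <- semiquant_flow(conv$conc, aif, t_min, mtt_floor_s = mtt_floor_s)
    maps$ktrans[v] <- ft$params$ktrans
    maps$kep[v] <- ft$params$kep
    maps$ve[v] <- ft$params$ve
    maps$vp[v] <- ft$params$vp
    maps$rsq[v] <- ft$rsq
    maps$fp_rbf[v] <- fu$params$fp
    maps$cbv[v] <- sq$cbv
    maps$mtt[v] <- sq$mtt
    maps$rbf_auc[v] <- sq$rbf_auc
  }

  units <- c(ktrans = "1/min", kep = "1/min", ve = "fraction", vp = "fraction",
             fp_rbf = "1/min", rbf_auc = "1/min", cbv = "fraction",
             mtt = "min", rsq = "")
  out <- lapply(names(maps), function(nm) {
    volume_map(maps[[nm]], units = units[[nm]], affine = series$affine,
               name = nm)
  })
  names(out) <- names(maps)
  out$excluded <- mask_voi(excluded, affine = series$affine, label = "brain")
  structure(out, class = "kinetic_maps")
}

#' @export
print.kinetic_maps <- function(x, ...) {
  cat(sprintf("<kinetic_maps> %s grid, %d voxels fitted, %d excluded\n",
              paste(dim(x$ktrans$data), collapse = "x"),
              sum(is.finite(x$ktrans$data)), sum(x$excluded$data)))
  invisible(x)
}
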