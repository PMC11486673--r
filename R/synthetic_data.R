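# Digital reference phantom with known kinetic ground truth.
#
# The phantom emulates a TWIST-like dynamic acquisition over a small head:
# a spherical tumour obeying a chosen forward model, a mirrored contralateral
# "normal white matter" region with near-zero leakage, and an arterial column
# carrying whole-blood signal derived from an analytic AIF. Concentration
# curves are rendered into SPGR signal through the relaxometry forward model,
# optionally with additive Gaussian noise, so the whole analysis chain can be
# validated against ground truth without any clinical data.

#' Tissue kinetic parameters (extended Tofts)
#'
#' @param ktrans volume transfer constant, per minute (>= 0).
#' @param ve extravascular-extracellular volume fraction in [0, 1]; must be
#'   positive whenever `ktrans > 0`.
#' @param vp plasma volume fraction in [0, 1].
#' @return Object of class `tissue_kinetic_params` with derived
#'   `kep = ktrans / ve` (per minute; 0 when `ktrans = 0`).
#' @export
tissue_kinetic_params <- function(ktrans, ve, vp) {
  if (!is_scalar_number(ktrans) || ktrans < 0) stop_input("ktrans must be >= 0")
  if (!is_scalar_number(ve) || ve < 0 || ve > 1) stop_input("ve must be in [0, 1]")
  if (!is_scalar_number(vp) || vp < 0 || vp > 1) stop_input("vp must be in [0, 1]")
  if (ktrans > 0 && ve <= 0) stop_input("ve must be > 0 when ktrans > 0")
  kep <- if (ktrans > 0) ktrans / ve else 0
  structure(list(ktrans = ktrans, ve = ve, vp = vp, kep = kep),
            class = "tissue_kinetic_params")
}

#' Two-compartment uptake kinetic parameters
#'
#' @param fp plasma flow per unit tissue volume, per minute (> 0).
#' @param vp plasma volume fraction in [0, 1] (> 0 so the plasma transit time
#'   is defined).
#' @param ps permeability-surface-area product, per minute (>= 0).
#' @return Object of class `uptake_kinetic_params` with derived extraction
#'   fraction `e = ps / (fp + ps)` and plasma mean transit time
#'   `tp = vp / (fp + ps)` in minutes.
#' @export
uptake_kinetic_params <- function(fp, vp, ps) {
  if (!is_scalar_number(fp) || fp <= 0) stop_input("fp must be > 0")
  if (!is_scalar_number(vp) || vp <= 0 || vp > 1) stop_input("vp must be in (0, 1]")
  if (!is_scalar_number(ps) || ps < 0) stop_input("ps must be >= 0")
  e <- ps / (fp + ps)
  tp <- vp / (fp + ps)
  structure(list(fp = fp, vp = vp, ps = ps, e = e, tp = tp),
            class = "uptake_kinetic_params")
}

# ---------------------------------------------------------------------------
# Analytic arterial input functions

# Parker population AIF constants (mixed-Gaussian + sigmoid-gated washout).
.parker <- list(A = c(0.809, 0.330), T = c(0.17046, 0.365),
                sigma = c(0.0563, 0.132), alpha = 1.050, beta = 0.1685,
                s = 38.078, tau = 0.483)

#' Analytic arterial input function
#'
#' Plasma gadolinium concentration over time from a population model. Two
#' shapes are available: `"parker"` (mixed-Gaussian bolus plus sigmoid-gated
#' exponential washout; the package default and the template for measured-AIF
#' voxel scoring) and `"biexponential"` (Weinmann-type decay convolved with
#' nothing — an instantaneous-bolus form handy for closed-form cross-checks).
#' The curve is identically zero for `t <= bolus_arrival`.
#'
#' @param t time in minutes, nonnegative and increasing.
#' @param model `"parker"` or `"biexponential"`.
#' @param dose_scale multiplicative scale on the whole curve (1 = published
#'   population amplitude; 0 gives an identically zero curve).
#' @param bolus_arrival bolus arrival time in minutes; the curve is 0 at and
#'   before this time. Default 0.
#' @param biexp_params for the biexponential model: list with amplitudes `a`
#'   (mM) and decay rates `m` (per minute), each length 2. Defaults follow
#'   the classical plasma-clearance fit for a 0.1 mmol/kg Gd-DTPA dose.
#' @return numeric vector of plasma concentration in mM, same length as `t`.
#' @export
analytic_aif <- function(t, model = c("parker", "biexponential"),
                         dose_scale = 1, bolus_arrival = 0,
                         biexp_params = list(a = c(3.99, 4.78) * 0.1,
                                             m = c(0.144, 0.0111))) {
  model <- match.arg(model)
  if (any(t < 0)) stop_input("t must be nonnegative")
  if (length(t) > 1 && any(diff(t) <= 0)) stop_input("t must be increasing")
  ts <- t - bolus_arrival
  cp <- numeric(length(t))
  on <- ts > 0
  if (any(on)) {
    u <- ts[on]
    cp[on] <- if (model == "parker") {
      p <- .parker
      g <- p$A[1] / (p$sigma[1] * sqrt(2 * pi)) *
             exp(-(u - p$T[1])^2 / (2 * p$sigma[1]^2)) +
           p$A[2] / (p$sigma[2] * sqrt(2 * pi)) *
             exp(-(u - p$T[2])^2 / (2 * p$sigma[2]^2))
      g + p$alpha * exp(-p$beta * u) / (1 + exp(-p$s * (u - p$tau)))
    } else {
      biexp_params$a[1] * exp(-biexp_params$m[1] * u) +
        biexp_params$a[2] * exp(-biexp_params$m[2] * u)
    }
  }
  dose_scale * cp
}

# ---------------------------------------------------------------------------
# Forward models

#' Extended Tofts forward model
#'
#' Tissue concentration
#' `Ct(t) = vp * Cp(t) + Ktrans * int_0^t Cp(u) exp(-kep (t - u)) du`,
#' with the convolution evaluated by trapezoidal quadrature on the sample
#' grid (which may be nonuniform).
#'
#' @param params a [tissue_kinetic_params()].
#' @param cp plasma concentration curve in mM, same length as `t`.
#' @param t time in minutes.
#' @return tissue concentration Ct(t) in mM.
#' @export
forward_tofts <- function(params, cp, t) {
  if (length(cp) != length(t)) stop_input("cp and t must have equal length")
  ct <- params$vp * cp
  if (params$ktrans > 0) {
    kep <- params$kep
    ct <- ct + params$ktrans * kernel_conv(cp, t, function(s) exp(-kep * s))
  }
  ct
}

#' Two-compartment uptake forward model
#'
#' Tissue concentration `Ct = Fp * (R conv Cp)` with impulse residue
#' `R(s) = E + (1 - E) exp(-s / Tp)`, where `E = PS / (Fp + PS)` is the
#' extraction fraction and `Tp = vp / (Fp + PS)` the plasma mean transit
#' time. Backflux from the interstitium is neglected (uptake regime).
#'
#' @param params an [uptake_kinetic_params()].
#' @param cp plasma concentration curve in mM.
#' @param t time in minutes.
#' @return tissue concentration Ct(t) in mM.
#' @export
forward_2cu <- function(params, cp, t) {
  if (length(cp) != length(t)) stop_input("cp and t must have equal length")
  e <- params$e; tp <- params$tp
  params$fp * kernel_conv(cp, t, function(s) e + (1 - e) * exp(-s / tp))
}

# Fast variants for the fitting hot path: grid precomputed once per voxel set.
forward_tofts_grid <- function(ktrans, ve, vp, cp, grid) {
  ct <- vp * cp
  if (ktrans > 0) {
    kep <- ktrans / ve
    ct <- ct + ktrans * kernel_conv_fast(cp, grid, function(s) exp(-kep * s))
  }
  ct
}

forward_2cu_grid <- function(fp, vp, ps, cp, grid) {
  e <- ps / (fp + ps)
  tp <- vp / (fp + ps)
  fp * kernel_conv_fast(cp, grid, function(s) e + (1 - e) * exp(-s / tp))
}

# ---------------------------------------------------------------------------
# Phantom configuration and generation

#' Digital phantom configuration
#'
#' Defines the geometry, ground-truth kinetics, relaxometry and acquisition
#' settings of the synthetic head phantom. Defaults mimic a TWIST-like
#' 3 T acquisition: TR 4.83 ms, TE 1.87 ms, flip 12 degrees, 70 frames at
#' 5 s spacing with the bolus arriving at frame 3, 1.4 x 1.4 x 3 mm voxels.
#'
#' Regions: a spherical tumour in the right hemisphere, its mirror-image
#' contralateral control sphere (near-zero leakage, white-matter T1), and a
#' rectangular arterial column. Regions must be disjoint; the brain mask is
#' their union.
#'
#' @param dims grid size, length 3. Default `c(32, 32, 8)`.
#' @param tumour_centre,tumour_radius sphere centre (1-based voxel coords)
#'   and radius in voxels. The control sphere is the left-right mirror.
#' @param artery_corner,artery_size corner (1-based) and size of the arterial
#'   box. Default a 2 x 2 column spanning all slices.
#' @param tumour_params kinetics of the tumour region: a
#'   [tissue_kinetic_params()] (extended Tofts rendering) or an
#'   [uptake_kinetic_params()] (two-compartment uptake rendering).
#' @param control_params kinetics of the contralateral control region.
#' @param t10_ms named list of pre-contrast T1 values in ms for `tumour`,
#'   `control`, `blood`.
#' @param m0 equilibrium signal scale, shared by all regions.
#' @param r1 contrast agent relaxivity in /s/mM.
#' @param hct haematocrit; artery voxels carry whole-blood concentration
#'   `(1 - hct) * Cp`.
#' @param aif_model,dose_scale passed to [analytic_aif()].
#' @param n_frames,frame_spacing number of frames and spacing in seconds.
#' @param bolus_frame frame index (1-based) at which the bolus arrives; the
#'   frames before it are baseline.
#' @param tr,te,flip_angle acquisition parameters (ms, ms, degrees).
#' @param voxel_size_mm voxel edge lengths in mm.
#' @param sigma noise standard deviation as a fraction of each voxel's
#'   baseline signal; 0 disables noise.
#' @param seed RNG seed; mandatory when `sigma > 0`.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(dims = c(32, 32, 8),
                           tumour_centre = c(24, 16, 4), tumour_radius = 3.6,
                           artery_corner = c(15, 5, 1), artery_size = c(2, 2, 8),
                           tumour_params = tissue_kinetic_params(0.25, 0.4, 0.05),
                           control_params = tissue_kinetic_params(0.002, 0.2, 0.01),
                           t10_ms = list(tumour = 1400, control = 1100, blood = 1664),
                           m0 = 1000, r1 = 3.7, hct = 0.45,
                           aif_model = "parker", dose_scale = 1,
                           n_frames = 70, frame_spacing = 5, bolus_frame = 3,
                           tr = 4.83, te = 1.87, flip_angle = 12,
                           voxel_size_mm = c(1.4, 1.4, 3),
                           sigma = 0.05, seed = 1234) {
  if (sigma > 0 && (is.null(seed) || is.na(seed))) {
    stop_input("a seed is mandatory when sigma > 0")
  }
  cfg <- structure(list(dims = dims, tumour_centre = tumour_centre,
                        tumour_radius = tumour_radius,
                        artery_corner = artery_corner, artery_size = artery_size,
                        tumour_params = tumour_params,
                        control_params = control_params,
                        t10_ms = t10_ms, m0 = m0, r1 = r1, hct = hct,
                        aif_model = aif_model, dose_scale = dose_scale,
                        n_frames = n_frames, frame_spacing = frame_spacing,
                        bolus_frame = bolus_frame, tr = tr, te = te,
                        flip_angle = flip_angle, voxel_size_mm = voxel_size_mm,
                        sigma = sigma, seed = seed),
                   class = "phantom_config")
  geom <- phantom_geometry(cfg)  # validates disjointness
  cfg
}

# Region index sets (linear voxel indices) for a phantom config.
phantom_geometry <- function(cfg) {
  d <- cfg$dims
  ijk <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  sphere <- function(centre, radius) {
    which(colSums((t(ijk) - centre)^2) <= radius^2)
  }
  tum <- sphere(cfg$tumour_centre, cfg$tumour_radius)
  mirror_centre <- cfg$tumour_centre
  mirror_centre[1] <- d[1] + 1 - mirror_centre[1]
  ctl <- sphere(mirror_centre, cfg$tumour_radius)
  a0 <- cfg$artery_corner; a1 <- a0 + cfg$artery_size - 1
  art <- which(ijk[, 1] >= a0[1] & ijk[, 1] <= a1[1] &
               ijk[, 2] >= a0[2] & ijk[, 2] <= a1[2] &
               ijk[, 3] >= a0[3] & ijk[, 3] <= a1[3])
  if (length(intersect(tum, ctl)) || length(intersect(tum, art)) ||
      length(intersect(ctl, art))) {
    stop_input("phantom regions overlap; adjust geometry")
  }
  if (!length(tum) || !length(ctl) || !length(art)) {
    stop_input("every phantom region must contain at least one voxel")
  }
  list(tumour = tum, control = ctl, artery = art)
}

phantom_frame_times <- function(cfg) (seq_len(cfg$n_frames) - 1) * cfg$frame_spacing

#' Generate a digital phantom
#'
#' Renders the configured regions into a noisy (or noiseless) SPGR dynamic
#' series, together with the ground-truth T1 map, ground-truth kinetic maps,
#' and the region masks. Tissue regions follow their configured forward model
#' (extended Tofts or two-compartment uptake); artery voxels carry the
#' whole-blood concentration `(1 - hct) * Cp(t)` so that the measured-AIF
#' path, including the haematocrit correction, can be exercised end to end.
#'
#' @param cfg a [phantom_config()].
#' @return list with components `series` ([dce_series()]), `t10`
#'   ([volume_map()], ms), `truth` (list of ground-truth [volume_map()]s:
#'   `ktrans`, `ve`, `vp`, `kep`, `fp`, `ps`, NaN outside the regions each
#'   applies to), `masks` (list of [mask_voi()]: `tumour`, `control`,
#'   `artery`, `brain`), `aif` (the true plasma AIF as an [aif_curve()]) and
#'   `config`.
#' @export
generate_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  geom <- phantom_geometry(cfg)
  d <- cfg$dims
  t_s <- phantom_frame_times(cfg)
  bolus_min <- t_s[cfg$bolus_frame] / 60
  t_min <- t_s / 60
  cp <- analytic_aif(t_min, model = cfg$aif_model, dose_scale = cfg$dose_scale,
                     bolus_arrival = bolus_min)

  region_ct <- function(params) {
    if (inherits(params, "tissue_kinetic_params")) forward_tofts(params, cp, t_min)
    else forward_2cu(params, cp, t_min)
  }
  curves <- list(tumour = region_ct(cfg$tumour_params),
                 control = region_ct(cfg$control_params),
                 artery = (1 - cfg$hct) * cp)
  t10s <- c(tumour = cfg$t10_ms$tumour, control = cfg$t10_ms$control,
            artery = cfg$t10_ms$blood)

  affine <- diag(c(cfg$voxel_size_mm, 1))
  nt <- length(t_s)
  sig <- array(0, dim = c(d, nt))
  t10 <- array(NaN, dim = d)
  nvox <- prod(d)

  for (rg in names(curves)) {
    # concentration -> per-frame T1 -> SPGR signal (relaxometry forward ops)
    t1_ms <- concentration_to_t1(curves[[rg]], t10s[[rg]], cfg$r1)
    s <- spgr_signal(cfg$m0, t1_ms, cfg$tr, cfg$flip_angle)
    for (f in seq_len(nt)) sig[geom[[rg]] + (f - 1) * nvox] <- s[f]
    t10[geom[[rg]]] <- t10s[[rg]]
  }

  if (cfg$sigma > 0) {
    set.seed(cfg$seed)
    base <- apply(sig[, , , seq_len(max(cfg$bolus_frame - 1, 1)), drop = FALSE],
                  1:3, mean)
    noise <- array(stats::rnorm(length(sig)), dim = dim(sig))
    sig <- sig + noise * as.vector(base) * cfg$sigma
  }

  truth <- list()
  blank <- array(NaN, dim = d)
  fill <- function(vals) {      # vals: named per-region values (NA = skip)
    m <- blank
    for (rg in names(vals)) if (!is.na(vals[[rg]])) m[geom[[rg]]] <- vals[[rg]]
    m
  }
  pt <- cfg$tumour_params; pc <- cfg$control_params
  pval <- function(p, field) if (!is.null(p[[field]])) p[[field]] else NA_real_
  for (field in c("ktrans", "ve", "vp", "kep", "fp", "ps")) {
    truth[[field]] <- volume_map(
      fill(list(tumour = pval(pt, field), control = pval(pc, field))),
      units = if (field %in% c("ve", "vp")) "fraction" else "1/min",
      affine = affine, name = field)
  }

  masks <- list()
  for (rg in c("tumour", "control", "artery")) {
    m <- array(0, dim = d); m[geom[[rg]]] <- 1
    masks[[rg]] <- mask_voi(m, affine = affine,
                            label = if (rg == "tumour") "tumour" else rg)
  }
  brain <- array(0, dim = d)
  brain[unlist(geom)] <- 1
  masks$brain <- mask_voi(brain, affine = affine, label = "brain")

  series <- dce_series(sig, frame_times = t_s, tr = cfg$tr, te = cfg$te,
                       flip_angle = cfg$flip_angle,
                       voxel_size = cfg$voxel_size_mm, affine = affine)
  aif <- aif_curve(t = t_min, cp = cp, source = "analytic")
  list(series = series,
       t10 = volume_map(t10, units = "ms", affine = affine, name = "T1"),
       truth = truth, masks = masks, aif = aif, config = cfg)
}
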