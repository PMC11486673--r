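# SPGR relaxometry: variable-flip-angle T1 estimation and bidirectional
# signal <-> gadolinium concentration conversion with baseline-T1 correction.
#
# Unit conventions: T1 and TR in ms everywhere in this file; relaxivity r1 in
# /s/mM, so rate arithmetic converts ms -> s (1/T1[s] = 1000/T1[ms]).

#' Relaxation state of a voxel or region
#'
#' @param t10 pre-contrast T1 in ms (> 0).
#' @param m0 equilibrium signal scale, arbitrary units (> 0).
#' @param r1 longitudinal relaxivity of the contrast agent in /s/mM (> 0).
#'   Default 3.7, a typical value for gadopentetate dimeglumine at 3 T.
#' @return Object of class `relaxation_state`.
#' @export
relaxation_state <- function(t10, m0, r1 = 3.7) {
  if (!is_scalar_number(t10) || t10 <= 0) stop_input("t10 must be > 0 (ms)")
  if (!is_scalar_number(m0) || m0 <= 0) stop_input("m0 must be > 0")
  if (!is_scalar_number(r1) || r1 <= 0) stop_input("r1 must be > 0 (/s/mM)")
  structure(list(t10 = t10, m0 = m0, r1 = r1), class = "relaxation_state")
}

#' Spoiled gradient-echo steady-state signal
#'
#' `S = m0 sin(a) (1 - E1) / (1 - E1 cos(a))` with `E1 = exp(-TR/T1)`.
#'
#' @param m0 equilibrium signal scale.
#' @param t1 longitudinal relaxation time in ms (vectorised).
#' @param tr repetition time in ms.
#' @param flip flip angle in degrees, in (0, 90].
#' @return signal, same length as `t1`.
#' @export
spgr_signal <- function(m0, t1, tr, flip) {
  if (any(t1 <= 0, na.rm = TRUE)) stop_input("t1 must be > 0")
  a <- flip * pi / 180
  e1 <- exp(-tr / t1)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

# Gadolinium concentration -> T1 (ms): 1/T1 = 1/T10 + r1*C with rates in /s.
concentration_to_t1 <- function(conc, t10_ms, r1) {
  1000 / (1000 / t10_ms + r1 * conc)
}

#' Variable-flip-angle T1 estimation (linearised DESPOT1)
#'
#' Regresses `S/sin(a)` on `S/tan(a)` across flip angles; the slope is
#' `E1 = exp(-TR/T1)` and the intercept `m0 (1 - E1)`.
#'
#' @param signals SPGR signal at each flip angle.
#' @param flips flip angles in degrees (>= 2 distinct values).
#' @param tr repetition time in ms.
#' @return list with `t10` (ms), `m0`, and `ok` (`FALSE` with `NaN` estimates
#'   when the data are degenerate or the slope is nonphysical, i.e. outside
#'   (0, 1)).
#' @export
fit_t1_vfa <- function(signals, flips, tr) {
  if (length(signals) != length(flips)) {
    stop_input("signals and flips must have equal length")
  }
  if (length(unique(flips)) < 2) {
    stop_estimation("need >= 2 distinct flip angles")
  }
  # flat data (identical signal at every angle) is treated as unidentifiable:
  # it arises from saturated or noise-floor voxels, not from a usable decay
  if (stats::sd(signals) == 0) {
    return(list(t10 = NaN, m0 = NaN, ok = FALSE))
  }
  a <- flips * pi / 180
  y <- signals / sin(a)
  x <- signals / tan(a)
  if (stats::sd(x) < .Machine$double.eps * max(abs(x), 1)) {
    return(list(t10 = NaN, m0 = NaN, ok = FALSE))
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  e1 <- fit$coefficients[2]
  b0 <- fit$coefficients[1]
  if (!is.finite(e1) || e1 <= 0 || e1 >= 1) {
    return(list(t10 = NaN, m0 = NaN, ok = FALSE))
  }
  list(t10 = unname(-tr / log(e1)), m0 = unname(b0 / (1 - e1)), ok = TRUE)
}

#' Convert a dynamic SPGR signal curve to gadolinium concentration
#'
#' Baseline-T1-corrected conversion: the pre-bolus frames give the baseline
#' signal `S0`; together with the measured pre-contrast `t10` they fix the
#' effective `m0` for the voxel. Each frame's signal is then inverted through
#' the SPGR equation to `T1(t)` and converted to concentration via
#' `C(t) = (1/T1(t) - 1/T10) / r1` (rates in /s). Frames whose signal lies
#' outside the invertible range of the model become `NaN`. Negative
#' concentrations (zero-mean noise at pre-bolus frames) are retained, not
#' clamped, so that downstream fits stay unbiased.
#'
#' @param s_t dynamic signal curve for one voxel.
#' @param baseline_frames number of leading frames treated as pre-contrast
#'   baseline (>= 1).
#' @param state a [relaxation_state()] with the voxel's `t10`, `r1` (`m0` is
#'   re-derived from the baseline, so only its positivity matters).
#' @param tr repetition time in ms.
#' @param flip flip angle in degrees.
#' @return list with `conc` (mM, `NaN` where inversion is infeasible),
#'   `t1_ms` (per-frame T1), `s0` (baseline signal) and `excluded` (`TRUE`
#'   when no frame could be converted).
#' @export
signal_to_concentration <- function(s_t, baseline_frames, state, tr, flip) {
  if (baseline_frames < 1) stop_input("baseline_frames must be >= 1")
  s0 <- mean(s_t[seq_len(baseline_frames)])
  if (!is.finite(s0) || s0 <= 0) {
    return(list(conc = rep(NaN, length(s_t)), t1_ms = rep(NaN, length(s_t)),
                s0 = s0, excluded = TRUE))
  }
  a <- flip * pi / 180
  e10 <- exp(-tr / state$t10)
  # effective m0 from the baseline signal and the known pre-contrast T1
  m0 <- s0 * (1 - e10 * cos(a)) / (sin(a) * (1 - e10))
  # invert S = m0 sin(a)(1-E1)/(1-E1 cos(a))  =>  E1 = (ms - S)/(ms c - S c)
  ms <- m0 * sin(a)
  e1 <- (ms - s_t) / (ms - s_t * cos(a))
  feasible <- is.finite(e1) & e1 > 0 & e1 < 1
  t1 <- rep(NaN, length(s_t))
  t1[feasible] <- -tr / log(e1[feasible])
  conc <- (1000 / t1 - 1000 / state$t10) / state$r1
  list(conc = conc, t1_ms = t1, s0 = s0, excluded = !any(is.finite(conc)))
}
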