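# Measured arterial input function: candidate-voxel scoring inside an artery
# mask, top-k averaging, and whole-blood -> plasma conversion.
#
# A fixed population AIF is deliberately not offered as a default substitute
# for measurement: inter-individual AIF variation is large, so the measured
# route is primary and the analytic curve serves as scoring template and
# phantom ground truth.

#' Arterial input function curve
#'
#' @param t time in minutes.
#' @param cp plasma concentration in mM, finite, same length as `t`.
#' @param source `"measured"` or `"analytic"`.
#' @param n_voxels_used number of artery voxels averaged (measured AIFs).
#' @param quality mean shape score of the selected voxels (measured AIFs).
#' @return Object of class `aif_curve`.
#' @export
aif_curve <- function(t, cp, source = c("measured", "analytic"),
                      n_voxels_used = NA_integer_, quality = NA_real_) {
  source <- match.arg(source)
  if (length(t) != length(cp)) stop_input("t and cp must have equal length")
  if (any(!is.finite(cp))) stop_input("cp must be finite")
  if (source == "measured" && (is.na(n_voxels_used) || n_voxels_used < 1)) {
    stop_input("a measured AIF needs n_voxels_used >= 1")
  }
  structure(list(t = as.numeric(t), cp = as.numeric(cp), source = source,
                 n_voxels_used = n_voxels_used, quality = quality),
            class = "aif_curve")
}

#' @export
print.aif_curve <- function(x, ...) {
  cat(sprintf("<aif_curve %s> %d samples, peak %.3g mM at %.2f min",
              x$source, length(x$t), max(x$cp), x$t[which.max(x$cp)]))
  if (x$source == "measured") {
    cat(sprintf(" (%d voxels, quality %.3f)", x$n_voxels_used, x$quality))
  }
  cat("\n")
  invisible(x)
}

#' Score arterial candidate voxels against a canonical AIF shape
#'
#' Each candidate concentration curve is scored as a weighted sum of (i) its
#' Pearson correlation with the template (shape, scale-invariant) and (ii)
#' its peak amplitude normalised by the largest candidate peak (so
#' partial-volume voxels with the right shape but depressed amplitude rank
#' below full-blood voxels). Flat curves score 0 on both components.
#'
#' @param conc_series matrix of candidate curves, one row per voxel
#'   (columns = frames).
#' @param template canonical AIF shape on the same frame grid (defaults used
#'   by callers: the analytic Parker curve).
#' @param w_cor,w_peak weights of the two components; default 0.7 / 0.3.
#' @return data frame with `voxel` (row index into `conc_series`), `score`,
#'   `cor` and `peak`, sorted by decreasing score with ties broken by
#'   ascending voxel index.
#' @export
score_aif_candidates <- function(conc_series, template,
                                 w_cor = 0.7, w_peak = 0.3) {
  if (is.null(dim(conc_series))) conc_series <- matrix(conc_series, nrow = 1)
  if (nrow(conc_series) < 1) stop_input("artery mask contains no voxels")
  if (ncol(conc_series) != length(template)) {
    stop_input("candidate curves and template differ in length")
  }
  n <- nrow(conc_series)
  cors <- numeric(n); peaks <- numeric(n)
  for (i in seq_len(n)) {
    cu <- conc_series[i, ]
    ok <- is.finite(cu)
    cors[i] <- if (sum(ok) > 2 && stats::sd(cu[ok]) > 0 && stats::sd(template[ok]) > 0) {
      stats::cor(cu[ok], template[ok])
    } else 0
    peaks[i] <- if (any(ok)) max(cu[ok], 0) else 0
  }
  peak_norm <- if (max(peaks) > 0) peaks / max(peaks) else peaks
  score <- w_cor * cors + w_peak * peak_norm
  out <- data.frame(voxel = seq_len(n), score = score, cor = cors, peak = peaks)
  out[order(-out$score, out$voxel), , drop = FALSE]
}

#' Extract a measured whole-blood AIF from an artery mask
#'
#' Scores every voxel of the artery mask with [score_aif_candidates()] and
#' averages the concentration curves of the `k` best-scoring voxels. The
#' result is a whole-blood curve; apply [blood_to_plasma()] before kinetic
#' modelling.
#'
#' @param conc_series matrix of per-voxel concentration curves (rows =
#'   voxels of the artery mask, in mask order; columns = frames).
#' @param t time in minutes, length = columns of `conc_series`.
#' @param k number of voxels to average. Clinical practice selects roughly
#'   5-15; default 10.
#' @param template canonical AIF shape; default the analytic Parker curve on
#'   the subject's frame grid (with no arrival shift applied, since measured
#'   curves carry their own delay and correlation is shift-sensitive only
#'   through shape).
#' @param w_cor,w_peak scoring weights, see [score_aif_candidates()].
#' @return An [aif_curve()] with `source = "measured"`; `cp` holds the
#'   whole-blood concentration, `quality` the mean score of the selected
#'   voxels.
#' @export
extract_aif <- function(conc_series, t, k = 10, template = NULL,
                        w_cor = 0.7, w_peak = 0.3) {
  if (is.null(dim(conc_series))) conc_series <- matrix(conc_series, nrow = 1)
  n <- nrow(conc_series)
  if (k > n) {
    stop_input("k = ", k, " voxels requested but the artery mask has only ",
               n, " voxels")
  }
  if (is.null(template)) template <- analytic_aif(t, model = "parker")
  ranked <- score_aif_candidates(conc_series, template,
                                 w_cor = w_cor, w_peak = w_peak)
  top <- ranked$voxel[seq_len(k)]
  cb <- colMeans(conc_series[top, , drop = FALSE])
  cb[!is.finite(cb)] <- 0
  aif_curve(t = t, cp = cb, source = "measured", n_voxels_used = k,
            quality = mean(ranked$score[seq_len(k)]))
}

#' Convert whole-blood to plasma concentration
#'
#' `Cp = Cb / ((1 - hct) * pv_factor)`: haematocrit correction (contrast
#' stays in plasma) plus a scalar partial-volume factor for vessels smaller
#' than a voxel.
#'
#' @param cb whole-blood concentration curve (numeric vector or
#'   [aif_curve()]).
#' @param hct haematocrit fraction in [0, 1). Default 0.45.
#' @param pv_factor partial-volume scale (> 0); 1 = no correction.
#' @return Same type as `cb`, converted to plasma concentration.
#' @export
blood_to_plasma <- function(cb, hct = 0.45, pv_factor = 1) {
  if (!is_scalar_number(hct) || hct < 0 || hct >= 1) {
    stop_input("hct must be in [0, 1)")
  }
  if (!is_scalar_number(pv_factor) || pv_factor <= 0) {
    stop_input("pv_factor must be > 0")
  }
  scale <- 1 / ((1 - hct) * pv_factor)
  if (inherits(cb, "aif_curve")) {
    cb$cp <- cb$cp * scale
    cb
  } else {
    cb * scale
  }
}

#' Write an AIF curve to CSV
#'
#' Two data columns (`time_s`, `cp_mM`) preceded by `#`-prefixed metadata
#' header lines (source, voxel count, quality score).
#'
#' @param aif an [aif_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_aif_csv <- function(aif, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# source: %s", aif$source),
               sprintf("# n_voxels_used: %s", aif$n_voxels_used),
               sprintf("# quality: %s", format(aif$quality, digits = 6)),
               "time_s,cp_mM"), con)
  utils::write.table(data.frame(time_s = aif$t * 60, cp_mM = aif$cp), con,
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an AIF curve written by [write_aif_csv()]
#'
#' @param path CSV path.
#' @return An [aif_curve()].
#' @export
read_aif_csv <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get <- function(key) {
    hit <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (!length(hit)) return(NA)
    trimws(sub(paste0("^# ", key, ":"), "", hit[1]))
  }
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  src <- get("source"); if (is.na(src)) src <- "measured"
  nv <- suppressWarnings(as.integer(get("n_voxels_used")))
  qu <- suppressWarnings(as.numeric(get("quality")))
  aif_curve(t = df$time_s / 60, cp = df$cp_mM, source = src,
            n_voxels_used = if (src == "measured") nv else NA_integer_,
            quality = qu)
}
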