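# VOI summarisation and the group-level statistical report.
#
# Per-subject summaries average parametric maps over the contrast-enhancing
# tumour VOI and a mirrored contralateral control VOI, skipping excluded
# (zero-signal / failed-fit) voxels; the report then runs the paired and
# unpaired exact tests and the volume correlations over the cohort table.

#' Mean of a parametric map over a VOI
#'
#' Averages map values over the mask, skipping voxels that are in the
#' exclusion mask or non-finite in the map. Counts of used and excluded
#' voxels are reported so summaries stay auditable.
#'
#' @param map a [volume_map()].
#' @param mask a [mask_voi()] on the same grid.
#' @param excluded optional exclusion [mask_voi()] (e.g. from
#'   [compute_parameter_maps()]).
#' @return list with `mean` (`NaN`, with a warning, if no voxel is usable),
#'   `n_used` and `n_excluded`.
#' @export
voi_mean <- function(map, mask, excluded = NULL) {
  if (!all(dim(map$data) == dim(mask$data))) {
    stop_input("map and mask must share one grid")
  }
  sel <- mask$data > 0
  if (!any(sel)) stop_input("mask is empty")
  drop <- !is.finite(map$data)
  if (!is.null(excluded)) drop <- drop | excluded$data > 0
  use <- sel & !drop
  n_used <- sum(use)
  n_excluded <- sum(sel & drop)
  if (n_used == 0) {
    warning("no usable voxels in VOI '", mask$label, "'; mean is NaN")
    return(list(mean = NaN, n_used = 0L, n_excluded = n_excluded))
  }
  list(mean = mean(map$data[use]), n_used = n_used, n_excluded = n_excluded)
}

#' Mirror a tumour VOI to the contralateral hemisphere
#'
#' Reflects the tumour mask across the midline plane, intersects with the
#' brain mask, and — if the reflected region lost more than 10% of the
#' tumour's voxel count (e.g. because it fell partly outside the brain) —
#' grows it by deterministic 6-neighbour dilation inside the brain until the
#' counts match. A tumour crossing the midline triggers a warning and the
#' overlapping part is removed from the control.
#'
#' @param tumour_mask,brain_mask [mask_voi()]s on one grid.
#' @param axis reflection axis (1 = left-right). Default 1.
#' @param midline voxel coordinate (1-based) of the midline plane; default
#'   the grid centre `(dim + 1) / 2`.
#' @return A control [mask_voi()] with label `"control"`.
#' @export
mirror_control_voi <- function(tumour_mask, brain_mask, axis = 1,
                               midline = NULL) {
  d <- dim(tumour_mask$data)
  if (!all(d == dim(brain_mask$data))) stop_input("masks must share one grid")
  if (is.null(midline)) midline <- (d[axis] + 1) / 2
  idx <- which(tumour_mask$data > 0, arr.ind = TRUE)
  n_t <- nrow(idx)
  if (!n_t) stop_input("tumour mask is empty")
  ref <- idx
  ref[, axis] <- round(2 * midline - ref[, axis])
  inside <- ref[, axis] >= 1 & ref[, axis] <= d[axis]
  ref <- ref[inside, , drop = FALSE]
  ctl <- array(0, dim = d)
  ctl[ref] <- 1
  ctl <- ctl * (brain_mask$data > 0)
  overlap <- ctl > 0 & tumour_mask$data > 0
  if (any(overlap)) {
    warning("tumour crosses the midline; control taken from the ",
            "non-overlapping reflected part")
    ctl[overlap] <- 0
  }
  if (sum(ctl) == 0) {
    stop_input("reflected tumour lies entirely outside the brain mask; ",
               "supply a manual control mask")
  }
  if (sum(ctl) < 0.9 * n_t) {
    ctl <- dilate_to_count(ctl, brain_mask$data > 0 & !(tumour_mask$data > 0),
                           n_t)
  }
  mask_voi(ctl, affine = tumour_mask$affine, label = "control")
}

# Deterministic 6-neighbour dilation of `core` within `allowed` until `target`
# voxels are reached (or growth stalls); voxels added in a given round are
# taken in ascending linear-index order, excess trimmed.
dilate_to_count <- function(core, allowed, target) {
  d <- dim(core)
  current <- which(core > 0)
  repeat {
    if (length(current) >= target) break
    cand <- integer(0)
    ai <- which(core > 0, arr.ind = TRUE)
    for (shift in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                       c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      nb <- sweep(ai, 2, shift, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- (nb[, 3] - 1) * d[1] * d[2] + (nb[, 2] - 1) * d[1] + nb[, 1]
      cand <- c(cand, lin)
    }
    cand <- sort(unique(cand))
    cand <- cand[allowed[cand] & core[cand] == 0]
    if (!length(cand)) break  # growth stalled
    need <- target - length(current)
    take <- cand[seq_len(min(need, length(cand)))]
    core[take] <- 1
    current <- which(core > 0)
  }
  core
}

#' Mean signal enhancement curve over a VOI
#'
#' Mean mask signal per frame as percent enhancement over the pre-bolus
#' baseline: `100 (S(t) - S0) / S0`.
#'
#' @param series a [dce_series()].
#' @param mask a [mask_voi()] on the series grid.
#' @param baseline_frames leading frames defining `S0` (>= 1).
#' @return data frame with `time_s` and `enhancement_pct`.
#' @export
enhancement_curve <- function(series, mask, baseline_frames = 2) {
  d <- dim(series$data)
  if (!all(d[1:3] == dim(mask$data))) stop_input("series and mask grids differ")
  sel <- which(mask$data > 0)
  if (!length(sel)) stop_input("mask is empty")
  nvox <- prod(d[1:3])
  s <- vapply(seq_len(d[4]),
              function(f) mean(series$data[sel + (f - 1) * nvox]),
              numeric(1))
  s0 <- mean(s[seq_len(baseline_frames)])
  if (!is.finite(s0) || s0 <= 0) stop_input("baseline signal is nonpositive")
  data.frame(time_s = series$frame_times, enhancement_pct = 100 * (s - s0) / s0)
}

#' Build a per-subject VOI summary row
#'
#' @param subject subject identifier.
#' @param group `"meningioma"` or `"other"`.
#' @param voi_label VOI name (e.g. `"tumour"`, `"control"`).
#' @param maps a `kinetic_maps` object from [compute_parameter_maps()].
#' @param mask the VOI [mask_voi()].
#' @param rbf_estimator which flow map feeds the summary: the model-based
#'   `"fp"` (default) or the semiquantitative `"auc"`.
#' @return one-row data frame with the VOI-summary columns (`voi_volume` in
#'   mm^3 from the mask affine).
#' @export
summarise_voi <- function(subject, group, voi_label, maps, mask,
                          rbf_estimator = c("fp", "auc")) {
  rbf_estimator <- match.arg(rbf_estimator)
  rbf_map <- if (rbf_estimator == "fp") maps$fp_rbf else maps$rbf_auc
  mk <- voi_mean(maps$ktrans, mask, maps$excluded)
  mr <- voi_mean(rbf_map, mask, maps$excluded)
  vol_mm3 <- sum(mask$data > 0) * abs(det(mask$affine[1:3, 1:3]))
  data.frame(subject = subject, group = group, voi_label = voi_label,
             n_voxels = sum(mask$data > 0),
             n_excluded = mk$n_excluded,
             mean_ktrans = mk$mean, mean_rbf = mr$mean,
             voi_volume = vol_mm3, stringsAsFactors = FALSE)
}

#' Cohort-level group comparison report
#'
#' Runs the study's statistical battery over a per-subject VOI summary
#' table: (i) exact paired Wilcoxon signed-rank tests of control vs tumour
#' Ktrans and rBF within the meningioma group (differences taken as
#' control - tumour), (ii) exact Mann-Whitney tests of tumour Ktrans and rBF
#' between the meningioma and other groups, and (iii) Pearson correlations
#' of each parameter against tumour VOI volume within the meningioma group
#' (when volumes are available for >= 3 subjects). Tests whose group sizes
#' are insufficient are skipped with a warning, never a failure.
#'
#' Rendered p-values are rounded half-up to 4 decimals and medians to 3;
#' full precision is kept in the returned objects and the CSV.
#'
#' @param summaries data frame of VOI summaries (columns `subject`, `group`,
#'   `voi_label`, `mean_ktrans`, `mean_rbf`, optionally `voi_volume`).
#' @param sidedness `"two"` (default) or `"one"`, passed to every test.
#' @return Object of class `group_report`: list with `comparisons` (named
#'   [group_comparison()]s), `table` (tidy data frame, one row per test) and
#'   `text` (plain-text rendering). Row order of `summaries` does not affect
#'   the result.
#' @export
group_comparison_report <- function(summaries, sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  s <- summaries[order(summaries$subject, summaries$voi_label), , drop = FALSE]
  men_t <- s[s$group == "meningioma" & s$voi_label == "tumour", ]
  men_c <- s[s$group == "meningioma" & s$voi_label == "control", ]
  oth_t <- s[s$group == "other" & s$voi_label == "tumour", ]

  comparisons <- list()
  rows <- list()
  add <- function(name, parameter, cmp) {
    comparisons[[name]] <<- cmp
    est <- unlist(cmp$estimate)
    rows[[name]] <<- data.frame(
      test = cmp$test, parameter = parameter,
      statistic = unname(cmp$statistic[1]),
      estimate = unname(est[1]),
      estimate_rendered = paste(sprintf("%.3f", round_half_up(est, 3)),
                                collapse = " / "),
      p_value = cmp$p_value,
      p_rendered = sprintf("%.4f", round_half_up(cmp$p_value, 4)),
      sidedness = cmp$sidedness,
      n = paste(cmp$n, collapse = "+"), stringsAsFactors = FALSE)
  }

  paired <- merge(men_c, men_t, by = "subject",
                  suffixes = c("_control", "_tumour"))
  for (par in c("ktrans", "rbf")) {
    col <- paste0("mean_", par)
    if (nrow(paired) >= 2) {
      add(paste0("wilcoxon_", par), par,
          wilcoxon_signed_rank_exact(paired[[paste0(col, "_control")]],
                                     paired[[paste0(col, "_tumour")]],
                                     sidedness = sidedness))
    } else {
      warning("paired Wilcoxon (", par, ") skipped: need >= 2 paired ",
              "meningioma subjects")
    }
    if (nrow(men_t) >= 1 && nrow(oth_t) >= 1) {
      add(paste0("mann_whitney_", par), par,
          mann_whitney_exact(men_t[[col]], oth_t[[col]],
                             sidedness = sidedness))
    } else {
      warning("Mann-Whitney (", par, ") skipped: both groups must be nonempty")
    }
    if ("voi_volume" %in% names(men_t)) {
      okv <- is.finite(men_t$voi_volume) & is.finite(men_t[[col]])
      if (sum(okv) >= 3 && stats::sd(men_t$voi_volume[okv]) > 0 &&
          stats::sd(men_t[[col]][okv]) > 0) {
        add(paste0("pearson_", par, "_volume"), par,
            pearson_correlation(men_t$voi_volume[okv], men_t[[col]][okv],
                                sidedness = sidedness))
      }
    }
  }

  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(test = character(0), parameter = character(0),
               statistic = numeric(0), estimate = numeric(0),
               estimate_rendered = character(0), p_value = numeric(0),
               p_rendered = character(0), sidedness = character(0),
               n = character(0))
  rownames(table) <- NULL
  text <- c("Group comparison report",
            sprintf("  meningioma n = %d (paired n = %d), other n = %d",
                    nrow(men_t), nrow(paired), nrow(oth_t)),
            vapply(seq_len(nrow(table)), function(i) {
              sprintf("  %-28s %-7s estimate %s  p = %s (%s-sided)",
                      table$test[i], table$parameter[i],
                      table$estimate_rendered[i], table$p_rendered[i],
                      table$sidedness[i])
            }, character(1)))
  structure(list(comparisons = comparisons, table = table, text = text),
            class = "group_report")
}

#' @export
print.group_report <- function(x, ...) {
  writeLines(x$text)
  invisible(x)
}

#' Bundled canine brain-tumour cohort table
#'
#' Per-subject mean Ktrans (/min) and rBF values in the contrast-enhancing
#' tumour VOI and the contralateral white-matter control VOI, for a cohort
#' of six dogs with histologically confirmed meningiomas and three dogs with
#' other intracranial tumours of similar MRI appearance. Shipped as the
#' package's worked small-cohort example; subjects are anonymised.
#'
#' @return data frame in the VOI-summary layout accepted by
#'   [group_comparison_report()].
#' @export
canine_voi_table <- function() {
  read_voi_table(system.file("extdata", "canine_voi_summary.csv",
                             package = "dcekinetics", mustWork = TRUE))
}
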