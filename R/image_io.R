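# Imaging containers and NIfTI / CSV I/O.
#
# All analysis is carried out after resampling every input onto a common
# reference grid (clinically, the post-contrast T1-weighted volume); the
# containers below therefore always carry a 4x4 voxel-to-world affine.
# Voxel indices are 0-based in world-coordinate computations, matching the
# NIfTI convention.

#' Dynamic contrast-enhanced series
#'
#' Container for a 4D DCE-MRI acquisition: the raw signal array plus the
#' acquisition metadata needed for relaxometry (TR, flip angle) and kinetic
#' modelling (frame times).
#'
#' @param data 4D numeric array (x, y, z, t) of MR signal, arbitrary units.
#' @param frame_times numeric vector of frame acquisition times in seconds
#'   from the first frame; strictly increasing, length equal to `dim(data)[4]`.
#' @param tr repetition time in ms.
#' @param te echo time in ms.
#' @param flip_angle flip angle in degrees, in (0, 90).
#' @param voxel_size length-3 numeric, voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-world matrix.
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(data, frame_times, tr, te = NA_real_, flip_angle,
                       voxel_size = c(1, 1, 1), affine = diag(4)) {
  if (length(dim(data)) != 4) stop_input("`data` must be a 4D array")
  nt <- dim(data)[4]
  if (length(frame_times) != nt) {
    stop_input("frame_times has length ", length(frame_times),
               " but the series has ", nt, " frames")
  }
  if (any(diff(frame_times) <= 0)) {
    stop_input("frame_times must be strictly increasing")
  }
  if (nt < 3) stop_input("a dynamic series needs at least 3 frames")
  if (!is_scalar_number(tr) || tr <= 0) stop_input("tr must be > 0 (ms)")
  if (!is_scalar_number(flip_angle) || flip_angle <= 0 || flip_angle >= 90) {
    stop_input("flip_angle must be in (0, 90) degrees")
  }
  structure(list(data = data, frame_times = as.numeric(frame_times),
                 tr = tr, te = te, flip_angle = flip_angle,
                 voxel_size = voxel_size, affine = affine),
            class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dce_series> %dx%dx%d voxels, %d frames (%.1f-%.1f s)\n",
              d[1], d[2], d[3], d[4], x$frame_times[1],
              x$frame_times[length(x$frame_times)]))
  cat(sprintf("  TR %.3g ms, flip %.3g deg, voxels %s mm\n",
              x$tr, x$flip_angle, paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}

#' Scalar volume map
#'
#' 3D scalar image (a T1 map, a Ktrans map, ...) with units and a semantic
#' name. `NaN` marks excluded voxels throughout the package.
#'
#' @param data 3D numeric array.
#' @param units free-text unit label (e.g. `"ms"`, `"1/min"`).
#' @param affine 4x4 voxel-to-world matrix.
#' @param name semantic label (e.g. `"T1"`, `"ktrans"`).
#' @return An object of class `volume_map`.
#' @export
volume_map <- function(data, units = "", affine = diag(4), name = "") {
  if (length(dim(data)) != 3) stop_input("`data` must be a 3D array")
  if (any(is.infinite(data))) stop_input("volume_map entries must be finite or NaN")
  structure(list(data = data, units = units, affine = affine, name = name),
            class = "volume_map")
}

#' @export
print.volume_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_map '%s'> %dx%dx%d [%s], %d NaN\n", x$name,
              d[1], d[2], d[3], x$units, sum(is.nan(x$data))))
  invisible(x)
}

#' Binary volume of interest mask
#'
#' @param data 3D array with values in \{0, 1\} (logical accepted).
#' @param affine 4x4 voxel-to-world matrix.
#' @param label one of `tumour`, `tumour_CE`, `control`, `artery`, `brain`.
#' @return An object of class `mask_voi`.
#' @export
mask_voi <- function(data, affine = diag(4),
                     label = c("tumour", "tumour_CE", "control", "artery", "brain")) {
  label <- match.arg(label)
  if (length(dim(data)) != 3) stop_input("`data` must be a 3D array")
  v <- unique(as.vector(data))
  if (!all(v %in% c(0, 1))) stop_input("mask values must be 0/1")
  structure(list(data = array(as.numeric(data), dim(data)),
                 affine = affine, label = label),
            class = "mask_voi")
}

#' @export
print.mask_voi <- function(x, ...) {
  cat(sprintf("<mask_voi '%s'> %s, %d voxels set\n", x$label,
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

mask_count <- function(mask) sum(mask$data > 0)

# ---------------------------------------------------------------------------
# NIfTI I/O (via RNifti; sform carries the affine exactly, qform is unset so
# sheared affines survive the round trip)

nifti_from <- function(data, affine, voxel_size = NULL) {
  img <- RNifti::asNifti(data)
  if (is.null(voxel_size)) {
    voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  pd <- RNifti::pixdim(img)
  pd[1:3] <- voxel_size
  RNifti::pixdim(img) <- pd
  RNifti::`sform<-`(img, structure(affine, code = 2L))
}

nifti_affine <- function(img) {
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  attributes(aff) <- list(dim = c(4L, 4L))
  aff
}

# as.array() on a niftiImage keeps image attributes; strip to a plain array
plain_array <- function(img) {
  array(as.numeric(img), dim = dim(img))
}

#' Read a 4D dynamic series from NIfTI
#'
#' NIfTI headers do not reliably carry per-frame timing, so frame times must
#' be supplied explicitly (typically from the run configuration); they are
#' never guessed from TR.
#'
#' @param path path to a 4D `.nii`/`.nii.gz` file.
#' @param frame_times frame times in seconds, length = number of frames.
#' @param tr,te,flip_angle acquisition parameters (ms, ms, degrees).
#' @return A [dce_series()].
#' @export
read_dce_series <- function(path, frame_times, tr, te = NA_real_, flip_angle) {
  img <- RNifti::readNifti(path)
  arr <- plain_array(img)
  if (length(dim(arr)) != 4) {
    stop_input(path, " is not a 4D NIfTI (dims: ",
               paste(dim(arr), collapse = "x"), ")")
  }
  dce_series(arr, frame_times = frame_times, tr = tr, te = te,
             flip_angle = flip_angle,
             voxel_size = RNifti::pixdim(img)[1:3],
             affine = nifti_affine(img))
}

#' Write a dynamic series to NIfTI
#'
#' @param series a [dce_series()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_dce_series <- function(series, path) {
  RNifti::writeNifti(nifti_from(series$data, series$affine, series$voxel_size),
                     path, datatype = "double")
  invisible(path)
}

#' Read a scalar volume map from NIfTI
#'
#' @param path path to a 3D NIfTI file.
#' @param units,name passed to [volume_map()].
#' @return A [volume_map()].
#' @export
read_volume_map <- function(path, units = "", name = "") {
  img <- RNifti::readNifti(path)
  arr <- plain_array(img)
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) arr <- arr[, , , 1]
  if (length(dim(arr)) != 3) stop_input(path, " is not a 3D NIfTI")
  volume_map(arr, units = units, affine = nifti_affine(img), name = name)
}

#' Write a scalar volume map to NIfTI
#'
#' `NaN` entries (excluded voxels) are preserved by writing floating-point
#' data. Units and name go to a JSON sidecar next to the image.
#'
#' @param map a [volume_map()].
#' @param path output path; sidecar is `<path>.json`.
#' @param sidecar write the JSON sidecar? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_volume_map <- function(map, path, sidecar = TRUE) {
  RNifti::writeNifti(nifti_from(map$data, map$affine), path,
                     datatype = "double")
  if (sidecar) {
    jsonlite::write_json(list(name = map$name, units = map$units),
                         paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' @param path path to a 3D NIfTI file with 0/1 values.
#' @param label passed to [mask_voi()].
#' @return A [mask_voi()].
#' @export
read_mask_voi <- function(path, label = "tumour") {
  img <- RNifti::readNifti(path)
  arr <- plain_array(img)
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) arr <- arr[, , , 1]
  mask_voi(arr != 0, affine = nifti_affine(img), label = label)
}

#' Write a binary mask to NIfTI
#'
#' @param mask a [mask_voi()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_voi <- function(mask, path) {
  RNifti::writeNifti(nifti_from(mask$data, mask$affine), path,
                     datatype = "uint8")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Resampling

#' Resample an image onto a reference grid
#'
#' Maps every reference voxel centre through the reference affine and the
#' inverse of the moving affine, then interpolates. Scalar maps use trilinear
#' interpolation (`mode = "linear"`); masks must use `mode = "nearest"`,
#' which keeps them binary. Points falling outside the moving volume get 0
#' (masks) or `NaN` (maps).
#'
#' @param moving a [volume_map()] or [mask_voi()].
#' @param reference a [volume_map()] (or any object with `data` and `affine`)
#'   defining the target grid.
#' @param mode `"linear"` or `"nearest"`.
#' @return Same class as `moving`, on the reference grid.
#' @export
resample_to_reference <- function(moving, reference,
                                  mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  if (inherits(moving, "mask_voi") && mode != "nearest") {
    stop_input("masks must be resampled with mode = 'nearest'")
  }
  aff_m <- moving$affine
  aff_r <- reference$affine
  if (abs(det(aff_m)) < 1e-12 || abs(det(aff_r)) < 1e-12) {
    stop_input("singular affine: cannot resample")
  }
  rd <- dim(reference$data)[1:3]
  md <- dim(moving$data)

  # 0-based reference voxel grid -> world -> 0-based moving voxel coords
  ijk <- as.matrix(expand.grid(i = 0:(rd[1] - 1), j = 0:(rd[2] - 1),
                               k = 0:(rd[3] - 1)))
  M <- solve(aff_m) %*% aff_r
  xyz <- cbind(ijk, 1) %*% t(M)      # rows: moving voxel coords (0-based)

  vals <- if (mode == "nearest") {
    idx <- round(xyz[, 1:3]) + 1     # to 1-based
    inside <- idx[, 1] >= 1 & idx[, 1] <= md[1] &
              idx[, 2] >= 1 & idx[, 2] <= md[2] &
              idx[, 3] >= 1 & idx[, 3] <= md[3]
    v <- rep(if (inherits(moving, "mask_voi")) 0 else NaN, nrow(idx))
    if (any(inside)) {
      lin <- (idx[inside, 3] - 1) * md[1] * md[2] +
             (idx[inside, 2] - 1) * md[1] + idx[inside, 1]
      v[inside] <- moving$data[lin]
    }
    v
  } else {
    trilinear_sample(moving$data, xyz[, 1:3])
  }
  out <- array(vals, dim = rd)
  if (inherits(moving, "mask_voi")) {
    mask_voi(out, affine = aff_r, label = moving$label)
  } else {
    volume_map(out, units = moving$units, affine = aff_r, name = moving$name)
  }
}

# Trilinear interpolation at 0-based fractional coordinates (rows of `pts`);
# outside the volume -> NaN.
trilinear_sample <- function(vol, pts) {
  d <- dim(vol)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  out <- rep(NaN, nrow(pts))
  inside <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 &
            z >= 0 & z <= d[3] - 1
  if (!any(inside)) return(out)
  x <- x[inside]; y <- y[inside]; z <- z[inside]
  x0 <- pmin(floor(x), d[1] - 2); y0 <- pmin(floor(y), d[2] - 2)
  z0 <- pmin(floor(z), d[3] - 2)
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0); z0 <- pmax(z0, 0)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  # clamped lookup: corners with zero weight may fall outside size-1 dims
  at <- function(i, j, k) {
    i <- pmin(pmax(i, 0), d[1] - 1)
    j <- pmin(pmax(j, 0), d[2] - 1)
    k <- pmin(pmax(k, 0), d[3] - 1)
    vol[k * d[1] * d[2] + j * d[1] + i + 1]
  }
  v <- at(x0, y0, z0)         * (1 - fx) * (1 - fy) * (1 - fz) +
       at(x0 + 1, y0, z0)     * fx       * (1 - fy) * (1 - fz) +
       at(x0, y0 + 1, z0)     * (1 - fx) * fy       * (1 - fz) +
       at(x0, y0, z0 + 1)     * (1 - fx) * (1 - fy) * fz +
       at(x0 + 1, y0 + 1, z0) * fx       * fy       * (1 - fz) +
       at(x0 + 1, y0, z0 + 1) * fx       * (1 - fy) * fz +
       at(x0, y0 + 1, z0 + 1) * (1 - fx) * fy       * fz +
       at(x0 + 1, y0 + 1, z0 + 1) * fx   * fy       * fz
  out[inside] <- v
  out
}

# ---------------------------------------------------------------------------
# Tabular output

voi_table_columns <- c("subject", "group", "voi_label", "n_voxels",
                       "n_excluded", "mean_ktrans", "mean_rbf", "voi_volume")

#' Write per-subject VOI summaries to CSV
#'
#' @param rows a data frame with the VOI-summary columns (`subject`, `group`,
#'   `voi_label`, `n_voxels`, `n_excluded`, `mean_ktrans`, `mean_rbf`,
#'   optionally `voi_volume` in mm^3), or an empty data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_voi_table <- function(rows, path) {
  cols <- intersect(voi_table_columns, names(rows))
  if (nrow(rows) == 0) {
    cols <- setdiff(voi_table_columns, "voi_volume")
    rows <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  }
  utils::write.csv(rows[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read a per-subject VOI summary CSV
#'
#' @param path CSV path as written by [write_voi_table()].
#' @return data frame.
#' @export
read_voi_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
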