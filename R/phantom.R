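# Built-in synthetic datasets: the geometric validation phantom (a cube
# with a known linear value law and three reference planes, hand-
# checkable by construction), its closed-form expectation oracle, and a
# two-compartment edge phantom emulating the geometry of an isotropic
# 3D LGE acquisition for sharpness experiments. All synthetic.

#' Generate the geometric validation dataset
#'
#' An 11 x 11 x 11 cube with 1 mm isotropic resolution and the iso-center
#' at the volume midpoint. The voxel value is constant in x and y and
#' decreases linearly in z from 100 at the center by 20 per mm to 0 at
#' both z borders, so every reformatted value can be checked by hand.
#' Three 11 x 11 reference slices (nominal thickness tag 2 mm) are
#' provided:
#' \describe{
#'   \item{parplane}{parallel to the x-y plane at z = 0 (1 x 1 mm).}
#'   \item{perplane}{parallel to the x-z plane at y = 0 (1 x 1 mm);
#'     rows run along z.}
#'   \item{diagplane}{tilted 45 degrees in the y-z plane through the
#'     iso-center, spanning the cube's full y-z diagonal; pixel spacing
#'     1 x sqrt(2) mm with columns along the diagonal.}
#' }
#'
#' @param out_dir optional directory; when given, the volume is written
#'   as a DICOM series and each plane as a DICOM file (all re-readable
#'   through [load_volume_series()] / [load_reference_slice()]).
#' @return a list with `volume` ([volume_grid()]), `parplane`,
#'   `perplane`, `diagplane` ([slice_header()]s) and, when `out_dir` is
#'   given, `paths` (list of written file paths).
#' @export
generate_validation_dataset <- function(out_dir = NULL) {
  n <- 11L
  z <- seq(-5, 5)
  vals <- array(0, dim = c(n, n, n))
  for (k in seq_len(n)) vals[, , k] <- 100 - 20 * abs(z[k])

  study_uid <- dcm_uid()
  vol_series <- dcm_uid()
  volume <- volume_grid(
    values = vals, origin = c(-5, -5, -5),
    row_cosine = c(0, 1, 0), col_cosine = c(1, 0, 0),
    normal_cosine = c(0, 0, 1),
    spacing = c(1, 1, 1),
    provenance = list(series_uid = vol_series, series_number = 101L,
                      study_uid = study_uid)
  )

  s2 <- 1 / sqrt(2)
  parplane <- slice_header(
    position = c(-5, -5, 0), row_cosine = c(0, 1, 0), col_cosine = c(1, 0, 0),
    pixel_spacing = c(1, 1), rows = n, cols = n, slice_thickness = 2,
    study_uid = study_uid, series_number = 201L
  )
  perplane <- slice_header(
    position = c(-5, 0, -5), row_cosine = c(0, 0, 1), col_cosine = c(1, 0, 0),
    pixel_spacing = c(1, 1), rows = n, cols = n, slice_thickness = 2,
    study_uid = study_uid, series_number = 202L
  )
  diagplane <- slice_header(
    position = c(-5, -5, -5), row_cosine = c(1, 0, 0),
    col_cosine = c(0, s2, s2),
    pixel_spacing = c(1, sqrt(2)), rows = n, cols = n, slice_thickness = 2,
    study_uid = study_uid, series_number = 203L
  )

  out <- list(volume = volume, parplane = parplane, perplane = perplane,
              diagplane = diagplane)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
    vol_dir <- file.path(out_dir, "volume")
    if (!dir.exists(vol_dir)) dir.create(vol_dir)
    vol_paths <- character(n)
    for (k in seq_len(n)) {
      vol_paths[k] <- file.path(vol_dir, sprintf("vol_%02d.dcm", k))
      dcm_write(vol_paths[k], list(
        SOPInstanceUID = dcm_uid(),
        SeriesInstanceUID = vol_series,
        StudyInstanceUID = study_uid,
        SeriesNumber = 101L, InstanceNumber = k,
        SeriesDescription = "SYNTHETIC validation cube",
        SliceThickness = 1,
        ImagePositionPatient = c(-5, -5, z[k]),
        ImageOrientationPatient = c(1, 0, 0, 0, 1, 0),
        PixelSpacing = c(1, 1)
      ), vals[, , k])
    }
    # plane pixel content: the true value law read out at each center
    plane_vals <- list(
      parplane = matrix(100, n, n),
      perplane = matrix(rep(100 - 20 * abs(z), n), n, n, byrow = FALSE),
      diagplane = matrix(rep(100 - 20 * abs(z), each = n), n, n)
    )
    plane_paths <- list()
    for (nm in c("parplane", "perplane", "diagplane")) {
      h <- out[[nm]]
      p <- file.path(out_dir, paste0(nm, ".dcm"))
      dcm_write(p, list(
        SOPInstanceUID = h$sop_uid,
        SeriesInstanceUID = h$series_uid,
        StudyInstanceUID = study_uid,
        SeriesNumber = h$series_number, InstanceNumber = 1L,
        SeriesDescription = paste("SYNTHETIC validation", nm),
        SliceThickness = h$slice_thickness,
        ImagePositionPatient = h$position,
        ImageOrientationPatient = c(h$col_cosine, h$row_cosine),
        PixelSpacing = h$pixel_spacing
      ), plane_vals[[nm]])
      plane_paths[[nm]] <- p
    }
    out$paths <- c(list(volume = vol_paths), plane_paths)
  }
  out
}

#' Hand-calculation oracle for the validation dataset
#'
#' Closed-form expected reformatted values for the validation phantom
#' under a rectangular slice profile, computed directly from the linear
#' value law v(z) = 100 - 20*|z| -- deliberately sharing no interpolation
#' code with [reslice()]. Through-plane samples that exit the cube are
#' excluded with weight renormalization, mirroring the resampler's
#' boundary convention.
#'
#' @param plane `"parplane"`, `"perplane"` or `"diagplane"`.
#' @param thickness one of 0, 2, 2.82, 4.23 (mm).
#' @return 11 x 11 matrix of expected rounded integer values.
#' @export
expected_values_oracle <- function(plane, thickness) {
  plane <- match.arg(plane, c("parplane", "perplane", "diagplane"))
  allowed <- c(0, 2, 2.82, 4.23)
  if (!any(abs(thickness - allowed) < 1e-9)) {
    stop("oracle supports thicknesses 0, 2, 2.82 and 4.23 mm only",
         call. = FALSE)
  }
  num <- round_half_away(thickness / 2)  # z_res is 1 mm
  offsets <- if (num == 0) 0 else (-num:num) * thickness / (2 * num)
  vlaw <- function(z) 100 - 20 * abs(z)
  s2 <- 1 / sqrt(2)
  n <- 11L
  out <- matrix(0, n, n)
  for (r in seq_len(n)) {
    for (cc in seq_len(n)) {
      # patient coords of sample d along the plane normal
      yz <- switch(plane,
        parplane = cbind(y = (r - 6) + 0 * offsets, z = offsets),
        perplane = cbind(y = -offsets, z = (r - 6) + 0 * offsets),
        diagplane = cbind(y = (cc - 6) + offsets * s2,
                          z = (cc - 6) - offsets * s2)
      )
      ok <- abs(yz[, "y"]) <= 5 + 1e-9 & abs(yz[, "z"]) <= 5 + 1e-9
      out[r, cc] <- round_half_away(mean(vlaw(yz[ok, "z"])))
    }
  }
  out
}

#' Generate a two-compartment edge phantom
#'
#' A synthetic stand-in for an isotropic 3D acquisition containing a
#' sharp tissue interface: two intensity compartments (low 100, high
#' 400) separated by a planar boundary oblique to the grid, on a
#' 1.25 mm isotropic grid centered on the iso-center, with optional
#' Gaussian noise. The boundary tilts through-plane, so reslicing at
#' increasing slice thickness widens the edge transition and lowers the
#' image sharpness -- the behaviour the blur measure quantifies.
#'
#' @param size in-plane matrix size (>= 8); used for rows and columns.
#' @param edge_axis 1 or 2: the in-plane axis the boundary chiefly
#'   faces (1 = rows, 2 = columns).
#' @param n_slices number of slices (>= 8); defaults to `size`.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param seed integer seed; regeneration with the same seed is
#'   bit-identical and the caller's RNG state is left untouched.
#' @return a [volume_grid()] with 1.25 mm isotropic spacing.
#' @export
generate_edge_phantom <- function(size = 48L, edge_axis = 1L,
                                  n_slices = size, noise_sd = 5,
                                  seed = 1L) {
  size <- as.integer(size)
  n_slices <- as.integer(n_slices)
  if (size < 8L || n_slices < 8L) {
    stop("edge phantom needs at least 8 voxels per axis", call. = FALSE)
  }
  if (!edge_axis %in% 1:2) stop("edge_axis must be 1 or 2", call. = FALSE)
  sp <- 1.25
  d <- c(size, size, n_slices)
  # mm offsets from the volume center along (row, col, slice) axes
  ri <- (seq_len(d[1]) - (d[1] + 1) / 2) * sp
  ci <- (seq_len(d[2]) - (d[2] + 1) / 2) * sp
  si <- (seq_len(d[3]) - (d[3] + 1) / 2) * sp
  bn <- if (edge_axis == 1L) c(0.8, 0.1, 0.55) else c(0.1, 0.8, 0.55)
  bn <- bn / vnorm(bn)
  sdist <- outer(outer(ri * bn[1], ci * bn[2], `+`), si * bn[3], `+`)
  vals <- ifelse(sdist > 0, 400, 100)
  if (noise_sd > 0) {
    vals <- vals + with_local_seed(seed, array(stats::rnorm(prod(d), 0, noise_sd), d))
    vals <- pmax(vals, 0)
  }
  volume_grid(
    values = vals,
    origin = -sp * c((d[2] - 1) / 2, (d[1] - 1) / 2, (d[3] - 1) / 2),
    row_cosine = c(0, 1, 0), col_cosine = c(1, 0, 0),
    normal_cosine = c(0, 0, 1),
    spacing = c(sp, sp, sp),
    provenance = list(series_uid = dcm_uid(), series_number = 301L,
                      study_uid = dcm_uid())
  )
}
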