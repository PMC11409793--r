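# Patient-space geometry of the reference plane and the through-plane
# parallel-slice sampling scheme that discretizes slice thickness.

#' Reference plane of a 2D slice
#'
#' Builds the patient-space plane a reslicing targets: the center of
#' pixel (0,0), the in-plane direction cosines, and the plane normal
#' `col_cosine x row_cosine` (the standard DICOM slice normal; an axial
#' slice gets (0, 0, 1)).
#'
#' @param header a [slice_header()].
#' @return an object of class `reference_plane` with fields `origin`,
#'   `row_cosine`, `col_cosine`, `normal_cosine`, `pixel_spacing`,
#'   `rows`, `cols`.
#' @export
plane_from_header <- function(header) {
  stopifnot(inherits(header, "slice_header"))
  n <- cross3(header$col_cosine, header$row_cosine)
  n <- n / vnorm(n)
  structure(list(
    origin = header$position,
    row_cosine = header$row_cosine,
    col_cosine = header$col_cosine,
    normal_cosine = n,
    pixel_spacing = header$pixel_spacing,
    rows = header$rows, cols = header$cols
  ), class = "reference_plane")
}

#' Pixel centers of a reference plane
#'
#' Patient-space centers of every pixel: center of pixel (i, j), 0-based,
#' is `origin + i*spacing_row*row_cosine + j*spacing_col*col_cosine`.
#'
#' @param plane a `reference_plane`.
#' @return numeric array of dim (rows, cols, 3): the LPS mm coordinates.
#' @export
pixel_centers <- function(plane) {
  stopifnot(inherits(plane, "reference_plane"))
  i <- seq_len(plane$rows) - 1
  j <- seq_len(plane$cols) - 1
  out <- array(0, dim = c(plane$rows, plane$cols, 3L))
  for (ax in 1:3) {
    out[, , ax] <- plane$origin[ax] +
      outer(i * plane$pixel_spacing[1] * plane$row_cosine[ax],
            j * plane$pixel_spacing[2] * plane$col_cosine[ax], `+`)
  }
  out
}

#' Through-plane parallel-slice stack
#'
#' Discretizes a slice thickness into `2*num + 1` parallel slices along
#' the plane normal. The per-side count is
#' `num = round(slice_thickness / (2 * z_res))` (round half away from
#' zero), where `z_res` is the volume's through-plane resolution, and for
#' `num > 0` the inter-slice distance is `dist = slice_thickness /
#' (2 * num)`, so the signed offsets `k*dist`, `k = -num..num`, span
#' exactly `[-thickness/2, +thickness/2]`. A 0 mm thickness (and any
#' thickness small enough that `num` rounds to 0, which is treated the
#' same with a warning) samples the central slice only.
#'
#' @param slice_thickness thickness in mm, within [0, 99.99].
#' @param z_res volume through-plane resolution in mm (> 0).
#' @return an object of class `parallel_stack` with fields
#'   `slice_thickness`, `num`, `dist` (`NA` when `num == 0`), `offsets`.
#' @export
build_parallel_stack <- function(slice_thickness, z_res) {
  if (!is.finite(slice_thickness) ||
      slice_thickness < 0 || slice_thickness > 99.99) {
    stop("slice thickness must be between 0 mm and 99.99 mm, got ",
         slice_thickness, call. = FALSE)
  }
  if (!is.finite(z_res) || z_res <= 0) {
    stop("z_res must be a positive length in mm", call. = FALSE)
  }
  num <- as.integer(round_half_away(slice_thickness / (2 * z_res)))
  if (num == 0L) {
    if (slice_thickness > 0) {
      warning(sprintf(paste0("slice thickness %.4g mm is below the ",
                             "through-plane resolution %.4g mm; sampling ",
                             "the central slice only (as for 0 mm)"),
                      slice_thickness, z_res))
    }
    dist <- NA_real_
    offsets <- 0
  } else {
    dist <- slice_thickness / (2 * num)
    offsets <- (-num:num) * dist
  }
  structure(list(slice_thickness = slice_thickness, num = num,
                 dist = dist, offsets = offsets),
            class = "parallel_stack")
}

#' @export
print.parallel_stack <- function(x, ...) {
  cat(sprintf("<parallel_stack> thickness %.4g mm: num=%d, dist=%s mm (%d slices)\n",
              x$slice_thickness, x$num,
              ifelse(is.na(x$dist), "-", format(x$dist)),
              length(x$offsets)))
  invisible(x)
}

#' Slice header coincident with a native volume slice
#'
#' Convenience constructor for a reference slice that lies exactly on
#' grid slice `k` of a volume (useful for phantoms and QC).
#'
#' @param volume a [volume_grid()].
#' @param k 1-based slice index; defaults to the middle slice.
#' @param slice_thickness thickness tag for the header; defaults to the
#'   volume's through-plane spacing.
#' @return a [slice_header()].
#' @export
volume_slice_header <- function(volume, k = (dim(volume$values)[3] + 1) %/% 2,
                                slice_thickness = volume$spacing[3]) {
  stopifnot(inherits(volume, "volume_grid"))
  d <- dim(volume$values)
  if (k < 1 || k > d[3]) stop("slice index out of range", call. = FALSE)
  slice_header(
    position = volume$origin + (k - 1) * volume$spacing[3] * volume$normal_cosine,
    row_cosine = volume$row_cosine, col_cosine = volume$col_cosine,
    pixel_spacing = volume$spacing[1:2],
    rows = d[1], cols = d[2],
    slice_thickness = slice_thickness,
    series_uid = volume$provenance$series_uid %||% dcm_uid(),
    study_uid = volume$provenance$study_uid %||% dcm_uid()
  )
}
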