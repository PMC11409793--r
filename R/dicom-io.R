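# Geometry-aware containers for DICOM slices and volumes, and the
# import/export operations built on the Part-10 codec.
#
# Index conventions used throughout the package (0-based in formulas,
# 1-based in R arrays):
#   * image matrices are values[row, col];
#   * `row_cosine` is the patient-space direction in which the ROW index
#     increases (DICOM ImageOrientationPatient elements 4..6);
#   * `col_cosine` is the direction in which the COLUMN index increases
#     (ImageOrientationPatient elements 1..3);
#   * positions refer to pixel/voxel CENTERS in the DICOM LPS frame, so
#     ImagePositionPatient is the center of pixel (0, 0);
#   * the slice normal is col_cosine x row_cosine, the standard DICOM
#     normal (axial slices get (0, 0, 1)).

#' Construct a 2D slice header
#'
#' A `slice_header` carries the patient-space geometry and identifiers of
#' a single-frame DICOM image: where pixel (0,0) sits, which way the row
#' and column indices run, and how far apart pixels are.
#'
#' @param position 3-vector, mm: patient-space (LPS) center of pixel (0,0).
#' @param row_cosine unit 3-vector along increasing row index.
#' @param col_cosine unit 3-vector along increasing column index.
#' @param pixel_spacing length-2 numeric, mm: (between-rows, between-columns).
#' @param rows,cols matrix size.
#' @param slice_thickness nominal slice thickness in mm, or `NA` if the
#'   source file carried no thickness tag (never silently defaulted).
#' @param series_uid,sop_uid,study_uid DICOM identifier strings.
#' @param series_number integer series number.
#' @param rescale_slope,rescale_intercept stored-value rescaling.
#' @return an object of class `slice_header`.
#' @export
slice_header <- function(position, row_cosine, col_cosine, pixel_spacing,
                         rows, cols, slice_thickness = NA_real_,
                         series_uid = dcm_uid(), sop_uid = dcm_uid(),
                         study_uid = dcm_uid(), series_number = 1L,
                         rescale_slope = 1, rescale_intercept = 0) {
  check_cosines(row_cosine, col_cosine, tol = 1e-4, what = "slice header")
  if (rows < 1 || cols < 1) stop("rows and cols must be >= 1", call. = FALSE)
  if (any(pixel_spacing <= 0)) stop("pixel spacings must be > 0", call. = FALSE)
  structure(list(
    position = as.numeric(position),
    row_cosine = as.numeric(row_cosine),
    col_cosine = as.numeric(col_cosine),
    pixel_spacing = as.numeric(pixel_spacing),
    rows = as.integer(rows), cols = as.integer(cols),
    slice_thickness = as.numeric(slice_thickness),
    series_uid = series_uid, sop_uid = sop_uid, study_uid = study_uid,
    series_number = as.integer(series_number),
    rescale_slope = rescale_slope, rescale_intercept = rescale_intercept
  ), class = "slice_header")
}

#' @export
print.slice_header <- function(x, ...) {
  cat(sprintf("<slice_header> %dx%d px, spacing %.4g x %.4g mm\n",
              x$rows, x$cols, x$pixel_spacing[1], x$pixel_spacing[2]))
  cat(sprintf("  position: (%.3f, %.3f, %.3f) mm\n",
              x$position[1], x$position[2], x$position[3]))
  cat(sprintf("  thickness: %s mm, series %s\n",
              ifelse(is.na(x$slice_thickness), "<absent>",
                     format(x$slice_thickness)), x$series_uid))
  invisible(x)
}

#' Construct a 3D volume grid
#'
#' A `volume_grid` is a scalar field on a regular grid in patient space:
#' `values[i, j, k]` sits at
#' `origin + (i-1)*spacing[1]*row_cosine + (j-1)*spacing[2]*col_cosine +
#'  (k-1)*spacing[3]*normal_cosine`.
#' `spacing[3]` is the through-plane resolution of the 3D acquisition
#' (the inter-slice distance along the acquisition direction).
#'
#' @param values 3D numeric array indexed (row, col, slice); finite.
#' @param origin 3-vector mm: center of voxel (0,0,0).
#' @param row_cosine,col_cosine,normal_cosine mutually orthogonal unit
#'   3-vectors (normal defaults to `col_cosine x row_cosine`).
#' @param spacing length-3 numeric, mm: (row, col, slice).
#' @param provenance named list of source identifiers (series UID, number).
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(values, origin, row_cosine, col_cosine,
                        normal_cosine = cross3(col_cosine, row_cosine),
                        spacing, provenance = list()) {
  if (length(dim(values)) != 3L) stop("values must be a 3D array", call. = FALSE)
  if (!all(is.finite(values))) stop("volume values must be finite", call. = FALSE)
  check_cosines(row_cosine, col_cosine, tol = 1e-4, what = "volume")
  if (abs(vnorm(normal_cosine) - 1) > 1e-4 ||
      abs(sum(normal_cosine * row_cosine)) > 1e-4 ||
      abs(sum(normal_cosine * col_cosine)) > 1e-4) {
    stop("normal_cosine must be a unit vector orthogonal to the in-plane axes",
         call. = FALSE)
  }
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be three positive lengths (mm)", call. = FALSE)
  }
  structure(list(
    values = values, origin = as.numeric(origin),
    row_cosine = as.numeric(row_cosine), col_cosine = as.numeric(col_cosine),
    normal_cosine = as.numeric(normal_cosine),
    spacing = as.numeric(spacing), provenance = provenance
  ), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin: (%.3f, %.3f, %.3f) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# Pull the geometry-bearing attributes out of a parsed DICOM dataset,
# erroring with the list of missing mandatory tag names.
.required_geometry <- function(ds, path) {
  need <- c("ImagePositionPatient", "ImageOrientationPatient", "PixelSpacing",
            "Rows", "Columns", "SeriesInstanceUID", "SOPInstanceUID",
            "StudyInstanceUID")
  have <- vapply(need, function(nm) {
    !is.null(ds$elements[[.dcm_tag_for_name(nm)]])
  }, logical(1))
  if (!all(have)) {
    stop("DICOM file ", path, " is missing required tag(s): ",
         paste(need[!have], collapse = ", "), call. = FALSE)
  }
  nfr <- dcm_numbers(ds, "NumberOfFrames")
  if (!is.null(nfr) && nfr > 1) {
    stop("multi-frame (enhanced) DICOM input is not supported: ", path,
         call. = FALSE)
  }
  invisible(TRUE)
}

.header_from_dataset <- function(ds, path) {
  .required_geometry(ds, path)
  iop <- dcm_numbers(ds, "ImageOrientationPatient")
  ps <- dcm_numbers(ds, "PixelSpacing")
  st <- dcm_numbers(ds, "SliceThickness")
  sn <- dcm_numbers(ds, "SeriesNumber")
  slope <- dcm_numbers(ds, "RescaleSlope")
  inter <- dcm_numbers(ds, "RescaleIntercept")
  slice_header(
    position = dcm_numbers(ds, "ImagePositionPatient"),
    row_cosine = iop[4:6], col_cosine = iop[1:3],
    pixel_spacing = ps,
    rows = dcm_numbers(ds, "Rows"), cols = dcm_numbers(ds, "Columns"),
    slice_thickness = if (is.null(st)) NA_real_ else st,
    series_uid = dcm_string(ds, "SeriesInstanceUID"),
    sop_uid = dcm_string(ds, "SOPInstanceUID"),
    study_uid = dcm_string(ds, "StudyInstanceUID"),
    series_number = if (is.null(sn)) 1L else sn,
    rescale_slope = if (is.null(slope)) 1 else slope,
    rescale_intercept = if (is.null(inter)) 0 else inter
  )
}

#' Load a 2D reference DICOM slice
#'
#' Reads one single-frame DICOM file and returns its geometry as a
#' [slice_header()]. An absent SliceThickness tag is recorded as `NA`,
#' never defaulted.
#'
#' @param path path to a DICOM file.
#' @return a `slice_header`.
#' @export
load_reference_slice <- function(path) {
  .header_from_dataset(dcm_read(path), path)
}

#' Load a 3D acquisition from a DICOM series
#'
#' Reads two or more single-frame DICOM files belonging to one series,
#' sorts them by the projection of ImagePositionPatient onto the slice
#' normal, verifies a uniform inter-slice spacing, applies the rescale
#' slope/intercept and assembles a [volume_grid()]. The result is
#' independent of the input file order.
#'
#' @param paths character vector of DICOM file paths (>= 2).
#' @param spacing_tol relative tolerance on inter-slice gap uniformity.
#' @return a `volume_grid` whose `spacing[3]` is the inter-slice distance.
#' @export
load_volume_series <- function(paths, spacing_tol = 1e-3) {
  if (length(paths) < 2) {
    stop("a 3D series needs at least 2 slices, got ", length(paths),
         call. = FALSE)
  }
  dss <- lapply(paths, dcm_read)
  hdr <- mapply(.header_from_dataset, dss, paths, SIMPLIFY = FALSE)

  uids <- vapply(hdr, `[[`, character(1), "series_uid")
  if (length(unique(uids)) != 1L) {
    stop("mixed SeriesInstanceUIDs in input: ",
         paste(unique(uids), collapse = ", "), call. = FALSE)
  }
  ref <- hdr[[1]]
  for (h in hdr[-1]) {
    if (max(abs(h$row_cosine - ref$row_cosine),
            abs(h$col_cosine - ref$col_cosine)) > 1e-4 ||
        h$rows != ref$rows || h$cols != ref$cols ||
        max(abs(h$pixel_spacing - ref$pixel_spacing)) > 1e-6) {
      stop("slices in the series disagree on orientation, matrix size ",
           "or pixel spacing", call. = FALSE)
    }
  }
  normal <- cross3(ref$col_cosine, ref$row_cosine)
  proj <- vapply(hdr, function(h) sum(h$position * normal), numeric(1))
  ord <- order(proj)
  proj <- proj[ord]
  gaps <- diff(proj)
  if (any(gaps <= 0)) {
    stop("duplicate slice positions in series", call. = FALSE)
  }
  mg <- mean(gaps)
  bad <- which(abs(gaps - mg) / mg > spacing_tol)
  if (length(bad)) {
    stop(sprintf(paste0("non-uniform inter-slice spacing: gap between ",
                        "sorted slices %d and %d is %.6g mm (mean %.6g mm)"),
                 bad[1], bad[1] + 1L, gaps[bad[1]], mg), call. = FALSE)
  }
  vals <- array(0, dim = c(ref$rows, ref$cols, length(paths)))
  for (k in seq_along(ord)) {
    i <- ord[k]
    px <- dcm_pixels(dss[[i]])
    vals[, , k] <- hdr[[i]]$rescale_slope * px + hdr[[i]]$rescale_intercept
  }
  volume_grid(
    values = vals,
    origin = hdr[[ord[1]]]$position,
    row_cosine = ref$row_cosine, col_cosine = ref$col_cosine,
    normal_cosine = normal,
    spacing = c(ref$pixel_spacing, mg),
    provenance = list(series_uid = ref$series_uid,
                      series_number = ref$series_number,
                      study_uid = ref$study_uid)
  )
}

#' Export a reformatted image as DICOM
#'
#' Writes the rounded integer image of a reslice result as a single-frame
#' DICOM file that copies the reference slice's geometry (position,
#' orientation, pixel spacing, matrix size, study UID) but carries a NEW
#' SeriesInstanceUID, NEW SOPInstanceUID and a new series number. The
#' SliceThickness tag records the reslicing thickness actually used, and
#' the series description records the source series, profile and
#' thickness. Stored pixels are unsigned 16-bit (slope 1, intercept 0);
#' values are clipped to [0, 65535].
#'
#' @param result a `reslice_result` (see [reslice()]).
#' @param reference the [slice_header()] the reslicing targeted.
#' @param out_dir output directory (created if missing).
#' @param series_number series number for the export; default
#'   `3000 + reference$series_number`.
#' @param series_uid series UID for the export; a fresh UID by default.
#' @param filename file name; autogenerated from profile/thickness/UID
#'   by default.
#' @return the written file path (invisibly a character scalar).
#' @export
export_resliced_dicom <- function(result, reference, out_dir,
                                  series_number = NULL, series_uid = NULL,
                                  filename = NULL) {
  stopifnot(inherits(result, "reslice_result"),
            inherits(reference, "slice_header"))
  if (nrow(result$values) != reference$rows ||
      ncol(result$values) != reference$cols) {
    stop(sprintf("result matrix (%dx%d) does not match reference (%dx%d)",
                 nrow(result$values), ncol(result$values),
                 reference$rows, reference$cols), call. = FALSE)
  }
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  if (is.null(series_number)) series_number <- 3000L + reference$series_number
  if (is.null(series_uid)) series_uid <- dcm_uid()
  sop_uid <- dcm_uid()
  if (is.null(filename)) {
    filename <- sprintf("resliced_%s_%.4gmm_%s.dcm", result$profile_name,
                        result$thickness_used,
                        substr(sop_uid, nchar(sop_uid) - 9L, nchar(sop_uid)))
  }
  path <- file.path(out_dir, filename)
  # LO values are capped at 64 chars; keep the description compact
  desc <- sprintf("RS %s %s %.4gmm", result$source_series,
                  result$profile_name, result$thickness_used)
  if (nchar(desc) > 64) desc <- substr(desc, 1, 64)
  attrs <- list(
    SOPClassUID = SOP_CLASS_SC,
    SOPInstanceUID = sop_uid,
    SeriesInstanceUID = series_uid,
    StudyInstanceUID = reference$study_uid,
    SeriesNumber = as.integer(series_number),
    InstanceNumber = 1L,
    SeriesDescription = desc,
    SliceThickness = result$thickness_used,
    ImagePositionPatient = reference$position,
    ImageOrientationPatient = c(reference$col_cosine, reference$row_cosine),
    PixelSpacing = reference$pixel_spacing
  )
  dcm_write(path, attrs, result$values)
  invisible(path)
}
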