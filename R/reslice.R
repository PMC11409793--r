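# The two-step interpolation at the heart of the tool: (1) trilinear
# sampling of the 3D grid at every reference pixel center, repeated for
# each parallel slice of the through-plane stack; (2) profile-weighted
# totalization across the stack followed by integer rounding.

# Vectorized trilinear interpolation of a volume_grid at patient-space
# points (N x 3). Points outside the pixel-center bounding box are
# invalid (no extrapolation). Returns list(values, valid).
.trilinear <- function(volume, points) {
  d <- dim(volume$values)
  rel <- sweep(points, 2, volume$origin)
  r <- (rel %*% volume$row_cosine)[, 1] / volume$spacing[1]
  cc <- (rel %*% volume$col_cosine)[, 1] / volume$spacing[2]
  s <- (rel %*% volume$normal_cosine)[, 1] / volume$spacing[3]

  eps <- 1e-9
  valid <- r >= -eps & r <= d[1] - 1 + eps &
    cc >= -eps & cc <= d[2] - 1 + eps &
    s >= -eps & s <= d[3] - 1 + eps

  vals <- rep(NA_real_, nrow(points))
  if (any(valid)) {
    r <- pmin(pmax(r[valid], 0), d[1] - 1)
    cc <- pmin(pmax(cc[valid], 0), d[2] - 1)
    s <- pmin(pmax(s[valid], 0), d[3] - 1)
    r0 <- pmin(floor(r), d[1] - 2); r0 <- pmax(r0, 0)
    c0 <- pmin(floor(cc), d[2] - 2); c0 <- pmax(c0, 0)
    s0 <- pmin(floor(s), d[3] - 2); s0 <- pmax(s0, 0)
    fr <- r - r0; fc <- cc - c0; fs <- s - s0
    v <- volume$values
    base <- r0 + c0 * d[1] + s0 * d[1] * d[2] + 1  # 1-based flat index
    dR <- 1; dC <- d[1]; dS <- d[1] * d[2]
    vals[valid] <-
      v[base]                 * (1 - fr) * (1 - fc) * (1 - fs) +
      v[base + dR]            * fr       * (1 - fc) * (1 - fs) +
      v[base + dC]            * (1 - fr) * fc       * (1 - fs) +
      v[base + dR + dC]       * fr       * fc       * (1 - fs) +
      v[base + dS]            * (1 - fr) * (1 - fc) * fs +
      v[base + dR + dS]       * fr       * (1 - fc) * fs +
      v[base + dC + dS]       * (1 - fr) * fc       * fs +
      v[base + dR + dC + dS]  * fr       * fc       * fs
  }
  list(values = vals, valid = valid)
}

#' Sample the volume across the parallel-slice stack
#'
#' Trilinearly interpolates the 3D volume at every reference pixel
#' center shifted by each stack offset along the plane normal:
#' `value[i, j, k]` is the sample at
#' `pixel_center(i, j) + offsets[k] * normal_cosine`. Samples whose
#' location leaves the volume's pixel-center bounding box are flagged
#' invalid.
#'
#' @param volume a [volume_grid()].
#' @param plane a `reference_plane` (see [plane_from_header()]).
#' @param stack a `parallel_stack` (see [build_parallel_stack()]).
#' @return an object of class `sampled_stack`: list with `values`
#'   (rows x cols x n_offsets array, `NA` where invalid) and
#'   `valid_mask` (same shape, logical).
#' @export
sample_stack <- function(volume, plane, stack) {
  stopifnot(inherits(volume, "volume_grid"),
            inherits(plane, "reference_plane"),
            inherits(stack, "parallel_stack"))
  centers <- pixel_centers(plane)
  n_px <- plane$rows * plane$cols
  pts0 <- matrix(centers, nrow = n_px, ncol = 3L)
  K <- length(stack$offsets)
  vals <- array(NA_real_, dim = c(plane$rows, plane$cols, K))
  valid <- array(FALSE, dim = c(plane$rows, plane$cols, K))
  for (k in seq_len(K)) {
    pts <- sweep(pts0, 2, stack$offsets[k] * plane$normal_cosine, `+`)
    tri <- .trilinear(volume, pts)
    vals[, , k] <- tri$values
    valid[, , k] <- tri$valid
  }
  if (!any(valid)) {
    stop("no overlap: the reference plane lies entirely outside the volume",
         call. = FALSE)
  }
  structure(list(values = vals, valid_mask = valid), class = "sampled_stack")
}

#' Profile-weighted totalization of the sampled stack
#'
#' Collapses the parallel slices into one image:
#' `value[i, j] = round(sum_k w_k * value[i, j, k] / sum_k w_k)`,
#' with the sums running over VALID samples only (invalid samples are
#' excluded from numerator and denominator, i.e. the weights are
#' renormalized at the volume boundary). Rounding is half away from
#' zero; results are clipped to the unsigned 16-bit export range.
#' Pixels with no valid sample -- or whose valid samples all carry zero
#' profile weight, which can happen at the volume boundary for profiles
#' that vanish at the slice edges -- are set to 0 and counted in the
#' out-of-volume tally.
#'
#' @param samples a `sampled_stack`.
#' @param weights numeric vector, one weight per stack offset.
#' @return an object of class `reslice_result` (provenance fields are
#'   filled by [reslice()]): `values` (integer matrix), `float_values`
#'   (pre-rounding, `NA` where out of volume), `n_out_of_volume`.
#' @export
totalize <- function(samples, weights) {
  stopifnot(inherits(samples, "sampled_stack"))
  K <- dim(samples$values)[3]
  if (length(weights) != K) {
    stop("need one weight per stack slice: got ", length(weights),
         " weights for ", K, " slices", call. = FALSE)
  }
  w <- array(rep(weights, each = prod(dim(samples$values)[1:2])),
             dim = dim(samples$values))
  w[!samples$valid_mask] <- 0
  v <- samples$values
  v[!samples$valid_mask] <- 0
  wsum <- apply(w, c(1, 2), sum)
  num <- apply(w * v, c(1, 2), sum)
  usable <- wsum > 0
  fl <- matrix(NA_real_, nrow(wsum), ncol(wsum))
  fl[usable] <- num[usable] / wsum[usable]
  out <- round_half_away(fl)
  out[!usable] <- 0
  out[out < 0] <- 0
  out[out > 65535] <- 65535
  structure(list(
    values = matrix(as.integer(out), nrow(out), ncol(out)),
    float_values = fl,
    n_out_of_volume = sum(!usable),
    thickness_used = NA_real_, profile_name = NA_character_,
    source_series = NA_character_, reference_sop = NA_character_
  ), class = "reslice_result")
}

# Resolve a thickness argument: numeric mm, or the presets
# "reference_2d" (the reference slice's own thickness tag) and
# "volume_z" (the volume's through-plane resolution).
.resolve_thickness <- function(thickness, volume, reference) {
  if (is.character(thickness)) {
    switch(thickness,
      reference_2d = {
        if (is.na(reference$slice_thickness)) {
          stop("thickness preset 'reference_2d' requires the reference ",
               "slice to carry a SliceThickness tag", call. = FALSE)
        }
        reference$slice_thickness
      },
      volume_z = volume$spacing[3],
      stop("unknown thickness preset '", thickness,
           "' (use a number in mm, 'reference_2d' or 'volume_z')",
           call. = FALSE)
    )
  } else {
    as.numeric(thickness)
  }
}

#' Reslice a 3D volume at a 2D reference slice
#'
#' The full reformatting pipeline: build the reference plane, discretize
#' the requested slice thickness into a parallel-slice stack, trilinearly
#' sample the volume across the stack, and totalize under the chosen
#' slice-profile weighting. The output image has exactly the reference
#' slice's matrix size and pixel grid.
#'
#' @param volume a [volume_grid()].
#' @param reference a [slice_header()].
#' @param thickness slice thickness in mm (0 to 99.99), or the preset
#'   `"reference_2d"` (the reference's own thickness tag; errors if the
#'   tag is absent) or `"volume_z"` (the volume's through-plane
#'   resolution).
#' @param profile slice profile name or [slice_profile()]; default
#'   rectangular.
#' @return a `reslice_result`: rounded integer `values` plus
#'   `float_values`, the stack (`num`, `dist`), the out-of-volume pixel
#'   tally and provenance identifiers.
#' @export
#' @examples
#' ph <- generate_validation_dataset()
#' res <- reslice(ph$volume, ph$parplane, thickness = 2,
#'                profile = "rectangular")
#' res$values[6, 6]  # central pixel
reslice <- function(volume, reference, thickness = 0,
                    profile = "rectangular") {
  stopifnot(inherits(volume, "volume_grid"),
            inherits(reference, "slice_header"))
  profile <- slice_profile(profile)
  thickness <- .resolve_thickness(thickness, volume, reference)
  plane <- plane_from_header(reference)
  stack <- build_parallel_stack(thickness, volume$spacing[3])
  samples <- sample_stack(volume, plane, stack)
  w <- profile_weights(profile, stack$num)
  res <- totalize(samples, w)
  res$thickness_used <- thickness
  res$profile_name <- profile$name
  res$source_series <- volume$provenance$series_uid %||% NA_character_
  res$reference_sop <- reference$sop_uid
  res$num <- stack$num
  res$dist <- stack$dist
  res
}

#' @export
print.reslice_result <- function(x, ...) {
  cat(sprintf("<reslice_result> %dx%d px, thickness %.4g mm, profile %s\n",
              nrow(x$values), ncol(x$values), x$thickness_used,
              x$profile_name))
  if (x$n_out_of_volume > 0) {
    cat(sprintf("  %d pixel(s) entirely outside the volume (set to 0)\n",
                x$n_out_of_volume))
  }
  invisible(x)
}
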