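# Independent brute-force oracle for the resampling pipeline: scalar
# 8-corner trilinear interpolation plus an explicit per-pixel weighted
# mean, written without touching any of the package's interpolation
# code so the two routes can be compared.

brute_trilinear <- function(values, origin, axes, spacing, p) {
  rel <- p - origin
  idx <- c(sum(rel * axes[1, ]) / spacing[1],
           sum(rel * axes[2, ]) / spacing[2],
           sum(rel * axes[3, ]) / spacing[3])
  d <- dim(values)
  if (any(idx < -1e-9) || any(idx > d - 1 + 1e-9)) return(NA_real_)
  idx <- pmin(pmax(idx, 0), d - 1)
  lo <- pmax(pmin(floor(idx), d - 2), 0)
  f <- idx - lo
  acc <- 0
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    wt <- (if (a) f[1] else 1 - f[1]) *
      (if (b) f[2] else 1 - f[2]) *
      (if (cc) f[3] else 1 - f[3])
    acc <- acc + wt * values[lo[1] + a + 1, lo[2] + b + 1, lo[3] + cc + 1]
  }
  acc
}

# Pre-rounding reformatted image by brute force; weight_fun maps the
# normalized offset u in [-1, 1] to a weight.
brute_reslice_float <- function(volume, header, thickness,
                                weight_fun = function(u) rep(1, length(u))) {
  axes <- rbind(volume$row_cosine, volume$col_cosine, volume$normal_cosine)
  normal <- c(
    header$col_cosine[2] * header$row_cosine[3] -
      header$col_cosine[3] * header$row_cosine[2],
    header$col_cosine[3] * header$row_cosine[1] -
      header$col_cosine[1] * header$row_cosine[3],
    header$col_cosine[1] * header$row_cosine[2] -
      header$col_cosine[2] * header$row_cosine[1]
  )
  num <- floor(thickness / (2 * volume$spacing[3]) + 0.5)  # half away, x >= 0
  if (num == 0) {
    offsets <- 0
    w <- 1
  } else {
    offsets <- (-num:num) * thickness / (2 * num)
    w <- weight_fun((-num:num) / num)
  }
  out <- matrix(NA_real_, header$rows, header$cols)
  for (r in seq_len(header$rows)) {
    for (cc in seq_len(header$cols)) {
      center <- header$position +
        (r - 1) * header$pixel_spacing[1] * header$row_cosine +
        (cc - 1) * header$pixel_spacing[2] * header$col_cosine
      sv <- vapply(offsets, function(d) {
        brute_trilinear(volume$values, volume$origin, axes, volume$spacing,
                        center + d * normal)
      }, numeric(1))
      ok <- !is.na(sv)
      if (any(ok) && sum(w[ok]) > 0) {
        out[r, cc] <- sum(w[ok] * sv[ok]) / sum(w[ok])
      }
    }
  }
  out
}

# Random but well-posed volume/plane configurations for property tests:
# a small volume with random orthonormal axes and spacings, and an
# oblique plane whose origin sits near the volume center so that at
# least part of the plane intersects the grid.
random_orthonormal3 <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_config <- function() {
  d <- sample(5:16, 3, replace = TRUE)
  sp <- runif(3, 0.6, 2)
  q <- random_orthonormal3()
  origin <- runif(3, -20, 20)
  vol <- volume_grid(
    values = array(runif(prod(d), 0, 1000), dim = d),
    origin = origin,
    row_cosine = q[, 1], col_cosine = q[, 2], normal_cosine = q[, 3],
    spacing = sp,
    provenance = list(series_uid = "test")
  )
  center <- origin + q[, 1] * sp[1] * (d[1] - 1) / 2 +
    q[, 2] * sp[2] * (d[2] - 1) / 2 + q[, 3] * sp[3] * (d[3] - 1) / 2
  qp <- random_orthonormal3()
  rows <- sample(3:7, 1)
  cols <- sample(3:7, 1)
  ps <- runif(2, 0.5, 1.5)
  hdr <- slice_header(
    position = center -
      (rows - 1) / 2 * ps[1] * qp[, 1] - (cols - 1) / 2 * ps[2] * qp[, 2] +
      runif(3, -1, 1),
    row_cosine = qp[, 1], col_cosine = qp[, 2],
    pixel_spacing = ps, rows = rows, cols = cols,
    slice_thickness = NA_real_
  )
  list(volume = vol, header = hdr,
       thickness = runif(1, 0, 3 * sp[3]))
}
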