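# Plane construction, pixel centers, and the parallel-slice stack that
# discretizes slice thickness.

axial_header <- function(rows = 11, cols = 11, origin = c(-5, -5, 0)) {
  slice_header(position = origin, row_cosine = c(0, 1, 0),
               col_cosine = c(1, 0, 0), pixel_spacing = c(1, 1),
               rows = rows, cols = cols)
}

test_that("plane normals follow the DICOM cross-product convention", {
  pl <- plane_from_header(axial_header())
  expect_equal(pl$normal_cosine, c(0, 0, 1))

  # tilted 45 degrees in y-z: normal has no x component
  ph <- generate_validation_dataset()
  pld <- plane_from_header(ph$diagplane)
  expect_equal(pld$normal_cosine[1], 0)
  expect_equal(abs(pld$normal_cosine[2:3]), rep(1 / sqrt(2), 2),
               tolerance = 1e-12)

  # swapping the in-plane cosines negates the normal
  h <- axial_header()
  swapped <- slice_header(position = h$position, row_cosine = h$col_cosine,
                          col_cosine = h$row_cosine,
                          pixel_spacing = h$pixel_spacing,
                          rows = h$rows, cols = h$cols)
  expect_equal(plane_from_header(swapped)$normal_cosine,
               -plane_from_header(h)$normal_cosine)
})

test_that("pixel centers realize the affine pixel-to-patient map", {
  pl <- plane_from_header(axial_header())
  ctr <- pixel_centers(pl)
  expect_equal(dim(ctr), c(11, 11, 3))
  expect_equal(range(ctr[, , 1]), c(-5, 5))
  expect_equal(range(ctr[, , 2]), c(-5, 5))
  expect_true(all(ctr[, , 3] == 0))
  expect_equal(ctr[6, 6, ], c(0, 0, 0))

  one <- slice_header(position = c(3, 4, 5), row_cosine = c(0, 1, 0),
                      col_cosine = c(1, 0, 0), pixel_spacing = c(2, 2),
                      rows = 1, cols = 1)
  expect_equal(pixel_centers(plane_from_header(one))[1, 1, ], c(3, 4, 5))

  # one diagonal step on the 45-degree plane moves (0, 1, 1) in patient mm
  ph <- generate_validation_dataset()
  ctrd <- pixel_centers(plane_from_header(ph$diagplane))
  expect_equal(ctrd[6, 7, ] - ctrd[6, 6, ], c(0, 1, 1), tolerance = 1e-12)
  expect_equal(ctrd[6, 6, ], c(0, 0, 0), tolerance = 1e-12)
})

test_that("slice header and volume constructors validate their invariants", {
  expect_error(slice_header(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(1, 1), 4, 4),
               "orthogonal")
  expect_error(slice_header(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0), c(1, 1), 4, 4),
               "unit")
  expect_error(slice_header(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 1), 4, 4),
               "spacing")
  expect_error(volume_grid(array(c(1, NA), c(2, 2, 2)), c(0, 0, 0),
                           c(0, 1, 0), c(1, 0, 0), spacing = c(1, 1, 1)),
               "finite")
})

test_that("parallel stack reproduces the num and dist formulas", {
  s0 <- build_parallel_stack(0, 1)
  expect_identical(s0$num, 0L)
  expect_identical(s0$offsets, 0)

  s2 <- build_parallel_stack(2, 1)
  expect_identical(s2$num, 1L)
  expect_equal(s2$dist, 1)
  expect_equal(s2$offsets, c(-1, 0, 1))

  s423 <- build_parallel_stack(4.23, 1)
  expect_identical(s423$num, 2L)
  expect_equal(s423$dist, 1.0575)
  expect_equal(s423$offsets, c(-2.115, -1.0575, 0, 1.0575, 2.115))

  # non-unit through-plane resolution
  s7 <- build_parallel_stack(7, 1.25)
  expect_identical(s7$num, 3L)
  expect_equal(s7$dist, 7 / 6)

  expect_error(build_parallel_stack(-0.1, 1), "between 0 mm and 99.99")
  expect_error(build_parallel_stack(100, 1), "between 0 mm and 99.99")
  expect_error(build_parallel_stack(1, 0), "positive")

  # sub-resolution thickness degrades to the central slice, with a warning
  expect_warning(s <- build_parallel_stack(0.3, 1), "central slice")
  expect_identical(s$num, 0L)
  expect_identical(s$offsets, 0)
})

test_that("stack invariants hold across a fine thickness sweep", {
  z_res <- 1
  for (th in seq(0, 99.99, by = 0.37)) {
    st <- suppressWarnings(build_parallel_stack(th, z_res))
    expect_identical(st$num, as.integer(round_half_away(th / (2 * z_res))))
    # offsets symmetric about zero
    expect_equal(rev(-st$offsets), st$offsets)
    if (st$num > 0) {
      expect_equal(st$dist, th / (2 * st$num))
      expect_equal(range(st$offsets), c(-th / 2, th / 2))
    }
  }
  # num monotone non-decreasing in thickness
  nums <- vapply(seq(0, 20, by = 0.05), function(th)
    suppressWarnings(build_parallel_stack(th, 1.3))$num, integer(1))
  expect_true(all(diff(nums) >= 0))
  # thickness an even multiple of z_res gives dist == z_res exactly
  for (m in 1:6) {
    expect_identical(build_parallel_stack(2 * 1.25 * m, 1.25)$dist, 1.25)
  }
})

test_that("rounding in num is half away from zero, not banker's", {
  # thickness/(2 z_res) exactly 0.5, 1.5, 2.5 -> num 1, 2, 3
  expect_identical(build_parallel_stack(1, 1)$num, 1L)
  expect_identical(build_parallel_stack(3, 1)$num, 2L)
  expect_identical(build_parallel_stack(5, 1)$num, 3L)
})

test_that("volume_slice_header reproduces a native grid slice's geometry", {
  ph <- generate_validation_dataset()
  h <- volume_slice_header(ph$volume)  # middle slice, k = 6 -> z = 0
  expect_equal(h$position, c(-5, -5, 0))
  expect_equal(h$pixel_spacing, c(1, 1))
  expect_equal(h$slice_thickness, 1)
  h2 <- volume_slice_header(ph$volume, k = 1)
  expect_equal(h2$position, c(-5, -5, -5))
  expect_error(volume_slice_header(ph$volume, k = 12), "out of range")
})
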