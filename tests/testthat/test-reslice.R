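# The two-step interpolation: trilinear stack sampling and
# profile-weighted totalization.

test_that("stack samples land on grid planes for the validation phantom", {
  ph <- generate_validation_dataset()
  plane <- plane_from_header(ph$parplane)

  # 0 mm: the plane coincides with the z = 0 grid slice, values exact
  s0 <- sample_stack(ph$volume, plane, build_parallel_stack(0, 1))
  expect_true(all(s0$valid_mask))
  expect_equal(s0$values[, , 1], matrix(100, 11, 11))

  # 2 mm: the k = +/-1 slices land on the z = +/-1 grid planes
  s2 <- sample_stack(ph$volume, plane, build_parallel_stack(2, 1))
  expect_equal(s2$values[, , 1], matrix(80, 11, 11))
  expect_equal(s2$values[, , 2], matrix(100, 11, 11))
  expect_equal(s2$values[, , 3], matrix(80, 11, 11))

  # oblique plane: center pixel's +/-1 samples sit at z = -/+ 1/sqrt(2)
  sd2 <- sample_stack(ph$volume, plane_from_header(ph$diagplane),
                      build_parallel_stack(2, 1))
  expect_equal(sd2$values[6, 6, c(1, 3)], rep(100 - 20 / sqrt(2), 2),
               tolerance = 1e-12)

  # plane entirely outside the volume
  far <- slice_header(position = c(100, 100, 100), row_cosine = c(0, 1, 0),
                      col_cosine = c(1, 0, 0), pixel_spacing = c(1, 1),
                      rows = 4, cols = 4)
  expect_error(sample_stack(ph$volume, plane_from_header(far),
                            build_parallel_stack(0, 1)),
               "no overlap")
})

test_that("totalization is the rounded weighted mean over valid samples", {
  mk <- function(v, valid = rep(TRUE, length(v))) {
    structure(list(values = array(v, c(1, 1, length(v))),
                   valid_mask = array(valid, c(1, 1, length(v)))),
              class = "sampled_stack")
  }
  expect_identical(totalize(mk(c(80, 100, 80)), c(1, 1, 1))$values[1, 1], 87L)
  # constant samples give the constant back under any weighting
  expect_identical(totalize(mk(rep(42.4, 5)),
                            profile_weights("std_normal_2", 2))$values[1, 1],
                   42L)
  # invalid samples are excluded with weight renormalization
  r <- totalize(mk(c(999, 100, 80), c(FALSE, TRUE, TRUE)), c(1, 1, 1))
  expect_identical(r$values[1, 1], 90L)
  expect_equal(r$float_values[1, 1], 90)
  # a pixel with no valid sample becomes 0 and is tallied
  r2 <- totalize(mk(c(1, 2), c(FALSE, FALSE)), c(1, 1))
  expect_identical(r2$values[1, 1], 0L)
  expect_identical(r2$n_out_of_volume, 1L)
  expect_true(is.na(r2$float_values[1, 1]))
  # valid samples that all carry zero profile weight are likewise tallied
  # (happens at the volume boundary for profiles vanishing at the edges)
  r3 <- totalize(mk(c(5, 6, 7), c(TRUE, FALSE, TRUE)), c(0, 1, 0))
  expect_identical(r3$values[1, 1], 0L)
  expect_identical(r3$n_out_of_volume, 1L)
  expect_error(totalize(mk(c(1, 2, 3)), c(1, 1)), "one weight per")
})

test_that("reslice reproduces the phantom value law at 0 mm", {
  ph <- generate_validation_dataset()
  rp <- reslice(ph$volume, ph$parplane, 0)
  expect_true(all(rp$values == 100L))
  expect_identical(dim(rp$values), c(11L, 11L))

  ladder <- c(0, 20, 40, 60, 80, 100, 80, 60, 40, 20, 0)
  rper <- reslice(ph$volume, ph$perplane, 0)
  for (j in 1:11) expect_equal(rper$values[, j], ladder)
  rdiag <- reslice(ph$volume, ph$diagplane, 0)
  for (i in 1:11) expect_equal(rdiag$values[i, ], ladder)
})

test_that("reslice matches hand-calculable thickness cases", {
  ph <- generate_validation_dataset()
  expect_identical(reslice(ph$volume, ph$parplane, 2)$values,
                   matrix(87L, 11, 11))
  # diagplane center at 4.23 mm: mean of trilinear samples at
  # z = 0, +/- dist/sqrt(2), +/- 2 dist/sqrt(2)
  rd <- reslice(ph$volume, ph$diagplane, 4.23)
  expect_identical(rd$values[6, 6], 82L)
  d <- 4.23 / 4
  expect_equal(rd$float_values[6, 6],
               mean(100 - 20 * abs(c(0, -1, 1, -2, 2) * d / sqrt(2))),
               tolerance = 1e-12)
  # perplane: offsets move along y where the value law is constant
  expect_identical(reslice(ph$volume, ph$perplane, 4.23)$values,
                   reslice(ph$volume, ph$perplane, 0)$values)
})

test_that("constant volumes stay constant for every thickness and profile", {
  vol <- volume_grid(array(57, c(9, 9, 9)), origin = c(0, 0, 0),
                     row_cosine = c(0, 1, 0), col_cosine = c(1, 0, 0),
                     spacing = c(1, 1, 1),
                     provenance = list(series_uid = "const"))
  h <- slice_header(position = c(2, 2, 4.3), row_cosine = c(0, 1, 0),
                    col_cosine = c(1, 0, 0), pixel_spacing = c(0.8, 0.8),
                    rows = 5, cols = 5)
  for (th in c(0, 2, 5)) {
    for (pf in list_profiles()) {
      r <- suppressWarnings(reslice(vol, h, th, pf))
      expect_true(all(r$values == 57L), info = paste(th, pf))
    }
  }
})

test_that("a 0 mm reslice is bit-identical across all six profiles", {
  vol <- generate_edge_phantom(size = 24, n_slices = 24)
  h <- volume_slice_header(vol)
  imgs <- lapply(list_profiles(), function(pf)
    reslice(vol, h, 0, pf)$values)
  for (i in 2:length(imgs)) expect_identical(imgs[[i]], imgs[[1]])
})

test_that("a grid-coincident plane at 0 mm reproduces the slice exactly", {
  set.seed(42)
  cfg <- random_config()
  vol <- cfg$volume
  k <- sample(dim(vol$values)[3], 1)
  h <- volume_slice_header(vol, k = k)
  r <- reslice(vol, h, 0)
  expect_equal(r$float_values, vol$values[, , k], tolerance = 1e-12)
})

test_that("pre-rounding reslice values agree with the brute-force oracle", {
  set.seed(7)
  for (i in 1:30) {
    cfg <- random_config()
    got <- suppressWarnings(
      reslice(cfg$volume, cfg$header, cfg$thickness, "cosine_plus_1"))
    want <- brute_reslice_float(cfg$volume, cfg$header, cfg$thickness,
                                function(u) cos(pi * u) + 1)
    want[is.na(want)] <- NA_real_
    expect_equal(got$float_values, want, tolerance = 1e-9)
  }
})

test_that("flipping the plane normal leaves totalized values unchanged", {
  ph <- generate_validation_dataset()
  h <- ph$diagplane
  flipped <- slice_header(position = h$position, row_cosine = h$col_cosine,
                          col_cosine = h$row_cosine,
                          pixel_spacing = rev(h$pixel_spacing),
                          rows = h$cols, cols = h$rows,
                          slice_thickness = h$slice_thickness)
  for (pf in c("rectangular", "std_normal_2")) {
    a <- reslice(ph$volume, h, 2.82, pf)$values
    b <- reslice(ph$volume, flipped, 2.82, pf)$values
    expect_identical(b, t(a), info = pf)
  }
})

test_that("thickness presets resolve against reference tag and volume", {
  ph <- generate_validation_dataset()
  r <- reslice(ph$volume, ph$parplane, "reference_2d")
  expect_equal(r$thickness_used, 2)  # the phantom planes carry a 2 mm tag
  r2 <- reslice(ph$volume, ph$parplane, "volume_z")
  expect_equal(r2$thickness_used, 1)
  naref <- slice_header(position = c(-5, -5, 0), row_cosine = c(0, 1, 0),
                        col_cosine = c(1, 0, 0), pixel_spacing = c(1, 1),
                        rows = 11, cols = 11, slice_thickness = NA_real_)
  expect_error(reslice(ph$volume, naref, "reference_2d"), "SliceThickness")
  expect_error(reslice(ph$volume, ph$parplane, "nearest"), "preset")
  expect_error(reslice(ph$volume, ph$parplane, 150), "99.99")
})
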