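# Small numerical helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to the nearest integer with exact .5 ties going away from zero
#' (2.5 -> 3, -2.5 -> -3), i.e. everyday hand-calculation rounding rather
#' than the IEEE banker's rounding of [base::round()].
#'
#' @param x numeric vector.
#' @return numeric vector of integers (as doubles).
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 2.4))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Cross product of two 3-vectors.
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v^2))

# Check a pair of direction cosines: unit norm and mutual orthogonality.
check_cosines <- function(row_cosine, col_cosine, tol = 1e-4, what = "slice") {
  if (length(row_cosine) != 3L || length(col_cosine) != 3L) {
    stop("direction cosines must be 3-vectors", call. = FALSE)
  }
  if (abs(vnorm(row_cosine) - 1) > tol || abs(vnorm(col_cosine) - 1) > tol) {
    stop(sprintf("%s direction cosines are not unit vectors (tol %g)", what, tol),
         call. = FALSE)
  }
  if (abs(sum(row_cosine * col_cosine)) > tol) {
    stop(sprintf("%s direction cosines are not orthogonal (tol %g)", what, tol),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Quadrant swap that moves the zero-frequency FFT coefficient to the
# matrix centre (the usual fftshift).
fftshift2 <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  ri <- ((seq_len(nr) - 1L - nr %/% 2L) %% nr) + 1L
  ci <- ((seq_len(nc) - 1L - nc %/% 2L) %% nc) + 1L
  m[ri, ci, drop = FALSE]
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
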