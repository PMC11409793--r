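# Through-plane slice profiles: symmetric weight functions over the
# normalized offset u = k/num in [-1, 1]. An ideal acquisition has a
# rectangular profile; real scanner excitation profiles taper towards
# the slice edges, which the narrower shapes emulate. The weights are
# not normalized here -- normalization happens in the totalization
# denominator.

.profiles <- list(
  rectangular   = function(u) rep(1, length(u)),
  triangular    = function(u) 1 - abs(u),
  cosine_plus_1 = function(u) cos(pi * u) + 1,
  sinc          = function(u) ifelse(u == 0, 1, sin(pi * u) / (pi * u)),
  std_normal_2  = function(u) exp(-(2 * u)^2 / 2),
  std_normal_5  = function(u) exp(-(5 * u)^2 / 2)
)

#' Available slice profiles
#'
#' @return character vector of the six supported profile names.
#' @export
list_profiles <- function() names(.profiles)

#' Slice profile weight function
#'
#' @param name one of `rectangular`, `triangular`, `cosine_plus_1`,
#'   `sinc`, `std_normal_2`, `std_normal_5`.
#' @return an object of class `slice_profile`: a list with `name` and
#'   `weight(u)`, a symmetric non-negative function on [-1, 1] with
#'   `weight(0) > 0`.
#' @export
slice_profile <- function(name) {
  if (inherits(name, "slice_profile")) return(name)
  if (!is.character(name) || length(name) != 1 || !name %in% names(.profiles)) {
    stop("unknown slice profile ", deparse(name), "; valid names: ",
         paste(names(.profiles), collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, weight = .profiles[[name]]),
            class = "slice_profile")
}

#' Profile weights for a parallel-slice stack
#'
#' Evaluates the profile at the normalized offsets `k/num`,
#' `k = -num..num`. For `num == 0` (a 0 mm thickness) the single central
#' slice gets weight 1 and the profile is irrelevant by construction.
#'
#' @param profile a profile name or [slice_profile()].
#' @param num non-negative integer: parallel slices per side.
#' @return numeric vector of length `2*num + 1`.
#' @export
profile_weights <- function(profile, num) {
  profile <- slice_profile(profile)
  num <- as.integer(num)
  if (num < 0) stop("num must be non-negative", call. = FALSE)
  if (num == 0L) return(1)
  profile$weight((-num:num) / num)
}
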