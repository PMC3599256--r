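#' Round doubles to IEEE-754 binary32
#'
#' Rounds every element of `x` to the nearest representable single-precision
#' (binary32) value, using round-to-nearest-even, and returns the result as a
#' double vector.  This is the primitive behind the device-faithful numeric
#' mode: the emulated datapath applies it to the result of every add,
#' multiply, divide and compare-select before the value is consumed again.
#'
#' Values whose magnitude exceeds the binary32 range become `Inf`; subnormal
#' magnitudes are rounded to the nearest subnormal (or zero), exactly as a C
#' `(float)` cast would.
#'
#' @param x numeric vector.
#' @return double vector of the same length, each element exactly
#'   representable in binary32.
#' @export
#' @examples
#' round_b32(0.1) == 0.1          # FALSE: 0.1 is not representable
#' round_b32(0.5) == 0.5          # TRUE: powers of two are exact
round_b32 <- function(x) {
  y <- readBin(writeBin(as.double(x), raw(), size = 4L),
               what = "double", size = 4L, n = length(x))
  if (!is.null(dim(x))) dim(y) <- dim(x)
  y
}

#' Validate a numeric mode
#'
#' The package computes in one of two numeric modes: `"exact"` (double
#' precision throughout, true natural log) and `"device"` (every arithmetic
#' result rounded to binary32 before reuse, natural log replaced by the
#' segmented polynomial approximation of [approx_ln()]).
#'
#' @param mode character scalar, `"exact"` or `"device"`.
#' @return the validated mode string.
#' @export
as_numeric_mode <- function(mode) {
  if (!is.character(mode) || length(mode) != 1L || !mode %in% c("exact", "device"))
    stop("`mode` must be \"exact\" or \"device\"", call. = FALSE)
  mode
}

# Internal: assert all values finite (validation guard shared by the kernel).
check_finite <- function(x, what) {
  if (!all(is.finite(x)))
    stop(sprintf("non-finite value in %s", what), call. = FALSE)
  invisible(x)
}
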