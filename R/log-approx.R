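# Segmented polynomial approximation of the natural logarithm.
#
# The device datapath cannot afford a true ln().  Instead the positive reals
# are tiled into 16 segments whose width scales logarithmically (each segment
# spans a factor of 4, i.e. two octaves), a 4-step unrolled binary search on
# the argument selects the segment, and a degree-4 polynomial (5 coefficients,
# fitted at Chebyshev nodes) evaluates ln(x) within the segment via the power
# chain x, x^2, x^3, x^4.  Segment thresholds are powers of two: a hardware
# implementation compares binary32 exponent fields, so the search constants
# are 2^e rather than round decimal numbers.

#' Select the log-approximation segment for a positive argument
#'
#' Implements the literal 4-iteration logarithmic binary search of the device
#' log: the exponent probe starts at -16 and moves by 8, 4, 2, 1; the segment
#' index gains 8, 4, 2, 1 on each "greater-or-equal" branch.  Thresholds are
#' the powers `2^probe`, so segment `s` (for `1 <= s <= 14`) covers
#' `[2^(2s-32), 2^(2s-30))`, segment 0 covers everything below `2^-30` and
#' segment 15 everything at or above `2^-2`.
#'
#' @param x numeric vector of positive values.
#' @return integer vector of segment indices in `0:15`.
#' @seealso [derive_segment_bounds()], [approx_ln()]
#' @export
#' @examples
#' select_segment(0.5)    # 15
#' select_segment(2^-17)  # 7
select_segment <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop("select_segment() requires finite x > 0", call. = FALSE)
  probe <- rep(-16, length(x))
  seg <- rep(0L, length(x))
  probe_incr <- 8
  seg_incr <- 8L
  for (i in 1:4) {
    lower <- x < 2^probe
    probe <- ifelse(lower, probe - probe_incr, probe + probe_incr)
    seg <- seg + ifelse(lower, 0L, seg_incr)
    probe_incr <- probe_incr / 2
    seg_incr <- seg_incr %/% 2L
  }
  as.integer(seg)
}

#' Closed-form segment intervals of the device log
#'
#' Makes the geometry implied by [select_segment()] explicit: segment 0 is
#' `(0, 2^-30)`, segment `s` for `1 <= s <= 14` is `[2^(2s-32), 2^(2s-30))`
#' and segment 15 is `[2^-2, Inf)`.  The test suite checks these intervals
#' against a brute-force trace of the search on a dense log-uniform grid.
#'
#' @return data frame with columns `segment`, `lower`, `upper`
#'   (half-open intervals `[lower, upper)`; segment 0 is open at 0).
#' @export
derive_segment_bounds <- function() {
  s <- 0:15
  lower <- c(0, 2^(2 * (1:15) - 32))
  upper <- c(2^(2 * (0:14) - 30), Inf)
  data.frame(segment = s, lower = lower, upper = upper)
}

#' Fit the 16-segment Chebyshev log table
#'
#' Per segment, interpolates `ln(x)` at 5 Chebyshev nodes mapped to the
#' segment's intersection with `[fit_domain_floor, fit_domain_ceiling]`,
#' yielding a degree-4 polynomial in raw `x` (the device evaluates the power
#' chain on the argument itself, never on a rescaled variable).  The linear
#' solve is carried out in the scaled variable `u = x / lower` for
#' conditioning; the returned coefficients are in `x`.
#'
#' Kernel arguments (per-site scalers and root conditional likelihoods) lie
#' in `(0, 1]` once partials are max-normalized, so segment 15 is fitted on
#' `[2^-2, 1]` by default and segment 0 on `[floor, 2^-30]`.
#'
#' @param fit_domain_floor lower end of the validated domain
#'   (default `2^-32`, the bottom of the segment tiling).
#' @param fit_domain_ceiling upper end of the validated domain (default 1).
#' @return object of class `log_approx_table`: list with `coeffs` (16 x 5
#'   matrix, powers 0..4), `bounds` (the segment intervals), `residual`
#'   (per-segment max absolute fit error measured on a dense grid),
#'   `fit_domain` (length-2 numeric).
#' @export
fit_log_table <- function(fit_domain_floor = 2^-32, fit_domain_ceiling = 1) {
  if (!(fit_domain_floor > 0 && fit_domain_floor < 2^-30))
    stop("fit_domain_floor must be positive and below 2^-30", call. = FALSE)
  if (fit_domain_ceiling < 1)
    stop("fit_domain_ceiling must be >= 1", call. = FALSE)
  bounds <- derive_segment_bounds()
  coeffs <- matrix(0, 16L, 5L)
  residual <- numeric(16L)
  for (s in 0:15) {
    a <- max(bounds$lower[s + 1L], fit_domain_floor)
    b <- min(bounds$upper[s + 1L], fit_domain_ceiling)
    k <- 1:5
    t <- cos((2 * k - 1) / 10 * pi)
    u <- (1 + b / a) / 2 + (b / a - 1) / 2 * t   # Chebyshev nodes in x/a
    d <- solve(outer(u, 0:4, "^"), log(a * u))
    co <- d / a^(0:4)
    coeffs[s + 1L, ] <- co
    grid <- exp(seq(log(a), log(b), length.out = 512L))
    residual[s + 1L] <- max(abs(drop(outer(grid, 0:4, "^") %*% co) - log(grid)))
  }
  structure(list(coeffs = coeffs, bounds = bounds, residual = residual,
                 fit_domain = c(fit_domain_floor, fit_domain_ceiling)),
            class = "log_approx_table")
}

# Internal memoized default table (deterministic, so built once per session).
log_table_cache <- new.env(parent = emptyenv())

#' Default device log table
#'
#' The table produced by [fit_log_table()] with default domain, built once
#' and cached for the session (the fit is deterministic).
#'
#' @return a `log_approx_table`.
#' @export
default_log_table <- function() {
  if (is.null(log_table_cache$tab))
    log_table_cache$tab <- fit_log_table()
  log_table_cache$tab
}

#' Segmented polynomial natural log
#'
#' Evaluates the device approximation of `ln(x)`: segment selection by
#' [select_segment()], then `sum(coeff[s, i] * x^(i-1))` with the power chain
#' `x, x^2, x^3, x^4`.  In device mode every multiply and add in the chain is
#' rounded to binary32 (including the coefficients themselves), reproducing
#' the single-precision datapath bit for bit.
#'
#' Arguments outside the table's validated fit domain are allowed but
#' flagged with a warning: the polynomial extrapolates there.
#'
#' @param x numeric vector of positive values.
#' @param table a `log_approx_table`, default [default_log_table()].
#' @param mode numeric mode, `"exact"` (double evaluation of the same
#'   polynomial) or `"device"` (binary32 per-operation rounding).
#' @return numeric vector of approximate natural logs.
#' @export
#' @examples
#' approx_ln(0.25)            # close to log(0.25)
#' abs(approx_ln(0.7) - log(0.7)) < 3e-3
approx_ln <- function(x, table = default_log_table(), mode = "exact") {
  mode <- as_numeric_mode(mode)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("approx_ln() requires finite x > 0", call. = FALSE)
  dom <- table$fit_domain
  if (any(x < dom[1] | x > dom[2]))
    warning("approx_ln(): argument outside validated fit domain [",
            format(dom[1]), ", ", format(dom[2]), "]; extrapolating",
            call. = FALSE)
  co <- table$coeffs
  if (mode == "device") {
    r <- round_b32
    co <- r(co)
    x <- r(x)
    s <- select_segment(x) + 1L
    x2 <- r(x * x); x3 <- r(x2 * x); x4 <- r(x3 * x)
    acc <- r(co[s, 1L] + r(co[s, 2L] * x))
    acc <- r(acc + r(co[s, 3L] * x2))
    acc <- r(acc + r(co[s, 4L] * x3))
    r(acc + r(co[s, 5L] * x4))
  } else {
    s <- select_segment(x) + 1L
    x2 <- x * x; x3 <- x2 * x; x4 <- x3 * x
    ((((co[s, 1L] + co[s, 2L] * x) + co[s, 3L] * x2) + co[s, 4L] * x3) +
       co[s, 5L] * x4)
  }
}

#' Write / read a log table as structured text
#'
#' Serializes segment index, bounds and the 5 polynomial coefficients to a
#' tab-separated file (full double precision), and reads it back.  The table
#' is regenerated deterministically by [fit_log_table()]; the file format
#' exists for inspection and fixtures.
#'
#' @param table a `log_approx_table`.
#' @param path file path.
#' @return `write_log_table()` returns `path` invisibly; `read_log_table()`
#'   returns a `log_approx_table`.
#' @export
write_log_table <- function(table, path) {
  df <- data.frame(segment = 0:15,
                   lower = table$bounds$lower,
                   upper = table$bounds$upper,
                   c0 = table$coeffs[, 1], c1 = table$coeffs[, 2],
                   c2 = table$coeffs[, 3], c3 = table$coeffs[, 4],
                   c4 = table$coeffs[, 5])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# plfpipe log table; fit domain [%.17g, %.17g]",
                     table$fit_domain[1], table$fit_domain[2]), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  apply(df, 1L, function(r) writeLines(paste(sprintf("%.17g", r), collapse = "\t"), con))
  invisible(path)
}

#' @rdname write_log_table
#' @export
read_log_table <- function(path) {
  header <- readLines(path, n = 1L)
  dom <- as.numeric(strsplit(sub(".*\\[(.*)\\].*", "\\1", header), ", ")[[1]])
  df <- utils::read.table(path, header = TRUE, skip = 1L, sep = "\t")
  tab <- fit_log_table(dom[1], dom[2])   # bounds/residual re-derived
  tab$coeffs <- as.matrix(df[, c("c0", "c1", "c2", "c3", "c4")])
  dimnames(tab$coeffs) <- NULL
  tab
}
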