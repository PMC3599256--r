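# Segmented polynomial log: search trace, segment tiling, fit quality.

test_that("segment selection follows the literal 4-step binary search", {
  # hand-traced: every compare takes the >= branch for x = 0.5
  expect_identical(select_segment(0.5), 15L)
  expect_identical(select_segment(1), 15L)
  # hand-traced: >=2^-16, >=2^-24 is moot; path for 2^-17: <2^-16, >=2^-24,
  # >=2^-20, >=2^-18 -> segment 7
  expect_identical(select_segment(2^-17), 7L)
  # below every threshold
  expect_identical(select_segment(1e-40), 0L)
  # vectorized and piecewise-constant, non-decreasing
  xs <- exp(seq(log(2^-36), log(4), length.out = 4001))
  segs <- select_segment(xs)
  expect_true(all(diff(segs) >= 0L))
  expect_error(select_segment(0), "x > 0")
  expect_error(select_segment(-1), "x > 0")
})

test_that("closed-form segment bounds agree with brute-force search tracing", {
  bounds <- derive_segment_bounds()
  expect_identical(nrow(bounds), 16L)
  # tiling: contiguous half-open intervals covering (0, Inf)
  expect_identical(bounds$lower[-1], bounds$upper[-16])
  expect_identical(bounds$upper[16], Inf)
  # segment 15 starts at the final-level threshold 2^-2
  expect_identical(bounds$lower[16], 2^-2)
  # dense log-uniform grid: interval membership == literal search trace
  xs <- exp(seq(log(2^-35), log(2^2), length.out = 1e5))
  segs <- select_segment(xs)
  by_bounds <- findInterval(xs, bounds$lower[-1])  # 0..15
  expect_identical(segs, as.integer(by_bounds))
})

test_that("log table fit is deterministic and its residuals bound the error", {
  tab1 <- fit_log_table()
  tab2 <- fit_log_table()
  expect_identical(tab1$coeffs, tab2$coeffs)
  expect_identical(dim(tab1$coeffs), c(16L, 5L))
  # Chebyshev residual oracle: dense sampling of each fitted segment
  for (s in c(1L, 8L, 15L, 16L)) {
    a <- max(tab1$bounds$lower[s], tab1$fit_domain[1])
    b <- min(tab1$bounds$upper[s], tab1$fit_domain[2])
    grid <- exp(seq(log(a), log(b), length.out = 2000L))
    err <- abs(drop(outer(grid, 0:4, "^") %*% tab1$coeffs[s, ]) - log(grid))
    expect_lte(max(err), tab1$residual[s] * (1 + 1e-6))
  }
  # the segment-15 polynomial at x = 1 is within the segment's residual
  p15 <- sum(tab1$coeffs[16, ] * 1^(0:4))
  expect_lte(abs(p15 - 0), tab1$residual[16])
  expect_error(fit_log_table(fit_domain_floor = 1e-3), "below 2\\^-30")
})

test_that("approx_ln tracks the true log within the device error budget", {
  tab <- default_log_table()
  expect_identical(select_segment(0.25), 15L)
  expect_lt(abs(approx_ln(0.25) - log(0.25)) / abs(log(0.25)), 0.01)
  # 1e4 log-uniform samples over the validated domain; near the zero
  # crossing at x = 1 the error is measured against an absolute floor of 1
  set.seed(1)
  xs <- exp(runif(1e4, log(2^-32), log(1)))
  err_exact <- abs(approx_ln(xs) - log(xs)) / pmax(abs(log(xs)), 1)
  expect_lt(max(err_exact), 0.01)
  err_dev <- abs(approx_ln(xs, mode = "device") - log(xs)) / pmax(abs(log(xs)), 1)
  expect_lt(max(err_dev), 0.01)
  # segment-boundary discontinuities bounded by adjacent residuals
  bounds <- derive_segment_bounds()
  for (s in 2:15) {
    edge <- bounds$lower[s + 1]
    lo <- approx_ln(edge * (1 - 1e-7))
    hi <- approx_ln(edge)
    expect_lte(abs(hi - lo), tab$residual[s] + tab$residual[s + 1])
  }
  expect_warning(approx_ln(2^-40), "outside validated fit domain")
  expect_error(approx_ln(-1), "x > 0")
})

test_that("device-mode approx_ln rounds every step to binary32", {
  xs <- c(0.3, 0.07, 2^-9, 2^-21)
  v <- approx_ln(xs, mode = "device")
  expect_identical(v, round_b32(v))   # result representable in binary32
  # binary32 rounding is idempotent and exact on powers of two
  expect_identical(round_b32(round_b32(pi)), round_b32(pi))
  expect_identical(round_b32(2^-20), 2^-20)
})

test_that("log table serializes to text and back", {
  tab <- fit_log_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_log_table(tab, path)
  back <- read_log_table(path)
  expect_equal(back$coeffs, tab$coeffs, tolerance = 1e-15)
  expect_equal(back$fit_domain, tab$fit_domain)
})
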