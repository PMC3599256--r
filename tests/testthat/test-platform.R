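# Platform performance model: bandwidth chain, roofline, data layout,
# memory FSM.

test_that("peak bandwidth follows the MC -> AE -> board chain", {
  cfg <- platform_config()
  expect_equal(peak_bandwidth(cfg, "mc"), 2.4)
  expect_equal(peak_bandwidth(cfg, "ae"), 19.2)
  expect_equal(peak_bandwidth(cfg, "board"), 76.8)
  expect_error(platform_config(n_ae = 0), "positive")
})

test_that("memory efficiency is transactions per cycle", {
  expect_equal(memory_efficiency(50, 50, 100), 1.0)
  expect_equal(memory_efficiency(0, 0, 100), 0.0)
  expect_equal(memory_efficiency(30, 15, 100), 0.45)
  expect_error(memory_efficiency(1, 1, 0), "cycles")
})

test_that("roofline prediction reproduces the printed numbers", {
  ai <- arithmetic_intensity(130, 64)
  expect_equal(round(ai, 2), 2.03)
  expect_equal(round(predicted_throughput(ai, 76.8, 0.5)), 78)
  expect_equal(predicted_throughput(ai, 76.8, 0), 0)
  # linearity in each argument
  expect_equal(predicted_throughput(2 * ai, 76.8, 0.5),
               2 * predicted_throughput(ai, 76.8, 0.5))
  expect_equal(predicted_throughput(ai, 76.8 / 2, 0.5),
               predicted_throughput(ai, 76.8, 0.25))
  expect_error(predicted_throughput(ai, 76.8, 1.5), "eff")
})

test_that("scatter layout strides 64 bytes per PE and 512 bytes per AE", {
  x <- seq_len(1024)           # 2 full rounds of 4 AE x 8 PE x 16 elements
  map <- scatter_to_coprocessor(x)
  blk0 <- function(ae, pe) map$global_offset[map$ae == ae & map$pe == pe][1]
  expect_identical(blk0(1, 0) - blk0(0, 0), 512)
  expect_identical(blk0(0, 1) - blk0(0, 0), 64)
  # each PE block holds 16 elements (64 bytes) = 4 sites of a 4-state array
  expect_identical(sum(map$ae == 0 & map$pe == 0 & map$offset < 64), 16L)
  # bijection: gather inverts scatter, global offsets unique and contiguous
  expect_identical(gather_from_coprocessor(map), as.numeric(x))
  expect_identical(anyDuplicated(map$global_offset), 0L)
  expect_setequal(map$global_offset, (x - 1) * 4)
  expect_error(scatter_to_coprocessor(seq_len(100)), "multiple")
})

test_that("FSM trace issues LD1/LD2/LD3 per site and conserves traffic", {
  tr0 <- fsm_trace(0)
  expect_identical(nrow(tr0$trace), 0L)
  # FIFO deeper than the whole run: no interruption, unit efficiency
  tr <- fsm_trace(100)
  expect_identical(tr$interruptions, 0L)
  expect_equal(tr$efficiency, 1.0)
  expect_identical(tr$reads, 1000L)                 # 10 values per site
  expect_identical(tr$writes, 600L)                 # 6 values per site
  expect_identical(tr$read_cycles, 300L)            # 3 cycles per site
  expect_equal(tr$write_cycles, 150)                # 1.5 cycles per site
  expect_identical(tr$trace$state[1:6], c("LD1", "LD2", "LD3",
                                          "LD1", "LD2", "LD3"))
  # shallow threshold: load sequence interrupted by store bursts
  tr2 <- fsm_trace(100, output_fifo_almost_full = 10)
  expect_gt(tr2$interruptions, 0L)
  expect_identical(tr2$reads, 1000L)
  expect_identical(tr2$writes, 600L)
  expect_equal(tr2$efficiency, 1.0)                 # stall-free upper bound
  # every site's loads appear exactly once
  expect_identical(as.integer(table(tr2$trace$site)), rep(3L, 100))
})

test_that("platform config round-trips through the config file format", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# test platform", "n_ae 2", "clock_hz 100e6"), path)
  cfg <- read_platform_config(path)
  expect_identical(cfg$n_ae, 2)
  expect_equal(peak_bandwidth(cfg, "board"), 2 * 8 * 16 * 100e6 / 1e9)
  map <- scatter_to_coprocessor(seq_len(512))
  rep_path <- withr::local_tempfile(fileext = ".tsv")
  write_layout_report(map, rep_path)
  back <- utils::read.table(rep_path, header = TRUE, sep = "\t")
  expect_identical(nrow(back), 512L)
})
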