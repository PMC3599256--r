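# Data-flow-graph IR: canonical builders, op profiles, interpreter.

test_that("column DFG has the canonical shape and op profile", {
  g <- build_column_dfg()
  expect_length(g$inputs, 8L)
  expect_length(g$outputs, 1L)
  expect_identical(count_ops(g), c(add = 6L, mul = 9L, div = 0L, cmp = 0L))
  # identity-row constants: one-hot children evaluate to 1
  ev <- evaluate_dfg(g, c(1, 0, 0, 0, 1, 0, 0, 0))
  expect_identical(unname(ev$outputs), 1)
})

test_that("kernel DFG reproduces the printed op profile deterministically", {
  g1 <- build_kernel_dfg()
  g2 <- build_kernel_dfg()
  expect_identical(count_ops(g1), c(add = 38L, mul = 55L, div = 4L, cmp = 11L))
  expect_identical(count_ops(g1), count_ops(g2))
  expect_identical(vapply(g1$nodes, `[[`, "", "op"),
                   vapply(g2$nodes, `[[`, "", "op"))
  expect_length(g1$inputs, 10L)
  expect_length(g1$outputs, 6L)
  expect_false(is.na(g1$accumulator))
  # empty graph counts to zero
  empty <- plfpipe:::finish_dfg(plfpipe:::new_dfg_builder(),
                                integer(), integer())
  expect_identical(count_ops(empty), c(add = 0L, mul = 0L, div = 0L, cmp = 0L))
})

test_that("interpreter equals the fused site kernel bit for bit in device mode", {
  tipP <- update_transition_matrix(jc69_eigen(), 0.1)
  g <- build_kernel_dfg()
  set.seed(13)
  acc_sk <- 0; acc_dfg <- 0
  for (i in 1:100) {
    inp <- runif(10, 0.05, 1)
    sk <- site_kernel(tipP, tipP, inp[1:4], inp[5:8], inp[9], inp[10],
                      rep(0.25, 4), mode = "device", acc_in = acc_sk)
    ev <- evaluate_dfg(g, inp, mode = "device", acc_in = acc_dfg)
    expect_identical(unname(ev$outputs), c(sk$clP, sk$scP, sk$lnScaler_out))
    expect_identical(ev$acc, sk$acc_out)
    acc_sk <- sk$acc_out; acc_dfg <- ev$acc
  }
})

test_that("interpreter matches the site kernel to 1e-12 in exact mode", {
  tipP <- update_transition_matrix(jc69_eigen(), 0.25)
  g <- build_kernel_dfg(tipP, tipP)
  set.seed(19)
  for (i in 1:20) {
    inp <- runif(10, 0.05, 1)
    sk <- site_kernel(tipP, tipP, inp[1:4], inp[5:8], inp[9], inp[10],
                      rep(0.25, 4), mode = "exact")
    ev <- evaluate_dfg(g, inp, mode = "exact")
    expect_equal(unname(ev$outputs), c(sk$clP, sk$scP, sk$lnScaler_out),
                 tolerance = 1e-12)
  }
})

test_that("interpreter flags arity mismatches and division by zero", {
  g <- build_kernel_dfg()
  expect_error(evaluate_dfg(g, rep(0.5, 9)), "expected 10 inputs")
  expect_error(evaluate_dfg(g, rep(0, 10)), "division by zero at node")
})

test_that("DFGs serialize to structured text and back", {
  for (g in list(build_column_dfg(), build_kernel_dfg())) {
    path <- withr::local_tempfile(fileext = ".dfg")
    write_dfg(g, path)
    back <- read_dfg(path)
    expect_identical(count_ops(back), count_ops(g))
    expect_identical(back$inputs, g$inputs)
    expect_identical(back$outputs, g$outputs)
    set.seed(2)
    inp <- runif(length(g$inputs), 0.1, 1)
    expect_identical(evaluate_dfg(back, inp, "device")$outputs,
                     evaluate_dfg(g, inp, "device")$outputs)
  }
  # dot rendering emits one vertex per node
  g <- build_column_dfg()
  dot <- withr::local_tempfile(fileext = ".dot")
  write_dfg_dot(g, dot)
  expect_identical(sum(grepl("^  n[0-9]+ \\[", readLines(dot))),
                   length(g$nodes))
})
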