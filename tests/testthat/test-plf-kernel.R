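# Per-site likelihood kernel: PLF columns, rescaling, scaler bookkeeping,
# root accumulation, numeric-mode contracts.

test_that("compute_site_partials matches the direct double-precision form", {
  # identity transition preserves one-hot children
  expect_equal(compute_site_partials(diag(4), diag(4),
                                     c(1, 0, 0, 0), c(1, 0, 0, 0)),
               c(1, 0, 0, 0))
  # uniform transition rows x all-ones children: every sum of products is 1
  U <- matrix(0.25, 4, 4)
  expect_equal(compute_site_partials(U, U, rep(1, 4), rep(1, 4)), rep(1, 4))
  # random binary32 inputs vs an independent double evaluation
  set.seed(42)
  for (rep in 1:20) {
    tL <- matrix(round_b32(runif(16)), 4)
    tR <- matrix(round_b32(runif(16)), 4)
    cl <- round_b32(runif(4)); cr <- round_b32(runif(4))
    ref <- as.numeric((tL %*% cl) * (tR %*% cr))
    got <- compute_site_partials(tL, tR, cl, cr, mode = "device")
    expect_equal(got, ref, tolerance = 1e-5)
  }
  expect_error(compute_site_partials(diag(4), diag(4), c(Inf, 0, 0, 0), rep(1, 4)),
               "non-finite")
})

test_that("conservation: stochastic matrices keep partials in [0, 1]", {
  set.seed(7)
  for (rep in 1:20) {
    eig <- random_reversible_eigen()
    tL <- update_transition_matrix(eig, rexp(1, 5))
    tR <- update_transition_matrix(eig, rexp(1, 5))
    cl <- runif(4); cr <- runif(4)
    out <- compute_site_partials(tL, tR, cl, cr)
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("rescale_site max-normalizes and guards degenerate sites", {
  r <- rescale_site(c(0.5, 0.25, 0.1, 0.05))
  expect_equal(r$values, c(1, 0.5, 0.2, 0.1))
  expect_equal(r$scaler, 0.5)
  r2 <- rescale_site(c(1, 1, 1, 1))
  expect_equal(r2$values, rep(1, 4))
  expect_equal(r2$scaler, 1)
  expect_error(rescale_site(c(0, 0, 0, 0)), "degenerate site")
})

test_that("node updates accumulate log-scalers additively", {
  set.seed(11)
  n <- 32L
  clL <- partials_table(matrix(runif(4 * n), n), "tip")
  clR <- partials_table(matrix(runif(4 * n), n), "tip")
  P1 <- update_transition_matrix(jc69_eigen(), 0.2)
  sc <- scale_buffers(n)
  up1 <- update_partials_node(P1, P1, clL, clR, sc, "exact")
  # fresh buffers: lnScaler == scP after one node
  expect_identical(up1$scale$lnScaler, up1$scale$scP)
  # every output row max-normalized to exactly 1
  expect_true(all(apply(up1$partials$values, 1, max) == 1))
  # cascade a second node: lnScaler = scP1 + scP2
  scp1 <- up1$scale$scP
  up2 <- update_partials_node(P1, P1, up1$partials, clR, up1$scale, "exact")
  expect_equal(up2$scale$lnScaler, scp1 + up2$scale$scP, tolerance = 1e-12)
  # device mode keeps rows within one binary32 ulp of 1
  scd <- scale_buffers(n)
  upd <- update_partials_node(P1, P1, clL, clR, scd, "device")
  expect_true(all(abs(apply(upd$partials$values, 1, max) - 1) <= 2^-23))
})

test_that("root log-likelihood reproduces closed forms", {
  n <- 8L
  root <- partials_table(matrix(1, n, 4), "root")
  sc <- scale_buffers(n)
  expect_equal(root_log_likelihood(root, rep(0.25, 4), sc, rep(1, n)), 0)
  one <- partials_table(matrix(c(1, 0, 0, 0), 1, 4), "root")
  expect_equal(root_log_likelihood(one, rep(0.25, 4), scale_buffers(1), 2),
               2 * log(0.25))
  expect_error(root_log_likelihood(one, c(0.3, 0.3, 0.3, 0.3),
                                   scale_buffers(1), 1), "sum to 1")
  zero <- partials_table(matrix(c(0, 1, 0, 0), 1, 4), "root")
  expect_error(root_log_likelihood(zero, c(1 - 1e-12, 0, 0, 0),
                                   scale_buffers(1), 1), "degenerate site")
})

test_that("exact-mode lnL equals unscaled pruning and brute-force enumeration", {
  set.seed(23)
  for (n_taxa in c(3L, 5L, 8L)) {
    ds <- generate_dataset(synthetic_spec(n_taxa, n_sites = 10L,
                                          seed = 100L + n_taxa))
    files <- write_dataset_files(ds)
    res <- run_end_to_end(files$tree, files$alignment, mode = "exact")
    ref <- oracle_pruning_lnl(ds$tree$phylo, ds$alignment)
    expect_equal(res$lnl_exact, ref, tolerance = 1e-9)
    if (n_taxa <= 5L) {   # brute force is exponential in internal nodes
      ref_bf <- oracle_bruteforce_lnl(ds$tree$phylo, ds$alignment)
      expect_equal(res$lnl_exact, ref_bf, tolerance = 1e-9)
    }
  }
})

test_that("exact-mode lnL is invariant to rescaling on well-scaled inputs", {
  set.seed(31)
  for (rep in 1:5) {
    ds <- generate_dataset(synthetic_spec(4L + rep, n_sites = 64L,
                                          seed = 200L + rep))
    pat <- compress_patterns(ds$alignment)
    inst <- create_instance(ds$tree$n_tips, length(pat$weights), "exact")
    inst <- set_instance_data(inst, pat$patterns, ds$eigen$pi, pat$weights,
                              ds$eigen)
    on_ <- calculate_root_log_likelihood(update_partials(inst, ds$tree), ds$tree)
    off <- calculate_root_log_likelihood(
      update_partials(inst, ds$tree, rescale = FALSE), ds$tree)
    expect_equal(on_, off, tolerance = 1e-9)
  }
})

test_that("device and exact mode agree within 1 percent on synthetic data", {
  set.seed(5)
  worst <- 0
  for (rep in 1:6) {
    ds <- generate_dataset(synthetic_spec(4L + rep %% 5, n_sites = 128L,
                                          seed = 300L + rep))
    files <- write_dataset_files(ds)
    res <- run_end_to_end(files$tree, files$alignment)
    worst <- max(worst, res$rel_diff)
  }
  expect_lt(worst, 0.01)
})

test_that("partials round-trip through the plain-text format", {
  set.seed(3)
  pt <- partials_table(matrix(runif(40), 10), "root")
  path <- withr::local_tempfile(fileext = ".txt")
  write_partials(pt, path)
  back <- read_partials(path)
  expect_identical(back$role, "root")
  expect_equal(back$values, pt$values, tolerance = 1e-15)
})
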