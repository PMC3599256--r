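# Instance lifecycle, transition matrices, traversal, pattern compression,
# newick I/O.

test_that("instance creation allocates buffers and zeroed scalers", {
  inst <- create_instance(4, 128)
  expect_length(inst$partials, 7L)       # 4 tip + 3 internal
  expect_identical(inst$scale$lnScaler, numeric(128))
  expect_identical(inst$scale$scP, numeric(128))
  expect_error(create_instance(1, 10), "n_tips")
  expect_error(create_instance(4, 0), "n_patterns")
})

test_that("tip setters expand state codes and validate frequencies", {
  inst <- create_instance(2, 3)
  tips <- rbind(c("A", "N", "T"), c("C", "-", "G"))
  inst <- set_instance_data(inst, tips, rep(0.25, 4), c(1, 2, 1))
  expect_equal(inst$partials[[1]]$values[1, ], c(1, 0, 0, 0))
  expect_equal(inst$partials[[1]]$values[2, ], c(1, 1, 1, 1))
  expect_equal(inst$partials[[2]]$values[3, ], c(0, 0, 1, 0))
  expect_error(set_instance_data(inst, tips, c(0.3, 0.3, 0.3, 0.3), c(1, 1, 1)),
               "sum to 1")
  expect_error(set_instance_data(inst, tips, rep(0.25, 4), c(1, 0, 1)),
               "positive integers")
})

test_that("transition matrices honor the eigen-system", {
  eig <- jc69_eigen()
  expect_equal(update_transition_matrix(eig, 0), diag(4), tolerance = 1e-12)
  # JC69 closed form
  for (t in c(0.05, 0.3, 1.7)) {
    P <- update_transition_matrix(eig, t)
    expect_equal(diag(P), rep(0.25 + 0.75 * exp(-4 * t / 3), 4),
                 tolerance = 1e-10)
    expect_equal(P[1, 2], 0.25 - 0.25 * exp(-4 * t / 3), tolerance = 1e-10)
  }
  # random reversible models stay row-stochastic
  set.seed(17)
  for (rep in 1:10) {
    eigr <- random_reversible_eigen()
    P <- update_transition_matrix(eigr, rexp(1, 2))
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-9)
    expect_true(all(P >= 0 & P <= 1))
  }
  expect_error(update_transition_matrix(eig, -1), "branch length")
})

test_that("newick parsing is strict and round-trips", {
  tr <- parse_newick("((A:0.1,B:0.2):0.05,C:0.3);")
  expect_identical(tr$n_tips, 3L)
  expect_identical(nrow(tr$ops), 2L)
  expect_error(parse_newick("(A,B);"), "branch lengths")
  expect_error(parse_newick("(A:1,B:1,C:1);"), "binary")
  expect_error(parse_newick("((A:1,B:1"), "malformed")
  s <- write_newick(tr)
  tr2 <- parse_newick(s)
  expect_identical(tr2$tip_labels, tr$tip_labels)
  expect_equal(tr2$ops, tr$ops)
})

test_that("postorder operation lists visit children before parents", {
  set.seed(29)
  for (rep in 1:10) {
    ds <- generate_dataset(synthetic_spec(sample(3:10, 1), n_sites = 4L,
                                          seed = 400L + rep))
    ops <- ds$tree$ops
    done <- rep(FALSE, 2L * ds$tree$n_tips - 1L)
    done[seq_len(ds$tree$n_tips)] <- TRUE
    legal <- TRUE
    for (j in seq_len(nrow(ops))) {
      if (!done[ops$left[j]] || !done[ops$right[j]]) legal <- FALSE
      done[ops$parent[j]] <- TRUE
    }
    expect_true(legal)
    expect_true(all(done))
    # every internal node exactly once
    expect_identical(sort(ops$parent),
                     as.integer(ds$tree$n_tips + seq_len(ds$tree$n_tips - 1L)))
  }
})

test_that("traversal drives one kernel invocation per internal node", {
  ds <- generate_dataset(synthetic_spec(4, n_sites = 16L, seed = 8))
  pat <- compress_patterns(ds$alignment)
  inst <- create_instance(4, length(pat$weights))
  inst <- set_instance_data(inst, pat$patterns, rep(0.25, 4), pat$weights,
                            jc69_eigen())
  inst <- update_partials(inst, ds$tree)
  expect_identical(inst$n_kernel_calls, 3L)
  # lnScaler equals the sum of per-node scP contributions
  ln <- numeric(length(pat$weights))
  inst2 <- create_instance(4, length(pat$weights))
  inst2 <- set_instance_data(inst2, pat$patterns, rep(0.25, 4), pat$weights,
                             jc69_eigen())
  sc <- scale_buffers(length(pat$weights))
  for (j in seq_len(nrow(ds$tree$ops))) {
    op <- ds$tree$ops[j, ]
    tl <- update_transition_matrix(jc69_eigen(), op$t_left)
    tr <- update_transition_matrix(jc69_eigen(), op$t_right)
    res <- update_partials_node(tl, tr, inst2$partials[[op$left]],
                                inst2$partials[[op$right]],
                                scale_buffers(length(pat$weights)), "exact")
    inst2$partials[[op$parent]] <- res$partials
    ln <- ln + res$scale$scP
  }
  expect_equal(inst$scale$lnScaler, ln, tolerance = 1e-12)
})

test_that("all-ambiguous tips give zero log-likelihood at any 2-tip tree", {
  tr <- parse_newick("(A:0.2,B:0.7);")
  inst <- create_instance(2, 5)
  tips <- matrix("N", 2, 5, dimnames = list(c("A", "B"), NULL))
  inst <- set_instance_data(inst, tips, rep(0.25, 4), rep(1L, 5), jc69_eigen())
  inst <- update_partials(inst, tr)
  expect_equal(calculate_root_log_likelihood(inst, tr), 0)
})

test_that("lnL is invariant under re-rooting along the root edge", {
  set.seed(37)
  ds <- generate_dataset(synthetic_spec(6, n_sites = 64L, seed = 500))
  files <- write_dataset_files(ds)
  base <- run_end_to_end(files$tree, files$alignment, mode = "exact")$lnl_exact
  phy <- ds$tree$phylo
  e <- which(phy$edge[, 1] == ds$tree$root)
  delta <- phy$edge.length[e[1]] / 2
  phy$edge.length[e[1]] <- phy$edge.length[e[1]] - delta
  phy$edge.length[e[2]] <- phy$edge.length[e[2]] + delta
  moved <- file.path(files$dir, "moved.nwk")
  writeLines(ape::write.tree(phy), moved)
  shifted <- run_end_to_end(moved, files$alignment, mode = "exact")$lnl_exact
  expect_equal(shifted, base, tolerance = 1e-9)
})

test_that("lnL is nonpositive and deterministic across traversals", {
  ds <- generate_dataset(synthetic_spec(5, n_sites = 32L, seed = 600))
  pat <- compress_patterns(ds$alignment)
  inst <- create_instance(5, length(pat$weights))
  inst <- set_instance_data(inst, pat$patterns, rep(0.25, 4), pat$weights,
                            jc69_eigen())
  inst <- update_partials(inst, ds$tree)
  l1 <- calculate_root_log_likelihood(inst, ds$tree)
  expect_lte(l1, 0)
  inst <- reset_scale_factors(inst)
  inst <- update_partials(inst, ds$tree)
  expect_identical(calculate_root_log_likelihood(inst, ds$tree), l1)
})

test_that("exact mode agrees with an independent likelihood implementation", {
  skip_if_not_installed("phangorn")
  ds <- generate_dataset(synthetic_spec(6, n_sites = 200L, seed = 5))
  files <- write_dataset_files(ds)
  res <- run_end_to_end(files$tree, files$alignment, mode = "exact")
  fit <- phangorn::pml(ds$tree$phylo, phangorn::phyDat(ds$alignment,
                                                       type = "DNA"),
                       model = "JC")
  expect_equal(res$lnl_exact, as.numeric(stats::logLik(fit)), tolerance = 1e-8)
})

test_that("pattern compression conserves sites and multiplicities", {
  aln <- matrix(rep(c("A", "C"), each = 100), nrow = 2, byrow = TRUE)
  pat <- compress_patterns(aln)
  expect_identical(ncol(pat$patterns), 1L)
  expect_identical(pat$weights, 100L)
  set.seed(41)
  aln2 <- matrix(sample(c("A", "C", "G", "T"), 4 * 57, replace = TRUE), 4)
  pat2 <- compress_patterns(aln2)
  expect_identical(sum(pat2$weights), 57L)
  # all-distinct columns keep weight 1
  aln3 <- rbind(c("A", "C", "G"), c("A", "A", "A"))
  expect_identical(compress_patterns(aln3)$weights, c(1L, 1L, 1L))
  expect_error(compress_patterns(list()), "character matrix")
})

test_that("alignments read back identically from FASTA", {
  ds <- generate_dataset(synthetic_spec(4, n_sites = 50L, seed = 900))
  files <- write_dataset_files(ds)
  aln <- read_alignment(files$alignment)
  expect_identical(aln[ds$tree$tip_labels, ], ds$alignment)
})
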