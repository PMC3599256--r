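# Independent oracles used across the suite.  These deliberately avoid the
# package's own kernel/tree code paths: closed-form JC69 transition
# probabilities, a direct recursive pruning on the ape edge table, and a
# brute-force sum over ancestral state assignments.

# Closed-form JC69 transition matrix (no eigen-decomposition involved).
jc_p_oracle <- function(t) {
  same <- 0.25 + 0.75 * exp(-4 * t / 3)
  diff <- 0.25 - 0.25 * exp(-4 * t / 3)
  m <- matrix(diff, 4, 4)
  diag(m) <- same
  m
}

onehot_oracle <- function(code) {
  switch(code,
         A = c(1, 0, 0, 0), C = c(0, 1, 0, 0),
         G = c(0, 0, 1, 0), T = c(0, 0, 0, 1),
         c(1, 1, 1, 1))
}

# Unscaled double-precision Felsenstein pruning on an ape phylo, JC69,
# uniform frequencies.  alignment: character matrix with rownames.
oracle_pruning_lnl <- function(phy, alignment, weights = NULL) {
  n <- length(phy$tip.label)
  if (is.null(weights)) weights <- rep(1, ncol(alignment))
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  partial <- function(node, site) {
    if (node <= n) {
      return(onehot_oracle(alignment[phy$tip.label[node], site]))
    }
    e <- kids[[as.character(node)]]
    v <- rep(1, 4)
    for (ed in e) {
      child <- phy$edge[ed, 2]
      v <- v * (jc_p_oracle(phy$edge.length[ed]) %*% partial(child, site))
    }
    as.numeric(v)
  }
  lnl <- 0
  for (site in seq_len(ncol(alignment))) {
    lnl <- lnl + weights[site] * log(sum(0.25 * partial(n + 1L, site)))
  }
  lnl
}

# Brute-force likelihood: sum over every assignment of states to all
# internal nodes of prod(transition probs) * pi at the root.  JC69,
# uniform frequencies.  Exponential in internal-node count.
oracle_bruteforce_lnl <- function(phy, alignment, weights = NULL) {
  n <- length(phy$tip.label)
  if (is.null(weights)) weights <- rep(1, ncol(alignment))
  n_int <- phy$Nnode
  int_ids <- n + seq_len(n_int)
  P <- lapply(seq_len(nrow(phy$edge)), function(e) jc_p_oracle(phy$edge.length[e]))
  lnl <- 0
  grid <- as.matrix(expand.grid(rep(list(1:4), n_int)))
  for (site in seq_len(ncol(alignment))) {
    tipv <- lapply(seq_len(n), function(i)
      onehot_oracle(alignment[phy$tip.label[i], site]))
    total <- 0
    for (g in seq_len(nrow(grid))) {
      state <- integer(n + n_int)
      state[int_ids] <- grid[g, ]
      p <- 0.25            # root prior
      for (e in seq_len(nrow(phy$edge))) {
        par <- phy$edge[e, 1]; child <- phy$edge[e, 2]
        p <- p * if (child <= n) {
          sum(P[[e]][state[par], ] * tipv[[child]])
        } else P[[e]][state[par], state[child]]
      }
      total <- total + p
    }
    lnl <- lnl + weights[site] * log(total)
  }
  lnl
}

# Random small DFG over add/mul/cmp nodes (no div, to avoid zero
# denominators) for scheduler property tests.  Built through the package's
# internal builder so node ids stay topological.
random_small_dfg <- function(n_arith, n_inputs = 3L) {
  b <- plfpipe:::new_dfg_builder()
  ins <- vapply(seq_len(n_inputs), function(i)
    plfpipe:::bnode(b, "input", label = paste0("in", i)), integer(1))
  pool <- ins
  ops <- c("add", "mul", "cmp")
  last <- ins[1]
  for (k in seq_len(n_arith)) {
    op <- sample(ops, 1)
    opnds <- sample(pool, 2, replace = TRUE)
    last <- plfpipe:::bnode(b, op, opnds)
    pool <- c(pool, last)
  }
  out <- plfpipe:::bnode(b, "output", last)
  plfpipe:::finish_dfg(b, ins, out, name = "random")
}

# Small synthetic dataset written to temp files; returns paths + dataset.
write_dataset_files <- function(ds, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  nwk <- file.path(dir, "tree.nwk")
  fas <- file.path(dir, "aln.fasta")
  writeLines(ds$newick, nwk)
  write_alignment_fasta(ds$alignment, fas)
  list(tree = nwk, alignment = fas, dir = dir)
}
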