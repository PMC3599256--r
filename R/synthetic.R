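# Synthetic data: random rooted binary trees with exponential branch
# lengths and alignments evolved site-independently down the tree, so the
# whole stack is testable without external data.

#' Synthetic dataset specification
#'
#' Defaults emulate the platform's load-balanced workload: site counts in
#' multiples of 128 (so every processing element receives the same number
#' of sites) and exponential branch lengths with mean 0.1 expected
#' substitutions per site, a typical scale for within-family nucleotide
#' alignments.
#'
#' @param n_taxa number of tips (`>= 2`).
#' @param n_sites alignment length (default 128; any positive length is
#'   allowed for the software path -- the layout mapper enforces its own
#'   multiple).
#' @param bl_mean mean of the exponential branch-length distribution
#'   (substitutions/site).
#' @param model `"JC69"` or an [eigen_system()].
#' @param seed integer seed making every output reproducible.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_taxa, n_sites = 128L, bl_mean = 0.1,
                           model = "JC69", seed = 1L) {
  if (!(is.numeric(n_taxa) && n_taxa >= 2))
    stop("n_taxa must be >= 2", call. = FALSE)
  if (!(is.numeric(n_sites) && n_sites >= 1))
    stop("n_sites must be >= 1", call. = FALSE)
  if (bl_mean <= 0) stop("bl_mean must be positive", call. = FALSE)
  structure(list(n_taxa = as.integer(n_taxa), n_sites = as.integer(n_sites),
                 bl_mean = bl_mean, model = model, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic tree, alignment and eigen-system
#'
#' Draws a random rooted binary topology, exponential branch lengths, then
#' evolves each site independently down the tree: the root state from the
#' model's stationary frequencies, each child state from the parent's via
#' the edge's transition matrix ([update_transition_matrix()]).
#' Deterministic under the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `tree` (a `plf_tree`), `newick` (string), `alignment`
#'   (character matrix, rows named by tip labels), `eigen`
#'   (the [eigen_system()] used) and `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  eig <- if (inherits(spec$model, "eigen_system")) spec$model
         else if (identical(spec$model, "JC69")) jc69_eigen()
         else stop("model must be \"JC69\" or an eigen_system", call. = FALSE)
  phy <- ape::rtree(spec$n_taxa, rooted = TRUE, br = NULL,
                    tip.label = paste0("t", seq_len(spec$n_taxa)))
  phy$edge.length <- stats::rexp(nrow(phy$edge), rate = 1 / spec$bl_mean)
  tree <- as_plf_tree(phy)
  n_nodes <- 2L * spec$n_taxa - 1L
  states <- matrix(NA_integer_, n_nodes, spec$n_sites)
  root <- tree$root
  states[root, ] <- sample.int(4L, spec$n_sites, replace = TRUE, prob = eig$pi)
  # parents before children: walk the postorder operation list backwards
  for (j in rev(seq_len(nrow(tree$ops)))) {
    op <- tree$ops[j, ]
    for (side in c("left", "right")) {
      child <- op[[side]]
      P <- update_transition_matrix(eig, op[[paste0("t_", side)]])
      cum <- t(apply(P, 1L, cumsum))
      u <- stats::runif(spec$n_sites)
      # inverse-CDF draw per site, conditional on the parent state
      states[child, ] <- 1L + rowSums(cum[states[op$parent, ], , drop = FALSE] < u)
    }
  }
  aln <- matrix(c("A", "C", "G", "T")[states[seq_len(spec$n_taxa), ]],
                nrow = spec$n_taxa)
  rownames(aln) <- tree$tip_labels
  list(tree = tree, newick = write_newick(tree), alignment = aln,
       eigen = eig, spec = spec)
}

#' Write an alignment as FASTA
#'
#' @param alignment character matrix with row names.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(alignment))) {
    writeLines(paste0(">", rownames(alignment)[i]), con)
    writeLines(paste0(alignment[i, ], collapse = ""), con)
  }
  invisible(path)
}

#' Full likelihood evaluation in both numeric modes
#'
#' Executes the canonical call order -- set data, update transition
#' matrices, update partials, root log-likelihood -- on a tree and
#' alignment, in exact and device mode, and reports both values plus their
#' relative difference.
#'
#' @param tree_file newick file (strict rooted binary, branch lengths).
#' @param alignment_file FASTA or relaxed PHYLIP file.
#' @param mode `"both"` (default), `"exact"` or `"device"`.
#' @param report optional path; a plain-text report is written there.
#' @param eigen the substitution model (default [jc69_eigen()]).
#' @param pi state frequencies (default: the eigen-system's stationary
#'   frequencies).
#' @return list with `lnl_exact`, `lnl_device` (NA when not requested),
#'   `rel_diff`, `n_patterns`, `n_taxa`.
#' @export
run_end_to_end <- function(tree_file, alignment_file, mode = "both",
                           report = NULL, eigen = jc69_eigen(), pi = NULL) {
  txt <- tryCatch(suppressWarnings(paste(readLines(tree_file), collapse = "")),
                  error = function(e)
                    stop(sprintf("cannot read tree file '%s': %s",
                                 tree_file, conditionMessage(e)), call. = FALSE))
  tree <- parse_newick(txt)
  aln <- read_alignment(alignment_file)
  missing <- setdiff(tree$tip_labels, rownames(aln))
  if (length(missing))
    stop(sprintf("alignment '%s' lacks taxa: %s", alignment_file,
                 paste(missing, collapse = ", ")), call. = FALSE)
  aln <- aln[tree$tip_labels, , drop = FALSE]
  pat <- compress_patterns(aln)
  if (is.null(pi)) pi <- eigen$pi
  one_mode <- function(m) {
    inst <- create_instance(tree$n_tips, length(pat$weights), m)
    inst <- set_instance_data(inst, pat$patterns, pi, pat$weights, eigen)
    inst <- update_partials(inst, tree)
    calculate_root_log_likelihood(inst, tree)
  }
  lnl_exact <- if (mode %in% c("both", "exact")) one_mode("exact") else NA_real_
  lnl_device <- if (mode %in% c("both", "device")) one_mode("device") else NA_real_
  rel_diff <- if (mode == "both") abs(lnl_device - lnl_exact) / abs(lnl_exact)
              else NA_real_
  res <- list(lnl_exact = lnl_exact, lnl_device = lnl_device,
              rel_diff = rel_diff, n_patterns = length(pat$weights),
              n_taxa = tree$n_tips)
  if (!is.null(report)) {
    writeLines(c(sprintf("tree\t%s", tree_file),
                 sprintf("alignment\t%s", alignment_file),
                 sprintf("n_taxa\t%d", res$n_taxa),
                 sprintf("n_patterns\t%d", res$n_patterns),
                 sprintf("lnl_exact\t%.12g", res$lnl_exact),
                 sprintf("lnl_device\t%.12g", res$lnl_device),
                 sprintf("rel_diff\t%.6g", res$rel_diff)), report)
  }
  res
}
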