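# BEAGLE-style instance API: instance lifecycle, tip/frequency/weight
# setters, eigen-system transition matrices, postorder tree traversal
# driving the kernel, and the root log-likelihood call.

#' Construct an eigen-system for a substitution model
#'
#' Holds the spectral decomposition `Q = E diag(lambda) E^-1` of a 4x4
#' nucleotide rate matrix, from which per-edge transition matrices
#' `P(t) = E diag(exp(lambda t)) E^-1` are built.
#'
#' @param eigenvalues length-4 numeric.
#' @param eigenvectors,inverse_eigenvectors 4x4 matrices with
#'   `E %*% Einv` equal to the identity within 1e-8.
#' @param pi the stationary state frequencies of the model (carried along
#'   for convenience; default uniform).
#' @return object of class `eigen_system`.
#' @export
eigen_system <- function(eigenvalues, eigenvectors, inverse_eigenvectors,
                         pi = rep(0.25, 4)) {
  stopifnot(length(eigenvalues) == 4L,
            all(dim(eigenvectors) == c(4L, 4L)),
            all(dim(inverse_eigenvectors) == c(4L, 4L)))
  if (max(abs(eigenvectors %*% inverse_eigenvectors - diag(4))) > 1e-8)
    stop("eigenvectors %*% inverse_eigenvectors must be the identity (1e-8)",
         call. = FALSE)
  structure(list(eigenvalues = as.numeric(eigenvalues),
                 eigenvectors = eigenvectors,
                 inverse_eigenvectors = inverse_eigenvectors,
                 pi = pi),
            class = "eigen_system")
}

# Internal: eigen-system of a general time-reversible rate matrix with
# stationary frequencies pi and symmetric exchangeabilities (6 upper
# off-diagonal rates, order AC, AG, AT, CG, CT, GT), normalized so the mean
# substitution rate is 1 (branch lengths in expected substitutions/site).
gtr_eigen <- function(pi, rates, normalize = TRUE) {
  stopifnot(length(pi) == 4L, length(rates) == 6L, all(pi > 0), all(rates > 0))
  pi <- pi / sum(pi)
  S <- matrix(0, 4, 4)
  S[upper.tri(S)] <- rates
  S <- S + t(S)
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  if (normalize) Q <- Q / sum(pi * -diag(Q))
  # symmetrize: B = D^{1/2} Q D^{-1/2} has real spectrum
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  es <- eigen((B + t(B)) / 2, symmetric = TRUE)
  E <- diag(1 / d) %*% es$vectors
  Einv <- t(es$vectors) %*% diag(d)
  eigen_system(es$values, E, Einv, pi = pi)
}

#' Jukes-Cantor (JC69) eigen-system
#'
#' Uniform-rate nucleotide model normalized to one expected substitution per
#' unit branch length; eigenvalues are `0` and `-4/3` (multiplicity 3), and
#' `P_ii(t) = 1/4 + 3/4 exp(-4 t / 3)`.
#'
#' @return an [eigen_system()].
#' @export
jc69_eigen <- function() gtr_eigen(rep(0.25, 4), rep(1, 6))

#' Random reversible eigen-system
#'
#' Draws stationary frequencies from a Dirichlet (concentration `alpha`) and
#' exchangeabilities from an exponential, then builds the normalized GTR
#' eigen-system.  Uses the current RNG stream (set a seed for
#' reproducibility).
#'
#' @param alpha Dirichlet concentration for the frequencies (default 5, which
#'   keeps frequencies away from degenerate corners).
#' @return an [eigen_system()].
#' @export
random_reversible_eigen <- function(alpha = 5) {
  pi <- stats::rgamma(4, shape = alpha)
  pi <- pi / sum(pi)
  rates <- stats::rexp(6) + 0.1
  gtr_eigen(pi, rates)
}

#' Transition probability matrix from an eigen-system
#'
#' `P(t) = E diag(exp(lambda t)) E^-1`, with tiny negative entries produced
#' by rounding noise (more negative than -1e-12 is an error) clamped to 0
#' and entries marginally above 1 clamped to 1.
#'
#' @param eigen an [eigen_system()].
#' @param t branch length in expected substitutions per site (`t >= 0`).
#' @return 4x4 row-stochastic matrix (rows = parent state).
#' @export
#' @examples
#' update_transition_matrix(jc69_eigen(), 0)      # identity
#' rowSums(update_transition_matrix(jc69_eigen(), 0.3))
update_transition_matrix <- function(eigen, t) {
  stopifnot(inherits(eigen, "eigen_system"))
  if (!is.finite(t) || t < 0) stop("branch length must be finite and >= 0",
                                   call. = FALSE)
  P <- eigen$eigenvectors %*% diag(exp(eigen$eigenvalues * t)) %*%
    eigen$inverse_eigenvectors
  if (any(P < -1e-12) || any(P > 1 + 1e-12))
    stop("transition matrix entries outside [0,1] beyond rounding tolerance",
         call. = FALSE)
  P[P < 0] <- 0
  P[P > 1] <- 1
  P
}

#' Create a likelihood instance
#'
#' Allocates partials buffers for `n_tips` tip and `n_tips - 1` internal
#' nodes, zeroed scale buffers, and records the numeric mode.
#'
#' @param n_tips number of tips (`>= 2`).
#' @param n_patterns number of site patterns (`>= 1`).
#' @param mode numeric mode.
#' @return object of class `plf_instance`.
#' @export
create_instance <- function(n_tips, n_patterns, mode = "exact") {
  mode <- as_numeric_mode(mode)
  if (!(is.numeric(n_tips) && n_tips >= 2))
    stop("n_tips must be >= 2", call. = FALSE)
  if (!(is.numeric(n_patterns) && n_patterns >= 1))
    stop("n_patterns must be >= 1", call. = FALSE)
  n_tips <- as.integer(n_tips); n_patterns <- as.integer(n_patterns)
  structure(list(
    n_tips = n_tips, n_patterns = n_patterns, mode = mode,
    partials = vector("list", 2L * n_tips - 1L),
    tmatrices = vector("list", 2L * n_tips - 1L),
    pi = NULL, w = NULL, eigen = NULL,
    scale = scale_buffers(n_patterns),
    n_kernel_calls = 0L
  ), class = "plf_instance")
}

# State-code expansion: A,C,G,T one-hot; N and - fully ambiguous.
state_to_partials <- function(codes) {
  onehot <- rbind(A = c(1, 0, 0, 0), C = c(0, 1, 0, 0),
                  G = c(0, 0, 1, 0), T = c(0, 0, 0, 1),
                  N = c(1, 1, 1, 1), "-" = c(1, 1, 1, 1))
  codes <- toupper(codes)
  bad <- setdiff(unique(codes), rownames(onehot))
  if (length(bad))
    stop("unknown state code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  onehot[codes, , drop = FALSE]
}

#' Load tips, frequencies and weights into an instance
#'
#' Tips may be given as a character matrix of state codes (rows = taxa over
#' `A,C,G,T,N,-`; codes expand to one-hot partials, `N`/`-` to full
#' ambiguity) or as a list of `n_patterns x 4` partials matrices.
#'
#' @param inst a [create_instance()] object.
#' @param tips character matrix or list of partials matrices, one per tip.
#' @param pi length-4 state frequencies summing to 1 within 1e-6.
#' @param w pattern weights (positive integers).
#' @param eigen optional [eigen_system()] stored for traversal.
#' @return the updated instance.
#' @export
set_instance_data <- function(inst, tips, pi, w, eigen = NULL) {
  stopifnot(inherits(inst, "plf_instance"))
  if (abs(sum(pi) - 1) > 1e-6)
    stop("state frequencies must sum to 1 (1e-6)", call. = FALSE)
  if (any(w < 1) || any(w != round(w)))
    stop("pattern weights must be positive integers", call. = FALSE)
  if (length(w) != inst$n_patterns)
    stop("length(w) must equal n_patterns", call. = FALSE)
  if (is.matrix(tips) && is.character(tips)) {
    if (nrow(tips) != inst$n_tips || ncol(tips) != inst$n_patterns)
      stop("tip state matrix must be n_tips x n_patterns", call. = FALSE)
    tips <- lapply(seq_len(nrow(tips)), function(i) state_to_partials(tips[i, ]))
  }
  if (!is.list(tips) || length(tips) != inst$n_tips)
    stop("tips must be a list with one entry per tip", call. = FALSE)
  for (i in seq_along(tips)) {
    m <- as.matrix(tips[[i]])
    if (nrow(m) != inst$n_patterns || ncol(m) != 4L)
      stop("tip partials must be n_patterns x 4", call. = FALSE)
    inst$partials[[i]] <- partials_table(m, "tip")
  }
  inst$pi <- as.numeric(pi)
  inst$w <- as.numeric(w)
  if (!is.null(eigen)) inst$eigen <- eigen
  inst
}

#' Reset cumulative scale buffers
#'
#' Zeroes `scP` and `lnScaler`; done automatically at the start of every
#' full traversal by [update_partials()].
#'
#' @param inst a `plf_instance`.
#' @return the updated instance.
#' @export
reset_scale_factors <- function(inst) {
  inst$scale <- scale_buffers(inst$n_patterns)
  inst
}

#' Parse a strict rooted binary newick tree
#'
#' Branch lengths are mandatory (transition matrices are per-edge functions
#' of them) and polytomies are rejected (the kernel is a two-child PLF).
#' Node ids follow the convention tips `1..n`, internals `n+1..2n-1` with
#' the root at `n+1`.
#'
#' @param text newick string.
#' @return object of class `plf_tree`: list with `n_tips`, `tip_labels`,
#'   `ops` (postorder data frame: `parent`, `left`, `right`, `t_left`,
#'   `t_right`), `root`, and the underlying `ape::phylo` in `$phylo`.
#' @export
#' @examples
#' tr <- parse_newick("((A:0.1,B:0.2):0.05,C:0.3);")
#' nrow(tr$ops)  # 2 internal nodes
parse_newick <- function(text) {
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("malformed newick", call. = FALSE)
  as_plf_tree(phy)
}

# Internal: convert an ape phylo into the package's tree structure.
as_plf_tree <- function(phy) {
  if (is.null(phy$edge.length) || anyNA(phy$edge.length))
    stop("branch lengths are required on every edge", call. = FALSE)
  n <- length(phy$tip.label)
  if (n < 2L) stop("tree must have at least 2 tips", call. = FALSE)
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  if (any(vapply(kids, length, 1L) != 2L))
    stop("tree must be strictly binary (rooted, no polytomies)", call. = FALSE)
  # postorder over internal nodes: children before parents
  ord <- ape::reorder.phylo(phy, "postorder")
  internal <- unique(ord$edge[, 1])
  ops <- do.call(rbind, lapply(internal, function(node) {
    e <- kids[[as.character(node)]]
    data.frame(parent = node,
               left = phy$edge[e[1], 2], right = phy$edge[e[2], 2],
               t_left = phy$edge.length[e[1]], t_right = phy$edge.length[e[2]])
  }))
  structure(list(n_tips = n, tip_labels = phy$tip.label, ops = ops,
                 root = n + 1L, phylo = phy),
            class = "plf_tree")
}

#' Write a tree back to newick
#'
#' @param tree a `plf_tree`.
#' @param path optional file; if `NULL` the newick string is returned.
#' @return newick string (invisibly when writing to file).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "plf_tree"))
  s <- ape::write.tree(tree$phylo)
  if (!is.null(path)) { writeLines(s, path); return(invisible(s)) }
  s
}

#' Update partials for all internal nodes of a tree
#'
#' Resets the scale buffers, builds a per-edge transition matrix from the
#' instance's eigen-system, then runs the kernel node update
#' ([update_partials_node()]) for every postorder operation; the scale
#' buffers accumulate log-scalers across nodes.
#'
#' @param inst a `plf_instance` with tips, frequencies, weights and an
#'   eigen-system set.
#' @param tree a `plf_tree` whose tip order matches the tip buffers.
#' @param rescale logical; disable per-node rescaling only to verify the
#'   scaling invariance of the exact-mode likelihood.
#' @return the updated instance (internal partials filled, scale buffers
#'   current, `n_kernel_calls` counting node updates).
#' @export
update_partials <- function(inst, tree, rescale = TRUE) {
  stopifnot(inherits(inst, "plf_instance"), inherits(tree, "plf_tree"))
  if (tree$n_tips != inst$n_tips)
    stop("tree and instance disagree on the number of tips", call. = FALSE)
  if (is.null(inst$eigen)) stop("no eigen-system set", call. = FALSE)
  for (i in seq_len(inst$n_tips))
    if (is.null(inst$partials[[i]])) stop("tip partials not set", call. = FALSE)
  inst <- reset_scale_factors(inst)
  inst$n_kernel_calls <- 0L
  for (j in seq_len(nrow(tree$ops))) {
    op <- tree$ops[j, ]
    tipL <- update_transition_matrix(inst$eigen, op$t_left)
    tipR <- update_transition_matrix(inst$eigen, op$t_right)
    inst$tmatrices[[op$left]] <- tipL
    inst$tmatrices[[op$right]] <- tipR
    res <- update_partials_node(tipL, tipR,
                                inst$partials[[op$left]],
                                inst$partials[[op$right]],
                                inst$scale, inst$mode, rescale = rescale)
    res$partials$role <- if (op$parent == tree$root) "root" else "internal"
    inst$partials[[op$parent]] <- res$partials
    inst$scale <- res$scale
    inst$n_kernel_calls <- inst$n_kernel_calls + 1L
  }
  inst
}

#' Root log-likelihood of a traversed instance
#'
#' Delegates to [root_log_likelihood()] on the root buffer.
#'
#' @param inst a `plf_instance` after [update_partials()].
#' @param tree the `plf_tree` that was traversed.
#' @return scalar log-likelihood.
#' @export
calculate_root_log_likelihood <- function(inst, tree) {
  stopifnot(inherits(inst, "plf_instance"), inherits(tree, "plf_tree"))
  root <- inst$partials[[tree$root]]
  if (is.null(root)) stop("update_partials() has not been run", call. = FALSE)
  root_log_likelihood(root, inst$pi, inst$scale, inst$w, inst$mode)
}

#' Compress an alignment into site patterns and weights
#'
#' Collapses identical alignment columns into unique patterns with
#' multiplicities; the weights sum to the alignment length.
#'
#' @param alignment character matrix, rows = taxa, columns = sites, over
#'   `A,C,G,T,N,-` (case-insensitive).
#' @return list with `patterns` (character matrix of unique columns) and
#'   `weights` (integer multiplicities).
#' @export
compress_patterns <- function(alignment) {
  if (!is.matrix(alignment) || !is.character(alignment))
    stop("alignment must be a character matrix", call. = FALSE)
  alignment <- toupper(alignment)
  keys <- apply(alignment, 2L, paste0, collapse = "")
  first <- !duplicated(keys)
  idx <- match(keys, keys[first])
  list(patterns = alignment[, first, drop = FALSE],
       weights = as.integer(tabulate(idx, nbins = sum(first))))
}

#' Read a nucleotide alignment (FASTA or relaxed PHYLIP)
#'
#' @param path file path.
#' @param format `"auto"` (FASTA if the file starts with `>`), `"fasta"`
#'   or `"phylip"` (sequential).
#' @return character matrix, rows = taxa (named), columns = sites.
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(trimws(first), ">")) "fasta" else "phylip"
  }
  dna <- if (format == "fasta") ape::read.FASTA(path)
         else ape::read.dna(path, format = "sequential")
  m <- toupper(as.character(as.matrix(dna)))
  lens <- ncol(m)
  if (is.null(lens)) stop("ragged alignment", call. = FALSE)
  m
}

#' Dump instance state to structured text
#'
#' Writes dimensions, numeric mode, frequencies, weights, cumulative
#' log-scalers and the root partials (when present) to a plain-text file,
#' for fixtures and debugging.
#'
#' @param inst a `plf_instance`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
dump_instance <- function(inst, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("n_tips\t%d", inst$n_tips),
               sprintf("n_patterns\t%d", inst$n_patterns),
               sprintf("mode\t%s", inst$mode),
               sprintf("pi\t%s", paste(sprintf("%.17g", inst$pi), collapse = "\t")),
               sprintf("w\t%s", paste(inst$w, collapse = "\t")),
               sprintf("lnScaler\t%s",
                       paste(sprintf("%.17g", inst$scale$lnScaler), collapse = "\t"))),
             con)
  root <- inst$partials[[inst$n_tips + 1L]]
  if (!is.null(root))
    for (k in seq_len(nrow(root$values)))
      writeLines(sprintf("root\t%s",
                         paste(sprintf("%.17g", root$values[k, ]), collapse = "\t")), con)
  invisible(path)
}
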