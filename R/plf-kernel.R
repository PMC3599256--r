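# Per-site phylogenetic likelihood kernel: PLF column computation, max-based
# rescaling, log-scaler bookkeeping and weighted root log-likelihood
# accumulation.  Every routine runs in one of two numeric modes:
#   exact  - double precision, true ln()
#   device - every add/mul/div result rounded to binary32 before reuse,
#            ln() replaced by the segmented polynomial of approx_ln()

#' Construct a partials table
#'
#' A partials table holds per-site conditional likelihoods: an `n_sites x 4`
#' matrix of nonnegative finite values, one column per nucleotide state
#' (A, C, G, T), plus a role tag.
#'
#' @param values numeric matrix with 4 columns, finite and nonnegative.
#' @param role one of `"tip"`, `"internal"`, `"root"`.
#' @return object of class `partials_table` (list with `values`, `role`).
#' @export
partials_table <- function(values, role = c("internal", "tip", "root")) {
  role <- match.arg(role)
  values <- as.matrix(values)
  if (ncol(values) != 4L)
    stop("partials must have 4 columns (states A, C, G, T)", call. = FALSE)
  check_finite(values, "partials")
  if (any(values < 0)) stop("partials must be nonnegative", call. = FALSE)
  structure(list(values = values, role = role), class = "partials_table")
}

#' Construct zeroed scale buffers
#'
#' `scP` holds the log of the current node's per-site scaler; `lnScaler`
#' accumulates log-scalers additively over the nodes processed so far and is
#' initialized to zero.
#'
#' @param n_sites number of site patterns.
#' @return object of class `scale_buffers` (list with `scP`, `lnScaler`).
#' @export
scale_buffers <- function(n_sites) {
  structure(list(scP = numeric(n_sites), lnScaler = numeric(n_sites)),
            class = "scale_buffers")
}

#' One PLF column: combine two children at a single site
#'
#' Computes `clP[s] = (sum_x P_l[s,x] clL[x]) * (sum_y P_r[s,y] clR[y])` for
#' each parent state `s`, i.e. one column of the conditional likelihood
#' table.  Each sum-of-four-products is accumulated as a sequential chain
#' (three adds, no initial add to zero), matching the device pipeline.
#'
#' @param tipL,tipR 4x4 transition probability matrices (rows = parent
#'   state, columns = child state).
#' @param clL_site,clR_site length-4 child conditional likelihoods.
#' @param mode numeric mode (see [as_numeric_mode()]).
#' @return length-4 numeric vector of parent conditional likelihoods.
#' @export
#' @examples
#' compute_site_partials(diag(4), diag(4), c(1, 0, 0, 0), c(1, 0, 0, 0))
compute_site_partials <- function(tipL, tipR, clL_site, clR_site,
                                  mode = "exact") {
  mode <- as_numeric_mode(mode)
  check_finite(c(tipL, tipR, clL_site, clR_site), "compute_site_partials inputs")
  if (any(c(clL_site, clR_site) < 0))
    stop("child partials must be nonnegative", call. = FALSE)
  if (mode == "device") {
    r <- round_b32
    tipL <- r(tipL); tipR <- r(tipR)
    clL_site <- r(clL_site); clR_site <- r(clR_site)
  } else r <- identity
  sopL <- r(r(r(r(tipL[, 1] * clL_site[1]) + r(tipL[, 2] * clL_site[2])) +
               r(tipL[, 3] * clL_site[3])) + r(tipL[, 4] * clL_site[4]))
  sopR <- r(r(r(r(tipR[, 1] * clR_site[1]) + r(tipR[, 2] * clR_site[2])) +
               r(tipR[, 3] * clR_site[3])) + r(tipR[, 4] * clR_site[4]))
  r(sopL * sopR)
}

#' Max-normalize one site column
#'
#' The scaler is the maximum of the four entries, found by a chain of three
#' pairwise compares (ties keep the earlier state); each entry is divided by
#' it, so the maximum output is exactly 1.
#'
#' @param clP_site length-4 nonnegative vector with at least one positive
#'   entry.
#' @param mode numeric mode.
#' @return list with `values` (normalized 4-vector) and `scaler`.
#' @export
rescale_site <- function(clP_site, mode = "exact") {
  mode <- as_numeric_mode(mode)
  if (all(clP_site == 0))
    stop("degenerate site: all four conditional likelihoods are zero",
         call. = FALSE)
  r <- if (mode == "device") round_b32 else identity
  m <- clP_site[1]
  for (i in 2:4) if (m < clP_site[i]) m <- clP_site[i]
  list(values = r(clP_site / m), scaler = m)
}

# Internal vectorized node update over all sites of a pattern table.
# clL, clR: n x 4 matrices.  Returns list(values, scaler) with n x 4 / n.
plf_node_sites <- function(tipL, tipR, clL, clR, mode) {
  r <- if (mode == "device") round_b32 else identity
  if (mode == "device") {
    tipL <- r(tipL); tipR <- r(tipR); clL <- r(clL); clR <- r(clR)
  }
  n <- nrow(clL)
  clP <- matrix(0, n, 4L)
  for (s in 1:4) {
    sopL <- r(r(r(r(clL[, 1] * tipL[s, 1]) + r(clL[, 2] * tipL[s, 2])) +
                 r(clL[, 3] * tipL[s, 3])) + r(clL[, 4] * tipL[s, 4]))
    sopR <- r(r(r(r(clR[, 1] * tipR[s, 1]) + r(clR[, 2] * tipR[s, 2])) +
                 r(clR[, 3] * tipR[s, 3])) + r(clR[, 4] * tipR[s, 4]))
    clP[, s] <- r(sopL * sopR)
  }
  scaler <- clP[, 1]
  for (s in 2:4) {
    hit <- scaler < clP[, s]
    scaler[hit] <- clP[hit, s]
  }
  if (any(scaler == 0)) {
    k <- which(scaler == 0)[1]
    stop(sprintf("degenerate site %d: all four conditional likelihoods are zero", k),
         call. = FALSE)
  }
  list(values = r(clP / scaler), scaler = scaler)
}

#' Update partials for one internal node across all sites
#'
#' For every site: PLF column ([compute_site_partials()]), max-based
#' rescaling ([rescale_site()]), then scaler bookkeeping
#' `scP[k] = ln(scaler_k)` and additive accumulation
#' `lnScaler[k] <- lnScaler[k] + scP[k]`.
#'
#' @param tipL,tipR 4x4 transition matrices for the two child edges.
#' @param clL,clR child [partials_table()]s, site-aligned.
#' @param scale a [scale_buffers()] object carried across node updates.
#' @param mode numeric mode.
#' @param rescale logical; rescaling can be disabled to verify the scaling
#'   invariance of the exact-mode likelihood (the device pipeline always
#'   rescales).
#' @return list with `partials` (a `partials_table`, role `"internal"`) and
#'   `scale` (updated `scale_buffers`).
#' @export
update_partials_node <- function(tipL, tipR, clL, clR, scale, mode = "exact",
                                 rescale = TRUE) {
  mode <- as_numeric_mode(mode)
  stopifnot(inherits(clL, "partials_table"), inherits(clR, "partials_table"),
            inherits(scale, "scale_buffers"))
  if (nrow(clL$values) != nrow(clR$values) ||
      nrow(clL$values) != length(scale$lnScaler))
    stop("partials tables and scale buffers are not site-aligned", call. = FALSE)
  if (!rescale) {
    r <- if (mode == "device") round_b32 else identity
    out <- plf_node_sites_noscale(tipL, tipR, clL$values, clR$values, r)
    return(list(partials = partials_table(out, "internal"), scale = scale))
  }
  res <- plf_node_sites(tipL, tipR, clL$values, clR$values, mode)
  scP <- if (mode == "device") {
    approx_ln(res$scaler, mode = "device")
  } else log(res$scaler)
  r <- if (mode == "device") round_b32 else identity
  scale$scP <- scP
  scale$lnScaler <- r(scale$lnScaler + scP)
  list(partials = partials_table(res$values, "internal"), scale = scale)
}

# No-rescaling PLF (verification path only).
plf_node_sites_noscale <- function(tipL, tipR, clL, clR, r) {
  if (!identical(r, identity)) {
    tipL <- r(tipL); tipR <- r(tipR); clL <- r(clL); clR <- r(clR)
  }
  clP <- matrix(0, nrow(clL), 4L)
  for (s in 1:4) {
    sopL <- r(r(r(r(clL[, 1] * tipL[s, 1]) + r(clL[, 2] * tipL[s, 2])) +
                 r(clL[, 3] * tipL[s, 3])) + r(clL[, 4] * tipL[s, 4]))
    sopR <- r(r(r(r(clR[, 1] * tipR[s, 1]) + r(clR[, 2] * tipR[s, 2])) +
                 r(clR[, 3] * tipR[s, 3])) + r(clR[, 4] * tipR[s, 4]))
    clP[, s] <- r(sopL * sopR)
  }
  clP
}

#' Weighted root log-likelihood
#'
#' Returns `sum_k w[k] * (lnScaler[k] + ln(sum_s pi_s clP[k, s]))`, the tree
#' log-likelihood given an already rescaled root partials table and the
#' current cumulative log-scalers.  The ln is the true natural log in exact
#' mode and the segmented approximation in device mode; the outer sum is a
#' deterministic left-to-right reduction in site order.
#'
#' @param root root [partials_table()] (already max-normalized when
#'   rescaling is on).
#' @param pi length-4 state frequencies summing to 1 (within 1e-9).
#' @param scale current [scale_buffers()].
#' @param w integer pattern weights (all >= 1).
#' @param mode numeric mode.
#' @return scalar log-likelihood.
#' @export
root_log_likelihood <- function(root, pi, scale, w, mode = "exact") {
  mode <- as_numeric_mode(mode)
  stopifnot(inherits(root, "partials_table"), inherits(scale, "scale_buffers"))
  if (abs(sum(pi) - 1) > 1e-9)
    stop("state frequencies must sum to 1", call. = FALSE)
  if (any(w < 1)) stop("pattern weights must be >= 1", call. = FALSE)
  cl <- root$values
  n <- nrow(cl)
  if (length(w) != n || length(scale$lnScaler) != n)
    stop("weights/scale buffers not site-aligned with root partials", call. = FALSE)
  r <- if (mode == "device") round_b32 else identity
  if (mode == "device") { cl <- r(cl); pi <- r(pi); w <- r(w) }
  condLike <- r(r(r(r(pi[1] * cl[, 1]) + r(pi[2] * cl[, 2])) +
                   r(pi[3] * cl[, 3])) + r(pi[4] * cl[, 4]))
  if (any(condLike <= 0)) {
    k <- which(condLike <= 0)[1]
    stop(sprintf("degenerate site %d: root conditional likelihood <= 0", k),
         call. = FALSE)
  }
  lnc <- if (mode == "device") approx_ln(condLike, mode = "device") else log(condLike)
  term <- r(scale$lnScaler + lnc)
  contrib <- r(w * term)
  lnL <- 0
  for (k in seq_len(n)) lnL <- r(lnL + contrib[k])
  lnL
}

#' Fused per-site kernel (device reference computation)
#'
#' The per-site computation as the hardware pipeline performs it, fused in
#' one pass: PLF column, max scaler, normalization, `scP = ln(scaler)`,
#' `lnScaler' = lnScaler + scP`, root dot product with the state
#' frequencies, and the weighted likelihood contribution
#' `numSites * (lnScaler' + ln(condLike))` feeding the accumulator.  It
#' consumes the 10 per-site inputs (4 left + 4 right child likelihoods,
#' cumulative log-scaler, pattern weight) and produces the 6 per-site
#' outputs (4 normalized likelihoods, `scP`, updated `lnScaler`).  This is
#' the oracle the data-flow-graph interpreter and the pipeline simulator are
#' checked against, bit for bit in device mode.  Both modes evaluate the
#' segmented log polynomial (it is part of the device structure); `"exact"`
#' here means the same computation carried out in double precision.
#'
#' @param tipL,tipR 4x4 transition matrices (graph constants).
#' @param clL,clR length-4 child conditional likelihoods.
#' @param lnScaler_in cumulative log-scaler entering the site.
#' @param numSites pattern weight of the site.
#' @param pi length-4 state frequencies.
#' @param table log table for device mode.
#' @param mode numeric mode.
#' @param acc_in running log-likelihood accumulator value.
#' @return list with `clP` (4), `scP`, `lnScaler_out`, `contrib`, `acc_out`.
#' @export
site_kernel <- function(tipL, tipR, clL, clR, lnScaler_in, numSites, pi,
                        table = default_log_table(), mode = "device",
                        acc_in = 0) {
  mode <- as_numeric_mode(mode)
  r <- if (mode == "device") round_b32 else identity
  if (mode == "device") {
    tipL <- r(tipL); tipR <- r(tipR); clL <- r(clL); clR <- r(clR)
    lnScaler_in <- r(lnScaler_in); numSites <- r(numSites); pi <- r(pi)
  }
  clP <- numeric(4)
  for (s in 1:4) {
    sopL <- r(r(r(r(tipL[s, 1] * clL[1]) + r(tipL[s, 2] * clL[2])) +
                 r(tipL[s, 3] * clL[3])) + r(tipL[s, 4] * clL[4]))
    sopR <- r(r(r(r(tipR[s, 1] * clR[1]) + r(tipR[s, 2] * clR[2])) +
                 r(tipR[s, 3] * clR[3])) + r(tipR[s, 4] * clR[4]))
    clP[s] <- r(sopL * sopR)
  }
  scaler <- clP[1]
  for (s in 2:4) if (scaler < clP[s]) scaler <- clP[s]
  if (scaler == 0)
    stop("degenerate site: all four conditional likelihoods are zero",
         call. = FALSE)
  clP <- r(clP / scaler)
  # the fused kernel always evaluates the segmented polynomial (it is the
  # device structure); mode only controls per-operation rounding
  lg <- function(v) approx_ln(v, table, mode = mode)
  scP <- lg(scaler)
  lnScaler_out <- r(lnScaler_in + scP)
  condLike <- r(r(r(r(pi[1] * clP[1]) + r(pi[2] * clP[2])) +
                   r(pi[3] * clP[3])) + r(pi[4] * clP[4]))
  if (condLike <= 0)
    stop("degenerate site: root conditional likelihood <= 0", call. = FALSE)
  contrib <- r(numSites * r(lnScaler_out + lg(condLike)))
  list(clP = clP, scP = scP, lnScaler_out = lnScaler_out,
       contrib = contrib, acc_out = r(acc_in + contrib))
}

#' Write / read partials as plain text
#'
#' One site per line, four whitespace-separated values (full double
#' precision); a `# role:` header line records the table's role.
#'
#' @param pt a [partials_table()].
#' @param path file path.
#' @return `write_partials()` returns `path` invisibly; `read_partials()`
#'   returns a `partials_table`.
#' @export
write_partials <- function(pt, path) {
  stopifnot(inherits(pt, "partials_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# role: ", pt$role), con)
  utils::write.table(format(pt$values, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_partials
#' @export
read_partials <- function(path) {
  role <- sub("^# role: *", "", readLines(path, n = 1L))
  m <- as.matrix(utils::read.table(path, skip = 1L))
  dimnames(m) <- NULL
  partials_table(m, role)
}
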