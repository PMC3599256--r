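# Typed data-flow-graph IR for arithmetic kernels.
#
# Node ops: input, const, add, mul, div, cmp, select, output.
#   cmp(a, b)        -> 1 if a < b else 0
#   select(c, a, b)  -> a if c != 0 else b
# The graph is a DAG except for one designated accumulator node (the tree
# log-likelihood add), whose previous value feeds back one site later.
# Selects, constants, inputs and outputs are not floating-point operations;
# count_ops() counts only add/mul/div/cmp.

new_dfg_builder <- function() {
  b <- new.env(parent = emptyenv())
  b$nodes <- list()
  b
}

bnode <- function(b, op, operands = integer(), value = NA_real_, label = "") {
  id <- length(b$nodes) + 1L
  arity <- c(input = 0L, const = 0L, add = 2L, mul = 2L, div = 2L,
             cmp = 2L, select = 3L, output = 1L)[[op]]
  if (length(operands) != arity)
    stop(sprintf("op %s needs %d operands", op, arity), call. = FALSE)
  b$nodes[[id]] <- list(id = id, op = op, operands = as.integer(operands),
                        value = value, label = label)
  id
}

bconst <- function(b, value, label = "") bnode(b, "const", value = value, label = label)

# chain sum of a list of node ids: ((p1 + p2) + p3) + ... (no add to zero)
bchain_add <- function(b, ids, label = "") {
  acc <- ids[1]
  for (i in seq_along(ids)[-1]) acc <- bnode(b, "add", c(acc, ids[i]), label = label)
  acc
}

# binary mux tree over constant/value node ids keyed by cmp bits; cmp = 1
# selects the lower half (argument below threshold)
bmux <- function(b, cmps, values) {
  if (length(values) == 1L) return(values)
  half <- length(values) %/% 2L
  lo <- bmux(b, cmps[-1], values[seq_len(half)])
  hi <- bmux(b, cmps[-1], values[half + seq_len(half)])
  bnode(b, "select", c(cmps[1], lo, hi))
}

# Unrolled segmented-log block: 4 threshold compares (thresholds selected by
# the preceding compare bits), coefficient mux networks, power chain
# x, x^2, x^3, x^4, four coefficient products (c0 folded) and a 4-add chain.
# `coeff_ids` is a 16 x 5 matrix of const node ids shared across blocks.
blog_block <- function(b, x, coeff_ids, thresh_ids) {
  cmps <- integer(4)
  cmps[1] <- bnode(b, "cmp", c(x, thresh_ids[[1]][1]), label = "log_cmp")
  for (lvl in 2:4) {
    thr <- bmux(b, cmps[seq_len(lvl - 1L)], thresh_ids[[lvl]])
    cmps[lvl] <- bnode(b, "cmp", c(x, thr), label = "log_cmp")
  }
  co <- vapply(1:5, function(i) bmux(b, cmps, coeff_ids[, i]), integer(1))
  x2 <- bnode(b, "mul", c(x, x), label = "pow")
  x3 <- bnode(b, "mul", c(x2, x), label = "pow")
  x4 <- bnode(b, "mul", c(x3, x), label = "pow")
  p1 <- bnode(b, "mul", c(co[2], x))
  p2 <- bnode(b, "mul", c(co[3], x2))
  p3 <- bnode(b, "mul", c(co[4], x3))
  p4 <- bnode(b, "mul", c(co[5], x4))
  bchain_add(b, c(co[1], p1, p2, p3, p4), label = "log_sum")
}

# Threshold constants of the 4-level binary search (powers of two).
make_thresh_ids <- function(b) {
  exps <- list(-16,
               c(-24, -8),
               c(-28, -20, -12, -4),
               c(-30, -26, -22, -18, -14, -10, -6, -2))
  lapply(exps, function(e) vapply(e, function(k)
    bconst(b, 2^k, label = sprintf("thr_2^%d", k)), integer(1)))
}

make_coeff_ids <- function(b, table) {
  co <- table$coeffs
  ids <- matrix(0L, 16L, 5L)
  for (s in 1:16) for (i in 1:5)
    ids[s, i] <- bconst(b, co[s, i], label = sprintf("coef_s%d_p%d", s - 1L, i - 1L))
  ids
}

finish_dfg <- function(b, inputs, outputs, accumulator = NA_integer_,
                       name = "dfg") {
  structure(list(nodes = b$nodes, inputs = as.integer(inputs),
                 outputs = as.integer(outputs),
                 accumulator = as.integer(accumulator), name = name),
            class = "dfg")
}

#' Single-column PLF expression as a data-flow graph
#'
#' Encodes `clP[0] = (sum tipL[A,] * clL) * (sum tipR[A,] * clR)` with the 8
#' transition-table entries as graph constants: 8 inputs, 1 output, 9
#' multiplications and 6 additions (two 3-add chains).
#'
#' @param tipL_row,tipR_row length-4 constant rows of the transition tables
#'   (defaults give the identity row, so one-hot inputs evaluate to 1).
#' @return a `dfg`.
#' @export
build_column_dfg <- function(tipL_row = c(1, 0, 0, 0),
                             tipR_row = c(1, 0, 0, 0)) {
  b <- new_dfg_builder()
  inL <- vapply(1:4, function(i) bnode(b, "input", label = paste0("clL", i - 1)), integer(1))
  inR <- vapply(1:4, function(i) bnode(b, "input", label = paste0("clR", i - 1)), integer(1))
  cL <- vapply(1:4, function(i) bconst(b, tipL_row[i], paste0("tipL", i - 1)), integer(1))
  cR <- vapply(1:4, function(i) bconst(b, tipR_row[i], paste0("tipR", i - 1)), integer(1))
  pL <- vapply(1:4, function(i) bnode(b, "mul", c(cL[i], inL[i])), integer(1))
  sopL <- bchain_add(b, pL)
  pR <- vapply(1:4, function(i) bnode(b, "mul", c(cR[i], inR[i])), integer(1))
  sopR <- bchain_add(b, pR)
  clP <- bnode(b, "mul", c(sopL, sopR), label = "clP0")
  out <- bnode(b, "output", clP, label = "clP0")
  finish_dfg(b, c(inL, inR), out, name = "column")
}

#' Full per-site kernel as a data-flow graph
#'
#' The fused per-site computation of [site_kernel()]: 10 logical inputs
#' (4 left + 4 right child likelihoods, cumulative log-scaler, pattern
#' weight), 6 outputs (4 normalized likelihoods, `scP`, updated log-scaler),
#' and an internal feedback add accumulating the tree log-likelihood.
#' Transition-table entries, state frequencies, search thresholds and
#' polynomial coefficients are graph constants.  The construction follows
#' fixed conventions -- 3-add chains for every sum of four products, a
#' 3-compare/3-select max, two unrolled log blocks with shared constant
#' tables, additive scaler accumulation -- which yield the op profile
#' `add 38, mul 55, div 4, cmp 11`.
#'
#' @param tipL,tipR 4x4 constant transition matrices (default: JC69 at
#'   branch length 0.1).
#' @param pi length-4 state frequencies.
#' @param table log table whose coefficients become graph constants.
#' @return a `dfg` with `accumulator` set to the feedback add node.
#' @export
build_kernel_dfg <- function(tipL = update_transition_matrix(jc69_eigen(), 0.1),
                             tipR = update_transition_matrix(jc69_eigen(), 0.1),
                             pi = rep(0.25, 4),
                             table = default_log_table()) {
  b <- new_dfg_builder()
  inL <- vapply(1:4, function(i) bnode(b, "input", label = paste0("clL", i - 1)), integer(1))
  inR <- vapply(1:4, function(i) bnode(b, "input", label = paste0("clR", i - 1)), integer(1))
  inScale <- bnode(b, "input", label = "lnScaler")
  inW <- bnode(b, "input", label = "numSites")
  cL <- matrix(0L, 4, 4); cR <- matrix(0L, 4, 4)
  for (s in 1:4) for (j in 1:4) {
    cL[s, j] <- bconst(b, tipL[s, j], sprintf("tipL%d%d", s - 1, j - 1))
    cR[s, j] <- bconst(b, tipR[s, j], sprintf("tipR%d%d", s - 1, j - 1))
  }
  cPi <- vapply(1:4, function(i) bconst(b, pi[i], paste0("pi", i - 1)), integer(1))
  thresh_ids <- make_thresh_ids(b)
  coeff_ids <- make_coeff_ids(b, table)
  # PLF columns
  clP <- integer(4)
  for (s in 1:4) {
    pL <- vapply(1:4, function(j) bnode(b, "mul", c(cL[s, j], inL[j])), integer(1))
    sopL <- bchain_add(b, pL, label = "sopL")
    pR <- vapply(1:4, function(j) bnode(b, "mul", c(cR[s, j], inR[j])), integer(1))
    sopR <- bchain_add(b, pR, label = "sopR")
    clP[s] <- bnode(b, "mul", c(sopL, sopR), label = sprintf("clP%d", s - 1))
  }
  # max of four: 3 compares + 3 selects, ties keep the earlier state
  m <- clP[1]
  for (s in 2:4) {
    c_ <- bnode(b, "cmp", c(m, clP[s]), label = "max_cmp")
    m <- bnode(b, "select", c(c_, clP[s], m), label = "max_sel")
  }
  # normalize
  norm <- vapply(1:4, function(s)
    bnode(b, "div", c(clP[s], m), label = sprintf("norm%d", s - 1)), integer(1))
  # scP = ln(scaler); lnScaler' = lnScaler + scP
  scP <- blog_block(b, m, coeff_ids, thresh_ids)
  lnScalerOut <- bnode(b, "add", c(inScale, scP), label = "lnScaler_out")
  # condLike = sum pi_s * norm_s ; ln(condLike)
  q <- vapply(1:4, function(s) bnode(b, "mul", c(cPi[s], norm[s])), integer(1))
  condLike <- bchain_add(b, q, label = "condLike")
  lnc <- blog_block(b, condLike, coeff_ids, thresh_ids)
  t1 <- bnode(b, "add", c(lnScalerOut, lnc), label = "site_lnl")
  t2 <- bnode(b, "mul", c(inW, t1), label = "weighted")
  acc <- bnode(b, "add", c(t2, t2), label = "lnL_acc")  # 2nd operand = feedback
  b$nodes[[acc]]$operands <- c(t2, NA_integer_)         # mark feedback slot
  outs <- vapply(1:4, function(s)
    bnode(b, "output", norm[s], label = sprintf("clP%d", s - 1)), integer(1))
  outs <- c(outs, bnode(b, "output", scP, label = "scP"),
            bnode(b, "output", lnScalerOut, label = "lnScaler"))
  finish_dfg(b, c(inL, inR, inScale, inW), outs, accumulator = acc,
             name = "kernel")
}

#' Count floating-point operations in a data-flow graph
#'
#' Counts `add`, `mul`, `div` and `cmp` nodes only; selects, constants,
#' inputs and outputs are excluded (they are wiring, not arithmetic).
#'
#' @param g a `dfg`.
#' @return named integer vector `c(add, mul, div, cmp)`.
#' @export
#' @examples
#' count_ops(build_column_dfg())   # mul 9, add 6
count_ops <- function(g) {
  stopifnot(inherits(g, "dfg"))
  ops <- vapply(g$nodes, `[[`, "", "op")
  c(add = sum(ops == "add"), mul = sum(ops == "mul"),
    div = sum(ops == "div"), cmp = sum(ops == "cmp"))
}

#' Interpret a data-flow graph on one input tuple
#'
#' Topological-order interpretation (node creation order is topological by
#' construction).  In device mode every add/mul/div result -- and every
#' constant and input on entry -- is rounded to binary32, reproducing the
#' device datapath bit for bit.
#'
#' @param g a `dfg`.
#' @param inputs numeric vector matching the graph's input arity.
#' @param mode numeric mode.
#' @param acc_in running accumulator value entering this site (graphs with
#'   a feedback accumulator).
#' @return list with `outputs` (named numeric vector) and `acc` (the
#'   accumulator value after this site; `NA` if the graph has none).
#' @export
evaluate_dfg <- function(g, inputs, mode = "exact", acc_in = 0) {
  mode <- as_numeric_mode(mode)
  stopifnot(inherits(g, "dfg"))
  if (length(inputs) != length(g$inputs))
    stop(sprintf("expected %d inputs, got %d", length(g$inputs), length(inputs)),
         call. = FALSE)
  r <- if (mode == "device") round_b32 else identity
  vals <- numeric(length(g$nodes))
  inputs <- r(inputs)
  vals[g$inputs] <- inputs
  acc_out <- NA_real_
  for (nd in g$nodes) {
    v <- switch(nd$op,
      input = next,
      const = r(nd$value),
      add = {
        if (!is.na(g$accumulator) && nd$id == g$accumulator) {
          acc_out <- r(vals[nd$operands[1]] + acc_in)
          acc_out
        } else r(vals[nd$operands[1]] + vals[nd$operands[2]])
      },
      mul = r(vals[nd$operands[1]] * vals[nd$operands[2]]),
      div = {
        den <- vals[nd$operands[2]]
        if (den == 0)
          stop(sprintf("division by zero at node %d", nd$id), call. = FALSE)
        r(vals[nd$operands[1]] / den)
      },
      cmp = as.numeric(vals[nd$operands[1]] < vals[nd$operands[2]]),
      select = if (vals[nd$operands[1]] != 0) vals[nd$operands[2]]
               else vals[nd$operands[3]],
      output = vals[nd$operands[1]])
    vals[nd$id] <- v
  }
  outs <- vals[g$outputs]
  names(outs) <- vapply(g$nodes[g$outputs], `[[`, "", "label")
  list(outputs = outs, acc = acc_out)
}

#' Serialize / deserialize a data-flow graph as structured text
#'
#' One node per line: `node <id> <op> [value=...] [operands=a,b,c]
#' [label=...]`, plus header lines for inputs, outputs and the accumulator.
#'
#' @param g a `dfg`.
#' @param path file path.
#' @return `write_dfg()` returns `path` invisibly; `read_dfg()` a `dfg`.
#' @export
write_dfg <- function(g, path) {
  stopifnot(inherits(g, "dfg"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# plfpipe dfg v1",
               paste("name", g$name),
               paste("inputs", paste(g$inputs, collapse = ",")),
               paste("outputs", paste(g$outputs, collapse = ",")),
               paste("accumulator", if (is.na(g$accumulator)) "none" else g$accumulator)),
             con)
  for (nd in g$nodes) {
    parts <- c(sprintf("node %d %s", nd$id, nd$op))
    if (nd$op == "const") parts <- c(parts, sprintf("value=%.17g", nd$value))
    if (length(nd$operands))
      parts <- c(parts, paste0("operands=", paste(nd$operands, collapse = ",")))
    if (nzchar(nd$label)) parts <- c(parts, paste0("label=", nd$label))
    writeLines(paste(parts, collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_dfg
#' @export
read_dfg <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  field <- function(key) sub(paste0("^", key, " "), "",
                             lines[startsWith(lines, paste0(key, " "))][1])
  name <- field("name")
  inputs <- as.integer(strsplit(field("inputs"), ",")[[1]])
  outputs <- as.integer(strsplit(field("outputs"), ",")[[1]])
  accf <- field("accumulator")
  acc <- if (accf == "none") NA_integer_ else as.integer(accf)
  nodes <- list()
  for (ln in lines[startsWith(lines, "node ")]) {
    toks <- strsplit(ln, " ", fixed = TRUE)[[1]]
    id <- as.integer(toks[2]); op <- toks[3]
    value <- NA_real_; operands <- integer(); label <- ""
    for (t in toks[-(1:3)]) {
      if (startsWith(t, "value=")) value <- as.numeric(sub("value=", "", t))
      if (startsWith(t, "operands=")) {
        parts <- strsplit(sub("operands=", "", t), ",")[[1]]
        parts[parts == "NA"] <- NA_character_     # feedback slot
        operands <- as.integer(parts)
      }
      if (startsWith(t, "label=")) label <- sub("label=", "", t)
    }
    nodes[[id]] <- list(id = id, op = op, operands = operands,
                        value = value, label = label)
  }
  structure(list(nodes = nodes, inputs = inputs, outputs = outputs,
                 accumulator = acc, name = name), class = "dfg")
}

#' Render a data-flow graph to Graphviz dot text
#'
#' @param g a `dfg`.
#' @param path file path for the `.dot` text.
#' @return `path`, invisibly.
#' @export
write_dfg_dot <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("digraph %s {", g$name), con)
  for (nd in g$nodes) {
    lab <- if (nzchar(nd$label)) paste0(nd$op, "\\n", nd$label) else nd$op
    writeLines(sprintf("  n%d [label=\"%s\"];", nd$id, lab), con)
    for (o in nd$operands)
      if (!is.na(o)) writeLines(sprintf("  n%d -> n%d;", o, nd$id), con)
  }
  writeLines("}", con)
  invisible(path)
}
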