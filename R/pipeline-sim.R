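# Cycle-accurate simulation of a synthesized pipeline.
#
# The simulator is stall-free: it models the processing-element datapath
# only (operand delay lines, mux steering, binary32 functional units, the
# feedback accumulator); memory stalls belong to the platform model.  A new
# site enters every DII cycles, node `i` of site `s` fires at cycle
# `start_i + s * DII`, and the site's outputs complete at
# `latency + s * DII`, so n sites take `latency + (n-1) * DII` cycles.

#' Simulate a pipeline schedule on a stream of sites
#'
#' Drives the schedule cycle by cycle: each node fires at its scheduled
#' cycle (offset by site * DII), reads its operands through the routing
#' (mux) table recorded in the netlist, and applies its unit's operation --
#' rounded to binary32 in device mode.  The accumulator carries across
#' sites.  With an uncorrupted schedule the outputs equal
#' [evaluate_dfg()] bit for bit.
#'
#' @param sched a `pipeline_schedule` (from [asap_schedule()] or
#'   [parse_netlist()]).
#' @param g the `dfg` the schedule implements (node ops and constant
#'   values; operand wiring comes from the schedule's routing table).
#' @param site_stream numeric matrix, one row per site, columns matching
#'   the graph's inputs.
#' @param mode numeric mode.
#' @param trace_cap maximum number of per-firing trace records kept
#'   (default 10000; the cycle counting is exact regardless).
#' @return list with `outputs` (n_sites x n_outputs matrix), `acc`
#'   (accumulator value per site), `total_cycles`
#'   (`latency + (n-1) * DII`), `output_cycles` (completion cycle per
#'   site) and `trace` (data frame: cycle, node, op, unit, site, value).
#' @export
simulate_pipeline <- function(sched, g, site_stream, mode = "device",
                              trace_cap = 10000L) {
  mode <- as_numeric_mode(mode)
  stopifnot(inherits(sched, "pipeline_schedule"), inherits(g, "dfg"))
  if (sched$n_nodes != length(g$nodes))
    stop("schedule and DFG disagree on node count", call. = FALSE)
  ops <- vapply(g$nodes, `[[`, "", "op")
  if (!identical(ops, as.character(sched$nodes$op)))
    stop("schedule and DFG disagree on node ops", call. = FALSE)
  site_stream <- as.matrix(site_stream)
  n_sites <- nrow(site_stream)
  if (n_sites > 0 && ncol(site_stream) != length(g$inputs))
    stop("site_stream columns must match graph inputs", call. = FALSE)
  r <- if (mode == "device") round_b32 else identity
  n <- length(g$nodes)
  starts <- sched$nodes$start
  unit_lbl <- ifelse(is.na(sched$nodes$unit), NA_character_,
                     paste0(sched$nodes$op, sched$nodes$unit))
  const_val <- r(vapply(g$nodes, function(nd)
    if (nd$op == "const") nd$value else NA_real_, 0))
  out_mat <- matrix(NA_real_, n_sites, length(sched$outputs))
  colnames(out_mat) <- vapply(g$nodes[sched$outputs], `[[`, "", "label")
  acc_vec <- numeric(n_sites)
  acc <- 0
  trace <- vector("list", min(n_sites * n, trace_cap))
  tr <- 0L
  vals <- numeric(n)
  for (s in seq_len(n_sites)) {
    site_off <- (s - 1L) * sched$dii
    vals[g$inputs] <- r(site_stream[s, ])
    for (i in seq_len(n)) {
      op <- ops[i]
      if (op == "input") next
      rt <- sched$routing[[i]]
      v <- switch(op,
        const = const_val[i],
        add = {
          if (!is.na(sched$accumulator) && i == sched$accumulator) {
            acc <- r(vals[rt[1]] + acc)
            acc
          } else r(vals[rt[1]] + vals[rt[2]])
        },
        mul = r(vals[rt[1]] * vals[rt[2]]),
        div = {
          if (vals[rt[2]] == 0)
            stop(sprintf("division by zero at node %d, site %d", i, s),
                 call. = FALSE)
          r(vals[rt[1]] / vals[rt[2]])
        },
        cmp = as.numeric(vals[rt[1]] < vals[rt[2]]),
        select = if (vals[rt[1]] != 0) vals[rt[2]] else vals[rt[3]],
        output = vals[rt[1]])
      vals[i] <- v
      if (tr < trace_cap) {
        tr <- tr + 1L
        trace[[tr]] <- list(cycle = starts[i] + site_off, node = i, op = op,
                            unit = unit_lbl[i], site = s, value = v)
      }
    }
    out_mat[s, ] <- vals[sched$outputs]
    acc_vec[s] <- acc
  }
  total_cycles <- if (n_sites == 0) 0 else sched$latency + (n_sites - 1L) * sched$dii
  trace_df <- if (tr == 0L) {
    data.frame(cycle = numeric(), node = integer(), op = character(),
               unit = character(), site = integer(), value = numeric())
  } else {
    do.call(rbind, lapply(trace[seq_len(tr)], as.data.frame))
  }
  list(outputs = out_mat, acc = acc_vec, total_cycles = total_cycles,
       output_cycles = if (n_sites == 0) numeric() else
         sched$latency + (seq_len(n_sites) - 1L) * sched$dii,
       trace = trace_df)
}

#' Random-stream equivalence check: simulator vs interpreter
#'
#' Generates a seeded random site stream, runs both the cycle-accurate
#' simulator and the direct DFG interpreter, and requires bit-identical
#' outputs and accumulator values at every site.  On mismatch the report
#' locates the first differing site and node (with its cycle and unit).
#'
#' @param sched a `pipeline_schedule`.
#' @param g the `dfg` it implements.
#' @param n_sites number of random sites to stream.
#' @param seed RNG seed.
#' @param mode numeric mode.
#' @return list with `pass`, `n_sites`, and on failure `first_mismatch`
#'   (site, node, cycle, unit, simulated, expected).
#' @export
verify_equivalence <- function(sched, g, n_sites, seed = 1L,
                               mode = "device") {
  if (n_sites == 0)
    return(list(pass = TRUE, n_sites = 0L, first_mismatch = NULL))
  set.seed(seed)
  stream <- matrix(stats::runif(n_sites * length(g$inputs), 0.05, 1),
                   nrow = n_sites)
  sim <- simulate_pipeline(sched, g, stream, mode, trace_cap = 0L)
  acc <- 0
  for (s in seq_len(n_sites)) {
    ref <- evaluate_dfg(g, stream[s, ], mode, acc_in = acc)
    acc <- if (is.na(ref$acc)) acc else ref$acc
    ok_out <- identical(unname(sim$outputs[s, ]), unname(ref$outputs))
    ok_acc <- is.na(ref$acc) || identical(sim$acc[s], ref$acc)
    if (!ok_out || !ok_acc) {
      # locate the first node whose simulated value differs
      tr <- simulate_pipeline(sched, g, stream[seq_len(s), , drop = FALSE],
                              mode, trace_cap = s * length(g$nodes))
      site_tr <- tr$trace[tr$trace$site == s, ]
      ref_vals <- dfg_node_values(g, stream[s, ], mode,
                                  acc_in = if (s > 1) {
                                    a <- 0
                                    for (k in seq_len(s - 1)) {
                                      rk <- evaluate_dfg(g, stream[k, ], mode, a)
                                      if (!is.na(rk$acc)) a <- rk$acc
                                    }
                                    a
                                  } else 0)
      bad <- site_tr[abs(site_tr$value - ref_vals[site_tr$node]) > 0 |
                       xor(is.na(site_tr$value), is.na(ref_vals[site_tr$node])), ]
      fm <- if (nrow(bad)) bad[1, ] else
        list(site = s, node = NA, cycle = NA, unit = NA)
      return(list(pass = FALSE, n_sites = n_sites,
                  first_mismatch = list(site = s, node = fm$node,
                                        cycle = fm$cycle, unit = fm$unit)))
    }
  }
  list(pass = TRUE, n_sites = as.integer(n_sites), first_mismatch = NULL)
}

# Internal: per-node values of one interpreter pass (for mismatch location).
dfg_node_values <- function(g, inputs, mode, acc_in = 0) {
  r <- if (mode == "device") round_b32 else identity
  vals <- numeric(length(g$nodes))
  vals[g$inputs] <- r(inputs)
  for (nd in g$nodes) {
    v <- switch(nd$op,
      input = next,
      const = r(nd$value),
      add = if (!is.na(g$accumulator) && nd$id == g$accumulator)
              r(vals[nd$operands[1]] + acc_in)
            else r(vals[nd$operands[1]] + vals[nd$operands[2]]),
      mul = r(vals[nd$operands[1]] * vals[nd$operands[2]]),
      div = r(vals[nd$operands[1]] / vals[nd$operands[2]]),
      cmp = as.numeric(vals[nd$operands[1]] < vals[nd$operands[2]]),
      select = if (vals[nd$operands[1]] != 0) vals[nd$operands[2]]
               else vals[nd$operands[3]],
      output = vals[nd$operands[1]])
    vals[nd$id] <- v
  }
  vals
}

#' Dump a simulation trace to structured text
#'
#' Tab-separated `(cycle, node, op, unit, site, value)` records, bounded by
#' the simulator's `trace_cap`.
#'
#' @param sim result of [simulate_pipeline()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sim_trace <- function(sim, path) {
  utils::write.table(sim$trace, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
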