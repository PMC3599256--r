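# Throughput/resource-constrained pipeline synthesis.
#
# The data introduction interval (DII) is the number of cycles the pipeline
# needs to read one full input set through its physical ports; a new site
# enters every DII cycles, so two operations may share a functional unit iff
# their start cycles differ modulo DII.  The resource lower bound per
# operation type is ceil(M / DII) units for M operations of that type.

#' Operator latency/register table
#'
#' Per-operator pipeline latencies and slice-register costs of the
#' single-precision floating-point units the synthesizer instantiates, in a
#' low-latency and a max-latency profile.  Defaults: fadd 3 cycles/139
#' registers (low) vs 12/547 (max); fmul 3/87 vs 8/361; fdiv 11/499 vs
#' 28/1377; fcomp 1/2 vs 2/8.  The low-latency divider is fixed at 11
#' cycles, the depth needed to meet a 150 MHz clock.
#'
#' @param overrides optional data frame (columns as the default) replacing
#'   rows by `op`.
#' @return object of class `operator_spec`: data frame with columns `op`
#'   (add/mul/div/cmp), `unit`, `low_latency`, `low_registers`,
#'   `max_latency`, `max_registers`.
#' @export
operator_spec <- function(overrides = NULL) {
  spec <- data.frame(
    op = c("add", "mul", "div", "cmp"),
    unit = c("fadd", "fmul", "fdiv", "fcomp"),
    low_latency = c(3L, 3L, 11L, 1L),
    low_registers = c(139L, 87L, 499L, 2L),
    max_latency = c(12L, 8L, 28L, 2L),
    max_registers = c(547L, 361L, 1377L, 8L),
    stringsAsFactors = FALSE)
  if (!is.null(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      j <- match(overrides$op[i], spec$op)
      if (is.na(j)) stop("unknown op in overrides: ", overrides$op[i], call. = FALSE)
      for (col in intersect(names(overrides), names(spec)[-1]))
        spec[j, col] <- overrides[i, col]
    }
  }
  if (any(spec$low_latency > spec$max_latency))
    stop("low latency must not exceed max latency", call. = FALSE)
  structure(spec, class = c("operator_spec", "data.frame"))
}

#' Read an operator spec from a config file
#'
#' Tab-separated file with a header matching the columns of
#' [operator_spec()]; missing ops keep their defaults.
#'
#' @param path file path.
#' @return an `operator_spec`.
#' @export
read_operator_spec <- function(path) {
  operator_spec(utils::read.table(path, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE))
}

#' Data introduction interval
#'
#' `DII = ceil(logical_ports / physical_ports)`: the cycles needed to read
#' one full input set.  The kernel has 10 logical inputs on 4 physical
#' ports, hence DII 3.
#'
#' @param logical_ports number of logical input ports (values per site).
#' @param physical_ports number of physical input ports (values per cycle).
#' @return integer cycle count.
#' @export
#' @examples
#' compute_dii(10, 4)  # 3
compute_dii <- function(logical_ports, physical_ports) {
  if (!(logical_ports >= 1 && physical_ports >= 1))
    stop("port counts must be >= 1", call. = FALSE)
  as.integer(ceiling(logical_ports / physical_ports))
}

#' Minimum functional units for full throughput
#'
#' `R = ceil(M / DII)`: with one site entering every DII cycles, M
#' operations of a type need at least this many units.
#'
#' @param op_count number of operations of the type in the DFG.
#' @param dii data introduction interval in cycles.
#' @return integer unit count.
#' @export
#' @examples
#' min_functional_units(38, 3)  # 13 adders
#' min_functional_units(55, 3)  # 19 multipliers
min_functional_units <- function(op_count, dii) {
  if (dii < 1) stop("dii must be >= 1", call. = FALSE)
  as.integer(ceiling(op_count / dii))
}

# latency/register lookup helpers
spec_latency <- function(spec, op, profile)
  spec[[paste0(profile, "_latency")]][match(op, spec$op)]
spec_registers <- function(spec, op, profile)
  spec[[paste0(profile, "_registers")]][match(op, spec$op)]

#' ASAP modulo scheduling with functional-unit sharing
#'
#' Schedules every node of a data-flow graph at the earliest cycle where
#' (a) all operands are ready and (b) a functional unit of its type has a
#' free slot at that cycle modulo DII, allocating new units only while the
#' type's count is below `ceil(M/DII)` and otherwise deferring the node to
#' the next cycle with a free slot.  Ready nodes are served
#' first-come-first-served, ordered by (ready cycle, node id), which makes
#' the schedule deterministic.  Compares occupy a unit; the select fed by a
#' compare is combinational (zero latency, register cost only).  Input `k`
#' arrives at cycle `floor((k-1)/ports)` -- for the kernel this mirrors the
#' memory FSM: cycle 0 the four left likelihoods, cycle 1 the four right
#' likelihoods, cycle 2 the log-scaler and pattern weight.
#'
#' The designated feedback accumulator is legal only if its unit latency is
#' at most the DII (the previous site's value must be back in time);
#' otherwise synthesis fails naming the accumulator.
#'
#' @param g a `dfg`.
#' @param dii data introduction interval (cycles).
#' @param spec an [operator_spec()].
#' @param latency_profile `"low"` or `"max"`.
#' @param ports physical input ports; default `ceiling(n_inputs / dii)`.
#' @return object of class `pipeline_schedule`: node start/avail/unit
#'   binding table, unit table, input slot map, DII, pipeline latency,
#'   per-type resource usage, register estimate and the operand routing
#'   table used by the simulator.
#' @export
asap_schedule <- function(g, dii, spec = operator_spec(),
                          latency_profile = c("low", "max"), ports = NULL) {
  latency_profile <- match.arg(latency_profile)
  stopifnot(inherits(g, "dfg"))
  dii <- as.integer(dii)
  if (dii < 1) stop("dii must be >= 1", call. = FALSE)
  n <- length(g$nodes)
  ops <- vapply(g$nodes, `[[`, "", "op")
  if (is.null(ports)) ports <- as.integer(ceiling(length(g$inputs) / dii))
  counts <- count_ops(g)
  caps <- vapply(names(counts), function(o) min_functional_units(counts[[o]], dii),
                 integer(1))
  # unit occupancy: per type, list of integer vectors of occupied classes
  units <- list(add = list(), mul = list(), div = list(), cmp = list())
  start <- rep(NA_real_, n); avail <- rep(NA_real_, n)
  unit_of <- rep(NA_integer_, n)
  input_cycle <- floor((seq_along(g$inputs) - 1L) / ports)
  input_slot <- (seq_along(g$inputs) - 1L) %% ports + 1L
  arith <- ops %in% c("add", "mul", "div", "cmp")
  scheduled <- logical(n)
  # inputs/consts are immediately available
  for (k in seq_along(g$inputs)) {
    i <- g$inputs[k]
    start[i] <- avail[i] <- input_cycle[k]; scheduled[i] <- TRUE
  }
  for (i in which(ops == "const")) {
    start[i] <- avail[i] <- 0; scheduled[i] <- TRUE
  }
  lat <- c(add = spec_latency(spec, "add", latency_profile),
           mul = spec_latency(spec, "mul", latency_profile),
           div = spec_latency(spec, "div", latency_profile),
           cmp = spec_latency(spec, "cmp", latency_profile))
  acc_id <- g$accumulator
  repeat {
    todo <- which(!scheduled)
    if (!length(todo)) break
    ready_val <- rep(Inf, length(todo))
    for (j in seq_along(todo)) {
      i <- todo[j]
      opnd <- g$nodes[[i]]$operands
      opnd <- opnd[!is.na(opnd)]            # feedback slot excluded
      if (all(scheduled[opnd])) ready_val[j] <- max(0, avail[opnd])
    }
    j <- which.min(ready_val + todo / (n + 1))  # FCFS: ready cycle, then id
    i <- todo[j]; ready <- ready_val[j]
    op <- ops[i]
    if (!arith[i]) {                         # select / output: combinational
      start[i] <- avail[i] <- ready
    } else {
      placed <- FALSE
      for (delta in 0:(dii - 1L)) {
        st <- ready + delta
        cls <- st %% dii
        free <- which(vapply(units[[op]], function(u) !(cls %in% u), TRUE))
        if (length(free)) {
          u <- free[1]
          units[[op]][[u]] <- c(units[[op]][[u]], cls)
          start[i] <- st; unit_of[i] <- u; placed <- TRUE; break
        }
        if (length(units[[op]]) < caps[[op]]) {
          units[[op]][[length(units[[op]]) + 1L]] <- cls
          start[i] <- st; unit_of[i] <- length(units[[op]]); placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("internal scheduling failure: no slot within one DII window",
             call. = FALSE)
      avail[i] <- start[i] + lat[[op]]
    }
    scheduled[i] <- TRUE
  }
  if (!is.na(acc_id) && lat[["add"]] > dii)
    stop(sprintf("synthesis error: feedback accumulator '%s' needs adder latency <= DII (%d > %d)",
                 g$nodes[[acc_id]]$label, lat[["add"]], dii), call. = FALSE)
  latency <- max(avail[g$outputs])
  resources <- vapply(units, length, integer(1))
  unit_rows <- do.call(rbind, lapply(names(units), function(o) {
    if (!length(units[[o]])) return(NULL)
    data.frame(type = o, unit = seq_along(units[[o]]),
               latency = lat[[o]],
               registers = spec_registers(spec, o, latency_profile))
  }))
  nodes <- data.frame(id = seq_len(n), op = ops, start = start, avail = avail,
                      unit = unit_of)
  sched <- structure(list(
    graph_name = g$name, dii = dii, ports = ports,
    latency_profile = latency_profile, nodes = nodes,
    units = unit_rows, latency = latency, resources = resources,
    input_slots = data.frame(input = g$inputs, cycle = input_cycle,
                             slot = input_slot),
    routing = lapply(g$nodes, `[[`, "operands"),
    outputs = g$outputs, inputs = g$inputs, accumulator = acc_id,
    n_nodes = n), class = "pipeline_schedule")
  sched$registers <- estimate_registers(sched, spec)
  sched
}

#' Register estimate for a schedule
#'
#' Sum of the bound units' register costs plus 32 registers (one 32-bit
#' word) per cycle of operand skew -- the alignment delay between an
#' operand becoming available and its consumer starting.  Constant operands
#' are hard-wired and cost no delay registers.
#'
#' @param sched a `pipeline_schedule`.
#' @param spec the [operator_spec()] used to build it.
#' @return integer register count.
#' @export
estimate_registers <- function(sched, spec = operator_spec()) {
  stopifnot(inherits(sched, "pipeline_schedule"))
  unit_regs <- if (is.null(sched$units)) 0L else sum(sched$units$registers)
  skew <- 0
  nd <- sched$nodes
  is_const <- nd$op == "const"
  for (i in seq_len(nrow(nd))) {
    if (!nd$op[i] %in% c("add", "mul", "div", "cmp", "select")) next
    opnd <- sched$routing[[i]]
    opnd <- opnd[!is.na(opnd)]
    opnd <- opnd[!is_const[opnd]]
    skew <- skew + sum(nd$start[i] - nd$avail[opnd])
  }
  as.integer(unit_regs + 32 * skew)
}

#' Independent schedule legality checker
#'
#' Walks a schedule against its graph and verifies (a) every node starts no
#' earlier than each forward operand's availability, (b) no functional unit
#' serves two nodes whose start cycles are congruent modulo DII, (c) inputs
#' are not consumed before their port cycle and no more than `ports` inputs
#' share a cycle.  Written independently of the scheduler.
#'
#' @param sched a `pipeline_schedule`.
#' @param g the `dfg` it was built from.
#' @return list with `ok` (logical) and `violations` (character vector).
#' @export
check_schedule <- function(sched, g) {
  v <- character()
  nd <- sched$nodes
  for (i in seq_len(nrow(nd))) {
    opnd <- g$nodes[[i]]$operands
    opnd <- opnd[!is.na(opnd)]
    if (!length(opnd)) next
    bad <- opnd[nd$avail[opnd] > nd$start[i] + 1e-9]
    if (length(bad))
      v <- c(v, sprintf("node %d starts at %g before operand %d is ready (%g)",
                        i, nd$start[i], bad[1], nd$avail[bad[1]]))
  }
  arith <- nd$op %in% c("add", "mul", "div", "cmp")
  for (ty in unique(nd$op[arith])) {
    sel <- which(arith & nd$op == ty)
    key <- paste(nd$unit[sel], nd$start[sel] %% sched$dii)
    dup <- duplicated(key)
    if (any(dup))
      v <- c(v, sprintf("unit conflict: %s unit %d class %s", ty,
                        nd$unit[sel][dup][1],
                        (nd$start[sel] %% sched$dii)[dup][1]))
  }
  slots <- sched$input_slots
  if (any(table(slots$cycle) > sched$ports))
    v <- c(v, "more inputs in one cycle than physical ports")
  if (any(nd$start[slots$input] < slots$cycle))
    v <- c(v, "input consumed before its port cycle")
  list(ok = length(v) == 0L, violations = v)
}

#' Brute-force minimum unit usage for small graphs
#'
#' Exhaustively searches all per-node deferrals within one DII window
#' (deferring a node shifts its congruence class; offsets beyond DII-1
#' repeat classes) and returns, per operation type, the smallest number of
#' functional units any legal schedule needs.  Exponential in the number of
#' arithmetic nodes -- intended for graphs with at most ~8 of them.
#'
#' @param g a `dfg`.
#' @param dii data introduction interval.
#' @param spec an [operator_spec()].
#' @param latency_profile `"low"` or `"max"`.
#' @return named integer vector of per-type minima.
#' @export
brute_force_min_units <- function(g, dii, spec = operator_spec(),
                                  latency_profile = "low") {
  ops <- vapply(g$nodes, `[[`, "", "op")
  arith_ids <- which(ops %in% c("add", "mul", "div", "cmp"))
  if (length(arith_ids) > 10L)
    stop("brute force limited to <= 10 arithmetic nodes", call. = FALSE)
  lat <- c(add = spec_latency(spec, "add", latency_profile),
           mul = spec_latency(spec, "mul", latency_profile),
           div = spec_latency(spec, "div", latency_profile),
           cmp = spec_latency(spec, "cmp", latency_profile),
           select = 0, output = 0)
  n <- length(g$nodes)
  best <- c(add = Inf, mul = Inf, div = Inf, cmp = Inf)
  n_combo <- dii^length(arith_ids)
  for (combo in seq_len(n_combo) - 1L) {
    delay <- integer(n)
    c_ <- combo
    for (k in seq_along(arith_ids)) {
      delay[arith_ids[k]] <- c_ %% dii
      c_ <- c_ %/% dii
    }
    avail <- numeric(n)
    for (i in seq_len(n)) {
      nd <- g$nodes[[i]]
      if (nd$op %in% c("input", "const")) { avail[i] <- 0; next }
      opnd <- nd$operands[!is.na(nd$operands)]
      st <- (if (length(opnd)) max(avail[opnd]) else 0) + delay[i]
      avail[i] <- st + (if (nd$op %in% names(lat)) lat[[nd$op]] else 0)
      delay[i] <- st                        # reuse as start
    }
    for (ty in c("add", "mul", "div", "cmp")) {
      sel <- arith_ids[ops[arith_ids] == ty]
      if (!length(sel)) { best[[ty]] <- min(best[[ty]], 0); next }
      need <- max(table(delay[sel] %% dii))
      best[[ty]] <- min(best[[ty]], need)
    }
  }
  storage.mode(best) <- "integer"
  best
}

#' Emit / parse a textual netlist
#'
#' Deterministic structured-text description of a schedule: DII, ports,
#' latency, functional units, per-node start/binding and the operand
#' routing (mux) table.  `parse_netlist()` reconstructs an equivalent
#' schedule object.
#'
#' @param sched a `pipeline_schedule`.
#' @param path file path.
#' @return `emit_netlist()` returns `path` invisibly; `parse_netlist()` a
#'   `pipeline_schedule` (without register estimate recomputation).
#' @export
emit_netlist <- function(sched, path) {
  stopifnot(inherits(sched, "pipeline_schedule"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# plfpipe netlist v1",
               paste("name", sched$graph_name),
               paste("dii", sched$dii),
               paste("ports", sched$ports),
               paste("latency_profile", sched$latency_profile),
               paste("latency", sched$latency),
               paste("registers", sched$registers),
               paste("accumulator",
                     if (is.na(sched$accumulator)) "none" else sched$accumulator),
               paste("inputs", paste(sched$inputs, collapse = ",")),
               paste("outputs", paste(sched$outputs, collapse = ","))), con)
  if (!is.null(sched$units))
    for (i in seq_len(nrow(sched$units)))
      writeLines(sprintf("unit %s %d latency %d registers %d",
                         sched$units$type[i], sched$units$unit[i],
                         sched$units$latency[i], sched$units$registers[i]), con)
  for (i in seq_len(nrow(sched$input_slots)))
    writeLines(sprintf("slot %d cycle %d port %d",
                       sched$input_slots$input[i], sched$input_slots$cycle[i],
                       sched$input_slots$slot[i]), con)
  nd <- sched$nodes
  for (i in seq_len(nrow(nd))) {
    route <- sched$routing[[i]]
    writeLines(sprintf("node %d %s start %g avail %g unit %s route %s",
                       nd$id[i], nd$op[i], nd$start[i], nd$avail[i],
                       if (is.na(nd$unit[i])) "-" else nd$unit[i],
                       if (length(route)) paste(ifelse(is.na(route), "F", route),
                                                collapse = ",") else "-"), con)
  }
  invisible(path)
}

#' @rdname emit_netlist
#' @export
parse_netlist <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  field <- function(key) sub(paste0("^", key, " "), "",
                             lines[startsWith(lines, paste0(key, " "))][1])
  unit_lines <- lines[startsWith(lines, "unit ")]
  units <- if (length(unit_lines)) do.call(rbind, lapply(unit_lines, function(ln) {
    t <- strsplit(ln, " ")[[1]]
    data.frame(type = t[2], unit = as.integer(t[3]),
               latency = as.integer(t[5]), registers = as.integer(t[7]))
  })) else NULL
  slot_lines <- lines[startsWith(lines, "slot ")]
  slots <- do.call(rbind, lapply(slot_lines, function(ln) {
    t <- strsplit(ln, " ")[[1]]
    data.frame(input = as.integer(t[2]), cycle = as.integer(t[4]),
               slot = as.integer(t[6]))
  }))
  node_lines <- lines[startsWith(lines, "node ")]
  nodes <- do.call(rbind, lapply(node_lines, function(ln) {
    t <- strsplit(ln, " ")[[1]]
    data.frame(id = as.integer(t[2]), op = t[3], start = as.numeric(t[5]),
               avail = as.numeric(t[7]),
               unit = if (t[9] == "-") NA_integer_ else as.integer(t[9]))
  }))
  routing <- lapply(node_lines, function(ln) {
    t <- strsplit(ln, " ")[[1]]
    rt <- t[11]
    if (rt == "-") integer() else {
      parts <- strsplit(rt, ",")[[1]]
      as.integer(ifelse(parts == "F", NA, parts))
    }
  })
  accf <- field("accumulator")
  structure(list(
    graph_name = field("name"), dii = as.integer(field("dii")),
    ports = as.integer(field("ports")),
    latency_profile = field("latency_profile"), nodes = nodes,
    units = units, latency = as.numeric(field("latency")),
    resources = {
      r <- c(add = 0L, mul = 0L, div = 0L, cmp = 0L)
      if (!is.null(units)) for (ty in names(r)) r[[ty]] <- sum(units$type == ty)
      r
    },
    input_slots = slots,
    routing = routing,
    outputs = as.integer(strsplit(field("outputs"), ",")[[1]]),
    inputs = as.integer(strsplit(field("inputs"), ",")[[1]]),
    accumulator = if (accf == "none") NA_integer_ else as.integer(accf),
    registers = as.integer(field("registers")),
    n_nodes = length(node_lines)), class = "pipeline_schedule")
}
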