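# Performance model of a multi-FPGA coprocessor: peak-bandwidth accounting,
# memory efficiency, roofline throughput prediction, the strided
# scatter/gather data layout and an idealized memory-FSM trace generator.
#
# The board hosts 4 application engines (AEs, one FPGA each) with 8
# processing elements (PEs) per AE; 8 memory controllers (MCs) each move 16
# bytes per 150 MHz cycle.  The per-AE and per-board accounting credits
# every AE with all 8 MCs and the board with 4 AEs -- the platform's own
# convention, adopted verbatim so the model reproduces the printed chain
# 2.4 -> 19.2 -> 76.8 GB/s.

#' Platform configuration
#'
#' @param n_ae application engines (FPGAs) on the board.
#' @param pes_per_ae kernel pipelines per AE.
#' @param n_mc memory controllers.
#' @param clock_hz coprocessor clock in Hz.
#' @param bytes_per_mc_cycle bytes one MC moves per cycle (two independent
#'   64-bit transactions).
#' @param input_fifo_depth entries in each 64-bit input operand FIFO.
#' @param output_fifo_depth_n,output_fifo_depth_m entries in the deep
#'   (per-likelihood-column) and shallow (per-scaler) output FIFOs.
#' @param element_bytes bytes per array element (binary32 word).
#' @return object of class `platform_config`.
#' @export
platform_config <- function(n_ae = 4L, pes_per_ae = 8L, n_mc = 8L,
                            clock_hz = 150e6, bytes_per_mc_cycle = 16L,
                            input_fifo_depth = 512L,
                            output_fifo_depth_n = 2048L,
                            output_fifo_depth_m = 512L,
                            element_bytes = 4L) {
  cfg <- list(n_ae = n_ae, pes_per_ae = pes_per_ae, n_mc = n_mc,
              clock_hz = clock_hz, bytes_per_mc_cycle = bytes_per_mc_cycle,
              input_fifo_depth = input_fifo_depth,
              output_fifo_depth_n = output_fifo_depth_n,
              output_fifo_depth_m = output_fifo_depth_m,
              element_bytes = element_bytes)
  if (any(vapply(cfg, function(x) !(is.numeric(x) && x > 0), TRUE)))
    stop("all platform parameters must be positive", call. = FALSE)
  structure(cfg, class = "platform_config")
}

#' Read a platform configuration from a key-value config file
#'
#' Plain-text `key value` pairs (one per line, `#` comments) overriding the
#' [platform_config()] defaults.
#'
#' @param path file path.
#' @return a `platform_config`.
#' @export
read_platform_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[ \t]+")[[1]]
    args[[kv[1]]] <- as.numeric(kv[2])
  }
  do.call(platform_config, args)
}

#' Data layout specification
#'
#' Each PE owns 64-byte blocks (16 binary32 elements = 4 sites of a 4-state
#' array); the same PE's space in two consecutive AEs is 512 bytes apart
#' (8 PEs x 64 bytes).
#'
#' @param pe_block_bytes bytes per PE block.
#' @param ae_stride_bytes stride between consecutive AEs for one PE.
#' @param sites_per_pe_round sites a PE consumes per block round.
#' @return object of class `layout_spec`.
#' @export
layout_spec <- function(pe_block_bytes = 64L, ae_stride_bytes = 512L,
                        sites_per_pe_round = 4L) {
  structure(list(pe_block_bytes = pe_block_bytes,
                 ae_stride_bytes = ae_stride_bytes,
                 sites_per_pe_round = sites_per_pe_round),
            class = "layout_spec")
}

#' Peak theoretical memory bandwidth
#'
#' `mc` = bytes per MC cycle x clock; `ae` = all MCs x mc; `board` = all
#' AEs x ae (the platform's accounting convention).
#'
#' @param cfg a [platform_config()].
#' @param scope `"mc"`, `"ae"` or `"board"`.
#' @return bandwidth in GB/s (decimal GB).
#' @export
#' @examples
#' peak_bandwidth(platform_config(), "mc")     # 2.4
#' peak_bandwidth(platform_config(), "board")  # 76.8
peak_bandwidth <- function(cfg = platform_config(),
                           scope = c("board", "ae", "mc")) {
  scope <- match.arg(scope)
  mc <- cfg$bytes_per_mc_cycle * cfg$clock_hz / 1e9
  switch(scope, mc = mc, ae = cfg$n_mc * mc,
         board = cfg$n_ae * cfg$n_mc * mc)
}

#' Memory efficiency
#'
#' `(reads + writes) / cycles`: the fraction of execution cycles that carry
#' a memory transaction.  Multiplying peak bandwidth by it gives actual
#' bandwidth.
#'
#' @param reads,writes transaction counts.
#' @param cycles execution cycles (`>= 1`).
#' @return fraction in `[0, 1]` (may exceed 1 if counts are per-value on a
#'   multi-value bus; the caller chooses the accounting unit).
#' @export
memory_efficiency <- function(reads, writes, cycles) {
  if (cycles < 1) stop("cycles must be >= 1", call. = FALSE)
  (reads + writes) / cycles
}

#' Arithmetic intensity
#'
#' Floating-point operations per byte of memory traffic; the kernel
#' performs 130 single-precision operations per 64 bytes of I/O.
#'
#' @param flops_per_site floating-point operations per site.
#' @param io_bytes_per_site bytes read + written per site.
#' @return ops/byte.
#' @export
#' @examples
#' arithmetic_intensity(130, 64)  # 2.03125
arithmetic_intensity <- function(flops_per_site = 130,
                                 io_bytes_per_site = 64) {
  flops_per_site / io_bytes_per_site
}

#' Roofline throughput prediction
#'
#' `throughput = arithmetic intensity x peak bandwidth x memory
#' efficiency`, in Gflops: a bandwidth-bound kernel's attainable rate.
#'
#' @param ai arithmetic intensity (ops/byte).
#' @param peak peak bandwidth (GB/s).
#' @param eff memory efficiency fraction in `[0, 1]`.
#' @return Gflops.
#' @export
#' @examples
#' predicted_throughput(130 / 64, 76.8, 0.5)  # 78
predicted_throughput <- function(ai, peak, eff) {
  if (ai < 0 || peak < 0 || eff < 0 || eff > 1)
    stop("ai, peak must be >= 0 and eff in [0, 1]", call. = FALSE)
  ai * peak * eff
}

#' Scatter a host array to the coprocessor layout
#'
#' Bijectively maps host element indices to `(ae, pe, byte offset)` under
#' the strided layout: consecutive 16-element (64-byte) blocks go to PE 0-7
#' of AE 0, then PE 0-7 of AE 1, ..., so one PE's blocks in consecutive AEs
#' sit exactly `ae_stride_bytes` apart and each block holds 4 sites of a
#' 4-state array.  The element count must be a multiple of
#' `n_ae * pes_per_ae * 16` (i.e. the site count a multiple of 128).
#'
#' @param host_array numeric vector of elements (values are carried along;
#'   the map depends only on the length).
#' @param layout a [layout_spec()].
#' @param cfg a [platform_config()].
#' @return data frame (class `coproc_layout`) with columns `host_index`
#'   (1-based), `ae`, `pe` (0-based), `offset` (byte offset inside the
#'   PE's region), `global_offset` (byte address in the interleaved
#'   space), `value`.
#' @export
scatter_to_coprocessor <- function(host_array, layout = layout_spec(),
                                   cfg = platform_config()) {
  n <- length(host_array)
  epb <- layout$pe_block_bytes / cfg$element_bytes       # elements per block
  round_elems <- cfg$n_ae * cfg$pes_per_ae * epb
  if (n == 0 || n %% round_elems != 0)
    stop(sprintf("element count must be a positive multiple of %d (site count a multiple of 128)",
                 round_elems), call. = FALSE)
  i <- seq_len(n) - 1L
  j <- i %% epb                      # element within block
  blk <- i %/% epb
  pe <- blk %% cfg$pes_per_ae
  ae <- (blk %/% cfg$pes_per_ae) %% cfg$n_ae
  round <- blk %/% (cfg$pes_per_ae * cfg$n_ae)
  offset <- round * layout$pe_block_bytes + j * cfg$element_bytes
  global_offset <- round * (cfg$n_ae * layout$ae_stride_bytes) +
    ae * layout$ae_stride_bytes + pe * layout$pe_block_bytes +
    j * cfg$element_bytes
  structure(data.frame(host_index = seq_len(n), ae = ae, pe = pe,
                       offset = offset, global_offset = global_offset,
                       value = host_array),
            class = c("coproc_layout", "data.frame"))
}

#' Gather a scattered array back to host order
#'
#' Inverse of [scatter_to_coprocessor()]; `gather(scatter(x))` is `x`.
#'
#' @param map a `coproc_layout` from [scatter_to_coprocessor()].
#' @return numeric vector in host order.
#' @export
gather_from_coprocessor <- function(map) {
  stopifnot(inherits(map, "coproc_layout"))
  out <- numeric(nrow(map))
  out[map$host_index] <- map$value
  out
}

#' Write a layout report as tab-separated text
#'
#' @param map a `coproc_layout`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_layout_report <- function(map, path) {
  utils::write.table(map, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Idealized memory-FSM request trace
#'
#' Generates the repeating load sequence of the memory controller FSM --
#' LD1 (four left-likelihood values), LD2 (four right-likelihood values),
#' LD3 (log-scaler + pattern weight) -- interrupting to a store burst
#' whenever the modeled output FIFO reaches the almost-full threshold,
#' resuming the load sequence afterward and draining the FIFOs at the end.
#' Stores move four values per cycle (128-bit writes), so each site costs
#' 3 read cycles and 1.5 write cycles.  The model is stall-free: every
#' cycle issues a request, making the efficiency estimate an idealized
#' upper bound of 1.
#'
#' FIFO occupancy is accounted in pending sites: each completed site parks
#' one entry in each of the four column FIFOs (depth N) and one scaler
#' entry per four sites in each round-robin scaler FIFO (depth M), so both
#' FIFO groups reach capacity at `min(N, 4 M)` pending sites.
#'
#' @param n_sites number of sites to stream (`>= 0`).
#' @param cfg a [platform_config()].
#' @param output_fifo_almost_full almost-full threshold in pending sites;
#'   default 8 below the FIFO capacity
#'   `min(output_fifo_depth_n, 4 * output_fifo_depth_m)`.
#' @return list with `trace` (data frame: cycle, state, site), counts
#'   (`reads`, `writes`, `read_cycles`, `write_cycles`, `interruptions`),
#'   `cycles` (total) and `efficiency` (the stall-free estimate).
#' @export
fsm_trace <- function(n_sites, cfg = platform_config(),
                      output_fifo_almost_full = NULL) {
  if (n_sites < 0) stop("n_sites must be >= 0", call. = FALSE)
  cap <- min(cfg$output_fifo_depth_n, 4 * cfg$output_fifo_depth_m)
  if (is.null(output_fifo_almost_full))
    output_fifo_almost_full <- cap - 8L
  states <- character(); sites <- integer()
  pending <- 0L           # completed sites whose outputs wait in the FIFOs
  reads <- 0L; writes <- 0L; write_cycles <- 0
  interruptions <- 0L
  store_burst <- function(pending) {
    # 6 values per pending site, 4 values per store cycle
    ncyc <- ceiling(pending * 6 / 4)
    states <<- c(states, rep("ST", ncyc))
    sites <<- c(sites, rep(NA_integer_, ncyc))
    writes <<- writes + pending * 6L
    write_cycles <<- write_cycles + ncyc
    0L
  }
  for (k in seq_len(n_sites)) {
    if (pending >= output_fifo_almost_full) {
      interruptions <- interruptions + 1L
      pending <- store_burst(pending)
    }
    states <- c(states, "LD1", "LD2", "LD3")
    sites <- c(sites, k, k, k)
    reads <- reads + 10L
    pending <- pending + 1L
  }
  if (pending > 0L) pending <- store_burst(pending)
  cycles <- length(states)
  trace <- data.frame(cycle = seq_len(cycles) - 1L, state = states,
                      site = sites)
  list(trace = trace,
       reads = reads, writes = writes,
       read_cycles = 3L * as.integer(n_sites), write_cycles = write_cycles,
       interruptions = interruptions, cycles = cycles,
       efficiency = if (cycles == 0) 1 else
         (3 * n_sites + write_cycles) / cycles)
}
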