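Package: plfpipe
Title: Phylogenetic Likelihood Kernels and Throughput-Constrained Pipeline Synthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reference implementation of the per-site phylogenetic likelihood
    function (Felsenstein pruning for the 4-state nucleotide model) with
    max-based per-site rescaling and log-scaler bookkeeping, in an exact
    double-precision mode and a device-faithful mode that rounds every
    arithmetic result to IEEE-754 binary32 and replaces the natural log by a
    16-segment degree-4 Chebyshev polynomial approximation selected by an
    unrolled logarithmic binary search.  On top of the kernel, the package
    provides a BEAGLE-style instance API (eigen-system transition matrices,
    tip/frequency/weight setters, postorder tree traversal, root
    log-likelihood), a typed data-flow-graph IR with canonical builders for
    the per-site kernel, a throughput/resource-constrained pipeline
    synthesizer (data introduction interval calculus, minimum functional-unit
    bounds, ASAP modulo scheduling with deferral, register estimation, text
    netlists), a cycle-accurate pipeline simulator proven bit-equivalent to
    the DFG interpreter, and a memory-bandwidth performance model of a
    multi-FPGA coprocessor (peak-bandwidth chain, memory efficiency,
    roofline throughput, strided scatter/gather data layout, memory-FSM
    trace generator).  A synthetic-data module generates random trees and
    alignments so the whole stack is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
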