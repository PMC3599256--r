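---
title: "From the phylogenetic likelihood function to a synthesized pipeline: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From the phylogenetic likelihood function to a synthesized pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plfpipe)
```

# The model

`plfpipe` computes the likelihood of a rooted binary tree under a 4-state
(nucleotide) continuous-time Markov substitution model, by Felsenstein's
pruning recursion.  For site $i$ and parent state $s$, the conditional
likelihood combines the two children through their edge transition
probabilities:

$$
L_k^{(i)}(s) \;=\;
\Bigl(\sum_{x} P_l(x \mid s, t_l)\, L_l^{(i)}(x)\Bigr)
\Bigl(\sum_{y} P_r(y \mid s, t_r)\, L_r^{(i)}(y)\Bigr),
$$

with $P(t) = E\,\mathrm{diag}(e^{\lambda_j t})\,E^{-1}$ built from the
eigen-system of the rate matrix.  Long trees drive the conditional
likelihoods toward zero, so after every internal-node update each site row
is divided by its maximum (the *scaler*) and the log of that scaler is
accumulated per site in a cumulative buffer `lnScaler`, initialized to
zero.  At the root,

$$
\ln L \;=\; \sum_k w_k \Bigl( \mathrm{lnScaler}_k +
  \ln \sum_s \pi_s\, L_{\mathrm{root}}^{(k)}(s) \Bigr),
$$

where $w_k$ are site-pattern multiplicities and $\pi$ the state
frequencies.  Identical alignment columns are collapsed into patterns with
weights before any likelihood work (`compress_patterns()`).

The cumulative scaler update is *additive*, `lnScaler[k] += scP[k]`: the
buffer starts at zero, a multiplicative update would be identically zero,
and the per-site kernel's addition count (38) is only reachable with the
additive form.  Cumulative scale buffers in mainstream likelihood libraries
behave the same way.

# Two numeric modes

Every kernel routine runs in one of two modes:

* **exact** — double precision throughout, true `log()`.  This is the
  reference semantics, validated against an independent recursive pruning
  oracle, brute-force summation over ancestral states on small trees, and
  an established phylogenetics package.
* **device** — a faithful emulation of a single-precision hardware
  datapath: the result of *every* add, multiply and divide is rounded to
  IEEE-754 binary32 (`round_b32()`, an exact float round-trip) before it is
  consumed again, and the natural log is replaced by the segmented
  polynomial described below.  Compare/select pairs pass values through
  unrounded (they move data, not arithmetic).

Device mode is deliberately order-pinned: sums of four products are
sequential three-add chains, the max-of-four is a chain of three pairwise
compares (ties keep the earlier state index), and the root reduction is
left-to-right in site order.  This makes the fused per-site computation
(`site_kernel()`) reproducible bit for bit by two independent executables:
the data-flow-graph interpreter (`evaluate_dfg()`) and the cycle-accurate
pipeline simulator (`simulate_pipeline()`).  Degenerate all-zero site
columns raise an error rather than emitting infinities: the emulated
datapath has no NaN path, and an all-zero column means the computation has
already underflowed beyond recovery.

# The segmented log

The device log tiles the positive reals into 16 segments selected by a
4-step unrolled binary search (probe exponent starting at $-16$, moving by
$8, 4, 2, 1$), each segment carrying a degree-4 polynomial in the raw
argument (5 coefficients, evaluated through the power chain
$x, x^2, x^3, x^4$).

**Threshold base.**  The search constants are powers of *two*
($2^{-16}, 2^{-24}, \dots$), so segment $s$ spans two octaves,
$[2^{2s-32}, 2^{2s-30})$.  This is a deliberate design decision.  A
hardware segment search is a compare on the binary32 exponent field, which
naturally yields power-of-two thresholds; and the choice is forced
quantitatively: with power-of-ten thresholds a segment spans two *decades*,
and no degree-4 polynomial in raw $x$ can track $\ln x$ over two decades to
better than roughly $0.3$ absolute — three orders of magnitude short of
what a 1% end-to-end likelihood accuracy budget allows per call.  Over a
two-octave segment the same 5-coefficient fit achieves a residual of about
$3 \times 10^{-3}$, and every coefficient stays representable in binary32
(the largest is $\sim 3 \times 10^{36}$, inside the binary32 range).

**Fit.**  Coefficients interpolate $\ln x$ at five Chebyshev nodes mapped
to each segment (computed in the scaled variable $x/\mathrm{lower}$ for
conditioning, then mapped back to raw-$x$ coefficients, so the evaluated
polynomial is exactly what the power chain computes).  Kernel arguments —
per-site scalers and root conditional likelihoods — lie in $(0, 1]$ once
partials are max-normalized, so segment 15 is fitted on $[2^{-2}, 1]$ and
the validated domain is $[2^{-32}, 1]$; arguments outside it are flagged
and extrapolated.  The fit is deterministic, and the per-segment residual
reported by `fit_log_table()` is itself checked against dense sampling in
the test suite.  Near $x = 1$, where $\ln x$ crosses zero, relative error
is measured against an absolute floor of 1 (a ratio against a vanishing
reference is not meaningful); everywhere else the plain relative error is
used.  The end-to-end consequence is what matters and is measured directly:
across randomized 4–8-taxon suites the device-mode log-likelihood stays
within about $0.2\%$ of exact, versus the 1% budget.

# The kernel as a data-flow graph

`build_kernel_dfg()` reconstructs the fused per-site computation as a typed
DFG: 10 logical inputs (4 + 4 child likelihoods, `lnScaler`, the pattern
weight), 6 outputs (4 normalized likelihoods, `scP`, updated `lnScaler`),
an internal feedback add accumulating $\ln L$, and constants for the
transition-table entries (invariant across sites, hence wired, not
streamed), state frequencies, search thresholds and polynomial
coefficients.  The construction conventions are normative for this package
and reproduce the canonical op profile exactly:

| block | add | mul | div | cmp |
|---|---|---|---|---|
| 8 sums of 4 products + 4 column products | 24 | 36 | — | — |
| max of four | — | — | — | 3 |
| normalization | — | — | 4 | — |
| two log blocks (4 thresholds, powers, 4 products, 4 adds each) | 8 | 14 | — | 8 |
| root dot product | 3 | 4 | — | — |
| scaler update, site term, weighting, $\ln L$ feedback | 3 | 1 | — | — |
| **total** | **38** | **55** | **4** | **11** |

Coefficient and threshold *selection* is a mux network (select nodes driven
by the compare bits); selects, constants, inputs and outputs are wiring,
not floating-point operations, and are excluded from `count_ops()`.

# Pipeline synthesis

The data introduction interval is
$\mathrm{DII} = \lceil \text{logical ports} / \text{physical ports}\rceil$;
with 10 inputs on 4 physical ports the kernel's DII is 3.  Because a new
site enters every DII cycles, two operations can share one functional unit
exactly when their start cycles differ modulo DII — plain per-cycle
conflict checking would be wrong — and the per-type resource floor is
$\lceil M/\mathrm{DII} \rceil$ units for $M$ operations.  For the kernel at
DII 3 this gives 13 adders, 19 multipliers, 2 dividers, 4 comparators, and
the scheduler attains those bounds.

Scheduling is ASAP with deferral: ready operations are served
first-come-first-served ordered by (ready cycle, node id); a node takes the
earliest cycle where a unit of its type has a free congruence class,
allocating new units only below the floor and otherwise deferring — pure
ASAP without deferral cannot respect the floor.  Within one DII window
every congruence class is reachable, so deferral never needs more than
DII − 1 cycles.  Input ports follow the memory state machine: cycle 0 the
four left likelihoods, cycle 1 the four right, cycle 2 scaler and weight.
The $\ln L$ feedback add is legal only if the adder latency is at most the
DII; the low-latency profile (3-cycle adder) satisfies this at DII 3, the
max-latency profile (12 cycles) is rejected with a synthesis error.
Operator latencies and register costs come from a two-profile table
(`operator_spec()`); the low-latency divider is pinned at 11 cycles, the
depth required to close timing at 150 MHz.  Register pressure is estimated
as the sum of unit costs plus 32 registers per cycle of operand skew;
constants are hard-wired and cost nothing.

The schedule serializes to a deterministic text netlist (units, bindings,
input slots, operand routing) that parses back into an equivalent
schedule.  The pipeline latency this package reports (41 cycles for the
kernel under the low-latency profile) reflects *this* graph's depth —
select networks are combinational here — and latency is therefore reported,
not asserted against any external figure.

# Cycle-accurate simulation

`simulate_pipeline()` executes a schedule stall-free: node $j$ of site $s$
fires at cycle $\mathrm{start}_j + s\,\mathrm{DII}$, operands flow through
the netlist routing table, units apply binary32 arithmetic in device mode,
and the accumulator carries across sites.  Outputs complete at
$\mathrm{latency} + s\,\mathrm{DII}$, so $n$ sites take
$\mathrm{latency} + (n-1)\,\mathrm{DII}$ cycles.  The simulator is proven
bit-identical to the DFG interpreter on seeded random streams
(`verify_equivalence()`, 1000 sites in the acceptance suite), and a
corrupted mux entry is detected and located to the first divergent node.
The separation is deliberate: correctness is bit-exact and lives here;
memory stalls are statistical and live in the platform model.

# The platform model

The modeled board has 4 application engines with 8 processing elements
each and 8 memory controllers moving 16 bytes per 150 MHz cycle: a peak
bandwidth chain of 2.4 GB/s per controller, 19.2 GB/s per engine and
76.8 GB/s aggregate.  This accounting credits each engine with all eight
controllers and the board with four engines — the platform's own
convention, adopted verbatim so the model reproduces its printed numbers
rather than a re-derivation.  Memory efficiency is transactions per
execution cycle; attainable throughput follows the roofline form
$\text{intensity} \times \text{peak} \times \text{efficiency}$.  The
kernel moves 10 input + 6 output binary32 words per site (64 bytes)
against 130 floating-point operations, an intensity of 2.03 ops/byte, so
at 50% efficiency the board sustains about 78 Gflops.

The data layout stripes host arrays in 64-byte blocks per processing
element (16 elements — four sites of a 4-state array) with a 512-byte
stride between the same element's space on consecutive engines;
`scatter_to_coprocessor()` realizes the map bijectively and enforces the
site count to be a multiple of 128 so every element receives equal work.
Pattern-weight words are packed contiguously inside each element's region
for the four sites it handles per round — one consistent reading of an
under-specified packing.  The memory state machine generator
(`fsm_trace()`) emits the LD1/LD2/LD3 load sequence (3 read cycles and 1.5
write cycles per site), interrupts to store bursts at an almost-full FIFO
threshold (occupancy accounted in pending sites; both FIFO groups fill at
$\min(N, 4M)$ sites for column-FIFO depth $N$ and scaler-FIFO depth $M$),
and drains at the end.  It is an idealized upper bound: every cycle issues
a request, so its efficiency estimate is 1.  DRAM bank contention,
crossbar arbitration, request reordering and read/write bus turns — the
effects that push measured efficiencies far below 1 on real hardware — are
intentionally out of scope, because they depend on a proprietary memory
scheduler that cannot be modeled from first principles.

# Synthetic data: what it does and does not cover

`generate_dataset()` draws a random rooted binary topology, exponential
branch lengths and evolves each site independently down the tree from the
model's stationary distribution.  Defaults are one study condition chosen
once: alignment lengths in multiples of 128 (mirroring the per-element
load balancing; any length is allowed for the software path) and branch
lengths exponential with mean 0.1 substitutions/site, a typical scale for
within-family nucleotide alignments that keeps transition matrices
well-conditioned without making sites uninformative.  The generator covers
JC69 and random reversible (GTR-style) models with Dirichlet frequencies.
It does *not* emulate rate heterogeneity across sites, indels or alignment
error, non-stationary or non-reversible processes, or base-composition
shifts — so passing device-accuracy suites here demonstrates datapath
fidelity under realistic likelihood magnitudes, not robustness of any
inference procedure on real data.

# Validation problem sizes

The shipped suites use sizes chosen to exercise every code path while
keeping the full run in tens of seconds: oracle comparisons on 3–8-taxon
trees (brute-force enumeration up to 5 taxa, where $4^{n-1}$ ancestral
assignments stay tractable), device-vs-exact suites of 14–50 datasets
spanning 128–1024 sites and both model families, simulator equivalence on
200–1000 random sites, and exhaustive minimal-binding search on random
graphs of at most 8 arithmetic nodes at DII ≤ 3 (the exact search is
exponential).  All randomness is seeded.

# Known limitations

* Nucleotide (4-state) models only; no amino-acid or codon state spaces.
* One rate category, one partition, strictly binary rooted trees.
* The device datapath emulates binary32 only; no double-precision device
  mode.
* The platform model predicts idealized bounds; it does not reproduce
  measured wall-clock times or measured memory efficiencies, which are
  dominated by effects outside the model.
* The brute-force scheduler oracle, and hence the optimality property it
  certifies, is limited to small graphs; for the full kernel the
  scheduler is checked against the analytic resource floor instead.
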