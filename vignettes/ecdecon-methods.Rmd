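---
title: "ecdecon: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ecdecon: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model implemented by `ecdecon`, the
parameters that matter, the design decisions taken where the design was
genuinely open, and what the simulated benchmarks do and do not show
about real data.

## The model

ecDNA reconstruction is cast as a path problem on a breakpoint
multigraph followed by a sparse regression. The inputs are (1) filtered
structural-variant junctions (each with two breakends and a
variant-supporting read count) and (2) a per-base coverage track of the
long-read alignment. Clean breakpoints — breakends merged by single
linkage within a 50 bp window, represented by the cluster median —
segment the amplified regions into fragments; `n` breakpoints strictly
inside a contiguous region give `n + 1` fragments. VCF positions are
1-based; internally every interval is 0-based half-open, and a
breakpoint at position `p` is the boundary after base `p`.

Each fragment contributes two vertices (`tail` at its start, `head` at
its end) and a fragment edge weighted by mean coverage. Junction edges
encode rearrangements (`DEL`/`BND` head–tail, `DUP` tail–head,
`INV`/`INVDUP` head–head plus tail–tail; `TRA` is treated as a `BND`,
honoring `STRANDS` when present; `INS` does not change segment order and
is ignored). Spatial edges join consecutive retained fragments on a
chromosome. A circular DNA element is an alternating closed walk:
fragment edge, junction edge, fragment edge, ... Entering a fragment at
its tail traverses it in `+` orientation.

Simple cycles are enumerated by a depth-first search that expands
neighbors in descending edge weight (ties broken by position, then edge
kind, then edge id), closing a walk when a junction returns to the entry
endpoint of the walk's first fragment. Cycles are stored canonically —
rotated so the genomically leftmost fragment is first, direction chosen
as the lexicographically smaller oriented sequence — so rotation and
reversal of the same ring hash identically, and enumeration is exactly
deterministic. Cycles sharing a fragment form clusters; within a
cluster, pairs (and up to triples) of sufficiently dissimilar cycles
(fragment-multiset Jaccard similarity at most 0.8) are spliced at their
leftmost shared fragment into *derived* cycles, the representation of
interspersed duplications. At most 8 simple cycles per cluster enter
combinations, ranked by support (minimum junction weight); this bounds
the design matrix at a few hundred columns.

Per cluster, the coverage of the cluster's fragments is regressed on
cycle membership with a non-negative LASSO:

$$\min_{b \ge 0}\; \frac{1}{|F_k|}\sum_j \Big(y_j - b_0 - \sum_i x_{ji} b_i\Big)^2 \;+\; \alpha \sum_i |b_i|,$$

where `x_ji` counts the occurrences of fragment `j` on cycle `i` and
`y_j` is the fragment's mean coverage. Coefficients are *not*
standardized away from coverage units: `b_i` reads directly as the
element's copy-coverage ("proportion"). The penalty `alpha = 0.1`
discards artifacts and redundant cycles. Selection keeps cycles with
`b_i > t` where `t = max_i(min_j coverage(f_j in cycle i)) / 4`, taking
the max over the cluster's candidate cycles; candidates at or below the
WGS background coverage are then dropped, and surviving elements longer
than 0.1 Mb are labeled ecDNA (shorter ones stay in the output labeled
"circular").

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_sv_cov` | 5 | × | minimum on-target coverage for an SV call |
| `min_vaf` | 0.01 | fraction | minimum variant allele fraction |
| `merge_window` | 50 | bp | breakend single-linkage merge window |
| `prune_cov` | 5 | × | fragments at or below this are pruned |
| `alpha` | 0.1 | coverage² per coverage | L1 penalty |
| `min_ecdna_len` | 100000 | bp | ecDNA label threshold |
| `region_gap` | 10000 | bp | gap defining "different regions" for the Multiregion topology |
| `max_simple` | 8 | count | simple cycles per cluster entering combinations |
| `dissim_threshold` | 0.8 | Jaccard | maximum similarity still allowed to merge |
| `eval_tol` | 50 | bp | breakend/boundary tolerance in evaluation |
| `wgs_mean` | `"auto"` | × | background coverage (median outside amplified regions) |

`region_gap` separates a genuine multi-region amplicon from an
intra-region deletion; small deletions are well under 10 kb while
distinct amplified regions sit tens of kilobases apart, so the default
cleanly separates the two notions (it is configurable).

## Design decisions

**Intercept identifiability.** The intercept models linear-genome
background coverage, but within a cluster every fragment is covered by
candidate cycles, so a free unpenalized intercept is unidentifiable
whenever the cluster's coverage is uniform — it absorbs the whole
amplification and nothing is selected. The background is only observable
*outside* the amplified regions; the pipeline therefore measures it
there (median coverage outside the amplified regions, the operational
"WGS mean coverage") and fixes `b0` to that value. `fit_lasso()` retains
the free intercept as its default for well-conditioned designs.

**Merged versus co-occurring elements.** A derived cycle's occurrence
column is exactly the sum of its constituents' columns. The L1 penalty
therefore always prefers moving shared weight onto the merged cycle: if
the truth is `ABC` at 30× plus `BD` at 20× sharing B, the raw optimum is
`ABC` at 10× plus merged `ABDBC` at 20× — an equally exact fit. Both
readings explain the data; the package resolves the degeneracy at
candidate selection: a derived cycle holding weight *while one of its
constituents also holds weight* is unmerged (its weight redistributed
onto all constituents; the fit is unchanged by the exact collinearity).
When the data are consistent with a single merged structure the
constituents sit at zero and the merged ring is reported — the signature
of a genuine interspersed duplication. The preference is for the less
complex structural explanation whenever coverage demands unequal
proportions.

**Junction-spanning counts.** Without an alignment file the spanning
count of a spatial edge is approximated by the minimum flanking
coverage. At an SV breakend that overestimates: reads supporting the
junction do not span the reference-adjacency point, so their support is
subtracted (clamped at zero) when the graph is built. Without this, a
reference-continuity path through an inverted segment carries more
weight than the inverted path itself.

**Indistinguishable cycles.** Two cycles over the same fragment multiset
(e.g. the inverted and the reference-orientation reading of a segment)
produce identical regression columns, and the optimizer's split between
them is arbitrary. The design matrix keeps one representative per
column: the cycle whose junctions carry the most read support (minimum,
then mean junction weight). Orientation is thus decided by SV evidence,
not by fit.

**Topology of reconstructions.** Reconstructed rings are classified
geometrically (overlap/orientation of consecutive fragments, multiset
coverage, block gaps, junction geometry), because a legal walk may
traverse a spatial edge across a deletion gap while the equivalent SV
edge exists in parallel. The classifier accepts explicit junction types
for callers that have them. In every ring one backward head-to-tail
junction is inherent to circularity and is not counted as an SV.

## Numerical choices

The LASSO is solved by cyclic coordinate descent with an exact
soft-threshold/clamp update, convergence at a maximum coefficient change
below 1e-6, and a cap of 1e5 sweeps (non-convergence is an error, not a
silent return). The reported objective is recomputed from the cost
function directly and is asserted against an independent evaluation to
1e-8 in the tests; glmnet (at `lambda = alpha/2`, no standardization,
non-negative bounds) and non-negative least squares serve as independent
oracles. Scaling coverage by `k` scales the fit by `k` when `alpha` is
scaled by `k` (the penalty is linear in the coefficients while the loss
is quadratic). Degenerate inputs: an all-zero response yields a zero
fit; an empty graph yields no cycles; a run with no surviving SVs
succeeds with empty outputs.

## The simulator: what it emulates, what it does not

Templates are drawn per topology class: amplified regions of 50–500 kb
(uniform), small deletions of 0.1–5 kb, inversions and tandem
duplications of 1–20 kb, foldback segments of 2–20 kb — focal amplicons
with sub-region-scale rearrangements, the regime reported for
neuroblastoma ecDNA. Event boundaries keep at least 300 bp apart so
breakpoints stay distinct after the 50 bp merge. Per-template
copy-coverage is drawn from 20–80× over a 5× background.

Emission is *idealized*: it writes what read simulation, alignment and
SV calling would produce under good conditions — one VCF record per
junction with support equal to the rounded proportion, optional uniform
breakend jitter, optional record drop-out, and a coverage track equal to
background plus proportion-weighted fragment multiplicity with Gaussian
noise on 100 bp bins inside the amplicon footprint. It does **not**
model sequencing error, chimeric reads, mappability, caller-specific
biases, or coverage waviness in the background — so passing benchmarks
demonstrate the correctness and resolution of the graph/regression
machinery, not robustness to upstream artifacts. The benchmark problem
sizes (100 templates per complex class with coverage noise σ = 2× and
±10 bp jitter; 50 per simple class noise-free; 20 seeded noisy mixtures)
were chosen as representative desk-scale batches.

The mixture benchmark uses two elements sharing a fragment at 40× and
140× over a 5× background. The selection threshold couples elements in
one cluster (`t` is a max over the cluster's cycles), so elements whose
proportions differ by more than about four-fold cannot both survive
selection — with 40×/140× both elements clear `t` at every dilution
ratio from 10% to 100%. This four-fold window is a genuine property of
the selection rule, not of the implementation.

## Known limitations

* A full foldback ring (a segment immediately followed by its inverted
  copy) is not a *simple* cycle — the fold repeats the fragment — so
  reconstruction recovers the ring minus the folded copy; the normalized
  largest contig is then `1 − L/(T + L)` for fold length `L` and base
  length `T`. Complex nested duplication/foldback mixtures can also
  split weight between near-equivalent derived rings and fall below the
  selection threshold; these are the observed sub-0.6 outcomes in the
  complex-topology benchmark.
* Repeat-containing structures beyond the splice construction (two or
  three rings at a time) are out of scope; the order of repeated
  segments may remain ambiguous.
* Elements at proportions below the WGS background, or below a quarter
  of the cluster's strongest cycle coverage, are filtered by design.
* Breakpoint recall uses greedy smallest-offset one-to-one matching; it
  equals the exhaustive optimum when junctions are separated by more
  than the matching tolerance (always the case for the simulated
  conditions; asserted against an exhaustive oracle in the tests).
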