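# ecdecon

Reconstruction and deconvolution of circular extrachromosomal DNA (ecDNA)
from long-read whole-genome sequencing derivatives: structural-variant
calls (Sniffles-style VCF) plus an alignment coverage track
(bedGraph/BigWig).

## The problem

ecDNA is a circular form of oncogene amplification found across cancers.
A single element can be heavily rearranged (deletions, inversions,
duplications, foldbacks), and several structurally distinct elements with
*overlapping genomic footprints* can co-occur in one tumor. Assembly- and
alignment-based reconstruction struggles with both: repeats break
contiguity, and overlapping elements leave an ambiguous mixture of
breakpoints and coverage.

`ecdecon` addresses this with a breakpoint-graph + regression approach:

1. **Genome fragmentation** — SV calls are filtered (FILTER `PASS` /
   `STRANDBIAS`, on-target coverage ≥ 5×, VAF ≥ 0.01), breakends within
   50 bp are merged into clean breakpoints, and the amplified regions are
   segmented into non-overlapping fragments annotated with mean coverage.
2. **Graph encoding** — a weighted undirected multigraph `G = (V, E)`
   over fragment endpoints (`tail` = start, `head` = end). Fragment edges
   carry mean coverage `w_f`; SV edges carry variant-read support `w_sv`
   (`BND`/`DEL`: head–tail, `DUP`: tail–head, `INV`/`INVDUP`: head–head
   and tail–tail); spatial edges join genomic neighbors with the
   junction-spanning read count `w_s`. Fragments at ≤ 5× or standalone
   are pruned.
3. **Cycle search** — a deterministic weighted depth-first search
   enumerates unique simple circular paths (canonicalized so the leftmost
   genomic fragment comes first). Cycles sharing fragments form clusters;
   within a cluster, sufficiently dissimilar cycles are spliced into
   *derived* cycles that model interspersed duplications.
4. **Quantification** — per cluster, a non-negative LASSO fits fragment
   coverage `y` against cycle-membership counts `X`:
   `min_b mean((y − b0 − X b)^2) + α Σ|b_i|`, α = 0.1, intercept `b0` =
   linear-genome background. The sparse coefficients `b*` are the
   estimated per-cycle proportions (in coverage units); cycles with
   `b_i > t`, `t = max(min fragment coverage per cycle)/4`, are kept.
5. **Candidate selection & output** — cycles with proportion at or below
   the WGS background are dropped; elements > 0.1 Mb are labeled `ecDNA`.
   Outputs: BED-like reconstruction threads, a summary table, optional
   FASTA sequence, and the per-cluster fit report.

Each reconstruction is ranked into one of seven topology classes of
increasing complexity: SimpleCircularization, SimpleSVs, MixedSVs,
Multiregion, Multichromosomal, Duplications, Foldbacks.

A simulator generates ground-truth templates for all seven classes and
emits matched idealized fixtures (VCF + coverage + truth BED), and the
evaluation module scores reconstructions by the normalized largest contig
(longest correctly reconstructed contiguous stretch / true length) and
breakpoint recall/precision.

## Worked example: deconvolving two elements that share a fragment

Two circles co-occur: `ABC` (chr1:100–400 kb at 30×) and `BD`
(chr1:200–300 kb + 400–500 kb at 20×), sharing fragment B over a 5×
background. Their breakpoint profile is identical to that of one merged
`ABDBC` circle; only the coverage proportions can separate the readings.

```r
library(ecdecon)
set.seed(1)
ringABC <- data.frame(chrom = "chr1", start = 100000, end = 400000, orient = "+")
ringBD  <- data.frame(chrom = "chr1", start = c(200000, 400000),
                      end = c(300000, 500000), orient = c("+", "+"))
truth <- ground_truth(list(ringABC, ringBD), proportions = c(30, 20), background = 5)
fx  <- emit_fixture(truth, noise_spec(), "fixture_dir")
res <- run_reconstruct(fx$vcf, fx$coverage, "out_dir")
```

`out_dir/summary.txt`:

```
circ_id  n_fragments  total_len  proportion  topology               label  chromosomes
1        3            300000     29.8667     SimpleCircularization  ecDNA  chr1
2        2            200000     19.9333     Multiregion            ecDNA  chr1
```

The two elements are recovered with estimated proportions 29.9× and
19.9× (truth 30× and 20×; the small deficit is the L1 shrinkage at
α = 0.1). Scoring against the truth:

```r
run_evaluate(fx$truth_bed, file.path("out_dir", "reconstructions.bed"))
#> mean contig 1.000  recall 1.000
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/ecdecon.R` with `reconstruct`, `simulate` and `evaluate`
subcommands.

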