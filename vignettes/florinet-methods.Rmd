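---
title: "florinet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{florinet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical machinery inside florinet, the
reasoning behind its defaults, and what the synthetic study conditions do
and do not establish about real data.

## The analysis in one paragraph

Given a genome, a gene annotation, a set of TF binding motifs, a
gene-by-sample count matrix over three conditions (control C, induced I,
flowered F) and a curated floral gene list, florinet builds one
transcription regulatory network per condition contrast. Candidate edges
come from motif occurrences in promoters; edges are kept only when the
TF–target pair is strongly coexpressed, at least one member is
differentially expressed, and at least one member is floral-listed. The
C–I and C–F networks are then compared node by node, and TF families are
tested for enrichment among the nodes whose wiring differs.

## Promoter windows

The scan region is the half-open 600-bp window spanning 500 bp upstream
of the TSS through 100 bp downstream, so the TSS base sits at 0-based
index 500 of the returned sequence. Upstream/downstream inclusivity is a
convention choice; the half-open window of total width
`upstream + downstream` is adopted because it is width-stable and
unambiguous. Coordinates are 1-based inclusive only on disk (GFF3); every
internal coordinate is 0-based half-open, converted exactly once at the
reader, which keeps strand mirroring honest (`extract_promoters()` is
tested to be invariant under reverse-complementing the genome and
flipping all strands). Windows are clipped at chromosome bounds and
flagged; overlap with neighboring genes is not trimmed, and promoters
shorter than a motif simply yield no hits. The TSS is the annotated gene
start (strand-aware); isoform-level alternative TSSs are out of scope.

## Motif scanning with exact p-values

Each motif column probability vector $p_i$ is mixed with the background
$q$ using a pseudocount fraction $c$ (default 0.1, the FIMO convention):
$p'_{ib} = (p_{ib} + c\,q_b)/(1 + c)$, and scored as
$s(i,b) = \log_2(p'_{ib}/q_b)$ bits. Scores are discretized to 1/1000 bit
— the standard accuracy/speed trade-off for exact p-value dynamic
programming — and the exact null distribution of the window score is the
position-wise convolution of the column score distributions under $q$.
The survival function of that distribution is queried for every scored
window; a hit is any window with $P(\text{score} \ge s) \le 10^{-5}$,
applied per test with no multiplicity correction (the cutoff is a raw
per-occurrence threshold, as in FIMO usage). Tests verify the DP tail
against exhaustive enumeration of all $4^w$ words to within one
discretization bin.

Numerical details worth recording:

* Zero-probability cells with a zero pseudocount would give $-\infty$
  log-odds; cells are floored at −64 bits, far below any attainable
  threshold, so tail probabilities in the region that matters are
  unaffected. A zero *background* frequency is rejected outright.
* Both promoter strands are scanned (configurable). The reverse-strand
  model is the reverse-complemented matrix with its own exact null
  distribution, so p-values remain exact under non-palindromic
  backgrounds.
* Windows overlapping an `N` are skipped (score undefined), not scored
  against the background.
* The background defaults to uniform 0.25 with an option to estimate
  0-order composition from the promoter set (`estimate_background()`).

A width note: under a uniform background the smallest achievable exact
p-value for a width-$w$ motif is $4^{-w}$, since at best a single word
attains the maximum score. At $w = 8$ that is $1.5\times10^{-5}$ — *above*
the $10^{-5}$ cutoff — so planted sites of width-8 motifs could never be
recovered at the default threshold. The synthetic generator therefore
defaults to width-10 motifs ($4^{-10} \approx 9.5\times10^{-7}$), also a
typical plant TF motif width.

## Differential expression

Counts are normalized by median-of-ratios size factors: the reference is
the per-gene geometric mean across samples (genes containing any zero are
excluded from the reference set but still normalized), and each sample's
factor is the median ratio to the reference. The per-gene test is a
negative-binomial Wald test on the log2 ratio of normalized group means
(second condition over first), with a method-of-moments dispersion pooled
across the two conditions, floored at $10^{-8}$ with a Poisson fallback
when the moment estimate is negative. The Wald statistic is referred to a
t distribution with $n_a + n_b - 2$ degrees of freedom — the small-sample
reference appropriate when the variance is estimated; with 4 + 4
replicates a normal reference is visibly anticonservative, while the
t-reference test holds its nominal level on a fully null NB simulation
(the calibration test requires the raw-p ≤ 0.05 fraction to land in
[0.03, 0.07] on 2,000 null genes). A 0.5 pseudo-mean stabilizes fold
changes of very low-count genes; genes with zero counts everywhere are
reported untested. FDR is Benjamini–Hochberg across tested genes.

A gene is a DEG when |fold change| ≥ 2 and FDR ≤ 0.05. The methods-level
definition (FDR) is the default; a `raw_p` criterion is available because
figure-level DEG counts in this literature are sometimes reported at
unadjusted P ≤ 0.05. The module also accepts a precomputed DE table
(`read_de_table()`), so any external caller can substitute for the
built-in test. No dispersion shrinkage, covariates, or outlier handling
are attempted — the test is intentionally minimal and self-contained.

## Network assembly

Coexpression is Spearman's ρ with average ranks for ties, computed on
normalized counts over the samples of the contrast's two conditions
(default; an all-samples scope is available). A constant expression
vector has undefined rank correlation and is reported as missing — never
as 0 — and edges without a defined ρ are dropped. The coexpression
criterion defaults to |ρ| > 0.9 ("absolute" mode): negative correlations
are retained as repression-like edges carrying sign −, since a signed
reading of "> 0.9" could never produce the negative-regulation edges the
analysis is meant to display; the literal signed mode is exposed as an
option. The DEG criterion is satisfied if either member of the pair is a
DEG in the I-vs-C or the F-vs-C comparison (configurable via `deg_rule`);
the comparison-specific alternative is one configuration away. Multiple
motif hits collapse to a single edge with the hit count kept as an
attribute; self-edges are excluded at the correlation stage.

Edge filtering is monotone by construction: tightening the scan
threshold, the ρ threshold, the DEG set or the floral set can only remove
edges — a property the test suite checks across threshold grids.

## Differential network and enrichment

A node is *distinguishing* when it is present in only one network or
present in both with a different signed neighbor set (a sign flip alone
rewires both endpoints). The enrichment universe defaults to the union of
both networks' node sets — the smallest defensible universe; all-TF or
all-gene universes can be passed explicitly. The test is the upper-tail
hypergeometric probability of the observed family overlap among
distinguishing nodes, with the odds ratio of the corresponding 2×2 table;
a Haldane correction of 0.5 per cell is applied (and flagged) when any
cell is zero. Across multiple families, BH-adjusted p-values are reported
alongside raw ones.

## K-mer survey

Every N-free window of length k (default 17) contributes its canonical
form — the lexicographic minimum of the k-mer and its reverse complement —
to a multiplicity histogram (implemented in C++ with 2-bit rolling
encoding; reverse-complementing all reads provably leaves the histogram
unchanged). Genome size is the retained k-mer total divided by the
depth. "Average depth" is ambiguous in the formula's usual statement:
the default takes the histogram peak (mode above the error trough),
which is robust to error k-mers inflating the raw mean; a literal
coverage-weighted mean mode is available and the choice is recorded in
the output. The error cutoff defaults to the first local minimum of the
observed histogram, or 1 when the histogram rises from the start (the
error-free case). In-memory counting is adequate at the package's scale;
read pre-filtering and organelle/contaminant removal are upstream steps
outside its scope, as is mixture-model (GenomeScope-style) fitting.

## The synthetic study conditions

The generator's defaults define the package's reference conditions: a
0.5 Mb two-chromosome uniform-background genome; 300 genes (each with
≥ 600 bp clearance so no promoter is clipped); 20 TFs with width-10
motifs at ~1.8 bits/column; 150 planted TF→target edges, each with an
exact consensus site written into the target's promoter at a recorded
offset and strand; three conditions × 4 replicates; NB dispersion 0.1
around mean 100; 25% repression-like edges; and a 5-TF differential
family, silent (mean 0.02) outside F and activity-driven within F, each
with 4 dedicated targets.

Expression follows a latent-activity model: each TF's per-sample activity
drives its own expression (effect 2 on the natural-log scale) and its
targets' (effect 3, signed). Within every condition the activity values
are a permuted, lightly jittered equally spaced grid (sd 0.5) — a
stratified draw chosen so that adjacent activity levels stay separated
relative to the NB noise floor ($\sqrt{0.1 + 1/100} \approx 0.33$ on the
log scale) and rank correlations near ±1 are attainable at n = 8; at
dispersion 0 (the noiseless limit) every always-active edge has Spearman
ρ exactly ±1. Normal TFs additionally carry a ±log(4) condition offset in
I and F, making TFs and their targets ≥ 2-fold DE by construction and the
0.9 coexpression criterion both attainable and violable. Each sub-generator
(genome, motifs/sites, expression, reads) runs on its own RNG stream
derived from the master seed, so stages can change independently without
perturbing one another's draws.

What the generator deliberately does **not** emulate: repeats and
realistic genome composition, isoforms and alternative TSSs, batch
effects, library-size gradients (size factors are ≈ 1 by design),
multi-regulator targets (each target has exactly one regulator, because a
target integrating several independent TFs cannot exceed ρ = 0.9 with any
of them — a real limitation of correlation-gated network inference worth
keeping visible), heteroskedastic dispersion trends, and sequencing error
models beyond uniform substitution. The dynamic range of strongly
regulated synthetic genes is exaggerated relative to typical RNA-seq:
that is the price of demanding |ρ| > 0.9 at n = 8 under NB noise.
Passing the recovery tests therefore demonstrates correctness of the
machinery under the stated model, not performance on real tissues.

## Problem sizes

The shipped tests and the acceptance script use the 300-gene default
pipeline (a few seconds end to end), a 2,000-gene null plus 400-gene
planted DE calibration, exhaustive motif enumeration up to width 6, and a
1 Mb / 30× k-mer survey — sizes chosen so the whole suite runs on a
laptop in about a minute while still exercising every stage at
non-trivial scale.

## Known limitations

* Edge direction is motif-based, not causal; coexpression is symmetric.
* The hypergeometric universe, the DEG-comparison rule and the signed
  versus absolute ρ reading are genuinely underdetermined design choices;
  all are exposed as options, and conclusions sensitive to them should be
  reported across settings.
* The NB test has no dispersion moderation: at 2–3 replicates its power
  is limited, and the calibration guarantees are stated for ≥ 4
  replicates.
* In-memory k-mer counting targets desk-scale data, not billion-read
  surveys.
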