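---
title: "Pooled CRISPRi screens: design and statistics in crisprikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled CRISPRi screens: design and statistics in crisprikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

crisprikit implements the two halves of a pooled CRISPRi functional-genomics
platform for bacteria: designing genome-scale (or tiling) sgRNA libraries
from a genome and its annotation, and turning pooled-screen sequencing
counts into per-gene fitness estimates, hit calls and classifier
benchmarks. This vignette explains the models and the decisions behind
them; the README shows a worked end-to-end example.

```{r setup, message = FALSE}
library(crisprikit)
library(dplyr)
```

## Library design

**Target geometry.** CRISPRi represses a gene efficiently when the sgRNA
base-pairs with the non-template (coding-sense) strand, which places the
protospacer and its NGG PAM on the template strand. On the coding sequence
this is visible as a `CC` dinucleotide: for every `CC` at coding positions
`(p-1, p)` with `2 <= p <= L-21`, the 20-nt spacer is the reverse
complement of `cds[p+2 .. p+21]`, and the guide is named `gene_p` after
the coding coordinate of the 5'-most PAM guanine. A coding-strand reading
of N20-NGG would be geometrically impossible for PAM positions as small as
p = 9, which real libraries contain; the template-strand convention is the
one consistent with such names.

**Off-target scoring.** Candidate off-target sites are all genomic
23-mers (both strands) ending in NGG or NAG whose 20-mer prefix is within
5 mismatches of the spacer. The spacer is split by distance to the PAM
into Region III (positions 1-8, 5' end), Region II (9-13) and Region I
(14-20, PAM-proximal); each mismatch adds the penalty of its region --
2.5/4.5/8 for NGG sites, 3/7/10 for NAG, 100 per mismatch for any other
PAM. PAM-proximal mismatches disable CRISPRi, so a site with only
Region-I mismatches accumulates a large penalty and is *tolerated*; a
site whose total penalty falls **below** the threshold is significant and
eliminates the guide. The thresholds are 11 in tiling mode (maximize
guides per gene) and 21 in genome mode (minimize screen false positives):
under threshold 21 even a site with two Region-I mismatches plus one
Region-II mismatch (penalty `8*2 + 4.5 = 20.5`) still rejects its guide.
Spacers must also have GC content within [0.30, 0.85], bounds inclusive.

```{r}
offtarget_penalty("NGG", c(20, 16, 12))
offtarget_penalty("NGG", c(18, 3))
```

**Gene clusters.** Duplicated genes (tRNA isoacceptor families, rRNA
operon copies, near-identical paralogs) are clustered by single-linkage
over pairwise local alignments at >= 95% identity and >= 95% mutual
coverage; guides are designed on the longest member and must match every
member's coding sequence exactly, so a cluster is knocked down as a unit
and perfect-match sites inside any member are exempt from the off-target
test. At genome scale a precomputed cluster table (e.g. from BLASTN) can
be supplied instead of the internal aligner.

**Selection.** Tiling mode walks the ORF 5' to 3' and keeps the first 50
passing guides. Genome mode first takes everything in the "active
region" -- the 5% of the ORF nearest the start codon, where tiling
screens show distinctly higher activity -- and then fills up to 15 guides
at evenly spaced rank quantiles of the remaining position-ordered
candidates. The rank-quantile rule is a deterministic reading of
"uniformly select from the remainder"; determinism keeps designs
byte-reproducible. Ties among more than 15 active-region candidates are
broken toward the most 5'-proximal, and the active-region membership of a
guide is judged by its PAM position `p/L` (the alternative, the spacer 5'
end, differs by at most 22 nt and changes nothing at these scales).

**Negative controls.** 400 random 20-mers are accepted only if they have
proper GC content and *zero* candidate sites (NGG or NAG, up to 5
mismatches) anywhere in the genome. They are the backbone of every
statistic downstream. The sampler is seeded and budgeted (an error names
the budget if a degenerate genome makes the quota unreachable).

## From reads to counts

Reads carry the spacer in a fixed cassette, `GCAC<N20>GTTT`. Processing
follows the screen's published filters: reads longer than 194 nt are
dropped; both ends are trimmed of bases below Q25; a read survives only
with zero bases below Q10, more than 85% at or above Q20 and more than
60% at or above Q30 ("Q10 < 1" is read as a count -- the other two
criteria are fractions). The first intact cassette (exact flanks, forward
orientation searched before reverse complement) yields the spacer, which
is counted against the library by exact match only -- a one-mismatch
spacer is synthesis or sequencing noise, and rescuing it would blur the
negative controls.

Counts are normalized per library by `total_i / mean(totals)` so all
libraries share the mean depth (Eq.-1-style normalization; idempotent);
sgRNAs under 20 reads in the experiment's initial/control library are
removed (strict `<`); replicates are combined entrywise by the geometric
mean, with zero propagating (a pseudocount enters later, at the fitness
stage, not here). Normalization precedes replicate averaging; the
alternative order is not distinguishable from the paper-facing outputs
and is recorded in the table metadata.

## Fitness, Z scores and the quasi-gene null

sgRNA fitness is the centered, pseudocounted log2 ratio

```
fitness' = log2((sel + 1) / (ctrl + 1)),   fitness = fitness' - median(fitness'[NC])
```

The +1 pseudocount matters only for depleted guides (control counts are
>= 20 by filter, selective counts may be 0). The negative-control fitness
distribution is treated as a normal null; its sample standard deviation
sigma turns fitness into `Z = fitness / sigma`, and |Z| >= 2 is the
conventional per-guide activity call.

**Gene scores.** A gene subset's score is `|median(fitness)| *
(-log10 P)`, with P a two-sided Mann-Whitney U test of the subset against
all negative controls -- effect size and rank separation both count.

**Quasi genes.** To convert scores to false-positive rates for genes with
1..15 guides, the package builds 15 quasi-gene sets from the negative
controls: size 1 enumerates all 400 singletons; each larger size has
10,000 members. Members are drawn without replacement within a quasi
gene; the implementation draws each quasi gene as a 15-member ordering
and scores every prefix, so the size-i column is marginally a uniform
size-i sample *and* every draw carries a full trajectory of the adaptive
procedure below. `FPR(lambda)` -- the fraction of same-size quasi scores
above lambda -- is linearly interpolated between adjacent sorted scores
and clamped to `[1/(2 N_i), 1]`, where `N_i` is that curve's member
count: an empirical tail cannot resolve probabilities below half a
member, so the singleton curve floors at 1/800, the others at 1/20,000.

**Adaptive subset selection and calibration.** Guides are sorted by
position in the ORF; for every prefix of size M the score and its raw
size-M FPR are computed, and the prefix with the smallest raw FPR (ties
toward the smallest, most 5'-proximal M) defines the gene's fitness,
P and score. The minimum of N correlated uniform variates is not itself
uniform, so the raw minimum is anti-conservative as a tail probability --
on fully null simulated screens about a quarter of genes reach a raw
min-FPR below 0.05. The package therefore calibrates it: each quasi-gene
trajectory's own min-over-M FPR forms the null distribution of the
adaptive statistic at each gene size, and the reported gene FPR is the
fraction of same-size null trajectories at or below the gene's raw
minimum. This second stage restores uniformity (measured fractions
0.008/0.042/0.089 at nominal 0.01/0.05/0.10 on a 1000-gene null screen)
while leaving the paper-facing selection rule and metrics untouched; the
uncalibrated value is kept in the `fpr_raw` column.

**Exact versus approximate rank tests.** Quasi-gene members duplicate
values in the control pool by construction, so their MWU P values can
only come from the tie-corrected normal approximation. Using exact
enumeration on the gene side while the null curves are approximate skews
the score-to-FPR mapping at small subset sizes (small-sample exact P
values are far smaller than approximate ones); the FPR pipeline therefore
uses the approximation at every size for both sides. `mwu_test()` itself
performs exact enumeration for tie-free samples when the smaller side has
at most 8 observations, and is verified against an exhaustive permutation
oracle.

**q-values and hits.** Calibrated FPRs are treated as P values in the
Storey-Tibshirani procedure with pi0 estimated at lambda = 0.5 (a fixed
lambda is robust to the discreteness of empirical FPRs; the spline
refinement buys nothing at 10^2..10^4 genes). Hits are genes with
q below the FDR threshold (default 0.05); genes at fitness <= -6 carry a
`no_doubling` tag (a clone that stops dividing is diluted 2-fold per
culture doubling, so ~15 doublings put full growth arrest at or beyond
-6 given ~100x depth -- see `resolution_limit()`); and phenotype screens
can exclude reference essentials (fitness <= -4, q <= 0.01) via
`essentiality_exclusion()`.

## Classifier benchmarking

Three essentiality classifiers map results onto [0, 1] predictions:
CRISPRi (`1 - FPR` for depleted genes, else 0), transposon insertion
index (0 if the per-gene index reaches 0.00125; otherwise
`1 - exp(-local_index * length)`, with the local index counted in a
10-kb window and divided by 10,000), and genetic footprinting (`1 - P`
for flagged-essential genes). ROC curves come from a threshold sweep over
unique scores with trapezoidal AUC, equal to the pairwise concordance
probability; an O(n^2) oracle and pROC cross-check it in the tests. The
insertion-index window is centered on the gene midpoint with the gene
body included, and the divisor stays 10,000 when a window is truncated at
a contig end -- the source text does not anchor the window, and this is
recorded as a limitation (windows anchored at the gene start, or
excluding the body, would shift local indices by small amounts for genes
near insertion-density gradients).

## What the simulators emulate

`simulate_genome_annotation()` builds random chromosomes with real ORF
structure (ATG, stop, no internal stops, both strands, optional >= 99%
duplicate pairs for clustering); `simulate_screen_counts()` draws
multinomial counts (overdispersion optional via a Dirichlet knob; no
variance model is published, so multinomial is the default) from initial
abundances log-uniform within 10-fold and selective abundances scaled by
`2^(activity x effect)`; `simulate_reads()` wraps counts into
cassette-bearing reads at random offsets and orientations, resampling the
random padding in the rare read where it would spell out a second,
accidental cassette, so an error-free run round-trips exactly;
`simulate_tn_insertions()` places uniform insertions and suppresses them
inside designated essential genes. Everything is seed-deterministic.

**Activity model.** Guide activity multiplies the gene effect on the
log2 scale. Downstream guides draw activity from Beta(2, 2); guides in
the first 5% of the ORF draw from Beta(6, 1) (median ~0.89). The strong
5' skew is deliberate: in real screens most guides near the start codon
are close to fully active -- that is what lets the majority of essential
genes reach depletion near the resolution limit -- and a mediocre
(mean-0.5) active region would make a -6 knockdown look like -3 under the
linear model, which no published screen shows. Both shape pairs are
arguments.

**What passing these simulations does not show.** The generators have no
operon structure, so CRISPRi's polar effects -- the main source of real
false positives -- are absent; no PCR jackpots, no plasmid
co-transformation, no position-dependent *count* biases, and gene effects
are constant within a gene up to activity scaling. Passing calibration
and FDR control here validates the statistical machinery under the
model's assumptions, not robustness to those artifacts.

## Problem sizes and numerical choices

The test suite runs null calibration on one screen of 1,000 genes x 10
sgRNAs with 400 negative controls at 100x depth and the default 10,000
quasi genes per size, and FDR/recovery on twenty screens of 200 genes
with 10% of genes planted at effect -6 -- sizes chosen so the binomial
bands in the assertions are meaningfully tight while a full run of the
suite stays comfortable on a laptop. Degenerate inputs are errors, not
guesses: zero-variance controls, empty control sets, zero library
totals, genes above the null model's maximum size (capped with a
warning). Interpolation endpoints, floors and tie-breaks are described
above; all randomness flows through explicit seeds, and identical seeds
give byte-identical designs, counts, null models and calls.

## Known limitations

- Polar effects and operon-aware corrections are out of scope; hit lists
  from real screens need the same manual curation the original analysis
  applied.
- The cluster aligner is quadratic in gene count and meant for desk-scale
  genomes; at full genome scale, import a precomputed cluster table.
- The calibrated FPR is tied to the quasi-gene model: with very few
  negative controls (< ~50) the curves are coarse and q-values
  conservative.
- The insertion-index window anchoring is a convention (see above).
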