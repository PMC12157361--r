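---
title: "Purity-aware ecDNA detection and its statistics: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Purity-aware ecDNA detection and its statistics: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecdnatools)
```

## The problem

Extrachromosomal DNA (ecDNA) elements are circular, chromosome-independent
amplicons that amplify oncogenes to very high copy number and associate with
poor outcomes across cancers. Detecting them from whole-genome sequencing
starts from read-depth copy number, and read depth is diluted by the normal
cells in a tumor sample: a segment at 10 copies in tumor cells sequenced at
15% purity shows a depth ratio of only 1.6, and a caller that assumes a pure
diploid sample reports copy number 3.2 — below any amplification threshold.
This package implements a purity/ploidy-aware pipeline around that problem:
copy-number rescaling and amplicon seed calling, a breakpoint-graph amplicon
classifier, genome-instability metrics, chromothripsis criteria, cargo and
driver-mutation classification, and the association/survival statistics that
connect them, all exercised against a synthetic cohort generator with known
ground truth.

## The copy-number model

For a segment with observed log2 tumor/normal depth ratio $\log R$, tumor
purity $\rho \in (0, 1]$ and tumor ploidy $\psi > 0$, the tumor-cell total
copy number is

$$\mathrm{TCN} \;=\; \frac{\psi\, 2^{\log R} - 2(1 - \rho)}{\rho},$$

i.e. the observed depth is a mixture of tumor cells (ploidy $\psi$) and
normal diploid cells. Setting $\rho = 1, \psi = 2$ recovers the naive
estimate $2 \cdot 2^{\log R}$. Under noise at low purity the numerator can
go negative; we clamp at zero and count the clamps
(`rescale_total_copy_number()`). Note the denominator inside $2^{\log R}$'s
coefficient is the tumor ploidy $\psi$, not the mixture ploidy
$\rho\psi + 2(1-\rho)$; the rescaling is implemented exactly in this form,
and the simulator's forward model is its algebraic inverse, so the pair
round-trips to machine precision. Users whose logR was normalized to the
mixture ploidy should be aware of the discrepancy.

Seed regions — the intervals handed to amplicon reconstruction — are maximal
runs of segments with $\mathrm{TCN} \ge$ `min_cn` (default 4.5), merged
across gaps up to 300 kb and kept when at least 50 kb long. These thresholds
are the conventional amplicon-seeding values; they are exposed as arguments
because no single choice suits every depth profile. TCN stays real-valued
for seeding; rounding happens only where a rule demands integers (wGII,
WGD, oscillation states).

## Amplicon classification

`build_breakpoint_graph()` pads seeds by 100 kb, admits structural variants
with both breakends inside padded seeds, and builds the standard
oriented-endpoint graph: each interval contributes a left and right endpoint
joined by a sequence edge; reference adjacency contributes concordant
junctions; SV breakends attach to the endpoint matching their orientation. A
circular structure is a closed walk alternating sequence and junction edges,
found by cycle detection on the induced directed graph (the concordant-only
subgraph follows the linear reference and is acyclic, so any cycle uses a
discordant junction). Classification is a deliberate simplification of full
amplicon reconstruction, and is documented as such:

* **ecDNA** — a cycle through at least one discordant junction and
  maximum CN at least `min_ecdna_cn` (default 4.5);
* **BFB** — no qualifying cycle, but foldback inversions (head-to-head or
  tail-to-tail with breakend distance $\le$ 30 kb) make up at least 25% of
  the component's SVs;
* **complex non-cyclic** — any other SV-bearing component;
* **linear** — no SVs at all.

Ties (cycle *and* high foldback fraction) resolve to ecDNA. A sample is
ecDNA-positive when it carries one or more ecDNA amplicons. Strand pairs map
to SV types by the usual BEDPE convention: (+,−) deletion-like, (−,+)
duplication-like, (+,+) head-to-head inversion, (−,−) tail-to-tail
inversion, cross-chromosome translocation.

## Genome instability metrics

* **WGD**: a sample is whole-genome doubled when the major allele copy
  number is $\ge 3$ over *more than* half the genome. We read "half of the
  segments" as length-weighted genome fraction so the call cannot change
  when a segment is split in two (the count-based reading is available via
  `weight = "count"`).
* **wGII**: overall ploidy is the length-weighted mean TCN; per autosome,
  the aberrant fraction is the length-weighted fraction of bases with
  $\mathrm{round(TCN)} \ne \mathrm{round(ploidy)}$; the 22 fractions are
  summed and divided by 22. Rounding both sides is a deliberate choice —
  comparing raw TCN against a non-integer ploidy would mark every base
  aberrant.
* **Telomere length**: a read is telomeric at $\ge 7$ non-overlapping
  TTAGGG (or CCCTAA) repeats; per read group, length is proportional to the
  telomeric-read fraction, and the sample estimate is the read-count
  weighted mean over groups. The proportionality constant defaults to 1:
  it cancels in the tumor/normal log2 ratio, which is the quantity used
  downstream.
* **Mitochondrial copy number**: from the mito/nuclear depth ratio, the
  mixture's nuclear content $\rho\psi + 2(1-\rho)$ converts depth ratio to
  mitochondrial copies per cell; subtracting the normal contribution
  (estimated from the matched normal) and dividing by $\rho$ yields the
  tumor-cell value, clamped at zero.

## Chromothripsis criteria

Intrachromosomal SVs are clustered by single-linkage over breakend
positions (gap $\le$ 1 Mb; both breakends of one SV are linked by
construction). A cluster is a high-confidence chromothripsis call when all
of the following hold: (i) more than 6 clustered DUP/DEL/h2hINV/t2tINV
records; (ii) more than 7 switches in the longest run of segments whose
rounded TCN alternates between exactly two states (no third state tolerated
inside the run); (iii) breakpoint enrichment in the region, one-sided
binomial tail p < 0.05 against uniform placement; and (iv) join randomness,
chi-square goodness of fit of the four join types against ¼ each with
p > 0.05, *or* at least 4 inter-chromosomal rearrangements touching the
region. We read the criterion-(iv) "and/or" as an inclusive OR attached
to criterion (iv) only, with (i)–(iii) always required — the most
conservative reading. The binomial and chi-square models are explicit,
swappable stand-ins for the corresponding tests inside the established
chromothripsis caller, whose internal tests are not specified by the
criteria. ecDNA–chromothripsis overlap is any $\ge 1$ bp intersection
(threshold configurable), reported with total intersected bases.

## Cargo and driver mutations

Genes and enhancers count as ecDNA cargo only when 100% contained in the
merged ecDNA intervals; promoters (1000 bp upstream of the TSS,
strand-aware, clipped at chromosome bounds) count on any overlap. The
containment rule for genes mirrors the enhancer rule — a partial
gene is unlikely to act as cargo — and can be relaxed to any-overlap via
`gene_rule`. Intervals are merged before testing, so containment is
subdivision-safe. Cargo categories are prioritized oncogene >
immunomodulatory > other gene > regulatory-only > unknown, and an ecDNA
carrying an oncogene is never called immunomodulatory. The immunomodulatory
and oncogene rosters are inputs, not recomputed. A mutation is a potential
driver when it meets any of six criteria: truncating in a tumor suppressor;
missense recurring in $\ge 3$ samples; boostDM score > 0.5; OncoKB
"Oncogenic"/"Likely Oncogenic"; in the TCGA MC3 driver set; or missense
"likely pathogenic" in a tumor suppressor.

## Statistics

Logistic regression is ordinary maximum likelihood (IRLS) with Wald
intervals; separation is detected and refused with a pointer to the Firth
variant. Firth's penalized logistic regression maximizes
$\ell(\beta) + \tfrac12 \log\det I(\beta)$ by modified-score iteration with
step-halving, guaranteeing finite estimates under complete separation; its
intervals invert the penalized likelihood-ratio test (profile), falling
back to Wald when profiling fails, and per-term p-values are penalized
LRTs. On a single 2×2 table the Firth estimate coincides with the
half-cell-corrected cross-product ratio, which the tests exploit as a
closed-form check. Mann-Whitney tests are exact (full enumeration,
mid-ranks for ties) up to 12 combined observations, then normal with tie
correction. 2×2 odds ratios are cross-products (0.5 added to every cell
iff any cell is zero) or the conditional MLE, always with the two-sided
conditional exact Fisher p (tables with probability at most the observed).
Cox models use Efron tie handling; the three-level amplification factor
(ecDNA / other focal amplification / none) takes "other focal
amplification" as the reference, so the ecDNA coefficient is the
ecDNA-versus-chromosomal-amplification contrast. BH-FDR is applied within
each analysis family.

## The synthetic cohort generator

The generator is first-class, tested code: it produces the statistical
structure the analysis assumes, with ground truth, so every stage is
testable offline.

* **Genome**: 22 autosomes of 10 Mb (real lengths loadable). Chromosomes
  are tiled gap-free with Poisson-random segment boundaries.
* **Purity** uniform on [0.2, 0.9] by default — the wide range typical of
  lung WGS cohorts; **WGD** in 40% of samples, modeled as a doubled
  baseline (2+2) plus copy-neutral allelic imbalance (3+1) over ~70% of the
  genome, so the major-CN rule detects it without inflating total CN.
* **Events**: ecDNA prevalence 19% marginally, injected as cyclic amplicons
  (one head-to-tail junction closing a 0.5–2 Mb locus at TCN 8–40); BFB as
  two tight foldback inversions at one boundary; linear amplifications with
  no SV; chromothripsis as 10–16 clustered SVs (types uniform over
  DUP/DEL/h2hINV/t2tINV) over a 3 Mb window whose copy number oscillates
  between the retained state and a one-copy loss.
* **logR noise** is Gaussian per segment with sd 0.01: segment-level logR
  is a mean over thousands of bins after segmentation, so small sd is the
  realistic regime.
* **Effects**: ecDNA status is drawn from a logistic model whose linear
  predictor carries $\log(4.0) \cdot \mathrm{WGD}$ (intercept solved for
  the marginal prevalence); survival is exponential with hazard multiplied
  by 2.17 for ecDNA-positive samples, with independent exponential
  censoring tuned to a 30% censoring fraction. Telomere read groups and
  mito/nuclear depths are emitted with known ground-truth ratios.
* **Determinism**: all randomness derives from one integer seed;
  per-sample streams are derived from (seed, sample index), so identical
  configurations give byte-identical output files.

Event flags are drawn *before* genomes are built, so the injected genomic
lesions agree exactly with the clinical table (every flagged sample carries
its cyclic junction, and no unflagged sample does).

What the generator does **not** emulate — and hence what green tests do not
certify about real data: read-level artifacts (mappability, GC, replication
timing waves), subclonal copy number, segmentation errors, allele-specific
CN noise, SV breakend imprecision, co-located overlapping events, and
realistic genome/chromosome-arm structure. The classifier's 100% accuracy
on noiseless injections is a correctness check of the decision rule, not an
accuracy claim for real tumors.

## Numerical choices and degenerate inputs

Logistic/Firth convergence is score-based (max |score| < 1e-10, with
step-halving on the penalized likelihood); profile CI roots are bracketed
outward in standard-error steps and solved by `uniroot` to 1e-6. Seed
calling refuses unsorted input rather than sorting silently. Negative
rescaled TCN clamps to 0 with a counted warning. Oscillation counting
tolerates no third state inside a run; equal neighboring values break the
run. Empty segment lists, zero-read telomere groups, non-positive depths
and all-zero 2×2 tables raise errors rather than propagate NaN.

## Problem sizes

The bundled analyses and tests use a 200-sample cohort on the 10 Mb toy
genome (whole suite ~35 s); the effect-recovery study uses 100 replicates
of 1,000-sample clinical tables (~20 s). These sizes give stable estimates
for every reported quantity — e.g. binomial sd ~2% on coverage rates —
while keeping the workflow comfortably interactive.

## Known limitations

The amplicon classifier is a decision rule over a breakpoint graph, not a
copy-count deconvolution; it cannot separate intertwined amplicons sharing
a component, and its ecDNA/BFB boundary is only as good as the foldback
heuristic. The chromothripsis engine's (iii)/(iv) tests are stand-ins, and
their miss rate (~4–5% of genuine clustered events fail the chi-square
randomness check by chance) bounds cohort sensitivity near 0.95. The WGD
rule depends on the conventional major-CN cutoff of 3, which requires
post-doubling gains or imbalance to trigger; a freshly doubled 2+2 genome
is not called. Mann-Whitney exact enumeration is limited to 12 combined
observations.
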