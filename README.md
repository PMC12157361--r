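# ecdnatools

Purity-aware detection and characterization of extrachromosomal DNA (ecDNA)
in tumor whole genomes, with the genome-instability metrics and statistics
that go with it.

ecDNA elements are circular amplicons that drive oncogene amplification and
worse survival in lung and other cancers. Detecting them from whole-genome
sequencing starts from read-depth copy number, which is diluted by normal
cells: at 15% tumor purity, a 12-copy amplicon shows a tumor/normal depth
ratio of only ~1.7 and a naive caller reports copy number ~3.4 — invisible
to any amplification threshold. `ecdnatools` implements the bespoke
computational stages of a large lung-cancer ecDNA study as a reusable,
tested R package:

* **Copy number** — purity/ploidy rescaling
  `TCN = (ψ·2^logR − 2(1−ρ)) / ρ` (purity ρ, ploidy ψ) and amplicon seed
  calling (CN ≥ 4.5, ≥ 50 kb, merged across ≤ 300 kb).
* **Amplicons** — an oriented-endpoint breakpoint graph over padded seeds;
  each connected component is classified ecDNA (cycle through a discordant
  junction + high CN), BFB (foldback-inversion dominated), complex
  non-cyclic, or linear. A documented simplification of full amplicon
  reconstruction.
* **Instability** — whole-genome doubling (major CN ≥ 3 over > 50% of the
  genome, length-weighted), wGII (per-autosome aberrant fractions divided
  by 22), telomere tumor/normal log2 ratio from ≥ 7 TTAGGG/CCCTAA repeats
  per read, purity/ploidy-adjusted mitochondrial copy number.
* **Chromothripsis** — the four high-confidence criteria: > 6 clustered
  SVs, > 7 two-state copy-number oscillations, breakpoint enrichment
  (binomial, p < 0.05), join randomness (chi-square, p > 0.05) and/or ≥ 4
  inter-chromosomal rearrangements; plus ecDNA-overlap measurement.
* **Cargo** — oncogene / immunomodulatory / regulatory cargo with 100%
  containment rules, strand-aware promoters, and the six-criterion driver
  mutation classifier.
* **Statistics** — logistic and Firth-penalized logistic regression
  (hand-implemented modified-score iteration with profile-penalized CIs),
  BH-FDR, exact Mann-Whitney, 2×2 odds ratios with Fisher exact tests, and
  Cox proportional hazards (Efron ties) with the three-level amplification
  factor referenced to "other focal amplification".
* **Synthetic cohorts** — a first-class generator that emits segment
  tables, BEDPE SVs, telomere read groups, depths, clinical covariates and
  survival with known ground truth and injected effect sizes (WGD→ecDNA
  OR 4.0, ecDNA survival HR 2.17), so the whole pipeline is testable
  offline.

## Worked example

A 15%-purity tumor with a 12-copy circular amplicon on chr7:

```r
library(ecdnatools)

cfg  <- simulation_config(n_samples = 1, logr_noise_sd = 0, rng_seed = 7)
prof <- simulate_segment_profile(cfg, 1, is_wgd = FALSE, purity = 0.15)
prof <- inject_focal_amplicon(prof, "chr7", 2e6, 3e6, cn = 12, kind = "cyclic")

model <- ploidy_model(prof$purity, prof$ploidy)
#> <ploidy_model> purity = 0.150, ploidy = 2.045

seg <- prof$segments
seg$logR[seg$chrom == "chr7" & seg$start == 2e6]       # 0.775
uncorrected_total_copy_number(0.775)                   # 3.42 -- missed

res <- amplicon_pipeline(seg, model, prof$sv)
res$seeds
#>   chrom start   end max_tcn
#> 1  chr7 2e+06 3e+06      12
res$classes                  # "ecDNA"
res$summary$ecdna_positive   # TRUE

amplicon_pipeline(seg, model, prof$sv, corrected = FALSE)$seeds
#> (no rows -- the uncorrected pipeline misses the amplicon entirely)
```

The corrected pipeline recovers the true copy number (12) and classifies
the amplicon as ecDNA from its cycle-closing junction; the naive pipeline
sees CN 3.4 and finds nothing.

## The analysis workflow

Numbered drivers under `analysis/` run the full study workflow on a
simulated 200-sample cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R        # cohort + ground truth
Rscript analysis/02_copy_number_seeds.R      # corrected vs uncorrected seeds
Rscript analysis/03_amplicons.R              # ecDNA/BFB/linear classification
Rscript analysis/04_instability.R            # WGD, wGII, telomeres, mito CN
Rscript analysis/05_chromothripsis.R         # criteria + ecDNA overlap
Rscript analysis/06_cargo.R                  # cargo + driver mutations
Rscript analysis/07_associations_survival.R  # logistic/Firth/Cox layer
```

On the default cohort this reports, among others: 29/29 ecDNA-positive
samples recovered (100% agreement), chromothripsis sensitivity 0.96 at
specificity 1.00, a WGD→ecDNA odds ratio of 3.5 (injected 4.0) and an
ecDNA-vs-chromosomal-amplification hazard ratio of 2.05 (injected 2.17).

## Scope

Purity/ploidy estimation, segmentation, SV calling, full amplicon graph
reconstruction, signature extraction and driver-gene discovery are treated
as upstream inputs (or simulated); see the vignette
(`vignettes/ecdna-pipeline.Rmd`) for the models, parameter defaults, design
decisions and known limitations.
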