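#!/usr/bin/env Rscript
# Cargo classification of called ecDNA amplicons against a synthetic gene /
# enhancer annotation of the toy genome (oncogenes, immunomodulatory genes,
# other genes, enhancers, promoters), plus the six-criterion driver-mutation
# classifier on a synthetic mutation table.

library(ecdnatools)

set.seed(1)
genome <- toy_genome()

# synthetic annotation: 8 genes per chromosome (1 oncogene, 1 immuno, 6
# other), 20 enhancers per chromosome
genes <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
  ch <- genome$chrom[i]
  start <- sort(sample(seq(1e5, 9.6e6, by = 1e5), 8))
  data.frame(name = sprintf("%s_g%d", ch, 1:8), chrom = ch, start = start,
             end = start + sample(2e4:2e5, 8), strand = sample(c("+", "-"),
                                                               8, TRUE),
             is_oncogene = c(TRUE, rep(FALSE, 7)),
             is_immunomodulatory = c(FALSE, TRUE, rep(FALSE, 6)),
             is_tumor_suppressor = c(rep(FALSE, 7), TRUE),
             stringsAsFactors = FALSE)
}))
enhancers <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
  start <- sort(sample(seq(5e4, 9.9e6, by = 5e4), 20))
  data.frame(chrom = genome$chrom[i], start = start,
             end = start + sample(500:5000, 20), stringsAsFactors = FALSE)
}))
promoters <- promoter_regions(genes)

amps <- read.delim("results/amplicons.tsv")
ec <- amps[amps$class == "ecDNA", ]
parse_intervals <- function(s) {
  parts <- strsplit(strsplit(s, ";")[[1]], "[:-]")
  data.frame(chrom = vapply(parts, `[`, "", 1),
             start = as.numeric(vapply(parts, `[`, "", 2)),
             end = as.numeric(vapply(parts, `[`, "", 3)))
}
cargo <- do.call(rbind, lapply(seq_len(nrow(ec)), function(i) {
  iv <- parse_intervals(ec$intervals[i])
  ann <- annotate_ecdna(iv, genes, enhancers, promoters)
  data.frame(sample_id = ec$sample_id[i], amplicon_id = ec$amplicon_id[i],
             category = classify_cargo(ann),
             genes = paste(ann$genes, collapse = ","),
             has_enhancer = ann$has_enhancer,
             has_promoter = ann$has_promoter, stringsAsFactors = FALSE)
}))
write.table(cargo, "results/cargo.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("cargo classes for", nrow(cargo), "ecDNA amplicons:\n")
print(table(cargo$category))

# synthetic mutation table over the annotated genes
muts <- data.frame(
  gene = sample(genes$name, 300, TRUE),
  consequence = sample(c("truncating", "missense", "other"), 300, TRUE,
                       prob = c(0.2, 0.5, 0.3)),
  recurrence_count = sample(1:5, 300, TRUE, prob = c(0.5, 0.25, 0.15,
                                                     0.07, 0.03)),
  boostdm_score = ifelse(runif(300) < 0.3, runif(300), NA),
  oncokb_label = sample(c(NA, "Oncogenic", "Likely Oncogenic", "VUS"), 300,
                        TRUE, prob = c(0.6, 0.1, 0.1, 0.2)),
  mc3_flag = runif(300) < 0.05,
  pathogenicity_label = sample(c(NA, "likely pathogenic", "benign"), 300,
                               TRUE, prob = c(0.7, 0.15, 0.15)),
  stringsAsFactors = FALSE)
muts$is_driver <- vapply(seq_len(nrow(muts)), function(i) {
  g <- genes[genes$name == muts$gene[i], ]
  classify_driver_mutation(muts$consequence[i], g$is_tumor_suppressor,
                           muts$recurrence_count[i], muts$boostdm_score[i],
                           muts$oncokb_label[i], muts$mc3_flag[i],
                           muts$pathogenicity_label[i])
}, logical(1))
write.table(muts, "results/driver_mutations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("driver mutations: %d/%d records classified as potential drivers\n",
            sum(muts$is_driver), nrow(muts)))
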