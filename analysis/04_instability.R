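#!/usr/bin/env Rscript
# Genome-instability metrics per sample: whole-genome doubling (major CN >= 3
# over more than half the genome), wGII, telomere-length tumor/normal log2
# ratio from read-group repeat counts, and purity/ploidy-adjusted
# mitochondrial copy number.

library(ecdnatools)

dir <- "results/cohort"
samples <- read.delim(file.path(dir, "samples.tsv"))
telomere <- read.delim(file.path(dir, "telomere_readgroups.tsv"))
depths <- read.delim(file.path(dir, "depths.tsv"))
truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                             simplifyVector = TRUE)$samples

rows <- lapply(seq_len(nrow(samples)), function(i) {
  sid <- samples$sample_id[i]
  seg <- read_segments(file.path(dir, paste0(sid, ".segments.tsv")))
  m <- ploidy_model(samples$purity[i], samples$ploidy[i])
  seg$tcn <- as.numeric(rescale_total_copy_number(seg$logR, m, warn = FALSE))
  gii <- compute_wgii(seg)
  tl <- telomere[telomere$sample_id == sid, ]
  tl_t <- estimate_sample_tl(tl[tl$tissue == "tumor", ])
  tl_n <- estimate_sample_tl(tl[tl$tissue == "normal", ])
  dp <- depths[depths$sample_id == sid, ]
  data.frame(
    sample_id = sid, is_wgd = call_wgd(seg), wgii = gii$wgii,
    ploidy_lw = gii$ploidy_lw,
    tl_log2_ratio = tl_log2_ratio(tl_t, tl_n),
    mt_cn = mito_copy_number(dp$depth_mt_t, dp$depth_nuc_t, dp$depth_mt_n,
                             dp$depth_nuc_n, m),
    stringsAsFactors = FALSE)
})
instability <- do.call(rbind, rows)
write.table(instability, "results/instability.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

merged <- merge(instability, truth, by = "sample_id")
cat("instability metrics written to results/instability.tsv\n")
cat(sprintf("  WGD call agreement with truth: %.1f%%\n",
            100 * mean(merged$is_wgd.x == merged$is_wgd.y)))
cat(sprintf("  wGII: median %.3f (WGD %.3f, non-WGD %.3f)\n",
            median(merged$wgii), median(merged$wgii[merged$is_wgd.y]),
            median(merged$wgii[!merged$is_wgd.y])))
cat(sprintf("  TL log2 ratio vs truth: r = %.3f\n",
            cor(merged$tl_log2_ratio, merged$tl_log2_ratio_true)))
cat(sprintf("  mito CN vs truth: median relative error %.2f%%\n",
            100 * median(abs(merged$mt_cn - merged$mt_cn_true) /
                           merged$mt_cn_true)))
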