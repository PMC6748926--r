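#!/usr/bin/env Rscript
# MAG relative sequence abundance from per-contig coverage, and variant
# co-occurrence across samples.

suppressPackageStartupMessages(library(sodamat))
data_dir <- "results/data"

raw <- sodamat:::read_tsv_meta(file.path(data_dir, "depth_table.tsv"))
meta <- attr(raw, "meta")
tab <- ContigCoverageTable(raw, sample_cols = c("S1", "S2"))
total_bases <- c(S1 = as.numeric(meta[["total_bases_S1"]]),
                 S2 = as.numeric(meta[["total_bases_S2"]]))

abund <- mag_abundance_table(tab, total_bases = total_bases)
message("MAG relative sequence abundances (fraction of sequenced nucleotides):")
print(abund, digits = 4)
message(sprintf("per-sample sums incl. unbinned: %s",
                paste(sprintf("%.6f", colSums(abund[c("S1", "S2")])),
                      collapse = ", ")))

mags <- setdiff(abund$mag, "unbinned")
co <- variant_cooccurrence(as.matrix(abund[abund$mag %in% mags,
                                           c("S1", "S2")]))
message(sprintf("all MAGs co-detected in at least one sample: %s",
                co$all_cooccur))

sodamat:::write_tsv_meta(abund, "results/mag_abundance.tsv")
message("wrote results/mag_abundance.tsv")
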