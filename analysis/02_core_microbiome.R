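#!/usr/bin/env Rscript
# Core-microbiome detection: which OTUs are present in every lake, how much
# of the richness and of the reads they account for, and how similar the
# communities are (Bray-Curtis).

suppressPackageStartupMessages(library(sodamat))
data_dir <- "results/data"
out <- "results"

tab <- read_otu_table(file.path(data_dir, "otu_counts.tsv"),
                      file.path(data_dir, "otu_meta.tsv"))
truth <- jsonlite::read_json(file.path(data_dir, "otu_truth.json"),
                             simplifyVector = TRUE)

presence <- presence_by_lake(tab, min_count = 1)
core <- find_core(presence)
summ <- core_summary(tab, core)
message(sprintf("%d of %d OTUs are core (present in all %d lakes)",
                length(core), nrow(tab$counts), ncol(presence)))
message(sprintf("core richness fraction: %.1f%%; core read fraction: %.1f%%",
                100 * summ$richness_fraction, 100 * summ$read_fraction))
message(sprintf("planted core recovered exactly: %s",
                setequal(core, truth$core_otu_ids)))

sodamat:::write_tsv_meta(data.frame(otu = core),
                         file.path(out, "core_otus.tsv"))
jsonlite::write_json(summ[c("richness_fraction", "read_fraction",
                            "read_fraction_per_sample_mean")],
                     file.path(out, "core_summary.json"), auto_unbox = TRUE,
                     digits = NA)

bc <- bray_curtis(exclude_rare(tab, 0.01))
sodamat:::write_tsv_meta(data.frame(sample = rownames(bc), bc,
                                    check.names = FALSE),
                         file.path(out, "bray_curtis.tsv"))
message("wrote core_otus.tsv, core_summary.json, bray_curtis.tsv")
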