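#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume, with
# planted ground truth, under results/data/.

suppressPackageStartupMessages(library(sodamat))
seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Simulating the OTU community: 4 lakes x 3 years, 500 OTUs, ",
        "planted core of 100")
comm <- simulate_otu_table(community_sim_config(seed = seed))
write_otu_table(comm$table, file.path(out, "otu_counts.tsv"),
                file.path(out, "otu_meta.tsv"), meta_header = c(seed = seed))
jsonlite::write_json(comm$truth[c("core_otu_ids", "expected_read_fraction")],
                     file.path(out, "otu_truth.json"), auto_unbox = TRUE,
                     digits = NA)

message("Simulating a depth table for 4 MAGs plus unbinned contigs")
depth <- simulate_depth_table(
  c(MAG_01 = 0.22, MAG_02 = 0.004, MAG_03 = 0.105, MAG_04 = 0.0007),
  total_bases = c(S1 = 6e8, S2 = 3e8), n_contigs = 7, seed = seed)
sodamat:::write_tsv_meta(depth$contigs, file.path(out, "depth_table.tsv"),
                         c(seed = seed, total_bases_S1 = 6e8,
                           total_bases_S2 = 3e8))

message("Simulating a genome with 8 genes and one neutral variant")
mcfg <- mutation_sim_config(genome_length = 24000, n_genes = 8,
                            substitution_rate = 0.03, seed = seed)
genome <- simulate_genome(mcfg)
variant <- mutate_genome(genome, mcfg)
alns <- gene_variant_alignments(genome, list(v1 = variant))
dir.create(file.path(out, "alignments"), showWarnings = FALSE)
for (g in names(alns)) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(alns[[g]]),
                              file.path(out, "alignments",
                                        paste0(g, ".fasta")))
}
write.table(variant$log, file.path(out, "mutation_log.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("Simulating 48 matched genome pairs across two regions")
rp <- simulate_region_pair(region_pair_sim_config(
  n_genomes = 48, genome_length = 10200, divergence_noise_sd = 0.2,
  seed = seed))
# sequences are bulky and re-derivable from the seed; only the truth is kept
sodamat:::write_tsv_meta(rp$truth, file.path(out, "region_truth.tsv"),
                         c(seed = seed, truth_r = rp$truth_r))

message("Simulating the metaproteome PSM table (8 MAGs + unbinned)")
ps <- simulate_psm_table(proteome_sim_config(seed = seed))
sodamat:::write_tsv_meta(ps$table, file.path(out, "psm_table.tsv"),
                         c(seed = seed))
jsonlite::write_json(list(mag_shares = as.list(ps$truth$mag_shares),
                          category_shares = as.list(ps$truth$category_shares),
                          contaminant_ids = ps$truth$contaminant_ids),
                     file.path(out, "psm_truth.json"), auto_unbox = TRUE,
                     digits = NA)
message("Done; inputs under ", out)
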