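test_that("simulate_otu_table plants the forced design and is deterministic", {
  cfg <- community_sim_config(n_otus = 500, core_fraction = 0.2, seed = 7)
  sim <- simulate_otu_table(cfg)
  expect_length(sim$truth$core_otu_ids, 100)
  expect_identical(sim, simulate_otu_table(cfg))

  sim2 <- simulate_otu_table(community_sim_config(n_lakes = 4, n_years = 3,
                                                  n_otus = 50, seed = 2))
  expect_equal(ncol(sim2$table$counts), 12)
  expect_equal(nrow(sim2$table$meta), 12)

  # structural zeros: every non-core OTU is excluded from >= 1 lake
  noncore <- setdiff(rownames(sim$table$counts), sim$truth$core_otu_ids)
  mem <- sim$truth$lake_membership[noncore, , drop = FALSE]
  expect_true(all(rowSums(mem) < ncol(mem)))
  expect_true(all(sim$truth$lake_membership[sim$truth$core_otu_ids, ]))
  # and the counts respect the membership
  pres <- presence_by_lake(sim$table, 1)
  expect_true(all(pres[!sim$truth$lake_membership] == FALSE))

  expect_error(community_sim_config(n_otus = 0), "positive")
})

test_that("simulate_genome emits valid in-frame CDS annotations", {
  cfg <- mutation_sim_config(genome_length = 6000, n_genes = 5, seed = 11)
  g <- simulate_genome(cfg)
  expect_identical(g, simulate_genome(cfg))
  expect_equal(nrow(g$cds), 5)
  lens <- g$cds$end - g$cds$start + 1
  expect_true(all(lens %% 3 == 0))
  # non-overlapping
  ord <- order(g$cds$start)
  expect_true(all(g$cds$start[ord][-1] > g$cds$end[ord][-5]))
  for (i in seq_len(5)) {
    cds <- substr(g$sequence, g$cds$start[i], g$cds$end[i])
    expect_identical(substr(cds, 1, 3), "ATG")
    aa <- translate_codons(substring(cds, seq(1, nchar(cds), 3),
                                     seq(3, nchar(cds), 3)))
    expect_false(any(aa[-length(aa)] == "*"))
  }

  one <- simulate_genome(mutation_sim_config(genome_length = 300, n_genes = 1,
                                             seed = 1))
  expect_equal(nrow(one$cds), 1)
  expect_lte(one$cds$end - one$cds$start + 1, 300)
  expect_error(mutation_sim_config(genome_length = 10, n_genes = 5),
               "infeasible")
})

test_that("mutate_genome logs are exhaustive and class-pure", {
  cfg <- mutation_sim_config(genome_length = 9000, n_genes = 6,
                             substitution_rate = 0.03, seed = 4)
  genome <- simulate_genome(cfg)

  # rate 0: identical sequence, empty log
  cfg0 <- mutation_sim_config(genome_length = 9000, n_genes = 6,
                              substitution_rate = 0, seed = 4)
  v0 <- mutate_genome(genome, cfg0)
  expect_identical(v0$sequence, genome$sequence)
  expect_equal(nrow(v0$log), 0)

  # log completeness: reference + log reproduces the variant exactly
  v <- mutate_genome(genome, cfg)
  chars <- strsplit(genome$sequence, "")[[1]]
  expect_identical(chars[v$log$position], v$log$ref)
  chars[v$log$position] <- v$log$alt
  expect_identical(paste(chars, collapse = ""), v$sequence)

  # class purity: exhaustive re-classification of logged CDS mutations
  for (mode in c("synonymous_only", "nonsynonymous_only")) {
    cfgm <- mutation_sim_config(genome_length = 9000, n_genes = 6,
                                substitution_rate = 0.03,
                                mutation_mode = mode, seed = 4)
    vm <- mutate_genome(genome, cfgm)
    expect_gt(nrow(vm$log), 0)
    want <- if (mode == "synonymous_only") "synonymous" else "non-synonymous"
    map <- sodamat:::cds_site_map(genome)
    ref_chars <- strsplit(genome$sequence, "")[[1]]
    recls <- vapply(seq_len(nrow(vm$log)), function(i) {
      p <- vm$log$position[i]
      codon <- paste(ref_chars[map$codon_start[p]:(map$codon_start[p] + 2)],
                     collapse = "")
      classify_substitution(codon, map$codon_pos[p], vm$log$alt[i])
    }, character(1))
    expect_true(all(recls == want))
    expect_true(all(vm$log$class == want))
  }
})

test_that("neutral mutation count matches the binomial expectation", {
  cfg <- mutation_sim_config(genome_length = 50001, n_genes = 10,
                             substitution_rate = 0.05, seed = 21)
  genome <- simulate_genome(cfg)
  v <- mutate_genome(genome, cfg)
  expected <- 50001 * 0.05
  sd3 <- 3 * sqrt(50001 * 0.05 * 0.95)
  expect_lt(abs(nrow(v$log) - expected), sd3)
})

test_that("synonymous-only variants screen as fully synonymous", {
  cfg <- mutation_sim_config(genome_length = 9000, n_genes = 4,
                             substitution_rate = 0.04,
                             mutation_mode = "synonymous_only", seed = 9)
  genome <- simulate_genome(cfg)
  alns <- gene_variant_alignments(genome, list(mutate_genome(genome, cfg)))
  res <- screen_genes(alns)
  with_snps <- res[res$n_snps > 0, ]
  expect_gt(nrow(with_snps), 0)
  expect_true(all(with_snps$nonsyn_fraction == 0))
})

test_that("simulate_region_pair plants matched pairs with a known correlation", {
  cfg <- region_pair_sim_config(n_genomes = 48, genome_length = 2000, seed = 5)
  rp <- simulate_region_pair(cfg)
  expect_identical(rp, simulate_region_pair(cfg))
  expect_equal(nrow(rp$truth), 48)
  expect_equal(nrow(rp$region_a), 48)
  expect_true(all(rp$truth$divergence >= 0 & rp$truth$divergence <= 30))

  noiseless <- simulate_region_pair(region_pair_sim_config(
    n_genomes = 20, genome_length = 3000, divergence_slope = -3,
    divergence_noise_sd = 0, seed = 2))
  expect_lt(abs(noiseless$truth_r - (-1)), 0.02)  # off -1 only by rounding to whole sites

  flat <- simulate_region_pair(region_pair_sim_config(
    n_genomes = 48, genome_length = 3000, divergence_slope = 0,
    divergence_noise_sd = 1, seed = 2))
  expect_lt(abs(flat$truth_r), 0.35)
})

test_that("simulate_psm_table plants recoverable shares and violators", {
  cfg <- proteome_sim_config(seed = 3)
  ps <- simulate_psm_table(cfg)
  expect_identical(ps, simulate_psm_table(cfg))
  expect_equal(sum(ps$truth$mag_shares), 1)
  expect_true("unbinned" %in% names(ps$truth$mag_shares))

  clean <- simulate_psm_table(proteome_sim_config(
    fdr_contamination_fraction = 0, seed = 3))
  expect_length(clean$truth$contaminant_ids, 0)
  expect_equal(nrow(filter_identifications(clean$table)$rejected), 0)

  flt <- filter_identifications(ps$table)
  expect_setequal(flt$rejected$protein_id, ps$truth$contaminant_ids)

  # one MAG, uniform proteins: recovered share is exactly 1
  rec <- data.frame(mag = "MAG_01", length_aa = 300, counts = rep(10, 5),
                    unique_peptides = 3, protein_unique_peptides = 1,
                    fdr = 0.01)
  fr <- relative_abundance_nsaf(rec)
  expect_equal(mag_share(fr, rec$mag, "MAG_01"), 1)
})
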