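#' Engineer a two-variant gene alignment with exact screen statistics
#'
#' Builds an in-frame gene (ATG followed by AAA codons) and a variant carrying
#' exactly `n_snps` single-base differences, of which exactly `n_nonsyn` are
#' non-synonymous (AAA -> GAA, Lys -> Glu, first codon position) and the rest
#' synonymous (AAA -> AAG, third position). Used to probe the strict screen
#' thresholds.
#'
#' @param n_snps Total SNP columns to plant.
#' @param n_nonsyn Non-synonymous SNPs among them.
#' @param n_positions Alignment length (multiple of 3, >= `3 * (n_snps + 1)`).
#' @return Named character vector of two aligned sequences.
#' @export
engineer_screen_alignment <- function(n_snps, n_nonsyn, n_positions) {
  stopifnot(n_nonsyn <= n_snps, n_positions %% 3 == 0,
            n_positions >= 3 * (n_snps + 1))
  n_codons <- n_positions / 3
  ref <- paste(c("ATG", rep("AAA", n_codons - 1)), collapse = "")
  var <- seq_chars(ref)
  # codons 2..(n_snps + 1): first n_nonsyn get pos-1 A->G, rest pos-3 A->G
  for (i in seq_len(n_snps)) {
    codon_start <- 3 * i + 1  # codon i + 1
    if (i <= n_nonsyn) var[codon_start] <- "G" else var[codon_start + 2] <- "G"
  }
  c(ref = ref, var = paste(var, collapse = ""))
}

pipeline_stages <- c("simulate", "core", "mag_abund", "select_screen",
                     "cross_region", "proteome")

#' Build a validated pipeline run configuration
#'
#' @param stages Character vector of stages to run, in any order (executed in
#'   dependency order); subset of `simulate`, `core`, `mag_abund`,
#'   `select_screen`, `cross_region`, `proteome`.
#' @param seed Integer seed forwarded to every generator.
#' @param out_dir Output directory (created if missing).
#' @param community,mutation,region,proteome Lists of overrides for the
#'   corresponding `*_sim_config()` constructors.
#' @param thresholds A [screen_thresholds()] object.
#' @param min_count,rare_threshold,min_abundance Stage parameters for core
#'   detection, rare-OTU exclusion and variant co-occurrence.
#' @param ... Rejected: any unknown key raises an error naming it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(stages = pipeline_stages, seed = 1,
                       out_dir = tempfile("sodamat_run_"),
                       community = list(), mutation = list(), region = list(),
                       proteome = list(), thresholds = screen_thresholds(),
                       min_count = 1, rare_threshold = 0.01,
                       min_abundance = 0, ...) {
  extra <- list(...)
  if (length(extra)) {
    stop_input("unknown configuration key(s): ",
               paste(names(extra), collapse = ", "))
  }
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop_input("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(stages = stages, seed = seed, out_dir = out_dir,
                 community = community, mutation = mutation, region = region,
                 proteome = proteome, thresholds = thresholds,
                 min_count = min_count, rare_threshold = rare_threshold,
                 min_abundance = min_abundance),
            class = "run_config")
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the synthetic analysis pipeline
#'
#' Executes the requested stages in dependency order (simulation first), logs
#' record counts at every filter to stderr, writes each stage's tables under
#' `config$out_dir`, emits the resolved configuration as JSON, and finishes
#' with a manifest listing every output file and its MD5 checksum. Identical
#' seed and configuration give a byte-identical manifest.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `outputs` (named file paths) and `manifest`
#'   (data.frame: file, md5).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!length(config$stages)) {
    warning("empty stage list; nothing to do")
    return(invisible(list(outputs = character(), manifest = NULL)))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- file.path(config$out_dir, "")
  stages <- pipeline_stages[pipeline_stages %in% config$stages]
  log <- function(...) message("[sodamat] ", sprintf(...))
  outputs <- character()
  add <- function(path) outputs <<- c(outputs, path)

  resolved <- unclass(config)
  resolved$thresholds <- unclass(config$thresholds)
  resolved$version <- as.character(packageVersion("sodamat"))
  cfg_path <- file.path(config$out_dir, "run_config.json")
  write_json_out(resolved, cfg_path); add(cfg_path)

  sim <- NULL
  need_sim <- TRUE  # downstream stages consume the simulated inputs
  if (need_sim) {
    log("simulate: seed %d", config$seed)
    sim <- list(
      community = simulate_otu_table(
        do.call(community_sim_config, c(config$community, seed = config$seed))),
      depth = simulate_depth_table(
        c(MAG_01 = 0.25, MAG_02 = 0.15, MAG_03 = 0.05),
        seed = config$seed),
      region = simulate_region_pair(
        do.call(region_pair_sim_config,
                c(if (length(config$region)) config$region
                  else list(n_genomes = 12, genome_length = 5000),
                  seed = config$seed))),
      proteome = simulate_psm_table(
        do.call(proteome_sim_config, c(config$proteome, seed = config$seed))))
    mut_cfg <- do.call(mutation_sim_config,
                       c(if (length(config$mutation)) config$mutation
                         else list(genome_length = 9000, n_genes = 3),
                         list(seed = config$seed)))
    genome <- simulate_genome(mut_cfg)
    sim$alignments <- gene_variant_alignments(
      genome, list(v1 = mutate_genome(genome, mut_cfg)))
  }

  if ("simulate" %in% stages) {
    p1 <- file.path(config$out_dir, "otu_counts.tsv")
    p2 <- file.path(config$out_dir, "otu_meta.tsv")
    write_otu_table(sim$community$table, p1, p2,
                    meta_header = c(seed = config$seed))
    add(p1); add(p2)
    p <- file.path(config$out_dir, "otu_truth.json")
    write_json_out(sim$community$truth[c("core_otu_ids",
                                         "expected_read_fraction")], p)
    add(p)
    p <- file.path(config$out_dir, "depth_table.tsv")
    write_tsv_meta(sim$depth$contigs, p, c(seed = config$seed)); add(p)
    p <- file.path(config$out_dir, "psm_table.tsv")
    write_tsv_meta(sim$proteome$table, p, c(seed = config$seed)); add(p)
    aln_dir <- file.path(config$out_dir, "alignments")
    dir.create(aln_dir, showWarnings = FALSE)
    for (g in names(sim$alignments)) {
      p <- file.path(aln_dir, paste0(g, ".fasta"))
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(sim$alignments[[g]]), p)
      add(p)
    }
  }

  if ("core" %in% stages) {
    tab <- sim$community$table
    log("core: %d OTUs in, rare threshold %.3f", nrow(tab$counts),
        config$rare_threshold)
    presence <- presence_by_lake(tab, config$min_count)
    core <- find_core(presence)
    summ <- core_summary(tab, core, config$min_count)
    log("core: %d core OTUs out of %d", length(core), nrow(tab$counts))
    p <- file.path(config$out_dir, "core_otus.tsv")
    write_tsv_meta(data.frame(otu = core), p); add(p)
    p <- file.path(config$out_dir, "core_summary.json")
    write_json_out(summ[c("richness_fraction", "read_fraction",
                          "read_fraction_per_sample_mean")], p)
    add(p)
    bc <- bray_curtis(exclude_rare(tab, config$rare_threshold))
    p <- file.path(config$out_dir, "bray_curtis.tsv")
    write_tsv_meta(data.frame(sample = rownames(bc), bc,
                              check.names = FALSE), p)
    add(p)
  }

  if ("mag_abund" %in% stages) {
    abund <- mag_abundance_table(sim$depth)
    log("mag_abund: %d MAGs x %d samples", nrow(abund),
        length(sim$depth$sample_cols))
    p <- file.path(config$out_dir, "mag_abundance.tsv")
    write_tsv_meta(abund, p); add(p)
  }

  if ("select_screen" %in% stages) {
    res <- screen_genes(sim$alignments, config$thresholds)
    log("select_screen: %d genes in, %d diversified", nrow(res),
        sum(res$diversified))
    p <- file.path(config$out_dir, "selection_screen.tsv")
    write_tsv_meta(res, p); add(p)
    p <- file.path(config$out_dir, "selection_summary.json")
    write_json_out(list(n_genes = nrow(res),
                        n_diversified = sum(res$diversified)), p)
    add(p)
  }

  if ("cross_region" %in% stages) {
    match <- best_match(sim$region$region_a, sim$region$region_b,
                        fragment_length = 1020)
    corr <- distance_abundance_correlation(100 - match$ani,
                                           sim$region$region_a$abundance,
                                           transform = "log10")
    log("cross_region: n = %d, r = %.3f, p = %.3g", corr$n, corr$r,
        corr$p_two_sided)
    p <- file.path(config$out_dir, "region_matches.tsv")
    write_tsv_meta(match, p); add(p)
    p <- file.path(config$out_dir, "distance_abundance.json")
    write_json_out(unclass(corr), p); add(p)
  }

  if ("proteome" %in% stages) {
    flt <- filter_identifications(sim$proteome$table)
    log("proteome: %d records in, %d retained, %d rejected",
        nrow(sim$proteome$table), nrow(flt$retained), nrow(flt$rejected))
    fr <- relative_abundance_nsaf(flt$retained)
    shares <- mag_shares(fr, flt$retained$mag)
    p <- file.path(config$out_dir, "mag_proteome_shares.tsv")
    write_tsv_meta(data.frame(mag = names(shares), share = round(shares, 6)),
                   p)
    add(p)
    alloc <- lapply(setdiff(names(shares), "unbinned"), function(m) {
      cs <- category_allocation(fr, flt$retained$mag,
                                flt$retained$category, m)
      data.frame(mag = m, category = names(cs), share = round(cs, 6),
                 stringsAsFactors = FALSE)
    })
    p <- file.path(config$out_dir, "category_allocation.tsv")
    write_tsv_meta(do.call(rbind, alloc), p); add(p)
  }

  manifest <- data.frame(
    file = sub(out, "", outputs, fixed = TRUE),
    md5 = unname(tools::md5sum(outputs)), stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  p <- file.path(config$out_dir, "manifest.tsv")
  write_tsv_meta(manifest, p)
  invisible(list(outputs = outputs, manifest = manifest))
}

#' Generate small bundled fixture datasets
#'
#' Emits one toy instance of each input kind, with truth JSON: an OTU table
#' (3 lakes x 2 years, 50 OTUs, planted core of 10), a depth table, a set of
#' gene alignments engineered against the screen thresholds (one passing gene
#' and one failing each single threshold at its printed boundary), a small
#' region pair, and a PSM table containing one record violating each
#' identification filter rule.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return Invisibly, named list of written paths.
#' @export
generate_fixtures <- function(seed = 1, out_dir = tempfile("sodamat_fix_")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  comm <- simulate_otu_table(community_sim_config(
    n_lakes = 3, n_years = 2, n_otus = 50, core_fraction = 0.2,
    depth_per_sample = 5000, seed = seed))
  paths$otu_counts <- file.path(out_dir, "otu_counts.tsv")
  paths$otu_meta <- file.path(out_dir, "otu_meta.tsv")
  write_otu_table(comm$table, paths$otu_counts, paths$otu_meta,
                  meta_header = c(seed = seed))
  paths$otu_truth <- file.path(out_dir, "otu_truth.json")
  write_json_out(comm$truth[c("core_otu_ids", "expected_read_fraction")],
                 paths$otu_truth)

  depth <- simulate_depth_table(c(MAG_01 = 0.3, MAG_02 = 0.1), seed = seed)
  paths$depth <- file.path(out_dir, "depth_table.tsv")
  write_tsv_meta(depth$contigs, paths$depth, c(seed = seed))

  # screen fixtures: pass, then one failure at each printed boundary
  aln <- list(
    gene_pass = engineer_screen_alignment(51, 43, 4251),      # frac .0120, nonsyn .843
    gene_low_snps = engineer_screen_alignment(50, 42, 4167),  # 50 SNPs (not > 50)
    gene_low_frac = engineer_screen_alignment(51, 43, 5100),  # frac exactly 0.01
    gene_low_nonsyn = engineer_screen_alignment(80, 66, 6000) # nonsyn exactly .825
  )
  aln_dir <- file.path(out_dir, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  for (g in names(aln)) {
    p <- file.path(aln_dir, paste0(g, ".fasta"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(aln[[g]]), p)
    paths[[g]] <- p
  }

  region <- simulate_region_pair(region_pair_sim_config(
    n_genomes = 6, genome_length = 3000, seed = seed))
  paths$region_truth <- file.path(out_dir, "region_truth.tsv")
  write_tsv_meta(region$truth, paths$region_truth, c(seed = seed))
  for (side in c("region_a", "region_b")) {
    p <- file.path(out_dir, paste0(side, ".fasta"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(
      stats::setNames(region[[side]]$sequence, region[[side]]$id)), p)
    paths[[side]] <- p
  }

  psm <- simulate_psm_table(proteome_sim_config(
    n_mags = 3, proteins_per_mag = 20, total_psms = 20000,
    fdr_contamination_fraction = 0.05, seed = seed))
  # guarantee one violator of each rule
  violators <- data.frame(
    protein_id = c("VIOL_fdr", "VIOL_unique", "VIOL_protein_unique"),
    mag = "unbinned", category = "other", length_aa = 300L,
    counts = 5L,
    unique_peptides = c(4L, 1L, 4L),
    protein_unique_peptides = c(2L, 2L, 0L),
    fdr = c(0.06, 0.01, 0.01), stringsAsFactors = FALSE)
  psm_tab <- rbind(psm$table, violators)
  paths$psm <- file.path(out_dir, "psm_table.tsv")
  write_tsv_meta(psm_tab, paths$psm, c(seed = seed))
  paths$psm_truth <- file.path(out_dir, "psm_truth.json")
  write_json_out(list(mag_shares = as.list(psm$truth$mag_shares),
                      contaminant_ids = c(psm$truth$contaminant_ids,
                                          violators$protein_id)),
                 paths$psm_truth)
  invisible(paths)
}
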