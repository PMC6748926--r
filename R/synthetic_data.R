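#' Configuration for the synthetic OTU community generator
#'
#' The defaults emulate the sampling design of the multi-lake mat survey the
#' pipeline was built for: four lakes sampled over three years, a few hundred
#' OTUs with a lognormal rank-abundance shape, and a planted core (one fifth
#' of the OTUs) that is boosted in abundance and present in every lake, while
#' every non-core OTU is structurally absent from at least one lake.
#'
#' @param n_lakes,n_years Sampling design; one sample per (lake, year).
#' @param n_otus Total OTU count.
#' @param core_fraction Fraction of OTUs planted as core; `core_fraction *
#'   n_otus` must round to the core set size.
#' @param abundance_log_mean,abundance_log_sd Lognormal parameters of the mean
#'   OTU abundance (relative weights).
#' @param core_boost Multiplicative abundance factor (>= 1) for core OTUs.
#' @param depth_per_sample Total reads per sample (multinomial draw size).
#' @param seed Integer seed for this generator's random stream.
#' @return A list of class `community_sim_config`.
#' @export
community_sim_config <- function(n_lakes = 4, n_years = 3, n_otus = 500,
                                 core_fraction = 0.2,
                                 abundance_log_mean = 0,
                                 abundance_log_sd = 1.2,
                                 core_boost = 10,
                                 depth_per_sample = 50000,
                                 seed = 1) {
  if (n_lakes < 1 || n_years < 1 || n_otus < 1 || depth_per_sample <= 0) {
    stop_input("community_sim_config: dimensions and depth must be positive")
  }
  if (core_fraction < 0 || core_fraction > 1) {
    stop_input("core_fraction must be in [0, 1]")
  }
  if (core_boost < 1) stop_input("core_boost must be >= 1")
  structure(list(n_lakes = n_lakes, n_years = n_years, n_otus = n_otus,
                 core_fraction = core_fraction,
                 abundance_log_mean = abundance_log_mean,
                 abundance_log_sd = abundance_log_sd,
                 core_boost = core_boost,
                 depth_per_sample = depth_per_sample, seed = seed),
            class = "community_sim_config")
}

#' Simulate an OTU count table with a planted core microbiome
#'
#' Core OTUs have nonzero expected abundance in every lake; each non-core OTU
#' is restricted to a random proper subset of lakes (structural zeros), so the
#' planted core is exactly recoverable by presence/absence intersection.
#' Counts are drawn multinomially per sample at `depth_per_sample`.
#'
#' @param config A [community_sim_config()].
#' @return List with `table` (an [OtuTable()]) and `truth` (list:
#'   `core_otu_ids`, `lake_membership` OTU x lake logical matrix,
#'   `expected_read_fraction` of core reads pooled over samples).
#' @export
simulate_otu_table <- function(config) {
  stopifnot(inherits(config, "community_sim_config"))
  with_stream(config$seed, "otu_table", {
    n <- config$n_otus
    lakes <- paste0("L", seq_len(config$n_lakes))
    otu_ids <- sprintf("OTU_%04d", seq_len(n))
    n_core <- round(config$core_fraction * n)
    core_ids <- sort(sample(otu_ids, n_core))
    is_core <- otu_ids %in% core_ids

    base <- rlnorm(n, config$abundance_log_mean, config$abundance_log_sd)
    base[is_core] <- base[is_core] * config$core_boost

    membership <- matrix(TRUE, n, config$n_lakes,
                         dimnames = list(otu_ids, lakes))
    if (config$n_lakes > 1) {
      for (i in which(!is_core)) {
        k <- sample(seq_len(config$n_lakes - 1), 1)
        membership[i, ] <- FALSE
        membership[i, sample(config$n_lakes, k)] <- TRUE
      }
    } else if (any(!is_core)) {
      stop_input("non-core OTUs need >= 2 lakes for structural zeros")
    }

    samples <- expand.grid(lake = lakes,
                           year = 2014 + seq_len(config$n_years) - 1,
                           stringsAsFactors = FALSE)
    samples$sample <- sprintf("%s_Y%d", samples$lake, samples$year)
    counts <- matrix(0L, n, nrow(samples),
                     dimnames = list(otu_ids, samples$sample))
    core_expected <- numeric(nrow(samples))
    for (s in seq_len(nrow(samples))) {
      w <- base * membership[, samples$lake[s]] *
        rlnorm(n, 0, 0.3)  # mild year-to-year wobble
      p <- w / sum(w)
      core_expected[s] <- sum(p[is_core])
      counts[, s] <- rmultinom(1, config$depth_per_sample, p)
    }
    meta <- data.frame(sample = samples$sample, lake = samples$lake,
                       year = samples$year, marker = "16S",
                       stringsAsFactors = FALSE)
    list(table = OtuTable(counts, meta),
         truth = list(core_otu_ids = core_ids,
                      lake_membership = membership,
                      expected_read_fraction = mean(core_expected)))
  })
}

#' Configuration for the synthetic genome / mutation generator
#'
#' @param genome_length Genome length in bp.
#' @param n_genes Number of CDS intervals to plant (`genome_length >=
#'   3 * n_genes` and the packing must fit).
#' @param substitution_rate Per-site substitution probability in `[0, 1)`.
#' @param mutation_mode One of `"neutral"`, `"synonymous_only"`,
#'   `"nonsynonymous_only"`. The constrained modes mutate CDS sites only and
#'   at most once per codon, so planted classes stay recoverable by
#'   column-wise codon classification.
#' @param seed Integer seed.
#' @return A list of class `mutation_sim_config`.
#' @export
mutation_sim_config <- function(genome_length = 50000, n_genes = 25,
                                substitution_rate = 0.05,
                                mutation_mode = c("neutral",
                                                  "synonymous_only",
                                                  "nonsynonymous_only"),
                                seed = 1) {
  mutation_mode <- match.arg(mutation_mode)
  if (genome_length < 3 * n_genes || n_genes < 0) {
    stop_input("infeasible: genome_length must be >= 3 * n_genes")
  }
  if (substitution_rate < 0 || substitution_rate >= 1) {
    stop_input("substitution_rate must be in [0, 1)")
  }
  structure(list(genome_length = genome_length, n_genes = n_genes,
                 substitution_rate = substitution_rate,
                 mutation_mode = mutation_mode, seed = seed),
            class = "mutation_sim_config")
}

# Sample one in-frame gene body: ATG + random non-stop codons.
random_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(matrix(sample(BASES, 3 * (n_codons - 1), replace = TRUE),
                         ncol = 3), 1, paste, collapse = "")
  hit <- codons %in% stops
  while (any(hit)) {
    codons[hit] <- apply(matrix(sample(BASES, 3 * sum(hit), replace = TRUE),
                                ncol = 3), 1, paste, collapse = "")
    hit <- codons %in% stops
  }
  paste(c("ATG", codons), collapse = "")
}

#' Simulate a reference genome with annotated in-frame CDS intervals
#'
#' CDS intervals are non-overlapping, each a multiple of 3, begin with a start
#' codon (ATG) and contain no internal stop codon (table 11).
#'
#' @param config A [mutation_sim_config()].
#' @return List of class `sim_genome`: `sequence` (character scalar), `cds`
#'   (data.frame: gene_id, start, end; 1-based inclusive), `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "mutation_sim_config"))
  with_stream(config$seed, "genome", {
    L <- config$genome_length
    n <- config$n_genes
    chars <- sample(BASES, L, replace = TRUE)
    cds <- data.frame(gene_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
    if (n > 0) {
      # budget: genes take ~60% of the genome, split evenly with jitter
      max_codons <- floor(L / (3 * n))
      target <- max(1L, floor(0.6 * max_codons))
      slot <- floor(L / n)
      starts <- integer(n); lens <- integer(n)
      for (g in seq_len(n)) {
        n_codons <- max(1L, target + sample(-min(3L, target - 1L):3L, 1))
        n_codons <- min(n_codons, max_codons)
        len <- 3L * n_codons
        lo <- (g - 1L) * slot + 1L
        hi <- g * slot - len + 1L
        start <- if (hi > lo) sample(lo:hi, 1) else lo
        gene <- random_cds(n_codons)
        chars[start:(start + len - 1L)] <- seq_chars(gene)
        starts[g] <- start; lens[g] <- len
      }
      cds <- data.frame(gene_id = sprintf("gene_%03d", seq_len(n)),
                        start = starts, end = starts + lens - 1L,
                        stringsAsFactors = FALSE)
    }
    structure(list(sequence = paste(chars, collapse = ""), cds = cds,
                   config = config),
              class = "sim_genome")
  })
}

# Map genome position -> (gene, codon start, position in codon); NA outside CDS.
cds_site_map <- function(genome) {
  L <- nchar(genome$sequence)
  gene <- rep(NA_character_, L)
  codon_start <- rep(NA_integer_, L)
  codon_pos <- rep(NA_integer_, L)
  for (g in seq_len(nrow(genome$cds))) {
    idx <- genome$cds$start[g]:genome$cds$end[g]
    gene[idx] <- genome$cds$gene_id[g]
    off <- idx - genome$cds$start[g]
    codon_pos[idx] <- off %% 3L + 1L
    codon_start[idx] <- idx - off %% 3L
  }
  list(gene = gene, codon_start = codon_start, codon_pos = codon_pos)
}

#' Mutate a simulated genome with class-controlled substitutions
#'
#' In `neutral` mode every site may be substituted to a uniform alternative
#' base. In `synonymous_only` mode only CDS sites with at least one synonymous
#' alternative are eligible and the drawn alternative never changes the
#' encoded amino acid; `nonsynonymous_only` is the converse. Constrained modes
#' touch each codon at most once. Sites drawn where the mode has no legal
#' substitution are never emitted mislabeled - they are simply not eligible.
#'
#' @param genome A `sim_genome` from [simulate_genome()].
#' @param config A [mutation_sim_config()]; `substitution_rate`,
#'   `mutation_mode` and `seed` are used.
#' @return List: `sequence` (variant), `log` (data.frame: position, ref, alt,
#'   class in synonymous/non-synonymous/noncoding, gene_id, codon_index). The
#'   log is exhaustive: applying it to the reference reproduces the variant.
#' @export
mutate_genome <- function(genome, config) {
  stopifnot(inherits(genome, "sim_genome"),
            inherits(config, "mutation_sim_config"))
  with_stream(config$seed, "mutate", {
    chars <- seq_chars(genome$sequence)
    L <- length(chars)
    map <- cds_site_map(genome)
    mode <- config$mutation_mode

    legal_alts <- function(pos) {
      ref <- chars[pos]
      alts <- setdiff(BASES, ref)
      if (mode == "neutral" || is.na(map$gene[pos])) return(alts)
      codon <- paste(chars[map$codon_start[pos]:(map$codon_start[pos] + 2L)],
                     collapse = "")
      cls <- classify_substitution(codon, map$codon_pos[pos], alts)
      if (mode == "synonymous_only") alts[cls == "synonymous"]
      else alts[cls == "non-synonymous"]
    }

    pool <- if (mode == "neutral") {
      seq_len(L)
    } else {
      cds_sites <- which(!is.na(map$gene))
      cds_sites[vapply(cds_sites, function(p) length(legal_alts(p)) > 0,
                       logical(1))]
    }
    m <- rbinom(1, length(pool), config$substitution_rate)
    sites <- if (m > 0) sort(sample(pool, m)) else integer()
    if (mode != "neutral" && length(sites)) {
      # at most one substitution per codon
      sites <- sites[!duplicated(map$codon_start[sites])]
    }

    log <- data.frame(position = integer(), ref = character(),
                      alt = character(), class = character(),
                      gene_id = character(), codon_index = integer(),
                      stringsAsFactors = FALSE)
    if (length(sites)) {
      ref <- chars[sites]
      alt <- vapply(sites, function(p) {
        a <- legal_alts(p)
        if (length(a) == 1) a else sample(a, 1)
      }, character(1))
      cls <- vapply(seq_along(sites), function(i) {
        p <- sites[i]
        if (is.na(map$gene[p])) return("noncoding")
        codon <- paste(chars[map$codon_start[p]:(map$codon_start[p] + 2L)],
                       collapse = "")
        classify_substitution(codon, map$codon_pos[p], alt[i])
      }, character(1))
      gene <- map$gene[sites]
      codon_index <- ifelse(is.na(gene), NA_integer_,
                            (map$codon_start[sites] -
                               genome$cds$start[match(gene, genome$cds$gene_id)]) %/% 3L + 1L)
      chars[sites] <- alt
      log <- data.frame(position = sites, ref = ref, alt = alt, class = cls,
                        gene_id = gene, codon_index = codon_index,
                        stringsAsFactors = FALSE)
    }
    list(sequence = paste(chars, collapse = ""), log = log)
  })
}

#' Extract the aligned variant set for each gene of a mutated genome
#'
#' Cuts each CDS out of the reference and one or more variant sequences,
#' giving gap-free in-frame alignments for the selection screen.
#'
#' @param genome A `sim_genome`.
#' @param variants List of results from [mutate_genome()] (or character
#'   sequences of the same length as the reference).
#' @return Named list (by gene id) of named character vectors.
#' @export
gene_variant_alignments <- function(genome, variants) {
  seqs <- c(list(ref = genome$sequence),
            lapply(variants, function(v) if (is.list(v)) v$sequence else v))
  if (is.null(names(seqs)) || any(names(seqs)[-1] == "")) {
    names(seqs)[-1] <- paste0("var", seq_along(seqs[-1]))
  }
  out <- lapply(seq_len(nrow(genome$cds)), function(g) {
    vapply(seqs, substr, character(1),
           start = genome$cds$start[g], stop = genome$cds$end[g])
  })
  names(out) <- genome$cds$gene_id
  out
}

#' Configuration for the two-region genome-pair generator
#'
#' Emulates a comparison of matched genome bins between two distant lake
#' regions: each region-A genome has exactly one region-B partner derived from
#' it by substitution at a planted divergence that declines (by default) with
#' the genome's log abundance.
#'
#' @param n_genomes Number of matched pairs.
#' @param genome_length Genome length (bp).
#' @param divergence_slope Change in planted divergence (percent) per unit
#'   log10 relative abundance.
#' @param divergence_base Divergence (percent) at the mean log10 abundance.
#' @param divergence_noise_sd Gaussian noise (percent) on planted divergence.
#' @param abund_log10_mean,abund_log10_sd Normal parameters of log10 relative
#'   abundance (fractions; defaults span roughly 0.1-10%).
#' @param seed Integer seed.
#' @return A list of class `region_pair_sim_config`.
#' @export
region_pair_sim_config <- function(n_genomes = 48, genome_length = 10000,
                                   divergence_slope = -3,
                                   divergence_base = 6,
                                   divergence_noise_sd = 0.5,
                                   abund_log10_mean = -2,
                                   abund_log10_sd = 0.5,
                                   seed = 1) {
  if (n_genomes < 1 || genome_length < 100) {
    stop_input("region_pair_sim_config: dimensions too small")
  }
  structure(list(n_genomes = n_genomes, genome_length = genome_length,
                 divergence_slope = divergence_slope,
                 divergence_base = divergence_base,
                 divergence_noise_sd = divergence_noise_sd,
                 abund_log10_mean = abund_log10_mean,
                 abund_log10_sd = abund_log10_sd, seed = seed),
            class = "region_pair_sim_config")
}

#' Simulate matched genome collections for two regions
#'
#' Planted divergences are clamped to `[0, 30]` percent; the realised
#' divergence of each pair (the exact substituted fraction) is recorded as
#' truth, together with the Pearson correlation of realised divergence vs
#' log10 abundance.
#'
#' @param config A [region_pair_sim_config()].
#' @return List: `region_a`, `region_b` (data.frames: id, sequence,
#'   abundance), `truth` (data.frame: id_a, id_b, divergence percent,
#'   abundance), `truth_r`.
#' @export
simulate_region_pair <- function(config) {
  stopifnot(inherits(config, "region_pair_sim_config"))
  with_stream(config$seed, "region_pair", {
    n <- config$n_genomes
    L <- config$genome_length
    log_a <- stats::rnorm(n, config$abund_log10_mean, config$abund_log10_sd)
    abundance <- 10^log_a
    planted <- config$divergence_base +
      config$divergence_slope * (log_a - config$abund_log10_mean) +
      stats::rnorm(n, 0, config$divergence_noise_sd)
    planted <- pmin(pmax(planted, 0), 30)

    seqs_a <- character(n); seqs_b <- character(n); realised <- numeric(n)
    for (i in seq_len(n)) {
      chars <- sample(BASES, L, replace = TRUE)
      m <- round(planted[i] / 100 * L)
      sites <- if (m > 0) sample.int(L, m) else integer()
      var <- chars
      if (m > 0) {
        var[sites] <- vapply(chars[sites],
                             function(b) sample(setdiff(BASES, b), 1),
                             character(1))
      }
      seqs_a[i] <- paste(chars, collapse = "")
      seqs_b[i] <- paste(var, collapse = "")
      realised[i] <- 100 * m / L
    }
    ids_a <- sprintf("CAR_%02d", seq_len(n))
    ids_b <- sprintf("KUL_%02d", seq_len(n))
    truth <- data.frame(id_a = ids_a, id_b = ids_b, divergence = realised,
                        abundance = abundance, stringsAsFactors = FALSE)
    truth_r <- if (n >= 3 && stats::sd(realised) > 0) {
      cor(realised, log_a)
    } else {
      NA_real_
    }
    list(region_a = data.frame(id = ids_a, sequence = seqs_a,
                               abundance = abundance,
                               stringsAsFactors = FALSE),
         region_b = data.frame(id = ids_b, sequence = seqs_b,
                               abundance = NA_real_,
                               stringsAsFactors = FALSE),
         truth = truth, truth_r = truth_r)
  })
}

#' Configuration for the synthetic metaproteome generator
#'
#' @param n_mags Number of genome bins with expressed proteins.
#' @param proteins_per_mag Proteins per bin (the unbinned remainder gets the
#'   same number).
#' @param category_weights Named numeric: expression weight of each functional
#'   category within a bin (normalised internally). Defaults include the
#'   housekeeping trio used for expression normalisation.
#' @param total_psms Total peptide-spectral matches to distribute.
#' @param fdr_contamination_fraction Fraction of additional records planted to
#'   violate the identification filters.
#' @param seed Integer seed.
#' @return A list of class `proteome_sim_config`.
#' @export
proteome_sim_config <- function(n_mags = 8, proteins_per_mag = 120,
                                category_weights = c(
                                  photosynthesis = 0.30,
                                  carbon_fixation = 0.10,
                                  transport = 0.15,
                                  ribosomal_proteins = 0.12,
                                  translation_factors = 0.05,
                                  chaperones = 0.08,
                                  other = 0.20),
                                total_psms = 200000,
                                fdr_contamination_fraction = 0.05,
                                seed = 1) {
  if (n_mags < 1 || proteins_per_mag < 1 || total_psms < 1) {
    stop_input("proteome_sim_config: dimensions must be positive")
  }
  if (fdr_contamination_fraction < 0 || fdr_contamination_fraction >= 1) {
    stop_input("fdr_contamination_fraction must be in [0, 1)")
  }
  if (is.null(names(category_weights)) || any(category_weights < 0)) {
    stop_input("category_weights must be a named non-negative vector")
  }
  structure(list(n_mags = n_mags, proteins_per_mag = proteins_per_mag,
                 category_weights = category_weights / sum(category_weights),
                 total_psms = total_psms,
                 fdr_contamination_fraction = fdr_contamination_fraction,
                 seed = seed),
            class = "proteome_sim_config")
}

#' Simulate a protein identification table with planted proteome shares
#'
#' Spectral counts are drawn multinomially from length-weighted true protein
#' abundances, so that NSAF normalisation recovers the planted shares. A
#' configurable fraction of extra records is planted to violate the
#' identification filters (FDR > 0.05, < 2 unique peptides, or no
#' protein-unique peptide) and flagged in the truth.
#'
#' @param config A [proteome_sim_config()].
#' @return List: `table` (data.frame: protein_id, mag, category, length_aa,
#'   counts, unique_peptides, protein_unique_peptides, fdr), `truth` (list:
#'   `mag_shares` named incl. `"unbinned"`, summing to 1;
#'   `category_shares` within-bin, identical across bins by construction;
#'   `contaminant_ids`).
#' @export
simulate_psm_table <- function(config) {
  stopifnot(inherits(config, "proteome_sim_config"))
  with_stream(config$seed, "psm_table", {
    mags <- c(sprintf("MAG_%02d", seq_len(config$n_mags)), "unbinned")
    g <- rgamma(length(mags), shape = 2)
    mag_shares <- g / sum(g)
    names(mag_shares) <- mags

    cats <- names(config$category_weights)
    rows <- list()
    for (m in seq_along(mags)) {
      k <- config$proteins_per_mag
      cat_of <- sample(cats, k, replace = TRUE)
      # exact within-bin category shares: each category's (renormalised)
      # weight is split across its proteins at random
      present <- intersect(cats, unique(cat_of))
      cw <- config$category_weights[present] / sum(config$category_weights[present])
      w <- runif(k, 0.5, 1.5)
      rel <- numeric(k)
      for (cc in present) {
        idx <- cat_of == cc
        rel[idx] <- cw[[cc]] * w[idx] / sum(w[idx])
      }
      abund <- mag_shares[m] * rel
      rows[[m]] <- data.frame(
        protein_id = sprintf("%s_p%04d", mags[m], seq_len(k)),
        mag = mags[m], category = cat_of,
        length_aa = sample(200:600, k, replace = TRUE),
        true_abundance = abund, stringsAsFactors = FALSE)
    }
    prot <- do.call(rbind, rows)
    rownames(prot) <- NULL
    p <- prot$true_abundance * prot$length_aa
    prot$counts <- as.integer(rmultinom(1, config$total_psms, p / sum(p)))
    prot$unique_peptides <- 2L + rbinom(nrow(prot), 8, 0.5)
    prot$protein_unique_peptides <- 1L + rbinom(nrow(prot), 4, 0.5)
    prot$fdr <- round(runif(nrow(prot), 0, 0.05), 4)

    n_contam <- round(config$fdr_contamination_fraction * nrow(prot))
    contaminant_ids <- character()
    if (n_contam > 0) {
      kind <- rep_len(c("fdr", "unique", "protein_unique"), n_contam)
      contam <- data.frame(
        protein_id = sprintf("CONTAM_p%04d", seq_len(n_contam)),
        mag = sample(mags, n_contam, replace = TRUE),
        category = sample(cats, n_contam, replace = TRUE),
        length_aa = sample(200:600, n_contam, replace = TRUE),
        true_abundance = 0,
        counts = as.integer(1 + rbinom(n_contam, 20, 0.3)),
        unique_peptides = ifelse(kind == "unique", 1L,
                                 2L + rbinom(n_contam, 8, 0.5)),
        protein_unique_peptides = ifelse(kind == "protein_unique", 0L,
                                         1L + rbinom(n_contam, 4, 0.5)),
        fdr = ifelse(kind == "fdr", round(runif(n_contam, 0.051, 0.5), 4),
                     round(runif(n_contam, 0, 0.05), 4)),
        stringsAsFactors = FALSE)
      contaminant_ids <- contam$protein_id
      prot <- rbind(prot, contam)
    }
    prot$true_abundance <- NULL
    list(table = prot,
         truth = list(mag_shares = mag_shares,
                      category_shares = config$category_weights,
                      contaminant_ids = contaminant_ids))
  })
}

#' Construct a per-contig depth table from known MAG abundances
#'
#' Inverts the MAG relative-abundance formula: each contig of a bin gets depth
#' `abundance * total_bases / genome_size`, so the abundance estimator must
#' recover the planted values exactly. Bin abundances plus the implied
#' unbinned remainder sum to 1 per sample.
#'
#' @param mag_abundances Named numeric (fractions, sum <= 1) per MAG; the
#'   remainder is assigned to `"unbinned"` contigs.
#' @param total_bases Named numeric, total nucleotides sequenced per sample.
#' @param n_contigs Contigs per bin.
#' @param seed Integer seed (contig length splits).
#' @return A [ContigCoverageTable()].
#' @export
simulate_depth_table <- function(mag_abundances,
                                 total_bases = c(S1 = 6e8),
                                 n_contigs = 5, seed = 1) {
  if (is.null(names(mag_abundances)) || any(mag_abundances < 0) ||
      sum(mag_abundances) > 1 + 1e-12) {
    stop_input("mag_abundances must be named, non-negative, and sum to <= 1")
  }
  with_stream(seed, "depth_table", {
    ab <- c(mag_abundances, unbinned = 1 - sum(mag_abundances))
    rows <- list()
    for (m in names(ab)) {
      genome_size <- round(runif(1, 1e6, 5e6))
      cuts <- sort(sample(seq_len(genome_size - 1), n_contigs - 1))
      lens <- diff(c(0, cuts, genome_size))
      depth <- vapply(total_bases,
                      function(tb) ab[[m]] * tb / genome_size, numeric(1))
      d <- data.frame(contig = sprintf("%s_c%02d", m, seq_len(n_contigs)),
                      length = lens, mag = m, stringsAsFactors = FALSE)
      for (s in names(total_bases)) d[[s]] <- depth[[s]]
      rows[[m]] <- d
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    ContigCoverageTable(tab, sample_cols = names(total_bases))
  })
}
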