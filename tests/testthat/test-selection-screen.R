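test_that("classify_substitution matches the genetic-code hand cases", {
  expect_equal(classify_substitution("AAA", 3, "G"), "synonymous")      # Lys
  expect_equal(classify_substitution("GAT", 3, "A"), "non-synonymous")  # Asp->Glu
  expect_equal(classify_substitution("TGG", 3, "A"), "non-synonymous")  # Trp->stop
  expect_error(classify_substitution("AAA", 1, "A"), "substitution")
  expect_error(classify_substitution("AAA", 4, "G"), "position")
})

test_that("classifier agrees with an independent translation oracle on all 576 cases", {
  skip_if_not_installed("seqinr")
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  n_checked <- 0
  for (codon in codons) {
    for (pos in 1:3) {
      ref_base <- substr(codon, pos, pos)
      for (alt in setdiff(c("A", "C", "G", "T"), ref_base)) {
        expect_identical(classify_substitution(codon, pos, alt),
                         classify_oracle(codon, pos, alt))
        n_checked <- n_checked + 1
      }
    }
  }
  expect_equal(n_checked, 576)
})

test_that("call_snps finds polymorphic gap-free columns and classifies them", {
  # two identical sequences: no SNPs
  same <- c(a = "ATGAAA", b = "ATGAAA")
  expect_equal(nrow(call_snps(same)$snps), 0)
  expect_equal(call_snps(same)$n_considered_positions, 6)

  # column {A,A,G}: consensus A, alternative G
  tri <- c(a = "ATGAAA", b = "ATGAAA", c = "ATGAAG")
  called <- call_snps(tri)
  expect_equal(nrow(called$snps), 1)
  expect_equal(called$snps$column, 6)
  expect_equal(called$snps$consensus, "A")
  expect_equal(called$snps$alternatives, "G")
  expect_equal(called$snps$codon_index, 2)
  expect_equal(called$snps$codon_position, 3)
  expect_equal(called$snps$classification, "synonymous")  # AAA -> AAG

  # a gap removes the column from SNPs and considered positions
  gapped <- c(a = "ATGAAA", b = "ATG-AA")
  cg <- call_snps(gapped)
  expect_equal(cg$n_considered_positions, 5)
  expect_equal(nrow(cg$snps), 0)

  # SNP with a gap in its codon context is excluded from classification
  ctx <- c(a = "ATGA-ATTT", b = "ATGG-ATTT")
  cc <- call_snps(ctx)
  expect_equal(nrow(cc$snps), 1)
  expect_equal(cc$snps$classification, "excluded")

  expect_error(call_snps("ATG"), "2 sequences")
  expect_error(call_snps(c("ATG", "ATGA")), "same length")
})

test_that("majority consensus with lexicographic tie-break", {
  aln <- c(a = "T", b = "T", c = "G", d = "G")
  called <- call_snps(aln)
  expect_equal(called$snps$consensus, "G")
  aln2 <- c(a = "TTT", b = "TTT", c = "TTA", d = "TTA")  # Phe vs Leu, tie
  expect_equal(call_snps(aln2)$snps$consensus, "A")
})

test_that("screen_gene applies all three strict thresholds", {
  pass <- screen_gene(engineer_screen_alignment(51, 43, 4251), gene_id = "g")
  expect_true(pass$diversified)
  expect_equal(pass$n_snps, 51)
  expect_equal(pass$nonsyn_fraction, 43 / 51)

  at_snps <- screen_gene(engineer_screen_alignment(50, 42, 4167))
  expect_false(at_snps$diversified)           # 50 is not > 50

  at_frac <- screen_gene(engineer_screen_alignment(51, 43, 5100))
  expect_equal(at_frac$snp_position_fraction, 0.01)
  expect_false(at_frac$diversified)           # 0.01 is not > 0.01

  at_nonsyn <- screen_gene(engineer_screen_alignment(80, 66, 6000))
  expect_equal(at_nonsyn$nonsyn_fraction, 0.825)
  expect_false(at_nonsyn$diversified)         # 0.825 is not > 0.825
})

test_that("adding a non-synonymous SNP never revokes a diversified call", {
  params <- list(c(51, 43, 4251), c(60, 50, 4500), c(100, 90, 9000))
  for (p in params) {
    before <- screen_gene(engineer_screen_alignment(p[1], p[2], p[3]))
    after <- screen_gene(engineer_screen_alignment(p[1] + 1, p[2] + 1, p[3]))
    if (before$diversified) expect_true(after$diversified)
    expect_gte(after$nonsyn_fraction, before$nonsyn_fraction)
    expect_gt(after$snp_position_fraction, before$snp_position_fraction)
  }
})

test_that("degenerate alignments are flagged, not crashed", {
  allgap <- c(a = "---AAA", b = "---AAA")
  res <- screen_gene(allgap)
  expect_false(res$diversified)
  expect_equal(res$n_considered_positions, 3)
})

test_that("expected_neutral_nonsyn_fraction enumerates all substitutions", {
  expect_equal(expected_neutral_nonsyn_fraction("ATGAAA"), 17 / 18)
  expect_equal(expected_neutral_nonsyn_fraction("ATGATGATG"), 1)  # Met only
  cds <- paste(rep(c("ATG", "GGC", "CTT", "AAA"), 25), collapse = "")
  f <- expected_neutral_nonsyn_fraction(cds)
  expect_gte(f, 0); expect_lte(f, 1)
  expect_error(expected_neutral_nonsyn_fraction("ATGA"), "multiple of 3")
})

test_that("random substitutions calibrate against the neutral expectation", {
  genome <- simulate_genome(mutation_sim_config(genome_length = 3000,
                                                n_genes = 1, seed = 13))
  cds <- substr(genome$sequence, genome$cds$start, genome$cds$end)
  expected <- expected_neutral_nonsyn_fraction(cds)
  L <- nchar(cds)
  obs <- withr::with_seed(99, {
    pos <- sample(L, 4000, replace = TRUE)
    ref <- substring(cds, pos, pos)
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                  character(1))
    codon_i <- (pos - 1) %/% 3
    codons <- substring(cds, codon_i * 3 + 1, codon_i * 3 + 3)
    mean(classify_substitution(codons, (pos - 1) %% 3 + 1, alt) ==
           "non-synonymous")
  })
  expect_lt(abs(obs - expected), 0.02)
})

test_that("alignment FASTA directories round-trip", {
  d <- withr::local_tempdir()
  aln <- engineer_screen_alignment(10, 5, 300)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(aln),
                              file.path(d, "geneX.fasta"))
  back <- read_gene_alignments(d)
  expect_named(back, "geneX")
  expect_equal(unname(back$geneX), unname(aln))
  expect_error(read_gene_alignments(withr::local_tempdir()), "no FASTA")
})
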