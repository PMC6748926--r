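test_that("presence_by_lake applies the min_count rule per lake", {
  counts <- rbind(OTU1 = c(5, 7), OTU2 = c(0, 9))
  colnames(counts) <- c("s1", "s2")
  tab <- toy_otu_table(counts, lakes = c("L1", "L2"))

  p1 <- presence_by_lake(tab, 1)
  expect_equal(p1["OTU1", ], c(L1 = TRUE, L2 = TRUE))
  expect_equal(p1["OTU2", ], c(L1 = FALSE, L2 = TRUE))

  p6 <- presence_by_lake(tab, 6)
  expect_equal(p6["OTU1", ], c(L1 = FALSE, L2 = TRUE))

  expect_error(presence_by_lake(tab, 0), "min_count")

  # years pool within a lake
  counts3 <- rbind(OTU1 = c(3, 0))
  colnames(counts3) <- c("a", "b")
  tab3 <- toy_otu_table(counts3, lakes = c("L1", "L1"), years = c(2014, 2015))
  expect_true(presence_by_lake(tab3, 1)["OTU1", "L1"])
})

test_that("find_core intersects presence across lakes", {
  pres <- rbind(A = c(TRUE, TRUE), B = c(FALSE, TRUE), C = c(TRUE, FALSE))
  colnames(pres) <- c("L1", "L2")
  expect_identical(find_core(pres), "A")

  single <- matrix(c(TRUE, TRUE), 2, 1,
                   dimnames = list(c("A", "B"), "L1"))
  expect_identical(find_core(single), c("A", "B"))

  empty <- matrix(logical(), 0, 2, dimnames = list(character(), c("L1", "L2")))
  expect_identical(find_core(empty), character(0))
})

test_that("core_summary computes richness and read fractions", {
  counts <- rbind(OTU1 = c(5, 7), OTU2 = c(0, 9), OTU3 = c(3, 0))
  colnames(counts) <- c("s1", "s2")
  tab <- toy_otu_table(counts, lakes = c("L1", "L2"))

  s <- core_summary(tab, "OTU1")
  expect_equal(s$richness_fraction, 1 / 3)
  expect_equal(s$read_fraction, 12 / 24)

  all_core <- core_summary(tab, rownames(counts))
  expect_equal(all_core$richness_fraction, 1)
  expect_equal(all_core$read_fraction, 1)

  none <- core_summary(tab, character(0))
  expect_equal(none$richness_fraction, 0)
  expect_equal(none$read_fraction, 0)

  # conservation: core + complement read fractions sum to 1
  comp <- core_summary(tab, setdiff(rownames(counts), "OTU1"))
  expect_equal(s$read_fraction + comp$read_fraction, 1)
})

test_that("exclude_rare drops OTUs below the threshold in every sample", {
  counts <- rbind(rare = c(5, 5), mid = c(20, 0), big = c(975, 995))
  colnames(counts) <- c("s1", "s2")
  tab <- toy_otu_table(counts, lakes = c("L1", "L2"))

  kept <- exclude_rare(tab, 0.01)
  expect_false("rare" %in% rownames(kept$counts))   # 0.5% everywhere
  expect_true("mid" %in% rownames(kept$counts))     # 2% in one sample
  expect_identical(rownames(exclude_rare(tab, 0)$counts), rownames(counts))

  # raising the threshold never retains more OTUs
  n_kept <- vapply(c(0, 0.005, 0.01, 0.05, 0.5),
                   function(t) nrow(exclude_rare(tab, t)$counts), numeric(1))
  expect_true(all(diff(n_kept) <= 0))
})

test_that("exclude_taxon removes labelled OTUs and demands taxonomy", {
  counts <- rbind(OTU1 = c(1, 1), OTU2 = c(2, 2))
  colnames(counts) <- c("s1", "s2")
  tax <- c(OTU1 = "Eukaryota;Metazoa;Rotifera", OTU2 = "Bacteria;Cyanobacteria")
  tab <- toy_otu_table(counts, lakes = c("L1", "L2"), taxonomy = tax)

  expect_identical(rownames(exclude_taxon(tab, "Metazoa")$counts), "OTU2")
  expect_equal(nrow(exclude_taxon(tab, "Archaea")$counts), 2)

  no_tax <- toy_otu_table(counts, lakes = c("L1", "L2"))
  expect_error(exclude_taxon(no_tax, "Metazoa"), "taxonomy")
})

test_that("bray_curtis matches hand cases and the brute-force oracle", {
  counts <- cbind(s1 = c(1, 1, 0), s2 = c(0, 1, 1), s3 = c(1, 1, 0),
                  s4 = c(2, 0, 0), s5 = c(0, 0, 3))
  rownames(counts) <- paste0("OTU", 1:3)
  tab <- toy_otu_table(counts, lakes = paste0("L", 1:5))
  bc <- bray_curtis(tab)

  expect_equal(bc["s1", "s3"], 0)          # identical samples
  expect_equal(bc["s4", "s5"], 1)          # disjoint samples
  expect_equal(bc["s1", "s2"], 0.5)        # hand computation
  expect_true(all(abs(bc - t(bc)) < 1e-15))
  expect_true(all(diag(bc) == 0))
  expect_true(all(bc >= 0 & bc <= 1))

  for (seed in 1:3) {
    cts <- withr::with_seed(seed, matrix(rpois(100, 20), 10, 10,
      dimnames = list(paste0("o", 1:10), paste0("s", 1:10))))
    rt <- toy_otu_table(cts, lakes = paste0("L", 1:10))
    expect_lt(max(abs(bray_curtis(rt) - bc_oracle(cts))), 1e-12)
    expect_lt(max(abs(bray_curtis(rt, relative = FALSE) -
                        bc_oracle(cts, relative = FALSE))), 1e-12)
  }
})

test_that("planted core is recovered exactly and min_count is monotone", {
  sim <- simulate_otu_table(community_sim_config(seed = 42))
  core1 <- find_core(presence_by_lake(sim$table, 1))
  expect_setequal(core1, sim$truth$core_otu_ids)

  sizes <- vapply(c(1, 2, 5, 20, 100),
                  function(m) length(find_core(presence_by_lake(sim$table, m))),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))

  s <- core_summary(sim$table, core1)
  expect_lt(abs(s$read_fraction - sim$truth$expected_read_fraction), 0.005)
})

test_that("OtuTable IO round-trips through its own reader", {
  sim <- simulate_otu_table(community_sim_config(n_otus = 30, seed = 3))
  d <- withr::local_tempdir()
  write_otu_table(sim$table, file.path(d, "c.tsv"), file.path(d, "m.tsv"),
                  meta_header = c(seed = 3))
  back <- read_otu_table(file.path(d, "c.tsv"), file.path(d, "m.tsv"))
  expect_equal(back$counts, sim$table$counts)
  expect_equal(back$meta$lake, sim$table$meta$lake)
})
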