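#' Per-contig coverage table with bin membership
#'
#' Depth-table dialect: one row per contig with its length, bin (MAG)
#' membership (`"unbinned"` for unassigned contigs) and mean fold coverage in
#' each sample.
#'
#' @param df data.frame with columns `contig`, `length`, `mag` and one numeric
#'   depth column per sample.
#' @param sample_cols Character vector naming the depth columns (defaults to
#'   every column other than contig/length/mag).
#' @return A list of class `ContigCoverageTable`.
#' @export
ContigCoverageTable <- function(df, sample_cols = NULL) {
  need <- c("contig", "length", "mag")
  if (!all(need %in% names(df))) {
    stop_input("depth table needs columns contig, length, mag")
  }
  sample_cols <- sample_cols %||% setdiff(names(df), need)
  if (!length(sample_cols)) stop_input("depth table has no sample columns")
  if (any(df$length <= 0)) stop_input("contig lengths must be > 0")
  if (any(as.matrix(df[sample_cols]) < 0)) stop_input("depths must be >= 0")
  structure(list(contigs = df, sample_cols = sample_cols),
            class = "ContigCoverageTable")
}

#' Length-weighted fold coverage of one MAG in one sample
#'
#' `sum(len_i * depth_i) / sum(len_i)` over the MAG's contigs, the
#' depth-table convention that preserves nucleotide accounting.
#'
#' @param contigs A [ContigCoverageTable()].
#' @param mag MAG id.
#' @param sample Sample (depth column) name.
#' @return Fold coverage (numeric scalar).
#' @export
mag_coverage <- function(contigs, mag, sample) {
  stopifnot(inherits(contigs, "ContigCoverageTable"))
  if (!sample %in% contigs$sample_cols) {
    stop_input("unknown sample: ", sample)
  }
  rows <- contigs$contigs[contigs$contigs$mag == mag, , drop = FALSE]
  if (!nrow(rows)) stop_input("MAG has no contigs: ", mag)
  sum(rows$length * rows[[sample]]) / sum(rows$length)
}

#' MAG relative sequence abundance
#'
#' The estimator `(MAG contig sequencing coverage) x (MAG genome size) /
#' (total nucleotides sequenced)`.
#'
#' @param mag_coverage Fold coverage (from [mag_coverage()]).
#' @param genome_size MAG assembly size in bp (sum of its contig lengths).
#' @param total_bases Total nucleotides sequenced in the sample.
#' @return Fraction of sequenced nucleotides attributable to the MAG.
#' @export
relative_abundance <- function(mag_coverage, genome_size, total_bases) {
  if (any(total_bases <= 0)) stop_input("total_bases must be > 0")
  mag_coverage * genome_size / total_bases
}

#' MAG x sample relative abundance table
#'
#' Applies [mag_coverage()] and [relative_abundance()] to every (MAG, sample)
#' pair, with genome size taken as the sum of the MAG's contig lengths. When
#' `total_bases` is `NULL` it is computed per sample as `sum(length * depth)`
#' over all contigs (full-assembly accounting), in which case abundances,
#' including the unbinned remainder, sum to 1.
#'
#' @param contigs A [ContigCoverageTable()].
#' @param total_bases Optional named numeric, total nucleotides sequenced per
#'   sample (names = sample columns).
#' @return data.frame: mag, genome_size, then one abundance column per sample.
#' @export
mag_abundance_table <- function(contigs, total_bases = NULL) {
  stopifnot(inherits(contigs, "ContigCoverageTable"))
  df <- contigs$contigs
  samples <- contigs$sample_cols
  if (is.null(total_bases)) {
    total_bases <- vapply(samples, function(s) sum(df$length * df[[s]]),
                          numeric(1))
  }
  if (is.null(names(total_bases))) names(total_bases) <- samples
  mags <- unique(df$mag)
  out <- data.frame(mag = mags,
                    genome_size = vapply(mags, function(m)
                      sum(df$length[df$mag == m]), numeric(1)),
                    stringsAsFactors = FALSE)
  for (s in samples) {
    out[[s]] <- vapply(mags, function(m)
      relative_abundance(mag_coverage(contigs, m, s),
                         sum(df$length[df$mag == m]),
                         total_bases[[s]]), numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Co-occurrence of near-identical MAG variants across samples
#'
#' A variant is treated as present in a sample when its abundance strictly
#' exceeds `min_abundance` (default 0: any nonzero evidence). Variants
#' co-occur in a sample when all of them are present there; `all_cooccur` is
#' true when at least one sample contains every variant.
#'
#' @param abundance Numeric variant x sample matrix.
#' @param min_abundance Presence threshold (strict).
#' @return List: `presence` (logical matrix), `cooccur_by_sample` (logical per
#'   sample), `all_cooccur` (flag).
#' @export
variant_cooccurrence <- function(abundance, min_abundance = 0) {
  abundance <- as.matrix(abundance)
  presence <- abundance > min_abundance
  cooccur <- apply(presence, 2, all)
  list(presence = presence, cooccur_by_sample = cooccur,
       all_cooccur = any(cooccur))
}

#' Read a depth table plus bin-membership table
#'
#' @param depth_path TSV with columns contigName, contigLen and one average
#'   depth column per sample (or already contig/length + samples).
#' @param bins_path TSV with columns contig, mag; contigs absent from it are
#'   `"unbinned"`.
#' @return A [ContigCoverageTable()].
#' @export
read_depth_table <- function(depth_path, bins_path) {
  d <- read_tsv_meta(depth_path)
  names(d)[names(d) == "contigName"] <- "contig"
  names(d)[names(d) == "contigLen"] <- "length"
  b <- read_tsv_meta(bins_path)
  d$mag <- b$mag[match(d$contig, b$contig)]
  d$mag[is.na(d$mag)] <- "unbinned"
  ContigCoverageTable(d, setdiff(names(d), c("contig", "length", "mag")))
}
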