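#' Classify a single-nucleotide substitution as synonymous or non-synonymous
#'
#' Substitutes `alt_base` at `position_in_codon` of `ref_codon` and translates
#' both codons with the bacterial genetic code (translation table 11). A
#' substitution is synonymous when the amino acid is unchanged; any amino-acid
#' change, stop gain or stop loss is non-synonymous.
#'
#' @param ref_codon Character vector of reference codons (3 letters, `A,C,G,T`).
#' @param position_in_codon Integer vector in `1:3` (recycled).
#' @param alt_base Character vector of alternative bases, each different from
#'   the reference base at that position.
#' @return Character vector, `"synonymous"` or `"non-synonymous"`.
#' @examples
#' classify_substitution("AAA", 3, "G")  # Lys -> Lys, synonymous
#' classify_substitution("GAT", 3, "A")  # Asp -> Glu, non-synonymous
#' @export
classify_substitution <- function(ref_codon, position_in_codon, alt_base) {
  n <- max(length(ref_codon), length(position_in_codon), length(alt_base))
  ref_codon <- toupper(rep_len(ref_codon, n))
  position_in_codon <- rep_len(as.integer(position_in_codon), n)
  alt_base <- toupper(rep_len(alt_base, n))
  if (any(position_in_codon < 1L | position_in_codon > 3L)) {
    stop_input("position_in_codon must be 1, 2 or 3")
  }
  if (!all(alt_base %in% BASES)) stop_input("alt_base must be one of A,C,G,T")
  ref_base <- substr(ref_codon, position_in_codon, position_in_codon)
  if (any(ref_base == alt_base)) {
    stop_input("alt_base equals the reference base; not a substitution")
  }
  alt_codon <- ref_codon
  substr(alt_codon, position_in_codon, position_in_codon) <- alt_base
  ifelse(translate_codons(ref_codon) == translate_codons(alt_codon),
         "synonymous", "non-synonymous")
}

#' Screen thresholds for the diversifying-selection screen
#'
#' Defaults are the published screen: a gene is kept only with more than 50
#' SNPs, more than 1% of its positions polymorphic, and a non-synonymous SNP
#' fraction above 0.825. All three are strict inequalities.
#'
#' @param min_snps SNP count that must be strictly exceeded.
#' @param min_snp_position_fraction Fraction of considered positions carrying a
#'   SNP that must be strictly exceeded.
#' @param min_nonsyn_fraction Non-synonymous fraction among classified SNPs
#'   that must be strictly exceeded.
#' @return A list of class `screen_thresholds`.
#' @export
screen_thresholds <- function(min_snps = 50,
                              min_snp_position_fraction = 0.01,
                              min_nonsyn_fraction = 0.825) {
  stopifnot(min_snps >= 0, min_snp_position_fraction >= 0,
            min_nonsyn_fraction >= 0)
  structure(list(min_snps = min_snps,
                 min_snp_position_fraction = min_snp_position_fraction,
                 min_nonsyn_fraction = min_nonsyn_fraction),
            class = "screen_thresholds")
}

check_alignment <- function(alignment) {
  if (inherits(alignment, "DNAStringSet")) {
    alignment <- as.character(alignment)
  }
  if (length(alignment) < 2) stop_input("alignment needs at least 2 sequences")
  alignment <- toupper(alignment)
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1) {
    stop_input("aligned sequences must all have the same length")
  }
  ok <- grepl("^[ACGTN-]*$", alignment)
  if (!all(ok)) stop_input("alignment rows may only contain A,C,G,T,N,-")
  alignment
}

alignment_matrix <- function(alignment) {
  do.call(rbind, strsplit(alignment, "", fixed = TRUE))
}

# Majority state per column; ties broken by the lexicographically smallest
# state (gap sorts after bases, so a base wins a base-gap tie).
column_consensus <- function(col) {
  tab <- table(factor(col, levels = c(BASES, "N", "-")))
  names(tab)[which.max(tab)]  # which.max takes the first (lexicographic) max
}

#' Call SNP columns on an in-frame gene-variant alignment
#'
#' A SNP is an alignment column with at least two distinct states in
#' `{A,C,G,T}` and no gap or `N` in any row. Columns containing a gap or `N`
#' are excluded both from the SNP list and from the count of considered
#' positions. Each SNP is placed in its codon (frame anchored at the first
#' column whose consensus is not a gap) and classified against the consensus
#' codon; SNPs whose codon context contains a gap/`N` (or is truncated) are
#' reported with classification `"excluded"`.
#'
#' @param alignment Named character vector (or `DNAStringSet`) of 2-5 equal
#'   length aligned sequences over `A,C,G,T,N,-`.
#' @param require_all_nonsyn For multi-allelic SNPs: if `FALSE` (default) the
#'   SNP is non-synonymous when any alternative state is non-synonymous
#'   against the consensus codon; if `TRUE`, all alternatives must be.
#' @return A list with `snps` (data.frame: column, consensus, alternatives,
#'   codon_index, codon_position, classification) and `n_considered_positions`
#'   (gap/N-free column count).
#' @export
call_snps <- function(alignment, require_all_nonsyn = FALSE) {
  alignment <- check_alignment(alignment)
  mat <- alignment_matrix(alignment)
  ncol_aln <- ncol(mat)

  clean <- apply(mat, 2, function(col) all(col %in% BASES))
  n_considered <- sum(clean)

  consensus <- apply(mat, 2, column_consensus)
  anchor <- which(consensus != "-")[1]
  if (is.na(anchor)) stop_input("alignment has no non-gap consensus column")

  is_snp <- clean & apply(mat, 2, function(col) length(unique(col)) >= 2)
  cols <- which(is_snp)
  if (!length(cols)) {
    return(list(
      snps = data.frame(column = integer(), consensus = character(),
                        alternatives = character(), codon_index = integer(),
                        codon_position = integer(),
                        classification = character(),
                        stringsAsFactors = FALSE),
      n_considered_positions = n_considered))
  }

  codon_index <- ifelse(cols >= anchor, (cols - anchor) %/% 3 + 1L, NA_integer_)
  codon_pos <- ifelse(cols >= anchor, (cols - anchor) %% 3 + 1L, NA_integer_)

  snps <- lapply(seq_along(cols), function(i) {
    j <- cols[i]
    cons <- consensus[j]
    alts <- setdiff(unique(mat[, j]), cons)
    cls <- "excluded"
    if (!is.na(codon_index[i])) {
      start <- anchor + 3L * (codon_index[i] - 1L)
      ctx <- start:(start + 2L)
      if (max(ctx) <= ncol_aln && all(consensus[ctx] %in% BASES)) {
        cons_codon <- paste(consensus[ctx], collapse = "")
        calls <- classify_substitution(cons_codon, codon_pos[i], alts)
        cls <- if (require_all_nonsyn) {
          if (all(calls == "non-synonymous")) "non-synonymous" else "synonymous"
        } else {
          if (any(calls == "non-synonymous")) "non-synonymous" else "synonymous"
        }
      }
    }
    data.frame(column = j, consensus = cons,
               alternatives = paste(sort(alts), collapse = ","),
               codon_index = codon_index[i], codon_position = codon_pos[i],
               classification = cls, stringsAsFactors = FALSE)
  })
  list(snps = do.call(rbind, snps), n_considered_positions = n_considered)
}

#' Apply the diversifying-selection screen to one gene alignment
#'
#' Computes the SNP count, the fraction of considered (gap/N-free) positions
#' carrying a SNP, and the non-synonymous fraction among classified SNPs, then
#' applies the three strict thresholds.
#'
#' @param alignment As for [call_snps()].
#' @param thresholds A [screen_thresholds()] object.
#' @param gene_id Optional identifier carried into the result.
#' @param require_all_nonsyn Passed to [call_snps()].
#' @return One-row data.frame: `gene_id`, `n_snps`, `n_considered_positions`,
#'   `snp_position_fraction`, `nonsyn_fraction`, `diversified`, `flag`.
#' @export
screen_gene <- function(alignment, thresholds = screen_thresholds(),
                        gene_id = NA_character_,
                        require_all_nonsyn = FALSE) {
  stopifnot(inherits(thresholds, "screen_thresholds"))
  called <- call_snps(alignment, require_all_nonsyn = require_all_nonsyn)
  n_snps <- nrow(called$snps)
  n_pos <- called$n_considered_positions
  flag <- ""
  if (n_pos == 0) {
    flag <- "no_considered_positions"
    frac <- NA_real_
  } else {
    frac <- n_snps / n_pos
  }
  classified <- called$snps$classification[called$snps$classification != "excluded"]
  nonsyn <- if (length(classified)) {
    mean(classified == "non-synonymous")
  } else {
    NA_real_
  }
  diversified <- !is.na(frac) && !is.na(nonsyn) &&
    n_snps > thresholds$min_snps &&
    frac > thresholds$min_snp_position_fraction &&
    nonsyn > thresholds$min_nonsyn_fraction
  data.frame(gene_id = gene_id, n_snps = n_snps,
             n_considered_positions = n_pos,
             snp_position_fraction = frac, nonsyn_fraction = nonsyn,
             diversified = diversified, flag = flag,
             stringsAsFactors = FALSE)
}

#' Screen a set of gene alignments
#'
#' @param alignments Named list of alignments (each as for [call_snps()]).
#' @param thresholds A [screen_thresholds()] object.
#' @param require_all_nonsyn Passed to [call_snps()].
#' @return data.frame with one row per gene (see [screen_gene()]).
#' @export
screen_genes <- function(alignments, thresholds = screen_thresholds(),
                         require_all_nonsyn = FALSE) {
  ids <- names(alignments) %||% as.character(seq_along(alignments))
  res <- Map(function(a, id) screen_gene(a, thresholds, gene_id = id,
                                         require_all_nonsyn = require_all_nonsyn),
             alignments, ids)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Expected non-synonymous fraction of a CDS under uniform substitution
#'
#' Enumerates all `3L` single-nucleotide substitutions of an in-frame CDS and
#' returns the proportion that change the encoded amino acid (table 11).
#' Serves as the neutral expectation against which observed non-synonymous
#' SNP fractions are compared.
#'
#' @param cds Character scalar, in-frame coding sequence over `A,C,G,T`,
#'   length a multiple of 3.
#' @return Fraction in `[0, 1]`.
#' @examples
#' expected_neutral_nonsyn_fraction("ATGAAA")  # 17/18
#' @export
expected_neutral_nonsyn_fraction <- function(cds) {
  cds <- toupper(cds)
  L <- nchar(cds)
  if (L %% 3 != 0 || L == 0) stop_input("CDS length must be a positive multiple of 3")
  if (!grepl("^[ACGT]*$", cds)) stop_input("CDS may only contain A,C,G,T")
  codons <- substring(cds, seq(1, L, 3), seq(3, L, 3))
  ref <- rep(codons, each = 9)
  pos <- rep(rep(1:3, each = 3), length(codons))
  refb <- substr(ref, pos, pos)
  alt <- vapply(seq_along(ref),
                function(i) setdiff(BASES, refb[i])[(i - 1) %% 3 + 1],
                character(1))
  mean(classify_substitution(ref, pos, alt) == "non-synonymous")
}

#' Read a directory of aligned gene-variant FASTA files
#'
#' One multi-FASTA per gene; row ids are variant ids; file base name (without
#' extension) is the gene id.
#'
#' @param dir Directory containing `.fasta`/`.fa`/`.fna` files.
#' @return Named list of character vectors (aligned sequences).
#' @export
read_gene_alignments <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|fna|fasta)$", full.names = TRUE)
  if (!length(files)) stop_input("no FASTA files found in ", dir)
  out <- lapply(files, function(f) as.character(Biostrings::readBStringSet(f)))
  names(out) <- sub("\\.(fa|fna|fasta)$", "", basename(files))
  out
}
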