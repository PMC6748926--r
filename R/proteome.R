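#' Filter protein identifications
#'
#' A record is discarded when its FDR strictly exceeds `fdr_max` (default 5%),
#' when it has fewer than `min_unique` unique peptides (default 2), or - when
#' required - no protein-unique peptide. A record at exactly the FDR bound is
#' retained. Every rejection is logged with its reason(s).
#'
#' @param records data.frame with columns `fdr`, `unique_peptides`,
#'   `protein_unique_peptides` (plus anything else, carried through).
#' @param fdr_max Maximum tolerated FDR (strict `>` discards).
#' @param min_unique Minimum unique peptides (discard when `<`).
#' @param require_protein_unique Discard records with zero protein-unique
#'   peptides.
#' @return List: `retained` (data.frame), `rejected` (data.frame with a
#'   `reason` column).
#' @export
filter_identifications <- function(records, fdr_max = 0.05, min_unique = 2,
                                   require_protein_unique = TRUE) {
  need <- c("fdr", "unique_peptides", "protein_unique_peptides")
  if (!all(need %in% names(records))) {
    stop_input("records need columns ", paste(need, collapse = ", "))
  }
  bad_fdr <- records$fdr > fdr_max
  bad_unique <- records$unique_peptides < min_unique
  bad_pu <- require_protein_unique & records$protein_unique_peptides < 1
  reject <- bad_fdr | bad_unique | bad_pu
  reason <- apply(cbind(fdr = bad_fdr, unique_peptides = bad_unique,
                        protein_unique = bad_pu), 1,
                  function(v) paste(names(v)[v], collapse = ","))
  rejected <- records[reject, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[reject]
  else rejected$reason <- character(0)
  list(retained = records[!reject, , drop = FALSE], rejected = rejected)
}

#' Relative protein abundances (NSAF)
#'
#' Normalised spectral abundance factor: `a_i = (c_i / L_i) / sum_j (c_j /
#' L_j)`. Fractions sum to 1 over the supplied (already filtered) records.
#' A plain count-fraction mode (`mode = "count"`) is available for
#' sensitivity analysis.
#'
#' @param records Filtered data.frame with columns `length_aa` and the count
#'   column named by `sample`.
#' @param sample Name of the spectral-count column (default `"counts"`).
#'   Technical replicates should be summed into one column beforehand.
#' @param mode `"nsaf"` (length-normalised, default) or `"count"`.
#' @return Numeric vector of per-protein fractions (sums to 1).
#' @export
relative_abundance_nsaf <- function(records, sample = "counts",
                                    mode = c("nsaf", "count")) {
  mode <- match.arg(mode)
  if (!sample %in% names(records)) stop_input("no count column: ", sample)
  c_i <- records[[sample]]
  if (any(c_i < 0)) stop_input("spectral counts must be >= 0")
  w <- if (mode == "nsaf") {
    if (any(records$length_aa <= 0)) stop_input("lengths must be > 0")
    c_i / records$length_aa
  } else {
    c_i
  }
  tot <- sum(w)
  if (tot == 0) stop_input("all spectral counts are zero")
  w / tot
}

#' Metaproteome share of one MAG
#'
#' Sum of the MAG's protein relative abundances divided by the sum over all
#' proteins (the denominator is explicit so pre-normalised and raw abundance
#' vectors behave the same).
#'
#' @param fractions Per-protein relative abundances.
#' @param mags Per-protein MAG ids (`"unbinned"` for unassigned).
#' @param mag MAG id to report.
#' @return Fraction in `[0, 1]`.
#' @export
mag_share <- function(fractions, mags, mag) {
  stopifnot(length(fractions) == length(mags))
  tot <- sum(fractions)
  if (tot == 0) return(0)
  sum(fractions[mags == mag]) / tot
}

#' Metaproteome shares of all MAGs
#'
#' @param fractions Per-protein relative abundances.
#' @param mags Per-protein MAG ids.
#' @return Named numeric vector over the distinct MAG ids (sums to 1 when
#'   `fractions` does).
#' @export
mag_shares <- function(fractions, mags) {
  vapply(sort(unique(mags)), function(m) mag_share(fractions, mags, m),
         numeric(1))
}

#' Within-MAG allocation over functional categories
#'
#' Category share = summed fractions of the MAG's proteins in the category,
#' divided by the MAG total; shares sum to 1 over categories. Missing or empty
#' category labels are pooled as `"other"`.
#'
#' @param fractions Per-protein relative abundances.
#' @param mags Per-protein MAG ids.
#' @param categories Per-protein functional category labels.
#' @param mag MAG id to report.
#' @return Named numeric vector of within-MAG category shares.
#' @export
category_allocation <- function(fractions, mags, categories, mag) {
  stopifnot(length(fractions) == length(mags),
            length(categories) == length(mags))
  categories <- as.character(categories)
  categories[is.na(categories) | categories == ""] <- "other"
  sel <- mags == mag
  tot <- sum(fractions[sel])
  if (tot == 0) {
    return(stats::setNames(numeric(0), character(0)))
  }
  shares <- tapply(fractions[sel], categories[sel], sum) / tot
  out <- as.numeric(shares)
  names(out) <- names(shares)
  out
}

#' Housekeeping-normalised expression of a category
#'
#' Divides a category's within-MAG share by the summed within-MAG share of the
#' housekeeping categories (ribosomal proteins, translation factors and
#' protein chaperones by default), making expression comparable between MAGs
#' of different absolute abundance.
#'
#' @param category_shares Named within-MAG category shares (from
#'   [category_allocation()]).
#' @param category Category to normalise.
#' @param housekeeping Character vector of housekeeping category names.
#' @return Ratio (numeric scalar); `NA` with a warning when the housekeeping
#'   share is zero.
#' @export
housekeeping_normalize <- function(category_shares, category,
                                   housekeeping = c("ribosomal_proteins",
                                                    "translation_factors",
                                                    "chaperones")) {
  hk <- sum(category_shares[names(category_shares) %in% housekeeping])
  share <- if (category %in% names(category_shares)) {
    category_shares[[category]]
  } else {
    0
  }
  if (hk <= 0) {
    warning("housekeeping share is zero; normalised value undefined")
    return(NA_real_)
  }
  share / hk
}
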