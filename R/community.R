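#' OTU count table with sample metadata
#'
#' Container for an OTU x sample count matrix plus per-sample metadata (lake,
#' year, marker gene). 16S and 18S tables are kept separate and never merged;
#' construct one object per marker.
#'
#' @param counts Non-negative integer matrix, OTUs in rows (unique rownames),
#'   samples in columns.
#' @param meta data.frame with columns `sample`, `lake`, `year` and optionally
#'   `marker`; one row per column of `counts`.
#' @param taxonomy Optional named character vector (per OTU) of taxonomy
#'   annotations.
#' @return A list of class `OtuTable` with elements `counts`, `meta`,
#'   `taxonomy`.
#' @export
OtuTable <- function(counts, meta, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop_input("counts must have unique OTU rownames")
  }
  if (any(counts < 0)) stop_input("counts must be non-negative")
  if (!all(c("sample", "lake", "year") %in% names(meta))) {
    stop_input("meta needs columns sample, lake, year")
  }
  meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
  if (anyNA(meta$sample)) {
    stop_input("every counts column needs a metadata row")
  }
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[rownames(counts)]
  }
  structure(list(counts = counts, meta = meta, taxonomy = taxonomy),
            class = "OtuTable")
}

#' @export
print.OtuTable <- function(x, ...) {
  cat(sprintf("OtuTable: %d OTUs x %d samples (%d lakes, years %s)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$meta$lake)),
              paste(range(x$meta$year), collapse = "-")))
  invisible(x)
}

#' Presence/absence of each OTU in each lake
#'
#' An OTU is present in a lake when its count reaches `min_count` in at least
#' one sample of that lake, pooling all years.
#'
#' @param table An [OtuTable()].
#' @param min_count Detection threshold (>= 1).
#' @return Logical OTU x lake matrix.
#' @export
presence_by_lake <- function(table, min_count = 1) {
  stopifnot(inherits(table, "OtuTable"))
  if (min_count < 1) stop_input("min_count must be >= 1")
  lakes <- unique(table$meta$lake)
  if (anyNA(lakes)) stop_input("unknown (NA) lake label in metadata")
  out <- vapply(lakes, function(l) {
    cols <- table$meta$sample[table$meta$lake == l]
    apply(table$counts[, cols, drop = FALSE] >= min_count, 1, any)
  }, logical(nrow(table$counts)))
  matrix(out, nrow = nrow(table$counts),
         dimnames = list(rownames(table$counts), lakes))
}

#' Core OTU set: OTUs present in every lake
#'
#' @param presence Logical OTU x lake matrix from [presence_by_lake()].
#' @return Character vector of core OTU ids (possibly empty).
#' @export
find_core <- function(presence) {
  if (!is.matrix(presence) || !is.logical(presence)) {
    stop_input("presence must be a logical matrix")
  }
  if (!nrow(presence)) return(character(0))
  rownames(presence)[rowSums(presence) == ncol(presence)]
}

#' Summary statistics of a core OTU set
#'
#' Richness fraction is the share of detected OTUs (nonzero total count over
#' the whole table) that are core; read fraction is the share of all counted
#' reads, pooled over samples, assigned to core OTUs. A per-sample mean read
#' fraction is also reported, since pooling vs averaging is a reading choice.
#'
#' @param table An [OtuTable()].
#' @param core Character vector of core OTU ids.
#' @param min_count Detection threshold used for the per-lake presence matrix
#'   included in the summary.
#' @return List of class `CoreSummary`: `core_otu_ids`, `richness_fraction`,
#'   `read_fraction`, `read_fraction_per_sample_mean`, `per_lake_presence`.
#' @export
core_summary <- function(table, core, min_count = 1) {
  stopifnot(inherits(table, "OtuTable"))
  detected <- rownames(table$counts)[rowSums(table$counts) > 0]
  core <- intersect(core, rownames(table$counts))
  total <- sum(table$counts)
  core_counts <- table$counts[core, , drop = FALSE]
  per_sample <- if (length(core)) {
    colSums(core_counts) / pmax(colSums(table$counts), 1)
  } else {
    rep(0, ncol(table$counts))
  }
  structure(list(
    core_otu_ids = core,
    richness_fraction = if (length(detected)) length(intersect(core, detected)) / length(detected) else 0,
    read_fraction = if (total > 0) sum(core_counts) / total else 0,
    read_fraction_per_sample_mean = mean(per_sample),
    per_lake_presence = presence_by_lake(table, min_count)),
    class = "CoreSummary")
}

#' Exclude OTUs that never reach a relative-abundance threshold
#'
#' An OTU is retained only when its within-sample relative abundance reaches
#' `threshold` in at least one sample (the published rule: OTUs below 1% in
#' all samples are excluded).
#'
#' @param table An [OtuTable()].
#' @param threshold Relative abundance in `[0, 1]`; default 0.01.
#' @return A filtered [OtuTable()].
#' @export
exclude_rare <- function(table, threshold = 0.01) {
  stopifnot(inherits(table, "OtuTable"))
  if (threshold <= 0) return(table)
  rel <- sweep(table$counts, 2, pmax(colSums(table$counts), 1), "/")
  keep <- apply(rel >= threshold, 1, any)
  OtuTable(table$counts[keep, , drop = FALSE], table$meta,
           table$taxonomy[rownames(table$counts)[keep]])
}

#' Exclude OTUs by taxonomy label
#'
#' Removes OTUs whose taxonomy annotation contains `label` (fixed-string
#' match, e.g. `"Metazoa"`). Requires the table to carry taxonomy.
#'
#' @param table An [OtuTable()] with non-null `taxonomy`.
#' @param label Character scalar to match.
#' @return A filtered [OtuTable()].
#' @export
exclude_taxon <- function(table, label) {
  stopifnot(inherits(table, "OtuTable"))
  if (is.null(table$taxonomy)) {
    stop_input("table has no taxonomy annotation; cannot exclude by taxon")
  }
  hit <- grepl(label, table$taxonomy, fixed = TRUE)
  hit[is.na(hit)] <- FALSE
  keep <- rownames(table$counts)[!hit]
  OtuTable(table$counts[keep, , drop = FALSE], table$meta,
           table$taxonomy[keep])
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(i, j) = 1 - 2 * sum_k min(x_ki, x_kj) / (sum_k x_ki + sum_k x_kj)`,
#' computed by default on per-sample relative abundances (sequencing depth
#' differs between samples); a raw-count mode is available.
#'
#' @param table An [OtuTable()].
#' @param relative Use relative abundances (default) or raw counts.
#' @return Symmetric sample x sample matrix with zero diagonal, values in
#'   `[0, 1]`.
#' @export
bray_curtis <- function(table, relative = TRUE) {
  stopifnot(inherits(table, "OtuTable"))
  x <- t(table$counts)
  if (relative) x <- x / pmax(rowSums(x), 1)
  as.matrix(vegan::vegdist(x, method = "bray"))
}

#' Read an OTU table and its sample metadata from TSV files
#'
#' @param counts_path TSV, first column OTU id, remaining columns counts.
#' @param meta_path TSV with columns sample, lake, year, optionally marker and
#'   taxonomy is read from an optional `taxonomy` column keyed by OTU id in
#'   `taxonomy_path`.
#' @param taxonomy_path Optional TSV with columns otu, taxonomy.
#' @return An [OtuTable()].
#' @export
read_otu_table <- function(counts_path, meta_path, taxonomy_path = NULL) {
  cts <- read_tsv_meta(counts_path)
  counts <- as.matrix(cts[, -1, drop = FALSE])
  rownames(counts) <- cts[[1]]
  meta <- read_tsv_meta(meta_path)
  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    tx <- read_tsv_meta(taxonomy_path)
    taxonomy <- stats::setNames(tx[[2]], tx[[1]])
  }
  OtuTable(counts, meta, taxonomy)
}

#' Write an OtuTable (counts + metadata) to TSV files
#'
#' @param table An [OtuTable()].
#' @param counts_path,meta_path Output paths.
#' @param meta_header Named character vector written as `#` header lines.
#' @return Invisibly, the two paths.
#' @export
write_otu_table <- function(table, counts_path, meta_path,
                            meta_header = character()) {
  df <- data.frame(otu = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_meta(df, counts_path, meta_header)
  write_tsv_meta(table$meta, meta_path, meta_header)
  invisible(c(counts_path, meta_path))
}
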