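#' Fragment-based average nucleotide identity (ANI)
#'
#' Desk-scale ANI estimator: the query is split into non-overlapping fragments
#' of `fragment_length` (a trailing partial fragment is dropped); each
#' fragment is seeded onto the reference by exact k-mer match and scored by
#' ungapped identity at the implied offset (out-of-bounds overhang counts as
#' mismatch); a fragment is recruited when its best identity reaches
#' `min_identity`. ANI is the mean identity of recruited fragments. The
#' estimator is directional: swapping query and reference re-fragments the
#' other sequence and may change the aligned fraction.
#'
#' Ungapped extension only - suitable for substitution-divergent genomes; for
#' indel-rich real genomes, import a precomputed ANI table instead.
#'
#' @param query,reference Character scalars (DNA over A,C,G,T).
#' @param fragment_length Fragment size in bp (>= 100; default 1020).
#' @param k Exact-match seed length (default 16).
#' @param min_identity Recruitment threshold in percent (default 80).
#' @param max_candidates Maximum distinct seed offsets scored per fragment.
#' @return List of class `AniEstimate`: `ani` (percent, `NA` when no fragment
#'   is recruited), `aligned_fraction`, `n_fragments`, `n_recruited`.
#' @export
estimate_ani <- function(query, reference, fragment_length = 1020, k = 16,
                         min_identity = 80, max_candidates = 8) {
  if (!nzchar(query) || !nzchar(reference)) {
    stop_input("query and reference must be non-empty")
  }
  if (fragment_length < 100) stop_input("fragment_length must be >= 100")
  query <- toupper(query); reference <- toupper(reference)
  nq <- nchar(query); nr <- nchar(reference)
  n_frag <- nq %/% fragment_length
  if (n_frag == 0) {
    stop_input("query shorter than one fragment")
  }
  if (nr < k) stop_input("reference shorter than the seed length")

  rchars <- seq_chars(reference)
  ref_kmers <- substring(reference, 1:(nr - k + 1), k:nr)

  identities <- rep(NA_real_, n_frag)
  for (f in seq_len(n_frag)) {
    fs <- (f - 1L) * fragment_length + 1L
    frag <- substr(query, fs, fs + fragment_length - 1L)
    fchars <- seq_chars(frag)
    seed_starts <- seq(1L, fragment_length - k + 1L, by = k)
    frag_kmers <- substring(frag, seed_starts, seed_starts + k - 1L)
    hits <- match(frag_kmers, ref_kmers)
    found <- which(!is.na(hits))
    if (!length(found)) next
    offsets <- unique(hits[found] - (seed_starts[found] - 1L))
    offsets <- utils::head(offsets, max_candidates)
    best <- 0
    for (off in offsets) {
      ri <- off:(off + fragment_length - 1L)
      valid <- ri >= 1L & ri <= nr
      m <- sum(fchars[valid] == rchars[ri[valid]])
      best <- max(best, 100 * m / fragment_length)
    }
    identities[f] <- best
  }
  recruited <- !is.na(identities) & identities >= min_identity
  structure(list(
    ani = if (any(recruited)) mean(identities[recruited]) else NA_real_,
    aligned_fraction = sum(recruited) / n_frag,
    n_fragments = n_frag, n_recruited = sum(recruited)),
    class = "AniEstimate")
}

#' Best ANI match of each query genome in a reference collection
#'
#' The partner maximises ANI; ties are broken by higher aligned fraction, then
#' by lexicographic id. Unrecruited comparisons (ANI undefined) never win.
#'
#' @param queries,references data.frames with columns `id`, `sequence` (as in
#'   [simulate_region_pair()] regions).
#' @param ... Passed to [estimate_ani()].
#' @return data.frame: query, partner, ani, aligned_fraction.
#' @export
best_match <- function(queries, references, ...) {
  if (!nrow(references)) stop_input("reference set is empty")
  if (!nrow(queries)) stop_input("query set is empty")
  out <- lapply(seq_len(nrow(queries)), function(i) {
    ests <- lapply(seq_len(nrow(references)), function(j) {
      estimate_ani(queries$sequence[i], references$sequence[j], ...)
    })
    ani <- vapply(ests, function(e) e$ani %||% NA_real_, numeric(1))
    af <- vapply(ests, function(e) e$aligned_fraction, numeric(1))
    ord <- order(-ifelse(is.na(ani), -Inf, ani), -af, references$id)
    best <- ord[1]
    data.frame(query = queries$id[i], partner = references$id[best],
               ani = ani[best], aligned_fraction = af[best],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pearson correlation between genetic distance and abundance
#'
#' Genetic distance is `100 - ANI` (percent). The two-sided p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom (the
#' standard product-moment test).
#'
#' @param distance Numeric vector of genetic distances.
#' @param abundance Numeric vector of relative abundances (same length).
#' @param transform `"identity"` (default) or `"log10"` applied to abundance.
#' @return List of class `CorrelationResult`: `r`, `n`, `p_two_sided`,
#'   `transform`.
#' @export
distance_abundance_correlation <- function(distance, abundance,
                                           transform = c("identity", "log10")) {
  transform <- match.arg(transform)
  keep <- is.finite(distance) & is.finite(abundance)
  distance <- distance[keep]; abundance <- abundance[keep]
  n <- length(distance)
  if (n < 3) stop_input("need at least 3 complete pairs")
  x <- if (transform == "log10") log10(abundance) else abundance
  ct <- suppressWarnings(cor.test(distance, x, method = "pearson"))
  structure(list(r = unname(ct$estimate), n = n,
                 p_two_sided = ct$p.value, transform = transform),
            class = "CorrelationResult")
}
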