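# Independent oracles and tiny fixture builders used across test files.

# Brute-force Bray-Curtis: per-pair loop straight from the formula.
bc_oracle <- function(counts, relative = TRUE) {
  x <- t(counts)
  if (relative) x <- x / pmax(rowSums(x), 1)
  n <- nrow(x)
  out <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- 0; den <- 0
      for (k in seq_len(ncol(x))) {
        num <- num + min(x[i, k], x[j, k])
        den <- den + x[i, k] + x[j, k]
      }
      out[i, j] <- if (den > 0) 1 - 2 * num / den else 0
    }
  }
  out
}

# Substitution-class oracle via an independent translation implementation.
classify_oracle <- function(ref_codon, pos, alt) {
  aa <- function(codon) {
    seqinr::translate(strsplit(codon, "")[[1]], numcode = 11)
  }
  alt_codon <- ref_codon
  substr(alt_codon, pos, pos) <- alt
  if (aa(ref_codon) == aa(alt_codon)) "synonymous" else "non-synonymous"
}

# Two-sided permutation estimate of the Pearson correlation p-value.
perm_p_oracle <- function(x, y, n_perm = 10000, seed = 1) {
  r_obs <- abs(cor(x, y))
  withr::with_seed(seed, {
    hits <- sum(replicate(n_perm, abs(cor(x, sample(y))) >= r_obs - 1e-15))
  })
  hits / n_perm
}

# Minimal OtuTable: counts matrix + one lake per column prefix.
toy_otu_table <- function(counts, lakes, years = NULL, taxonomy = NULL) {
  samples <- colnames(counts)
  if (is.null(years)) years <- rep(2014, length(samples))
  OtuTable(counts,
           data.frame(sample = samples, lake = lakes, year = years,
                      stringsAsFactors = FALSE),
           taxonomy)
}

random_seq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

# Plant exactly m uniform substitutions into a sequence.
plant_divergence <- function(sequence, m, seed) {
  chars <- strsplit(sequence, "")[[1]]
  withr::with_seed(seed, {
    idx <- sample(length(chars), m)
    chars[idx] <- vapply(chars[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  })
  paste(chars, collapse = "")
}

# Delta-method multinomial standard error of a group's NSAF share.
nsaf_share_se <- function(counts, lengths, group, total_psms, share) {
  w <- 1 / lengths
  t_w <- sum(w * counts)
  d <- w * (group - share) / t_w
  ph <- counts / total_psms
  sqrt(total_psms * (sum(ph * d^2) - sum(ph * d)^2))
}
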