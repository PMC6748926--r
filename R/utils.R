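#' @importFrom stats cor cor.test rbinom rlnorm rmultinom runif rgamma
#' @importFrom utils read.table write.table packageVersion
NULL

BASES <- c("A", "C", "G", "T")

# Bacterial genetic code (translation table 11); codon -> one-letter amino
# acid, "*" for stop. Table 11 differs from the standard code only in its
# start codons, which do not affect substitution classification.
genetic_code_11 <- function() {
  Biostrings::getGeneticCode("11")
}

#' Translate codons with the bacterial genetic code
#'
#' Vectorised codon -> amino-acid lookup under translation table 11
#' (one-letter code, `"*"` for stop).
#'
#' @param codons Character vector of 3-letter codons over `A,C,G,T`.
#' @return Character vector of amino acids.
#' @export
translate_codons <- function(codons) {
  code <- genetic_code_11()
  aa <- unname(code[toupper(codons)])
  if (anyNA(aa)) {
    bad <- unique(codons[is.na(aa)])
    stop("not a codon over {A,C,G,T}: ", paste(bad, collapse = ", "))
  }
  aa
}

# Per-generator random streams: each generator draws from its own stream,
# derived from the user seed and a generator tag, so adding draws to one
# generator never perturbs another.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

with_stream <- function(seed, tag, code) {
  withr::with_seed(derive_seed(seed, tag), code)
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# TSV with '#'-prefixed header metadata lines (diff-able, language neutral).
write_tsv_meta <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(paste0("# ", names(meta), "=", unname(meta)), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_meta <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- character()
  if (length(meta_lines)) {
    kv <- sub("^#\\s*", "", lines[meta_lines])
    meta <- sub("^[^=]*=", "", kv)
    names(meta) <- sub("=.*$", "", kv)
  }
  df <- read.table(text = lines[setdiff(seq_along(lines), meta_lines)],
                   sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
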