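#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors.  Only the
#' unambiguous alphabet A/C/G/T (upper case) is supported, which is all the
#' amplicon machinery in this package ever emits.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# random DNA of given lengths, uses the current RNG stream
random_dna <- function(n, len) {
  vapply(rep(len, length.out = n), function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside A/C/G/T: %s",
                  what, paste(head(x[bad], 3), collapse = ", ")))
  }
  invisible(x)
}

# Derive a reproducible sub-seed from a master seed and a stage label, so a
# stage re-run in isolation sees the same stream as inside the pipeline.
# Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647L)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
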