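#' Read paired FASTQ files
#'
#' Reads two 4-line-record FASTQ files (phred+33, optionally gzipped) and
#' returns the mate pairs in file order as one tibble.  Qualities are carried
#' along but never used for filtering: read sorting relies solely on barcode
#' and primer identity.
#'
#' @param path_r1,path_r2 Paths to the R1 and R2 FASTQ files.
#' @return A tibble with columns `read_id`, `seq_1`, `qual_1`, `seq_2`,
#'   `qual_2`, one row per mate pair, in file order.
#' @export
read_fastq_pairs <- function(path_r1, path_r2) {
  r1 <- read_fastq_one(path_r1)
  r2 <- read_fastq_one(path_r2)
  if (nrow(r1) != nrow(r2)) {
    abort(sprintf("pairing error: %s has %d records but %s has %d",
                  path_r1, nrow(r1), path_r2, nrow(r2)))
  }
  tibble(read_id = r1$read_id,
         seq_1 = r1$seq, qual_1 = r1$qual,
         seq_2 = r2$seq, qual_2 = r2$qual)
}

read_fastq_one <- function(path) {
  check_fastq_structure(path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      abort(sprintf("FASTQ parse error in %s: %s", path, conditionMessage(e)))
    })
  tibble(read_id = sub(" .*$", "", names(x) %||% character()),
         seq = unname(as.character(x)),
         qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
}

# structural validation of a 4-line-record FASTQ, naming the bad record
check_fastq_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4 != 0) {
    abort(sprintf("FASTQ parse error in %s: truncated record %d",
                  path, length(lines) %/% 4 + 1L))
  }
  heads <- lines[seq(1, length(lines), by = 4)]
  seps <- lines[seq(3, length(lines), by = 4)]
  bad <- which(!startsWith(heads, "@") | !startsWith(seps, "+"))
  if (length(bad)) {
    abort(sprintf("FASTQ parse error in %s: malformed record %d",
                  path, bad[1]))
  }
  invisible(path)
}

#' Write paired FASTQ files
#'
#' Inverse of [read_fastq_pairs()]; writing then re-reading reproduces the
#' pair tibble exactly.
#'
#' @param pairs Tibble as returned by [read_fastq_pairs()].
#' @param path_r1,path_r2 Output paths (a `.gz` suffix triggers compression).
#' @return The two paths, invisibly.
#' @export
write_fastq_pairs <- function(pairs, path_r1, path_r2) {
  write_fastq_one(pairs$read_id, pairs$seq_1, pairs$qual_1, path_r1)
  write_fastq_one(pairs$read_id, pairs$seq_2, pairs$qual_2, path_r2)
  invisible(c(path_r1, path_r2))
}

write_fastq_one <- function(ids, seqs, quals, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(
    x, path, format = "fastq", qualities = Biostrings::BStringSet(quals),
    compress = grepl("\\.gz$", path))
}
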