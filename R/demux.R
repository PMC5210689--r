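SORT_CATEGORIES <- c("NO_BARCODE", "ONE_BARCODE", "TWO_BC_NO_PRIMER",
                     "TWO_BC_NONMATCHING_PRIMERS", "TWO_BC_MATCHING_PRIMERS")

#' Levenshtein edit distance
#'
#' Unit-cost insertion/deletion/substitution distance between DNA strings,
#' the metric used throughout read sorting.
#'
#' @param a,b Character vectors (recycled to common length).
#' @return Integer vector of distances.
#' @export
#' @examples
#' edit_distance("ACGT", "AGT")
edit_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  as.integer(mapply(function(x, y) utils::adist(x, y), a, b))
}

# Match each sequence's prefix against a set of candidate prefixes of equal
# length `len`, allowing up to `max_edit` Levenshtein errors.  Returns the
# index of the unique best candidate, or NA (no candidate within budget, or a
# tie — ambiguity never guesses).
match_prefix_set <- function(seqs, candidates, max_edit = 0L) {
  len <- nchar(candidates[1])
  pre <- substr(seqs, 1, len)
  if (max_edit == 0L) {
    return(match(pre, candidates))
  }
  out <- rep(NA_integer_, length(seqs))
  for (i in seq_along(seqs)) {
    d <- utils::adist(pre[i], candidates)
    best <- min(d)
    if (best <= max_edit && sum(d == best) == 1L) out[i] <- which.max(d == best)
  }
  out
}

# per-mate side detection: does this read start with barcode+tail of the
# given oligo set?  Returns oligo row index or NA.
detect_side <- function(seqs, oligos, max_edit = 0L) {
  key <- paste0(oligos$barcode, oligos$tail)
  # tails within one side share length by construction; guard anyway
  if (length(unique(nchar(key))) != 1L) {
    idx <- rep(NA_integer_, length(seqs))
    for (i in seq_along(seqs)) {
      hit <- which(vapply(key, function(k)
        utils::adist(substr(seqs[i], 1, nchar(k)), k) <= max_edit, logical(1)))
      if (length(hit) == 1L) idx[i] <- hit
    }
    return(idx)
  }
  match_prefix_set(seqs, key, max_edit)
}

# primer detection at a fixed offset: compares the read segment starting at
# `offset + 1` with each locus primer.  Returns locus row index or NA.
detect_primer <- function(seqs, offsets, primers, max_edit = 0L) {
  out <- rep(NA_integer_, length(seqs))
  plen <- nchar(primers)
  if (max_edit == 0L) {
    for (l in seq_along(primers)) {
      seg <- substr(seqs, offsets + 1L, offsets + plen[l])
      hit <- !is.na(seg) & seg == primers[l] & is.na(out)
      out[hit] <- l
    }
    # exact matching: a read can match at most one primer unless one primer
    # is a prefix of another; first match in table order wins deterministically
    return(out)
  }
  for (i in seq_along(seqs)) {
    if (is.na(offsets[i])) next
    segs <- substr(rep(seqs[i], length(primers)), offsets[i] + 1L,
                   offsets[i] + plen)
    d <- mapply(function(s, p) utils::adist(s, p), segs, primers)
    best <- min(d)
    if (best <= max_edit && sum(d == best) == 1L) out[i] <- which.max(d == best)
  }
  out
}

#' Classify one read pair into a sort category
#'
#' Applies the hierarchical sorting rule to a single mate pair: count
#' identifiable barcode+tail prefixes across the two mates (either mate may
#' carry either side), then, when both sides are present, locate the locus
#' primers immediately 3' of each universal tail.  Reads with two valid
#' barcodes whose (forward, reverse) combination is not assigned to any
#' individual are demoted to `ONE_BARCODE` and tallied separately, so an
#' unused combination can never produce a genotype.  Pairs where both
#' identifiable prefixes belong to the same side, and pairs where only one
#' primer is identifiable, fall to `ONE_BARCODE` and `TWO_BC_NO_PRIMER`
#' respectively.
#'
#' @param seq_1,seq_2 The two mate sequences.
#' @param scheme An `msat_scheme`.
#' @param max_edit_barcode,max_edit_primer Levenshtein error budget for the
#'   barcode+tail prefix and the primer (default 0: exact identity).
#' @return A one-row tibble: `category`, `individual`, `locus`, `trimmed`
#'   (NA unless `TWO_BC_MATCHING_PRIMERS`), `unassigned_pair`.
#' @export
classify_pair <- function(seq_1, seq_2, scheme,
                          max_edit_barcode = 0L, max_edit_primer = 0L) {
  classify_pairs(tibble(seq_1 = seq_1, seq_2 = seq_2), scheme,
                 max_edit_barcode, max_edit_primer)
}

# vectorised classifier over a pair tibble
classify_pairs <- function(pairs, scheme, max_edit_barcode = 0L,
                           max_edit_primer = 0L) {
  n <- nrow(pairs)
  s1 <- toupper(pairs$seq_1); s2 <- toupper(pairs$seq_2)
  f1 <- detect_side(s1, scheme$forward, max_edit_barcode)
  f2 <- detect_side(s2, scheme$forward, max_edit_barcode)
  r1 <- detect_side(s1, scheme$reverse, max_edit_barcode)
  r2 <- detect_side(s2, scheme$reverse, max_edit_barcode)
  # a mate matching both sides is ambiguous -> drop both interpretations
  amb1 <- !is.na(f1) & !is.na(r1); f1[amb1] <- NA; r1[amb1] <- NA
  amb2 <- !is.na(f2) & !is.na(r2); f2[amb2] <- NA; r2[amb2] <- NA

  # orientation: forward side on mate 1 and reverse on mate 2, or swapped
  ori1 <- !is.na(f1) & !is.na(r2)
  ori2 <- !is.na(f2) & !is.na(r1) & !ori1
  two_bc <- ori1 | ori2
  n_hits <- (!is.na(f1) | !is.na(f2)) + (!is.na(r1) | !is.na(r2))
  # same-side double hits (e.g. forward prefix on both mates) count one side
  category <- rep("NO_BARCODE", n)
  category[n_hits >= 1L] <- "ONE_BARCODE"

  fwd_seq <- ifelse(ori1, s1, ifelse(ori2, s2, NA_character_))
  rev_seq <- ifelse(ori1, s2, ifelse(ori2, s1, NA_character_))
  # NA indices must be typed: a logical NA would index as a filter
  fwd_oligo <- ifelse(ori1, f1, ifelse(ori2, f2, NA_integer_))
  rev_oligo <- ifelse(ori1, r2, ifelse(ori2, r1, NA_integer_))

  fwd_off <- BARCODE_LEN + nchar(scheme$forward$tail)[fwd_oligo]
  rev_off <- BARCODE_LEN + nchar(scheme$reverse$tail)[rev_oligo]
  loc_f <- rep(NA_integer_, n); loc_r <- rep(NA_integer_, n)
  if (any(two_bc)) {
    loc_f[two_bc] <- detect_primer(fwd_seq[two_bc], fwd_off[two_bc],
                                   scheme$loci$fwd_primer, max_edit_primer)
    loc_r[two_bc] <- detect_primer(rev_seq[two_bc], rev_off[two_bc],
                                   scheme$loci$rev_primer, max_edit_primer)
  }
  both_primer <- two_bc & !is.na(loc_f) & !is.na(loc_r)
  category[two_bc] <- "TWO_BC_NO_PRIMER"
  category[both_primer & loc_f != loc_r] <- "TWO_BC_NONMATCHING_PRIMERS"
  match_ok <- both_primer & loc_f == loc_r
  category[match_ok] <- "TWO_BC_MATCHING_PRIMERS"

  # map barcode pair -> individual
  key <- paste(scheme$forward$id[fwd_oligo], scheme$reverse$id[rev_oligo],
               sep = "\r")
  akey <- paste(scheme$assignments$forward_id, scheme$assignments$reverse_id,
                sep = "\r")
  ind <- scheme$assignments$individual[match(key, akey)]
  unassigned <- match_ok & is.na(ind)
  category[unassigned] <- "ONE_BARCODE"   # demoted; tallied separately
  match_ok <- match_ok & !unassigned

  trimmed <- rep(NA_character_, n)
  if (any(match_ok)) {
    # the forward-side mate spans the whole molecule:
    # [BCf][tailF][amplicon][rc(tailR)][rc(BCr)]
    trimmed[match_ok] <- substr(
      fwd_seq[match_ok], fwd_off[match_ok] + 1L,
      nchar(fwd_seq[match_ok]) - rev_off[match_ok])
  }
  tibble(
    category = factor(category, levels = SORT_CATEGORIES),
    individual = ifelse(match_ok, ind, NA_character_),
    locus = ifelse(match_ok, scheme$loci$locus[loc_f], NA_character_),
    trimmed = trimmed,
    unassigned_pair = unassigned
  )
}

#' Demultiplex a paired amplicon run
#'
#' Sorts every mate pair into the five recovery categories and groups the
#' `TWO_BC_MATCHING_PRIMERS` reads into per-individual, per-locus bins of
#' trimmed amplicon sequences (barcode and universal tail removed, primers
#' retained so trimmed length equals the designed product length).
#'
#' @param pairs Pair tibble from [read_fastq_pairs()] (columns `read_id`,
#'   `seq_1`, `seq_2`; qualities optional and unused).
#' @param scheme An `msat_scheme`.
#' @param max_edit_barcode,max_edit_primer Levenshtein error budgets
#'   (default 0, exact identity).
#' @return An object of class `msat_demux`: list with `reads` (per-read
#'   classification tibble), `bins` (tibble `individual`, `locus`, `trimmed`)
#'   and `counts` (a `msat_category_counts`).
#' @export
demux_run <- function(pairs, scheme, max_edit_barcode = 0L,
                      max_edit_primer = 0L) {
  cls <- classify_pairs(pairs, scheme, max_edit_barcode, max_edit_primer)
  cls <- bind_cols(tibble(read_id = pairs$read_id %||%
                            paste0("read", seq_len(nrow(pairs)))), cls)
  counts <- category_counts(cls)
  bins <- cls %>%
    filter(.data$category == "TWO_BC_MATCHING_PRIMERS") %>%
    select("individual", "locus", "trimmed")
  structure(list(reads = cls, bins = bins, counts = counts),
            class = "msat_demux")
}

#' Tally sort categories
#'
#' @param reads Per-read classification tibble (column `category`, optionally
#'   `unassigned_pair`).
#' @return A `msat_category_counts`: named integer vector over the five
#'   categories with attributes `total` and `unassigned_pair`.
#' @export
category_counts <- function(reads) {
  counts <- table(factor(reads$category, levels = SORT_CATEGORIES))
  out <- setNames(as.integer(counts), SORT_CATEGORIES)
  stopifnot(sum(out) == nrow(reads))   # conservation, asserted on every run
  structure(out, total = nrow(reads),
            unassigned_pair = sum(reads$unassigned_pair %||% 0L),
            class = "msat_category_counts")
}

#' @export
print.msat_category_counts <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}

#' @method tidy msat_category_counts
#' @export
tidy.msat_category_counts <- function(x, ...) {
  total <- attr(x, "total")
  tibble(category = names(x), reads = as.integer(x),
         percent = if (total > 0) round(100 * as.integer(x) / total, 1) else
           rep(NA_real_, length(x)))
}

#' Write the category breakdown report
#'
#' TSV mirroring the standard run-summary layout: one row per category with
#' read count and percent of total (one decimal), plus a total row.  An empty
#' run produces a warning and a report with zero category rows.
#'
#' @param counts A `msat_category_counts`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_category_report <- function(counts, path) {
  total <- attr(counts, "total")
  if (total == 0) {
    warn("empty run: category report has no rows")
    writeLines("category\treads\tpercent", path)
    return(invisible(path))
  }
  df <- tidy(counts)
  df <- bind_rows(df, tibble(category = "total", reads = total,
                             percent = 100))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write demultiplexed output files
#'
#' One FASTA per sort category (reads in that category, forward mate as
#' sequenced) and one FASTA of trimmed sequences per individual x locus bin,
#' named `<individual>_<locus>.fasta`.
#'
#' @param demux An `msat_demux`.
#' @param pairs The pair tibble the demux was run on.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_demux_output <- function(demux, pairs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reads <- demux$reads
  for (cat in SORT_CATEGORIES) {
    idx <- which(reads$category == cat)
    x <- Biostrings::DNAStringSet(pairs$seq_1[idx])
    names(x) <- reads$read_id[idx]
    Biostrings::writeXStringSet(x, file.path(dir, paste0(cat, ".fasta")))
  }
  bins <- split(demux$bins, paste0(demux$bins$individual, "_",
                                   demux$bins$locus))
  for (nm in names(bins)) {
    x <- Biostrings::DNAStringSet(bins[[nm]]$trimmed)
    names(x) <- paste0(nm, "_", seq_len(length(x)))
    Biostrings::writeXStringSet(x, file.path(dir, paste0(nm, ".fasta")))
  }
  write_category_report(demux$counts, file.path(dir, "category_counts.tsv"))
  invisible(dir)
}
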