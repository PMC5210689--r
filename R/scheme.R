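#' Canonical universal tails
#'
#' The two universal tail sequences used by the two-step PCR design: the
#' M13-R tail carried by all forward-side barcodes and locus forward primers,
#' and the CAG tail carried by the reverse side.  The tails, not the barcode
#' sequences themselves, distinguish the two sides of the amplicon.
#'
#' @format Named character vector with entries `forward` (M13-R, 18 nt) and
#'   `reverse` (CAG, 16 nt).
#' @export
universal_tails <- c(
  forward = "GGAAACAGCTATGACCAT",
  reverse = "CAGTCGGGCGTCATCA"
)

BARCODE_LEN <- 11L

#' Build a locus definition table
#'
#' @param id Locus labels.
#' @param fwd_primer,rev_primer Locus-specific primer sequences (the primer as
#'   ordered, i.e. the reverse primer is given on its own strand).
#' @param repeat_unit_bp Repeat motif length in bp (>= 1).
#' @param min_bp,max_bp Expected trimmed-amplicon (primer-to-primer) length
#'   range in bp.
#' @return A tibble with one row per locus.
#' @export
locus_table <- function(id, fwd_primer, rev_primer, repeat_unit_bp,
                        min_bp = 120L, max_bp = 180L) {
  loci <- tibble(
    locus = as.character(id),
    fwd_primer = toupper(fwd_primer),
    rev_primer = toupper(rev_primer),
    repeat_unit_bp = as.integer(repeat_unit_bp),
    min_bp = as.integer(min_bp),
    max_bp = as.integer(max_bp)
  )
  if (any(!nzchar(loci$fwd_primer)) || any(!nzchar(loci$rev_primer))) {
    abort("locus primers must be non-empty")
  }
  check_dna(loci$fwd_primer, "forward primer")
  check_dna(loci$rev_primer, "reverse primer")
  if (any(loci$repeat_unit_bp < 1L)) abort("repeat_unit_bp must be >= 1")
  if (any(loci$min_bp > loci$max_bp)) abort("locus min_bp must be <= max_bp")
  if (anyDuplicated(loci$locus)) abort("duplicate locus ids")
  loci
}

new_scheme <- function(forward, reverse, loci, assignments) {
  structure(
    list(forward = forward, reverse = reverse, loci = loci,
         assignments = assignments),
    class = "msat_scheme"
  )
}

validate_scheme <- function(scheme) {
  with(scheme, {
    for (tbl in list(forward, reverse)) {
      if (any(nchar(tbl$barcode) != BARCODE_LEN)) {
        abort(sprintf("all barcodes must be %d nt", BARCODE_LEN))
      }
      check_dna(tbl$barcode, "barcode")
      check_dna(tbl$tail, "tail")
      if (anyDuplicated(tbl$barcode)) abort("duplicate barcode within a set")
      if (anyDuplicated(tbl$id)) abort("duplicate oligo id within a set")
    }
    if (nrow(assignments)) {
      bad_f <- setdiff(assignments$forward_id, forward$id)
      bad_r <- setdiff(assignments$reverse_id, reverse$id)
      if (length(bad_f) || length(bad_r)) {
        abort(sprintf("assignment references unknown oligo id(s): %s",
                      paste(c(bad_f, bad_r), collapse = ", ")))
      }
      pair <- paste(assignments$forward_id, assignments$reverse_id, sep = "\r")
      if (anyDuplicated(pair)) {
        dup <- assignments[duplicated(pair) | duplicated(pair, fromLast = TRUE), ]
        abort(sprintf(
          "duplicate barcode-pair assignment: individuals %s share a (forward, reverse) pair",
          paste(unique(dup$individual), collapse = ", ")))
      }
      if (anyDuplicated(assignments$individual)) {
        abort("an individual is assigned more than one barcode pair")
      }
      if (any(!nzchar(assignments$population))) {
        abort("population labels must be non-empty")
      }
    }
    cap <- nrow(forward) * nrow(reverse)
    if (nrow(assignments) > cap) {
      abort(sprintf("scheme capacity %d < %d individuals", cap,
                    nrow(assignments)))
    }
  })
  invisible(scheme)
}

#' Construct a combinatorial barcoding scheme
#'
#' Lays `individuals` out on the forward x reverse barcode grid in row-major
#' order (forward barcodes are rows, reverse barcodes are columns), attaching
#' the canonical universal tail of each side.  With `n_f` forward and `n_r`
#' reverse barcodes the scheme can address `n_f * n_r` individuals.
#'
#' @param forward_barcodes,reverse_barcodes Character vectors of 11-nt
#'   barcodes (or tibbles with columns `id`, `barcode`).
#' @param individuals Character vector of individual ids (may be empty).
#' @param loci Locus table from [locus_table()].
#' @param populations Named character vector or single label mapping
#'   individuals to population labels (default `"pop1"`).
#' @param tails Named character vector overriding [universal_tails].
#' @return An object of class `msat_scheme`.
#' @export
#' @examples
#' sc <- build_scheme(random_scheme_barcodes(2), random_scheme_barcodes(2),
#'                    individuals = c("i1", "i2", "i3"),
#'                    loci = locus_table("L1", "ACGTACGTACGTACGTACGT",
#'                                       "TGCATGCATGCATGCATGCA", 4))
#' scheme_capacity(sc)
build_scheme <- function(forward_barcodes, reverse_barcodes, individuals = character(),
                         loci, populations = "pop1", tails = universal_tails) {
  fwd <- as_oligo_tbl(forward_barcodes, "F", tails[["forward"]])
  rev <- as_oligo_tbl(reverse_barcodes, "R", tails[["reverse"]])
  n_ind <- length(individuals)
  cap <- nrow(fwd) * nrow(rev)
  if (n_ind > cap) {
    abort(sprintf("insufficient scheme capacity: %d individuals require > %d combinations (have %d forward x %d reverse = %d)",
                  n_ind, n_ind, nrow(fwd), nrow(rev), cap))
  }
  if (length(populations) == 1L && is.null(names(populations))) {
    populations <- setNames(rep(populations, n_ind), individuals)
  }
  if (n_ind && !all(individuals %in% names(populations))) {
    abort("every individual needs a population label")
  }
  idx <- seq_len(n_ind) - 1L   # row-major over the grid
  assignments <- tibble(
    individual = as.character(individuals),
    forward_id = fwd$id[idx %/% nrow(rev) + 1L],
    reverse_id = rev$id[idx %% nrow(rev) + 1L],
    population = if (n_ind) unname(populations[individuals]) else character()
  )
  sc <- new_scheme(fwd, rev, loci, assignments)
  validate_scheme(sc)
  sc
}

as_oligo_tbl <- function(x, prefix, tail) {
  if (is.data.frame(x)) {
    tbl <- tibble(id = as.character(x$id), barcode = toupper(x$barcode))
  } else {
    tbl <- tibble(id = paste0(prefix, str_pad(seq_along(x), 2, pad = "0")),
                  barcode = toupper(as.character(x)))
  }
  tbl$tail <- if ("tail" %in% names(x)) toupper(x$tail) else tail
  tbl
}

#' Scheme capacity
#'
#' Number of addressable individuals: `|forward| * |reverse|`.
#'
#' @param scheme An `msat_scheme`.
#' @return Integer.
#' @export
scheme_capacity <- function(scheme) {
  nrow(scheme$forward) * nrow(scheme$reverse)
}

#' @export
print.msat_scheme <- function(x, ...) {
  cat(sprintf(
    "<msat_scheme> %d forward x %d reverse barcodes (capacity %d), %d individuals, %d loci\n",
    nrow(x$forward), nrow(x$reverse), scheme_capacity(x),
    nrow(x$assignments), nrow(x$loci)))
  invisible(x)
}

#' Generate random well-separated barcodes
#'
#' Convenience generator of unique random 11-nt barcodes for simulations and
#' examples.  Rejection-samples until all pairwise Levenshtein distances reach
#' `min_edit`.
#'
#' @param n Number of barcodes.
#' @param min_edit Minimum pairwise edit distance (default 3).
#' @param seed Optional RNG seed.
#' @return Character vector of length `n`.
#' @export
random_scheme_barcodes <- function(n, min_edit = 3, seed = NULL) {
  set_seed_if(seed)
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    cand <- random_dna(1, BARCODE_LEN)
    if (!length(out) ||
        min(utils::adist(cand, out)) >= min_edit) {
      out <- c(out, cand)
    }
    guard <- guard + 1L
    if (guard > 2000L * n) abort("could not generate separated barcodes")
  }
  out
}

#' Validate pairwise separation of a barcode set
#'
#' Reports every pair of barcodes whose Levenshtein distance falls below
#' `min_edit`.  The check is advisory: schemes built from closer barcodes are
#' allowed (demultiplexing with a zero edit budget tolerates any distinct
#' barcodes), but separated sets are robust to sequencing error.
#'
#' @param barcodes Character vector of barcodes.
#' @param min_edit Minimum acceptable pairwise Levenshtein distance.
#' @return A tibble of offending pairs (`barcode_1`, `barcode_2`, `distance`)
#'   with attribute `pass` (TRUE iff no pair falls below `min_edit`).
#' @export
validate_barcode_set <- function(barcodes, min_edit = 3) {
  barcodes <- toupper(barcodes)
  if (anyDuplicated(barcodes)) abort("barcodes must be unique")
  n <- length(barcodes)
  if (n < 2) {
    out <- tibble(barcode_1 = character(), barcode_2 = character(),
                  distance = integer())
    attr(out, "pass") <- TRUE
    attr(out, "min_observed") <- NA_integer_
    return(out)
  }
  d <- utils::adist(barcodes)
  idx <- which(upper.tri(d) & d < min_edit, arr.ind = TRUE)
  out <- tibble(
    barcode_1 = barcodes[idx[, 1]],
    barcode_2 = barcodes[idx[, 2]],
    distance = as.integer(d[idx])
  ) %>% arrange(.data$distance)
  attr(out, "pass") <- nrow(out) == 0L
  attr(out, "min_observed") <- as.integer(min(d[upper.tri(d)]))
  out
}

#' Write a scheme to a YAML config file
#'
#' @param scheme An `msat_scheme`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  loci <- scheme$loci[, c("locus", "fwd_primer", "rev_primer",
                          "repeat_unit_bp", "min_bp", "max_bp")]
  doc <- list(
    format_version = 1L,
    tails = as.list(universal_tails),
    forward_oligos = purrr::transpose(as.list(scheme$forward)),
    reverse_oligos = purrr::transpose(as.list(scheme$reverse)),
    loci = purrr::transpose(as.list(loci)),
    assignments = purrr::transpose(as.list(scheme$assignments))
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Load a scheme from a YAML config file
#'
#' Reads the structured scheme config (oligos, loci, assignments,
#' populations) and validates all invariants: barcode length, uniqueness of
#' barcode-pair assignments, referenced oligos, and capacity.
#'
#' @param path Scheme config file written by [write_scheme()] (or by hand in
#'   the same layout).
#' @return An `msat_scheme`.
#' @export
load_scheme <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$format_version)) abort("scheme config lacks format_version")
  row_bind <- function(x) dplyr::bind_rows(lapply(x, tibble::as_tibble))
  fwd <- row_bind(doc$forward_oligos)
  rev <- row_bind(doc$reverse_oligos)
  loci <- row_bind(doc$loci)
  loci <- locus_table(loci$locus, loci$fwd_primer, loci$rev_primer,
                      loci$repeat_unit_bp, loci$min_bp, loci$max_bp)
  assignments <- if (length(doc$assignments)) row_bind(doc$assignments) else
    tibble(individual = character(), forward_id = character(),
           reverse_id = character(), population = character())
  sc <- new_scheme(fwd, rev, loci, assignments)
  validate_scheme(sc)
  sc
}
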