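#' Write a genotype table in Genepop format
#'
#' Genotypes are encoded in the 3-digit Genepop dialect with the allele code
#' equal to the trimmed-amplicon length in bp (the loci this package targets
#' fall in the 120-180 bp design window, so lengths always fit 3 digits).
#' Missing genotypes are written as `000000`.  Populations are emitted in
#' first-appearance order, separated by `Pop` lines.
#'
#' @param calls Genotype call tibble with columns `individual`, `locus`,
#'   `allele_a`, `allele_b`, `status`, `population` (see
#'   [assemble_matrix()]).
#' @param path Output file.
#' @param title Title line for the file header.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(calls, path, title = "msatgbs genotype export") {
  check_calls(calls)
  loci <- unique(calls$locus)
  called <- calls$status == "called"
  alleles <- c(calls$allele_a[called], calls$allele_b[called])
  if (length(alleles) && (min(alleles) < 1 || max(alleles) > 999)) {
    abort("Genepop encoding error: allele codes must lie in 001-999")
  }
  enc <- function(a, b, ok) {
    ifelse(ok,
           paste0(formatC(a, width = 3, flag = "0"),
                  formatC(b, width = 3, flag = "0")),
           "000000")
  }
  wide <- calls %>%
    mutate(code = enc(.data$allele_a, .data$allele_b,
                      .data$status == "called")) %>%
    select("individual", "population", "locus", "code") %>%
    pivot_wider(names_from = "locus", values_from = "code")
  lines <- c(title, loci)
  for (p in unique(wide$population)) {
    lines <- c(lines, "Pop")
    sub <- wide[wide$population == p, ]
    lines <- c(lines, paste0(sub$individual, " ,  ",
                             apply(sub[, loci, drop = FALSE], 1, paste,
                                   collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a Genepop file
#'
#' Parses the 3-digit (or 2-digit) Genepop dialect back into the package's
#' long genotype-call tibble.  `000` codes become missing calls with status
#' `no_reads`; population labels are `pop1`, `pop2`, ... in file order unless
#' the last individual name of each population is preferred (`label_by_last`).
#'
#' @param path Genepop file.
#' @param label_by_last Use the conventional "last individual names the
#'   population" rule for population labels (default FALSE).
#' @return A genotype call tibble.
#' @export
read_genepop <- function(path, label_by_last = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) abort("Genepop parse error: file too short")
  body <- lines[-1]
  is_pop <- toupper(trimws(body)) %in% c("POP")
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) abort("Genepop parse error: no Pop line")
  loci <- trimws(body[seq_len(first_pop - 1)])
  # loci may be comma-separated on one line
  if (length(loci) == 1 && grepl(",", loci)) {
    loci <- trimws(strsplit(loci, ",")[[1]])
  }
  recs <- list()
  pop_id <- 0L
  for (ln in body[first_pop:length(body)]) {
    if (toupper(trimws(ln)) == "POP") { pop_id <- pop_id + 1L; next }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) != 2) abort(sprintf("Genepop parse error at line: %s", ln))
    ind <- trimws(parts[1])
    codes <- strsplit(trimws(parts[2]), "[ \t]+")[[1]]
    if (length(codes) != length(loci)) {
      abort(sprintf("Genepop parse error: %d codes for %d loci (individual %s)",
                    length(codes), length(loci), ind))
    }
    w <- nchar(codes[1]) / 2
    a <- as.integer(substr(codes, 1, w))
    b <- as.integer(substr(codes, w + 1, 2 * w))
    recs[[length(recs) + 1L]] <- tibble(
      individual = ind, population = paste0("pop", pop_id), locus = loci,
      allele_a = ifelse(a == 0, NA_integer_, pmin(a, b)),
      allele_b = ifelse(a == 0, NA_integer_, pmax(a, b)),
      status = ifelse(a == 0, "no_reads", "called"))
  }
  out <- bind_rows(recs)
  if (label_by_last) {
    lab <- out %>% group_by(.data$population) %>%
      summarise(last = dplyr::last(unique(.data$individual)))
    out$population <- lab$last[match(out$population, lab$population)]
  }
  out$depth <- NA_integer_
  out[, c("individual", "locus", "allele_a", "allele_b", "status", "depth",
          "population")]
}

check_calls <- function(calls) {
  need <- c("individual", "locus", "allele_a", "allele_b", "status",
            "population")
  miss <- setdiff(need, names(calls))
  if (length(miss)) {
    abort(paste("genotype table lacks column(s):", paste(miss, collapse = ", ")))
  }
  invisible(calls)
}
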