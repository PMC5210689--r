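# Independent oracles used across the suite.  These deliberately share no
# code with the package: brute-force dynamic programming, exhaustive
# enumeration and literal per-allele transcription of the estimator
# definitions.

# full-table Levenshtein DP
dp_edit_distance <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(x) + 1, length(y) + 1)
  d[, 1] <- 0:length(x)
  d[1, ] <- 0:length(y)
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (x[i] != y[j]))
    }
  }
  d[length(x) + 1, length(y) + 1]
}

# literal per-allele Weir-Cockerham (1984) theta, scalar loops throughout
wc_theta_oracle <- function(geno_list) {
  # geno_list: per locus, a data.frame with columns a1, a2, pop
  num <- 0; den <- 0
  for (g in geno_list) {
    pops <- sort(unique(g$pop))
    r <- length(pops)
    if (r < 2) next
    alleles <- sort(unique(c(g$a1, g$a2)))
    if (length(alleles) < 2) next
    n_i <- sapply(pops, function(p) sum(g$pop == p))
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    for (u in alleles) {
      p_i <- h_i <- numeric(r)
      for (k in seq_len(r)) {
        gg <- g[g$pop == pops[k], ]
        p_i[k] <- (sum(gg$a1 == u) + sum(gg$a2 == u)) / (2 * nrow(gg))
        h_i[k] <- mean((gg$a1 == u) != (gg$a2 == u))
      }
      pbar <- sum(n_i * p_i) / (r * nbar)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / (r * nbar)
      a <- nbar / nc *
        (s2 - 1 / (nbar - 1) *
           (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
      b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

# exact rarefied richness by enumerating every g-subset of the gene vector
rs_enum_oracle <- function(allele_copies, g) {
  subsets <- utils::combn(seq_along(allele_copies), g)
  mean(apply(subsets, 2, function(j) length(unique(allele_copies[j]))))
}

# exact Levene-conditional HWE probability test for a biallelic sample
hwe_exact_oracle_biallelic <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  logp <- function(hAB) {
    aa <- (nA - hAB) / 2
    bb <- (2 * n - nA - hAB) / 2
    lfactorial(n) + hAB * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) -
      lfactorial(2 * n) - lfactorial(aa) - lfactorial(hAB) - lfactorial(bb)
  }
  hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  lp <- sapply(hs, logp)
  p_obs <- logp(nAB)
  sum(exp(lp[lp <= p_obs + 1e-9])) / sum(exp(lp))
}

# draw a called genotype tibble of HWE samples from given per-locus freqs
hwe_sample_calls <- function(freqs, n, pop = "pop1") {
  purrr::imap_dfr(freqs, function(f, loc) {
    lens <- suppressWarnings(as.integer(names(f)))
    if (any(is.na(lens))) lens <- seq_along(f) + 100L
    a <- sample(lens, n, replace = TRUE, prob = f)
    b <- sample(lens, n, replace = TRUE, prob = f)
    tibble::tibble(individual = sprintf("%s_i%03d", pop, seq_len(n)),
                   locus = if (is.character(loc) && nzchar(loc)) loc else
                     paste0("L", loc),
                   allele_a = pmin(a, b), allele_b = pmax(a, b),
                   status = "called", depth = NA_integer_, population = pop)
  })
}

# quick genotype tibble builder: g is a list pop -> list of c(a, b) rows
make_calls <- function(g, locus = "L1") {
  rows <- list()
  i <- 0
  for (pop in names(g)) {
    for (ab in g[[pop]]) {
      i <- i + 1
      rows[[i]] <- tibble::tibble(
        individual = paste0("i", i), locus = locus,
        allele_a = min(ab), allele_b = max(ab),
        status = "called", depth = NA_integer_, population = pop)
    }
  }
  dplyr::bind_rows(rows)
}

# small ready-made scheme for demux tests
toy_scheme <- function(n_f = 3, n_r = 3, n_loci = 2, n_ind = NULL,
                       seed = 7) {
  set.seed(seed)
  loci <- locus_table(
    id = paste0("LOC", seq_len(n_loci)),
    fwd_primer = vapply(seq_len(n_loci), function(i)
      paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""),
      character(1)),
    rev_primer = vapply(seq_len(n_loci), function(i)
      paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""),
      character(1)),
    repeat_unit_bp = rep(4, n_loci))
  n_ind <- n_ind %||% (n_f * n_r)
  build_scheme(random_scheme_barcodes(n_f), random_scheme_barcodes(n_r),
               individuals = paste0("ind", seq_len(n_ind)), loci = loci)
}

# construct a perfect read pair for an individual x locus of a scheme
perfect_pair <- function(scheme, individual, locus, insert_len = 150,
                         swap = FALSE) {
  asg <- scheme$assignments
  row <- asg[asg$individual == individual, ]
  fo <- scheme$forward[scheme$forward$id == row$forward_id, ]
  ro <- scheme$reverse[scheme$reverse$id == row$reverse_id, ]
  lc <- scheme$loci[scheme$loci$locus == locus, ]
  mid_len <- insert_len - nchar(lc$fwd_primer) - nchar(lc$rev_primer)
  mid <- paste(rep("A", mid_len), collapse = "")
  amplicon <- paste0(lc$fwd_primer, mid, revcomp(lc$rev_primer))
  top <- paste0(fo$barcode, fo$tail, amplicon, revcomp(ro$tail),
                revcomp(ro$barcode))
  bot <- revcomp(top)
  if (swap) list(seq_1 = bot, seq_2 = top, amplicon = amplicon)
  else list(seq_1 = top, seq_2 = bot, amplicon = amplicon)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

SORT_CATEGORIES_for_test <- function() {
  c("NO_BARCODE", "ONE_BARCODE", "TWO_BC_NO_PRIMER",
    "TWO_BC_NONMATCHING_PRIMERS", "TWO_BC_MATCHING_PRIMERS")
}
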