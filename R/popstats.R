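#' Filter genotypes on completeness
#'
#' Two-pass completeness filter: loci with call rate below `threshold`
#' across individuals are removed first, then individuals with call rate
#' below `threshold` across the retained loci.  Removing a weak locus can
#' therefore rescue an individual whose failures were concentrated there.
#' The pass order can be swapped.
#'
#' @param calls Complete genotype call tibble.
#' @param threshold Minimum genotyping success rate (default 0.75).
#' @param order `"loci_first"` (default) or `"individuals_first"`.
#' @return List: `calls` (filtered tibble), `removed_loci` and
#'   `removed_individuals` (tibbles with the offending call rates).
#' @export
filter_completeness <- function(calls, threshold = 0.75,
                                order = c("loci_first", "individuals_first")) {
  order <- match.arg(order)
  pass_locus <- function(cc) {
    r <- cc %>% group_by(.data$locus) %>%
      summarise(call_rate = mean(.data$status == "called"), .groups = "drop")
    bad <- r$locus[r$call_rate < threshold]
    list(calls = cc[!cc$locus %in% bad, , drop = FALSE],
         removed = r[r$locus %in% bad, ])
  }
  pass_ind <- function(cc) {
    r <- cc %>% group_by(.data$individual) %>%
      summarise(call_rate = mean(.data$status == "called"), .groups = "drop")
    bad <- r$individual[r$call_rate < threshold]
    list(calls = cc[!cc$individual %in% bad, , drop = FALSE],
         removed = r[r$individual %in% bad, ])
  }
  if (order == "loci_first") {
    a <- pass_locus(calls); b <- pass_ind(a$calls)
    out <- list(calls = b$calls, removed_loci = a$removed,
                removed_individuals = b$removed)
  } else {
    a <- pass_ind(calls); b <- pass_locus(a$calls)
    out <- list(calls = b$calls, removed_loci = b$removed,
                removed_individuals = a$removed)
  }
  if (!nrow(out$calls)) warn("completeness filter removed everything")
  out
}

#' Allele frequency table
#'
#' Per population x locus allele frequencies from called genotypes, with the
#' gene count `n_genes` (= 2 x called individuals; statistics use
#' pairwise-complete observations, so `n_genes` varies by locus).
#'
#' @param calls Genotype call tibble.
#' @return Tibble `population`, `locus`, `allele`, `count`, `frequency`,
#'   `n_genes`.
#' @export
allele_freqs <- function(calls) {
  check_calls(calls)
  long <- calls %>% filter(.data$status == "called") %>%
    select("population", "locus", "allele_a", "allele_b") %>%
    pivot_longer(c("allele_a", "allele_b"), values_to = "allele")
  long %>% count(.data$population, .data$locus, .data$allele,
                 name = "count") %>%
    group_by(.data$population, .data$locus) %>%
    mutate(n_genes = sum(.data$count),
           frequency = .data$count / .data$n_genes) %>%
    ungroup()
}

#' Per-locus, per-population allele summaries
#'
#' Number of alleles, allele size range, observed heterozygosity
#' `Ho` (fraction of called individuals heterozygous) and unbiased expected
#' heterozygosity `He = 2n/(2n-1) * (1 - sum p^2)` with `n` called
#' individuals.
#'
#' @param calls Genotype call tibble.
#' @return Tibble `locus`, `population`, `n_called`, `n_alleles`,
#'   `size_min`, `size_max`, `Ho`, `He`.
#' @export
summarize_alleles <- function(calls) {
  check_calls(calls)
  obs <- calls %>% filter(.data$status == "called") %>%
    group_by(.data$locus, .data$population) %>%
    summarise(n_called = n(),
              Ho = mean(.data$allele_a != .data$allele_b),
              size_min = min(pmin(.data$allele_a, .data$allele_b)),
              size_max = max(pmax(.data$allele_a, .data$allele_b)),
              .groups = "drop")
  he <- allele_freqs(calls) %>%
    group_by(.data$locus, .data$population) %>%
    summarise(n_alleles = n(),
              He = (1 - sum(.data$frequency^2)) *
                (.data$n_genes[1] / (.data$n_genes[1] - 1)),
              .groups = "drop")
  # n_genes = 2 -> unbiased factor 2n/(2n-1) = 2/1 handled by the formula
  obs %>% inner_join(he, by = c("locus", "population")) %>%
    select("locus", "population", "n_called", "n_alleles",
           "size_min", "size_max", "Ho", "He")
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random draw of `g` gene copies
#' from the sampled pool:
#' `Rs = sum_u [1 - choose(N - N_u, g) / choose(N, g)]`
#' with `N` genes sampled and `N_u` copies of allele `u`.  Rarefaction to a
#' common `g` makes richness comparable across unequal sample sizes.
#'
#' @param calls Genotype call tibble.
#' @param g Rarefaction gene count; default is the smallest `n_genes` over
#'   all population x locus cells with data.
#' @return Tibble `locus`, `population`, `n_genes`, `g`, `Rs`.
#' @export
allelic_richness <- function(calls, g = NULL) {
  freqs <- allele_freqs(calls)
  if (!nrow(freqs)) return(tibble(locus = character(),
                                  population = character(),
                                  n_genes = integer(), g = integer(),
                                  Rs = double()))
  if (is.null(g)) g <- min(freqs$n_genes)
  if (g < 2) abort("rarefaction gene count g must be >= 2")
  if (g > min(freqs$n_genes)) {
    abort(sprintf("g = %d exceeds the smallest sampled gene count (%d)",
                  g, min(freqs$n_genes)))
  }
  freqs %>% group_by(.data$locus, .data$population) %>%
    summarise(n_genes = .data$n_genes[1], g = g,
              Rs = sum(1 - exp(lchoose(.data$n_genes[1] - .data$count, g) -
                                 lchoose(.data$n_genes[1], g))),
              .groups = "drop")
}

#' Monte-Carlo exact test of Hardy-Weinberg proportions
#'
#' Exact probability test: the statistic is the conditional probability of
#' the observed genotype array given the allele counts (Levene's
#' distribution); the null distribution is sampled by complete random
#' re-pairing of the observed gene pool.  The p-value is the fraction of
#' shuffled arrays at most as probable as the observed one, with the
#' standard +1/+1 Monte-Carlo correction.  Monomorphic samples return 1.
#'
#' @param calls Genotype call tibble.
#' @param locus,population Cell to test.
#' @param n_perm Number of shuffles (default 10000).
#' @param seed Optional RNG seed.
#' @return p-value.
#' @export
hwe_exact_test <- function(calls, locus, population, n_perm = 10000,
                           seed = NULL) {
  set_seed_if(seed)
  sub <- calls[calls$locus == locus & calls$population == population &
                 calls$status == "called", ]
  if (nrow(sub) < 5) abort("HWE test needs >= 5 called individuals")
  a1 <- sub$allele_a; a2 <- sub$allele_b
  pool <- c(a1, a2)
  if (length(unique(pool)) < 2) return(1.0)
  obs <- hwe_log_prob(a1, a2)
  n <- length(a1)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    p <- sample(pool)
    if (hwe_log_prob(p[seq_len(n)], p[n + seq_len(n)]) <= obs + 1e-9) {
      hits <- hits + 1L
    }
  }
  (hits + 1) / (n_perm + 1)
}

# log conditional probability of a genotype array given its allele counts:
# log [ n! 2^h  prod_u a_u! / ( (2n)! prod_{j<=k} n_jk! ) ]
hwe_log_prob <- function(a1, a2) {
  n <- length(a1)
  h <- sum(a1 != a2)
  geno <- paste(pmin(a1, a2), pmax(a1, a2))
  ac <- table(c(a1, a2))
  gc <- table(geno)
  lfactorial(n) + h * log(2) + sum(lfactorial(ac)) -
    lfactorial(2 * n) - sum(lfactorial(gc))
}

#' Sequential Bonferroni (Holm) correction
#'
#' Step-down Holm procedure: with `k` p-values sorted ascending, the i-th is
#' significant iff every p_(j), j <= i, satisfies p_(j) <= alpha / (k-j+1);
#' testing stops at the first failure.  Equivalent to
#' `p.adjust(method = "holm") <= alpha`, which is how it is computed.
#'
#' @param p_values Numeric vector.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Tibble `p_value`, `p_adjusted`, `significant` in input order.
#' @export
sequential_bonferroni <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) {
    return(tibble(p_value = double(), p_adjusted = double(),
                  significant = logical()))
  }
  adj <- p.adjust(p_values, method = "holm")
  tibble(p_value = p_values, p_adjusted = adj, significant = adj <= alpha)
}
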