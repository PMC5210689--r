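#' Expected FST under pure drift
#'
#' Closed form for the differentiation accumulated by `t` generations of
#' drift at constant effective size `Ne`:
#' `E[FST] = 1 - (1 - 1/(2 Ne))^t`.
#'
#' @param Ne Effective population size (>= 1).
#' @param t Generations of drift (>= 0).
#' @return Expected FST.
#' @export
#' @examples
#' expected_fst(1000, 100)  # 0.0488
expected_fst <- function(Ne, t) {
  stopifnot(Ne >= 1, t >= 0)
  1 - (1 - 1 / (2 * Ne))^t
}

#' Generate synthetic base allele frequencies
#'
#' Self-contained designs draw, per locus, an allele count uniform on
#' `k_range` (defaults span the allele-number range typical of polymorphic
#' microsatellite panels) and frequencies from a symmetric Dirichlet(1).
#'
#' @param n_loci Number of loci.
#' @param k_range Inclusive range for the per-locus allele count
#'   (default 3-13).
#' @param seed Optional RNG seed.
#' @return List of per-locus frequency vectors (alleles named "1", "2", ...).
#' @export
make_base_freqs <- function(n_loci, k_range = c(3, 13), seed = NULL) {
  set_seed_if(seed)
  purrr::map(seq_len(n_loci), function(i) {
    k <- sample(seq(k_range[1], k_range[2]), 1)
    x <- stats::rgamma(k, 1)        # symmetric Dirichlet(1)
    setNames(x / sum(x), as.character(seq_len(k)))
  })
}

#' Read/write the frequency file format (TSV: locus, allele, frequency)
#' @param path TSV file.
#' @return List of per-locus frequency vectors.
#' @export
read_base_freqs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lapply(split(df, df$locus), function(d) setNames(d$frequency,
                                                   as.character(d$allele)))
}

#' @rdname read_base_freqs
#' @param freqs List of per-locus frequency vectors.
#' @export
write_base_freqs <- function(freqs, path) {
  df <- purrr::imap_dfr(freqs, function(f, nm) {
    tibble(locus = if (nzchar(nm)) nm else NA_character_,
           allele = names(f), frequency = unname(f))
  })
  if (all(is.na(df$locus))) df$locus <- rep(paste0("L", seq_along(freqs)),
                                            lengths(freqs))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate allele-frequency drift
#'
#' Each population drifts independently from the base frequencies: `t`
#' rounds of multinomial resampling of `2 Ne` gene copies per locus, with
#' renormalisation each round.  `t = 0` returns the base frequencies
#' unchanged; fixed alleles stay fixed.
#'
#' @param base_freqs List of per-locus frequency vectors.
#' @param Ne Effective size.
#' @param t Generations.
#' @param n_pops Number of independently drifting populations.
#' @param seed Optional RNG seed.
#' @return List of length `n_pops`, each a list of per-locus frequency
#'   vectors.
#' @export
drift_sample <- function(base_freqs, Ne, t, n_pops, seed = NULL) {
  set_seed_if(seed)
  purrr::map(seq_len(n_pops), function(p) {
    purrr::map(base_freqs, function(f) {
      for (g in seq_len(t)) {
        f <- setNames(as.vector(rmultinom(1, 2 * Ne, f)) / (2 * Ne), names(f))
      }
      f
    })
  })
}

#' Sample allele counts of an HWE population sample
#'
#' Allele counts of `n` diploids drawn at Hardy-Weinberg proportions are a
#' multinomial draw of `2n` gene copies.
#'
#' @param freqs List of per-locus allele frequency vectors.
#' @param n Diploid sample size.
#' @return List of per-locus named allele-count vectors.
#' @export
sample_allele_counts <- function(freqs, n) {
  lapply(freqs, function(f) setNames(as.vector(rmultinom(1, 2 * n, f)),
                                     names(f)))
}

#' Multi-locus allele-frequency homogeneity test
#'
#' Tests whether per-population allele counts are drawn from one pool.
#' `chi2`: per-locus Pearson chi-square of the population x allele count
#' table, with alleles whose pooled frequency falls below `pool_threshold`
#' collapsed into one class; statistics and degrees of freedom are summed
#' over loci for the overall p-value.  `fisher`: per-locus Monte-Carlo exact
#' test of the count table (the number of sampled tables equals
#' `batches * iterations`), with per-locus p-values combined by Fisher's
#' method (`-2 sum ln p` against chi-square with `2L` d.f.).
#'
#' @param counts Per-population list of per-locus named allele-count vectors
#'   (as from [sample_allele_counts()]).
#' @param method `"chi2"` or `"fisher"`.
#' @param pool_threshold Pooled-frequency threshold below which alleles are
#'   collapsed for the chi-square (default 0.02).
#' @param mc_settings List with `dememorization`, `batches`, `iterations`
#'   (Fisher Monte-Carlo size; defaults 1000/100/1000).
#' @param seed Optional RNG seed.
#' @return List `p_value`, `statistic`, `df`, `n_loci_used`.
#' @export
homogeneity_test <- function(counts, method = c("chi2", "fisher"),
                             pool_threshold = 0.02,
                             mc_settings = list(dememorization = 1000,
                                                batches = 100,
                                                iterations = 1000),
                             seed = NULL) {
  method <- match.arg(method)
  set_seed_if(seed)
  if (length(counts) < 2) abort("homogeneity test needs >= 2 populations")
  n_loci <- length(counts[[1]])
  tabs <- purrr::map(seq_len(n_loci), function(l) {
    alle <- sort(unique(unlist(lapply(counts, function(p) names(p[[l]])))))
    m <- do.call(rbind, lapply(counts, function(p) {
      v <- p[[l]][alle]; v[is.na(v)] <- 0; unname(v)
    }))                            # populations x alleles
    colnames(m) <- alle
    pooled <- colSums(m) / sum(m)
    rare <- pooled < pool_threshold
    if (any(rare) && sum(!rare) >= 1) {
      m <- cbind(m[, !rare, drop = FALSE], pooled = rowSums(m[, rare,
                                                              drop = FALSE]))
    }
    m <- m[, colSums(m) > 0, drop = FALSE]
    if (ncol(m) < 2) NULL else m
  })
  tabs <- purrr::compact(tabs)
  if (!length(tabs)) abort("no informative loci after pooling")
  if (method == "chi2") {
    stat <- 0; df <- 0
    for (m in tabs) {
      e <- outer(rowSums(m), colSums(m)) / sum(m)
      stat <- stat + sum((m - e)^2 / e)
      df <- df + (nrow(m) - 1) * (ncol(m) - 1)
    }
    list(p_value = pchisq(stat, df, lower.tail = FALSE), statistic = stat,
         df = df, n_loci_used = length(tabs))
  } else {
    B <- mc_settings$batches * mc_settings$iterations
    ps <- vapply(tabs, function(m) {
      fisher.test(m, simulate.p.value = TRUE, B = B)$p.value
    }, numeric(1))
    stat <- -2 * sum(log(pmax(ps, 1e-300)))
    df <- 2 * length(ps)
    list(p_value = pchisq(stat, df, lower.tail = FALSE), statistic = stat,
         df = df, n_loci_used = length(tabs))
  }
}

#' Power curve for detecting drift-generated differentiation
#'
#' For each drift duration `t`, runs `n_reps` replicates of
#' drift -> HWE sampling -> homogeneity test and reports the proportion of
#' replicates significant at `alpha`.  At `t = 0` the same proportion is the
#' empirical type-I error rate.
#'
#' @param base_freqs List of per-locus frequency vectors.
#' @param t_values Drift durations to evaluate.
#' @param Ne Effective size (default 1000).
#' @param n_pops Populations per replicate (default 2).
#' @param sample_sizes Diploid sample size per population (default 50).
#' @param n_reps Replicates per condition (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param tests Character subset of `c("chi2", "fisher")`.
#' @param mc_settings Fisher Monte-Carlo settings, see [homogeneity_test()].
#' @param seed Optional RNG seed.
#' @return Object of class `msat_power`: tibble `t_gen`, `expected_fst`,
#'   `test`, `power`, `n_reps`.
#' @export
power_curve <- function(base_freqs, t_values, Ne = 1000, n_pops = 2,
                        sample_sizes = 50, n_reps = 1000, alpha = 0.05,
                        tests = "chi2",
                        mc_settings = list(dememorization = 1000,
                                           batches = 100, iterations = 1000),
                        seed = NULL) {
  set_seed_if(seed)
  sample_sizes <- rep_len(sample_sizes, n_pops)
  empty <- tibble(t_gen = double(), expected_fst = double(),
                  test = character(), power = double(), n_reps = integer())
  if (n_reps == 0 || !length(t_values)) {
    class(empty) <- c("msat_power", class(empty))
    return(empty)
  }
  rows <- list()
  for (t_gen in t_values) {
    sig <- setNames(numeric(length(tests)), tests)
    for (rep_i in seq_len(n_reps)) {
      pops <- drift_sample(base_freqs, Ne, t_gen, n_pops)
      counts <- purrr::map2(pops, sample_sizes, sample_allele_counts)
      for (te in tests) {
        p <- homogeneity_test(counts, method = te,
                              mc_settings = mc_settings)$p_value
        if (p < alpha) sig[te] <- sig[te] + 1
      }
    }
    for (te in tests) {
      rows[[length(rows) + 1L]] <- tibble(
        t_gen = t_gen, expected_fst = expected_fst(Ne, t_gen), test = te,
        power = if (n_reps > 0) sig[[te]] / n_reps else NA_real_,
        n_reps = n_reps)
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("msat_power", class(out))
  out
}

#' @method autoplot msat_power
#' @export
autoplot.msat_power <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$expected_fst, y = .data$power, colour = .data$test)) +
    geom_line() + geom_point() +
    labs(x = expression(expected ~ F[ST]), y = "power") +
    theme_minimal()
}
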