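# ---- Weir & Cockerham variance components --------------------------------
#
# Per locus, per allele u, with r populations, n_i called individuals in
# population i, p_iu the sample allele frequency and h_iu the observed
# frequency of heterozygotes carrying u:
#   nbar = mean n_i,  nc = (r*nbar - sum n_i^2/(r*nbar)) / (r - 1)
#   pbar = sum n_i p_iu / (r nbar)
#   s2   = sum n_i (p_iu - pbar)^2 / ((r-1) nbar)
#   hbar = sum n_i h_iu / (r nbar)
#   a = nbar/nc * (s2 - (pbar(1-pbar) - (r-1)/r s2 - hbar/4) / (nbar-1))
#   b = nbar/(nbar-1) * (pbar(1-pbar) - (r-1)/r s2 - (2nbar-1)/(4nbar) hbar)
#   c = hbar/2
# theta = sum a / sum (a+b+c), summing over alleles (and loci for the
# multi-locus estimate).

# components for one locus; a1/a2 integer alleles of called individuals,
# pop their population labels. Returns c(a=, b=, c=) summed over alleles,
# or NULL when the locus is uninformative (monomorphic or < 2 pops).
wc_components_locus <- function(a1, a2, pop) {
  pop <- factor(pop)
  keep <- !is.na(a1)
  a1 <- a1[keep]; a2 <- a2[keep]; pop <- droplevels(pop[keep])
  r <- nlevels(pop)
  if (r < 2) return(NULL)
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2) return(NULL)
  n_i <- as.vector(table(pop))
  if (any(n_i == 0)) return(NULL)
  nbar <- mean(n_i)
  if (nbar <= 1) return(NULL)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  # dosage matrix individuals x alleles and heterozygote-carrier matrix
  dos <- vapply(alleles, function(u) (a1 == u) + (a2 == u),
                numeric(length(a1)))
  het <- vapply(alleles, function(u) as.numeric((a1 == u) != (a2 == u)),
                numeric(length(a1)))
  p_iu <- rowsum(dos, pop) / (2 * n_i)       # r x k
  h_iu <- rowsum(het, pop) / n_i
  pbar <- colSums(n_i * p_iu) / (r * nbar)
  s2 <- colSums(n_i * sweep(p_iu, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h_iu) / (r * nbar)
  a_u <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b_u <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_u <- hbar / 2
  c(a = sum(a_u), b = sum(b_u), c = sum(c_u))
}

# split called genotypes into fast per-locus vectors
locus_split <- function(calls) {
  cc <- calls[calls$status == "called", ]
  split(cc[, c("individual", "allele_a", "allele_b", "population")],
        cc$locus)
}

#' Weir-Cockerham FST (theta)
#'
#' Multi-locus and per-locus theta from the 1984 variance-components
#' estimator, computed from genotype counts (observed heterozygote
#' frequencies enter the components, so departures from HWE are handled).
#' The multi-locus estimate is the ratio of sums,
#' `theta = sum_loci a / sum_loci (a+b+c)`; loci that are monomorphic across
#' the included populations contribute nothing.  Negative estimates are
#' reported as computed.
#'
#' @param calls Genotype call tibble.
#' @param populations Optional subset of population labels (default: all).
#' @param loci Optional subset of loci.
#' @return An object of class `msat_fst`: list with `estimate`, `per_locus`
#'   (tibble `locus`, `a`, `b`, `c`, `theta`), `populations`, `n_ind`.
#' @export
wc_fst <- function(calls, populations = NULL, loci = NULL) {
  check_calls(calls)
  cc <- calls
  if (!is.null(populations)) cc <- cc[cc$population %in% populations, ]
  if (!is.null(loci)) cc <- cc[cc$locus %in% loci, ]
  comps <- purrr::compact(purrr::map(
    locus_split(cc),
    ~ wc_components_locus(.x$allele_a, .x$allele_b, .x$population)))
  if (!length(comps)) {
    abort("FST undefined: all loci monomorphic across the included populations")
  }
  per_locus <- tibble(
    locus = names(comps),
    a = unname(map_dbl(comps, "a")), b = unname(map_dbl(comps, "b")),
    c = unname(map_dbl(comps, "c"))
  ) %>% mutate(theta = .data$a / (.data$a + .data$b + .data$c))
  structure(list(
    estimate = sum(per_locus$a) / sum(per_locus$a + per_locus$b + per_locus$c),
    per_locus = per_locus,
    populations = sort(unique(cc$population)),
    n_ind = length(unique(cc$individual)),
    ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_
  ), class = "msat_fst")
}

#' @export
print.msat_fst <- function(x, ...) {
  cat(sprintf("<msat_fst> theta = %.4f over %d loci, %d populations\n",
              x$estimate, nrow(x$per_locus), length(x$populations)))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  95%% locus-bootstrap CI: %.4f - %.4f\n", x$ci_low, x$ci_high))
  }
  if (!is.na(x$p_value)) cat(sprintf("  permutation p = %.4g\n", x$p_value))
  invisible(x)
}

#' @method tidy msat_fst
#' @export
tidy.msat_fst <- function(x, ...) x$per_locus

#' @method glance msat_fst
#' @export
glance.msat_fst <- function(x, ...) {
  tibble(estimate = x$estimate, n_loci = nrow(x$per_locus),
         n_populations = length(x$populations), n_ind = x$n_ind,
         ci_low = x$ci_low, ci_high = x$ci_high, p_value = x$p_value)
}

#' Permutation test for pairwise FST
#'
#' Shuffles individuals between two population samples (sample sizes fixed),
#' recomputing the pairwise multi-locus theta each time.
#' `p = (#{theta_perm >= theta_obs} + 1) / (n_perm + 1)`.
#'
#' @param calls Genotype call tibble.
#' @param group_a,group_b Population labels.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional RNG seed.
#' @return List `theta`, `p_value`, `n_perm`.
#' @export
fst_permutation_test <- function(calls, group_a, group_b, n_perm = 10000,
                                 seed = NULL) {
  set_seed_if(seed)
  cc <- calls[calls$population %in% c(group_a, group_b), ]
  inds <- unique(cc$individual)
  popv <- cc$population[match(inds, cc$individual)]
  if (min(table(popv)) < 2) abort("permutation test needs >= 2 individuals per group")
  per_locus <- locus_split(cc)
  # per locus: indices into `inds` so a permuted label vector can be applied
  idx <- purrr::map(per_locus, ~ match(.x$individual, inds))
  theta_of <- function(labels) {
    comps <- purrr::compact(purrr::map2(
      per_locus, idx,
      ~ wc_components_locus(.x$allele_a, .x$allele_b, labels[.y])))
    if (!length(comps)) return(NA_real_)
    m <- vapply(comps, identity, numeric(3))
    sum(m["a", ]) / sum(m)
  }
  theta_obs <- theta_of(popv)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    th <- theta_of(sample(popv))
    if (!is.na(th) && th >= theta_obs - 1e-12) hits <- hits + 1L
  }
  list(theta = theta_obs, p_value = (hits + 1) / (n_perm + 1), n_perm = n_perm)
}

#' Locus-bootstrap confidence interval for multi-locus FST
#'
#' Resamples loci with replacement, recomputing the ratio-of-sums theta from
#' the per-locus variance components; percentile interval.  A single locus
#' yields a degenerate (zero-width) interval with a warning.
#'
#' @param fst An `msat_fst` from [wc_fst()].
#' @param n_boot Bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional RNG seed.
#' @return The `msat_fst` with `ci_low`/`ci_high` filled in and attribute
#'   `boot_thetas`.
#' @export
fst_bootstrap_ci <- function(fst, n_boot = 1000, level = 0.95, seed = NULL) {
  set_seed_if(seed)
  pl <- fst$per_locus
  L <- nrow(pl)
  if (L < 2) {
    warn("single locus: bootstrap interval is degenerate")
    fst$ci_low <- fst$ci_high <- fst$estimate
    return(fst)
  }
  boots <- vapply(seq_len(n_boot), function(i) {
    j <- sample.int(L, L, replace = TRUE)
    sum(pl$a[j]) / sum(pl$a[j] + pl$b[j] + pl$c[j])
  }, numeric(1))
  qs <- quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                 na.rm = TRUE, names = FALSE)
  fst$ci_low <- qs[1]; fst$ci_high <- qs[2]
  attr(fst, "boot_thetas") <- boots
  fst
}

#' All pairwise multi-locus FST estimates
#'
#' Theta for every unordered pair of populations, optionally with
#' permutation p-values.
#'
#' @param calls Genotype call tibble.
#' @param n_perm Permutations per pair (0 = no test).
#' @param seed Optional RNG seed.
#' @return Tibble `pop_a`, `pop_b`, `theta`, `p_value`.
#' @export
pairwise_fst <- function(calls, n_perm = 0, seed = NULL) {
  set_seed_if(seed)
  pops <- sort(unique(calls$population))
  pairs <- utils::combn(pops, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    pa <- pairs[1, k]; pb <- pairs[2, k]
    th <- tryCatch(wc_fst(calls, populations = c(pa, pb))$estimate,
                   error = function(e) NA_real_)
    pv <- if (n_perm > 0 && !is.na(th)) {
      fst_permutation_test(calls, pa, pb, n_perm = n_perm)$p_value
    } else NA_real_
    tibble(pop_a = pa, pop_b = pb, theta = th, p_value = pv)
  })
}

#' Nei's DA genetic distance
#'
#' `DA = 1 - (1/L) sum_loci sum_alleles sqrt(x_u * y_u)` over the `L` loci
#' with data in both populations.
#'
#' @param freqs Allele frequency table from [allele_freqs()].
#' @param pop_a,pop_b Population labels.
#' @return Distance in `[0, 1]`.
#' @export
nei_da <- function(freqs, pop_a, pop_b) {
  fa <- freqs[freqs$population == pop_a, ]
  fb <- freqs[freqs$population == pop_b, ]
  shared <- intersect(unique(fa$locus), unique(fb$locus))
  if (!length(shared)) abort("no shared loci with data in both populations")
  per_locus <- vapply(shared, function(l) {
    xa <- fa[fa$locus == l, ]; xb <- fb[fb$locus == l, ]
    m <- merge(xa[, c("allele", "frequency")], xb[, c("allele", "frequency")],
               by = "allele")
    sum(sqrt(m$frequency.x * m$frequency.y))
  }, numeric(1))
  1 - mean(per_locus)
}

#' Nei's DA distance matrix
#'
#' Symmetric matrix of pairwise DA over all populations, optionally with
#' locus-bootstrap support (fraction of bootstrap replicates in which a
#' pair's distance exceeds zero is less interesting than the replicate
#' distances themselves, so the bootstrap mean matrix is attached).
#'
#' @param calls Genotype call tibble.
#' @param n_boot Locus-bootstrap replicates (0 = none).
#' @param seed Optional RNG seed.
#' @return Symmetric numeric matrix with zero diagonal; when bootstrapped,
#'   attribute `boot` holds an array of replicate matrices.
#' @export
nei_da_matrix <- function(calls, n_boot = 0, seed = NULL) {
  set_seed_if(seed)
  freqs <- allele_freqs(calls)
  pops <- sort(unique(freqs$population))
  da_of <- function(f) {
    m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
    for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
      m[i, j] <- m[j, i] <- nei_da(f, pops[i], pops[j])
    }
    m
  }
  out <- da_of(freqs)
  if (n_boot > 0) {
    loci <- unique(freqs$locus)
    boot <- array(NA_real_, c(length(pops), length(pops), n_boot))
    for (b in seq_len(n_boot)) {
      take <- sample(loci, length(loci), replace = TRUE)
      # resampled loci keep their identity by suffixing the draw index
      f <- purrr::map_dfr(seq_along(take), function(k) {
        fk <- freqs[freqs$locus == take[k], ]
        fk$locus <- paste0(fk$locus, "#", k)
        fk
      })
      boot[, , b] <- da_of(f)
    }
    attr(out, "boot") <- boot
  }
  out
}
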