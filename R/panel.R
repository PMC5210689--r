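#' Locus-saturation analysis of global FST precision
#'
#' For each panel size, draws `reps` random locus subsets (without
#' replacement within a subset), recomputes the global multi-locus theta on
#' each, and summarises mean and 95% confidence interval across the
#' replicates (`mean +/- t_{0.975, reps-1} * sd / sqrt(reps)`; a percentile
#' interval over the replicate estimates is available as an option).  Shows
#' how estimate precision saturates as loci are added.
#'
#' @param calls Genotype call tibble.
#' @param sizes Panel sizes to evaluate (default 5-40 in the standard
#'   steps).
#' @param reps Replicates per size (default 10).
#' @param ci `"t"` (default) or `"percentile"`.
#' @param seed Optional RNG seed.
#' @return Object of class `msat_saturation`: tibble `n_loci`, `mean`,
#'   `ci_low`, `ci_high`, `estimates` (list column of the replicate thetas).
#' @export
saturation_curve <- function(calls, sizes = c(5, 10, 15, 20, 25, 30, 32, 35, 40),
                             reps = 10, ci = c("t", "percentile"),
                             seed = NULL) {
  ci <- match.arg(ci)
  set_seed_if(seed)
  full <- wc_fst(calls)
  pl <- full$per_locus
  L <- nrow(pl)
  if (max(sizes) > L) {
    abort(sprintf("requested panel size %d exceeds the %d informative loci",
                  max(sizes), L))
  }
  out <- purrr::map_dfr(sizes, function(s) {
    est <- vapply(seq_len(reps), function(r) {
      j <- sample.int(L, s)        # without replacement within a replicate
      sum(pl$a[j]) / sum(pl$a[j] + pl$b[j] + pl$c[j])
    }, numeric(1))
    m <- mean(est)
    if (ci == "t") {
      half <- qt(0.975, reps - 1) * sd(est) / sqrt(reps)
      lo <- m - half; hi <- m + half
    } else {
      qs <- quantile(est, c(0.025, 0.975), names = FALSE)
      lo <- qs[1]; hi <- qs[2]
    }
    tibble(n_loci = s, mean = m, ci_low = lo, ci_high = hi,
           estimates = list(est))
  })
  attr(out, "full_theta") <- full$estimate
  class(out) <- c("msat_saturation", class(out))
  out
}

#' @method autoplot msat_saturation
#' @export
autoplot.msat_saturation <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$n_loci, y = .data$mean)) +
    geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                  width = 0.8, colour = "grey50") +
    geom_point() + geom_line(linetype = 3) +
    labs(x = "number of loci", y = expression(global ~ F[ST])) +
    theme_minimal()
}

#' Single-locus pairwise FST across temporal replicates
#'
#' Splits the samples into two collection periods, computes the per-locus
#' pairwise theta independently within each period for every requested
#' population contrast, and reports the Spearman rank correlation of
#' per-locus theta between periods (temporal consistency: informative loci
#' should rank high in both periods).
#'
#' @param calls Genotype call tibble.  `population` labels here are the
#'   sample labels mapped by `temporal_split`.
#' @param contrasts List of 2-vectors of group names to contrast.
#' @param temporal_split Tibble mapping `population` (sample label) to
#'   `group` (the population contrasted) and `period` (1 or 2).
#' @return Object of class `msat_highgrade`: list with `per_locus` (tibble
#'   `contrast`, `locus`, `theta_p1`, `theta_p2`) and `consistency` (tibble
#'   `contrast`, `spearman_rho`, `n_loci`).
#' @export
single_locus_pairwise_fst <- function(calls, contrasts, temporal_split) {
  need <- c("population", "group", "period")
  if (!all(need %in% names(temporal_split))) {
    abort("temporal_split needs columns population, group, period")
  }
  cc <- calls %>%
    inner_join(temporal_split, by = "population",
               suffix = c("", ".split"))
  per <- purrr::map_dfr(contrasts, function(ct) {
    purrr::map_dfr(c(1, 2), function(pd) {
      sub <- cc[cc$period == pd & cc$group %in% ct, ]
      if (!nrow(sub) || length(unique(sub$group)) < 2) {
        abort(sprintf("contrast %s has no data for period %d",
                      paste(ct, collapse = " vs "), pd))
      }
      sub$population <- sub$group   # contrast at the group level
      fst <- wc_fst(sub)
      fst$per_locus %>%
        mutate(contrast = paste(ct, collapse = " vs "), period = pd) %>%
        select("contrast", "period", "locus", "theta")
    })
  }) %>%
    pivot_wider(names_from = "period", values_from = "theta",
                names_prefix = "theta_p")
  consistency <- per %>% group_by(.data$contrast) %>%
    summarise(spearman_rho = suppressWarnings(
      cor(.data$theta_p1, .data$theta_p2, method = "spearman",
          use = "complete.obs")),
      n_loci = sum(!is.na(.data$theta_p1) & !is.na(.data$theta_p2)),
      .groups = "drop")
  structure(list(per_locus = per, consistency = consistency),
            class = "msat_highgrade")
}

#' @export
print.msat_highgrade <- function(x, ...) {
  cat("<msat_highgrade> temporal single-locus FST report\n")
  print(x$consistency)
  invisible(x)
}

#' @method tidy msat_highgrade
#' @export
tidy.msat_highgrade <- function(x, ...) x$per_locus

#' @method glance msat_highgrade
#' @export
glance.msat_highgrade <- function(x, ...) x$consistency

#' Select a high-graded locus panel
#'
#' Ranks loci by their differentiation in *both* periods and keeps the top
#' `k`.  The default rule ranks by `min(theta_p1, theta_p2)`, so a locus
#' must be informative in both periods — loci behaving stochastically in a
#' single period (temporally unstable false positives) are penalised.
#' `mean` and `rank_sum` rules are available.  Note the selected panel's
#' theta on the data used for selection is optimistically biased.
#'
#' @param report An `msat_highgrade`.
#' @param k Panel size.
#' @param rule `"min"` (default), `"mean"` or `"rank_sum"`.
#' @param contrast Which contrast to rank on (default: first).
#' @return Tibble of the selected loci with their ranking score, best first.
#' @export
highgrade_select <- function(report, k, rule = c("min", "mean", "rank_sum"),
                             contrast = NULL) {
  rule <- match.arg(rule)
  per <- report$per_locus
  contrast <- contrast %||% per$contrast[1]
  per <- per[per$contrast == contrast &
               !is.na(per$theta_p1) & !is.na(per$theta_p2), ]
  if (k > nrow(per)) {
    abort(sprintf("k = %d exceeds the %d loci with data in both periods",
                  k, nrow(per)))
  }
  if (k == 0) {
    warn("empty panel requested: panel theta undefined")
    return(per[0, c("locus", "theta_p1", "theta_p2")])
  }
  score <- switch(rule,
    min = pmin(per$theta_p1, per$theta_p2),
    mean = (per$theta_p1 + per$theta_p2) / 2,
    rank_sum = -(rank(-per$theta_p1) + rank(-per$theta_p2)))
  per$score <- score
  per <- per[order(-per$score), ]
  head(per[, c("locus", "theta_p1", "theta_p2", "score")], k)
}
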