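hist_of <- function(counts, individual = "i1", locus = "L1") {
  seqs <- unlist(purrr::imap(counts, function(n, len)
    rep(strrep("A", as.integer(len)), n)))
  build_histogram(seqs, individual, locus)
}

test_that("histograms tally trimmed lengths and preserve totals", {
  h <- hist_of(c(`150` = 30))
  expect_equal(h$length_bp, 150L)
  expect_equal(h$reads, 30L)
  expect_equal(attr(h, "total"), 30L)
  h0 <- build_histogram(character(), "i1", "L1")
  expect_equal(nrow(h0), 0L)
  expect_equal(attr(h0, "total"), 0L)
})

test_that("histogram rules reproduce hand-worked calls", {
  p <- caller_params()
  # clean homozygote
  c1 <- call_genotype(hist_of(c(`150` = 30)), 4, p)
  expect_equal(c(c1$allele_a, c1$allele_b), c(150L, 150L))
  expect_equal(c1$status, "called")
  # depth boundary: 9 reads is one short of the 10-read rule
  c2 <- call_genotype(hist_of(c(`150` = 9)), 4, p)
  expect_equal(c2$status, "low_depth")
  expect_true(is.na(c2$allele_a))
  c2b <- call_genotype(hist_of(c(`150` = 10)), 4, p)
  expect_equal(c2b$status, "called")
  # stutter one repeat unit below the major peak is removed (12 < 0.5 * 30)
  c3 <- call_genotype(hist_of(c(`162` = 30, `158` = 12)), 4, p)
  expect_equal(c(c3$allele_a, c3$allele_b), c(162L, 162L))
  # genuine heterozygote: both peaks strong, not stutter-spaced
  c4 <- call_genotype(hist_of(c(`150` = 20, `162` = 18)), 4, p)
  expect_equal(c(c4$allele_a, c4$allele_b), c(150L, 162L))
  # a stutter-spaced pair with a strong minor is a heterozygote
  c5 <- call_genotype(hist_of(c(`162` = 30, `158` = 20)), 4, p)
  expect_equal(c(c5$allele_a, c5$allele_b), c(158L, 162L))
  # weak second peak, not stutter-spaced: homozygote for the major
  c6 <- call_genotype(hist_of(c(`150` = 30, `160` = 9)), 4, p)
  expect_equal(c(c6$allele_a, c6$allele_b), c(150L, 150L))
  # three strong peaks: ambiguous
  c7 <- call_genotype(hist_of(c(`150` = 15, `160` = 15, `170` = 15)), 4, p)
  expect_equal(c7$status, "ambiguous")
  # empty bin
  c8 <- call_genotype(build_histogram(character()), 4, p)
  expect_equal(c8$status, "no_reads")
})

test_that("calling is deterministic for identical histograms", {
  h <- hist_of(c(`150` = 13, `154` = 13, `158` = 4))
  calls <- purrr::map_dfr(1:5, ~ call_genotype(h, 4))
  expect_equal(nrow(dplyr::distinct(calls)), 1L)
})

test_that("sequence verification flags isometric allele mixtures", {
  ok <- rep(strrep("C", 150), 30)
  call <- call_genotype(build_histogram(ok, "i", "L"), 4)
  v1 <- verify_by_sequence(ok, call)
  expect_true(all(v1$verified))
  # 50/50 mixture of two sequences of the same length
  alt <- strrep("C", 150)
  substr(alt, 10, 12) <- "TTT"
  mix <- c(rep(strrep("C", 150), 15), rep(alt, 15))
  v2 <- verify_by_sequence(mix, call_genotype(build_histogram(mix, "i", "L"), 4))
  expect_false(any(v2$verified))
  expect_equal(v2$modal_frac, 0.5)
})

test_that("injected isometric alleles are flagged exactly where planted", {
  cfg <- sim_config(n_pops = 1, n_individuals = 6, n_loci = 2,
                    depth_mean = 30, depth_dispersion = 0,
                    stutter_prob = 0, error_rate = 0, p_one_barcode = 0,
                    p_no_barcode = 0, p_nonmatching_primers = 0,
                    p_no_primer = 0, seed = 41)
  truth <- simulate_truth(cfg)
  target <- tibble::tibble(individual = "pop1_i002",
                           locus = truth$loci$locus[1])
  rr <- render_reads(truth, homoplasy = target)
  dmx <- demux_run(rr$pairs, rr$scheme)
  flags <- dmx$bins %>%
    dplyr::group_by(individual, locus) %>%
    dplyr::summarise(flagged = {
      cl <- call_genotype(build_histogram(trimmed, individual[1], locus[1]),
                          truth$loci$repeat_unit_bp[
                            match(locus[1], truth$loci$locus)])
      v <- verify_by_sequence(trimmed, cl)
      any(!v$verified)
    }, .groups = "drop")
  tg <- truth$genotypes
  hom_target <- tg$allele_a[tg$individual == "pop1_i002" &
                              tg$locus == target$locus] ==
    tg$allele_b[tg$individual == "pop1_i002" & tg$locus == target$locus]
  flagged <- flags[flags$flagged, ]
  if (hom_target) {
    # homozygote: both gene copies same length, copy-a variant splits it 50/50
    expect_equal(nrow(flagged), 1L)
    expect_equal(flagged$individual, "pop1_i002")
    expect_equal(flagged$locus, target$locus)
  } else {
    # heterozygote: the variant copy is still internally concordant
    expect_equal(nrow(flagged), 0L)
  }
})

test_that("assemble_matrix completes the grid and rejects duplicates", {
  sc <- toy_scheme(n_f = 2, n_r = 2, n_loci = 2, n_ind = 2)
  calls <- tibble::tibble(
    individual = c("ind1", "ind1", "ind2"),
    locus = c("LOC1", "LOC2", "LOC1"),
    allele_a = c(150L, 121L, 150L), allele_b = c(154L, 121L, 150L),
    status = "called", depth = c(20L, 30L, 25L))
  grid <- assemble_matrix(calls, sc)
  expect_equal(nrow(grid), 4L)
  missing_cell <- grid[grid$individual == "ind2" & grid$locus == "LOC2", ]
  expect_equal(missing_cell$status, "no_reads")
  expect_true(all(!is.na(grid$population)))
  expect_error(assemble_matrix(dplyr::bind_rows(calls, calls[1, ]), sc),
               "duplicate")
})

test_that("zero-noise simulated run is re-genotyped with full concordance", {
  cfg <- sim_config(n_pops = 2, n_individuals = 10, n_loci = 3,
                    depth_mean = 30, depth_dispersion = 0,
                    stutter_prob = 0, error_rate = 0, p_one_barcode = 0,
                    p_no_barcode = 0, p_nonmatching_primers = 0,
                    p_no_primer = 0, seed = 42)
  truth <- simulate_truth(cfg)
  rr <- render_reads(truth)
  dmx <- demux_run(rr$pairs, rr$scheme)
  grid <- assemble_matrix(call_genotypes(dmx, rr$scheme$loci), rr$scheme)
  called <- grid[grid$status == "called", ]
  m <- dplyr::inner_join(called, truth$genotypes,
                         by = c("individual", "locus"),
                         suffix = c("", ".true"))
  expect_equal(nrow(m), nrow(called))
  expect_true(all(m$allele_a == m$allele_a.true))
  expect_true(all(m$allele_b == m$allele_b.true))
  # Poisson depth 20: essentially every bin is callable
  expect_gt(nrow(called) / nrow(truth$genotypes), 0.99)
})

test_that("concordance degrades gracefully as stutter rises", {
  conc <- vapply(c(0, 0.1, 0.3), function(st) {
    cfg <- sim_config(n_pops = 1, n_individuals = 15, n_loci = 3,
                      depth_mean = 30, depth_dispersion = 0,
                      stutter_prob = st, error_rate = 0, p_one_barcode = 0,
                      p_no_barcode = 0, p_nonmatching_primers = 0,
                      p_no_primer = 0, seed = 43)
    truth <- simulate_truth(cfg)
    rr <- render_reads(truth)
    grid <- assemble_matrix(
      call_genotypes(demux_run(rr$pairs, rr$scheme), rr$scheme$loci),
      rr$scheme)
    m <- dplyr::inner_join(grid, truth$genotypes,
                           by = c("individual", "locus"),
                           suffix = c("", ".true"))
    mean(m$status == "called" & m$allele_a == m$allele_a.true &
           m$allele_b == m$allele_b.true, na.rm = TRUE)
  }, numeric(1))
  expect_equal(conc[1], 1)
  expect_true(conc[2] >= conc[3])
})

test_that("stutter-aware calling recalls heterozygotes a naive caller drops", {
  # naive caller: modal length, heterozygote only when the second length
  # has a strict majority share of the remaining reads
  naive_call <- function(h) {
    if (attr(h, "total") < 10) return(c(NA, NA))
    o <- h[order(-h$reads), ]
    if (nrow(o) >= 2 && o$reads[2] >= 0.5 * o$reads[1]) {
      sort(c(o$length_bp[1], o$length_bp[2]))
    } else c(o$length_bp[1], o$length_bp[1])
  }
  cfg <- sim_config(n_pops = 2, n_individuals = 20, n_loci = 4,
                    depth_mean = 52, depth_dispersion = 0.5,
                    stutter_prob = 0.10, error_rate = 0.001,
                    p_one_barcode = 0, p_no_barcode = 0,
                    p_nonmatching_primers = 0, p_no_primer = 0, seed = 44)
  truth <- simulate_truth(cfg)
  rr <- render_reads(truth)
  dmx <- demux_run(rr$pairs, rr$scheme)
  unit <- setNames(truth$loci$repeat_unit_bp, truth$loci$locus)
  per_bin <- dmx$bins %>%
    dplyr::group_by(individual, locus) %>%
    dplyr::summarise(h = list(build_histogram(trimmed, individual[1],
                                              locus[1])), .groups = "drop")
  tg <- truth$genotypes
  hets <- tg[tg$allele_a != tg$allele_b, ]
  res <- dplyr::inner_join(per_bin, hets, by = c("individual", "locus"))
  hit_pkg <- hit_naive <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    h <- res$h[[i]]
    cl <- call_genotype(h, unit[[res$locus[i]]])
    hit_pkg[i] <- !is.na(cl$allele_a) && cl$allele_a == res$allele_a[i] &&
      cl$allele_b == res$allele_b[i]
    nv <- naive_call(h)
    hit_naive[i] <- !any(is.na(nv)) && nv[1] == res$allele_a[i] &&
      nv[2] == res$allele_b[i]
  }
  expect_gt(nrow(res), 20)
  expect_gte(mean(hit_pkg), mean(hit_naive))
})
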