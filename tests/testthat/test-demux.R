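test_that("edit_distance agrees with a brute-force DP oracle", {
  expect_equal(edit_distance("ACGT", "ACGT"), 0L)
  expect_equal(edit_distance("ACGT", "AGT"), 1L)
  set.seed(31)
  for (k in 1:40) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(3:15, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(3:15, 1), TRUE),
               collapse = "")
    expect_equal(edit_distance(a, b), dp_edit_distance(a, b))
  }
})

test_that("constructed pairs hit the expected sort categories", {
  sc <- toy_scheme(n_f = 3, n_r = 3, n_loci = 2, n_ind = 6)
  pp <- perfect_pair(sc, "ind2", "LOC1")
  hit <- classify_pair(pp$seq_1, pp$seq_2, sc)
  expect_equal(as.character(hit$category), "TWO_BC_MATCHING_PRIMERS")
  expect_equal(hit$individual, "ind2")
  expect_equal(hit$locus, "LOC1")
  expect_equal(hit$trimmed, pp$amplicon)
  expect_equal(nchar(hit$trimmed), 150L)

  # random sequences carry no recognisable barcode
  set.seed(32)
  rnd <- replicate(2, paste(sample(c("A", "C", "G", "T"), 250, TRUE),
                            collapse = ""))
  expect_equal(as.character(classify_pair(rnd[1], rnd[2], sc)$category),
               "NO_BARCODE")

  # one substituted barcode base at zero edit budget loses that side
  mut <- pp$seq_2
  substr(mut, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                               substr(mut, 3, 3))[1]
  expect_equal(as.character(classify_pair(pp$seq_1, mut, sc)$category),
               "ONE_BARCODE")

  # forward primer of LOC1 paired with reverse primer of LOC2
  asg <- sc$assignments[sc$assignments$individual == "ind2", ]
  fo <- sc$forward[sc$forward$id == asg$forward_id, ]
  ro <- sc$reverse[sc$reverse$id == asg$reverse_id, ]
  l1 <- sc$loci[1, ]; l2 <- sc$loci[2, ]
  chimera <- paste0(l1$fwd_primer, strrep("A", 110), revcomp(l2$rev_primer))
  top <- paste0(fo$barcode, fo$tail, chimera, revcomp(ro$tail),
                revcomp(ro$barcode))
  expect_equal(as.character(classify_pair(top, revcomp(top), sc)$category),
               "TWO_BC_NONMATCHING_PRIMERS")

  # two barcodes, primers unrecognisable
  blank <- paste0(fo$barcode, fo$tail, strrep("A", 150), revcomp(ro$tail),
                  revcomp(ro$barcode))
  expect_equal(as.character(classify_pair(blank, revcomp(blank), sc)$category),
               "TWO_BC_NO_PRIMER")
})

test_that("valid-but-unassigned barcode pairs never yield a genotype bin", {
  sc <- toy_scheme(n_f = 3, n_r = 3, n_loci = 2, n_ind = 4)
  # build a scheme-valid molecule from an unused combination: ind pattern is
  # row-major, so with 4 of 9 assigned, (F2, R3) is unused
  fo <- sc$forward[2, ]; ro <- sc$reverse[3, ]
  used <- paste(sc$assignments$forward_id, sc$assignments$reverse_id)
  expect_false(paste(fo$id, ro$id) %in% used)   # row-major layout leaves it free
  l1 <- sc$loci[1, ]
  amp <- paste0(l1$fwd_primer, strrep("A", 110), revcomp(l1$rev_primer))
  top <- paste0(fo$barcode, fo$tail, amp, revcomp(ro$tail),
                revcomp(ro$barcode))
  hit <- classify_pair(top, revcomp(top), sc)
  expect_equal(as.character(hit$category), "ONE_BARCODE")
  expect_true(hit$unassigned_pair)
  expect_true(is.na(hit$individual))
})

test_that("demux conserves totals, respects orientation and zero-noise truth", {
  cfg <- sim_config(n_pops = 2, n_individuals = 4, n_loci = 3,
                    depth_mean = 20, depth_dispersion = 0,
                    stutter_prob = 0, error_rate = 0, p_one_barcode = 0,
                    p_no_barcode = 0, p_nonmatching_primers = 0,
                    p_no_primer = 0, seed = 33)
  rr <- render_reads(simulate_truth(cfg))
  dmx <- demux_run(rr$pairs, rr$scheme)
  counts <- dmx$counts
  expect_equal(sum(counts), attr(counts, "total"))
  expect_equal(attr(counts, "total"), nrow(rr$pairs))
  # zero noise: every read matches and lands in its intended bin
  expect_equal(unname(counts[["TWO_BC_MATCHING_PRIMERS"]]), nrow(rr$pairs))
  joined <- dplyr::inner_join(dmx$reads, rr$truth_reads, by = "read_id",
                              suffix = c("", ".true"))
  expect_equal(nrow(joined), nrow(rr$pairs))
  expect_equal(joined$individual, joined$individual.true)
  expect_equal(joined$locus, joined$locus.true)
  expect_equal(nchar(joined$trimmed), joined$emitted_len)
  # orientation symmetry: swapping every mate changes nothing
  swapped <- rr$pairs
  names(swapped)[2:5] <- c("seq_2", "qual_2", "seq_1", "qual_1")
  dmx2 <- demux_run(swapped, rr$scheme)
  expect_equal(as.integer(dmx2$counts), as.integer(counts))
  expect_equal(dplyr::arrange(dmx2$bins, individual, locus, trimmed),
               dplyr::arrange(dmx$bins, individual, locus, trimmed))
})

test_that("empty input demultiplexes to empty bins with total zero", {
  sc <- toy_scheme()
  dmx <- demux_run(tibble::tibble(read_id = character(),
                                  seq_1 = character(),
                                  seq_2 = character()), sc)
  expect_equal(attr(dmx$counts, "total"), 0L)
  expect_equal(nrow(dmx$bins), 0L)
})

test_that("raising the edit budget never loses matching-primer reads", {
  cfg <- sim_config(n_pops = 1, n_individuals = 6, n_loci = 2,
                    depth_mean = 15, depth_dispersion = 0,
                    stutter_prob = 0.05, error_rate = 0.01,
                    p_one_barcode = 0.2, p_no_barcode = 0.1,
                    p_nonmatching_primers = 0.01, p_no_primer = 0.01,
                    seed = 34)
  rr <- render_reads(simulate_truth(cfg))
  n_match <- function(b_bc, b_pr) {
    d <- demux_run(rr$pairs, rr$scheme, max_edit_barcode = b_bc,
                   max_edit_primer = b_pr)
    unname(d$counts[["TWO_BC_MATCHING_PRIMERS"]])
  }
  m00 <- n_match(0, 0); m10 <- n_match(1, 0); m11 <- n_match(1, 1)
  expect_gte(m10, m00)
  expect_gte(m11, m10)
})

test_that("category corruption rates are recovered within binomial error", {
  cfg <- sim_config(n_pops = 1, n_individuals = 12, n_loci = 4,
                    depth_mean = 40, depth_dispersion = 0.3,
                    stutter_prob = 0.1, error_rate = 0,
                    p_one_barcode = 0.54, p_no_barcode = 0.24,
                    p_nonmatching_primers = 0.011, p_no_primer = 0.003,
                    seed = 35)
  rr <- render_reads(simulate_truth(cfg))
  dmx <- demux_run(rr$pairs, rr$scheme)
  n <- attr(dmx$counts, "total")
  expect_gt(n, 1000)
  probs <- c(NO_BARCODE = 0.24, ONE_BARCODE = 0.54,
             TWO_BC_NO_PRIMER = 0.003,
             TWO_BC_NONMATCHING_PRIMERS = 0.011,
             TWO_BC_MATCHING_PRIMERS = 1 - 0.54 - 0.24 - 0.011 - 0.003)
  for (cat in names(probs)) {
    p <- probs[[cat]]
    tol <- 3 * sqrt(p * (1 - p) / n)
    expect_lt(abs(dmx$counts[[cat]] / n - p), tol + 1e-9)
  }
})
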