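test_that("complete fixation gives theta = 1 and duplication gives ~ 0", {
  fixed <- make_calls(list(pA = purrr::map(1:20, ~ c(150, 150)),
                           pB = purrr::map(1:20, ~ c(154, 154))))
  expect_equal(wc_fst(fixed)$estimate, 1)
  # one sample split in two at random: null differentiation
  set.seed(61)
  freqs <- purrr::map(1:8, ~ {
    x <- stats::rgamma(5, 1); setNames(x / sum(x), 150 + 4 * (0:4))
  })
  names(freqs) <- paste0("L", 1:8)
  half <- hwe_sample_calls(freqs, 200, "all")
  half$population <- rep(c("g1", "g2"), each = 100)[
    match(half$individual, unique(half$individual))]
  expect_lt(abs(wc_fst(half)$estimate), 0.02)
})

test_that("theta equals an independent per-allele component oracle", {
  # 3-individual, 2-population, 2-allele toy table
  toy <- make_calls(list(pA = list(c(150, 150), c(150, 154)),
                         pB = list(c(154, 154))))
  oracle <- wc_theta_oracle(list(data.frame(
    a1 = c(150, 150, 154), a2 = c(150, 154, 154),
    pop = c("pA", "pA", "pB"))))
  expect_equal(wc_fst(toy)$estimate, oracle, tolerance = 1e-12)
  # larger random multi-locus tables
  set.seed(62)
  for (k in 1:5) {
    freqs <- purrr::map(1:3, ~ {
      x <- stats::rgamma(4, 1); setNames(x / sum(x), c(120, 124, 128, 132))
    })
    names(freqs) <- paste0("L", 1:3)
    calls <- dplyr::bind_rows(hwe_sample_calls(freqs, 15, "pA"),
                              hwe_sample_calls(freqs, 11, "pB"),
                              hwe_sample_calls(freqs, 9, "pC"))
    gl <- purrr::map(split(calls, calls$locus), ~ data.frame(
      a1 = .x$allele_a, a2 = .x$allele_b, pop = .x$population))
    expect_equal(wc_fst(calls)$estimate, wc_theta_oracle(gl),
                 tolerance = 1e-12)
  }
})

test_that("monomorphic loci are skipped and all-monomorphic errors", {
  g <- make_calls(list(pA = purrr::map(1:5, ~ c(150, 150)),
                       pB = purrr::map(1:5, ~ c(150, 150))))
  expect_error(wc_fst(g), "monomorphic")
  g2 <- dplyr::bind_rows(g, make_calls(list(
    pA = purrr::map(1:5, ~ c(120, 124)),
    pB = purrr::map(1:5, ~ c(124, 124))), locus = "L2"))
  fst <- wc_fst(g2)
  expect_equal(fst$per_locus$locus, "L2")
})

test_that("permutation p-values hit the floor under fixed differences", {
  fixed <- make_calls(list(pA = purrr::map(1:20, ~ c(150, 150)),
                           pB = purrr::map(1:20, ~ c(154, 154))))
  res <- fst_permutation_test(fixed, "pA", "pB", n_perm = 199, seed = 63)
  expect_equal(res$p_value, 1 / 200)
  expect_equal(res$theta, 1)
})

test_that("permutation p-values are null-calibrated", {
  set.seed(64)
  n_data <- 120
  n_perm <- 99
  ps <- vapply(seq_len(n_data), function(i) {
    freqs <- purrr::map(1:4, ~ {
      x <- stats::rgamma(4, 1); setNames(x / sum(x), c(120, 124, 128, 132))
    })
    names(freqs) <- paste0("L", 1:4)
    calls <- hwe_sample_calls(freqs, 24, "all")
    calls$population <- rep(c("g1", "g2"), each = 12)[
      match(calls$individual, unique(calls$individual))]
    fst_permutation_test(calls, "g1", "g2", n_perm = n_perm)$p_value
  }, numeric(1))
  # super-uniformity at the 5% level within 3 s.d. Monte-Carlo error
  frac <- mean(ps <= 0.05)
  expect_lt(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / n_data))
  expect_gt(mean(ps > 0.5), 0.3)
})

test_that("locus bootstrap is deterministic under seed and degenerate cases", {
  set.seed(65)
  freqs <- purrr::map(1:6, ~ {
    x <- stats::rgamma(3, 1); setNames(x / sum(x), c(120, 124, 128))
  })
  names(freqs) <- paste0("L", 1:6)
  calls <- dplyr::bind_rows(hwe_sample_calls(freqs, 30, "pA"),
                            hwe_sample_calls(freqs, 30, "pB"))
  fst <- wc_fst(calls)
  b1 <- fst_bootstrap_ci(fst, n_boot = 300, seed = 99)
  b2 <- fst_bootstrap_ci(fst, n_boot = 300, seed = 99)
  expect_identical(c(b1$ci_low, b1$ci_high), c(b2$ci_low, b2$ci_high))
  expect_lte(b1$ci_low, fst$estimate)
  expect_gte(b1$ci_high, fst$estimate)
  # identical per-locus components: zero-width interval at theta
  fst_same <- fst
  fst_same$per_locus <- fst$per_locus[rep(1, 5), ]
  fst_same$estimate <- fst$per_locus$theta[1]
  b3 <- fst_bootstrap_ci(fst_same, n_boot = 50, seed = 1)
  expect_equal(b3$ci_low, b3$ci_high)
  expect_equal(b3$ci_low, fst_same$estimate)
  # single locus flagged degenerate
  fst1 <- fst
  fst1$per_locus <- fst$per_locus[1, ]
  expect_warning(fst_bootstrap_ci(fst1, n_boot = 10), "degenerate")
})

test_that("Nei's DA matches hand computation and distance axioms", {
  # one locus, x = (1, 0), y = (0.5, 0.5): DA = 1 - sqrt(0.5)
  g <- dplyr::bind_rows(
    make_calls(list(pA = purrr::map(1:10, ~ c(150, 150)))),
    make_calls(list(pB = c(purrr::map(1:5, ~ c(150, 150)),
                           purrr::map(1:5, ~ c(154, 154))))))
  # pB genotypes give x_150 = 0.5 exactly
  freqs <- allele_freqs(g)
  expect_equal(nei_da(freqs, "pA", "pB"), 1 - sqrt(0.5), tolerance = 1e-12)
  # identical tables -> 0; disjoint allele sets -> 1
  expect_equal(nei_da(freqs, "pA", "pA"), 0)
  disj <- dplyr::bind_rows(
    make_calls(list(pA = purrr::map(1:5, ~ c(150, 150)))),
    make_calls(list(pB = purrr::map(1:5, ~ c(154, 154)))))
  expect_equal(nei_da(allele_freqs(disj), "pA", "pB"), 1)
  # matrix symmetry, zero diagonal, [0, 1]
  set.seed(66)
  freqs2 <- purrr::map(1:4, ~ {
    x <- stats::rgamma(4, 1); setNames(x / sum(x), c(120, 124, 128, 132))
  })
  names(freqs2) <- paste0("L", 1:4)
  calls <- dplyr::bind_rows(hwe_sample_calls(freqs2, 15, "pA"),
                            hwe_sample_calls(freqs2, 15, "pB"),
                            hwe_sample_calls(freqs2, 15, "pC"))
  m <- nei_da_matrix(calls)
  expect_equal(m, t(m))
  expect_equal(diag(m), setNames(rep(0, 3), c("pA", "pB", "pC")))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("theta tracks the drift expectation on simulated frequencies", {
  set.seed(67)
  n_rep <- 10
  est <- vapply(seq_len(n_rep), function(i) {
    base <- make_base_freqs(40)
    pops <- drift_sample(base, Ne = 1000, t = 100, n_pops = 2)
    calls <- dplyr::bind_rows(
      purrr::imap_dfr(pops, function(f, k) {
        names(f) <- paste0("L", seq_along(f))
        hwe_sample_calls(purrr::map(f, ~ setNames(.x, 100 + 2 *
                                                    seq_along(.x))),
                         200, paste0("p", k))
      }))
    wc_fst(calls)$estimate
  }, numeric(1))
  expect_lt(abs(mean(est) - expected_fst(1000, 100)) / expected_fst(1000, 100),
            0.2)
})
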