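#' Simulation configuration
#'
#' Study conditions for the synthetic amplicon run.  The defaults emulate a
#' multi-population microsatellite amplicon experiment: mean read depth 52
#' per individual x locus with negative-binomial overdispersion, 10% PCR
#' stutter per read (one repeat unit short), 0.001 per-base substitution
#' error, and barcode/primer loss rates that land reads in the four
#' non-matching sort categories at the rates seen in real runs (54% one
#' barcode, 24% no barcode, 1.1% non-matching primers, 0.3% no primers).
#' Population structure is drift-based: each population drifts `t`
#' generations at effective size `Ne` from shared base frequencies.
#'
#' @param n_pops Number of populations.
#' @param n_individuals Diploid individuals per population.
#' @param n_loci Number of microsatellite loci.
#' @param Ne,t Drift parameters (effective size, generations).
#' @param depth_mean Mean *recovered* reads per individual x locus (default
#'   52): the renderer scales the raw per-bin depth up by the category-noise
#'   rate so that reads with two matching barcodes and primers average
#'   `depth_mean`.
#' @param depth_dispersion Negative-binomial dispersion; the per-bin depth
#'   has variance `mu + dispersion * mu^2` (default 0.5; 0 gives Poisson).
#' @param stutter_prob Per-read probability of -1 repeat unit stutter
#'   (default 0.10).
#' @param plus_stutter_prob Optional per-read probability of +1 repeat
#'   stutter (default 0, for robustness experiments).
#' @param error_rate Per-base substitution error rate (default 0.001).
#' @param p_one_barcode,p_no_barcode,p_nonmatching_primers,p_no_primer
#'   Category-corruption probabilities (defaults 0.54, 0.24, 0.011, 0.003;
#'   must sum to < 1, the remainder are clean reads).
#' @param depth_is_recovered When TRUE (default), `depth_mean` is the target
#'   for recovered reads and raw depth is scaled up accordingly; set FALSE
#'   to treat `depth_mean` as the raw rendered depth (useful for
#'   forced-category experiments).
#' @param k_range Alleles per locus drawn uniformly from this range
#'   (default 3-13).
#' @param seed RNG seed for the whole simulation.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_pops = 2, n_individuals = 50, n_loci = 6,
                       Ne = 1000, t = 100, depth_mean = 52,
                       depth_dispersion = 0.5, stutter_prob = 0.10,
                       plus_stutter_prob = 0, error_rate = 0.001,
                       p_one_barcode = 0.54, p_no_barcode = 0.24,
                       p_nonmatching_primers = 0.011, p_no_primer = 0.003,
                       depth_is_recovered = TRUE,
                       k_range = c(3, 13), seed = 1L) {
  cfg <- as.list(environment())
  p <- c(p_one_barcode, p_no_barcode, p_nonmatching_primers, p_no_primer)
  stopifnot(all(p >= 0), all(p <= 1), sum(p) < 1,
            stutter_prob >= 0, stutter_prob <= 1,
            error_rate >= 0, error_rate < 1,
            Ne >= 1, t >= 0, depth_mean > 0)
  structure(cfg, class = "sim_config")
}

# amplicon anatomy: [fwd primer 20][left flank 10][motif tract][right flank
# 10][rc(rev primer) 20]; trimmed length = 60 + unit * repeats
SIM_PRIMER_LEN <- 20L
SIM_FLANK_LEN <- 10L
SIM_CONST_LEN <- 2L * SIM_PRIMER_LEN + 2L * SIM_FLANK_LEN

# design n_loci synthetic loci with allele-length sets inside 120-180 bp
make_sim_loci <- function(n_loci, k_range = c(3, 13)) {
  repeat_units <- sample(2:4, n_loci, replace = TRUE)
  prim <- random_dna(2 * n_loci, SIM_PRIMER_LEN)
  while (anyDuplicated(prim)) prim <- random_dna(2 * n_loci, SIM_PRIMER_LEN)
  rows <- purrr::map(seq_len(n_loci), function(i) {
    unit <- repeat_units[i]
    k_max_feasible <- (180L - 120L) %/% unit + 1L
    k <- sample(seq(k_range[1], min(k_range[2], k_max_feasible)), 1)
    r_min <- ceiling((120L - SIM_CONST_LEN) / unit)
    r_max <- (180L - SIM_CONST_LEN) %/% unit - (k - 1L)
    r0 <- if (r_max > r_min) sample(r_min:r_max, 1) else r_min
    lens <- SIM_CONST_LEN + unit * (r0 + seq_len(k) - 1L)
    list(
      locus = sprintf("SIM%03d", i),
      fwd_primer = prim[2 * i - 1], rev_primer = prim[2 * i],
      repeat_unit_bp = unit,
      motif = random_dna(1, unit),
      left_flank = random_dna(1, SIM_FLANK_LEN),
      right_flank = random_dna(1, SIM_FLANK_LEN),
      allele_lengths = lens
    )
  })
  loci <- locus_table(
    id = map_chr(rows, "locus"),
    fwd_primer = map_chr(rows, "fwd_primer"),
    rev_primer = map_chr(rows, "rev_primer"),
    repeat_unit_bp = map_int(rows, "repeat_unit_bp"),
    min_bp = map_int(rows, ~ as.integer(min(.x$allele_lengths))),
    max_bp = map_int(rows, ~ as.integer(max(.x$allele_lengths))))
  loci$motif <- map_chr(rows, "motif")
  loci$left_flank <- map_chr(rows, "left_flank")
  loci$right_flank <- map_chr(rows, "right_flank")
  loci$allele_lengths <- purrr::map(rows, "allele_lengths")
  loci
}

# trimmed amplicon sequence for one locus at one allele length
sim_amplicon <- function(locus_row, length_bp, variant = FALSE) {
  unit <- locus_row$repeat_unit_bp
  reps <- (length_bp - SIM_CONST_LEN) / unit
  stopifnot(reps == round(reps), reps >= 1)
  rflank <- locus_row$right_flank
  if (variant) {
    # isometric sequence variant: 3 substitutions in the right flank
    ch <- strsplit(rflank, "")[[1]]
    ch[1:3] <- vapply(ch[1:3], function(x) setdiff(c("A", "C", "G", "T"),
                                                   x)[1], character(1))
    rflank <- paste(ch, collapse = "")
  }
  paste0(locus_row$fwd_primer, locus_row$left_flank,
         strrep(locus_row$motif, reps), rflank,
         revcomp(locus_row$rev_primer))
}

#' Simulate population-genetic truth
#'
#' Draws per-locus base allele frequencies (symmetric Dirichlet over the
#' locus's allele-length set), drifts each population independently
#' (`Ne`, `t`), and samples each diploid as two independent gene copies
#' (HWE).  All downstream modules treat the result as ground truth.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_truth`: `loci` (locus table with simulation
#'   attributes), `base_freqs`, `pop_freqs` (per population), `genotypes`
#'   (complete called genotype tibble).
#' @export
simulate_truth <- function(config) {
  set_seed_if(config$seed)
  loci <- make_sim_loci(config$n_loci, config$k_range)
  base_freqs <- purrr::map(loci$allele_lengths, function(lens) {
    x <- stats::rgamma(length(lens), 1)
    setNames(x / sum(x), as.character(lens))
  })
  names(base_freqs) <- loci$locus
  pop_freqs <- drift_sample(base_freqs, config$Ne, config$t, config$n_pops)
  names(pop_freqs) <- paste0("pop", seq_len(config$n_pops))
  genos <- purrr::imap_dfr(pop_freqs, function(freqs, pop) {
    if (config$n_individuals == 0) {
      return(tibble(individual = character(), locus = character(),
                    allele_a = integer(), allele_b = integer(),
                    status = character(), depth = integer(),
                    population = character()))
    }
    inds <- sprintf("%s_i%03d", pop, seq_len(config$n_individuals))
    purrr::imap_dfr(freqs, function(f, loc) {
      lens <- as.integer(names(f))
      a <- sample(lens, config$n_individuals, replace = TRUE, prob = f)
      b <- sample(lens, config$n_individuals, replace = TRUE, prob = f)
      tibble(individual = inds, locus = loc,
             allele_a = pmin(a, b), allele_b = pmax(a, b),
             status = "called", depth = NA_integer_, population = pop)
    })
  })
  structure(list(loci = loci, base_freqs = base_freqs,
                 pop_freqs = pop_freqs, genotypes = genos,
                 config = config),
            class = "sim_truth")
}

#' Render truth as barcoded paired reads
#'
#' Synthesises the full two-step-PCR molecule for every read —
#' `[barcode_F][M13-R tail][amplicon][rc(CAG tail)][rc(barcode_R)]` — then
#' applies, in order: per-read allele choice (50/50), stutter, category
#' corruption (truncating barcodes or primers so the read lands in a chosen
#' non-matching category), per-base substitution error on each mate
#' independently (mate 2 is the reverse complement), and a random mate
#' orientation swap.  Corruption happens after faithful synthesis, so the
#' truth table always records what each read was meant to be.
#'
#' @param truth A `sim_truth`.
#' @param scheme Optional `msat_scheme` covering all simulated individuals
#'   and loci; generated from random well-separated barcodes when omitted.
#' @param homoplasy Optional tibble (`individual`, `locus`): those
#'   individuals' first gene copy is rendered as an isometric sequence
#'   variant (same length, different sequence) at the given locus.
#' @return List of class `sim_reads`: `pairs` (FASTQ pair tibble),
#'   `truth_reads` (per-read truth table), `scheme`.
#' @export
render_reads <- function(truth, scheme = NULL, homoplasy = NULL) {
  config <- truth$config
  set_seed_if(derive_seed(config$seed, "render"))
  genos <- truth$genotypes
  if (is.null(scheme)) {
    n_ind <- length(unique(genos$individual))
    n_side <- max(2L, ceiling(sqrt(n_ind)))
    pops <- genos$population[match(unique(genos$individual),
                                   genos$individual)]
    scheme <- build_scheme(
      random_scheme_barcodes(n_side), random_scheme_barcodes(n_side),
      individuals = unique(genos$individual), loci = truth$loci,
      populations = setNames(pops, unique(genos$individual)))
  }
  loci <- truth$loci
  tails_f <- setNames(scheme$forward$tail, scheme$forward$id)
  tails_r <- setNames(scheme$reverse$tail, scheme$reverse$id)
  bc_f <- setNames(scheme$forward$barcode, scheme$forward$id)
  bc_r <- setNames(scheme$reverse$barcode, scheme$reverse$id)
  asg <- scheme$assignments

  # per-bin raw depths, scaled so the *recovered* (two matching barcodes and
  # primers) reads average depth_mean per individual x locus
  bins <- genos %>% select("individual", "locus", "allele_a", "allele_b")
  p_noise <- config$p_one_barcode + config$p_no_barcode +
    config$p_nonmatching_primers + config$p_no_primer
  mu <- if (isTRUE(config$depth_is_recovered)) {
    config$depth_mean / (1 - p_noise)
  } else {
    config$depth_mean
  }
  bins$depth <- if (config$depth_dispersion > 0) {
    rnbinom(nrow(bins), mu = mu, size = 1 / config$depth_dispersion)
  } else {
    stats::rpois(nrow(bins), mu)
  }
  reads <- bins[rep(seq_len(nrow(bins)), bins$depth), ]
  n <- nrow(reads)
  if (n == 0) {
    return(structure(list(
      pairs = tibble(read_id = character(), seq_1 = character(),
                     qual_1 = character(), seq_2 = character(),
                     qual_2 = character()),
      truth_reads = tibble(), scheme = scheme), class = "sim_reads"))
  }
  reads$read_id <- sprintf("sim%07d", seq_len(n))
  # both alleles amplify equally: balanced per-bin allele representation
  # (the odd read at odd depth falls on a random allele), so allelic
  # dropout in the rendered data comes from stutter/error, not from the
  # generator's own sampling
  copy_a <- unlist(lapply(bins$depth, function(d) {
    if (d == 0) return(logical(0))
    sample(rep_len(sample(c(TRUE, FALSE)), d))
  }))
  reads$true_len <- ifelse(copy_a, reads$allele_a, reads$allele_b)
  unit <- setNames(loci$repeat_unit_bp, loci$locus)[reads$locus]
  st_minus <- runif(n) < config$stutter_prob
  st_plus <- !st_minus & runif(n) < config$plus_stutter_prob
  reads$emitted_len <- as.integer(unname(
    reads$true_len - st_minus * unit + st_plus * unit))
  reads$stutter <- st_minus | st_plus

  u <- runif(n)
  p <- cumsum(c(config$p_one_barcode, config$p_no_barcode,
                config$p_nonmatching_primers, config$p_no_primer))
  reads$intended_category <- c(
    "ONE_BARCODE", "NO_BARCODE", "TWO_BC_NONMATCHING_PRIMERS",
    "TWO_BC_NO_PRIMER", "TWO_BC_MATCHING_PRIMERS")[findInterval(u, p) + 1L]

  variant <- rep(FALSE, n)
  if (!is.null(homoplasy) && nrow(homoplasy)) {
    key <- paste(reads$individual, reads$locus)
    variant <- key %in% paste(homoplasy$individual, homoplasy$locus) & copy_a
  }

  # amplicon per (locus, length, variant), memoised
  amp_cache <- new.env(parent = emptyenv())
  amp_of <- function(loc, len, var) {
    k <- paste0(loc, ":", len, ":", var)
    if (is.null(amp_cache[[k]])) {
      amp_cache[[k]] <- sim_amplicon(
        as.list(loci[loci$locus == loc, ]), len, var)
    }
    amp_cache[[k]]
  }
  amplicon <- vapply(seq_len(n), function(i) {
    amp_of(reads$locus[i], reads$emitted_len[i], variant[i])
  }, character(1))

  ai <- match(reads$individual, asg$individual)
  f_id <- asg$forward_id[ai]; r_id <- asg$reverse_id[ai]
  bcf <- unname(bc_f[f_id]); bcr <- unname(bc_r[r_id])
  tf <- unname(tails_f[f_id]); tr <- unname(tails_r[r_id])

  cat_v <- reads$intended_category
  # category corruption: randomised segments can no longer match
  kill <- function(x, which_kill) ifelse(which_kill,
                                         random_dna(length(x), nchar(x)), x)
  one_side <- runif(n) < 0.5
  bcf <- kill(bcf, cat_v == "NO_BARCODE" |
                (cat_v == "ONE_BARCODE" & one_side))
  bcr <- kill(bcr, cat_v == "NO_BARCODE" |
                (cat_v == "ONE_BARCODE" & !one_side))
  np <- cat_v == "TWO_BC_NO_PRIMER"
  if (any(np)) {
    amplicon[np] <- paste0(
      random_dna(sum(np), SIM_PRIMER_LEN),
      substr(amplicon[np], SIM_PRIMER_LEN + 1L,
             nchar(amplicon[np]) - SIM_PRIMER_LEN),
      random_dna(sum(np), SIM_PRIMER_LEN))
  }
  nm <- cat_v == "TWO_BC_NONMATCHING_PRIMERS"
  if (any(nm)) {
    if (nrow(loci) >= 2) {
      li <- match(reads$locus[nm], loci$locus)
      other <- (li %% nrow(loci)) + 1L
      amplicon[nm] <- paste0(
        substr(amplicon[nm], 1L, nchar(amplicon[nm]) - SIM_PRIMER_LEN),
        revcomp(loci$rev_primer[other]))
    } else {
      # single-locus designs cannot produce a non-matching pair; those
      # reads fall to the no-primer corruption instead
      amplicon[nm] <- paste0(
        substr(amplicon[nm], 1L, nchar(amplicon[nm]) - SIM_PRIMER_LEN),
        random_dna(sum(nm), SIM_PRIMER_LEN))
      reads$intended_category[nm] <- "TWO_BC_NO_PRIMER"
    }
  }

  top <- paste0(bcf, tf, amplicon, revcomp(tr), revcomp(bcr))
  s1 <- add_substitution_errors(top, config$error_rate)
  s2 <- add_substitution_errors(revcomp(top), config$error_rate)
  swap <- runif(n) < 0.5
  pairs <- tibble(
    read_id = reads$read_id,
    seq_1 = ifelse(swap, s2, s1),
    qual_1 = strrep("I", nchar(ifelse(swap, s2, s1))),
    seq_2 = ifelse(swap, s1, s2),
    qual_2 = strrep("I", nchar(ifelse(swap, s1, s2))))
  truth_reads <- reads %>%
    select("read_id", "individual", "locus", "intended_category",
           "true_len", "emitted_len", "stutter")
  structure(list(pairs = pairs, truth_reads = truth_reads, scheme = scheme),
            class = "sim_reads")
}

# independent per-base substitution errors
add_substitution_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  len <- nchar(seqs)
  n_err <- rbinom(length(seqs), len, rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    pos <- sample.int(len[i], n_err[i])
    ch <- strsplit(seqs[i], "")[[1]]
    ch[pos] <- vapply(ch[pos], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Run the complete simulation
#'
#' [simulate_truth()] then [render_reads()], optionally writing the paired
#' FASTQ, the scheme config and the truth tables under `dir`.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @param ... Passed to [render_reads()].
#' @return List: `truth`, `reads` (a `sim_reads`), and written `paths` when
#'   `dir` is given.
#' @export
simulate_run <- function(config = sim_config(), dir = NULL, ...) {
  truth <- simulate_truth(config)
  reads <- render_reads(truth, ...)
  out <- list(truth = truth, reads = reads)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p1 <- file.path(dir, "sim_R1.fastq.gz")
    p2 <- file.path(dir, "sim_R2.fastq.gz")
    write_fastq_pairs(reads$pairs, p1, p2)
    write_scheme(reads$scheme, file.path(dir, "scheme.yaml"))
    utils::write.table(reads$truth_reads,
                       file.path(dir, "truth_reads.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth$genotypes,
                       file.path(dir, "truth_genotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$paths <- c(r1 = p1, r2 = p2,
                   scheme = file.path(dir, "scheme.yaml"))
  }
  out
}
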