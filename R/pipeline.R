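#' Run the full GBS pipeline on a simulated run
#'
#' Chains every stage: simulate truth, render barcoded reads, write and
#' re-read the paired FASTQ, demultiplex, call genotypes, assemble and
#' filter the genotype grid, and compute the statistics layer (allele
#' summaries, global FST with locus bootstrap, pairwise FST, Nei's DA).
#' Every stage derives its RNG stream from the one global seed, salted with
#' the stage name, so a stage re-run in isolation reproduces its pipeline
#' behaviour.  The effective configuration and seed are written to
#' `dir/manifest.yaml`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @param n_boot Locus-bootstrap replicates for the global FST (default
#'   200).
#' @param threshold Completeness threshold (default 0.75).
#' @return List with `truth`, `demux`, `calls`, `filtered`, `summary`,
#'   `fst`, `pairwise`, `da`, invisibly.
#' @export
run_pipeline <- function(config = sim_config(), dir = tempfile("msatgbs_run"),
                         n_boot = 200, threshold = 0.75) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_run(config, dir = dir)
  pairs <- read_fastq_pairs(file.path(dir, "sim_R1.fastq.gz"),
                            file.path(dir, "sim_R2.fastq.gz"))
  scheme <- load_scheme(file.path(dir, "scheme.yaml"))
  dmx <- demux_run(pairs, scheme)
  write_category_report(dmx$counts, file.path(dir, "category_counts.tsv"))
  calls <- call_genotypes(dmx, scheme$loci)
  grid <- assemble_matrix(calls, scheme)
  utils::write.table(grid, file.path(dir, "genotype_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  filt <- filter_completeness(grid, threshold = threshold)
  smry <- summarize_alleles(filt$calls)
  utils::write.table(smry, file.path(dir, "allele_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fst <- wc_fst(filt$calls)
  fst <- fst_bootstrap_ci(fst, n_boot = n_boot,
                          seed = derive_seed(config$seed, "bootstrap"))
  pw <- pairwise_fst(filt$calls)
  utils::write.table(pw, file.path(dir, "pairwise_fst.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  da <- nei_da_matrix(filt$calls)
  write_genepop(filt$calls, file.path(dir, "genotypes.genepop.txt"))
  yaml::write_yaml(list(
    seed = config$seed,
    config = unclass(config),
    stages = c("simulate", "demux", "call", "filter", "stats"),
    n_reads = nrow(pairs),
    n_individuals_retained = length(unique(filt$calls$individual)),
    n_loci_retained = length(unique(filt$calls$locus)),
    global_fst = fst$estimate,
    fst_ci = c(fst$ci_low, fst$ci_high)),
    file.path(dir, "manifest.yaml"))
  invisible(list(truth = sim$truth, demux = dmx, calls = grid,
                 filtered = filt, summary = smry, fst = fst, pairwise = pw,
                 da = da, dir = dir))
}

#' Command-line entry point
#'
#' Thin subcommand dispatcher over the package functions, used by the
#' `inst/cli/msatgbs` Rscript wrapper.  Subcommands: `simulate`, `demux`,
#' `call`, `filter`, `stats`, `power`, `saturate`, `highgrade`, `pipeline`.
#' All stochastic subcommands accept `--seed`.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit status (0 success, 1 stage failure, 2 usage error).
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- function(msg = NULL) {
    if (!is.null(msg)) message("error: ", msg)
    message("usage: msatgbs <simulate|demux|call|filter|stats|power|saturate|highgrade|pipeline> [--seed N] [--out DIR] ...")
    2L
  }
  if (!length(argv)) return(usage())
  cmd <- argv[1]; rest <- argv[-1]
  opt <- function(name, default = NULL) {
    i <- which(rest == paste0("--", name))
    if (!length(i)) return(default)
    if (i == length(rest)) return(NA)
    rest[i + 1]
  }
  seed <- as.integer(opt("seed", "1"))
  out <- opt("out", "msatgbs_out")
  tryCatch({
    switch(cmd,
      simulate = {
        simulate_run(sim_config(seed = seed), dir = out)
        message("simulated run written to ", out)
      },
      pipeline = {
        res <- run_pipeline(sim_config(seed = seed), dir = out)
        message(sprintf("pipeline complete: global FST %.4f (%s)",
                        res$fst$estimate, out))
      },
      demux = {
        r1 <- opt("r1"); r2 <- opt("r2"); sc <- opt("scheme")
        if (is.null(r1) || is.null(r2)) return(usage("demux needs --r1 and --r2"))
        if (is.null(sc)) return(usage("demux needs --scheme"))
        dmx <- demux_run(read_fastq_pairs(r1, r2), load_scheme(sc))
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_category_report(dmx$counts, file.path(out, "category_counts.tsv"))
        utils::write.table(dmx$reads, file.path(out, "read_assignments.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        message("demultiplexed ", nrow(dmx$reads), " pairs")
      },
      call = {
        asg <- opt("assignments"); sc <- opt("scheme")
        if (is.null(asg) || is.null(sc)) {
          return(usage("call needs --assignments and --scheme"))
        }
        scheme <- load_scheme(sc)
        reads <- utils::read.table(asg, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
        bins <- reads[reads$category == "TWO_BC_MATCHING_PRIMERS",
                      c("individual", "locus", "trimmed")]
        grid <- assemble_matrix(call_genotypes(tibble::as_tibble(bins),
                                               scheme$loci), scheme)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(grid, file.path(out, "genotype_calls.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        message("called ", sum(grid$status == "called"), " genotypes")
      },
      filter = {
        g <- opt("genotypes")
        if (is.null(g)) return(usage("filter needs --genotypes"))
        calls <- tibble::as_tibble(
          utils::read.table(g, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE))
        filt <- filter_completeness(calls,
                                    as.numeric(opt("threshold", "0.75")))
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(filt$calls, file.path(out, "genotypes_filtered.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        message(nrow(filt$removed_loci), " loci and ",
                nrow(filt$removed_individuals), " individuals removed")
      },
      stats = {
        g <- opt("genotypes")
        if (is.null(g)) return(usage("stats needs --genotypes"))
        calls <- tibble::as_tibble(
          utils::read.table(g, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE))
        fst <- fst_bootstrap_ci(wc_fst(calls), seed = seed)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(summarize_alleles(calls),
                           file.path(out, "allele_summary.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(pairwise_fst(calls),
                           file.path(out, "pairwise_fst.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        message(sprintf("global FST %.4f (%.4f-%.4f)", fst$estimate,
                        fst$ci_low, fst$ci_high))
      },
      power = {
        Ne <- as.integer(opt("Ne", "1000"))
        t_gen <- as.integer(opt("t", "100"))
        reps <- as.integer(opt("reps", "200"))
        base <- make_base_freqs(as.integer(opt("loci", "40")), seed = seed)
        tab <- power_curve(base, t_values = t_gen, Ne = Ne, n_reps = reps)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(tab, file.path(out, "power.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        print(as.data.frame(tab))
      },
      saturate = {
        g <- opt("genotypes")
        if (is.null(g)) return(usage("saturate needs --genotypes"))
        calls <- tibble::as_tibble(
          utils::read.table(g, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE))
        L <- length(unique(calls$locus))
        sizes <- sort(unique(pmin(c(5, 10, 15, 20, 25, 30, 32, 35, 40), L)))
        sat <- saturation_curve(calls, sizes = sizes, seed = seed)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(sat[, c("n_loci", "mean", "ci_low", "ci_high")],
                           file.path(out, "saturation.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        message("saturation curve over ", nrow(sat), " panel sizes")
      },
      highgrade = {
        g <- opt("genotypes"); sp <- opt("split")
        if (is.null(g) || is.null(sp)) {
          return(usage("highgrade needs --genotypes and --split"))
        }
        calls <- tibble::as_tibble(
          utils::read.table(g, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE))
        split_tbl <- tibble::as_tibble(
          utils::read.table(sp, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE))
        groups <- unique(split_tbl$group)
        rep <- single_locus_pairwise_fst(calls, list(groups[1:2]), split_tbl)
        panel <- highgrade_select(rep, as.integer(opt("k", "7")))
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(rep$per_locus, file.path(out, "highgrade.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeLines(panel$locus, file.path(out, "panel.txt"))
        message("selected panel: ", paste(panel$locus, collapse = ", "))
      },
      return(usage(paste("unknown subcommand:", cmd)))
    )
    0L
  }, error = function(e) {
    message(sprintf("stage '%s' failed: %s", cmd, conditionMessage(e)))
    1L
  })
}
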