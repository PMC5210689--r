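# msatgbs

Microsatellite genotyping by sequencing (GBS) with individual combinatorial
barcoding, plus the population-genetic analysis layer that typically follows
such an experiment.

## The problem

Microsatellites (short tandem repeats) remain a workhorse marker for
population assignment, stock identification and monitoring in non-model
organisms. Amplicon sequencing replaces capillary fragment sizing: each
individual's multiplexed PCR products are tagged with an ordered pair of
11-nt barcodes — one M13-R-tailed forward barcode and one CAG-tailed reverse
barcode — so that *n*<sub>F</sub> + *n*<sub>R</sub> oligos address
*n*<sub>F</sub> × *n*<sub>R</sub> individuals (e.g. 48 + 48 barcodes →
2304 combinations) on a single sequencing run. Reads are then sorted
hierarchically by barcode and locus-primer identity, and diploid genotypes
are called from per-individual, per-locus **read-length histograms**, with
PCR stutter (reads one repeat unit short of the template) the main artifact
to filter.

`msatgbs` implements the full path:

* **scheme** — build/validate combinatorial barcode schemes
  (`build_scheme()`, `validate_barcode_set()`, `load_scheme()`);
* **demux** — hierarchical five-category read sorting with Levenshtein
  matching (`demux_run()`): no barcode / one barcode / two barcodes no
  primers / two barcodes non-matching primers / two barcodes matching
  primers;
* **genotyping** — depth- and stutter-aware histogram calls with
  sequence-level verification (`call_genotype()`, `verify_by_sequence()`);
* **popstats** — 75% completeness filtering, exact HWE tests, sequential
  Bonferroni, observed/unbiased expected heterozygosity, rarefied allelic
  richness, Weir–Cockerham *F*<sub>ST</sub> with locus bootstrap and
  permutation tests, Nei's *D*<sub>A</sub>;
* **power** — POWSIM-style drift simulation: expected
  *F*<sub>ST</sub> = 1 − (1 − 1/(2*N*<sub>e</sub>))<sup>*t*</sup>, chi-square
  and Fisher allele-frequency homogeneity tests, power curves
  (`power_curve()`);
* **panel** — locus-saturation curves and temporal high-grading of marker
  panels (`saturation_curve()`, `highgrade_select()`);
* **simulator** — a first-class generator (`simulate_truth()`,
  `render_reads()`) that renders drift-structured multi-population truth as
  barcoded paired FASTQ with stutter, substitution error and barcode loss,
  with complete truth tables.

The core estimator is Weir & Cockerham's θ: per locus and allele the
variance components *a* (among populations), *b* (among individuals within
populations) and *c* (within individuals) are computed from genotype counts,
and the multi-locus estimate is the ratio of sums θ = Σ*a* / Σ(*a*+*b*+*c*).

## Worked example

Simulate a two-population amplicon run (24 individuals per population, 5
loci, 52× recovered depth, realistic barcode-loss rates), then demultiplex,
call, filter and estimate structure — the whole chain in one call:

```r
library(msatgbs)
cfg <- sim_config(n_pops = 2, n_individuals = 24, n_loci = 5, seed = 11)
run <- run_pipeline(cfg, dir = "demo_run", n_boot = 1000)

tidy(run$demux$counts)
#>   category                   reads percent
#> 1 NO_BARCODE                 14527    25.6
#> 2 ONE_BARCODE                30419    53.6
#> 3 TWO_BC_NO_PRIMER             606     1.1
#> 4 TWO_BC_NONMATCHING_PRIMERS   579     1
#> 5 TWO_BC_MATCHING_PRIMERS    10616    18.7

run$fst
#> <msat_fst> theta = 0.0421 over 5 loci, 2 populations
#>   95% locus-bootstrap CI: -0.0029 - 0.0984
```

The category percentages recover the configured corruption rates (54% one
barcode, 24% no barcode, ...; substitution errors demote a further ~2% of
clean reads). The two populations were drifted *t* = 100 generations at
*N*<sub>e</sub> = 1000, so the drift-expected *F*<sub>ST</sub> is
1 − (1 − 1/2000)<sup>100</sup> = 0.0488; the five-locus estimate 0.0421
carries it inside its locus-bootstrap interval. Per-locus components and
summaries are tibbles:

```r
head(tidy(run$fst), 3)
#>   locus         a        b     c    theta
#> 1 SIM001  0.124   -0.00541 0.795  0.136
#> 2 SIM002  0.00301  0.0591  0.651  0.00422
#> 3 SIM003 -0.00554  0.0633  0.409 -0.0119

head(summarize_alleles(run$filtered$calls), 2)
#>   locus  population n_called n_alleles size_min size_max    Ho    He
#> 1 SIM001 pop1             22         8      141      171 0.818 0.839
#> 2 SIM001 pop2             22         9      141      174 0.773 0.741
```

Negative per-locus θ values are reported as computed, as is conventional.
`autoplot()` methods draw length histograms, saturation curves and power
curves; a thin CLI (`inst/cli/msatgbs`) exposes `simulate`, `demux`, `call`,
`filter`, `stats`, `power`, `saturate`, `highgrade` and `pipeline`
subcommands.

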