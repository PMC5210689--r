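---
title: "Methods: amplicon microsatellite genotyping and its statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplicon microsatellite genotyping and its statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models and the choices behind
them: what each stage computes, which thresholds matter, what the built-in
simulator does and does not emulate, and where the design was genuinely
open.

## Amplicon anatomy and the barcoding scheme

A two-step PCR first amplifies each locus with tailed primers and then
anneals barcoded tails, so every sequenced molecule has the layout

```
[barcode_F (11 nt)][M13-R tail (18 nt)][fwd primer ... rev primer rc][CAG tail rc (16 nt)][barcode_R rc (11 nt)]
```

Read 1 and read 2 are the two strands; either mate may present either side,
so the demultiplexer tries both orientations. The forward side is defined by
the M13-R universal tail `GGAAACAGCTATGACCAT`, the reverse side by the CAG
tail `CAGTCGGGCGTCATCA` — sides are distinguished by tail, not by barcode
sequence, which is why a barcode may legitimately occur in both sets.
A scheme of $n_F$ forward and $n_R$ reverse barcodes addresses
$n_F \times n_R$ individuals; `build_scheme()` lays individuals on that grid
in row-major order. The within-set minimum pairwise Levenshtein distance is
checked advisorily (default 3) — sorting with a zero edit budget works for
any distinct barcodes, but separated sets tolerate sequencing error.

## Hierarchical read sorting

`demux_run()` classifies every mate pair into exactly one of five
categories, in this order: count identifiable barcode+tail prefixes on the
two mates (0 → `NO_BARCODE`, 1 → `ONE_BARCODE`); with both sides present,
look for locus primers immediately 3′ of each tail (none or one →
`TWO_BC_NO_PRIMER`; two primers from different loci →
`TWO_BC_NONMATCHING_PRIMERS`; same locus → `TWO_BC_MATCHING_PRIMERS`).
Matching is anchored at the read start — amplicons (120–180 bp plus tails
and barcodes) are fully spanned by MiSeq-length reads, so nothing floats —
and the default edit budget is zero for both barcodes and primers, with the
budgets exposed as `max_edit_barcode`/`max_edit_primer` (ties at a positive
budget are treated as no hit: ambiguity never guesses an individual).

Rules the five-category scheme leaves open, decided here: two same-side
prefixes (e.g. a forward-tailed barcode on both mates) are `ONE_BARCODE`; a
pair of valid barcodes whose combination is assigned to no individual is
demoted to `ONE_BARCODE` and tallied in a separate `unassigned_pair`
diagnostic, so unused combinations can never produce genotypes; exactly one
identifiable primer falls to `TWO_BC_NO_PRIMER`. Category counts always sum
to the number of input pairs, and this conservation is asserted on every
run.

The trimmed sequence spans forward primer through reverse-primer complement
— primers are retained so trimmed length equals the designed product length,
and barcodes/tails are removed. Quality strings are carried but never used:
sorting is purely identity-based.

## Genotype calling from read-length histograms

The expert practice this package automates scores a length histogram per
individual per locus. `call_genotype()` fixes that judgement as rules
(`caller_params()`):

| parameter | default | meaning |
|---|---|---|
| `min_reads` | 10 | minimum bin depth to attempt a call |
| `min_allele_frac` | 0.20 | minimum share of bin reads for a candidate peak |
| `stutter_ratio` | 0.5 | a peak one repeat unit below a retained peak is stutter when under half its height |
| `het_ratio` | 1/3 | minimum minor/major ratio to call a heterozygote |
| `max_secondary_frac` | 1/3 | a third strong peak at this share makes the bin ambiguous |

Only the 10-read depth rule is classical; the other values follow common
amplicon-microsatellite practice and are deliberately config-exposed so they
can be tuned against a validation set. Stutter is modelled at −1 repeat unit
only (the dominant PCR slippage product); +1 products are ordinary peaks.
Ties in peak support break toward the longer allele so identical histograms
always give identical calls. Degenerate inputs produce missing statuses
(`no_reads`, `low_depth`, `ambiguous`), never errors.

Allele identity is trimmed length in bp. `verify_by_sequence()` then checks,
per called length, that the modal sequence accounts for ≥ 2/3 of its reads;
failures flag length homoplasy (isometric alleles) but never change a call —
verification is advisory, exactly because length is the unit of analysis.

## The statistics layer

**Completeness.** `filter_completeness()` removes loci, then individuals,
below 75% genotyping success; the order is a config switch because removing
a failing locus can rescue a borderline individual (the two-pass outcome is
tested against a hand-computed example).

**Heterozygosity and richness.** Unbiased expected heterozygosity uses the
$2n/(2n-1)$ small-sample correction. Allelic richness is exact rarefaction:
$R_s = \sum_u [1 - \binom{N-N_u}{g}/\binom{N}{g}]$, validated against
exhaustive subset enumeration.

**HWE.** The exact test statistic is the conditional (Levene) probability of
the genotype array given allele counts; the null is sampled by re-pairing
the observed gene pool, with the $(+1)/(+1)$ Monte-Carlo correction.
Monomorphic samples return $p = 1$ by convention.

**FST.** θ follows the 1984 variance-components estimator computed from
genotype counts (observed heterozygote frequencies enter the components, so
HWE is not assumed). Multi-locus θ is the ratio of summed components;
monomorphic loci contribute nothing; negative estimates are reported as
computed. Uncertainty comes from two orthogonal resampling schemes: a locus
bootstrap (percentile interval over re-sampled per-locus components) and an
individual-permutation test for pairwise comparisons,
$p = (\#\{\theta^* \ge \theta\} + 1)/(B + 1)$. A toy-table oracle written as
literal per-allele loops pins the implementation to 1e-12.

**Nei's D<sub>A</sub>** is $1 - \frac{1}{L}\sum_l \sum_u \sqrt{x_u y_u}$
over loci with data in both populations.

**Multiple testing** uses the Holm step-down ("sequential Bonferroni"),
computed via `p.adjust(method = "holm")`; the tests verify the hand-applied
step-down thresholds and that Holm's rejection set contains plain
Bonferroni's.

## Power simulation

`power_curve()` follows the POWSIM recipe: drift two (configurably more)
populations $t$ generations at effective size $N_e$ by multinomial
resampling of $2N_e$ gene copies per locus per generation — so expected
differentiation is $1-(1-\frac{1}{2N_e})^t$ — sample $n$ diploids per
population under HWE, test allele-frequency homogeneity, and report the
significant fraction over replicates. At $t=0$ that fraction is the
empirical type-I error.

Two test routes are provided. The chi-square route sums per-locus Pearson
statistics and degrees of freedom over loci, pooling alleles whose pooled
frequency is below 0.02 (the pooling threshold is this package's stabiliser;
measured at the standard design the route is nominally sized, with empirical
α ≈ 0.05). The Fisher route runs a per-locus Monte-Carlo exact test with the
number of sampled tables equal to `batches × iterations` (defaults 100 ×
1000; a dememorization setting is accepted for interface compatibility but
has no analogue in independent table sampling) and combines loci by Fisher's
method. Base frequencies for self-contained designs draw 3–13 alleles per
locus with symmetric Dirichlet(1) weights — the allele-count range typical
of polymorphic microsatellite panels — and can be overridden from a
TSV frequency file.

## Panel evaluation

`saturation_curve()` quantifies how global-θ precision saturates with panel
size: for each size, random locus subsets (without replacement within a
subset, 10 replicates by default) and a mean ± $t_{0.975}$ interval across
replicates (a percentile option exists; with 10 replicates the t-interval is
the steadier summary). Because per-locus components are independent of the
subset, subsetting is exact, and at the full panel the interval collapses to
the full-set θ.

`single_locus_pairwise_fst()` supports temporal high-grading: per-locus
pairwise θ computed independently in two collection periods, with Spearman
rank correlation as the temporal-consistency summary. The default selection
rule ranks loci by `min(θ_period1, θ_period2)` — a locus must be informative
in *both* periods, penalising temporally unstable false positives; `mean`
and `rank_sum` rules are available. The selected panel's θ on the data used
to select it is optimistically biased, and the tests assert (and so
document) that optimism rather than hiding it.

## The simulator

`simulate_truth()` draws per-locus allele-length sets spaced by the repeat
unit inside the 120–180 bp design window, Dirichlet(1) base frequencies,
independent per-population drift ($N_e$, $t$), and HWE diploids.
`render_reads()` synthesises the full molecule per read and then corrupts:
−1-repeat stutter (default 10% of reads), per-base substitution error
(default 0.001), and category corruption at the rates a real run shows
(54% one barcode, 24% no barcode, 1.1% non-matching primers, 0.3% no
primers). Corruption happens after faithful synthesis, so the truth table
records what every read was meant to be — the oracle for the demux and
caller tests. Per-bin depth is negative binomial with mean 52 **recovered**
reads (variance $\mu + 0.5\mu^2$); raw depth is scaled up by the
category-noise total so the assigned reads hit that mean, matching how
per-bin coverage is quoted for real runs.

Two deliberate idealisations: (i) the two parental alleles of a bin are
represented in balanced proportions (odd read to a random allele) rather
than i.i.d. per read — amplification noise between alleles is not modelled,
which makes zero-noise truth recovery exact and pins allelic dropout on
stutter/error where the caller's rules act; (ii) no per-cycle quality decay,
chimeras or index hopping. Passing tests therefore demonstrate correctness
of the rules, not robustness to every artifact of real libraries.

## Numerical choices and problem sizes

All resampling operations take explicit seeds; the pipeline derives
per-stage seeds from one master seed salted with the stage name, so a stage
re-run in isolation reproduces its in-pipeline behaviour. Edit distances use
`utils::adist` (checked against a dynamic-programming oracle); rarefaction
uses `lchoose` ratios for numerical stability; the HWE statistic is computed
in log space.

The test-suite experiments run at desk scale chosen to make each property
sharp: drift-recovery at $n = 200$ diploids × 40 loci × 20 replicates;
bootstrap coverage at 100 replicate datasets × 1000 resamples; permutation
calibration at 200 datasets × 99 permutations; planted-panel recovery with
five fast-drifting loci ($N_e$ 100, $t$ 100) against ten near-static ones
($N_e$ 2000, $t$ 4) at 60 diploids per sample, where the signal is
unambiguous by design. The acceptance script's type-I-error experiment uses
the full 1000 replicates.

## Limitations

Length-based allele identity cannot separate isometric alleles (flagged,
not resolved); the caller is rule-based, not likelihood-based, and its
thresholds beyond the 10-read rule encode practice rather than theory;
multi-copy loci and polyploids are out of scope; the chi-square route
assumes enough genes per population that pooled-class expectations are
moderate (the 0.02 pooling threshold stabilises but does not guarantee
this for very small samples).
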