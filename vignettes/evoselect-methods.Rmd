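---
title: "Models and methods behind evoselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind evoselect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(evoselect)
```

`evoselect` re-implements, as tested and reusable code, the computational
skeleton of a directed-evolution experiment: a 59-codon stretch of the
*E. coli* *recA* gene (codons 79–137, 177 nt) is randomized by doped
degenerate-oligonucleotide synthesis, the plasmid library is pushed through
iterative conjugational selection with colony bottlenecks, and each cycle's
population is read out by paired-end amplicon deep sequencing. The package
covers the library design statistics, the coverage-confidence calculation,
the sequencing analysis pipeline, a synthetic-data simulator of the whole
selection, and the assay arithmetic used for the biochemical follow-up.

## The doped-library model

Degenerate synthesis spikes each coupling step with a small fraction of the
three incorrect nucleotides, so each position of the window substitutes
independently. We model the window as segments with constant per-position
substitution probability:

* default segments: 100 nt at p = 0.015 (doping ratio 98.5 : 0.5 : 0.5 :
  0.5) followed by 77 nt at p = 0.010 (99 : 0.33 : 0.33 : 0.33). Synthesis
  of doped oligos is practical only up to ~100 nt, which is why the window
  is split across two oligos; which oligo received which doping ratio and
  their exact lengths are not recorded, so this assignment is an assumption
  and both the segmentation and the probabilities are configurable.
* alternative bases are drawn uniformly from the three non-reference bases
  ("x% of each of the incorrect nucleotides" implies equality).

The number of substitutions per molecule is then a Poisson–binomial: the
convolution of one binomial per segment. `substitution_count_pmf()` computes
it by exact positionwise convolution and reports the wild-type / single /
double / triple / four-plus class fractions.

**Effective doping efficiency.** The nominal scheme predicts ~10% unmutated
molecules, while sequencing of the characterized library found >70% wild
type with 16.6% single mutants. Doping chemistry is known to
under-incorporate relative to nominal molar ratios, but the cause and size
of the discrepancy cannot be derived from first principles. We therefore
expose a single scalar that multiplies every per-position probability and
can be fitted to an observed wild-type fraction
(`fit_doping_efficiency(scheme, 0.70)` gives 0.157). The simulator uses the
fitted scheme so its libraries match the realized spectrum, not the nominal
one.

## Coverage confidence (coupon collector)

The window admits exactly 3 × 177 = 531 single-nucleotide substitutions
(`enumerate_single_substitutions()`). Whether a library of N single-mutant
clones plausibly contains *all* of them is the coupon-collector problem:
draws are uniform over 531 types and we ask for P(all types seen in N
draws).

* `simulate_completion_draws()` reproduces the original Monte Carlo
  ("pick numbers until the set is complete, one million trials"). It uses
  the exact stage decomposition — after k types are collected, the wait for
  a new type is geometric with success probability (m−k)/m, and the
  completion count is the sum of the m independent stage waits — which is
  distributed identically to literal drawing and vectorizes to 10^6 trials
  in tens of seconds. The literal process is kept as
  `simulate_completion_draws_naive()` and the two are compared in the
  tests.
* The empirical threshold takes the smallest n such that at least
  `level × n_trials` trials completed within n draws (strict "at least",
  matching the original counting rule).
* `exact_completion_cdf()` is the inclusion–exclusion sum
  P = Σ (−1)^k C(m,k) (1 − k/m)^n, with terms computed via `lchoose` and
  `log1p` in log space and accumulated by compensated (Kahan) summation in
  decreasing order of magnitude. When n is barely above m the true
  probability is smaller than the cancellation noise (the terms reach
  magnitudes of 10^5 and more while the result is ~10^−14); that regime is
  detected from the largest term magnitude, and the value is recomputed by
  an exact forward recursion over the number of collected types, which has
  no alternating signs and is stable down to double underflow.
* As an independent sanity check, the Gumbel asymptotic
  m ln m − m ln(−ln p) agrees with the exact thresholds to <0.5% at
  m = 531.

With m = 531 the exact 90% and 95% thresholds are 4,524 and 4,905 colonies,
and P(complete | 4,565 single-mutant colonies) = 0.907 — the basis for the
claim that a 27,500-colony library (16.6% single mutants) covers all single
substitutions with better than 90% confidence.

## The amplicon sequencing pipeline

The per-cycle readout mirrors the original analysis chain: merge mates →
quality-trim what fails to merge → concatenate those un-joined mates →
Smith–Waterman to the reference → nucleotide counts by position → translate
→ threshold → rank.

* **Merging** (`merge_read_pairs()`): best ungapped suffix–prefix overlap
  between the forward read and the reverse-complemented reverse read,
  choosing the overlap with the smallest mismatch fraction (ties to the
  longer overlap) and accepting it if length ≥ 6 and mismatch fraction
  ≤ 0.08. These two defaults emulate the behaviour of the overlap joiners
  commonly used for this step; they are dialect choices, not recorded
  parameters. Disagreements resolve toward the higher-quality base.
* **Trimming** (`quality_trim()`, Phred threshold 20): the read is
  truncated at its 5′-most base below threshold, keeping only the leading
  run of good bases. Un-merged mates are then joined as
  forward + revcomp(reverse).
* **Alignment** (`smith_waterman()`): affine-gap local alignment
  (Smith–Waterman–Gotoh) in compiled code, match +2, mismatch −3, gap open
  −5, gap extend −2 (configurable; no scoring was recorded for the original
  analysis). A gap of length L costs open + L·extend. Tie-breaking is
  deterministic: diagonal over query-consuming over reference-consuming
  moves, traceback from the rightmost maximal cell. Identical processed
  sequences are aligned once and weighted by their multiplicity (the
  unique-read counting the original analysis also used).
* **Calling** (`call_substitutions()`): substitutions only at aligned,
  non-gap, non-N window positions; everything else is *uncovered* rather
  than reference. Indels are not reported as variants (the selection
  concerns substitutions). Note that a true local aligner soft-clips a
  mismatch at the extreme end of a read; amplicon reads carry ~30 nt of
  non-mutagenized flank on both sides, so window positions are always
  internal in practice.
* **Classification** (`translate_genotype()`): standard genetic code;
  reads with no change or only synonymous changes are wild type at the
  protein level; otherwise the class counts changed residues. A read must
  cover ≥90% of the window to receive a genotype class (partial reads still
  feed the per-position counts).
* **Tabulation** (`tabulate_population()`): a read carrying k amino-acid
  changes counts toward all k labels, with each label's fraction split by
  the genotype context (single/double/triple) of its supporting reads. The
  detection threshold is strict: a label is reported iff its fraction
  exceeds 0.5%. The threshold is applied per amino-acid change (the
  original figures label amino-acid changes); per-genotype fractions are
  also computed.
* **Miscall background.** With per-base error rate e, sequencing errors
  alone put ~e/3 of the reads on every possible single-nucleotide route, so
  a label reachable by r routes is inflated by ~r·e/3 — at e = 0.003 that
  is 0.001–0.002 absolute, which matters for variants near 1%. The
  per-route rate is estimated from the data as the median over all 3L
  routes of the per-position alternative-base fraction
  (`estimate_miscall_rate()`; true variants occupy few routes, so the
  median is robust), and `tabulate_population()` can subtract each label's
  expected background (`fraction_corrected`, floored at 0). Raw fractions
  are always retained — they are what the original analysis reported.
* **Trajectories** (`enrichment_trajectories()`): one per label above
  threshold in any cycle, zeros where absent, a strict monotone-increase
  flag, and the first→last fold change.

## The selection simulator

No sequencing reads were deposited for the original experiment, so the
simulator is the package's test bed and defines the study conditions:

* the founding pool is 27,500 library molecules drawn from the fitted
  doping scheme;
* each conjugation cycle is a single multinomial draw of `bottleneck`
  colonies with probability ∝ frequency × fitness, so the expected
  post-cycle frequency is f·w / Σf·w. The default bottlenecks
  2000/10000/800/75/75/40 are the recorded per-cycle colony counts.
  Fitness enters once per cycle; there are no within-cycle growth dynamics
  — the simplest model consistent with the cycle narrative. A
  deterministic (infinite-population) mode reproduces the logistic closed
  form f_t = f₀wᵗ/(1−f₀+f₀wᵗ) exactly.
* the default enhanced-variant fitness is 2.8 ≈ 352.8/125.3, the ratio of
  an enhanced variant's transconjugant yield to wild type's;
* reads: 2 × 150 nt from an amplicon of the window plus 30-nt flanks,
  substitution-only i.i.d. errors at 0.003/base by default, constant
  quality at the Phred equivalent of the error rate. Selection and
  sequencing use separate seeds so read depth can change without
  perturbing the selection history.

What the simulator does **not** emulate: PCR amplification bias, duplicates
and chimeras; indel sequencing errors; position-dependent quality decline;
crossover-number stringency as anything other than a fitness scale;
within-cycle growth competition. Pipeline tests passing on simulated data
therefore demonstrate correct recovery under the stated error model, not
robustness to every artifact of real amplicon data.

**A note on monotone trajectories under severe bottlenecks.** With
bottlenecks of 75/75/40 colonies, neutral genotypes that survive drift to
cycle 6 at 1–5% produce 3-point estimated trajectories that strictly
increase with appreciable probability (roughly 1/6 each under exchangeable
noise, more for genuine drift risers), so among the ~20 persisting labels
one expects several monotone risers besides the advantaged variant. The
advantaged variant is reliably the riser with the largest fold change, but
*uniqueness* of monotonicity is a property of gentler regimes (bottlenecks
in the hundreds or more), and the test suite reflects that distinction.

## Assay arithmetic

All formulas carry their units in the function documentation:

* `nadh_slope_to_rate()`: rate (μM ATP/min) = |ΔA₃₈₀/min| / (1.21 mM⁻¹cm⁻¹
  × 1.0 cm) × 1000.
* `apparent_kcat()`: observed rate divided by available protomer binding
  sites, sites = min(protein, ssDNA/3) with 3 nt per RecA protomer — the
  min handles protein-limited and DNA-limited regimes.
* `percent_of_max()` reports to one decimal with round-half-even; raw
  values are available with `digits = NA`. Published ratios that were
  evidently computed from unrounded instrument values (e.g. a "27.6%"
  decline where the rounded inputs give 27.4%) are documented as such and
  not reconciled.
* `competition_fraction()` applies the plate counting rules — totals
  within 40–300 colonies and at least 20 colonies of each competitor —
  before averaging; exclusion is order-independent and idempotent.
* `survival_percent()` and `specific_fluorescence()` error on zero
  denominators, mirroring the suppression of early low-OD time points
  where ratios of near-zero readings are meaningless.

## Reference sequence

No *recA* coding sequence is printed in the original report and the
package fetches nothing, so it ships a **constructed stand-in**
(`inst/extdata/synthetic_recA_cds.fa`, loaded by `recA_reference()`): a
200-codon CDS whose 59-codon window encodes the residues the selection
names (V79, E86, C90, I93, H97, D100, I102, N113, …), so variant labels
such as V79L or E86G/C90G arise with their published identities; flanking
codons are arbitrary sense codons. Analyses of real data should substitute
the genuine sequence via `target_region()`.

## Problem sizes used by the test suite

Sizes were chosen as the smallest that leave comfortable statistical
margins: 10^6 Monte Carlo trials for the coverage thresholds (matching the
original count); 3 × 10^4 samples for the sampling goodness-of-fit; 10^4
replicates for the neutral-selection martingale; 500 random instances for
the alignment oracle; and the full study conditions (27,500 founders, six
cycles, 10^4 read pairs per sequenced cycle) for the end-to-end recovery
check.
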