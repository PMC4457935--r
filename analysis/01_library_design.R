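#!/usr/bin/env Rscript

# Library design statistics for the 59-codon doped-oligonucleotide library:
# the substitution-count spectrum under the nominal doping ratios, the
# effective-efficiency fit to the observed wild-type fraction, the 531
# possible single substitutions, and the coupon-collector coverage
# confidence for the realized library size.
#
# Writes results/library_design/. Monte Carlo here uses 1e5 trials as the
# fast check; scripts/acceptance.R runs the full 1e6.

suppressPackageStartupMessages(library(evoselect))
out_dir <- "results/library_design"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

reg <- recA_reference()
message("Target window: codons ", reg$codon_start, "-", reg$codon_end,
        " = CDS nt ", region_nt_span(reg)[["start_nt"]], "-",
        region_nt_span(reg)[["end_nt"]])

subs <- enumerate_single_substitutions(reg)
message(nrow(subs), " possible single substitutions")
write.table(subs, file.path(out_dir, "single_substitutions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# nominal doping: 100 nt at 1.5% + 77 nt at 1.0% per-position substitution
nominal <- doping_scheme()
spec_nom <- substitution_count_pmf(nominal, 8)
# effective efficiency fitted to the observed >70% wild-type plasmids
eff <- fit_doping_efficiency(nominal, 0.70)
fitted <- doping_scheme(efficiency = eff)
spec_fit <- substitution_count_pmf(fitted, 8)
message(sprintf("nominal WT fraction %.3f; fitted efficiency %.3f -> WT 0.70",
                spec_nom$class_fractions[["wild_type"]], eff))
spectra <- data.frame(
  k = 0:8,
  nominal = as.numeric(spec_nom$pmf),
  fitted = as.numeric(spec_fit$pmf))
write.table(spectra, file.path(out_dir, "substitution_spectrum.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

n_single <- single_mutant_colonies(27500, 0.166)
message("27,500 colonies x 16.6% single mutants = ", n_single)

thr <- data.frame(
  level = c(0.90, 0.95),
  exact = c(confidence_threshold(531, 0.90, "exact"),
            confidence_threshold(531, 0.95, "exact")),
  monte_carlo_1e5 = c(
    confidence_threshold(531, 0.90, "monte_carlo", n_trials = 1e5, seed = 7),
    confidence_threshold(531, 0.95, "monte_carlo", n_trials = 1e5, seed = 7)),
  gumbel = round(gumbel_threshold(531, c(0.90, 0.95)), 1))
print(thr)
write.table(thr, file.path(out_dir, "coverage_thresholds.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

rep <- coverage_report(531, n_single)
message(sprintf(
  "P(all 531 present | %d colonies) = %.4f -> meets 90%%: %s, 95%%: %s",
  n_single, rep$probability, rep$meets[["level_0.9"]],
  rep$meets[["level_0.95"]]))
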