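#!/usr/bin/env Rscript

# Amplicon deep-sequencing analysis of the simulated selection: merge the
# mates, align to the reference with Smith-Waterman, call substitutions,
# translate to protein-level genotypes, tabulate each cycle's population
# above the 0.5% detection threshold, and follow enrichment trajectories
# across cycles. Compares the recovered fractions with the simulator's
# ground truth.
#
# Reads results/simulation/ (run 02_simulate_selection.R first);
# writes results/enrichment/.

suppressPackageStartupMessages(library(evoselect))
in_dir <- "results/simulation"
out_dir <- "results/enrichment"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
if (!file.exists(file.path(in_dir, "cycle4_R1.fastq"))) {
  stop("run analysis/02_simulate_selection.R first")
}

reg <- recA_reference()
flank <- 30L
amp_start <- unname(region_nt_span(reg)[["start_nt"]]) - flank
amp_ref <- substr(reg$cds, amp_start,
                  unname(region_nt_span(reg)[["end_nt"]]) + flank)

tabs <- list()
for (cy in c("4", "5", "6")) {
  pairs <- read_fastq_pairs(file.path(in_dir, sprintf("cycle%s_R1.fastq", cy)),
                            file.path(in_dir, sprintf("cycle%s_R2.fastq", cy)))
  pr <- process_read_pairs(pairs, reg, reference = amp_ref,
                           ref_cds_start = amp_start)
  mr <- estimate_miscall_rate(pr$position_counts)
  tab <- tabulate_population(pr$records, cycle = as.integer(cy),
                             miscall_rate = mr, region = reg)
  tabs[[cy]] <- tab
  message(sprintf(
    "cycle %s: %d/%d pairs merged, %d classified, %d unique; miscall %.2e",
    cy, pr$n_merged, pr$n_pairs, pr$n_classified, pr$n_unique, mr))
  rep_tab <- tab$labels[tab$labels$reported, ]
  message("  changes above 0.5%: ",
          paste(utils::head(rep_tab$change, 8), collapse = ", "))
  write.table(tab$labels, file.path(out_dir, sprintf("cycle%s_labels.tsv", cy)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(pr$position_counts,
              file.path(out_dir, sprintf("cycle%s_position_counts.tsv", cy)),
              sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- read.delim(file.path(in_dir, sprintf("cycle%s_truth.tsv", cy)))
  cmp <- merge(truth, tab$labels[, c("change", "fraction",
                                     "fraction_corrected")],
               by = "change", all.x = TRUE, suffixes = c("_true", "_est"))
  cmp[is.na(cmp)] <- 0
  big <- cmp[cmp$fraction_true >= 0.01 & cmp$change != "WT", ]
  message(sprintf("  max |est - truth| over %d labels >= 1%%: %.4f",
                  nrow(big), max(abs(big$fraction_corrected -
                                       big$fraction_true))))
}

traj <- enrichment_trajectories(tabs)
s <- attr(traj, "summary")
s <- s[order(-s$fold_change), ]
write.table(traj, file.path(out_dir, "trajectories.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(s, file.path(out_dir, "trajectory_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("top risers by fold change:")
print(utils::head(s, 5), row.names = FALSE)
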