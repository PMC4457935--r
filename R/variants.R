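#' Call substitutions from a local alignment
#'
#' Walks the gapped alignment columns and reports nucleotide substitutions at
#' aligned, non-gap positions inside the target window. Positions of the
#' window that fall under a gap, carry an N, or lie outside the aligned span
#' are marked uncovered: they contribute neither a reference nor a variant
#' observation. Indels themselves are not reported as variants.
#'
#' @param aln A [smith_waterman()] alignment of a read against a reference
#'   sequence.
#' @param region The [target_region()] defining the window.
#' @param ref_cds_start CDS coordinate of the first base of the alignment
#'   reference (1 when the read was aligned to the full CDS; the amplicon
#'   start when aligned to an excised amplicon).
#' @return List: `substitutions` (data.frame `cds_pos`, `ref`, `alt`) and
#'   `covered` (logical vector over window positions, named by CDS position).
#' @export
call_substitutions <- function(aln, region, ref_cds_start = 1L) {
  sp <- region_nt_span(region)
  win_pos <- seq.int(sp[["start_nt"]], sp[["end_nt"]])
  covered <- stats::setNames(rep(FALSE, length(win_pos)), win_pos)
  subs <- data.frame(cds_pos = integer(), ref = character(), alt = character())
  if (is.na(aln$r_start) || nchar(aln$r_aln) == 0L) {
    return(list(substitutions = subs, covered = covered))
  }
  q <- strsplit(aln$q_aln, "")[[1]]
  r <- strsplit(aln$r_aln, "")[[1]]
  rpos <- ref_cds_start + aln$r_start - 1L + cumsum(r != "-") - 1L
  keep <- r != "-" & q != "-" & q != "N" &
    rpos >= sp[["start_nt"]] & rpos <= sp[["end_nt"]]
  covered[as.character(rpos[keep])] <- TRUE
  mism <- keep & q != r
  if (any(mism)) {
    subs <- data.frame(cds_pos = rpos[mism], ref = r[mism], alt = q[mism])
  }
  list(substitutions = subs, covered = covered)
}

#' Translate substitutions into a protein-level genotype
#'
#' Applies the substitutions to the window, translates with the standard
#' codon table, and names amino-acid changes one-letter style (e.g. "V79L",
#' stops as "*"). Reads with no substitution or only synonymous ones are
#' classed `wild_type_protein`; otherwise the class counts changed residues
#' (`single`, `double`, `triple`, `four_plus`).
#'
#' @param subs data.frame with `cds_pos`, `alt` (and optionally `ref`),
#'   positions inside the window.
#' @param region The [target_region()].
#' @return Object of class `genotype_record`: `nt_substitutions`,
#'   `aa_changes` (character, possibly empty), `class`, `label`
#'   (changes joined by "/", `"WT"` for wild-type protein).
#' @export
translate_genotype <- function(subs, region) {
  sp <- region_nt_span(region)
  if (nrow(subs) > 0 &&
      (any(subs$cds_pos < sp[["start_nt"]]) || any(subs$cds_pos > sp[["end_nt"]]))) {
    stop("substitution outside the target window")
  }
  aa_changes <- character()
  if (nrow(subs) > 0) {
    # translate only the codons touched by a substitution
    win <- region_sequence(region)
    off <- subs$cds_pos - sp[["start_nt"]]        # 0-based window offset
    codon_idx <- off %/% 3L                       # 0-based codon in window
    for (ci in sort(unique(codon_idx))) {
      ref_codon <- substr(win, 3L * ci + 1L, 3L * ci + 3L)
      mut <- strsplit(ref_codon, "")[[1]]
      here <- codon_idx == ci
      mut[off[here] - 3L * ci + 1L] <- subs$alt[here]
      aa_ref <- .codon_table[[ref_codon]]
      aa_mut <- .codon_table[[paste(mut, collapse = "")]]
      if (aa_ref != aa_mut) {
        aa_changes <- c(aa_changes,
                        paste0(aa_ref, region$codon_start + ci, aa_mut))
      }
    }
  }
  n <- length(aa_changes)
  cls <- switch(min(n, 4L) + 1L,
                "wild_type_protein", "single", "double", "triple", "four_plus")
  structure(
    list(nt_substitutions = subs, aa_changes = aa_changes, class = cls,
         label = if (n == 0L) "WT" else paste(aa_changes, collapse = "/")),
    class = "genotype_record"
  )
}

#' Process paired amplicon reads into per-read genotype calls
#'
#' The merge -> trim -> join -> align -> call -> translate pipeline applied
#' to a table of read pairs. Pairs that merge are aligned directly; pairs
#' that do not are 3'-quality-trimmed and concatenated (forward +
#' reverse-complemented reverse) before alignment. A read must cover at
#' least `min_window_coverage` of the window to receive a genotype class;
#' under-covered reads still contribute to per-position counts.
#'
#' @param pairs data.frame of read pairs (see [read_fastq_pairs()]).
#' @param region The [target_region()].
#' @param reference Alignment reference sequence (default the full CDS).
#' @param ref_cds_start CDS coordinate of `reference`'s first base.
#' @param min_overlap,max_mismatch_frac Merge parameters
#'   (see [merge_read_pairs()]).
#' @param q_trim Phred threshold for trimming unmerged mates.
#' @param min_window_coverage Minimum covered fraction of the window for
#'   genotype classification (default 0.9).
#' @param scoring Named list of Smith-Waterman parameters.
#' @return List: `records` (per classified read, a `genotype_record`;
#'   identical reads share one record), `n_pairs`, `n_merged`,
#'   `n_classified`, `n_unique` (distinct processed sequences, each aligned
#'   once), `position_counts` (per window position: covered reads,
#'   reference calls, alternative calls).
#' @export
process_read_pairs <- function(pairs, region, reference = region$cds,
                               ref_cds_start = 1L,
                               min_overlap = 6L, max_mismatch_frac = 0.08,
                               q_trim = 20L, min_window_coverage = 0.9,
                               scoring = list(match = 2, mismatch = -3,
                                              gap_open = -5, gap_extend = -2)) {
  sp <- region_nt_span(region)
  wlen <- sp[["length"]]
  pos_cov <- stats::setNames(integer(wlen), seq.int(sp[["start_nt"]], sp[["end_nt"]]))
  pos_alt <- numeric(wlen)
  n_merged <- 0L
  seqs <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    m <- merge_read_pairs(pairs$fwd_seq[i], pairs$fwd_qual[i],
                          pairs$rev_seq[i], pairs$rev_qual[i],
                          min_overlap, max_mismatch_frac)
    if (isTRUE(m$merged)) {
      n_merged <- n_merged + 1L
      seqs[i] <- m$sequence
    } else {
      tf <- quality_trim(pairs$fwd_seq[i], pairs$fwd_qual[i], q_trim)
      tr <- quality_trim(pairs$rev_seq[i], pairs$rev_qual[i], q_trim)
      j <- join_unmerged(tf$sequence, tf$qualities, tr$sequence, tr$qualities)
      seqs[i] <- j$sequence
    }
  }
  seqs <- seqs[nchar(seqs) > 0L]
  # align each distinct processed sequence once (unique-read counting)
  uniq <- unique(seqs)
  mult <- tabulate(match(seqs, uniq), nbins = length(uniq))
  u_rec <- vector("list", length(uniq))
  u_elig <- logical(length(uniq))
  bases <- c("A", "C", "G", "T")
  base_counts <- matrix(0, nrow = wlen, ncol = 4L, dimnames = list(NULL, bases))
  for (k in seq_along(uniq)) {
    aln <- smith_waterman(uniq[k], reference, scoring$match, scoring$mismatch,
                          scoring$gap_open, scoring$gap_extend)
    calls <- call_substitutions(aln, region, ref_cds_start)
    pos_cov <- pos_cov + calls$covered * mult[k]
    if (nrow(calls$substitutions) > 0) {
      j <- calls$substitutions$cds_pos - sp[["start_nt"]] + 1L
      pos_alt[j] <- pos_alt[j] + mult[k]
      base_counts[cbind(j, match(calls$substitutions$alt, bases))] <-
        base_counts[cbind(j, match(calls$substitutions$alt, bases))] + mult[k]
    }
    u_elig[k] <- mean(calls$covered) >= min_window_coverage
    if (u_elig[k]) u_rec[[k]] <- translate_genotype(calls$substitutions, region)
  }
  # reference-base column of the nucleotide-counts-by-position summary
  win <- strsplit(region_sequence(region), "")[[1]]
  ref_idx <- match(win, bases)
  base_counts[cbind(seq_len(wlen), ref_idx)] <- pos_cov - pos_alt
  records <- rep(u_rec[u_elig], times = mult[u_elig])
  pc <- data.frame(
    cds_pos = as.integer(names(pos_cov)),
    ref_base = win,
    covered = as.integer(pos_cov),
    ref = as.integer(pos_cov - pos_alt),
    alt = as.integer(pos_alt))
  pc <- cbind(pc, as.data.frame(base_counts))
  list(records = records,
       n_pairs = nrow(pairs), n_merged = n_merged,
       n_classified = length(records), n_unique = length(uniq),
       position_counts = pc)
}

#' Estimate the per-route miscall background
#'
#' Sequencing errors put a small, roughly uniform count on every one of the
#' 3L possible single-nucleotide substitution routes of the window, so a
#' label reachable by r single-nucleotide routes is inflated by about r
#' times the per-route miscall rate. True selected variants occupy only a
#' few routes, so the median per-route rate over all 3L routes is a robust
#' estimate of that background.
#'
#' @param position_counts The nucleotide-counts-by-position summary from
#'   [process_read_pairs()].
#' @return Median per-(position, alternative-base) miscall rate.
#' @export
estimate_miscall_rate <- function(position_counts) {
  bases <- c("A", "C", "G", "T")
  rates <- unlist(lapply(seq_len(nrow(position_counts)), function(i) {
    alts <- setdiff(bases, position_counts$ref_base[i])
    if (position_counts$covered[i] == 0) return(numeric())
    as.numeric(position_counts[i, alts]) / position_counts$covered[i]
  }))
  stats::median(rates)
}

#' Single-nucleotide routes to an amino-acid change
#'
#' Number of single-nucleotide substitutions of the reference codon that
#' produce the change (e.g. "I80L" from an ATA codon has 2: ATA>CTA and
#' ATA>TTA). Used to scale the miscall background per label.
#'
#' @param change Amino-acid change label like "V79L" (stop as "*").
#' @param region The [target_region()].
#' @return Integer route count.
#' @export
aa_change_routes <- function(change, region) {
  m <- regmatches(change, regexec("^([A-Z*])([0-9]+)([A-Z*])$", change))[[1]]
  if (length(m) != 4L) stop("cannot parse change label: ", change)
  codon_num <- as.integer(m[3])
  if (codon_num < region$codon_start || codon_num > region$codon_end) {
    stop("codon ", codon_num, " outside the window")
  }
  ci <- codon_num - region$codon_start
  codon <- substr(region_sequence(region), 3L * ci + 1L, 3L * ci + 3L)
  if (.codon_table[[codon]] != m[2]) {
    stop("label ", change, " does not match reference residue ",
         .codon_table[[codon]])
  }
  bases <- c("A", "C", "G", "T")
  n <- 0L
  for (p in 1:3) {
    for (b in setdiff(bases, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (.codon_table[[mut]] == m[4]) n <- n + 1L
    }
  }
  n
}

#' Tabulate a sequenced population
#'
#' Builds the per-cycle frequency table: fractions per genotype class and per
#' amino-acid-change label. A read carrying k amino-acid changes contributes
#' to all k labels, and each label's fraction is split by the genotype
#' context (single / double / triple / four_plus) of its supporting reads,
#' so stacked single/double/triple attributions can be reported. Labels at
#' or below the detection threshold are suppressed from the reported table
#' (`reported = FALSE`) but retained.
#'
#' @param records List of `genotype_record`s (one per classified read).
#' @param threshold Detection threshold on the population fraction; a label
#'   is reported iff its fraction is strictly greater (default 0.005, i.e.
#'   "more than 0.5%").
#' @param cycle Optional cycle label attached to the table.
#' @param miscall_rate Optional per-route miscall background (see
#'   [estimate_miscall_rate()]); with `region`, adds a `fraction_corrected`
#'   column subtracting each label's expected error background (floored
#'   at 0). Raw fractions are always kept.
#' @param region The [target_region()]; required with `miscall_rate`.
#' @return Object of class `population_table`: `cycle`, `n_reads`,
#'   `class_fractions`, `genotypes` (per full genotype label), `labels`
#'   (per amino-acid change, with context split and `reported` flag),
#'   `threshold`.
#' @export
tabulate_population <- function(records, threshold = 0.005, cycle = NA,
                                miscall_rate = NULL, region = NULL) {
  if (length(records) == 0L) stop("no classified reads")
  n <- length(records)
  classes <- vapply(records, function(r) r$class, "")
  class_fr <- vapply(c("wild_type_protein", "single", "double", "triple",
                       "four_plus"),
                     function(k) sum(classes == k) / n, numeric(1))
  geno_labels <- vapply(records, function(r) r$label, "")
  geno <- as.data.frame(table(label = geno_labels), stringsAsFactors = FALSE)
  names(geno)[2] <- "count"
  geno$fraction <- geno$count / n
  geno$reported <- geno$fraction > threshold
  geno <- geno[order(-geno$count), , drop = FALSE]
  rownames(geno) <- NULL
  pairs <- do.call(rbind, lapply(records, function(r) {
    if (length(r$aa_changes) == 0L) return(NULL)
    data.frame(change = r$aa_changes, context = r$class)
  }))
  if (is.null(pairs)) {
    labels <- data.frame(change = character(), count = integer(),
                         fraction = numeric(), single = numeric(),
                         double = numeric(), triple = numeric(),
                         four_plus = numeric(), reported = logical())
  } else {
    counts <- table(pairs$change)
    ctx <- table(pairs$change, factor(pairs$context,
                                      levels = c("single", "double", "triple",
                                                 "four_plus")))
    labels <- data.frame(
      change = names(counts),
      count = as.integer(counts),
      fraction = as.numeric(counts) / n,
      single = as.numeric(ctx[, "single"]) / n,
      double = as.numeric(ctx[, "double"]) / n,
      triple = as.numeric(ctx[, "triple"]) / n,
      four_plus = as.numeric(ctx[, "four_plus"]) / n,
      row.names = NULL
    )
    labels$reported <- labels$fraction > threshold
    labels <- labels[order(-labels$count), , drop = FALSE]
    rownames(labels) <- NULL
  }
  if (!is.null(miscall_rate) && nrow(labels) > 0L) {
    if (is.null(region)) stop("region is required with miscall_rate")
    routes <- vapply(labels$change, aa_change_routes, integer(1),
                     region = region)
    labels$fraction_corrected <- pmax(0, labels$fraction -
                                        routes * miscall_rate)
  }
  structure(list(cycle = cycle, n_reads = n, class_fractions = class_fr,
                 genotypes = geno, labels = labels, threshold = threshold),
            class = "population_table")
}

#' @export
print.population_table <- function(x, ...) {
  cat(sprintf("<population_table> cycle %s: %d reads, %.1f%% wild-type protein\n",
              as.character(x$cycle), x$n_reads,
              100 * x$class_fractions[["wild_type_protein"]]))
  rep_labels <- x$labels[x$labels$reported, , drop = FALSE]
  if (nrow(rep_labels)) {
    cat(sprintf("  %d change(s) above %.2g%%:\n", nrow(rep_labels),
                100 * x$threshold))
    print(utils::head(rep_labels[, c("change", "count", "fraction")], 10))
  }
  invisible(x)
}

#' Across-cycle enrichment trajectories
#'
#' One trajectory per amino-acid-change label that exceeds the detection
#' threshold in any cycle; cycles where a label is absent contribute
#' fraction 0. A trajectory is flagged monotone when its fraction strictly
#' increases at every step; the fold change is last/first (Inf when the
#' label was absent in the first cycle).
#'
#' @param tables List of [tabulate_population()] tables with strictly
#'   increasing `cycle` labels.
#' @return data.frame with one row per (label, cycle): `change`, `cycle`,
#'   `fraction`, plus per-label attributes joined on: `monotone`,
#'   `fold_change`. Also returned as attribute `summary`: one row per label.
#' @export
enrichment_trajectories <- function(tables) {
  if (length(tables) < 2L) stop("need at least 2 cycles")
  cycles <- vapply(tables, function(t) as.numeric(t$cycle), numeric(1))
  if (any(is.na(cycles)) || any(diff(cycles) <= 0)) {
    stop("cycle labels must be strictly increasing")
  }
  lab_sets <- lapply(tables, function(t) {
    t$labels[t$labels$reported, "change", drop = TRUE]
  })
  all_labels <- sort(unique(unlist(lab_sets)))
  long <- do.call(rbind, lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    fr <- stats::setNames(t$labels$fraction, t$labels$change)
    fraction <- ifelse(all_labels %in% names(fr), fr[all_labels], 0)
    data.frame(change = all_labels, cycle = cycles[i],
               fraction = as.vector(fraction), row.names = NULL)
  }))
  summ <- do.call(rbind, lapply(all_labels, function(lb) {
    fr <- long$fraction[long$change == lb]
    data.frame(change = lb,
               monotone = all(diff(fr) > 0),
               fold_change = if (fr[1] > 0) fr[length(fr)] / fr[1] else Inf,
               first = fr[1], last = fr[length(fr)])
  }))
  long <- merge(long, summ[, c("change", "monotone", "fold_change")],
                by = "change", sort = FALSE)
  attr(long, "summary") <- summ
  long
}

# standard genetic code, keyed by DNA codon
.codon_table <- local({
  tab <- as.list(Biostrings::GENETIC_CODE)
  tab
})
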