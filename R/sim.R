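#' Selection configuration
#'
#' Defaults mirror the motivating experiment: an initial pool of 27,500
#' library clones followed by six conjugational selection cycles whose
#' recovered-colony bottlenecks were approximately 2,000 / 10,000 / 800 /
#' 75 / 75 / 40.
#'
#' @param bottlenecks Integer vector of per-cycle colony counts.
#' @param initial_size Number of library molecules founding the population.
#' @param seed Seed for the selection RNG stream.
#' @return Object of class `selection_config`.
#' @export
selection_config <- function(bottlenecks = c(2000L, 10000L, 800L, 75L, 75L, 40L),
                             initial_size = 27500L, seed = 1L) {
  if (any(bottlenecks < 1L)) stop("bottlenecks must be >= 1")
  if (length(bottlenecks) < 1L) stop("need at least one cycle")
  if (initial_size < 1L) stop("initial_size must be >= 1")
  structure(list(bottlenecks = as.integer(bottlenecks),
                 n_cycles = length(bottlenecks),
                 initial_size = as.integer(initial_size),
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Sequencing configuration
#'
#' @param read_length Length of each mate (nt).
#' @param error_rate Per-base substitution error rate in [0, 0.1].
#' @param pairs_per_cycle Read pairs generated per sequenced cycle.
#' @param flank Non-mutagenized amplicon flank on each side of the window.
#' @param seed Seed for the sequencing RNG stream.
#' @return Object of class `sequencing_config`.
#' @export
sequencing_config <- function(read_length = 150L, error_rate = 0.003,
                              pairs_per_cycle = 10000L, flank = 30L,
                              seed = 2L) {
  if (error_rate < 0 || error_rate > 0.1) stop("error_rate must be in [0, 0.1]")
  if (read_length < 12L) stop("read_length too short to merge")
  structure(list(read_length = as.integer(read_length),
                 error_rate = error_rate,
                 pairs_per_cycle = as.integer(pairs_per_cycle),
                 flank = as.integer(flank), seed = as.integer(seed)),
            class = "sequencing_config")
}

#' Per-variant relative fitness
#'
#' Relative transconjugant yield per selection cycle, keyed by protein-level
#' label ("V79L", "E86G/C90G", ...); wild type is 1 by definition and any
#' unlisted genotype defaults to 1. The default enhancement of 2.8 is the
#' ratio of the enhanced-variant transconjugant yield to the wild-type yield
#' (about 352.8 vs 125.3 colonies per million donors).
#'
#' @param fitness Named numeric vector of relative yields (> 0).
#' @return Object of class `variant_fitness` (a named numeric vector).
#' @examples
#' variant_fitness(c(V79L = 2.8))
#' @export
variant_fitness <- function(fitness = numeric()) {
  if (length(fitness) && (is.null(names(fitness)) || any(names(fitness) == ""))) {
    stop("fitness values must be named by genotype label")
  }
  if (any(fitness <= 0)) stop("fitness values must be > 0")
  structure(fitness, class = "variant_fitness")
}

# Protein-level labels for a set of window sequences (vectorized translate).
window_labels <- function(seqs, region) {
  aa_ref <- strsplit(translate_cds(region_sequence(region)), "")[[1]]
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(seqs),
                                           if.fuzzy.codon = "X",
                                           no.init.codon = TRUE))
  vapply(strsplit(aa, ""), function(a) {
    d <- which(a != aa_ref)
    if (!length(d)) "WT" else {
      paste(paste0(aa_ref[d], region$codon_start + d - 1L, a[d]), collapse = "/")
    }
  }, "")
}

#' Found a population by sampling the mutagenized library
#'
#' Draws `n_molecules` molecules from the doped library and aggregates them
#' by window genotype. Uses R's global RNG.
#'
#' @param region A [target_region()].
#' @param scheme A [doping_scheme()].
#' @param n_molecules Number of founding molecules.
#' @return data.frame population: `seq` (window sequence), `count`, `label`
#'   (protein-level), with `sum(count) == n_molecules`.
#' @export
initialize_population <- function(region, scheme, n_molecules) {
  if (n_molecules < 1L) stop("n_molecules must be >= 1")
  seqs <- vapply(seq_len(n_molecules),
                 function(i) sample_library_molecule(region, scheme)$sequence, "")
  tab <- table(seqs)
  pop <- data.frame(seq = names(tab), count = as.numeric(tab))
  pop$label <- window_labels(pop$seq, region)
  pop[order(-pop$count), , drop = FALSE]
}

#' One conjugational selection cycle
#'
#' Models a cycle as a single multinomial draw of `bottleneck` transconjugant
#' colonies with per-genotype probability proportional to frequency times
#' fitness, so the expected post-cycle frequency of genotype g is
#' f_g w_g / sum(f w). In deterministic (infinite-population) mode the
#' expected frequencies are returned exactly instead of being sampled.
#'
#' @param pop Population data.frame (`seq`, `count`, `label`).
#' @param fitness A [variant_fitness()] (unlisted labels default to 1).
#' @param bottleneck Number of colonies recovered (>= 1).
#' @param deterministic If TRUE, skip sampling and set counts to
#'   `bottleneck` times the expected frequencies.
#' @return Population data.frame with genotypes at zero count dropped (kept
#'   in deterministic mode).
#' @export
selection_cycle <- function(pop, fitness = variant_fitness(), bottleneck,
                            deterministic = FALSE) {
  if (nrow(pop) == 0L) stop("population is empty")
  if (bottleneck < 1L) stop("bottleneck must be >= 1")
  w <- rep(1, nrow(pop))
  hit <- pop$label %in% names(fitness)
  w[hit] <- unclass(fitness)[pop$label[hit]]
  p <- pop$count * w
  p <- p / sum(p)
  if (deterministic) {
    pop$count <- bottleneck * p
    return(pop)
  }
  pop$count <- as.numeric(stats::rmultinom(1L, size = as.integer(bottleneck),
                                           prob = p))
  pop[pop$count > 0, , drop = FALSE]
}

#' Closed-form frequency trajectory under constant selection
#'
#' Infinite-population expectation for a single advantaged genotype at
#' initial frequency f0 and relative fitness w against a neutral background:
#' f_t = f0 w^t / (1 - f0 + f0 w^t).
#'
#' @param f0 Initial frequency.
#' @param w Relative fitness.
#' @param n_cycles Number of cycles.
#' @return Numeric vector of frequencies after cycles 1..n_cycles.
#' @export
logistic_selection_trajectory <- function(f0, w, n_cycles) {
  stopifnot(f0 >= 0, f0 <= 1, w > 0, n_cycles >= 1)
  t <- seq_len(n_cycles)
  f0 * w^t / (1 - f0 + f0 * w^t)
}

# inject iid substitution errors into equal-length sequences
apply_sequencing_errors <- function(seqs, error_rate) {
  if (length(seqs) == 0L || error_rate <= 0) return(seqs)
  L <- nchar(seqs[1])
  mat <- matrix(unlist(strsplit(seqs, "")), nrow = L)
  idx <- which(stats::runif(length(mat)) < error_rate)
  if (length(idx)) {
    bases <- c("A", "C", "G", "T")
    for (i in idx) {
      mat[i] <- sample(setdiff(bases, mat[i]), 1L)
    }
  }
  do.call(paste0, as.data.frame(t(mat), stringsAsFactors = FALSE))
}

#' Generate paired amplicon reads from a population
#'
#' Each pair is drawn from a genotype with probability proportional to its
#' frequency. The amplicon is the window plus fixed non-mutagenized flanks;
#' the forward mate reads its 5' end, the reverse mate the reverse
#' complement of its 3' end. Per-base substitution errors are i.i.d. at the
#' configured rate; base qualities are constant at the Phred equivalent of
#' that rate (Q40 for error-free reads). Uses R's global RNG.
#'
#' @param pop Population data.frame (`seq`, `count`, `label`).
#' @param region A [target_region()].
#' @param seq_cfg A [sequencing_config()].
#' @return data.frame of read pairs (`id`, `fwd_seq`, `fwd_qual`, `rev_seq`,
#'   `rev_qual`) with attribute `amplicon_cds_start`.
#' @export
generate_reads <- function(pop, region, seq_cfg) {
  sp <- region_nt_span(region)
  flank <- seq_cfg$flank
  a_start <- max(1L, sp[["start_nt"]] - flank)
  a_end <- min(nchar(region$cds), sp[["end_nt"]] + flank)
  left <- substr(region$cds, a_start, sp[["start_nt"]] - 1L)
  right <- substr(region$cds, sp[["end_nt"]] + 1L, a_end)
  amplicons <- paste0(left, pop$seq, right)
  alen <- nchar(amplicons[1])
  rl <- min(seq_cfg$read_length, alen)
  n <- seq_cfg$pairs_per_cycle
  counts <- as.integer(stats::rmultinom(1L, n, prob = pop$count))
  fwd <- rep(substr(amplicons, 1L, rl), counts)
  rev_ <- rep(vapply(substr(amplicons, alen - rl + 1L, alen), revcomp, "",
                     USE.NAMES = FALSE), counts)
  truth_label <- rep(pop$label, counts)
  ord <- sample.int(length(fwd))
  fwd <- apply_sequencing_errors(fwd[ord], seq_cfg$error_rate)
  rev_ <- apply_sequencing_errors(rev_[ord], seq_cfg$error_rate)
  q <- if (seq_cfg$error_rate > 0) {
    min(40L, as.integer(round(-10 * log10(seq_cfg$error_rate))))
  } else 40L
  qual <- strrep(intToUtf8(q + 33L), rl)
  out <- data.frame(id = sprintf("read_%06d", seq_along(fwd)),
                    fwd_seq = fwd, fwd_qual = qual,
                    rev_seq = rev_, rev_qual = qual,
                    truth_label = truth_label[ord])
  attr(out, "amplicon_cds_start") <- a_start
  out
}

#' Run a full synthetic selection experiment
#'
#' Library synthesis, iterative bottlenecked selection, and per-cycle read
#' generation, with ground truth retained for pipeline validation. Two RNG
#' streams are used: the selection stream (`sel_cfg$seed`) drives library
#' sampling and bottlenecks; the sequencing stream (`seq_cfg$seed`, advanced
#' per cycle) drives read generation, so read depth can change without
#' perturbing the selection history.
#'
#' @param region A [target_region()].
#' @param scheme A [doping_scheme()].
#' @param fitness A [variant_fitness()].
#' @param sel_cfg A [selection_config()].
#' @param seq_cfg A [sequencing_config()].
#' @param sequence_cycles Cycles (1-based) for which reads are generated;
#'   default the last three, mirroring deep sequencing of late cycles.
#' @return Object of class `selection_experiment`: `populations` (per-cycle
#'   data.frames, element "0" = founding pool), `truth` (per sequenced
#'   cycle, per-label true fractions), `reads` (per sequenced cycle),
#'   `amplicon_cds_start`, and the configs.
#' @export
run_experiment <- function(region, scheme, fitness = variant_fitness(),
                           sel_cfg = selection_config(),
                           seq_cfg = sequencing_config(),
                           sequence_cycles = NULL) {
  if (is.null(sequence_cycles)) {
    sequence_cycles <- seq_len(sel_cfg$n_cycles)
    sequence_cycles <- utils::tail(sequence_cycles, 3L)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sel_cfg$seed)
  pops <- vector("list", sel_cfg$n_cycles + 1L)
  names(pops) <- as.character(0:sel_cfg$n_cycles)
  pops[[1L]] <- initialize_population(region, scheme, sel_cfg$initial_size)
  for (cy in seq_len(sel_cfg$n_cycles)) {
    pops[[cy + 1L]] <- selection_cycle(pops[[cy]], fitness,
                                       sel_cfg$bottlenecks[cy])
  }
  truth <- list()
  reads <- list()
  a_start <- NA_integer_
  for (cy in sequence_cycles) {
    set.seed(seq_cfg$seed + cy)
    pop <- pops[[cy + 1L]]
    rd <- generate_reads(pop, region, seq_cfg)
    a_start <- attr(rd, "amplicon_cds_start")
    reads[[as.character(cy)]] <- rd
    truth[[as.character(cy)]] <- population_label_fractions(pop, region)
  }
  structure(list(populations = pops, truth = truth, reads = reads,
                 amplicon_cds_start = a_start,
                 sel_cfg = sel_cfg, seq_cfg = seq_cfg, fitness = fitness),
            class = "selection_experiment")
}

#' True per-label fractions of a population
#'
#' Fraction of molecules whose protein-level genotype carries each
#' amino-acid change (a molecule with k changes counts toward k labels), plus
#' the wild-type-protein fraction under label "WT".
#'
#' @param pop Population data.frame (`seq`, `count`, `label`).
#' @param region A [target_region()] (unused; kept for interface symmetry).
#' @return data.frame `change`, `fraction`.
#' @export
population_label_fractions <- function(pop, region) {
  total <- sum(pop$count)
  changes <- strsplit(pop$label, "/", fixed = TRUE)
  long <- data.frame(change = unlist(changes),
                     count = rep(pop$count, lengths(changes)))
  agg <- stats::aggregate(count ~ change, data = long, FUN = sum)
  data.frame(change = agg$change, fraction = agg$count / total)
}
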