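#' Target region of a coding sequence
#'
#' A `target_region` couples a coding sequence (CDS) with a codon window
#' subjected to degenerate-oligonucleotide mutagenesis. All coordinates are
#' 1-based and inclusive on the coding strand; codon 1 is the initiator Met.
#'
#' @param cds_sequence Character scalar, A/C/G/T only, length divisible by 3.
#' @param codon_start,codon_end Integer codon bounds (1-based, inclusive).
#' @return An object of class `target_region` with fields `cds`, `codon_start`,
#'   `codon_end`.
#' @examples
#' reg <- target_region(strrep("ATG", 60), codon_start = 2, codon_end = 10)
#' region_nt_span(reg)
#' @export
target_region <- function(cds_sequence, codon_start, codon_end) {
  stopifnot(is.character(cds_sequence), length(cds_sequence) == 1L)
  cds_sequence <- toupper(cds_sequence)
  if (nchar(cds_sequence) %% 3L != 0L) {
    stop("CDS length (", nchar(cds_sequence), ") is not divisible by 3")
  }
  if (grepl("[^ACGT]", cds_sequence)) {
    stop("CDS contains characters other than A/C/G/T")
  }
  n_codons <- nchar(cds_sequence) %/% 3L
  codon_start <- as.integer(codon_start)
  codon_end <- as.integer(codon_end)
  if (codon_start < 1L) stop("codon_start (", codon_start, ") must be >= 1")
  if (codon_end > n_codons) {
    stop("codon_end (", codon_end, ") exceeds CDS length of ", n_codons, " codons")
  }
  if (codon_start > codon_end) {
    stop("codon_start (", codon_start, ") exceeds codon_end (", codon_end, ")")
  }
  structure(
    list(cds = cds_sequence, codon_start = codon_start, codon_end = codon_end),
    class = "target_region"
  )
}

#' @export
print.target_region <- function(x, ...) {
  sp <- region_nt_span(x)
  cat(sprintf(
    "<target_region> CDS %d nt; codons %d-%d (CDS nt %d-%d, %d nt)\n",
    nchar(x$cds), x$codon_start, x$codon_end, sp[["start_nt"]],
    sp[["end_nt"]], sp[["length"]]
  ))
  invisible(x)
}

#' Nucleotide span of the codon window
#'
#' Converts the codon window of a [target_region()] to CDS nucleotide
#' coordinates. For codons 79-137 this is positions 235-411, i.e. 177 nt.
#'
#' @param region A [target_region()].
#' @return Named integer vector `c(start_nt, end_nt, length)`.
#' @export
region_nt_span <- function(region) {
  stopifnot(inherits(region, "target_region"))
  start_nt <- 3L * (region$codon_start - 1L) + 1L
  end_nt <- 3L * region$codon_end
  c(start_nt = start_nt, end_nt = end_nt, length = end_nt - start_nt + 1L)
}

#' Window sequence of a target region
#'
#' @param region A [target_region()].
#' @return Character scalar with the window nucleotides.
#' @export
region_sequence <- function(region) {
  sp <- region_nt_span(region)
  substr(region$cds, sp[["start_nt"]], sp[["end_nt"]])
}

#' Enumerate all single-nucleotide substitutions in the window
#'
#' Every position of the window can mutate to each of the three non-reference
#' bases, so an L-nt window yields exactly 3L distinct variants; the 177-nt
#' window targeted in the RecA selection yields 531.
#'
#' @param region A [target_region()].
#' @return data.frame with columns `cds_pos` (1-based CDS coordinate),
#'   `ref`, `alt`.
#' @export
enumerate_single_substitutions <- function(region) {
  sp <- region_nt_span(region)
  win <- region_sequence(region)
  if (nchar(win) == 0L) stop("empty window")
  bases <- c("A", "C", "G", "T")
  ref <- strsplit(win, "")[[1]]
  if (any(!ref %in% bases)) stop("window contains ambiguity codes")
  pos <- seq.int(sp[["start_nt"]], sp[["end_nt"]])
  out <- do.call(rbind, lapply(seq_along(ref), function(i) {
    data.frame(cds_pos = pos[i], ref = ref[i], alt = setdiff(bases, ref[i]))
  }))
  rownames(out) <- NULL
  out
}

#' Load the bundled synthetic recA reference
#'
#' The package ships a constructed stand-in for the E. coli recA coding
#' sequence (no sequence is printed in the source study and none is fetched):
#' the 59-codon mutagenesis window (codons 79-137) encodes the residues the
#' selection names (V79, E86, C90, I93, H97, D100, I102, N113, ...) so variant
#' labels such as V79L or E86G/C90G arise with their published identities;
#' flanking codons are arbitrary sense codons. See
#' `inst/extdata/synthetic_recA_cds.fa`.
#'
#' @return A [target_region()] with codons 79-137 as the window.
#' @export
recA_reference <- function() {
  fa <- system.file("extdata", "synthetic_recA_cds.fa", package = "evoselect",
                    mustWork = TRUE)
  seqs <- Biostrings::readDNAStringSet(fa)
  target_region(as.character(seqs[[1]]), codon_start = 79L, codon_end = 137L)
}

#' Translate a CDS (or window) using the standard code
#'
#' @param dna Character scalar of A/C/G/T with length divisible by 3.
#' @return Character scalar of one-letter amino acids (`*` for stop).
#' @export
translate_cds <- function(dna) {
  as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                     if.fuzzy.codon = "error",
                                     no.init.codon = TRUE))
}
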