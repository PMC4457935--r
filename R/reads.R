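#' @useDynLib evoselect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Reverse complement of a DNA string
#' @param x Character scalar (A/C/G/T/N).
#' @return Character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Phred+33 helpers
qual_to_int <- function(q) utf8ToInt(q) - 33L
int_to_qual <- function(v) intToUtf8(v + 33L)

#' Merge a read pair by its best ungapped overlap
#'
#' Emulates overlap-based paired-read joining: the reverse read is
#' reverse-complemented and the best ungapped suffix-prefix overlap with the
#' forward read is taken (smallest mismatch fraction, ties to the longer
#' overlap). The pair merges when that overlap is at least `min_overlap` long
#' with a mismatch fraction at most `max_mismatch_frac`; disagreements are
#' resolved toward the higher-quality base (forward wins ties) and the
#' overlap quality is the per-base maximum. Failure to merge is a normal
#' outcome, reported by `merged = FALSE`.
#'
#' @param fwd_seq,fwd_qual,rev_seq,rev_qual Forward/reverse sequence and
#'   Phred+33 quality strings (reverse read in sequencing orientation).
#' @param min_overlap Minimum acceptable overlap length (default 6).
#' @param max_mismatch_frac Maximum mismatch fraction in the overlap
#'   (default 0.08).
#' @return List: `merged` (logical), and when merged `sequence` and `quality`.
#' @export
merge_read_pairs <- function(fwd_seq, fwd_qual, rev_seq, rev_qual,
                             min_overlap = 6L, max_mismatch_frac = 0.08) {
  stopifnot(nchar(fwd_seq) == nchar(fwd_qual),
            nchar(rev_seq) == nchar(rev_qual))
  rc <- revcomp(rev_seq)
  rc_qual <- paste(rev(strsplit(rev_qual, "")[[1]]), collapse = "")
  ov <- .best_overlap(fwd_seq, rc, as.integer(min_overlap))
  L <- ov[1L]
  if (L < min_overlap || ov[2L] / L > max_mismatch_frac) {
    return(list(merged = FALSE))
  }
  nf <- nchar(fwd_seq)
  f_ov <- substr(fwd_seq, nf - L + 1L, nf)
  r_ov <- substr(rc, 1L, L)
  fq <- qual_to_int(substr(fwd_qual, nf - L + 1L, nf))
  rq <- qual_to_int(substr(rc_qual, 1L, L))
  fb <- strsplit(f_ov, "")[[1]]
  rb <- strsplit(r_ov, "")[[1]]
  cons <- ifelse(fq >= rq, fb, rb)
  seq <- paste0(substr(fwd_seq, 1L, nf - L),
                paste(cons, collapse = ""),
                substr(rc, L + 1L, nchar(rc)))
  qual <- paste0(substr(fwd_qual, 1L, nf - L),
                 int_to_qual(pmax(fq, rq)),
                 substr(rc_qual, L + 1L, nchar(rc_qual)))
  list(merged = TRUE, sequence = seq, quality = qual)
}

#' 3'-quality trimming
#'
#' Truncates a read at its 5'-most base with quality below `q_threshold`:
#' that base and everything 3' of it are dropped, so only the leading run
#' of at-or-above-threshold bases survives. A read whose first base is
#' low-quality becomes empty; a read with no base below threshold is
#' returned unchanged.
#'
#' @param sequence,qualities Sequence and Phred+33 quality strings of equal
#'   length.
#' @param q_threshold Phred threshold (default 20).
#' @return List with trimmed `sequence` and `qualities` (possibly empty).
#' @export
quality_trim <- function(sequence, qualities, q_threshold = 20L) {
  stopifnot(nchar(sequence) == nchar(qualities))
  if (nchar(sequence) == 0L) return(list(sequence = "", qualities = ""))
  q <- qual_to_int(qualities)
  low <- which(q < q_threshold)
  if (length(low) == 0L) {
    return(list(sequence = sequence, qualities = qualities))
  }
  keep <- min(low) - 1L
  list(sequence = substr(sequence, 1L, keep),
       qualities = substr(qualities, 1L, keep))
}

#' Concatenate an unmergeable pair
#'
#' Reads whose mates do not overlap are carried through the pipeline as the
#' forward read followed by the reverse complement of the reverse read, with
#' the reverse qualities reversed to match.
#'
#' @inheritParams merge_read_pairs
#' @return List with `sequence` and `quality`.
#' @export
join_unmerged <- function(fwd_seq, fwd_qual, rev_seq, rev_qual) {
  stopifnot(nchar(fwd_seq) == nchar(fwd_qual),
            nchar(rev_seq) == nchar(rev_qual))
  list(
    sequence = paste0(fwd_seq, revcomp(rev_seq)),
    quality = paste0(fwd_qual, paste(rev(strsplit(rev_qual, "")[[1]]),
                                     collapse = ""))
  )
}

#' Read paired FASTQ files
#'
#' @param fwd_path,rev_path Paths to the mate FASTQ files (Phred+33).
#' @return data.frame with columns `id`, `fwd_seq`, `fwd_qual`, `rev_seq`,
#'   `rev_qual`.
#' @export
read_fastq_pairs <- function(fwd_path, rev_path) {
  # the reader warns about dropped (empty) metadata columns on conversion
  f <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fwd_path))
  r <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(rev_path))
  if (length(f) != length(r)) stop("mate files differ in read count")
  data.frame(
    id = names(f),
    fwd_seq = as.character(f),
    fwd_qual = as.character(Biostrings::quality(f)),
    rev_seq = as.character(r),
    rev_qual = as.character(Biostrings::quality(r)),
    row.names = NULL
  )
}

#' Write paired FASTQ files
#'
#' @param pairs data.frame as returned by [read_fastq_pairs()].
#' @param fwd_path,rev_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_fastq_pairs <- function(pairs, fwd_path, rev_path) {
  write_one <- function(seqs, quals, ids, path) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
    names(x) <- ids
    # the writer warns that (empty) mcols are dropped; nothing is lost
    suppressWarnings(Biostrings::writeQualityScaledXStringSet(x, path))
  }
  write_one(pairs$fwd_seq, pairs$fwd_qual, pairs$id, fwd_path)
  write_one(pairs$rev_seq, pairs$rev_qual, pairs$id, rev_path)
  invisible(c(fwd_path, rev_path))
}
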