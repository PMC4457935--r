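#' Smith-Waterman local alignment
#'
#' Optimal local alignment of a read against the amplicon reference under an
#' affine gap model (Smith-Waterman-Gotoh dynamic programming, compiled). A
#' gap of length L costs `gap_open + L * gap_extend`. Ties are broken
#' deterministically: the traceback prefers diagonal over query-consuming
#' ("up") over reference-consuming ("left") moves, and starts from the
#' rightmost maximal cell (largest reference position, then largest query
#' position).
#'
#' @param query,reference Character scalars (non-empty).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters. Defaults
#'   +2/-3/-5/-2.
#' @return Object of class `sw_alignment`: `score`; `q_start`, `q_end`,
#'   `r_start`, `r_end` (1-based inclusive spans, NA when the best score is
#'   0); `q_aln`, `r_aln` (gapped alignment strings of equal length, `-` for
#'   gaps).
#' @examples
#' smith_waterman("ACGTACGT", "TTACGTACGTTT")$score
#' @export
smith_waterman <- function(query, reference, match = 2, mismatch = -3,
                           gap_open = -5, gap_extend = -2) {
  stopifnot(is.character(query), is.character(reference),
            length(query) == 1L, length(reference) == 1L)
  if (nchar(query) == 0L || nchar(reference) == 0L) {
    stop("empty sequence")
  }
  res <- .sw_align(query, reference, match, mismatch, gap_open, gap_extend)
  structure(res, class = "sw_alignment")
}

#' @export
print.sw_alignment <- function(x, ...) {
  cat(sprintf("<sw_alignment> score %g; query %s-%s, reference %s-%s\n",
              x$score, x$q_start, x$q_end, x$r_start, x$r_end))
  if (nchar(x$q_aln) > 0L) {
    cat(" query: ", x$q_aln, "\n", "  ref : ", x$r_aln, "\n", sep = "")
  }
  invisible(x)
}
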