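# Pairwise global alignment and p-distances for domain sequences.
#
# The family tree is built from pairwise distances, so a pairwise global
# (Needleman-Wunsch, affine-gap) alignment suffices; Biostrings provides the
# dynamic programming. Scoring convention: a gap run of length L costs
# gap_open + L * gap_extend (both negative).

#' Alignment scoring parameters
#'
#' @param match score for an identical column (default +1).
#' @param mismatch score for a substituted column (default -1).
#' @param gap_open cost of opening a gap run (default -2).
#' @param gap_extend cost per gapped column (default -1).
#' @return a named list of scoring parameters.
#' @export
align_params <- function(match = 1, mismatch = -1, gap_open = -2,
                         gap_extend = -1) {
  stopifnot(gap_open <= 0, gap_extend <= 0)
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

#' Optimal global alignment of two sequences
#'
#' Affine-gap Needleman-Wunsch alignment. A gap run of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param a,b non-empty residue strings.
#' @param params scoring parameters from [align_params()].
#' @return list with `seq_a`, `seq_b` (inputs), `aligned_a`, `aligned_b`
#'   (equal-length strings over residues plus `-`), and `score`.
#' @export
global_align <- function(a, b, params = align_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  alphabet <- sort(unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]])))
  mat <- matrix(params$mismatch, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(mat) <- params$match
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = -params$gap_open, gapExtension = -params$gap_extend)
  out <- list(seq_a = a, seq_b = b,
              aligned_a = as.character(Biostrings::alignedPattern(aln)),
              aligned_b = as.character(Biostrings::alignedSubject(aln)),
              score = Biostrings::score(aln))
  stopifnot(nchar(out$aligned_a) == nchar(out$aligned_b))
  out
}

#' Proportion of mismatched residues in an alignment (p-distance)
#'
#' Columns containing a gap in either row are excluded; the distance is the
#' fraction of the remaining columns where the residues differ.
#'
#' @param aln alignment as returned by [global_align()], or a list with
#'   `aligned_a` and `aligned_b`.
#' @return numeric in \[0, 1\].
#' @export
p_distance <- function(aln) {
  x <- strsplit(aln$aligned_a, "")[[1]]
  y <- strsplit(aln$aligned_b, "")[[1]]
  stopifnot(length(x) == length(y))
  comparable <- x != "-" & y != "-"
  if (!any(comparable)) {
    stop("no comparable (gap-free) columns; p-distance undefined")
  }
  mean(x[comparable] != y[comparable])
}

#' All-pairs p-distance matrix for a set of sequences
#'
#' Aligns every pair globally and records the p-distance. Used as the input
#' to [nj_tree()].
#'
#' @param seqs named character vector of residue strings (names are ids).
#' @param params scoring parameters for the pairwise alignments.
#' @return symmetric numeric matrix with dimnames = ids, zero diagonal.
#' @export
p_distance_matrix <- function(seqs, params = align_params()) {
  stopifnot(length(seqs) >= 2, !is.null(names(seqs)),
            !anyDuplicated(names(seqs)))
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pd <- p_distance(global_align(seqs[[i]], seqs[[j]], params = params))
      d[i, j] <- pd
      d[j, i] <- pd
    }
  }
  d
}
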