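#' Best local alignment (Smith-Waterman, affine gaps)
#'
#' Exhaustive dynamic programming over the full matrix (no word-hit
#' heuristics). Coordinates are 0-based half-open; a best score of 0 means
#' no positive-scoring local alignment exists and the segments are empty.
#'
#' @param query,target residue strings over the 20-letter alphabet plus X
#' @param scheme a [scoring_scheme()]
#' @return list with `score`, `query_start`, `query_end`, `target_start`,
#'   `target_end`
#' @export
smith_waterman <- function(query, target, scheme = scoring_scheme()) {
  if (!nzchar(query) || !nzchar(target)) stop("sequences must be non-empty")
  qa <- aa_encode(query); ta <- aa_encode(target)
  r <- cpp_sw_affine(qa, ta, scheme$submat, scheme$gap_open, scheme$gap_extend)
  list(score = r$score,
       query_start = r$a_start, query_end = r$a_end,
       target_start = r$b_start, target_end = r$b_end)
}

#' Global alignment (Needleman-Wunsch, affine gaps)
#'
#' @inheritParams smith_waterman
#' @param a,b residue strings
#' @return list with `score` and aligned strings `a_aln`, `b_aln` (gap "-")
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  ai <- aa_encode(a); bi <- aa_encode(b)
  r <- cpp_nw_global(ai, bi, scheme$submat, scheme$gap_open, scheme$gap_extend)
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  a_aln <- ifelse(r$a_aln == 0L, "-", ac[pmax(r$a_aln, 1L)])
  b_aln <- ifelse(r$b_aln == 0L, "-", bc[pmax(r$b_aln, 1L)])
  list(score = r$score,
       a_aln = paste(a_aln, collapse = ""),
       b_aln = paste(b_aln, collapse = ""))
}

#' Pairwise identity (CD-HIT convention)
#'
#' Identical aligned residues divided by the length of the shorter
#' sequence, from a global alignment.
#'
#' @inheritParams global_align
#' @return fraction in `[0, 1]`
#' @export
pairwise_identity <- function(a, b, scheme = scoring_scheme()) {
  al <- global_align(a, b, scheme)
  x <- strsplit(al$a_aln, "")[[1]]
  y <- strsplit(al$b_aln, "")[[1]]
  matches <- sum(x == y & x != "-")
  matches / min(nchar(a), nchar(b))
}
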