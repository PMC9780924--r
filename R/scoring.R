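#' @title Residue alphabets and scoring schemes
#' @name scoring
NULL

# canonical 20-letter order used internally; X is a 0-score wildcard (code 21)
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA21 <- c(AA20, "X")
DNA5 <- c("A", "C", "G", "T", "N")

#' Robinson-Robinson amino-acid background frequencies
#'
#' Fixed background composition (the standard BLAST null model), shipped
#' with the package so synthetic proteomes and PSSM log-odds are
#' reproducible without external downloads. Normalized to sum to 1.
#'
#' @return named numeric vector over the 20 standard residues
#' @export
aa_background <- function() {
  f <- c(A = 0.078047, R = 0.051269, N = 0.044873, D = 0.053640,
         C = 0.019246, Q = 0.042644, E = 0.062949, G = 0.073772,
         H = 0.021992, I = 0.051420, L = 0.090191, K = 0.057438,
         M = 0.022425, F = 0.038556, P = 0.052028, S = 0.071198,
         T = 0.058413, W = 0.013298, Y = 0.032165, V = 0.064409)
  f <- f[AA20]
  f / sum(f)
}

# encode a residue string as integer codes 1..21 (X = 21)
aa_encode <- function(s) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  idx <- match(ch, AA21)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("illegal residue character '%s' at position %d", ch[bad], bad))
  }
  idx
}

aa_decode <- function(codes) paste(AA21[codes], collapse = "")

# 21x21 substitution matrix in the internal residue order; X scores 0
substitution_matrix <- function(name = "BLOSUM62") {
  key <- paste0("submat_", name)
  if (!is.null(.ff_cache[[key]])) return(.ff_cache[[key]])
  e <- new.env()
  data(list = name, package = "Biostrings", envir = e)
  m <- e[[name]]
  sub <- matrix(0, 21, 21, dimnames = list(AA21, AA21))
  sub[AA20, AA20] <- m[AA20, AA20]
  .ff_cache[[key]] <- sub
  sub
}

#' Create a pairwise scoring scheme
#'
#' Affine gaps follow the BLAST convention: a gap of length `k` costs
#' `gap_open + k * gap_extend`.
#'
#' @param matrix substitution matrix name (only "BLOSUM62" is shipped)
#' @param gap_open,gap_extend positive gap penalties
#' @return object of class `scoring_scheme`
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be > 0")
  sub <- substitution_matrix(matrix)
  if (!isTRUE(all.equal(sub, t(sub)))) stop("substitution matrix must be symmetric")
  structure(list(matrix = matrix, submat = sub,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}
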