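#' CD-HIT-style greedy incremental identity clustering
#'
#' Sequences are processed longest-first (ties broken by id, so output is
#' independent of input order); each sequence joins the first existing
#' cluster whose representative identity is `>= threshold` (inclusive
#' boundary), else founds a new cluster. Identity is identical aligned
#' residues divided by the shorter sequence length, from a global
#' alignment ([pairwise_identity()]).
#'
#' @param sequences named character vector of sequences
#' @param threshold identity threshold in `(0, 1]` (e.g. 0.8 for domain
#'   redundancy removal, 0.9 for duplicate-gene grouping)
#' @param scheme alignment [scoring_scheme()]
#' @return list of `identity_cluster` objects (`representative`,
#'   `members`, `threshold`); together they partition the input. Empty
#'   input gives an empty list.
#' @export
greedy_identity_cluster <- function(sequences, threshold,
                                    scheme = scoring_scheme()) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (!length(sequences)) return(list())
  if (is.null(names(sequences))) stop("sequences must be named")
  ord <- order(-nchar(sequences), names(sequences))
  sequences <- sequences[ord]
  reps <- character(0)
  clusters <- list()
  for (i in seq_along(sequences)) {
    id <- names(sequences)[i]
    s <- sequences[[i]]
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (pairwise_identity(s, sequences[[reps[k]]], scheme) >= threshold) {
        clusters[[k]]$members <- c(clusters[[k]]$members, id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      clusters[[length(clusters) + 1L]] <-
        structure(list(representative = id, members = id,
                       threshold = threshold),
                  class = "identity_cluster")
    }
  }
  clusters
}

#' Flatten identity clusters into a table
#'
#' @param clusters output of [greedy_identity_cluster()]
#' @return data.frame with `cluster`, `representative`, `member`
#' @export
clusters_to_table <- function(clusters) {
  if (!length(clusters)) {
    return(data.frame(cluster = integer(0), representative = character(0),
                      member = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_along(clusters), function(k) {
    data.frame(cluster = k, representative = clusters[[k]]$representative,
               member = clusters[[k]]$members, stringsAsFactors = FALSE)
  }))
}
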