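#' Construct a multiple sequence alignment object
#'
#' @param rows equal-length aligned strings (gap "-")
#' @param ids sequence ids (default from names)
#' @return object of class `msa`
#' @export
msa <- function(rows, ids = names(rows)) {
  if (is.null(ids)) ids <- paste0("seq", seq_along(rows))
  rows <- as.character(rows)
  if (!length(rows)) stop("msa must have >= 1 row")
  if (length(unique(nchar(rows))) != 1L) stop("all msa rows must have equal length")
  structure(list(ids = ids, rows = setNames(rows, ids),
                 ncol = nchar(rows[[1]])), class = "msa")
}

#' Remove gaps from an aligned row
#' @param row aligned string
#' @return the ungapped sequence
#' @export
ungap <- function(row) gsub("-", "", row, fixed = TRUE)

# pair scores for sum-of-pairs scoring over AA21 + gap; residue-gap = -8,
# gap-gap = 0. Shared by progressive_align and the test oracle.
sp_pair_matrix <- function(scheme = scoring_scheme()) {
  S <- matrix(0, 22, 22, dimnames = list(c(AA21, "-"), c(AA21, "-")))
  S[AA21, AA21] <- scheme$submat
  S[AA21, "-"] <- -8
  S["-", AA21] <- -8
  S
}

# column symbol counts (22 symbols) of an alignment given as char matrix
.col_counts <- function(chm) {
  apply(chm, 2, function(col) tabulate(match(col, c(AA21, "-")), 22))
}

# merge two alignments by profile-profile Needleman-Wunsch maximizing the
# cross sum-of-pairs score (linear gaps via the residue-gap pair score)
.merge_profiles <- function(A, B, S) {
  cA <- .col_counts(A); cB <- .col_counts(B)
  la <- ncol(A); lb <- ncol(B)
  gapv <- numeric(22); gapv[22] <- 1
  diagS <- t(cA) %*% S %*% cB              # la x lb
  gapA <- as.numeric(t(cA) %*% S %*% gapv) * nrow(B) # cost of A-col vs gap
  gapB <- as.numeric(t(cB) %*% S %*% gapv) * nrow(A)
  M <- matrix(-Inf, la + 1, lb + 1)
  Tb <- matrix(0L, la + 1, lb + 1)
  M[1, 1] <- 0
  for (i in seq_len(la)) { M[i + 1, 1] <- M[i, 1] + gapA[i]; Tb[i + 1, 1] <- 2L }
  for (j in seq_len(lb)) { M[1, j + 1] <- M[1, j] + gapB[j]; Tb[1, j + 1] <- 3L }
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      d <- M[i, j] + diagS[i, j]
      u <- M[i, j + 1] + gapA[i]
      l <- M[i + 1, j] + gapB[j]
      best <- d; t <- 1L
      if (u > best) { best <- u; t <- 2L }
      if (l > best) { best <- l; t <- 3L }
      M[i + 1, j + 1] <- best; Tb[i + 1, j + 1] <- t
    }
  }
  i <- la; j <- lb
  ai <- integer(0); bj <- integer(0) # 0 = gap column
  while (i > 0 || j > 0) {
    t <- Tb[i + 1, j + 1]
    if (t == 1L) { ai <- c(i, ai); bj <- c(j, bj); i <- i - 1; j <- j - 1 }
    else if (t == 2L) { ai <- c(i, ai); bj <- c(0L, bj); i <- i - 1 }
    else { ai <- c(0L, ai); bj <- c(j, bj); j <- j - 1 }
  }
  padA <- matrix("-", nrow(A), length(ai))
  padA[, ai > 0] <- A[, ai[ai > 0], drop = FALSE]
  padB <- matrix("-", nrow(B), length(bj))
  padB[, bj > 0] <- B[, bj[bj > 0], drop = FALSE]
  rbind(padA, padB)
}

# k-mer (multiset) distance between two sequences
.kmer_dist <- function(a, b, k = 3) {
  if (nchar(a) < k || nchar(b) < k) {
    return(1 - pairwise_identity(a, b))
  }
  ka <- substring(a, 1:(nchar(a) - k + 1), k:nchar(a))
  kb <- substring(b, 1:(nchar(b) - k + 1), k:nchar(b))
  ta <- table(ka); tb <- table(kb)
  common <- intersect(names(ta), names(tb))
  shared <- sum(pmin(ta[common], tb[common]))
  1 - shared / min(length(ka), length(kb))
}

#' Progressive multiple alignment
#'
#' Guide tree from 3-mer distances (UPGMA); profiles merged leaves-first by
#' profile-profile Needleman-Wunsch with mean-of-pairs BLOSUM62 column
#' scores and linear gaps (residue-gap pair score -8). Deterministic.
#'
#' @param sequences named character vector (a single sequence is returned
#'   unchanged as a 1-row alignment)
#' @param scheme [scoring_scheme()] supplying the substitution matrix
#' @return an [msa] whose rows ungap to the input sequences
#' @export
progressive_align <- function(sequences, scheme = scoring_scheme()) {
  if (!length(sequences)) stop("no sequences")
  if (is.null(names(sequences))) names(sequences) <- paste0("seq", seq_along(sequences))
  n <- length(sequences)
  if (n == 1L) return(msa(sequences))
  S <- sp_pair_matrix(scheme)
  profs <- lapply(sequences, function(s) matrix(strsplit(s, "")[[1]], nrow = 1))
  prof_ids <- lapply(names(sequences), identity)
  if (n == 2L) {
    merged <- .merge_profiles(profs[[1]], profs[[2]], S)
    rows <- apply(merged, 1, paste, collapse = "")
    return(msa(rows, ids = names(sequences)))
  }
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- .kmer_dist(sequences[[i]], sequences[[j]])
  }
  hc <- hclust(as.dist(D), method = "average") # UPGMA guide tree
  nodes <- vector("list", nrow(hc$merge))
  node_ids <- vector("list", nrow(hc$merge))
  for (r in seq_len(nrow(hc$merge))) {
    pick <- function(v) {
      if (v < 0) list(p = profs[[-v]], id = prof_ids[[-v]])
      else list(p = nodes[[v]], id = node_ids[[v]])
    }
    a <- pick(hc$merge[r, 1]); b <- pick(hc$merge[r, 2])
    nodes[[r]] <- .merge_profiles(a$p, b$p, S)
    node_ids[[r]] <- c(a$id, b$id)
  }
  final <- nodes[[nrow(hc$merge)]]
  ids <- node_ids[[nrow(hc$merge)]]
  rows <- apply(final, 1, paste, collapse = "")
  out <- msa(rows, ids = ids)
  # restore input order
  msa(out$rows[names(sequences)], ids = names(sequences))
}

#' Sum-of-pairs score of an alignment
#'
#' Total over all row pairs and columns of the pair score (BLOSUM62;
#' residue-gap -8, gap-gap 0). Used to compare alignments of the same
#' sequences.
#'
#' @param aln an [msa] or aligned character vector
#' @param scheme [scoring_scheme()]
#' @return numeric score
#' @export
sum_of_pairs_score <- function(aln, scheme = scoring_scheme()) {
  rows <- as_aligned_rows(aln)
  S <- sp_pair_matrix(scheme)
  chm <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  total <- 0
  for (i in seq_len(nrow(chm) - 1)) for (j in (i + 1):nrow(chm)) {
    total <- total + sum(S[cbind(chm[i, ], chm[j, ])])
  }
  total
}

#' Conserved sites of an alignment
#'
#' At each column the two most abundant non-gap residues are reported (ties
#' broken alphabetically). The percentage uses the total number of rows as
#' denominator, including rows gapped at that column (293 of 389 rows gives
#' 75.32).
#'
#' @param aln an [msa] or aligned character vector
#' @param min_fraction optional filter: keep columns whose top residue
#'   fraction (of total rows) is at least this value
#' @return data.frame with `column` (1-based), `res1`, `count1`, `res2`,
#'   `count2`, `percent`
#' @export
conserved_sites <- function(aln, min_fraction = NULL) {
  rows <- as_aligned_rows(aln)
  chm <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  n <- nrow(chm)
  res <- lapply(seq_len(ncol(chm)), function(j) {
    col <- chm[, j]
    col <- col[col != "-"]
    if (!length(col)) {
      return(data.frame(column = j, res1 = NA_character_, count1 = 0L,
                        res2 = NA_character_, count2 = 0L, percent = 0,
                        stringsAsFactors = FALSE))
    }
    cnt <- table(col)
    ord <- order(-cnt, names(cnt)) # abundance, then alphabetical
    r1 <- names(cnt)[ord[1]]; c1 <- as.integer(cnt[ord[1]])
    if (length(ord) >= 2) {
      r2 <- names(cnt)[ord[2]]; c2 <- as.integer(cnt[ord[2]])
    } else {
      r2 <- NA_character_; c2 <- 0L
    }
    data.frame(column = j, res1 = r1, count1 = c1, res2 = r2, count2 = c2,
               percent = round(100 * c1 / n, 2), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (!is.null(min_fraction)) {
    out <- out[out$count1 / n >= min_fraction, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Fraction of conserved columns shared across species
#'
#' With all site lists expressed in joint-alignment column coordinates, the
#' shared fraction is the number of columns at which the top-2 residue sets
#' of *all* species have a non-empty common intersection, divided by the
#' number of columns conserved in at least one species.
#'
#' @param site_lists list (one per species) of [conserved_sites()] tables
#' @return fraction in `[0, 1]`; 0 with a warning when all lists are empty
#' @export
cross_species_conserved_overlap <- function(site_lists) {
  stopifnot(is.list(site_lists), length(site_lists) >= 1)
  nonempty <- vapply(site_lists, function(x) nrow(x) > 0, logical(1))
  if (!any(nonempty)) {
    warning("all conserved-site lists are empty")
    return(0)
  }
  all_cols <- sort(unique(unlist(lapply(site_lists, function(x) x$column))))
  shared <- 0L
  for (col in all_cols) {
    sets <- lapply(site_lists, function(x) {
      r <- x[x$column == col, , drop = FALSE]
      if (!nrow(r)) character(0) else stats::na.omit(c(r$res1[1], r$res2[1]))
    })
    inter <- Reduce(intersect, sets)
    if (length(inter)) shared <- shared + 1L
  }
  shared / length(all_cols)
}
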