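# Independent brute-force oracles. These deliberately do not reuse the
# package's internals beyond trivial accessors, so that each dual-route
# check compares two separately coded computations.

AAS20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) paste(sample(AAS20, len, TRUE), collapse = "")

blosum62 <- function() {
  e <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# plain 3-state affine-gap local alignment DP, score only
oracle_sw_score <- function(a, b, sub, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(M[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(M[i - 1, j] - open - ext, F[i - 1, j] - ext)
      M[i, j] <- max(0,
                     M[i - 1, j - 1] + sub[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, M[i, j])
    }
  }
  best
}

# exhaustive 3-sequence sum-of-pairs optimum: 3D DP, pair scores BLOSUM62,
# residue-gap -8, gap-gap 0 (the package's SP convention)
oracle_sp3_optimum <- function(s1, s2, s3, sub, gap = -8) {
  v1 <- strsplit(s1, "")[[1]]; v2 <- strsplit(s2, "")[[1]]; v3 <- strsplit(s3, "")[[1]]
  n1 <- length(v1); n2 <- length(v2); n3 <- length(v3)
  ps <- function(x, y) {
    if (is.na(x) && is.na(y)) return(0)
    if (is.na(x) || is.na(y)) return(gap)
    sub[x, y]
  }
  D <- array(-Inf, c(n1 + 1, n2 + 1, n3 + 1))
  D[1, 1, 1] <- 0
  moves <- expand.grid(d1 = 0:1, d2 = 0:1, d3 = 0:1)
  moves <- moves[rowSums(moves) > 0, ]
  for (i in 0:n1) for (j in 0:n2) for (k in 0:n3) {
    if (i + j + k == 0) next
    best <- -Inf
    for (mv in seq_len(nrow(moves))) {
      d1 <- moves$d1[mv]; d2 <- moves$d2[mv]; d3 <- moves$d3[mv]
      if (i - d1 < 0 || j - d2 < 0 || k - d3 < 0) next
      prev <- D[i - d1 + 1, j - d2 + 1, k - d3 + 1]
      if (!is.finite(prev)) next
      c1 <- if (d1) v1[i] else NA
      c2 <- if (d2) v2[j] else NA
      c3 <- if (d3) v3[k] else NA
      sc <- prev + ps(c1, c2) + ps(c1, c3) + ps(c2, c3)
      if (sc > best) best <- sc
    }
    D[i + 1, j + 1, k + 1] <- best
  }
  D[n1 + 1, n2 + 1, n3 + 1]
}

# independent NG86 counting oracle: recomputes the genetic code from
# Biostrings and enumerates sites and pathways naively
oracle_ng86_counts <- function(codons_a, codons_b) {
  gc <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  syn_sites <- function(codon) {
    ch <- strsplit(codon, "")[[1]]
    syn <- 0
    for (pos in 1:3) for (nt in nts[nts != ch[pos]]) {
      mut <- ch; mut[pos] <- nt
      if (gc[[paste(mut, collapse = "")]] == gc[[codon]]) syn <- syn + 1
    }
    syn / 3
  }
  all_paths <- function(from, to) {
    dp <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (!length(dp)) return(list())
    perm <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v)) for (p in perm(v[-i])) out <- c(out, list(c(v[i], p)))
      out
    }
    perm(dp)
  }
  walk <- function(from, to, ord, forbid_stops) {
    cur <- strsplit(from, "")[[1]]; tov <- strsplit(to, "")[[1]]
    sd <- 0; nd <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- tov[p]
      a1 <- gc[[paste(cur, collapse = "")]]
      a2 <- gc[[paste(nxt, collapse = "")]]
      if (forbid_stops && a2 == "*") return(NULL)
      if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  Sd <- 0; Nd <- 0
  for (i in seq_along(codons_a)) {
    paths <- all_paths(codons_a[i], codons_b[i])
    if (!length(paths)) next
    res <- Filter(Negate(is.null),
                  lapply(paths, function(o) walk(codons_a[i], codons_b[i], o, TRUE)))
    if (!length(res)) {
      res <- lapply(paths, function(o) walk(codons_a[i], codons_b[i], o, FALSE))
    }
    avg <- Reduce(`+`, res) / length(res)
    Sd <- Sd + avg[1]; Nd <- Nd + avg[2]
  }
  S <- (sum(vapply(codons_a, syn_sites, 1)) +
          sum(vapply(codons_b, syn_sites, 1))) / 2
  list(Sd = Sd, Nd = Nd, S = S, N = 3 * length(codons_a) - S)
}

random_sense_codons <- function(n) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  sample(sense, n, TRUE)
}

# brute-force agglomerative clustering: recompute all pairwise cluster
# distances each step (complete linkage), merge the closest pair, ties by
# smallest (i, j); returns the list of partitions after each merge
oracle_agglomerate <- function(x, linkage = "complete") {
  n <- nrow(x)
  clusters <- as.list(seq_len(n))
  partitions <- list()
  d0 <- as.matrix(dist(x))
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in 1:(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      cross <- d0[clusters[[i]], clusters[[j]], drop = FALSE]
      dij <- if (linkage == "complete") max(cross) else min(cross)
      if (dij < best[1]) best <- c(dij, i, j)
    }
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
    partitions[[length(partitions) + 1L]] <- clusters
  }
  partitions
}

# canonical form of a partition (list of index sets) for comparison
canon_partition <- function(p) {
  sets <- lapply(p, function(s) sort(s))
  sets[order(vapply(sets, min, 1))]
}

# partition from integer labels
labels_to_partition <- function(labels) {
  canon_partition(unname(split(seq_along(labels), labels)))
}
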