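#' @title Duplicate genes, tandem classification and NG86 Ka/Ks
#' @name evolution
NULL

NUC <- c("A", "C", "G", "T")

# codon -> amino acid (standard genetic code, "*" = stop)
genetic_code <- function() {
  if (is.null(.ff_cache$gcode)) .ff_cache$gcode <- Biostrings::GENETIC_CODE
  .ff_cache$gcode
}

translate_codons <- function(codons) {
  gc <- genetic_code()
  aa <- gc[codons]
  if (anyNA(aa)) stop("invalid codon: ", codons[which(is.na(aa))[1]])
  unname(aa)
}

#' Translate a coding sequence
#' @param cds nucleotide string, length a multiple of 3
#' @return amino-acid string ("*" for stop codons)
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stop("CDS length must be a multiple of 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(translate_codons(codons), collapse = "")
}

# NG86 synonymous site fraction of a sense codon (stops treated as
# nonsynonymous, per the original method: s = synonymous changes / 3)
.syn_fraction <- function(codon) {
  key <- paste0("synfrac_", codon)
  if (!is.null(.ff_cache[[key]])) return(.ff_cache[[key]])
  gc <- genetic_code()
  aa <- gc[[codon]]
  if (aa == "*") stop("stop codon in counted alignment: ", codon)
  syn <- 0L
  ch <- strsplit(codon, "")[[1]]
  for (pos in 1:3) for (nt in setdiff(NUC, ch[pos])) {
    mut <- ch; mut[pos] <- nt
    if (gc[[paste(mut, collapse = "")]] == aa) syn <- syn + 1L
  }
  .ff_cache[[key]] <- syn / 3
  syn / 3
}

# NG86 synonymous/nonsynonymous difference counts between two sense codons:
# equal weighting over all shortest mutational pathways, pathways through
# stop codons excluded (fallback: all pathways, if every one is blocked)
.pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  key <- paste0("pd_", c1, "_", c2)
  if (!is.null(.ff_cache[[key]])) return(.ff_cache[[key]])
  gc <- genetic_code()
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  diffpos <- which(a != b)
  perms <- if (length(diffpos) == 1L) list(diffpos) else {
    pm <- list()
    permute <- function(v, acc) {
      if (!length(v)) { pm[[length(pm) + 1L]] <<- acc; return(invisible()) }
      for (i in seq_along(v)) permute(v[-i], c(acc, v[i]))
    }
    permute(diffpos, integer(0))
    pm
  }
  eval_path <- function(order, allow_stops) {
    cur <- a; sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- b[p]
      aa_cur <- gc[[paste(cur, collapse = "")]]
      aa_nxt <- gc[[paste(nxt, collapse = "")]]
      if (!allow_stops && aa_nxt == "*") return(NULL)
      if (aa_nxt == aa_cur) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, eval_path, allow_stops = FALSE))
  if (!length(res)) res <- lapply(perms, eval_path, allow_stops = TRUE)
  out <- Reduce(`+`, res) / length(res)
  .ff_cache[[key]] <- out
  out
}

#' Codon-level pairwise alignment by back-translation
#'
#' Aligns the two proteins globally (unless an alignment is supplied) and
#' back-translates the protein alignment to codons. A single terminal stop
#' codon is stripped; internal stops are an error. Codon columns gapped in
#' either sequence are excluded.
#'
#' @param cds_a,cds_b coding sequences (nucleotide strings, multiples of 3)
#' @param protein_aln optional list with aligned strings `a_aln`, `b_aln`
#'   (as from [global_align()])
#' @param scheme [scoring_scheme()] for the protein alignment
#' @return list with `codons_a`, `codons_b`: equal-length vectors of
#'   ungapped codon pairs
#' @export
align_codons <- function(cds_a, cds_b, protein_aln = NULL,
                         scheme = scoring_scheme()) {
  strip <- function(cds) {
    cds <- toupper(cds)
    if (nchar(cds) %% 3 != 0) stop("CDS length must be a multiple of 3")
    p <- translate_cds(cds)
    if (endsWith(p, "*")) {
      cds <- substr(cds, 1, nchar(cds) - 3)
      p <- substr(p, 1, nchar(p) - 1)
    }
    if (grepl("*", p, fixed = TRUE)) stop("internal stop codon in CDS")
    list(cds = cds, protein = p)
  }
  A <- strip(cds_a); B <- strip(cds_b)
  if (is.null(protein_aln)) {
    protein_aln <- global_align(A$protein, B$protein, scheme)
  }
  pa <- strsplit(protein_aln$a_aln, "")[[1]]
  pb <- strsplit(protein_aln$b_aln, "")[[1]]
  if (sum(pa != "-") * 3 != nchar(A$cds) || sum(pb != "-") * 3 != nchar(B$cds)) {
    stop("protein alignment length does not match CDS (expected len(cds) = 3 * len(protein))")
  }
  ia <- 0L; ib <- 0L
  ca <- character(0); cb <- character(0)
  for (k in seq_along(pa)) {
    ga <- pa[k] == "-"; gb <- pb[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) {
      ca <- c(ca, substr(A$cds, 3 * ia - 2, 3 * ia))
      cb <- c(cb, substr(B$cds, 3 * ib - 2, 3 * ib))
    }
  }
  list(codons_a = ca, codons_b = cb)
}

#' Nei-Gojobori (1986) Ka/Ks
#'
#' Counting method with Jukes-Cantor correction. Site counts `S`, `N` are
#' the average over both sequences of per-codon synonymous/nonsynonymous
#' site fractions (mutations to stop codons counted as nonsynonymous);
#' difference counts `Sd`, `Nd` weight all shortest mutational pathways
#' equally, excluding pathways through stop codons. `p = d/sites` is
#' corrected as `d = -(3/4) ln(1 - (4/3) p)`.
#'
#' The `flag` is `"ok"` for a defined ratio, `"undefined"` when the ratio
#' is 0/0 (identical sequences) or a correction is infinite (`p >= 3/4`),
#' and `"infinite"` when `Ks = 0` with `Ka > 0`.
#'
#' @param codon_aln output of [align_codons()] (or any list with
#'   `codons_a`, `codons_b`)
#' @return list with `Ka`, `Ks`, `ratio`, `flag`, `Sd`, `Nd`, `S`, `N`
#' @export
ng86_kaks <- function(codon_aln) {
  ca <- codon_aln$codons_a; cb <- codon_aln$codons_b
  if (!length(ca) || length(ca) != length(cb)) {
    stop("codon alignment must contain >= 1 ungapped codon column")
  }
  Sa <- sum(vapply(ca, .syn_fraction, numeric(1)))
  Sb <- sum(vapply(cb, .syn_fraction, numeric(1)))
  S <- (Sa + Sb) / 2
  N <- 3 * length(ca) - S
  d <- vapply(seq_along(ca), function(i) .pair_diffs(ca[i], cb[i]), numeric(2))
  Sd <- sum(d[1, ]); Nd <- sum(d[2, ])
  jc <- function(p) {
    if (p >= 3 / 4) return(NA_real_)
    max(0, -0.75 * log(1 - 4 * p / 3))
  }
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  Ks <- jc(ps); Ka <- jc(pn)
  if (is.na(Ks) || is.na(Ka)) {
    ratio <- NA_real_; flag <- "undefined"
  } else if (Sd == 0 && Nd == 0) {
    ratio <- 0; flag <- "undefined" # 0/0 by convention
  } else if (Ks == 0 && Ka > 0) {
    ratio <- Inf; flag <- "infinite"
  } else if (Ks == 0) {
    ratio <- 0; flag <- "undefined"
  } else {
    ratio <- Ka / Ks; flag <- "ok"
  }
  list(Ka = Ka, Ks = Ks, ratio = ratio, flag = flag,
       Sd = Sd, Nd = Nd, S = S, N = N)
}

#' Find duplicate genes by identity clustering
#'
#' Clusters family proteins with [greedy_identity_cluster()] at the given
#' threshold (default 90% identity); clusters of size >= 2 are duplicate
#' groups. The duplicate fraction is reported as a percentage rounded to
#' two decimals (61 of 389 gives 15.68).
#'
#' @param proteins named character vector of family protein sequences
#' @param threshold identity threshold (default 0.9)
#' @param scheme [scoring_scheme()]
#' @return list with `clusters` (all clusters), `groups` (size >= 2),
#'   `n_total`, `n_duplicates`, `fraction_percent`
#' @export
find_duplicates <- function(proteins, threshold = 0.9,
                            scheme = scoring_scheme()) {
  if (!length(proteins)) stop("proteins must be non-empty")
  cl <- greedy_identity_cluster(proteins, threshold, scheme)
  groups <- Filter(function(x) length(x$members) >= 2, cl)
  nd <- sum(vapply(groups, function(x) length(x$members), integer(1)))
  list(clusters = cl, groups = groups, n_total = length(proteins),
       n_duplicates = nd,
       fraction_percent = round(100 * nd / length(proteins), 2))
}

#' All within-group duplicate pairs
#' @param groups duplicate groups from [find_duplicates()]
#' @return data.frame with columns `a`, `b`
#' @export
duplicate_pairs <- function(groups) {
  rows <- lapply(groups, function(g) {
    m <- sort(g$members)
    if (length(m) < 2) return(NULL)
    cb <- combn(m, 2)
    data.frame(a = cb[1, ], b = cb[2, ], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(a = character(0), b = character(0),
                                      stringsAsFactors = FALSE)
  out
}

#' Classify a duplicate pair as tandem or dispersed
#'
#' Tandem iff both genes lie on the same chromosome and the distance
#' between their start coordinates is at most `max_gap` (inclusive
#' boundary, default 200 kb); otherwise dispersed. Symmetric in the pair.
#'
#' @param gene_a,gene_b gene ids
#' @param loci locus table ([gene_loci()] / [read_gff()])
#' @param max_gap maximum start-to-start distance in bp (default 200,000)
#' @return `"tandem"` or `"dispersed"`
#' @export
classify_tandem <- function(gene_a, gene_b, loci, max_gap = 200000) {
  look <- function(g) {
    i <- match(g, loci$gene_id)
    if (is.na(i)) stop("locus not found for gene '", g, "'")
    loci[i, ]
  }
  la <- look(gene_a); lb <- look(gene_b)
  if (la$chrom == lb$chrom && abs(la$start - lb$start) <= max_gap) {
    "tandem"
  } else "dispersed"
}

#' Full duplicate-pair analysis
#'
#' For each pair: protein identity, NG86 Ka/Ks from the codon alignment,
#' and tandem/dispersed class from the loci.
#'
#' @param pairs data.frame with columns `a`, `b` (gene ids)
#' @param proteins named protein sequences
#' @param cds named coding sequences
#' @param loci locus table
#' @param max_gap tandem distance rule (bp)
#' @param scheme [scoring_scheme()]
#' @return data.frame: `a`, `b`, `identity`, `Ka`, `Ks`, `ratio`, `flag`,
#'   `dup_class`
#' @export
analyze_duplicate_pairs <- function(pairs, proteins, cds, loci,
                                    max_gap = 200000,
                                    scheme = scoring_scheme()) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$a[i]; b <- pairs$b[i]
    kk <- ng86_kaks(align_codons(cds[[a]], cds[[b]], scheme = scheme))
    data.frame(a = a, b = b,
               identity = pairwise_identity(proteins[[a]], proteins[[b]], scheme),
               Ka = kk$Ka, Ks = kk$Ks, ratio = kk$ratio, flag = kk$flag,
               dup_class = classify_tandem(a, b, loci, max_gap),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize selection over duplicate pairs
#'
#' Counts and the mean use defined ratios only (`flag == "ok"`); flagged
#' pairs are reported separately.
#'
#' @param pairs data.frame with `ratio` and `flag` columns (e.g. from
#'   [analyze_duplicate_pairs()])
#' @return list: `n`, `n_defined`, `mean_ratio`, `range`, `n_gt1`,
#'   `n_lt1`, `n_eq1`, `n_flagged`
#' @export
selection_summary <- function(pairs) {
  if (is.null(pairs) || !nrow(pairs)) {
    return(list(n = 0L, n_defined = 0L, mean_ratio = NA_real_,
                range = c(NA_real_, NA_real_), n_gt1 = 0L, n_lt1 = 0L,
                n_eq1 = 0L, n_flagged = 0L))
  }
  ok <- pairs$flag == "ok"
  r <- pairs$ratio[ok]
  list(n = nrow(pairs), n_defined = sum(ok),
       mean_ratio = if (length(r)) mean(r) else NA_real_,
       range = if (length(r)) range(r) else c(NA_real_, NA_real_),
       n_gt1 = sum(r > 1), n_lt1 = sum(r < 1), n_eq1 = sum(r == 1),
       n_flagged = sum(!ok))
}

#' Reciprocal-best-hit ortholog pairs
#'
#' Best hit of every A-protein in B and vice versa by Smith-Waterman
#' score; a pair is kept iff it is mutual-best. Ties are broken by id
#' order (first id wins), so the result is deterministic and forms a
#' matching: no gene appears in two pairs.
#'
#' @param proteome_a,proteome_b named protein sequence vectors
#' @param scheme [scoring_scheme()]
#' @param min_score discard best hits scoring below this (default 0)
#' @return data.frame with `a`, `b`, `score`
#' @export
rbh_orthologs <- function(proteome_a, proteome_b,
                          scheme = scoring_scheme(), min_score = 0) {
  if (!length(proteome_a) || !length(proteome_b)) {
    stop("both proteomes must be non-empty")
  }
  ids_a <- names(proteome_a); ids_b <- names(proteome_b)
  sc <- matrix(0, length(ids_a), length(ids_b), dimnames = list(ids_a, ids_b))
  for (i in seq_along(ids_a)) {
    ai <- aa_encode(proteome_a[[i]])
    for (j in seq_along(ids_b)) {
      sc[i, j] <- cpp_sw_affine(ai, aa_encode(proteome_b[[j]]),
                                scheme$submat, scheme$gap_open,
                                scheme$gap_extend)$score
    }
  }
  best_b <- apply(sc, 1, which.max) # ties: first (id order)
  best_a <- apply(sc, 2, which.max)
  rows <- list()
  for (i in seq_along(ids_a)) {
    j <- best_b[i]
    if (best_a[j] == i && sc[i, j] > min_score) {
      rows[[length(rows) + 1L]] <- data.frame(a = ids_a[i], b = ids_b[j],
                                              score = sc[i, j],
                                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(a = character(0), b = character(0),
                                      score = numeric(0),
                                      stringsAsFactors = FALSE)
  out
}
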