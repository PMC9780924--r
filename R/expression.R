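#' Median-of-ratios size-factor normalization
#'
#' The DESeq-style procedure: the pseudo-reference is the per-gene
#' geometric mean over samples; each sample's size factor is the median,
#' over genes with all-positive counts, of count/reference; normalized
#' values are counts divided by the size factor.
#'
#' @param counts genes x samples non-negative matrix (with dimnames)
#' @return list with `size_factors` (per sample) and `normalized` matrix
#' @export
median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need >= 2 samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no gene has positive counts in all samples; cannot estimate size factors")
  logref <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2, function(col) {
    median(exp(log(col) - logref))
  })
  list(size_factors = sf,
       normalized = sweep(counts, 2, sf, "/"))
}

#' Complete-linkage hierarchical clustering of expression profiles
#'
#' Rows (genes) are optionally z-scored on `log2(x + 1)` (clustering
#' expression *shape*, not magnitude), the Euclidean distance matrix is
#' clustered by agglomerative complete linkage, and the tree is cut into
#' exactly `k` clusters. Deterministic. The per-cluster mean profile of
#' the input matrix is returned as the cluster's expression model.
#'
#' @param mat normalized genes x samples matrix
#' @param k number of clusters (default 10)
#' @param linkage agglomeration method (default "complete")
#' @param scale_rows z-score rows of log2(x+1) before clustering
#'   (default TRUE; constant rows become all-zero)
#' @return object of class `cluster_assignment`: `labels` (named, 1..k),
#'   `k`, `profiles` (k x samples mean profiles), `scaled_profiles`, and
#'   the `hclust` tree
#' @export
hcluster <- function(mat, k = 10, linkage = "complete", scale_rows = TRUE) {
  mat <- as.matrix(mat)
  if (k > nrow(mat)) stop("k must be <= number of genes")
  if (k < 1) stop("k must be >= 1")
  x <- if (scale_rows) {
    lg <- log2(mat + 1)
    t(apply(lg, 1, function(r) {
      s <- sd(r)
      if (!is.finite(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
    }))
  } else mat
  hc <- hclust(dist(x, method = "euclidean"), method = linkage)
  labels <- cutree(hc, k = k)
  profiles <- do.call(rbind, lapply(seq_len(k), function(c) {
    colMeans(mat[labels == c, , drop = FALSE])
  }))
  scaled_profiles <- do.call(rbind, lapply(seq_len(k), function(c) {
    colMeans(x[labels == c, , drop = FALSE])
  }))
  rownames(profiles) <- rownames(scaled_profiles) <- paste0("cluster", seq_len(k))
  structure(list(labels = labels, k = k, profiles = profiles,
                 scaled_profiles = scaled_profiles, tree = hc),
            class = "cluster_assignment")
}

#' Expression-breadth categories
#'
#' Per gene: `"low"` when no sample reaches `expressed_threshold`;
#' otherwise `"tissue-specific"` when the tau specificity statistic
#' (`sum(1 - x/max(x)) / (n-1)`) is at least `tau_specific`;
#' otherwise `"ubiquitous"` when the fraction of samples at or above the
#' threshold is at least `ubiquitous_fraction`; else `"intermediate"`.
#' Thresholds are parameters, not claims: defaults are 1 normalized
#' count, fraction 1.0, tau 0.85.
#'
#' @param mat normalized genes x samples matrix
#' @param expressed_threshold minimal normalized value to call a gene
#'   expressed in a sample
#' @param ubiquitous_fraction fraction of samples required for
#'   "ubiquitous"
#' @param tau_specific tau cutoff for "tissue-specific"
#' @return named character vector of categories
#' @export
breadth_classify <- function(mat, expressed_threshold = 1,
                             ubiquitous_fraction = 1.0,
                             tau_specific = 0.85) {
  mat <- as.matrix(mat)
  apply(mat, 1, function(x) {
    if (max(x) < expressed_threshold || max(x) == 0) return("low")
    tau <- sum(1 - x / max(x)) / (length(x) - 1)
    if (tau >= tau_specific) return("tissue-specific")
    if (mean(x >= expressed_threshold) >= ubiquitous_fraction) return("ubiquitous")
    "intermediate"
  })
}

#' Relative expression by the 2^-ddCt method
#'
#' Per condition, `dCt = mean(Ct_target) - mean(Ct_reference)` over
#' replicates; `ddCt = dCt_condition - dCt_calibrator`; fold change is
#' `2^-ddCt` (1 in the calibrator condition by construction).
#'
#' @param records data.frame with columns `gene`, `condition`,
#'   `replicate`, `Ct`, `role` (`"target"` or `"reference"`)
#' @param calibrator calibrator condition name
#' @param reference_gene reference gene id (its rows must carry
#'   `role == "reference"` Ct values for every condition)
#' @return data.frame: `gene`, `condition`, `delta_ct`, `delta_delta_ct`,
#'   `fold_change`
#' @export
ddct <- function(records, calibrator, reference_gene) {
  need <- c("gene", "condition", "replicate", "Ct", "role")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(records$Ct)) || any(records$Ct <= 0)) {
    stop("Ct values must be finite and > 0")
  }
  conds <- unique(records$condition)
  if (!calibrator %in% conds) stop("calibrator condition not present: ", calibrator)
  ref <- records[records$gene == reference_gene & records$role == "reference", ]
  ref_ct <- tapply(ref$Ct, ref$condition, mean)
  missing_ref <- setdiff(conds, names(ref_ct))
  if (length(missing_ref)) {
    stop("missing reference-gene Ct for condition(s): ",
         paste(missing_ref, collapse = ", "))
  }
  targets <- records[records$role == "target" & records$gene != reference_gene, ]
  rows <- list()
  for (g in unique(targets$gene)) {
    sub <- targets[targets$gene == g, ]
    dct <- tapply(sub$Ct, sub$condition, mean) - ref_ct[unique(sub$condition)]
    if (!calibrator %in% names(dct)) {
      stop("gene '", g, "' has no Ct in calibrator condition")
    }
    ddct_v <- dct - dct[[calibrator]]
    rows[[g]] <- data.frame(gene = g, condition = names(dct),
                            delta_ct = as.numeric(dct),
                            delta_delta_ct = as.numeric(ddct_v),
                            fold_change = 2^(-as.numeric(ddct_v)),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
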