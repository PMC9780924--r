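#' Build calibrated profiles for a domain model library
#'
#' @param library named list of seed alignments (aligned character vectors
#'   or `msa` objects), one per domain model; names are the domain names
#' @param pseudocount_weight passed to [build_pssm()]
#' @param calibration_seed passed to [calibrate_evalue()]
#' @return named list of calibrated `profile_matrix` objects
#' @export
build_domain_library <- function(library, pseudocount_weight = 0.5,
                                 calibration_seed = 71L) {
  if (!length(library) || is.null(names(library))) {
    stop("domain library must be a non-empty named list")
  }
  lapply(setNames(names(library), names(library)), function(nm) {
    p <- build_pssm(as_aligned_rows(library[[nm]]),
                    pseudocount_weight = pseudocount_weight)
    calibrate_evalue(p, seed = substream_seed(calibration_seed, nm))
  })
}

#' Annotate C-terminal domains of a family member
#'
#' Scans the region downstream of the family (F-box) domain segment with
#' each model in the library; hits with `evalue <= evalue_threshold` are
#' resolved to a non-overlapping set greedily (best score first, then
#' leftmost, then domain name). The architecture label is
#' `"F-box+<name1>+<name2>..."` in N-to-C order, or `"FBXU"` when no
#' C-terminal hit survives.
#'
#' @param protein_id id of the protein
#' @param sequence the full protein sequence
#' @param fbox_hit list/row with `start`, `end`: 0-based half-open
#'   coordinates of the family domain within the protein
#' @param library domain model library: named list of seed alignments, or
#'   the output of [build_domain_library()]
#' @param evalue_threshold per-model E-value threshold (default 1e-2)
#' @return object of class `domain_annotation`: `protein`, `domains`
#'   (data.frame name/start/end/score/evalue) and `architecture`
#' @export
annotate_cterm_domains <- function(protein_id, sequence, fbox_hit, library,
                                   evalue_threshold = 1e-2) {
  len <- nchar(sequence)
  if (fbox_hit$start < 0 || fbox_hit$end > len || fbox_hit$start >= fbox_hit$end) {
    stop(sprintf("fbox_hit [%d,%d) outside protein '%s' (length %d)",
                 fbox_hit$start, fbox_hit$end, protein_id, len))
  }
  if (!length(library)) stop("domain library must be non-empty")
  if (!inherits(library[[1]], "profile_matrix")) {
    library <- build_domain_library(library)
  }
  offset <- fbox_hit$end # 0-based start of the C-terminal region
  region <- if (offset < len) substr(sequence, offset + 1, len) else ""
  cand <- list()
  if (nchar(region) > 0) {
    codes <- aa_encode(region)
    for (nm in names(library)) {
      prof <- library[[nm]]
      r <- profile_align1(prof, codes)
      if (r$score <= 0) next
      ev <- estimate_evalue(r$score, prof, nchar(region), 1)
      if (ev <= evalue_threshold) {
        cand[[length(cand) + 1L]] <- data.frame(
          name = nm, start = offset + r$b_start, end = offset + r$b_end,
          score = r$score, evalue = ev, stringsAsFactors = FALSE)
      }
    }
  }
  kept <- data.frame(name = character(0), start = integer(0), end = integer(0),
                     score = numeric(0), evalue = numeric(0),
                     stringsAsFactors = FALSE)
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$score, cand$start, cand$name), , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      ov <- nrow(kept) > 0 &&
        any(cand$start[i] < kept$end & cand$end[i] > kept$start)
      if (!ov) kept <- rbind(kept, cand[i, , drop = FALSE])
    }
    kept <- kept[order(kept$start), , drop = FALSE]
    rownames(kept) <- NULL
  }
  architecture <- if (nrow(kept)) {
    paste(c("F-box", kept$name), collapse = "+")
  } else "FBXU"
  structure(list(protein = protein_id, domains = kept,
                 fbox = list(start = fbox_hit$start, end = fbox_hit$end),
                 architecture = architecture),
            class = "domain_annotation")
}

#' Census of C-terminal domain types per species
#'
#' Counts, per species, the number of proteins containing each domain type;
#' a protein carrying two domain types increments both. Proteins with no
#' surviving C-terminal hit are tallied as `FBXU`.
#'
#' @param annotations list of `domain_annotation` objects
#' @param species character vector parallel to `annotations` (default one
#'   species "sp1")
#' @return matrix domain-type x species of counts (empty input gives a
#'   0 x 0 matrix)
#' @export
domain_census <- function(annotations, species = NULL) {
  if (!length(annotations)) return(matrix(integer(0), 0, 0))
  if (is.null(species)) species <- rep("sp1", length(annotations))
  stopifnot(length(species) == length(annotations))
  rows <- do.call(rbind, lapply(seq_along(annotations), function(i) {
    a <- annotations[[i]]
    types <- if (nrow(a$domains)) unique(a$domains$name) else "FBXU"
    data.frame(species = species[i], type = types, stringsAsFactors = FALSE)
  }))
  tab <- table(rows$type, rows$species)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m
}
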