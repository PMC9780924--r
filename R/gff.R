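#' Read gene loci from a GFF3 file
#'
#' Parses `gene` features (via rtracklayer) and converts the GFF 1-based
#' inclusive coordinates to the package-internal 0-based half-open
#' convention: internal `start = gff_start - 1`, `end = gff_end`. The
#' conversion is an exact bijection with [write_gff()].
#'
#' @param path GFF3 file
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open)
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  g <- g[g$type == "gene", , drop = FALSE]
  if (!nrow(g)) stop("no gene features in ", path)
  if (is.null(g$ID) || anyNA(g$ID)) {
    stop("gene feature missing ID attribute in ", path)
  }
  if (anyNA(g$start) || anyNA(g$end)) stop("non-numeric coordinate in ", path)
  if (any(g$end < g$start)) {
    bad <- which(g$end < g$start)[1]
    stop(sprintf("end < start for gene '%s'", g$ID[bad]))
  }
  out <- data.frame(gene_id = as.character(g$ID),
                    chrom = as.character(g$seqid),
                    start = as.integer(g$start) - 1L,
                    end = as.integer(g$end),
                    strand = as.character(g$strand),
                    stringsAsFactors = FALSE)
  out$strand[!out$strand %in% c("+", "-")] <- "+"
  if (anyDuplicated(out$gene_id)) stop("duplicate gene IDs in ", path)
  out
}

#' Write gene loci as GFF3
#'
#' @param loci data.frame as returned by [read_gff()] (0-based half-open)
#' @param path output path
#' @param source value of the GFF source column
#' @export
write_gff <- function(loci, path, source = "famforge") {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(loci)))
  if (any(loci$start >= loci$end)) stop("start must be < end (0-based half-open)")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     loci$chrom, source, loci$start + 1L, loci$end,
                     loci$strand, loci$gene_id), con)
  invisible(path)
}

#' Construct a gene locus table
#'
#' @param gene_id,chrom,start,end,strand parallel vectors; coordinates are
#'   0-based half-open
#' @return data.frame of loci
#' @export
gene_loci <- function(gene_id, chrom, start, end, strand = "+") {
  stopifnot(length(gene_id) == length(chrom), length(start) == length(end))
  if (any(start >= end)) stop("start must be < end")
  if (any(!nzchar(chrom))) stop("chromosome must be non-empty")
  data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
             start = as.integer(start), end = as.integer(end),
             strand = rep_len(strand, length(gene_id)),
             stringsAsFactors = FALSE)
}
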