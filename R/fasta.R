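#' Read a FASTA file into a sequence store
#'
#' Multi-line records are concatenated, sequences are uppercased, a single
#' trailing '*' is stripped, and every character is validated against the
#' chosen alphabet. Errors carry the offending line number, which is why
#' this reader is implemented in-package rather than delegated.
#'
#' @param path file path
#' @param alphabet "protein" (20 residues + X) or "dna" (ACGT + N)
#' @return named character vector of sequences with attribute `alphabet`
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  allowed <- if (alphabet == "protein") AA21 else DNA5
  ids <- character(0)
  seqs <- character(0)
  cur <- NULL
  cur_line <- 0L
  flush <- function() {
    if (is.null(cur)) return()
    s <- toupper(paste(cur$chunks, collapse = ""))
    s <- sub("\\*$", "", s)
    if (!nzchar(s)) stop(sprintf("empty record '%s' (line %d)", cur$id, cur$line))
    ch <- strsplit(s, "")[[1]]
    bad <- which(!ch %in% allowed)
    if (length(bad)) {
      stop(sprintf("illegal %s character '%s' in record '%s' (line %d)",
                   alphabet, ch[bad[1]], cur$id, cur$line))
    }
    if (cur$id %in% ids) stop(sprintf("duplicate id '%s' (line %d)", cur$id, cur$line))
    ids <<- c(ids, cur$id)
    seqs <<- c(seqs, s)
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      flush()
      id <- sub("^>\\s*", "", ln)
      id <- strsplit(id, "\\s+")[[1]][1]
      if (is.na(id) || !nzchar(id)) stop(sprintf("missing record id (line %d)", i))
      cur <- list(id = id, line = i, chunks = character(0))
    } else if (nzchar(trimws(ln))) {
      if (is.null(cur)) stop(sprintf("sequence data before first header (line %d)", i))
      cur$chunks <- c(cur$chunks, trimws(ln))
    }
  }
  flush()
  if (!length(ids)) stop("no FASTA records in ", path)
  structure(setNames(seqs, ids), alphabet = alphabet)
}

#' Write sequences as wrapped FASTA
#'
#' @param seqs named character vector
#' @param path output path
#' @param width line wrap (default 60 columns)
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
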