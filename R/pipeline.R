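#' Default run configuration
#'
#' Every tunable of every stage, with defaults equal to the published
#' workflow parameters: search E-value 1e-2, inclusion 1e-2, 10 iterations,
#' domain redundancy threshold 0.8, duplicate identity 0.9, tandem rule
#' 200 kb, 10 expression clusters.
#'
#' @return nested list of sections
#' @export
default_config <- function() {
  list(
    synth = list(enabled = TRUE, seed = 1,
                 n_background = 470, n_family = 30, domain_length = 48,
                 domain_identity = 0.8,
                 n_dup_pairs = 12, dup_omega = 0.5, tandem_fraction = 0.6,
                 expr_genes = 120, expr_samples = 8, expr_k = 4,
                 expr_dispersion = 0.05),
    inputs = list(proteome = "", seed_msa = "", cds = "", gff = "",
                  counts = ""),
    search = list(evalue = 1e-2, inclusion = 1e-2, max_iter = 10,
                  pseudocount = 0.5),
    cluster = list(redundancy_identity = 0.8),
    dups = list(identity = 0.9, tandem_max_gap = 200000),
    expression = list(k = 10, scale = TRUE),
    phenotype = list(enabled = FALSE, grades = "")
  )
}

# parse "a=b" flat config with [section] headers; unknown keys rejected
#' Read a flat key-value run configuration
#'
#' Format: `[section]` headers and `key = value` lines; `#` comments.
#' Unknown sections or keys are rejected. Values are parsed as numeric or
#' logical where possible.
#'
#' @param path config file
#' @return nested config list (defaults overridden by the file)
#' @export
read_config <- function(path) {
  cfg <- default_config()
  lines <- readLines(path)
  section <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(sub("#.*$", "", lines[i]))
    if (!nzchar(ln)) next
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!section %in% names(cfg)) {
        stop(sprintf("unknown config section '%s' (line %d)", section, i))
      }
      next
    }
    if (is.null(section)) stop(sprintf("key outside any section (line %d)", i))
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop(sprintf("malformed line %d: '%s'", i, ln))
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    if (!key %in% names(cfg[[section]])) {
      stop(sprintf("unknown key '%s' in section '%s' (line %d)", key, section, i))
    }
    parsed <- if (tolower(val) %in% c("true", "false")) {
      tolower(val) == "true"
    } else if (!is.na(suppressWarnings(as.numeric(val)))) {
      as.numeric(val)
    } else val
    cfg[[section]][[key]] <- parsed
  }
  cfg
}

# tiny deterministic FNV-1a hash of a string (config/manifest fingerprint)
fnv1a <- function(s) {
  h <- 2166136261
  for (c in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), c)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

log_msg <- function(...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the family-analysis pipeline end to end
#'
#' Stages (as configured): synthetic input generation -> iterative profile
#' search -> domain-segment redundancy clustering -> C-terminal domain
#' annotation and census -> conserved sites -> duplicate genes with Ka/Ks
#' and tandem classification -> expression normalization and clustering.
#' Writes per-stage TSV/JSON outputs plus a `manifest.json` carrying the
#' effective configuration, its hash, package version and seeds; a rerun
#' with identical config and inputs is byte-identical apart from
#' timestamps (which are confined to the log).
#'
#' @param config nested list as from [default_config()] / [read_config()]
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list of stage results
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  stage <- function(name, code) {
    log_msg("stage %s: start", name)
    r <- tryCatch(force(code), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    log_msg("stage %s: done", name)
    r
  }
  # resolve inputs (synthesize or load)
  if (isTRUE(config$synth$enabled)) {
    inp <- stage("synth", {
      fam <- make_family_proteome(synth_family_spec(
        n_background_proteins = config$synth$n_background,
        n_family_members = config$synth$n_family,
        domain_length = config$synth$domain_length,
        domain_identity_to_seed = config$synth$domain_identity,
        seed = config$synth$seed))
      dup <- make_duplicate_set(synth_dup_spec(
        n_pairs = config$synth$n_dup_pairs, omega = config$synth$dup_omega,
        tandem_fraction = config$synth$tandem_fraction,
        seed = config$synth$seed))
      expr <- make_expression_matrix(synth_expr_spec(
        n_genes = config$synth$expr_genes,
        n_samples = config$synth$expr_samples,
        k_clusters = config$synth$expr_k,
        dispersion = config$synth$expr_dispersion,
        seed = config$synth$seed))
      idir <- file.path(out_dir, "inputs")
      dir.create(idir, showWarnings = FALSE)
      write_fasta(fam$proteome, file.path(idir, "proteome.faa"))
      write_fasta(setNames(fam$seed_msa$rows, fam$seed_msa$ids),
                  file.path(idir, "seed_msa.afa"))
      write_fasta(dup$cds, file.path(idir, "dups.fna"))
      write_gff(dup$loci, file.path(idir, "dups.gff3"))
      write_tsv(data.frame(gene = rownames(expr$counts), expr$counts,
                           check.names = FALSE),
                file.path(idir, "counts.tsv"))
      write_tsv(fam$truth, file.path(idir, "truth_family.tsv"))
      write_tsv(dup$truth, file.path(idir, "truth_dups.tsv"))
      write_tsv(expr$truth, file.path(idir, "truth_expr.tsv"))
      list(proteome = fam$proteome, seed_msa = fam$seed_msa,
           cterm_library = fam$cterm_library, truth = fam$truth,
           dup = dup, counts = expr$counts)
    })
  } else {
    inp <- stage("load", {
      for (f in c("proteome", "seed_msa")) {
        if (!nzchar(config$inputs[[f]]) || !file.exists(config$inputs[[f]])) {
          stop("missing input path: ", f)
        }
      }
      sm <- read_fasta(config$inputs$seed_msa)
      list(proteome = read_fasta(config$inputs$proteome),
           seed_msa = msa(unname(sm), ids = names(sm)),
           cterm_library = NULL, truth = NULL,
           dup = if (nzchar(config$inputs$cds)) {
             list(cds = read_fasta(config$inputs$cds, "dna"),
                  loci = read_gff(config$inputs$gff))
           } else NULL,
           counts = if (nzchar(config$inputs$counts)) {
             m <- read.delim(config$inputs$counts, check.names = FALSE)
             mm <- as.matrix(m[, -1, drop = FALSE])
             rownames(mm) <- m[[1]]
             mm
           } else NULL)
    })
  }
  # iterative family search
  fam_sets <- stage("search", {
    iterative_expand(inp$seed_msa, inp$proteome,
                     evalue = config$search$evalue,
                     inclusion = config$search$inclusion,
                     max_iter = config$search$max_iter,
                     pseudocount_weight = config$search$pseudocount)
  })
  final <- fam_sets[[length(fam_sets)]]
  hits <- final$members
  hits_out <- hits
  write_tsv(hits_out, file.path(out_dir, "family_hits.tsv"))
  results$search <- fam_sets
  # domain segments + redundancy clustering
  segments <- setNames(substring(inp$proteome[hits$protein],
                                 hits$start + 1, hits$end), hits$protein)
  clusters <- stage("cluster", {
    greedy_identity_cluster(segments, config$cluster$redundancy_identity)
  })
  write_tsv(clusters_to_table(clusters), file.path(out_dir, "domain_clusters.tsv"))
  results$clusters <- clusters
  # conserved sites on the aligned member domains
  results$conserved <- stage("conserved", {
    aligned <- progressive_align(segments)
    cs <- conserved_sites(aligned)
    write_tsv(cs, file.path(out_dir, "conserved_sites.tsv"))
    cs
  })
  # C-terminal architecture (only when a model library is available)
  if (!is.null(inp$cterm_library)) {
    results$domains <- stage("domains", {
      lib <- build_domain_library(inp$cterm_library)
      ann <- lapply(seq_len(nrow(hits)), function(i) {
        annotate_cterm_domains(hits$protein[i],
                               inp$proteome[[hits$protein[i]]],
                               list(start = hits$start[i], end = hits$end[i]),
                               lib)
      })
      census <- domain_census(ann)
      arch <- vapply(ann, `[[`, character(1), "architecture")
      write_tsv(data.frame(protein = hits$protein, architecture = arch,
                           stringsAsFactors = FALSE),
                file.path(out_dir, "architectures.tsv"))
      list(annotations = ann, census = census)
    })
  }
  # duplicates / Ka-Ks / tandem
  if (!is.null(inp$dup)) {
    results$dups <- stage("dups", {
      prot <- vapply(inp$dup$cds, translate_cds, character(1))
      fd <- find_duplicates(prot, config$dups$identity)
      prs <- duplicate_pairs(fd$groups)
      pairs <- if (nrow(prs)) {
        analyze_duplicate_pairs(prs, prot, inp$dup$cds, inp$dup$loci,
                                max_gap = config$dups$tandem_max_gap)
      } else prs
      write_tsv(pairs, file.path(out_dir, "duplicate_pairs.tsv"))
      summ <- selection_summary(pairs)
      jsonlite::write_json(summ, file.path(out_dir, "selection_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      list(found = fd, pairs = pairs, summary = summ)
    })
  }
  # expression
  if (!is.null(inp$counts)) {
    results$expression <- stage("expression", {
      nrm <- median_of_ratios(inp$counts)
      k <- min(config$expression$k, nrow(inp$counts))
      cl <- hcluster(nrm$normalized, k = k,
                     scale_rows = isTRUE(config$expression$scale))
      write_tsv(data.frame(gene = names(cl$labels), cluster = cl$labels,
                           stringsAsFactors = FALSE),
                file.path(out_dir, "expression_clusters.tsv"))
      write_tsv(data.frame(cluster = rownames(cl$profiles), cl$profiles,
                           check.names = FALSE),
                file.path(out_dir, "cluster_profiles.tsv"))
      list(normalization = nrm, clusters = cl,
           breadth = breadth_classify(nrm$normalized))
    })
  }
  # phenotype
  if (isTRUE(config$phenotype$enabled) && nzchar(config$phenotype$grades)) {
    results$phenotype <- stage("phenotype", {
      g <- read.delim(config$phenotype$grades)
      sc <- score_grade_table(g)
      write_tsv(sc, file.path(out_dir, "disease_scores.tsv"))
      sc
    })
  }
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  manifest <- list(package = "famforge",
                   version = as.character(utils::packageVersion("famforge")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   config = config,
                   config_hash = fnv1a(as.character(cfg_json)),
                   family_size = nrow(hits),
                   iterations = length(fam_sets),
                   converged = final$converged)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
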