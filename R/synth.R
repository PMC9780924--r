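#' @title Truth-tagged synthetic data generators
#' @name synthetic_data
#'
#' @description
#' Generators for the statistical worlds the pipeline stages assume: a
#' proteome with a planted domain family (tunable divergence, optional
#' C-terminal domain architectures), duplicate CDS pairs evolved at a known
#' dN/dS with tandem/dispersed placement, negative-binomial count matrices
#' with planted cluster archetypes and size factors, and disease-grade
#' tables. Every entity gets exactly one truth row, and all randomness
#' flows from one integer seed through named sub-streams.
NULL

.check <- function(ok, field, msg) {
  if (!ok) stop(sprintf("invalid %s: %s", field, msg))
}

#' Specification of a synthetic domain-family proteome
#'
#' @param n_background_proteins number of background (non-family) proteins
#' @param n_family_members number of family members with a planted domain
#' @param domain_length planted domain length in residues (F-box-like
#'   default 48)
#' @param domain_identity_to_seed target identity of planted domains to the
#'   seed consensus, in `[0, 1]`. A vector gives divergence tiers: members
#'   of tier `t > 1` derive from a random member of tier `t - 1`
#'   (identities must be non-increasing), emulating family radiation.
#' @param cterm_domain_mix named fractions of C-terminal architectures;
#'   must include an `"unknown"` fraction (FBXU-like members) and sum to 1
#' @param protein_length_range min/max protein length in residues
#' @param seed master integer seed
#' @return object of class `synth_family_spec`
#' @export
synth_family_spec <- function(n_background_proteins = 470,
                              n_family_members = 30,
                              domain_length = 48,
                              domain_identity_to_seed = 0.8,
                              cterm_domain_mix = c(Kelch = 0.3, LRR = 0.2,
                                                   unknown = 0.5),
                              protein_length_range = c(200, 600),
                              seed = 1L) {
  .check(n_background_proteins >= 0, "n_background_proteins", "must be >= 0")
  .check(n_family_members >= 1, "n_family_members", "must be >= 1")
  .check(domain_length >= 10, "domain_length", "must be >= 10 residues")
  .check(all(domain_identity_to_seed >= 0 & domain_identity_to_seed <= 1),
         "domain_identity_to_seed", "must be in [0, 1]")
  .check(!is.unsorted(rev(domain_identity_to_seed)),
         "domain_identity_to_seed", "tier identities must be non-increasing")
  .check(!is.null(names(cterm_domain_mix)) && "unknown" %in% names(cterm_domain_mix),
         "cterm_domain_mix", "must be named and include an 'unknown' fraction")
  .check(abs(sum(cterm_domain_mix) - 1) <= 1e-9, "cterm_domain_mix",
         "fractions must sum to 1")
  .check(length(protein_length_range) == 2 &&
           protein_length_range[1] <= protein_length_range[2],
         "protein_length_range", "must be c(min, max) with min <= max")
  .check(protein_length_range[1] >= domain_length + 80,
         "protein_length_range",
         "min length must leave room for the domain and a C-terminus (domain_length + 80)")
  structure(list(n_background_proteins = as.integer(n_background_proteins),
                 n_family_members = as.integer(n_family_members),
                 domain_length = as.integer(domain_length),
                 domain_identity_to_seed = domain_identity_to_seed,
                 cterm_domain_mix = cterm_domain_mix,
                 protein_length_range = as.integer(protein_length_range),
                 seed = as.integer(seed)),
            class = "synth_family_spec")
}

# random background protein of given length
.bg_protein <- function(len, bg = aa_background()) {
  paste(sample(AA20, len, replace = TRUE, prob = bg), collapse = "")
}

# mutate `seq` (char vector) so that exactly `target_matches` positions
# match `consensus`, by mutating currently-matching positions
.mutate_toward <- function(seqv, consv, target_matches, bg = aa_background()) {
  matching <- which(seqv == consv)
  n_mut <- length(matching) - target_matches
  if (n_mut <= 0) return(seqv)
  pos <- if (length(matching) == 1L) matching else sample(matching, n_mut)
  for (p in pos) {
    alt <- setdiff(AA20, consv[p])
    w <- bg[alt] / sum(bg[alt])
    seqv[p] <- sample(alt, 1, prob = w)
  }
  seqv
}

# largest-remainder apportionment of n into named fractions (exact counts)
.apportion <- function(n, fractions) {
  raw <- fractions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-(raw - base), names(fractions))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Generate a proteome with a planted domain family
#'
#' Background proteins are i.i.d. draws from the Robinson-Robinson
#' background; each family member embeds a mutated copy of the seed-domain
#' consensus at a recorded offset, diverged to the spec's target identity
#' (exactly, by counting mutated positions), plus an optional planted
#' C-terminal domain drawn from the architecture mix in exact
#' largest-remainder proportions. Deterministic given `spec$seed`.
#'
#' @param spec a [synth_family_spec()]
#' @return list with `proteome` (named sequences), `seed_msa` (an [msa] of
#'   the consensus plus high-identity variants), `truth` (one row per
#'   protein: family membership, tier, domain and C-terminal coordinates,
#'   0-based half-open), `cterm_library` (named list of seed alignments
#'   per C-terminal domain model), `consensus`, and the spec
#' @export
make_family_proteome <- function(spec) {
  stopifnot(inherits(spec, "synth_family_spec"))
  bg <- aa_background()
  L <- spec$domain_length
  consensus <- with_substream(spec$seed, "family_consensus",
                              .bg_protein(L, bg))
  consv <- strsplit(consensus, "")[[1]]
  # seed MSA: consensus + 7 variants at 92% identity (a Pfam-seed stand-in)
  seed_rows <- with_substream(spec$seed, "family_seed_msa", {
    v <- vapply(1:7, function(i) {
      paste(.mutate_toward(consv, consv, round(0.92 * L), bg), collapse = "")
    }, character(1))
    c(consensus = consensus, setNames(v, paste0("seed", 1:7)))
  })
  # C-terminal domain models
  cterm_names <- setdiff(names(spec$cterm_domain_mix), "unknown")
  cterm_lib <- with_substream(spec$seed, "family_cterm_models", {
    lapply(setNames(cterm_names, cterm_names), function(nm) {
      cons <- .bg_protein(40, bg)
      cv <- strsplit(cons, "")[[1]]
      v <- vapply(1:5, function(i) {
        paste(.mutate_toward(cv, cv, round(0.9 * 40), bg), collapse = "")
      }, character(1))
      c(setNames(cons, paste0(nm, "_cons")), setNames(v, paste0(nm, 1:5)))
    })
  })
  nf <- spec$n_family_members
  tiers <- spec$domain_identity_to_seed
  tier_sizes <- .apportion(nf, setNames(rep(1 / length(tiers), length(tiers)),
                                        paste0("tier", seq_along(tiers))))
  tier_of <- rep(seq_along(tiers), tier_sizes)
  # planted domains, tier by tier (chained derivation)
  domains <- with_substream(spec$seed, "family_domains", {
    out <- vector("list", nf)
    tier_members <- split(seq_len(nf), tier_of)
    for (t in seq_along(tiers)) {
      target <- round(tiers[t] * L)
      for (i in tier_members[[as.character(t)]]) {
        parent <- if (t == 1) consv else {
          prev <- tier_members[[as.character(t - 1)]]
          pick <- if (length(prev) == 1L) prev else sample(prev, 1)
          out[[pick]]
        }
        out[[i]] <- .mutate_toward(parent, consv, target, bg)
      }
    }
    out
  })
  # exact architecture proportions, order shuffled deterministically
  arch_counts <- .apportion(nf, spec$cterm_domain_mix)
  arch_pool <- rep(names(spec$cterm_domain_mix), arch_counts)
  arch <- with_substream(spec$seed, "family_architectures",
                         arch_pool[sample.int(nf)])
  cterm_instance <- with_substream(spec$seed, "family_cterm_instances", {
    lapply(seq_len(nf), function(i) {
      if (arch[i] == "unknown") return(NULL)
      cons <- cterm_lib[[arch[i]]][[1]]
      cv <- strsplit(cons, "")[[1]]
      paste(.mutate_toward(cv, cv, round(0.8 * 40), bg), collapse = "")
    })
  })
  # assemble proteins
  lr <- spec$protein_length_range
  built <- with_substream(spec$seed, "family_assembly", {
    fam <- lapply(seq_len(nf), function(i) {
      len <- sample(lr[1]:lr[2], 1)
      ct <- cterm_instance[[i]]
      ct_len <- if (is.null(ct)) 0L else nchar(ct)
      max_off <- max(5L, min(floor(len / 3), len - L - ct_len - 20L))
      off <- sample(5:max_off, 1)
      nterm <- .bg_protein(off, bg)
      dom <- paste(domains[[i]], collapse = "")
      if (is.null(ct)) {
        tail_len <- len - off - L
        seqs <- paste0(nterm, dom, .bg_protein(tail_len, bg))
        list(seq = seqs, domain_start = off, cterm_start = NA_integer_,
             cterm_end = NA_integer_)
      } else {
        spacer <- sample(5:15, 1)
        tail_len <- len - off - L - spacer - ct_len
        seqs <- paste0(nterm, dom, .bg_protein(spacer, bg), ct,
                       .bg_protein(tail_len, bg))
        list(seq = seqs, domain_start = off,
             cterm_start = off + L + spacer,
             cterm_end = off + L + spacer + ct_len)
      }
    })
    bgp <- lapply(seq_len(spec$n_background_proteins), function(i) {
      .bg_protein(sample(lr[1]:lr[2], 1), bg)
    })
    list(fam = fam, bgp = bgp)
  })
  fam_ids <- sprintf("FAM%03d", seq_len(nf))
  bg_ids <- sprintf("BG%03d", seq_len(spec$n_background_proteins))
  proteome <- c(setNames(vapply(built$fam, `[[`, character(1), "seq"), fam_ids),
                setNames(unlist(built$bgp, use.names = FALSE) %||% character(0),
                         bg_ids))
  bg_truth <- if (length(bg_ids)) {
    data.frame(id = bg_ids, is_family = FALSE, tier = NA_integer_,
               identity_target = NA_real_, domain_start = NA_real_,
               domain_end = NA_real_, cterm_name = NA_character_,
               cterm_start = NA_real_, cterm_end = NA_real_,
               stringsAsFactors = FALSE)
  } else NULL
  truth <- rbind(
    data.frame(id = fam_ids, is_family = TRUE, tier = tier_of,
               identity_target = tiers[tier_of],
               domain_start = vapply(built$fam, function(x) as.numeric(x$domain_start), numeric(1)),
               domain_end = vapply(built$fam, function(x) as.numeric(x$domain_start), numeric(1)) + L,
               cterm_name = arch,
               cterm_start = vapply(built$fam, function(x) as.numeric(x$cterm_start), numeric(1)),
               cterm_end = vapply(built$fam, function(x) as.numeric(x$cterm_end), numeric(1)),
               stringsAsFactors = FALSE),
    bg_truth
  )
  list(proteome = proteome, seed_msa = msa(seed_rows), truth = truth,
       cterm_library = cterm_lib, consensus = consensus, spec = spec)
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a

#' Specification of a synthetic duplicate-gene set
#'
#' @param n_pairs number of duplicate CDS pairs
#' @param omega target dN/dS of the accept/reject evolution process (> 0)
#' @param target_identity target nucleotide identity of each pair
#' @param tandem_fraction fraction of pairs placed as tandem duplicates
#' @param tandem_max_gap tandem distance rule in bp (default 200,000)
#' @param n_chromosomes number of chromosomes (default 12)
#' @param cds_length ancestral CDS length in nt (multiple of 3, default
#'   900 = 300 codons)
#' @param seed master integer seed
#' @return object of class `synth_dup_spec`
#' @export
synth_dup_spec <- function(n_pairs = 20, omega = 0.5, target_identity = 0.9,
                           tandem_fraction = 0.6, tandem_max_gap = 200000,
                           n_chromosomes = 12, cds_length = 900, seed = 1L) {
  .check(n_pairs >= 1, "n_pairs", "must be >= 1")
  .check(omega > 0, "omega", "must be > 0")
  .check(target_identity > 0 && target_identity <= 1, "target_identity",
         "must be in (0, 1]")
  .check(tandem_fraction >= 0 && tandem_fraction <= 1, "tandem_fraction",
         "must be in [0, 1]")
  .check(tandem_max_gap > 0, "tandem_max_gap", "must be > 0")
  .check(n_chromosomes >= 2, "n_chromosomes", "must be >= 2")
  .check(cds_length %% 3 == 0 && cds_length >= 30, "cds_length",
         "must be a multiple of 3, >= 30")
  structure(list(n_pairs = as.integer(n_pairs), omega = omega,
                 target_identity = target_identity,
                 tandem_fraction = tandem_fraction,
                 tandem_max_gap = as.integer(tandem_max_gap),
                 n_chromosomes = as.integer(n_chromosomes),
                 cds_length = as.integer(cds_length),
                 seed = as.integer(seed)),
            class = "synth_dup_spec")
}

.sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

# evolve `cds` by accept/reject point mutations until `n_target` accepted:
# uniform site and nucleotide proposals, stop codons rejected outright,
# nonsynonymous changes accepted with relative probability omega
.evolve_cds <- function(cds, n_target, omega) {
  gc <- genetic_code()
  v <- strsplit(cds, "")[[1]]
  L <- length(v)
  p_syn <- if (omega >= 1) 1 / omega else 1
  p_non <- if (omega >= 1) 1 else omega
  accepted <- 0L
  attempts <- 0L
  while (accepted < n_target && attempts < 200L * n_target + 1000L) {
    attempts <- attempts + 1L
    pos <- sample.int(L, 1)
    nt <- sample(setdiff(NUC, v[pos]), 1)
    ci <- (pos - 1) %/% 3
    codon_old <- paste(v[(3 * ci + 1):(3 * ci + 3)], collapse = "")
    w <- v; w[pos] <- nt
    codon_new <- paste(w[(3 * ci + 1):(3 * ci + 3)], collapse = "")
    if (gc[[codon_new]] == "*") next
    syn <- gc[[codon_new]] == gc[[codon_old]]
    p <- if (syn) p_syn else p_non
    if (runif(1) <= p) {
      v <- w
      accepted <- accepted + 1L
    }
  }
  paste(v, collapse = "")
}

#' Generate duplicate CDS pairs with known dN/dS and placement
#'
#' Each pair descends from a random ancestral CDS (sense codons only); the
#' second copy is evolved by a codon-wise accept/reject point-mutation
#' process in which nonsynonymous changes are accepted with relative
#' probability `omega` (synonymous with probability 1) and stop codons are
#' rejected. `round(tandem_fraction * n_pairs)` pairs (round-half-up) are
#' placed within `tandem_max_gap` on one chromosome; the rest land on
#' different chromosomes or farther apart. When present, the first tandem
#' pair sits at exactly the `tandem_max_gap` start distance and the first
#' dispersed same-chromosome pair at `tandem_max_gap + 1`, so the boundary
#' is always exercised.
#'
#' @param spec a [synth_dup_spec()]
#' @return list with `cds` (named nucleotide sequences), `proteins`
#'   (their translations), `loci` (gene locus table), `truth` (per pair:
#'   genes, class, true omega, start distance), and the spec
#' @export
make_duplicate_set <- function(spec) {
  stopifnot(inherits(spec, "synth_dup_spec"))
  n <- spec$n_pairs
  Lc <- spec$cds_length %/% 3
  sense <- .sense_codons()
  n_mut <- max(1L, round((1 - spec$target_identity) * spec$cds_length))
  seqs <- with_substream(spec$seed, "dup_sequences", {
    lapply(seq_len(n), function(i) {
      anc <- paste(sample(sense, Lc, replace = TRUE), collapse = "")
      list(a = anc, b = .evolve_cds(anc, n_mut, spec$omega))
    })
  })
  n_tandem <- floor(spec$tandem_fraction * n + 0.5) # round-half-up
  classes <- rep(c("tandem", "dispersed"), c(n_tandem, n - n_tandem))
  glen <- spec$cds_length
  placement <- with_substream(spec$seed, "dup_coordinates", {
    chrom_slot <- integer(spec$n_chromosomes) # used blocks per chromosome
    stride <- spec$tandem_max_gap + 2e6
    place_on <- function(chrom) {
      chrom_slot[chrom] <<- chrom_slot[chrom] + 1L
      1e5 + (chrom_slot[chrom] - 1L) * stride
    }
    t_i <- 0L; d_i <- 0L
    lapply(seq_len(n), function(i) {
      if (classes[i] == "tandem") {
        t_i <<- t_i + 1L
        chrom <- (i - 1L) %% spec$n_chromosomes + 1L
        base <- place_on(chrom)
        gap <- if (t_i == 1L) spec$tandem_max_gap else
          sample((glen + 100L):spec$tandem_max_gap, 1)
        list(chrom_a = chrom, start_a = base, chrom_b = chrom,
             start_b = base + gap)
      } else {
        d_i <<- d_i + 1L
        if (d_i == 1L || d_i %% 2L == 1L) {
          chrom <- (i - 1L) %% spec$n_chromosomes + 1L
          base <- place_on(chrom)
          gap <- if (d_i == 1L) spec$tandem_max_gap + 1L else
            spec$tandem_max_gap + sample.int(1e6, 1)
          list(chrom_a = chrom, start_a = base, chrom_b = chrom,
               start_b = base + gap)
        } else {
          pick <- sample.int(spec$n_chromosomes, 2)
          list(chrom_a = pick[1], start_a = place_on(pick[1]),
               chrom_b = pick[2], start_b = place_on(pick[2]))
        }
      }
    })
  })
  ids_a <- sprintf("DUP%03da", seq_len(n))
  ids_b <- sprintf("DUP%03db", seq_len(n))
  cds <- c(setNames(vapply(seqs, `[[`, character(1), "a"), ids_a),
           setNames(vapply(seqs, `[[`, character(1), "b"), ids_b))
  chrom_name <- function(k) sprintf("chr%02d", k)
  loci <- gene_loci(
    gene_id = c(ids_a, ids_b),
    chrom = c(vapply(placement, function(p) chrom_name(p$chrom_a), character(1)),
              vapply(placement, function(p) chrom_name(p$chrom_b), character(1))),
    start = c(vapply(placement, function(p) p$start_a, numeric(1)),
              vapply(placement, function(p) p$start_b, numeric(1))),
    end = c(vapply(placement, function(p) p$start_a + glen, numeric(1)),
            vapply(placement, function(p) p$start_b + glen, numeric(1))))
  dist <- vapply(placement, function(p) {
    if (p$chrom_a == p$chrom_b) abs(p$start_b - p$start_a) else NA_real_
  }, numeric(1))
  truth <- data.frame(pair = seq_len(n), gene_a = ids_a, gene_b = ids_b,
                      class = classes, omega = spec$omega,
                      start_distance = dist, stringsAsFactors = FALSE)
  proteins <- vapply(cds, translate_cds, character(1))
  list(cds = cds, proteins = proteins, loci = loci, truth = truth,
       spec = spec)
}

#' Specification of a synthetic expression count matrix
#'
#' Defaults mirror the family-scale screen the pipeline targets: 389 genes
#' across 20 tissue samples in 10 expression clusters.
#'
#' @param n_genes,n_samples matrix dimensions
#' @param k_clusters number of planted archetype clusters
#' @param dispersion negative-binomial overdispersion (variance =
#'   `mu + dispersion * mu^2`); 0 gives noise-free rounded means
#' @param amplitude log2 standard deviation of archetype patterns across
#'   samples (default 1.0, i.e. typical two-fold swings)
#' @param size_factors per-sample scale (scalar recycled; all > 0)
#' @param seed master integer seed
#' @return object of class `synth_expr_spec`
#' @export
synth_expr_spec <- function(n_genes = 389, n_samples = 20, k_clusters = 10,
                            dispersion = 0.1, amplitude = 1.0,
                            size_factors = 1, seed = 1L) {
  .check(n_genes >= 1, "n_genes", "must be >= 1")
  .check(n_samples >= 2, "n_samples", "must be >= 2")
  .check(k_clusters >= 1 && k_clusters <= n_genes, "k_clusters",
         "must be in [1, n_genes]")
  .check(dispersion >= 0, "dispersion", "must be >= 0")
  .check(amplitude >= 0, "amplitude", "must be >= 0")
  sf <- rep_len(size_factors, n_samples)
  .check(all(sf > 0), "size_factors", "must be > 0")
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 k_clusters = as.integer(k_clusters),
                 dispersion = dispersion, amplitude = amplitude,
                 size_factors = sf,
                 seed = as.integer(seed)),
            class = "synth_expr_spec")
}

#' Generate a count matrix with planted clusters and size factors
#'
#' Each cluster gets a distinct archetype mean profile
#' `mu_js = 2^(base + amplitude * z_s)` (Gaussian pattern `z` projected so
#' per-sample cluster medians are zero, redrawn until pairwise pattern
#' distances exceed a separation target that relaxes when infeasible);
#' genes are
#' assigned to clusters round-robin; counts are negative-binomial with
#' mean `archetype * size_factor`. Deterministic given `spec$seed`.
#'
#' @param spec a [synth_expr_spec()]
#' @return list with `counts` (genes x samples integer matrix), `truth`
#'   (gene, cluster), `archetypes` (k x samples mean profiles),
#'   `size_factors`, and the spec
#' @export
make_expression_matrix <- function(spec) {
  stopifnot(inherits(spec, "synth_expr_spec"))
  k <- spec$k_clusters; ns <- spec$n_samples
  arch <- with_substream(spec$seed, "expr_archetypes", {
    # target separation, relaxed geometrically when k patterns cannot be
    # packed that far apart in ns-dimensional (row-centered) space;
    # pointless (and quadratic) for many archetypes, so only enforced for
    # cluster-scale k
    min_d <- if (k > 1 && k <= 100) 0.8 * sqrt(ns) else 0
    pats <- NULL
    while (is.null(pats)) {
      for (try in 1:30) {
        z <- matrix(rnorm(k * ns), k, ns)
        # alternating projection: per-sample median of cluster patterns -> 0
        # (so a "typical" gene is not sample-biased, the world median-of-
        # ratios normalization assumes) and per-cluster mean -> 0 (shape,
        # not magnitude; magnitude comes from `base`)
        for (it in 1:50) {
          z <- z - rowMeans(z)
          z <- sweep(z, 2, apply(z, 2, median))
        }
        dmin <- if (k > 1) min(dist(z)) else Inf
        if (dmin >= min_d) { pats <- z; break }
      }
      min_d <- min_d * 0.7
    }
    base <- runif(k, 5, 7)
    2^(base + spec$amplitude * pats)
  })
  rownames(arch) <- paste0("cluster", seq_len(k))
  cluster <- rep(seq_len(k), length.out = spec$n_genes)
  mu <- arch[cluster, , drop = FALSE] *
    matrix(spec$size_factors, spec$n_genes, ns, byrow = TRUE)
  counts <- with_substream(spec$seed, "expr_counts", {
    if (spec$dispersion == 0) {
      round(mu)
    } else {
      matrix(rnbinom(length(mu), mu = as.numeric(mu),
                     size = 1 / spec$dispersion),
             spec$n_genes, ns)
    }
  })
  gene_ids <- sprintf("G%04d", seq_len(spec$n_genes))
  dimnames(counts) <- list(gene_ids, sprintf("S%02d", seq_len(ns)))
  list(counts = counts,
       truth = data.frame(gene = gene_ids, cluster = cluster,
                          stringsAsFactors = FALSE),
       archetypes = arch, size_factors = spec$size_factors, spec = spec)
}

#' Generate a disease-grade table
#'
#' Multinomial draw of per-plant wilting grades 0..4.
#'
#' @param n_plants number of plants
#' @param grade_probs probability 5-vector over grades 0..4 (sums to 1)
#' @param seed integer seed
#' @param treatment,day labels for the output table
#' @return data.frame with `treatment`, `plant`, `day`, `grade`
#' @export
make_grade_table <- function(n_plants, grade_probs, seed = 1L,
                             treatment = "T1", day = 1L) {
  .check(n_plants >= 1, "n_plants", "must be >= 1")
  .check(length(grade_probs) == 5 && all(grade_probs >= 0) &&
           abs(sum(grade_probs) - 1) <= 1e-9,
         "grade_probs", "must be a non-negative 5-vector summing to 1")
  grades <- with_substream(seed, "grades",
                           sample(0:4, n_plants, replace = TRUE,
                                  prob = grade_probs))
  data.frame(treatment = treatment, plant = seq_len(n_plants), day = day,
             grade = grades, stringsAsFactors = FALSE)
}
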