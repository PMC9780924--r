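#' @title Profile (PSSM) construction, calibration and scanning
#' @name profile_search
#'
#' @description
#' The family-discovery engine: a position-specific scoring matrix is built
#' from aligned domain segments, calibrated against an empirical shuffle
#' null, and used to scan a proteome by exhaustive local dynamic
#' programming. Iterating scan -> include -> rebuild gives a PSI-BLAST-style
#' expansion of the family.
NULL

# accept an msa object or a character vector of equal-length aligned rows
as_aligned_rows <- function(x) {
  if (inherits(x, "msa")) x <- setNames(x$rows, x$ids)
  if (!is.character(x) || !length(x)) stop("alignment must be a non-empty character vector or msa")
  if (length(unique(nchar(x))) != 1L) stop("aligned rows must have equal length")
  if (is.null(names(x))) names(x) <- paste0("row", seq_along(x))
  x
}

#' Build a position-specific scoring matrix from aligned segments
#'
#' Per-column log-odds in bits:
#' `log2((f + w * bg) / ((1 + w) * bg))` where `f` is the observed non-gap
#' residue frequency, `bg` the background frequency and `w` the pseudocount
#' weight. Columns with more than 50% gap characters are dropped. Scores of
#' -Inf (pseudocount 0, unseen residue) are capped at -8 bits; the X
#' wildcard scores 0 everywhere.
#'
#' @param segments aligned rows (equal length, gap "-") or an `msa`
#' @param background named 20-vector of residue frequencies (sums to 1)
#' @param pseudocount_weight non-negative prior weight `w`
#' @return object of class `profile_matrix` with `length`, `scores`
#'   (columns x 21, bits), `background`, `pseudocount_weight`,
#'   `kept_columns`, and a `calibration` slot (NULL until
#'   [calibrate_evalue()] is run)
#' @export
build_pssm <- function(segments, background = aa_background(),
                       pseudocount_weight = 0.5) {
  rows <- as_aligned_rows(segments)
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  if (pseudocount_weight < 0) stop("pseudocount_weight must be >= 0")
  bg <- background[AA20]
  chm <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  L <- ncol(chm)
  gap_frac <- colMeans(chm == "-")
  keep <- which(gap_frac <= 0.5)
  if (!length(keep)) stop("all columns are majority-gap; cannot build profile")
  scores <- matrix(0, length(keep), 21, dimnames = list(NULL, AA21))
  cap <- -8 # bits; -16 half-bits
  for (k in seq_along(keep)) {
    col <- chm[, keep[k]]
    col <- col[col != "-" & col != "X"]
    cnt <- table(factor(col, levels = AA20))
    f <- if (length(col)) as.numeric(cnt) / length(col) else rep(0, 20)
    s <- log2((f + pseudocount_weight * bg) / ((1 + pseudocount_weight) * bg))
    s[!is.finite(s)] <- cap
    s <- pmax(s, cap)
    scores[k, AA20] <- s
  }
  structure(list(length = length(keep), scores = scores, background = bg,
                 pseudocount_weight = pseudocount_weight,
                 kept_columns = keep, source_columns = L,
                 calibration = NULL),
            class = "profile_matrix")
}

# default gap penalties for profile scans, in bits (~ BLOSUM62 11/1 half-bits)
profile_gap_open <- 5.5
profile_gap_extend <- 0.5

# raw local profile alignment of one encoded sequence
profile_align1 <- function(profile, seq_codes) {
  cpp_profile_local(profile$scores, seq_codes, profile_gap_open, profile_gap_extend)
}

#' Calibrate the E-value null of a profile
#'
#' Scores `n_shuffles` i.i.d. background sequences of length
#' `shuffle_length` with the profile and fits a Gumbel law to the maxima by
#' the method of moments (`lambda = pi / (sd * sqrt(6))`,
#' `mu = mean - gamma / lambda`). Empirical calibration is used instead of
#' Karlin-Altschul theory because profile scores are gapped.
#'
#' @param profile a `profile_matrix`
#' @param n_shuffles number of null sequences (default 200)
#' @param shuffle_length length of each null sequence
#' @param seed internal RNG seed for the null (fixed by default so
#'   calibration is deterministic)
#' @return the profile with its `calibration` slot filled
#' @export
calibrate_evalue <- function(profile, n_shuffles = 200, shuffle_length = 400,
                             seed = 71L) {
  stopifnot(inherits(profile, "profile_matrix"))
  bg <- profile$background
  scores <- with_substream(seed, "evalue_null", {
    vapply(seq_len(n_shuffles), function(i) {
      s <- sample.int(20, shuffle_length, replace = TRUE, prob = bg)
      profile_align1(profile, s)$score
    }, numeric(1))
  })
  sdev <- sd(scores)
  if (!is.finite(sdev) || sdev <= 0) stop("degenerate null score distribution; cannot calibrate")
  lambda <- pi / (sdev * sqrt(6))
  mu <- mean(scores) - 0.5772156649015329 / lambda
  profile$calibration <- list(lambda = lambda, mu = mu,
                              shuffle_length = shuffle_length,
                              n_shuffles = n_shuffles, seed = seed)
  profile
}

#' E-value of a raw profile score
#'
#' `E = db_size * (n / L0) * exp(-lambda * (S - mu))`, the expected number
#' of chance hits scoring at least `S` in a database of `database_size`
#' sequences of length `target_length`, under the fitted Gumbel null
#' (calibrated at length `L0`). Algebraically of the Karlin-Altschul form
#' `K * m * n * exp(-lambda * S)` with `K = db_size * exp(lambda * mu) /
#' (m * L0)`. Monotone decreasing in score.
#'
#' @param score raw score(s) in bits
#' @param profile calibrated `profile_matrix`
#' @param target_length length of the scored sequence
#' @param database_size number of sequences in the database
#' @return E-value(s), `>= 0`
#' @export
estimate_evalue <- function(score, profile, target_length, database_size = 1) {
  if (is.null(profile$calibration)) {
    stop("profile is not calibrated; run calibrate_evalue() first")
  }
  cal <- profile$calibration
  database_size * (target_length / cal$shuffle_length) *
    exp(-cal$lambda * (score - cal$mu))
}

# scan every protein with a calibrated profile; returns hits data.frame and
# the column-anchored segment per hit (for profile rebuilding)
profile_scan <- function(profile, proteome, evalue_threshold) {
  ids <- names(proteome)
  n_db <- length(proteome)
  hit_rows <- vector("list", n_db)
  segs <- character(0)
  for (i in seq_len(n_db)) {
    codes <- aa_encode(proteome[[i]])
    r <- profile_align1(profile, codes)
    ev <- estimate_evalue(r$score, profile, length(codes), n_db)
    if (ev <= evalue_threshold && r$score > 0) {
      anch <- r$anchored
      seg <- rep("-", profile$length)
      m <- anch > 0
      seg[m] <- AA21[codes[anch[m]]]
      hit_rows[[i]] <- data.frame(protein = ids[i], start = r$b_start,
                                  end = r$b_end, score = r$score,
                                  evalue = ev, stringsAsFactors = FALSE)
      segs <- c(segs, setNames(paste(seg, collapse = ""), ids[i]))
    }
  }
  hits <- do.call(rbind, hit_rows)
  if (is.null(hits)) {
    hits <- data.frame(protein = character(0), start = integer(0),
                       end = integer(0), score = numeric(0),
                       evalue = numeric(0), stringsAsFactors = FALSE)
  } else {
    ord <- order(hits$evalue, hits$protein)
    hits <- hits[ord, , drop = FALSE]
    rownames(hits) <- NULL
    segs <- segs[hits$protein]
  }
  attr(hits, "segments") <- segs
  hits
}

#' Scan a proteome with a seed-domain alignment
#'
#' Builds the initial profile from the seed MSA, calibrates its E-value
#' null, and scores every protein by best profile-to-sequence local
#' alignment. Hits with `evalue <= evalue_threshold` are returned sorted by
#' E-value then protein id; the column-anchored matched segments are
#' attached as attribute `"segments"` and the calibrated profile as
#' attribute `"profile"`.
#'
#' @param seed_msa aligned seed rows (>= 10 columns) or an `msa`
#' @param proteome named character vector of protein sequences
#' @param evalue_threshold inclusion E-value (default 1e-2)
#' @param pseudocount_weight passed to [build_pssm()]
#' @param calibration_seed passed to [calibrate_evalue()]
#' @return data.frame of hits (`protein`, `start`, `end`, `score`,
#'   `evalue`); coordinates 0-based half-open
#' @export
scan_with_seed_msa <- function(seed_msa, proteome, evalue_threshold = 1e-2,
                               pseudocount_weight = 0.5,
                               calibration_seed = 71L) {
  rows <- as_aligned_rows(seed_msa)
  if (nchar(rows[[1]]) < 10) stop("seed MSA must have >= 10 columns")
  if (!length(proteome)) stop("proteome must be non-empty")
  profile <- build_pssm(rows, pseudocount_weight = pseudocount_weight)
  profile <- calibrate_evalue(profile, seed = calibration_seed)
  hits <- profile_scan(profile, proteome, evalue_threshold)
  attr(hits, "profile") <- profile
  hits
}

#' Iterative PSI-BLAST-style family expansion
#'
#' Alternates scanning with profile rebuilding: hits with
#' `evalue <= inclusion` are added to the family, their column-anchored
#' domain segments are stacked into a new PSSM (re-calibrated per
#' iteration), and the proteome is rescanned, until no new member appears
#' or `max_iter` is reached. Membership is monotone non-decreasing (a
#' protein once included is never dropped).
#'
#' @inheritParams scan_with_seed_msa
#' @param evalue reporting threshold per scan
#' @param inclusion inclusion threshold for profile rebuilding
#' @param max_iter maximum number of scan iterations (default 10)
#' @return list of `family_set` objects, one per iteration, each with
#'   `iteration`, `members` (hits data.frame of all current members),
#'   `new_members`, and `converged`
#' @export
iterative_expand <- function(seed_msa, proteome, evalue = 1e-2,
                             inclusion = 1e-2, max_iter = 10,
                             pseudocount_weight = 0.5,
                             calibration_seed = 71L) {
  if (max_iter < 1) stop("max_iter must be >= 1")
  rows <- as_aligned_rows(seed_msa)
  profile <- build_pssm(rows, pseudocount_weight = pseudocount_weight)
  profile <- calibrate_evalue(profile, seed = calibration_seed)
  members <- character(0)
  best_hits <- list() # most recent hit row + segment per member
  out <- list()
  for (it in seq_len(max_iter)) {
    hits <- profile_scan(profile, proteome, max(evalue, inclusion))
    segs <- attr(hits, "segments")
    included <- hits$protein[hits$evalue <= inclusion]
    for (p in included) {
      best_hits[[p]] <- list(row = hits[hits$protein == p, , drop = FALSE],
                             segment = segs[[p]], iteration = it)
    }
    new_members <- setdiff(included, members)
    members <- union(members, included)
    member_rows <- do.call(rbind, lapply(members, function(p) {
      r <- best_hits[[p]]$row
      r$iteration <- best_hits[[p]]$iteration
      r
    }))
    if (!is.null(member_rows)) {
      member_rows <- member_rows[order(member_rows$evalue, member_rows$protein), ]
      rownames(member_rows) <- NULL
    }
    converged <- length(new_members) == 0L
    out[[it]] <- structure(list(iteration = it, members = member_rows,
                                new_members = new_members,
                                converged = converged),
                           class = "family_set")
    if (converged) break
    # rebuild the PSSM from the current scan's included segments only
    cur_segs <- vapply(included, function(p) segs[[p]], character(1))
    if (!length(cur_segs)) break
    profile <- build_pssm(cur_segs, background = profile$background,
                          pseudocount_weight = pseudocount_weight)
    profile <- calibrate_evalue(profile,
                                seed = substream_seed(calibration_seed,
                                                      paste0("iter", it)))
  }
  out
}
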