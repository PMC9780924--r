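test_that("NG86 reproduces the three-codon worked example", {
  kk <- ng86_kaks(list(codons_a = c("TTT", "GGG", "AAA"),
                       codons_b = c("TTC", "GGG", "AAA")))
  expect_equal(kk$Sd, 1)
  expect_equal(kk$Nd, 0)
  expect_equal(kk$S, 5 / 3)
  expect_equal(kk$N, 22 / 3)
  expect_equal(kk$Ka, 0)
  expect_equal(kk$Ks, -0.75 * log(1 - 0.8), tolerance = 1e-12) # ~1.2071
})

test_that("identical CDS give the 0/0 convention; symmetry holds", {
  c1 <- c("ATG", "GCT", "AAA")
  kk <- ng86_kaks(list(codons_a = c1, codons_b = c1))
  expect_equal(kk$Ka, 0)
  expect_equal(kk$Ks, 0)
  expect_equal(kk$ratio, 0)
  expect_equal(kk$flag, "undefined")
  set.seed(61)
  for (case in 1:10) {
    a <- random_sense_codons(10)
    b <- random_sense_codons(10)
    f <- ng86_kaks(list(codons_a = a, codons_b = b))
    r <- ng86_kaks(list(codons_a = b, codons_b = a))
    expect_equal(f[c("Ka", "Ks", "Sd", "Nd", "S", "N")],
                 r[c("Ka", "Ks", "Sd", "Nd", "S", "N")])
  }
})

test_that("NG86 counting equals the brute-force enumeration oracle", {
  set.seed(62)
  for (case in 1:60) {
    n <- sample(1:30, 1)
    a <- random_sense_codons(n)
    b <- a
    # mutate a few codons of b (keeping them sense)
    idx <- sample(n, min(n, sample(1:6, 1)))
    b[idx] <- random_sense_codons(length(idx))
    got <- ng86_kaks(list(codons_a = a, codons_b = b))
    want <- oracle_ng86_counts(a, b)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
    expect_equal(got$S, want$S, tolerance = 1e-12)
    expect_equal(got$N, want$N, tolerance = 1e-12)
  }
})

test_that("codon alignment back-translates and drops gapped columns", {
  # identical CDS: zero differences
  cds <- "ATGGCTAAATTTGGG"
  al <- align_codons(cds, cds)
  expect_equal(al$codons_a, al$codons_b)
  # protein-level gap: the missing codon is excluded from counting
  a <- "ATGGCTAAATTTGGG" # M A K F G
  b <- "ATGGCTTTTGGG"    # M A F G
  al <- align_codons(a, b)
  expect_equal(length(al$codons_a), 4)
  expect_equal(al$codons_b, c("ATG", "GCT", "TTT", "GGG"))
  # oracle back-translation on a mutated pair: ungapped columns must pair
  # the codons of matched residues
  set.seed(63)
  ca <- random_sense_codons(20)
  cb <- ca
  cb[5] <- "GCT"
  al <- align_codons(paste(ca, collapse = ""), paste(cb, collapse = ""))
  expect_equal(length(al$codons_a), 20)
  expect_equal(al$codons_a, unname(ca))
  expect_equal(al$codons_b, unname(cb))
})

test_that("terminal stops are stripped; internal stops and bad lengths error", {
  al <- align_codons("ATGGCTTAA", "ATGGCTTAA")
  expect_equal(length(al$codons_a), 2)
  expect_error(align_codons("ATGTAAGCT", "ATGGCTAAA"), "internal stop")
  expect_error(align_codons("ATGGC", "ATGGCT"), "multiple of 3")
  expect_error(ng86_kaks(list(codons_a = character(0), codons_b = character(0))),
               "codon")
})

test_that("tandem classification applies the inclusive 200 kb start rule", {
  loci <- gene_loci(c("g1", "g2", "g3", "g4", "g5"),
                    c("chr1", "chr1", "chr2", "chr1", "chr1"),
                    start = c(100000, 150000, 100000, 300000, 100000 + 200000),
                    end = c(101000, 151000, 101000, 301000, 301001))
  expect_equal(classify_tandem("g1", "g2", loci), "tandem")     # 50 kb
  expect_equal(classify_tandem("g1", "g3", loci), "dispersed")  # chromosomes
  expect_equal(classify_tandem("g1", "g5", loci), "tandem")     # exactly 200 kb
  expect_equal(classify_tandem("g2", "g4", loci), "tandem")     # 150 kb
  expect_equal(classify_tandem("g1", "g4", loci), "tandem")
  expect_equal(classify_tandem("g1", "g4", loci, max_gap = 150000), "dispersed")
  # symmetric in the pair
  expect_equal(classify_tandem("g2", "g1", loci),
               classify_tandem("g1", "g2", loci))
  expect_error(classify_tandem("g1", "nope", loci), "nope")
})

test_that("find_duplicates reports groups and the duplicate fraction", {
  seqs <- setNames(rep("ACDEFGHIKLMNPQRSTVWY", 4), paste0("g", 1:4))
  fd <- find_duplicates(seqs)
  expect_length(fd$groups, 1)
  expect_equal(fd$fraction_percent, 100)
  # planted groups among unrelated background
  set.seed(64)
  base <- vapply(1:5, function(i) random_protein(60), character(1))
  dups <- unlist(lapply(1:5, function(g) {
    setNames(rep(base[g], 2), paste0("d", g, c("a", "b")))
  }))
  bg <- setNames(vapply(1:20, function(i) random_protein(60), character(1)),
                 paste0("b", 1:20))
  fd <- find_duplicates(c(dups, bg), 0.9)
  expect_length(fd$groups, 5)
  expect_equal(fd$n_duplicates, 10)
  expect_equal(fd$fraction_percent, round(100 * 10 / 30, 2))
  pr <- duplicate_pairs(fd$groups)
  expect_equal(nrow(pr), 5)
})

test_that("selection summary counts defined ratios and flags separately", {
  pairs <- data.frame(ratio = c(0.5, 0.5, 2, Inf, NA),
                      flag = c("ok", "ok", "ok", "infinite", "undefined"))
  s <- selection_summary(pairs)
  expect_equal(s$n, 5L)
  expect_equal(s$n_defined, 3L)
  expect_equal(s$mean_ratio, 1)
  expect_equal(s$n_gt1, 1L)
  expect_equal(s$n_lt1, 2L)
  expect_equal(s$n_flagged, 2L)
  empty <- selection_summary(pairs[0, ])
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$mean_ratio))
})

test_that("a synthetic set under purifying selection summarizes below 1", {
  d <- make_duplicate_set(synth_dup_spec(n_pairs = 12, omega = 0.3,
                                         target_identity = 0.85, seed = 65))
  pairs <- analyze_duplicate_pairs(d$truth[, c("gene_a", "gene_b")] |>
                                     setNames(c("a", "b")),
                                   d$proteins, d$cds, d$loci)
  s <- selection_summary(pairs)
  expect_equal(s$mean_ratio, 0.3, tolerance = 0.35)
  expect_gt(s$n_lt1, s$n_gt1)
  # tandem labels reproduce truth exactly
  expect_equal(pairs$dup_class, d$truth$class)
})

test_that("RBH pairing is a mutual-best matching", {
  set.seed(66)
  prot <- setNames(vapply(1:8, function(i) random_protein(50), character(1)),
                   paste0("p", 1:8))
  # identical proteomes pair every protein with its copy
  ort <- rbh_orthologs(prot, setNames(prot, paste0("q", 1:8)))
  expect_equal(nrow(ort), 8)
  expect_equal(ort$b[match(paste0("p", 1:8), ort$a)], paste0("q", 1:8))
  # a duplicated gene resolves to exactly one pair via the id tie-break
  b2 <- c(prot, dup = prot[["p3"]])
  names(b2) <- c(paste0("q", 1:8), "q9dup")
  ort2 <- rbh_orthologs(prot, b2)
  expect_equal(anyDuplicated(ort2$a), 0)
  expect_equal(anyDuplicated(ort2$b), 0)
  expect_equal(ort2$b[ort2$a == "p3"], "q3") # first id wins the tie
  expect_false("q9dup" %in% ort2$b)
  # unrelated proteomes with a score threshold pair nothing or nearly so
  other <- setNames(vapply(1:8, function(i) random_protein(50), character(1)),
                    paste0("r", 1:8))
  ort3 <- rbh_orthologs(prot, other, min_score = 60)
  expect_lte(nrow(ort3), 1)
})
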