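test_that("median-of-ratios: identical samples and exact scalar multiples", {
  set.seed(71)
  base <- matrix(rpois(60, 50), 20, 3,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  same <- cbind(base[, 1], base[, 1], base[, 1])
  r <- median_of_ratios(same)
  expect_true(all(abs(r$size_factors - r$size_factors[1]) < 1e-12))
  # sample 2 = 3 * sample 1: size-factor ratio exactly 3 (geometric-mean
  # reference makes each ratio column constant-scaled)
  m <- cbind(A = base[, 1], B = 3 * base[, 1])
  r <- median_of_ratios(m)
  expect_equal(unname(r$size_factors["B"] / r$size_factors["A"]), 3,
               tolerance = 1e-12)
})

test_that("median-of-ratios agrees with the DESeq2 estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(72)
  m <- matrix(rnbinom(300, mu = 100, size = 5), 50, 6)
  m[1, ] <- 0 # a gene excluded by the all-positive rule
  sf_pkg <- median_of_ratios(m)$size_factors
  sf_ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(sf_pkg), unname(sf_ref), tolerance = 1e-10)
})

test_that("normalization errors without an all-positive gene", {
  m <- rbind(c(0, 5, 5), c(5, 0, 5), c(5, 5, 0))
  expect_error(median_of_ratios(m), "positive")
  expect_error(median_of_ratios(matrix(1:5, 5, 1)), "2 samples")
})

test_that("scaling one sample acts exactly as the global c^(1/m) factor", {
  e <- make_expression_matrix(synth_expr_spec(n_genes = 40, n_samples = 4,
                                              k_clusters = 4, seed = 73))
  n1 <- median_of_ratios(e$counts)
  c2 <- e$counts; c2[, 2] <- c2[, 2] * 7
  n2 <- median_of_ratios(c2)
  # size-factor ratios between unscaled samples exactly invariant; the
  # scaled sample's ratio picks up exactly c
  r1 <- n1$size_factors / n1$size_factors[1]
  r2 <- n2$size_factors / n2$size_factors[1]
  expect_equal(unname(r2[c(3, 4)]), unname(r1[c(3, 4)]), tolerance = 1e-12)
  expect_equal(unname(r2[2] / r1[2]), 7, tolerance = 1e-12)
  # every normalized entry shifts by the global nuisance factor 7^(1/4)
  expect_equal(n2$normalized, n1$normalized * 7^(1 / 4), tolerance = 1e-10)
})

test_that("complete-linkage clustering separates {0,1} from {10}", {
  m <- matrix(c(0, 1, 10), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  cl <- hcluster(m, k = 2, scale_rows = FALSE)
  expect_equal(cl$labels[["a"]], cl$labels[["b"]])
  expect_false(cl$labels[["a"]] == cl$labels[["c"]])
})

test_that("identical rows are always co-clustered", {
  set.seed(74)
  m <- matrix(rpois(40, 30), 10, 4)
  m[7, ] <- m[3, ]
  rownames(m) <- paste0("g", 1:10)
  for (k in c(2, 4, 8)) {
    cl <- hcluster(m, k = k, scale_rows = FALSE)
    expect_equal(cl$labels[["g3"]], cl$labels[["g7"]], info = paste("k", k))
  }
})

test_that("agglomeration equals the brute-force oracle at every cut", {
  set.seed(75)
  for (case in 1:5) {
    n <- sample(5:8, 1)
    m <- matrix(rnorm(n * 3), n, 3, dimnames = list(paste0("g", 1:n), NULL))
    parts <- oracle_agglomerate(m)
    for (k in (n - 1):2) {
      cl <- hcluster(m, k = k, scale_rows = FALSE)
      expect_equal(labels_to_partition(cl$labels),
                   canon_partition(parts[[n - k]]),
                   info = paste("case", case, "k", k))
    }
  }
})

test_that("relabeling genes permutes labels without changing the partition", {
  set.seed(76)
  m <- matrix(rnorm(36), 12, 3, dimnames = list(paste0("g", 1:12), NULL))
  cl1 <- hcluster(m, k = 3, scale_rows = FALSE)
  perm <- sample(12)
  cl2 <- hcluster(m[perm, ], k = 3, scale_rows = FALSE)
  expect_equal(labels_to_partition(cl1$labels[rownames(m)]),
               labels_to_partition(cl2$labels[rownames(m)]))
  expect_error(hcluster(m, k = 13), "k must be")
})

test_that("per-cluster mean profiles are the expression model of the cluster", {
  e <- make_expression_matrix(synth_expr_spec(n_genes = 60, n_samples = 6,
                                              k_clusters = 3,
                                              dispersion = 0.02, seed = 77))
  nrm <- median_of_ratios(e$counts)
  cl <- hcluster(nrm$normalized, k = 3)
  expect_equal(dim(cl$profiles), c(3, 6))
  for (c in 1:3) {
    expect_equal(cl$profiles[c, ],
                 colMeans(nrm$normalized[cl$labels == c, , drop = FALSE]))
  }
})

test_that("breadth categories follow the threshold rules", {
  m <- rbind(zero = rep(0, 10),
             constant = rep(5, 10),
             onehot = c(100, rep(0, 9)),
             broad = c(rep(5, 9), 0.5))
  cats <- breadth_classify(m)
  expect_equal(unname(cats["zero"]), "low")
  expect_equal(unname(cats["constant"]), "ubiquitous")
  expect_equal(unname(cats["onehot"]), "tissue-specific")
  expect_equal(unname(cats["broad"]), "intermediate")
  expect_equal(unname(breadth_classify(m, ubiquitous_fraction = 0.9)["broad"]),
               "ubiquitous")
})

test_that("2^-ddCt fold changes match the formula and its invariances", {
  rec <- expand.grid(gene = c("T", "REF"),
                     condition = c("treated", "control"),
                     replicate = 1:2, stringsAsFactors = FALSE)
  rec$role <- ifelse(rec$gene == "REF", "reference", "target")
  rec$Ct <- ifelse(rec$gene == "REF", 20,
                   ifelse(rec$condition == "treated", 25, 24))
  fc <- ddct(rec, calibrator = "control", reference_gene = "REF")
  expect_equal(fc$fold_change[fc$condition == "control"], 1)
  expect_equal(fc$fold_change[fc$condition == "treated"], 0.5) # ddCt = 1
  # replicate means respected to machine precision
  rec2 <- rec; rec2$Ct <- rec2$Ct + c(0.3, -0.3)[rec2$replicate]
  fc2 <- ddct(rec2, "control", "REF")
  expect_equal(fc2$fold_change, fc$fold_change, tolerance = 1e-12)
  # shifting every Ct leaves fold changes unchanged
  rec3 <- rec; rec3$Ct <- rec3$Ct + 3.7
  expect_equal(ddct(rec3, "control", "REF")$fold_change, fc$fold_change,
               tolerance = 1e-12)
  # missing reference Ct for a condition errors
  expect_error(ddct(rec[rec$role == "target" | rec$condition == "control", ],
                    "control", "REF"), "missing reference")
})
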