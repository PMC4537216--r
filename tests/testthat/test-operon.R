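toy_operons <- function() {
  data.frame(operon_id = c("op1", "op1", "op1", "op2", "op2", "op3"),
             gene = paste0("g", 1:6),
             position = c(1, 2, 3, 1, 2, 1),
             start = c(100, 1300, 2600, 5000, 6500, 9000),
             end = c(1000, 2200, 3500, 6000, 7400, 9900),
             strand = "+", stringsAsFactors = FALSE)
}

test_that("operon coherence summarizes pairwise rank correlations", {
  ops <- toy_operons()
  shared <- seq(1, 2, length.out = 9)
  prof <- rbind(g1 = shared, g2 = 3 * shared, g3 = shared + 1,
                g4 = shared, g5 = rev(shared), g6 = shared)
  coh <- operon_coherence(prof, ops)
  expect_equal(coh$coherence[coh$operon_id == "op1"], 1)   # shared shape
  expect_equal(coh$coherence[coh$operon_id == "op2"], -1)  # reversed pair
  expect_equal(coh$n_pairs, c(3, 1))
  expect_equal(attr(coh, "n_skipped"), 1)  # op3 has a single member

  # 3-member hand-set oracle
  set.seed(5)
  prof2 <- rbind(g1 = runif(9), g2 = runif(9), g3 = runif(9))
  ops2 <- ops[1:3, ]
  rho <- c(cor(prof2[1, ], prof2[2, ], method = "spearman"),
           cor(prof2[1, ], prof2[3, ], method = "spearman"),
           cor(prof2[2, ], prof2[3, ], method = "spearman"))
  expect_equal(operon_coherence(prof2, ops2)$coherence, mean(rho))
  expect_equal(operon_coherence(prof2, ops2, stat = "median")$coherence,
               median(rho))
})

test_that("distance table enumerates pairs with clamped genomic gaps", {
  ops <- toy_operons()
  set.seed(6)
  prof <- matrix(runif(6 * 9), 6, 9, dimnames = list(paste0("g", 1:6), NULL))
  dvc <- distance_vs_correlation(prof, ops)
  expect_equal(nrow(dvc$pairs), choose(3, 2) + choose(2, 2))  # 3 + 1
  row12 <- dvc$pairs[dvc$pairs$gene1 == "g1" & dvc$pairs$gene2 == "g2", ]
  expect_equal(row12$distance_bp, 1300 - 1000)
  row13 <- dvc$pairs[dvc$pairs$gene1 == "g1" & dvc$pairs$gene2 == "g3", ]
  expect_equal(row13$distance_bp, 2600 - 1000)
  adj <- distance_vs_correlation(prof, ops, adjacent_only = TRUE)
  expect_equal(nrow(adj$pairs), 2 + 1)

  # identical profiles at zero spread: trend undefined, flagged NA
  prof_same <- matrix(rep(seq_len(9), each = 6), 6, 9,
                      dimnames = list(paste0("g", 1:6), NULL))
  expect_true(is.na(distance_vs_correlation(prof_same, ops)$trend))
})

test_that("overlapping coding regions clamp to distance zero", {
  ops <- data.frame(operon_id = "op", gene = c("a", "b"), position = 1:2,
                    start = c(100, 500), end = c(600, 900), strand = "+")
  prof <- matrix(runif(18), 2, 9, dimnames = list(c("a", "b"), NULL))
  dvc <- distance_vs_correlation(prof, ops)
  expect_equal(dvc$pairs$distance_bp, 0)
})

test_that("k-means recovers separable groups and satisfies SSE contracts", {
  set.seed(7)
  g1 <- matrix(rnorm(20 * 9, 0, 0.05), 20, 9)
  g2 <- matrix(rnorm(20 * 9, 5, 0.05), 20, 9)
  x <- rbind(g1, g2)
  rownames(x) <- paste0("g", 1:40)
  km <- kmeans_profiles(x, 2, seed = 1)
  expect_equal(length(unique(km$cluster[1:20])), 1L)
  expect_equal(length(unique(km$cluster[21:40])), 1L)
  expect_false(km$cluster[1] == km$cluster[21])

  km_n <- kmeans_profiles(x, nrow(x), seed = 1)
  expect_equal(km_n$sse, 0, tolerance = 1e-8)
  expect_error(kmeans_profiles(x, 41, seed = 1), "exceed")

  km_a <- kmeans_profiles(x, 5, seed = 9)
  km_b <- kmeans_profiles(x, 5, seed = 9)
  expect_identical(km_a$cluster, km_b$cluster)
})

test_that("k-means SSE matches an independent Lloyd implementation", {
  set.seed(22)
  x <- matrix(rnorm(200 * 9), 200, 9, dimnames = list(paste0("g", 1:200), NULL))
  centers0 <- x[sample(200, 6), ]
  km <- kmeans_profiles(x, centers0)
  # hand-rolled Lloyd iteration from the same initial centers
  cen <- centers0
  for (iter in 1:100) {
    d2 <- as.matrix(dist(rbind(cen, x)))[1:6, -(1:6)]
    assign <- apply(d2, 2L, which.min)
    new_cen <- t(sapply(1:6, function(k) colMeans(x[assign == k, , drop = FALSE])))
    if (max(abs(new_cen - cen)) < 1e-12) break
    cen <- new_cen
  }
  sse <- sum((x - cen[assign, ])^2)
  expect_equal(km$sse, sse, tolerance = 1e-8)
})

test_that("RNA class fractions sum to one and renormalize without rRNA", {
  counts <- matrix(c(50, 30, 10, 10), 4, 1,
                   dimnames = list(c("a", "b", "c", "d"), NULL))
  cls <- c(a = "mRNA", b = "tRNA", c = "rRNA", d = "ncRNA")
  fr <- rna_fractions(counts, cls)
  expect_equal(as.vector(fr), c(0.5, 0.3, 0.1, 0.1))
  fr2 <- rna_fractions(counts, cls, drop_residual_rrna = TRUE)
  expect_equal(as.vector(fr2), c(5, 3, 1) / 9)

  set.seed(30)
  big <- matrix(rpois(40 * 6, 20), 40, 6,
                dimnames = list(paste0("g", 1:40), NULL))
  cls_big <- setNames(sample(c("mRNA", "tRNA", "rRNA", "ncRNA"), 40, TRUE),
                      rownames(big))
  frb <- rna_fractions(big, cls_big)
  expect_true(all(abs(colSums(frb) - 1) < 1e-12))
  # invariance to uniform per-sample scaling
  big2 <- sweep(big, 2L, c(1, 2, 3, 4, 5, 6), "*")
  expect_equal(rna_fractions(big2, cls_big), frb, tolerance = 1e-12)

  expect_error(rna_fractions(counts, cls[1:3]), "class")
})
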