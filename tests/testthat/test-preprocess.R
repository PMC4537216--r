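make_pm <- function(counts3d, time_h = NULL) {
  if (is.null(time_h)) time_h <- seq_len(dim(counts3d)[2L]) + 2
  profile_matrix(counts3d, time_h)
}

test_that("low-count filter applies the inclusive total-count rule", {
  counts <- array(0, c(3, 3, 2), dimnames = list(c("a", "b", "c"), NULL, NULL))
  counts["a", , ] <- 9 / 6    # total 9 -> removed
  counts["b", , ] <- 10 / 6   # total 10 -> retained
  counts["c", , ] <- 5        # comfortably retained
  pm <- make_pm(counts)
  kept <- filter_low_counts(pm, 10)
  expect_identical(genes(kept), c("b", "c"))
  expect_warning(filter_low_counts(pm, 1e9), "below")
})

test_that("depth normalization makes every sample sum to one", {
  counts <- array(c(2, 3, 5), c(3, 1, 1), dimnames = list(letters[1:3], NULL, NULL))
  pm <- make_pm(counts)
  expect_equal(as.vector(depth_normalize(pm)$counts), c(0.2, 0.3, 0.5))

  set.seed(4)
  big <- array(rpois(50 * 9 * 3, 40), c(50, 9, 3),
               dimnames = list(paste0("g", 1:50), NULL, NULL))
  norm <- depth_normalize(make_pm(big, the_grid))
  sums <- apply(norm$counts, c(2L, 3L), sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  # scale equivariance: multiplying one sample's counts changes nothing
  big2 <- big
  big2[, 4L, 2L] <- big2[, 4L, 2L] * 7
  norm2 <- depth_normalize(make_pm(big2, the_grid))
  expect_equal(norm$counts, norm2$counts, tolerance = 1e-12)
})

test_that("a zero-total sample is reported by name", {
  counts <- array(1, c(2, 2, 2), dimnames = list(c("a", "b"), NULL, NULL))
  counts[, 2L, 1L] <- 0
  expect_error(depth_normalize(make_pm(counts, c(3, 24))), "24")
})

test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(10, 20, 30, 40, 50,
                10, 20, 30, 40, 50), ncol = 2)
  expect_equal(size_factors_median_ratio(m), c(1, 1))
  m2 <- cbind(m[, 1L], 2 * m[, 1L])
  sf <- size_factors_median_ratio(m2)
  expect_equal(sf[2L] / sf[1L], 2, tolerance = 1e-12)

  set.seed(12)
  toy <- matrix(rpois(15, 60) + 1, 5, 3)
  # brute-force oracle: explicit loops over the definition
  geo <- exp(rowMeans(log(toy)))
  oracle <- numeric(3)
  for (s in 1:3) oracle[s] <- median(toy[, s] / geo)
  expect_equal(size_factors_median_ratio(toy), oracle, tolerance = 1e-12)
})

test_that("size factors agree with the established reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(33)
  toy <- matrix(rpois(60, 50) + 1, 10, 6)
  ref <- DESeq2::estimateSizeFactorsForMatrix(toy)
  expect_equal(unname(size_factors_median_ratio(toy)), unname(ref),
               tolerance = 1e-8)
})

test_that("size factors require a gene observed everywhere", {
  m <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(size_factors_median_ratio(m), "pseudocount")
})

test_that("fold-change filter keeps exactly the truly changing genes", {
  flat <- rep(1, 9)
  boundary <- c(rep(1, 8), 1.5)
  d <- rbind(flat = flat, boundary = boundary)
  expect_identical(fold_change_filter(d, 1.5), "boundary")

  set.seed(21)
  n <- 100
  fc_true <- c(runif(40, 1.6, 8), runif(60, 1.0, 1.4))
  profiles <- t(sapply(fc_true, function(f) seq(1, f, length.out = 9)))
  rownames(profiles) <- paste0("g", 1:n)
  kept <- fold_change_filter(profiles, 1.5)
  expect_setequal(kept, paste0("g", 1:40))
})

test_that("significance filter keeps changed genes and drops constant ones", {
  # a majority of stable genes pins the size factors; one gene steps 10x
  counts <- array(rep(c(50, 80, 120, 200, 100, 60, 90, 150, 110, 100),
                      4 * 3),
                  c(10, 4, 3),
                  dimnames = list(c(paste0("still", 1:9), "step"),
                                  NULL, NULL))
  counts["step", 3:4, ] <- 1000  # 10-fold noiseless step
  pm <- make_pm(counts, c(3, 4, 5, 6))
  kept <- significance_filter_rna(pm)
  expect_identical(as.character(kept), "step")
  expect_error(significance_filter_rna(
    make_pm(array(1, c(2, 2, 1)), c(3, 4))), "replicates")
})

test_that("replicate averaging matches a two-pass oracle with a floored SD", {
  counts <- array(c(1, 1, 1), c(1, 1, 3), dimnames = list("a", NULL, NULL))
  ap <- average_replicates(make_pm(counts, 3))
  expect_equal(unname(ap$d[1L, 1L]), 1)
  expect_equal(unname(ap$sigma[1L, 1L]), max(1e-6, 0.01 * 1))  # floored

  counts2 <- array(c(0, 1, 2), c(1, 1, 3), dimnames = list("a", NULL, NULL))
  ap2 <- average_replicates(make_pm(counts2, 3))
  expect_equal(unname(ap2$d[1L, 1L]), 1)
  expect_equal(unname(ap2$sigma[1L, 1L]), 1)

  set.seed(14)
  big <- array(rlnorm(20 * 9 * 3), c(20, 9, 3),
               dimnames = list(paste0("g", 1:20), NULL, NULL))
  ap3 <- average_replicates(make_pm(big, the_grid))
  for (g in 1:20) for (j in 1:9) {
    x <- big[g, j, ]
    floor_g <- max(1e-6, 0.01 * mean(apply(big[g, , , drop = FALSE], 2, mean)))
    expect_equal(unname(ap3$d[g, j]), mean(x), tolerance = 1e-12)
    expect_equal(unname(ap3$sigma[g, j]),
                 max(sd(x), floor_g), tolerance = 1e-12)
  }
})

test_that("max normalization peaks at one and is idempotent", {
  expect_equal(max_normalize(c(2, 4, 8)), c(0.25, 0.5, 1))
  v <- runif(9)
  expect_equal(max_normalize(max_normalize(v)), max_normalize(v))
  expect_error(max_normalize(c(0, 0, 0)), "all-zero")

  ap <- structure(list(d = rbind(a = c(2, 4, 8)), sigma = rbind(a = c(1, 1, 1)),
                       time_h = c(3, 4, 5), normalization = "depth"),
                  class = "averaged_profiles")
  mx <- max_normalize(ap)
  expect_equal(unname(mx$d[1L, ]), c(0.25, 0.5, 1))
  expect_equal(unname(mx$sigma[1L, ]), c(1, 1, 1) / 8)
})

test_that("length normalization divides counts by gene length", {
  expect_equal(length_normalize(300, 1500), 0.2)
  m <- matrix(c(300, 150, 600, 300), 2)
  expect_equal(length_normalize(m, c(1500, 300)),
               matrix(c(0.2, 0.5, 0.4, 1), 2))
  expect_error(length_normalize(1, 0), "> 0")
})
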