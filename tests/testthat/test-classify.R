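test_that("member behavior rule covers the category definitions", {
  trip <- function(a1, a2, a3) c(0, 1, 0, 330, a1, a2, a3)
  cases <- list(
    list(trip(0, 1, 1), "up"),            # rose, never fell
    list(trip(0, 1, 0), "transient_up"),  # rose then fell
    list(trip(1, 0.5, 0), "down"),        # two successive decreases
    list(trip(1, 0, 1), "transient_down"),
    list(trip(0.5, 0.5, 0.5), "flat"),
    list(trip(0.5, 0.55, 0.5), "flat"),   # within delta both ways
    list(trip(0.5, 0.5, 1), "up"),        # late rise only
    list(trip(0.5, 0.5, 0), "down")       # late fall only
  )
  for (cs in cases)
    expect_identical(call_member_behavior(cs[[1]], 0.1), cs[[2]])
  # boundary: a change of exactly delta is not significant
  expect_identical(call_member_behavior(trip(0.5, 0.6, 0.5), 0.1), "flat")
  expect_error(call_member_behavior(trip(0, 1, 1), -1), ">= 0")
})

test_that("gene call carries ensemble agreement and respects its threshold", {
  d <- evaluate_piecewise(c(2, 3, 30, 200, 0.2, 1, 1), the_grid, t0 = 3)
  up_member <- c(2, 3, 30, 200, 0.2, 1, 1)
  tup_member <- c(2, 3, 30, 100, 0.2, 1, 0.1)
  # unanimous ensemble
  ens <- fake_ensemble(rbind(up_member, up_member, up_member),
                       d = d, sigma = rep(10, 9))
  call <- call_gene_behavior(ens, delta = 0.05)
  expect_identical(call$category, "up")
  expect_equal(call$agreement, 1)
  # 50/50 split between up and transient_up -> ambiguous at 0.9
  ens2 <- fake_ensemble(rbind(up_member, tup_member),
                        d = d, sigma = rep(10, 9))
  call2 <- call_gene_behavior(ens2, delta = 0.05, agreement_min = 0.9)
  expect_identical(call2$category, "ambiguous")
  expect_equal(call2$agreement, 0.5)
  # no good fits -> ambiguous
  ens3 <- fake_ensemble(rbind(up_member), d = d + 100,
                        sigma = rep(0.01, 9))
  expect_identical(call_gene_behavior(ens3)$category, "ambiguous")
})

test_that("raising the agreement threshold is monotonically conservative", {
  d <- evaluate_piecewise(c(2, 3, 30, 200, 0.2, 1, 1), the_grid, t0 = 3)
  members <- rbind(matrix(rep(c(2, 3, 30, 200, 0.2, 1, 1), 4), 4, byrow = TRUE),
                   c(2, 3, 30, 100, 0.2, 1, 0.1))
  ens <- fake_ensemble(members, d = d, sigma = rep(10, 9))
  for (lo in c(0.5, 0.7)) for (hi in c(0.8, 0.95)) {
    if (hi <= lo) next
    c_lo <- call_gene_behavior(ens, delta = 0.05, agreement_min = lo)
    c_hi <- call_gene_behavior(ens, delta = 0.05, agreement_min = hi)
    if (c_lo$category == "ambiguous")
      expect_identical(c_hi$category, "ambiguous")
    else
      expect_true(c_hi$category %in% c(c_lo$category, "ambiguous"))
  }
})

test_that("classification is exhaustive and exclusive over a cohort", {
  cfg <- synthetic_config(n_genes = 40, seed = 2)
  ds <- simulate_dataset(cfg)
  mrna <- ds$truth$gene[ds$truth$rna_class == "mRNA"]
  pm <- simulate_replicate_profiles(ds$m_levels[mrna, ], cfg$time_grid,
                                    cv = 0.1, seed = 2)
  fits <- fit_profiles(max_normalize(average_replicates(pm)),
                       de_config(restarts = 5L), seed = 3)
  calls <- classify_genes(fits)
  expect_identical(sort(calls$gene), sort(mrna))
  expect_true(all(calls$category %in%
                    c("up", "down", "transient_up", "transient_down",
                      "flat", "ambiguous")))
  expect_true(all(calls$agreement >= 0 & calls$agreement <= 1))
})

test_that("hypergeometric enrichment matches the exact tail oracle", {
  calls <- data.frame(gene = paste0("g", 1:1000),
                      category = rep(c("up", "down"), c(30, 970)))
  sets <- list(
    same = paste0("g", 1:30),                      # identical to category
    disjoint = paste0("g", 500:539),
    partial = paste0("g", c(1:10, 101:130))        # 10 in, 30 out
  )
  enr <- enrich_categories(calls, sets)
  up <- enr[enr$category == "up", ]
  expect_lt(up$p[up$set == "same"], 1e-10)
  expect_equal(up$p[up$set == "disjoint"], 1)
  # 2x2 oracle: universe 1000, category 30, set 40, overlap 10
  oracle <- sum(dhyper(10:30, 40, 960, 30))
  expect_equal(up$p[up$set == "partial"], oracle, tolerance = 1e-12)
  expect_true(all(enr$q >= enr$p - 1e-12))
})

test_that("empty categories yield no rows rather than an error", {
  calls <- data.frame(gene = "g1", category = "up")
  enr <- enrich_categories(calls, list(s = "g1"))
  expect_identical(unique(enr$category), "up")
})

test_that("pathway averaging flags mutually cancelling sets", {
  rising <- seq(0, 1, length.out = 9)
  prof <- rbind(r1 = rising, r2 = rising, f1 = 1 - rising)
  pa <- pathway_average(prof, list(consistent = c("r1", "r2"),
                                   cancelling = c("r1", "f1")),
                        flat_threshold = 0.2)
  expect_equal(unname(pa$mean_profiles["consistent", ]), rising)
  expect_false(pa$flat[["consistent"]])
  expect_true(pa$flat[["cancelling"]])

  set.seed(9)
  prof2 <- matrix(runif(27), 3, 9, dimnames = list(c("a", "b", "c"), NULL))
  sets <- list(s1 = c("a", "b"), s2 = c("b", "c"), s3 = c("a", "b", "c"))
  pa2 <- pathway_average(prof2, sets)
  for (s in names(sets))
    expect_equal(unname(pa2$mean_profiles[s, ]),
                 colMeans(prof2[sets[[s]], , drop = FALSE]),
                 tolerance = 1e-12)
})
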