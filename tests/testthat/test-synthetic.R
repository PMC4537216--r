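test_that("drawn parameter sets realize their intended categories", {
  set.seed(13)
  cfg <- synthetic_config(n_genes = 200)
  tp <- sample_true_profiles(cfg, 200)
  pm <- do.call(rbind, lapply(tp$params, as.numeric))
  # with a vanishing change threshold, the classifier recovers the label
  expect_identical(call_member_behavior(pm, 0), tp$category)
  # forced shapes
  flat <- pm[tp$category == "flat", , drop = FALSE]
  expect_true(all(flat[, 5L] == flat[, 6L] & flat[, 6L] == flat[, 7L]))
  tu <- pm[tp$category == "transient_up", , drop = FALSE]
  expect_true(all(tu[, 6L] > tu[, 5L] & tu[, 7L] < tu[, 6L]))
  # knots stay inside the sampling window
  expect_true(all(3 + pm[, 1L] + pm[, 2L] + pm[, 3L] + pm[, 4L] <= 336))
})

test_that("category frequencies match the mix (exact binomial, alpha 0.01)", {
  set.seed(1)
  cfg <- synthetic_config(n_genes = 600)
  tp <- sample_true_profiles(cfg, 600)
  for (cat_name in names(cfg$category_mix)) {
    pv <- binom.test(sum(tp$category == cat_name), 600,
                     cfg$category_mix[[cat_name]])$p.value
    expect_gt(pv, 0.01)
  }
})

test_that("protein kinetics with k_d = 0 reduce to the transcript integral", {
  p <- piecewise_params(2, 5, 10, 30, 1, 0.2, 0.6, t0 = 3)
  grid <- sort(unique(c(the_grid, 3 + cumsum(as.numeric(p)[1:4]))))
  m <- evaluate_piecewise(p, grid)
  got <- simulate_protein_dynamics(p, k_s = 2, k_d = 0, p0 = 1.5, grid)
  expect_equal(got, 1.5 + 2 * cumulative_integral(m, grid),
               tolerance = 1e-12)
})

test_that("constant transcript drives the protein to k_s*c/k_d", {
  p <- piecewise_params(0, 0, 0, 0, 0.7, 0.7, 0.7, t0 = 3)
  got <- simulate_protein_dynamics(p, k_s = 3, k_d = 0.5, p0 = 0,
                                   c(3, 10, 100, 5000))
  expect_equal(got[4L], 3 * 0.7 / 0.5, tolerance = 1e-6)
})

test_that("closed-form kinetics match a fine-step numerical integrator", {
  skip_if_not_installed("deSolve")
  # ramp from 1 to 2 over [3, 8] h, then flat at 2
  p <- piecewise_params(0, 5, 0, 0, 1, 2, 2, t0 = 3)
  grid <- c(3, 4, 5, 6, 8)
  got <- simulate_protein_dynamics(p, k_s = 1, k_d = 0.5, p0 = 0, grid)
  rhs <- function(t, y, parms)
    list(1 * evaluate_piecewise(p, t) - 0.5 * y)
  ref <- deSolve::ode(c(p = 0), seq(3, 8, by = 0.001), rhs, NULL,
                      method = "rk4")
  ref_at <- ref[match(grid, ref[, 1L]), 2L]
  expect_equal(got, unname(ref_at), tolerance = 1e-6)
})

test_that("negative rates are a domain error", {
  p <- piecewise_params(1, 1, 1, 1, 1, 1, 1, t0 = 3)
  expect_error(simulate_protein_dynamics(p, -1, 0, 0, the_grid), ">= 0")
  expect_error(simulate_protein_dynamics(p, 1, -0.1, 0, the_grid), ">= 0")
})

test_that("protein trajectories stay nonnegative for random valid inputs", {
  set.seed(17)
  for (i in 1:50) {
    th <- random_params(1)[1L, ]
    p <- piecewise_params(th[1], th[2], th[3], th[4], th[5], th[6], th[7],
                          t0 = 3)
    got <- simulate_protein_dynamics(p, runif(1, 0, 5), runif(1, 0, 2),
                                     runif(1, 0, 3), the_grid)
    expect_true(all(got >= 0))
  }
})

test_that("count simulation is seed-reproducible and respects zero levels", {
  cfg <- synthetic_config(n_genes = 4, seed = 8, depth = 1e5)
  levels <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5), g3 = c(0, 0, 0),
                  g4 = c(2, 0, 1))
  cfg$time_grid <- c(3, 4, 5)
  a <- simulate_counts(levels, cfg)
  b <- simulate_counts(levels, cfg)
  expect_identical(a$counts, b$counts)
  expect_true(all(a$counts["g3", , ] == 0))
  expect_true(all(a$counts >= 0))
})

test_that("adding genes with zero mass does not perturb existing streams", {
  cfg <- synthetic_config(n_genes = 3, seed = 8, depth = 1e5)
  cfg$time_grid <- c(3, 4, 5)
  levels <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5), g3 = c(2, 1, 0))
  levels2 <- rbind(levels, g4 = c(0, 0, 0), g5 = c(0, 0, 0))
  a <- simulate_counts(levels, cfg)
  b <- simulate_counts(levels2, cfg)
  expect_identical(a$counts, b$counts[1:3, , , drop = FALSE])
})

test_that("near-Poisson counts at high depth have small replicate CV", {
  cfg <- synthetic_config(n_genes = 20, seed = 3, depth = 1e7,
                          dispersion = 0, n_replicates = 10L)
  cfg$time_grid <- c(3, 4, 5)
  set.seed(3)
  levels <- matrix(rlnorm(60, 0, 1), 20, 3,
                   dimnames = list(paste0("g", 1:20), NULL))
  pm <- simulate_counts(levels, cfg)
  rel <- sweep(levels, 2L, colSums(levels), "/")
  mu <- apply(pm$counts, c(1L, 2L), mean)
  cv <- apply(pm$counts, c(1L, 2L), sd) / mu
  big <- rel >= 1e-3
  expect_true(all(cv[big] < 0.02))  # Poisson CV 1/sqrt(mean) ~ 1%
})

test_that("proportional and integral regimes satisfy their rank signatures", {
  cfg <- synthetic_config(n_genes = 150, seed = 6,
                          category_mix = nonflat_mix,
                          operon_size_dist = c("1" = 1))
  ds <- simulate_dataset(cfg)
  tr <- ds$truth
  grid <- cfg$time_grid
  for (g in which(tr$regulation == "proportional")) {
    rho <- suppressWarnings(cor(ds$p_levels[g, ], ds$m_levels[g, ],
                                method = "spearman"))
    expect_gte(rho, 0.99)
  }
  for (g in which(tr$regulation == "integral")) {
    M <- cumulative_integral(ds$m_levels[g, ], grid)
    expect_equal(cor(ds$p_levels[g, ], M, method = "spearman"), 1)
  }
})

test_that("operon structure groups genes with shared shapes and coordinates", {
  set.seed(19)
  cfg <- synthetic_config(n_genes = 100, seed = 19)
  os <- build_operon_structure(cfg)
  op <- os$operons
  expect_equal(nrow(op), 100)
  expect_true(all(op$end > op$start))
  # coordinates are non-overlapping and ordered
  expect_true(all(diff(op$start) > 0))
  expect_true(all(op$start[-1L] > op$end[-nrow(op)]))
  expect_true(all(os$efficiency > 0))
  # dataset-level: members of one operon share the mRNA shape up to scale
  ds <- simulate_dataset(synthetic_config(n_genes = 60, seed = 19,
                                          category_mix = nonflat_mix,
                                          operon_size_dist = c("3" = 1)))
  for (oid in unique(ds$operons$operon_id)) {
    idx <- which(ds$operons$operon_id == oid)
    base <- ds$m_levels[idx[1L], ]
    for (j in idx[-1L]) {
      ratio <- ds$m_levels[j, ] / base
      expect_lt(diff(range(ratio)), 1e-9 * mean(ratio))
    }
  }
})

test_that("zero distance noise leaves co-operonic proportional proteins identical in rank", {
  cfg <- synthetic_config(n_genes = 30, seed = 23,
                          category_mix = nonflat_mix,
                          operon_size_dist = c("3" = 1),
                          distance_noise = 0,
                          regulation_mix = c(proportional = 1, integral = 0,
                                             intermediate = 0))
  ds <- simulate_dataset(cfg)
  coh <- operon_coherence(ds$p_levels, ds$operons)
  expect_true(all(abs(coh$coherence - 1) < 1e-12))
})

test_that("replicate-profile noise layer has the requested CV", {
  set.seed(2)
  levels <- matrix(rep(10, 9 * 4), 4, 9,
                   dimnames = list(paste0("g", 1:4), NULL))
  pm <- simulate_replicate_profiles(levels, the_grid, cv = 0.2,
                                    n_replicates = 200L, seed = 2)
  cv_hat <- apply(pm$counts, c(1L, 2L), sd) / apply(pm$counts, c(1L, 2L), mean)
  expect_equal(mean(cv_hat), 0.2, tolerance = 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(category_mix = c(up = 0.5, down = 0.4)),
               "sum to 1")
  expect_error(synthetic_config(regulation_mix = c(proportional = 1,
                                                   integral = 0.5,
                                                   intermediate = -0.5)),
               "nonnegative")
  expect_error(synthetic_config(n_replicates = 1), "n_replicates")
  expect_error(synthetic_config(time_grid = c(3, 2, 5)), "increasing")
})
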