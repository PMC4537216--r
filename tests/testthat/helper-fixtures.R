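# Shared fixtures, built in code.

the_grid <- c(3, 4, 5, 6, 8, 24, 48, 168, 336)

# Random valid parameter draws inside the search box of the default grid.
random_params <- function(n, t0 = 3, tspan = 333) {
  t(replicate(n, {
    tt <- runif(4, 0, tspan / 4)
    c(tt, runif(3, 0, 1.5))
  }))
}

# Independent piecewise-curve oracle: linear interpolation through the knot
# nodes (the curve is linear between knots and flat outside them).
oracle_piecewise <- function(th, t, t0) {
  k <- t0 + cumsum(th[1:4])
  nodes_t <- c(t0, k)
  nodes_v <- c(th[5], th[5], th[6], th[6], th[7])
  dup <- duplicated(nodes_t)
  out <- approx(nodes_t[!dup], nodes_v[!dup], xout = pmin(t, k[4]),
                rule = 2)$y
  # degenerate: all four knots at t0 -> terminal plateau everywhere
  if (all(dup[-1])) out <- ifelse(t <= t0, th[5], th[7])
  out
}

# A hand-built fit ensemble around given data (all members good by
# construction unless stated otherwise).
fake_ensemble <- function(params, d, sigma, time_h = the_grid) {
  structure(list(params = params, cost = rep(0, nrow(params)),
                 t0 = time_h[1L], time_h = time_h, d = d, sigma = sigma,
                 traces = list(), fit_mean = NULL, fit_sd = NULL,
                 config = de_config()),
            class = "fit_ensemble")
}

# Nonflat category mix used for cohorts where flat transcripts would carry
# no rank information.
nonflat_mix <- c(up = 0.05, down = 0.60, transient_up = 0.25,
                 transient_down = 0.10, flat = 0)

# Preprocessing shortcut used across tests: low-count filter, depth
# normalization, replicate averaging, max normalization.
quick_preprocess <- function(pm) {
  max_normalize(average_replicates(depth_normalize(filter_low_counts(pm))))
}
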