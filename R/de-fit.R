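#' Differential-evolution fitter configuration
#'
#' Settings for the population-based differential-evolution (DE) optimizer
#' used to fit the piecewise profile.  The defaults are an ensemble of 15
#' agents, a crossover frequency of 0.75 and a mixing strength of 0.6.  The
#' crossover frequency is the probability that a coordinate of an agent is
#' replaced in a given recombination; the mixing strength scales the
#' difference vector added during mutation.  Only recombinations that do not
#' increase the error-scaled cost are kept (greedy selection), so the best
#' cost is non-increasing across iterations.
#'
#' @param agents Population size (>= 4).
#' @param crossover Crossover frequency CR in \[0, 1\].
#' @param mixing Mixing strength (differential weight) F.
#' @param restarts Number of independent DE runs pooled into the final
#'   "population of fits" from which confidence information is drawn.
#' @param max_iter Iteration cap per restart.
#' @param reltol,patience Stop a restart early once the relative improvement
#'   of the best cost over `patience` iterations falls below `reltol`.
#' @param amp_factor Upper amplitude bound as a multiple of `max(d)`.
#' @return A list of class `"de_config"`.
#' @export
de_config <- function(agents = 15L, crossover = 0.75, mixing = 0.6,
                      restarts = 20L, max_iter = 2000L, reltol = 1e-6,
                      patience = 100L, amp_factor = 1.5) {
  stopifnot(agents >= 4L, crossover >= 0, crossover <= 1, mixing > 0,
            restarts >= 1L, max_iter >= 1L, reltol > 0, patience >= 1L,
            amp_factor > 0)
  structure(list(agents = as.integer(agents), crossover = crossover,
                 mixing = mixing, restarts = as.integer(restarts),
                 max_iter = as.integer(max_iter), reltol = reltol,
                 patience = as.integer(patience), amp_factor = amp_factor),
            class = "de_config")
}

#' Fit the piecewise profile with differential evolution
#'
#' Runs `config$restarts` independent DE/rand/1/bin searches over the
#' seven-parameter box (durations in `[0, T - t0]`, amplitudes in
#' `[0, amp_factor * max(d)]`, with the summed durations bounded by the span
#' of the grid) and pools the final populations.  The pooled population,
#' filtered to good fits, is the source of parameter confidence intervals
#' and of the behavior votes used by [call_gene_behavior()].
#'
#' @param d Replicate-mean profile at the grid times.
#' @param sigma Replicate SD at the grid times (strictly positive; floored
#'   upstream by [average_replicates()]).
#' @param time_h Sampling times in hours (strictly increasing); the origin
#'   `t0` is fixed at `time_h[1]`.
#' @param config A [de_config()].
#' @param seed Optional integer seed applied via [set.seed()] before the
#'   search; with a fixed seed the fit is bit-reproducible.
#' @return An object of class `"fit_ensemble"`: a list with `params`
#'   (members x 7 matrix, sorted by cost), `cost`, `t0`, `time_h`, `d`,
#'   `sigma`, `traces` (per-restart best-cost traces), `fit_mean`/`fit_sd`
#'   (per-time mean and SD of the member curves) and `config`.
#' @export
fit_profile_de <- function(d, sigma, time_h, config = de_config(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(d) == length(sigma), length(d) == length(time_h),
            length(d) >= 3L)
  if (any(!is.finite(d)) || any(!is.finite(sigma)))
    stop("non-finite values in profile data")
  if (any(diff(time_h) <= 0)) stop("time_h must be strictly increasing")
  t0 <- time_h[1L]
  tspan <- time_h[length(time_h)] - t0
  amax <- config$amp_factor * max(d, 1e-12)
  lower <- rep(0, 7)
  upper <- c(rep(tspan, 4), rep(amax, 3))
  res <- de_fit_cpp(as.numeric(d), as.numeric(sigma), as.numeric(time_h),
                    t0, lower, upper, config$agents, config$crossover,
                    config$mixing, config$max_iter, config$restarts,
                    config$reltol, config$patience)
  ord <- order(res$cost)
  params <- res$params[ord, , drop = FALSE]
  colnames(params) <- c("t1", "t2", "t3", "t4", "A1", "A2", "A3")
  curves <- member_curves(params, time_h, t0)
  structure(list(params = params, cost = res$cost[ord], t0 = t0,
                 time_h = time_h, d = d, sigma = sigma,
                 traces = res$traces,
                 fit_mean = colMeans(curves),
                 fit_sd = apply(curves, 2L, stats::sd),
                 config = config),
            class = "fit_ensemble")
}

# Evaluate every member's curve at the grid times: members x times matrix.
member_curves <- function(params, time_h, t0) {
  t(apply(params, 1L, function(th) evaluate_piecewise(th, time_h, t0 = t0)))
}

#' @export
print.fit_ensemble <- function(x, ...) {
  cat("DE fit ensemble:", nrow(x$params), "members,",
      length(x$traces), "restarts\n")
  cat("best cost:", format(x$cost[1L]), "\n")
  cat("best params:\n")
  print(x$params[1L, ])
  invisible(x)
}

#' Identify ensemble members that fit the data well
#'
#' A member is a good fit if it is on average, across the time course, one
#' replicate standard deviation or less away from the replicate average:
#' `mean_j |d_j - s_j| / sigma_j <= 1`.  The boundary is inclusive.
#'
#' @param ensemble A [fit_profile_de()] result.
#' @param d,sigma Optional data overriding those stored in the ensemble.
#' @return Logical vector over members; `TRUE` marks good fits.  If no
#'   member qualifies the vector is all-`FALSE` (the gene is later called
#'   ambiguous).
#' @export
good_fit_mask <- function(ensemble, d = ensemble$d, sigma = ensemble$sigma) {
  curves <- member_curves(ensemble$params, ensemble$time_h, ensemble$t0)
  dev <- sweep(abs(sweep(curves, 2L, d)), 2L, sigma, "/")
  rowMeans(dev) <= 1
}

#' Summarize response timescales across fitted genes
#'
#' For each gene the point estimate of a timescale is the average over its
#' good-fit members.  `t1` is the time to the first inflection;
#' `t_response = t2 + t3 + t4` is the time from the first inflection until
#' the profile levels off.  Genes without any good fit, and (optionally)
#' genes called flat -- which have no inflection -- are excluded.
#'
#' @param ensembles Named list of `fit_ensemble` objects.
#' @param exclude Character vector of gene names to drop (e.g. flat or
#'   ambiguous calls).
#' @return A data frame with columns `gene`, `t1`, `t_response`,
#'   `good_fraction`.
#' @export
summarize_timescales <- function(ensembles, exclude = character()) {
  keep <- setdiff(names(ensembles), exclude)
  rows <- lapply(keep, function(g) {
    e <- ensembles[[g]]
    ok <- good_fit_mask(e)
    if (!any(ok)) return(NULL)
    p <- e$params[ok, , drop = FALSE]
    data.frame(gene = g, t1 = mean(p[, 1L]),
               t_response = mean(p[, 2L] + p[, 3L] + p[, 4L]),
               good_fraction = mean(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), t1 = numeric(),
                      t_response = numeric(), good_fraction = numeric())
  rownames(out) <- NULL
  out
}

#' Fit many genes
#'
#' Convenience wrapper running [fit_profile_de()] over the rows of an
#' averaged-profile set.  Per-gene seeds are derived deterministically from
#' `seed` so the fit of one gene does not depend on which other genes are
#' present.
#'
#' @param profiles An `averaged_profiles` object (see
#'   [average_replicates()]).
#' @param config A [de_config()].
#' @param seed Master integer seed.
#' @return Named list of `fit_ensemble` objects.
#' @export
fit_profiles <- function(profiles, config = de_config(), seed = 1L) {
  genes <- rownames(profiles$d)
  out <- vector("list", length(genes))
  names(out) <- genes
  for (i in seq_along(genes)) {
    out[[i]] <- fit_profile_de(profiles$d[i, ], profiles$sigma[i, ],
                               profiles$time_h, config = config,
                               seed = derive_seed(seed, i))
  }
  out
}

# Deterministic per-unit substream seed below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483587)
}
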