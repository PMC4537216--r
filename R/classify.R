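#' Behavior category of a single parameter set
#'
#' Sorts one (or many) piecewise parameter sets into the behavioral
#' categories using the two amplitude changes `A2 - A1` and `A3 - A2`
#' against a change threshold `delta`.  A gene is up- (down-)regulated if it
#' significantly increased (decreased) at some point and did not
#' significantly decrease (increase) later; transiently up- (down-)
#' regulated if a significant increase (decrease) is followed by a
#' significant decrease (increase); and flat if neither change is
#' significant.
#'
#' @param params A [piecewise_params()] object, a numeric vector
#'   `(t1..t4, A1..A3)`, or a members x 7 matrix.
#' @param delta Change threshold on the amplitude scale, `>= 0`.
#' @return Character vector over rows: one of `up`, `down`, `transient_up`,
#'   `transient_down`, `flat`.
#' @export
call_member_behavior <- function(params, delta) {
  if (delta < 0) stop("delta must be >= 0")
  m <- if (is.matrix(params)) params else matrix(as.numeric(params), 1L)
  behavior_from_amplitudes(m[, 5L], m[, 6L], m[, 7L], delta)
}

# The category rule on an (initial, middle, final) amplitude triple.
behavior_from_amplitudes <- function(A1, A2, A3, delta) {
  d12 <- A2 - A1
  d23 <- A3 - A2
  out <- character(length(d12))
  flat12 <- abs(d12) <= delta
  flat23 <- abs(d23) <= delta
  out[flat12 & flat23] <- "flat"
  out[d12 > delta & d23 < -delta] <- "transient_up"
  out[d12 < -delta & d23 > delta] <- "transient_down"
  out[d12 > delta & d23 >= -delta] <- "up"
  out[flat12 & d23 > delta] <- "up"
  out[d12 < -delta & d23 <= delta] <- "down"
  out[flat12 & d23 < -delta] <- "down"
  out
}

# Effective amplitude triple of a member: its curve evaluated at the
# sampling grid -- initial level, interior extremum (only if one is
# actually observed at a grid time), final level.  The raw A2 parameter is
# unconstrained whenever the middle plateau falls between sampling times,
# so votes based on it would reflect an unidentifiable coordinate rather
# than the fitted trajectory.
effective_amplitudes <- function(params, time_h, t0, delta = 0) {
  curves <- member_curves(params, time_h, t0)
  n <- ncol(curves)
  A1 <- curves[, 1L]
  A3 <- curves[, n]
  hi <- apply(curves, 1L, max)
  lo <- apply(curves, 1L, min)
  ends_hi <- pmax(A1, A3)
  ends_lo <- pmin(A1, A3)
  # interior extremum if the grid sees one clearing the change threshold;
  # otherwise a between-ends value (the midpoint), which makes both deltas
  # share the sign of A3 - A1
  A2 <- (A1 + A3) / 2
  peak <- hi - ends_hi
  trough <- ends_lo - lo
  use_peak <- peak > delta & peak >= trough
  use_trough <- trough > delta & trough > peak
  A2[use_peak] <- hi[use_peak]
  A2[use_trough] <- lo[use_trough]
  cbind(A1 = A1, A2 = A2, A3 = A3)
}

#' Behavior call for a fitted gene with ensemble-agreement confidence
#'
#' Each good-fit member of the DE ensemble votes for a category via
#' [call_member_behavior()]; the gene receives the majority category,
#' together with the fraction of members that agree.  If no member fits
#' well, or the agreement falls below `agreement_min`, the gene is called
#' ambiguous.  The default change threshold ties "significant change" to
#' the measured replicate noise: the median over time of the gene's
#' replicate SD.
#'
#' Votes are cast on each member's *effective* amplitudes -- its curve
#' evaluated at the sampling grid (initial level, interior extremum where
#' one is observed, final level) -- rather than on the raw `A2` parameter,
#' which is unconstrained whenever the middle plateau falls between
#' sampling times.
#'
#' @param ensemble A [fit_profile_de()] result.
#' @param delta Change threshold; `NULL` uses `median(ensemble$sigma)`.
#' @param agreement_min Minimum agreement for a definite call.
#' @return A list of class `"behavior_call"`: `category`, `agreement`,
#'   `delta`, `votes` (named vote counts).
#' @export
call_gene_behavior <- function(ensemble, delta = NULL,
                               agreement_min = 0.9) {
  if (is.null(delta)) delta <- stats::median(ensemble$sigma)
  ok <- good_fit_mask(ensemble)
  if (!any(ok)) {
    return(structure(list(category = "ambiguous", agreement = 0,
                          delta = delta, votes = integer()),
                     class = "behavior_call"))
  }
  eff <- effective_amplitudes(ensemble$params[ok, , drop = FALSE],
                              ensemble$time_h, ensemble$t0, delta)
  votes <- table(behavior_from_amplitudes(eff[, 1L], eff[, 2L], eff[, 3L],
                                          delta))
  top <- names(votes)[which.max(votes)]
  agreement <- max(votes) / sum(votes)
  category <- if (agreement < agreement_min) "ambiguous" else top
  structure(list(category = category, agreement = unname(agreement),
                 delta = delta, votes = c(votes)),
            class = "behavior_call")
}

#' @export
print.behavior_call <- function(x, ...) {
  cat("behavior:", x$category, sprintf("(agreement %.2f, delta %.3g)\n",
                                       x$agreement, x$delta))
  invisible(x)
}

#' Behavior calls for a cohort of fitted genes
#'
#' @param ensembles Named list of `fit_ensemble` objects (see
#'   [fit_profiles()]).
#' @param delta Change threshold passed to [call_gene_behavior()]; `NULL`
#'   uses each gene's own noise-scaled default.
#' @param agreement_min Minimum agreement for a definite call.
#' @return Data frame with columns `gene`, `category`, `agreement`,
#'   `delta`.
#' @export
classify_genes <- function(ensembles, delta = NULL, agreement_min = 0.9) {
  calls <- lapply(ensembles, call_gene_behavior, delta = delta,
                  agreement_min = agreement_min)
  data.frame(gene = names(ensembles),
             category = vapply(calls, `[[`, "", "category"),
             agreement = vapply(calls, `[[`, 0, "agreement"),
             delta = vapply(calls, `[[`, 0, "delta"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric gene-set enrichment of behavior categories
#'
#' For every (category, gene set) pair, tests whether the category's genes
#' overlap the set more than expected by chance, with the hypergeometric
#' upper-tail probability.  The universe defaults to all genes carrying a
#' call (i.e. all genes that passed preprocessing), not the genome.
#' Benjamini-Hochberg adjustment is applied across sets within each
#' category.
#'
#' @param calls Data frame from [classify_genes()] (columns `gene`,
#'   `category`).
#' @param gene_sets Named list of character vectors (GMT-style).
#' @param universe Character vector of background genes.
#' @return Data frame: `category`, `set`, `overlap`, `set_size`,
#'   `category_size`, `universe`, `p`, `q`.
#' @export
enrich_categories <- function(calls, gene_sets, universe = calls$gene) {
  universe <- unique(universe)
  N <- length(universe)
  rows <- list()
  for (cat_name in sort(unique(calls$category))) {
    cat_genes <- intersect(calls$gene[calls$category == cat_name], universe)
    n_cat <- length(cat_genes)
    if (n_cat == 0L) next
    p <- vapply(gene_sets, function(set) {
      set <- intersect(set, universe)
      k <- length(intersect(set, cat_genes))
      stats::phyper(k - 1L, length(set), N - length(set), n_cat,
                    lower.tail = FALSE)
    }, 0)
    overlap <- vapply(gene_sets, function(set)
      length(intersect(intersect(set, universe), cat_genes)), 0L)
    set_size <- vapply(gene_sets, function(set)
      length(intersect(set, universe)), 0L)
    rows[[cat_name]] <- data.frame(
      category = cat_name, set = names(gene_sets), overlap = overlap,
      set_size = set_size, category_size = n_cat, universe = N,
      p = p, q = stats::p.adjust(p, method = "BH"),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(category = character(), set = character(),
                      overlap = integer(), set_size = integer(),
                      category_size = integer(), universe = integer(),
                      p = numeric(), q = numeric())
  rownames(out) <- NULL
  out
}

#' Average profiles within gene sets and flag inconsistent sets
#'
#' Averages the (max-normalized) member profiles of each gene set time point
#' by time point.  Sets whose members respond inconsistently cancel out and
#' yield a relatively flat average; such sets (range of the mean profile
#' below `flat_threshold`) are flagged.
#'
#' @param profiles An `averaged_profiles` object or gene x time matrix of
#'   max-normalized mean levels.
#' @param gene_sets Named list of character vectors.
#' @param flat_threshold Minimum range of the mean profile for a set to be
#'   considered consistent (on the normalized 0-1 scale).
#' @return A list with `mean_profiles` (set x time matrix), `flat` (logical
#'   per set), `n_genes` (members found per set).
#' @export
pathway_average <- function(profiles, gene_sets, flat_threshold = 0.2) {
  d <- if (inherits(profiles, "averaged_profiles")) profiles$d else
    as.matrix(profiles)
  mp <- t(vapply(gene_sets, function(set) {
    found <- intersect(set, rownames(d))
    if (length(found) == 0L) return(rep(NA_real_, ncol(d)))
    colMeans(d[found, , drop = FALSE])
  }, numeric(ncol(d))))
  n_genes <- vapply(gene_sets, function(set)
    length(intersect(set, rownames(d))), 0L)
  rng <- apply(mp, 1L, function(r) diff(range(r)))
  list(mean_profiles = mp, flat = !is.na(rng) & rng < flat_threshold,
       n_genes = n_genes)
}
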