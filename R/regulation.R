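#' Cumulative trapezoidal integral of a profile
#'
#' Integrates a sampled profile from the first time point to each later time
#' point with the trapezoidal rule.  `M(t_1) = 0` and the result is exact
#' for piecewise-linear inputs sampled at their knots.  This is the
#' transcript integral used by the integral-regulation model, in which a
#' stable protein accumulates the history of its mRNA.
#'
#' @param y Profile values at the grid times.
#' @param time_h Strictly increasing times (hours), same length as `y`.
#' @return Numeric vector of cumulative integrals, starting at 0.
#' @export
cumulative_integral <- function(y, time_h) {
  if (length(y) != length(time_h))
    stop("profile and time grid lengths differ")
  if (any(diff(time_h) <= 0)) stop("time grid must be strictly increasing")
  n <- length(y)
  c(0, cumsum(diff(time_h) * (y[-n] + y[-1L]) / 2))
}

#' Proportional and integral correlation of a protein with its transcript
#'
#' Computes the two Spearman rank correlations that probe the limiting
#' regimes of `dp/dt = k_s * m - k_d * p`: `rho_prop`, protein vs transcript
#' over time (fast-degradation limit: the protein tracks its mRNA), and
#' `rho_int`, protein vs the cumulative transcript integral (no-degradation
#' limit: the protein accumulates its mRNA history).  Ties receive average
#' ranks.  Constant series make the rank correlation undefined; such genes
#' return `NA` and are excluded from downstream histograms.
#'
#' @param p Protein profile over time.
#' @param m Transcript profile over the same grid.
#' @param time_h The sampling grid (hours).
#' @param min_points Minimum number of finite paired points (default 4).
#' @return Named numeric vector `c(rho_prop, rho_int)`, possibly `NA`.
#' @export
regulation_correlations <- function(p, m, time_h, min_points = 4L) {
  if (length(p) != length(m) || length(p) != length(time_h))
    stop("profiles and grid must have the same length")
  M <- cumulative_integral(m, time_h)
  ok <- is.finite(p) & is.finite(m)
  spear <- function(a, b) {
    if (sum(ok) < min_points) return(NA_real_)
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
    stats::cor(a[ok], b[ok], method = "spearman")
  }
  c(rho_prop = spear(p, m), rho_int = spear(p, M))
}

#' Classify a gene's regulation regime from its two correlations
#'
#' A protein is proportionally regulated if its correlation with the
#' transcript exceeds `threshold` (and is at least as large as the integral
#' correlation), integrally regulated if the correlation with the transcript
#' integral exceeds `threshold` (and strictly dominates), and intermediate
#' otherwise.  When both exceed the threshold the larger correlation wins.
#'
#' @param rho_prop,rho_int Correlations from [regulation_correlations()]
#'   (vectorized).
#' @param threshold Classification threshold, default 0.70.
#' @return Character vector: `proportional`, `integral`, `intermediate`, or
#'   `NA` where a correlation is missing.
#' @export
classify_regulation <- function(rho_prop, rho_int, threshold = 0.70) {
  out <- rep(NA_character_, length(rho_prop))
  ok <- is.finite(rho_prop) & is.finite(rho_int)
  out[ok] <- "intermediate"
  out[ok & rho_prop > threshold & rho_prop >= rho_int] <- "proportional"
  out[ok & rho_int > threshold & rho_int > rho_prop] <- "integral"
  out
}

#' Regulation calls for a cohort of genes
#'
#' Applies [regulation_correlations()] and [classify_regulation()] to every
#' gene shared between a protein and an mRNA profile set.
#'
#' @param protein,mrna `averaged_profiles` objects (or gene x time matrices
#'   with a shared time grid supplied via `time_h`).
#' @param time_h Sampling grid; taken from the profile objects if omitted.
#' @param threshold Classification threshold.
#' @return Data frame: `gene`, `rho_prop`, `rho_int`, `label`.
#' @export
regulation_calls <- function(protein, mrna, time_h = NULL,
                             threshold = 0.70) {
  pd <- if (inherits(protein, "averaged_profiles")) protein$d else
    as.matrix(protein)
  md <- if (inherits(mrna, "averaged_profiles")) mrna$d else as.matrix(mrna)
  if (is.null(time_h))
    time_h <- if (inherits(mrna, "averaged_profiles")) mrna$time_h else
      protein$time_h
  shared <- intersect(rownames(pd), rownames(md))
  rho <- t(vapply(shared, function(g)
    regulation_correlations(pd[g, ], md[g, ], time_h), numeric(2L)))
  data.frame(gene = shared, rho_prop = rho[, 1L], rho_int = rho[, 2L],
             label = classify_regulation(rho[, 1L], rho[, 2L], threshold),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-sectional mRNA-protein correlation at one time point
#'
#' Spearman correlation across genes between absolute protein and absolute
#' mRNA levels (length-normalized RNA, scaled protein) at a single time
#' point.  Genes absent from either table are dropped and counted.
#'
#' @param protein,mrna Gene x time matrices of absolute levels with gene
#'   rownames.
#' @param time_index Column (time point) at which to correlate.
#' @return A list: `rho`, `n` (genes used), `n_dropped`.
#' @export
crosssection_correlation <- function(protein, mrna, time_index = 1L) {
  shared <- intersect(rownames(protein), rownames(mrna))
  n_dropped <- length(union(rownames(protein), rownames(mrna))) -
    length(shared)
  p <- protein[shared, time_index]
  m <- mrna[shared, time_index]
  ok <- is.finite(p) & is.finite(m)
  if (sum(ok) < 10L)
    stop("fewer than 10 genes shared between the protein and mRNA tables")
  list(rho = stats::cor(p[ok], m[ok], method = "spearman"),
       n = sum(ok), n_dropped = n_dropped)
}
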