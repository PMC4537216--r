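#' Remove genes with low total counts
#'
#' Drops genes whose summed counts over the entire time course (all times,
#' all replicates) fall below `min_total`.  The default of 10 removes
#' molecules observed too rarely for their trajectory to be interpretable.
#'
#' @param x A [profile_matrix()] of raw counts.
#' @param min_total Minimum summed count for a gene to be retained
#'   (boundary inclusive).
#' @return The filtered `profile_matrix`.
#' @export
filter_low_counts <- function(x, min_total = 10) {
  tot <- apply(x$counts, 1L, sum)
  keep <- tot >= min_total
  if (!any(keep)) warning("all genes fall below the low-count threshold")
  subset_genes(x, which(keep))
}

#' Normalize each sample to its read depth
#'
#' Divides every sample (one time point of one replicate) by its total
#' count, so each sample's values sum to 1 and samples of different
#' sequencing depth become comparable.
#'
#' @param x A [profile_matrix()].
#' @return A `profile_matrix` on the relative (`"depth"`) scale.
#' @export
depth_normalize <- function(x) {
  tot <- apply(x$counts, c(2L, 3L), sum)
  if (any(tot <= 0)) {
    bad <- which(tot <= 0, arr.ind = TRUE)[1L, ]
    stop("sample at time ", x$time_h[bad[1L]], " h, replicate ", bad[2L],
         " has zero total count")
  }
  x$counts <- sweep(x$counts, c(2L, 3L), tot, "/")
  x$normalization <- "depth"
  x
}

#' Median-of-ratios size factors
#'
#' The size factor of a sample is the median, over genes observed in every
#' sample, of that sample's count divided by the gene's geometric mean count
#' across samples.  This is the estimator popularized by count-based
#' differential-expression analysis; it is robust to a minority of genes
#' changing strongly between samples.
#'
#' @param mat Gene x sample matrix of nonnegative counts.
#' @return Numeric vector of positive size factors, one per sample.
#' @export
size_factors_median_ratio <- function(mat) {
  mat <- as.matrix(mat)
  ok <- rowSums(mat > 0) == ncol(mat)
  if (!any(ok))
    stop("no gene has nonzero counts in all samples; ",
         "consider adding a pseudocount before estimating size factors")
  lg <- log(mat[ok, , drop = FALSE])
  loggeo <- rowMeans(lg)
  apply(lg, 2L, function(col) exp(stats::median(col - loggeo)))
}

#' Keep genes whose profile changes at least `threshold`-fold
#'
#' The fold change of a gene is the maximum over time of its replicate-mean
#' level divided by the minimum over time (the minimum floored to avoid
#' division by zero).  Genes below the threshold are considered unchanged
#' and dropped from the fitting path.
#'
#' @param profiles An `averaged_profiles` object (see
#'   [average_replicates()]) or a gene x time matrix of mean levels.
#' @param threshold Minimum max/min ratio (boundary inclusive), default 1.5.
#' @param floor Lower floor applied to the denominator; on the
#'   depth-normalized scale this should be about one count's worth
#'   (`1/depth`).
#' @return Character vector of retained gene names.
#' @export
fold_change_filter <- function(profiles, threshold = 1.5, floor = 1e-9) {
  d <- if (inherits(profiles, "averaged_profiles")) profiles$d else
    as.matrix(profiles)
  fc <- apply(d, 1L, max) / pmax(apply(d, 1L, min), floor)
  rownames(d)[fc >= threshold]
}

#' Per-time-point significance filter for RNA profiles
#'
#' Compares every later time point against the first (baseline) time point,
#' gene by gene, on size-factor-normalized counts, and keeps genes with a
#' significant difference (p below `alpha`) at one or more time points.  The
#' test is a Welch two-sample t-test on `log(normalized count + pseudocount)`
#' across replicates; Benjamini-Hochberg adjustment across all comparisons
#' is available but off by default (plain per-comparison p-values).
#'
#' @param x A [profile_matrix()] of raw counts.
#' @param baseline Index of the baseline time point (default first).
#' @param alpha Significance level.
#' @param pseudocount Added before the log transform.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Character vector of retained gene names; the gene x comparison
#'   p-value matrix is attached as attribute `"p_values"`.
#' @export
significance_filter_rna <- function(x, baseline = 1L, alpha = 0.05,
                                    pseudocount = 0.5,
                                    adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  dims <- dim(x$counts)
  if (dims[3L] < 2L)
    stop("need >= 2 replicates to estimate within-time variance")
  flat <- do.call(cbind, lapply(seq_len(dims[2L]), function(j)
    x$counts[, j, , drop = TRUE]))
  sf <- size_factors_median_ratio(flat)
  norm <- sweep(flat, 2L, sf, "/")
  nrep <- dims[3L]
  col_of <- function(j) ((j - 1L) * nrep + 1L):(j * nrep)
  others <- setdiff(seq_len(dims[2L]), baseline)
  lbase <- log(norm[, col_of(baseline), drop = FALSE] + pseudocount)
  p <- matrix(NA_real_, dims[1L], length(others),
              dimnames = list(genes(x), paste0("t", x$time_h[others])))
  for (k in seq_along(others)) {
    lcmp <- log(norm[, col_of(others[k]), drop = FALSE] + pseudocount)
    for (g in seq_len(dims[1L])) {
      p[g, k] <- tryCatch(
        stats::t.test(lcmp[g, ], lbase[g, ])$p.value,
        error = function(e) {
          # both groups constant: a nonzero difference is unambiguous
          if (abs(mean(lcmp[g, ]) - mean(lbase[g, ])) > 1e-12) 0 else 1
        })
    }
  }
  pa <- if (adjust == "BH") {
    matrix(stats::p.adjust(p, method = "BH"), nrow = nrow(p),
           dimnames = dimnames(p))
  } else p
  keep <- apply(pa, 1L, function(r) any(r < alpha, na.rm = TRUE))
  structure(genes(x)[keep], p_values = p)
}

#' Average replicates into mean and SD profiles
#'
#' Produces, per gene and time point, the replicate mean `d` and the sample
#' standard deviation `sigma` that the error-scaled fit cost divides by.
#' Because replicates can coincide (sigma of zero would make the cost
#' infinite), sigma is floored at
#' `max(abs_floor, rel_floor * mean(d))` per gene.
#'
#' @param x A [profile_matrix()] (normally depth-normalized).
#' @param rel_floor,abs_floor Relative and absolute components of the sigma
#'   floor.
#' @return An object of class `"averaged_profiles"`: list with `d` and
#'   `sigma` (gene x time matrices), `time_h` and `normalization`.
#' @export
average_replicates <- function(x, rel_floor = 0.01, abs_floor = 1e-6) {
  dims <- dim(x$counts)
  if (dims[3L] < 2L) stop("need >= 2 replicates")
  d <- apply(x$counts, c(1L, 2L), mean)
  s <- apply(x$counts, c(1L, 2L), stats::sd)
  floor_g <- pmax(abs_floor, rel_floor * rowMeans(d))
  s <- pmax(s, floor_g)  # recycles per-gene floor down columns
  structure(list(d = d, sigma = s, time_h = x$time_h,
                 normalization = x$normalization),
            class = "averaged_profiles")
}

#' @export
print.averaged_profiles <- function(x, ...) {
  cat("averaged_profiles:", nrow(x$d), "genes x", ncol(x$d),
      "times (", x$normalization, "scale )\n")
  invisible(x)
}

#' Normalize each profile to its maximum
#'
#' Scales each gene's mean profile so that it peaks at exactly 1; the
#' replicate SDs are scaled by the same factor so the error-scaled cost is
#' unchanged.  Idempotent.
#'
#' @param x An `averaged_profiles` object or a numeric vector.
#' @return Object of the same type on the `"max"` scale.
#' @export
max_normalize <- function(x) {
  if (is.numeric(x)) {
    m <- max(x)
    if (m <= 0) stop("cannot max-normalize an all-zero profile")
    return(x / m)
  }
  m <- apply(x$d, 1L, max)
  if (any(m <= 0)) {
    bad <- rownames(x$d)[which(m <= 0)[1L]]
    stop("cannot max-normalize all-zero profile of gene ", bad)
  }
  x$d <- x$d / m
  x$sigma <- x$sigma / m
  x$normalization <- "max"
  x
}

#' Normalize counts by gene length
#'
#' Divides counts by gene length (bp) so that abundances of transcripts of
#' different length become comparable on an absolute per-molecule scale.
#'
#' @param counts Gene x sample matrix (or vector) of counts.
#' @param lengths Gene lengths in bp, `> 0`, recycled along genes.
#' @return Length-normalized values, same shape as `counts`.
#' @export
length_normalize <- function(counts, lengths) {
  if (any(lengths <= 0)) stop("gene lengths must be > 0")
  if (is.matrix(counts)) counts / lengths else counts / lengths
}

# Subset an averaged_profiles object by gene names.
subset_profiles <- function(x, keep) {
  x$d <- x$d[keep, , drop = FALSE]
  x$sigma <- x$sigma[keep, , drop = FALSE]
  x
}
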