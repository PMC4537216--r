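#' Within-operon co-expression coherence
#'
#' Genes in an operon are co-transcribed as a single RNA, so their
#' transcript profiles are expected to correlate strongly; their proteins
#' need not, since translational and post-translational control act per
#' gene.  For every operon with at least two profiled members this computes
#' all pairwise Spearman correlations between member profiles and summarizes
#' them with the mean (default) or median.
#'
#' @param profiles Gene x time matrix (or `averaged_profiles`) of levels.
#' @param operons Operon table (columns `operon_id`, `gene`).
#' @param stat `"mean"` or `"median"` summary of the pairwise correlations.
#' @return Data frame `operon_id`, `n_profiled`, `n_pairs`, `coherence`;
#'   the number of operons skipped for having fewer than two profiled
#'   members is attached as attribute `"n_skipped"`.
#' @export
operon_coherence <- function(profiles, operons, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  d <- if (inherits(profiles, "averaged_profiles")) profiles$d else
    as.matrix(profiles)
  sfun <- if (stat == "mean") mean else stats::median
  skipped <- 0L
  rows <- list()
  for (oid in unique(operons$operon_id)) {
    members <- intersect(operons$gene[operons$operon_id == oid],
                         rownames(d))
    if (length(members) < 2L) { skipped <- skipped + 1L; next }
    rho <- pairwise_spearman(d[members, , drop = FALSE])
    rows[[oid]] <- data.frame(operon_id = oid,
                              n_profiled = length(members),
                              n_pairs = length(rho),
                              coherence = sfun(rho),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(operon_id = character(), n_profiled = integer(),
                      n_pairs = integer(), coherence = numeric())
  rownames(out) <- NULL
  structure(out, n_skipped = skipped)
}

# All C(n,2) pairwise Spearman correlations between the rows of a matrix.
pairwise_spearman <- function(m) {
  cm <- suppressWarnings(stats::cor(t(m), method = "spearman"))
  cm[upper.tri(cm)]
}

#' Protein co-expression versus inter-gene distance within operons
#'
#' Builds one row per within-operon gene pair with the pairwise Spearman
#' correlation of their protein profiles and the genomic distance (bp)
#' between their coding regions (gap between the nearer ends, clamped at 0
#' for overlaps).  The trend statistic is the Spearman correlation of the
#' pairwise profile correlation against distance; a negative trend means
#' nearby genes have more similar protein profiles.  Also reported are the
#' two alternative explanations: the correlation of a gene's mean protein
#' level with its distance from the transcript (operon) start, and with its
#' transcript length.
#'
#' @param profiles Gene x time matrix (or `averaged_profiles`) of protein
#'   levels.
#' @param operons Operon table with columns `operon_id`, `gene`, `start`,
#'   `end`.
#' @param adjacent_only If `TRUE`, use only consecutive gene pairs.
#' @return A list: `pairs` (data frame `operon_id, gene1, gene2,
#'   distance_bp, rho`), `trend` (Spearman of rho vs distance, `NA` if
#'   degenerate), `rho_vs_start_distance`, `rho_vs_length`.
#' @export
distance_vs_correlation <- function(profiles, operons,
                                    adjacent_only = FALSE) {
  d <- if (inherits(profiles, "averaged_profiles")) profiles$d else
    as.matrix(profiles)
  rows <- list()
  for (oid in unique(operons$operon_id)) {
    sub <- operons[operons$operon_id == oid, , drop = FALSE]
    sub <- sub[sub$gene %in% rownames(d), , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    n <- nrow(sub)
    if (n < 2L) next
    pair_idx <- if (adjacent_only) {
      cbind(seq_len(n - 1L), 2:n)
    } else {
      t(utils::combn(n, 2L))
    }
    for (r in seq_len(nrow(pair_idx))) {
      i <- pair_idx[r, 1L]; j <- pair_idx[r, 2L]
      dist_bp <- max(0L, sub$start[j] - sub$end[i])
      rho <- suppressWarnings(stats::cor(d[sub$gene[i], ], d[sub$gene[j], ],
                                         method = "spearman"))
      rows[[length(rows) + 1L]] <- data.frame(
        operon_id = oid, gene1 = sub$gene[i], gene2 = sub$gene[j],
        distance_bp = dist_bp, rho = rho, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs))
    pairs <- data.frame(operon_id = character(), gene1 = character(),
                        gene2 = character(), distance_bp = numeric(),
                        rho = numeric())
  ok <- is.finite(pairs$rho)
  trend <- if (sum(ok) >= 3L && stats::sd(pairs$distance_bp[ok]) > 0 &&
               stats::sd(pairs$rho[ok]) > 0) {
    stats::cor(pairs$rho[ok], pairs$distance_bp[ok], method = "spearman")
  } else NA_real_

  # alternative explanations: per-gene mean protein level vs distance from
  # operon start and vs gene length
  prof_genes <- intersect(operons$gene, rownames(d))
  meta <- operons[match(prof_genes, operons$gene), , drop = FALSE]
  op_start <- tapply(meta$start, meta$operon_id, min)[meta$operon_id]
  start_dist <- meta$start - unname(op_start)
  mean_level <- rowMeans(d[prof_genes, , drop = FALSE])
  gene_len <- meta$end - meta$start + 1L
  safe_cor <- function(a, b) {
    if (length(a) >= 3L && stats::sd(a) > 0 && stats::sd(b) > 0)
      stats::cor(a, b, method = "spearman") else NA_real_
  }
  list(pairs = pairs, trend = trend,
       rho_vs_start_distance = safe_cor(mean_level, start_dist),
       rho_vs_length = safe_cor(mean_level, as.numeric(gene_len)))
}

#' K-means clustering of expression profiles
#'
#' Clusters max-normalized profiles by Euclidean (geometric) distance with
#' Lloyd's k-means, taking the best of `n_init` seeded restarts by
#' within-cluster sum of squares.  Centroids are reordered for stable
#' heat-map display: by the time of their maximum, then by overall mean.
#' Conventional cluster counts are 15 for RNA and 25 for protein profiles.
#'
#' @param x Gene x time matrix of complete profiles.
#' @param k Number of clusters (`<= nrow(x)`), or a k x time matrix of
#'   initial centers for a single deterministic Lloyd run.
#' @param seed Integer seed for the restarts.
#' @param n_init Number of random restarts.
#' @param iter_max Lloyd iteration cap.
#' @return A list: `centroids` (k x time, display-ordered), `cluster`
#'   (named assignment vector using the display order), `sse` (total
#'   within-cluster sum of squares).
#' @export
kmeans_profiles <- function(x, k, seed = 1L, n_init = 10L, iter_max = 100L) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("profiles must be complete (no missing time points)")
  if (is.matrix(k)) {
    fit <- stats::kmeans(x, centers = k, iter.max = iter_max,
                         algorithm = "Lloyd")
  } else {
    if (k > nrow(x)) stop("k must not exceed the number of genes")
    set.seed(seed)
    fit <- suppressWarnings(
      stats::kmeans(x, centers = k, nstart = n_init, iter.max = iter_max,
                    algorithm = "Lloyd"))
  }
  ord <- order(apply(fit$centers, 1L, which.max),
               rowMeans(fit$centers))
  centroids <- fit$centers[ord, , drop = FALSE]
  rownames(centroids) <- paste0("c", seq_len(nrow(centroids)))
  remap <- match(seq_len(nrow(centroids)), ord)
  cluster <- stats::setNames(remap[fit$cluster], rownames(x))
  list(centroids = centroids, cluster = cluster, sse = fit$tot.withinss)
}

#' Per-sample RNA class fractions
#'
#' Computes, for every sample, the fraction of counts assigned to mRNA,
#' tRNA, rRNA and other noncoding RNA.  With `drop_residual_rrna` the rRNA
#' counts (e.g. residual reads surviving an rRNA depletion step) are
#' disregarded and the remaining classes renormalized.
#'
#' @param counts Gene x sample matrix of counts with gene rownames.
#' @param rna_class Character vector (or factor) of classes per gene, in
#'   `mRNA, tRNA, rRNA, ncRNA`; may be named by gene.
#' @param drop_residual_rrna Drop rRNA before computing fractions.
#' @return Class x sample matrix of fractions, columns summing to 1.
#' @export
rna_fractions <- function(counts, rna_class, drop_residual_rrna = FALSE) {
  counts <- as.matrix(counts)
  if (!is.null(names(rna_class)))
    rna_class <- rna_class[rownames(counts)]
  rna_class <- as.character(rna_class)
  if (anyNA(rna_class) || length(rna_class) != nrow(counts)) {
    bad <- rownames(counts)[which(is.na(rna_class))[1L]]
    stop("gene ", bad, " has no RNA class label")
  }
  classes <- c("mRNA", "tRNA", "rRNA", "ncRNA")
  unknown <- setdiff(unique(rna_class), classes)
  if (length(unknown))
    stop("unknown RNA class: ", paste(unknown, collapse = ", "))
  if (drop_residual_rrna) {
    keep <- rna_class != "rRNA"
    counts <- counts[keep, , drop = FALSE]
    rna_class <- rna_class[keep]
    classes <- setdiff(classes, "rRNA")
  }
  by_class <- rowsum(counts, group = factor(rna_class, levels = classes))
  sweep(by_class, 2L, colSums(by_class), "/")
}
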