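#' Gene x time x replicate count container
#'
#' The basic data container: a 3-D array of nonnegative counts (genes x
#' times x replicates) with the sampling grid and per-gene metadata.  RNA
#' and protein tables use the same container; for RNA the metadata carries
#' the gene length (bp) and RNA class (mRNA, tRNA, rRNA or ncRNA).
#'
#' @param counts 3-D numeric array, dims gene x time x replicate, with
#'   gene names on the first dimension.
#' @param time_h Strictly increasing sampling times in hours, one per
#'   column of the second dimension.
#' @param gene_meta Data frame with one row per gene (rownames = gene
#'   names); typically columns `length` and `rna_class`.
#' @param normalization Tag describing the scale of the values: `"counts"`,
#'   `"depth"`, `"size_factor"`, `"max"` or `"length"`.
#' @return An object of class `"profile_matrix"`.
#' @export
profile_matrix <- function(counts, time_h, gene_meta = NULL,
                           normalization = "counts") {
  if (length(dim(counts)) != 3L)
    stop("counts must be a 3-D array (gene x time x replicate)")
  if (dim(counts)[2L] != length(time_h))
    stop("second dimension of counts must match length(time_h)")
  if (any(diff(time_h) <= 0)) stop("time_h must be strictly increasing")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  if (is.null(dimnames(counts)[[1L]]))
    dimnames(counts)[[1L]] <- paste0("g", seq_len(dim(counts)[1L]))
  if (!is.null(gene_meta)) {
    if (nrow(gene_meta) != dim(counts)[1L])
      stop("gene_meta must have one row per gene")
    rownames(gene_meta) <- dimnames(counts)[[1L]]
  }
  structure(list(counts = counts, time_h = time_h, gene_meta = gene_meta,
                 normalization = normalization),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  d <- dim(x$counts)
  cat("profile_matrix:", d[1L], "genes x", d[2L], "times x", d[3L],
      "replicates (", x$normalization, "scale )\n")
  cat("time grid (h):", paste(x$time_h, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.profile_matrix <- function(x) dim(x$counts)

#' Gene names of a profile container
#' @param x A `profile_matrix`.
#' @return Character vector of gene names.
#' @export
genes <- function(x) dimnames(x$counts)[[1L]]

# Subset a profile_matrix by gene names or indices.
subset_genes <- function(x, keep) {
  x$counts <- x$counts[keep, , , drop = FALSE]
  if (!is.null(x$gene_meta))
    x$gene_meta <- x$gene_meta[dimnames(x$counts)[[1L]], , drop = FALSE]
  x
}
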