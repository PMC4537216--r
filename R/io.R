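#' Read and write long-format count tables
#'
#' Counts travel as UTF-8 tab-separated text with a header row and columns
#' `gene`, `time_h`, `replicate`, `count`.  Reading validates that every
#' count is a nonnegative integer and reports the offending cell otherwise;
#' `read(write(x))` round-trips exactly.
#'
#' @param x A [profile_matrix()] of counts.
#' @param path File path.
#' @return `write_counts_tsv()` returns `path` invisibly;
#'   `read_counts_tsv()` returns a `profile_matrix`.
#' @export
write_counts_tsv <- function(x, path) {
  dims <- dim(x$counts)
  long <- data.frame(
    gene = rep(genes(x), times = dims[2L] * dims[3L]),
    time_h = rep(rep(x$time_h, each = dims[1L]), times = dims[3L]),
    replicate = rep(seq_len(dims[3L]), each = dims[1L] * dims[2L]),
    count = as.vector(x$counts))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  long <- utils::read.delim(path, colClasses = c("character", "numeric",
                                                 "integer", "numeric"))
  need <- c("gene", "time_h", "replicate", "count")
  if (!all(need %in% names(long)))
    stop("count table must have columns ", paste(need, collapse = ", "))
  bad <- which(!is.finite(long$count) | long$count < 0 |
                 long$count != round(long$count))
  if (length(bad))
    stop("non-integer count for gene ", long$gene[bad[1L]], " at time ",
         long$time_h[bad[1L]], " h, replicate ", long$replicate[bad[1L]])
  gene_names <- unique(long$gene)
  time_h <- sort(unique(long$time_h))
  reps <- sort(unique(long$replicate))
  counts <- array(NA_real_, dim = c(length(gene_names), length(time_h),
                                    length(reps)),
                  dimnames = list(gene_names, NULL, NULL))
  idx <- cbind(match(long$gene, gene_names), match(long$time_h, time_h),
               match(long$replicate, reps))
  counts[idx] <- long$count
  if (anyNA(counts)) stop("count table is not a complete gene x time x ",
                          "replicate grid")
  profile_matrix(counts, time_h)
}

#' Read and write operon tables
#'
#' BED-like tab-separated layout with a header:
#' `operon_id`, `gene`, `start`, `end`, `strand` (plus any extra columns,
#' which are preserved).
#'
#' @param operons Operon data frame.
#' @param path File path.
#' @export
write_operon_table <- function(operons, path) {
  utils::write.table(operons, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_operon_table
#' @export
read_operon_table <- function(path) {
  op <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("operon_id", "gene", "start", "end", "strand")
  if (!all(need %in% names(op)))
    stop("operon table must have columns ", paste(need, collapse = ", "))
  op
}

#' Read and write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated fields
#' `set name, description, member genes...`.  A line without members is a
#' parse error reported with its line number.
#'
#' @param gene_sets Named list of character vectors.
#' @param path File path.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i)
    paste(c(names(gene_sets)[i], descriptions[i], gene_sets[[i]]),
          collapse = "\t"), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("GMT parse error at line ", i, ": set has no member genes")
    sets[[fields[1L]]] <- fields[-(1:2)]
  }
  sets
}

#' Write averaged profiles as TSV
#'
#' Long-format table `gene`, `time_h`, `d`, `sigma`.
#'
#' @param profiles An `averaged_profiles` object.
#' @param path File path.
#' @export
write_profiles_tsv <- function(profiles, path) {
  long <- data.frame(
    gene = rep(rownames(profiles$d), times = ncol(profiles$d)),
    time_h = rep(profiles$time_h, each = nrow(profiles$d)),
    d = as.vector(profiles$d), sigma = as.vector(profiles$sigma))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
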