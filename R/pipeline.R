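#' Assemble a pipeline run configuration
#'
#' A run is driven either by a synthetic-data block (the generator of
#' [simulate_dataset()]) or by input file paths (long-format count TSVs, an
#' operon table and a GMT gene-set file) -- exactly one of the two.  All
#' stage parameters live here so that a configuration fully determines a
#' run; rerunning the same configuration reproduces every output byte for
#' byte.
#'
#' @param synthetic A [synthetic_config()] (or list of its arguments), or
#'   `NULL` when reading from files.
#' @param inputs Named list of paths `rna`, `protein`, `operons`,
#'   `gene_sets`, or `NULL` when simulating.
#' @param outdir Output directory; created if missing.  `NULL` disables
#'   file output.
#' @param seed Global integer seed fanned out to every stochastic stage.
#' @param stages Named logical toggles: `fit`, `classify`, `regulation`,
#'   `operon`, `cluster`, `fractions`, `enrichment`.
#' @param min_total,fold_change,alpha Preprocessing thresholds (low-count
#'   filter, protein fold-change filter, RNA significance level).
#' @param k_rna,k_protein Cluster counts for the k-means stage.
#' @param delta Behavior change threshold (`NULL` = per-gene noise-scaled).
#' @param agreement_min Minimum ensemble agreement for a definite call.
#' @param rho_threshold Regulation classification threshold.
#' @param flat_threshold Pathway-average flatness threshold.
#' @param de A [de_config()].
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(synthetic = synthetic_config(), inputs = NULL,
                       outdir = NULL, seed = 1L,
                       stages = list(), min_total = 10, fold_change = 1.5,
                       alpha = 0.05, k_rna = 15L, k_protein = 25L,
                       delta = NULL, agreement_min = 0.9,
                       rho_threshold = 0.70, flat_threshold = 0.2,
                       de = de_config()) {
  if (is.null(synthetic) == is.null(inputs))
    stop("exactly one of `synthetic` and `inputs` must be given")
  if (!is.null(inputs)) {
    need <- c("rna", "protein", "operons", "gene_sets")
    missing_files <- unlist(inputs[need])[!file.exists(unlist(inputs[need]))]
    if (length(missing_files))
      stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_config"))
    synthetic <- do.call(synthetic_config, synthetic)
  defaults <- list(fit = TRUE, classify = TRUE, regulation = TRUE,
                   operon = TRUE, cluster = TRUE, fractions = TRUE,
                   enrichment = TRUE)
  defaults[names(stages)] <- stages
  structure(list(synthetic = synthetic, inputs = inputs, outdir = outdir,
                 seed = as.integer(seed), stages = defaults,
                 min_total = min_total, fold_change = fold_change,
                 alpha = alpha, k_rna = as.integer(k_rna),
                 k_protein = as.integer(k_protein), delta = delta,
                 agreement_min = agreement_min,
                 rho_threshold = rho_threshold,
                 flat_threshold = flat_threshold, de = de),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' The YAML mirrors the arguments of [run_config()]; `synthetic:`, `de:`
#' and `stages:` map to nested blocks.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) {
    if (!is.null(y$synthetic$category_mix))
      y$synthetic$category_mix <- unlist(y$synthetic$category_mix)
    if (!is.null(y$synthetic$regulation_mix))
      y$synthetic$regulation_mix <- unlist(y$synthetic$regulation_mix)
    if (!is.null(y$synthetic$operon_size_dist))
      y$synthetic$operon_size_dist <- unlist(y$synthetic$operon_size_dist)
    if (!is.null(y$synthetic$time_grid))
      y$synthetic$time_grid <- as.numeric(unlist(y$synthetic$time_grid))
  }
  if (!is.null(y$de)) y$de <- do.call(de_config, y$de)
  do.call(run_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (simulation or file input),
#' preprocessing (low-count filter, rRNA removal and significance filter on
#' the RNA side, depth normalization, replicate averaging, fold-change
#' filter on the protein side, max normalization), piecewise DE fitting,
#' behavior classification, the proportional/integral regulation analysis,
#' operon coherence and the distance trend, k-means clustering, RNA class
#' fractions, and gene-set enrichment of the behavior categories.  Every
#' stage logs its input and output gene counts in the run manifest; no gene
#' is dropped silently.
#'
#' @param config A [run_config()], or a path to a YAML file for
#'   [read_run_config()].
#' @return Invisibly, a list with all stage results and the `manifest`.
#'   When `config$outdir` is set, tables (TSV/CSV), the GMT and the JSON
#'   manifest are written there.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- list()
  counts_log <- list()
  odir <- config$outdir
  if (!is.null(odir) && !dir.exists(odir))
    dir.create(odir, recursive = TRUE)
  emit <- function(obj, file, writer = utils::write.csv) {
    if (!is.null(odir)) writer(obj, file.path(odir, file))
    invisible(NULL)
  }

  ## -- data ---------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    ds <- simulate_dataset(config$synthetic)
    rna_counts <- ds$rna; protein_counts <- ds$protein
    operons <- ds$operons; gene_sets <- ds$gene_sets
    out$dataset <- ds
    if (!is.null(odir)) {
      write_counts_tsv(rna_counts, file.path(odir, "counts_rna.tsv"))
      write_counts_tsv(protein_counts, file.path(odir, "counts_protein.tsv"))
      utils::write.table(ds$truth, file.path(odir, "truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_operon_table(operons, file.path(odir, "operons.tsv"))
      write_gmt(gene_sets, file.path(odir, "gene_sets.gmt"))
    }
  } else {
    rna_counts <- read_counts_tsv(config$inputs$rna)
    protein_counts <- read_counts_tsv(config$inputs$protein)
    operons <- read_operon_table(config$inputs$operons)
    gene_sets <- read_gmt(config$inputs$gene_sets)
    if (!is.null(config$inputs$rna_class)) {
      cls <- utils::read.delim(config$inputs$rna_class,
                               stringsAsFactors = FALSE)
      rna_counts$gene_meta <- data.frame(rna_class = cls$rna_class,
                                         row.names = cls$gene)[
                                           genes(rna_counts), , drop = FALSE]
    }
  }
  counts_log$rna_input <- length(genes(rna_counts))
  counts_log$protein_input <- length(genes(protein_counts))

  ## -- preprocess ---------------------------------------------------------
  rna_class <- if (!is.null(rna_counts$gene_meta) &&
                   "rna_class" %in% names(rna_counts$gene_meta)) {
    stats::setNames(rna_counts$gene_meta$rna_class, genes(rna_counts))
  } else {
    stats::setNames(rep("mRNA", length(genes(rna_counts))),
                    genes(rna_counts))
  }

  ## RNA class fractions are computed on the unfiltered counts
  if (isTRUE(config$stages$fractions)) {
    flat_rna <- apply(rna_counts$counts, c(1L, 2L), sum)
    colnames(flat_rna) <- paste0("t", rna_counts$time_h)
    fractions <- rna_fractions(flat_rna, rna_class)
    out$rna_fractions <- fractions
    emit(data.frame(rna_class = rownames(fractions), fractions,
                    check.names = FALSE),
         "rna_fractions.csv",
         function(x, f) utils::write.csv(x, f, row.names = FALSE))
  }

  ## rRNA reads are disregarded before relative RNA analysis
  rna_nr <- subset_genes(rna_counts,
                         which(rna_class[genes(rna_counts)] != "rRNA"))
  counts_log$rna_after_rrna_removal <- length(genes(rna_nr))

  rna_f <- filter_low_counts(rna_nr, config$min_total)
  protein_f <- filter_low_counts(protein_counts, config$min_total)
  counts_log$rna_after_low_count <- length(genes(rna_f))
  counts_log$protein_after_low_count <- length(genes(protein_f))

  sig_genes <- significance_filter_rna(rna_f, alpha = config$alpha)
  counts_log$rna_significant <- length(sig_genes)

  rna_avg <- average_replicates(depth_normalize(rna_f))
  protein_avg <- average_replicates(depth_normalize(protein_f))

  fc_genes <- fold_change_filter(protein_avg, config$fold_change,
                                 floor = 0.5 / config_depth(config,
                                                            protein_counts))
  counts_log$protein_after_fold_change <- length(fc_genes)

  rna_sel <- max_normalize(subset_profiles(rna_avg, sig_genes))
  protein_sel <- max_normalize(subset_profiles(protein_avg, fc_genes))
  out$rna_profiles <- rna_sel
  out$protein_profiles <- protein_sel
  if (!is.null(odir)) {
    write_profiles_tsv(rna_sel, file.path(odir, "profiles_rna.tsv"))
    write_profiles_tsv(protein_sel, file.path(odir, "profiles_protein.tsv"))
  }

  ## -- fit + classify -----------------------------------------------------
  if (isTRUE(config$stages$fit)) {
    fits_rna <- fit_profiles(rna_sel, config$de,
                             seed = derive_seed(config$seed, 101L))
    fits_protein <- fit_profiles(protein_sel, config$de,
                                 seed = derive_seed(config$seed, 202L))
    out$fits_rna <- fits_rna
    out$fits_protein <- fits_protein
    ts_rna <- summarize_timescales(fits_rna)
    ts_protein <- summarize_timescales(fits_protein)
    emit(ts_rna, "timescales_rna.csv",
         function(x, f) utils::write.csv(x, f, row.names = FALSE))
    emit(ts_protein, "timescales_protein.csv",
         function(x, f) utils::write.csv(x, f, row.names = FALSE))

    if (isTRUE(config$stages$classify)) {
      calls_rna <- classify_genes(fits_rna, delta = config$delta,
                                  agreement_min = config$agreement_min)
      calls_protein <- classify_genes(fits_protein, delta = config$delta,
                                      agreement_min = config$agreement_min)
      out$calls_rna <- calls_rna
      out$calls_protein <- calls_protein
      emit(calls_rna, "behavior_rna.csv",
           function(x, f) utils::write.csv(x, f, row.names = FALSE))
      emit(calls_protein, "behavior_protein.csv",
           function(x, f) utils::write.csv(x, f, row.names = FALSE))

      if (isTRUE(config$stages$enrichment)) {
        enr <- enrich_categories(calls_protein, gene_sets)
        out$enrichment <- enr
        emit(enr, "enrichment.csv",
             function(x, f) utils::write.csv(x, f, row.names = FALSE))
        pa <- pathway_average(protein_sel, gene_sets,
                              config$flat_threshold)
        out$pathway_average <- pa
        emit(data.frame(set = rownames(pa$mean_profiles),
                        flat = pa$flat, n_genes = pa$n_genes,
                        pa$mean_profiles, check.names = FALSE),
             "pathway_average.csv",
             function(x, f) utils::write.csv(x, f, row.names = FALSE))
      }
    }
  }

  ## -- regulation ---------------------------------------------------------
  if (isTRUE(config$stages$regulation)) {
    reg <- regulation_calls(protein_sel, rna_sel,
                            threshold = config$rho_threshold)
    out$regulation <- reg
    emit(reg, "regulation.csv",
         function(x, f) utils::write.csv(x, f, row.names = FALSE))
    counts_log$regulation_genes <- sum(!is.na(reg$label))
  }

  ## -- operon / cluster ---------------------------------------------------
  if (isTRUE(config$stages$operon)) {
    coh_rna <- operon_coherence(rna_sel, operons)
    coh_protein <- operon_coherence(protein_sel, operons)
    dvc <- distance_vs_correlation(protein_sel, operons)
    out$operon <- list(rna = coh_rna, protein = coh_protein,
                       distance = dvc)
    emit(coh_rna, "operon_coherence_rna.csv",
         function(x, f) utils::write.csv(x, f, row.names = FALSE))
    emit(coh_protein, "operon_coherence_protein.csv",
         function(x, f) utils::write.csv(x, f, row.names = FALSE))
    emit(dvc$pairs, "operon_distance_pairs.csv",
         function(x, f) utils::write.csv(x, f, row.names = FALSE))
  }

  if (isTRUE(config$stages$cluster)) {
    km_rna <- kmeans_profiles(rna_sel$d,
                              min(config$k_rna, nrow(rna_sel$d)),
                              seed = derive_seed(config$seed, 303L))
    km_protein <- kmeans_profiles(protein_sel$d,
                                  min(config$k_protein,
                                      nrow(protein_sel$d)),
                                  seed = derive_seed(config$seed, 404L))
    out$clusters <- list(rna = km_rna, protein = km_protein)
    emit(data.frame(gene = names(km_rna$cluster),
                    cluster = km_rna$cluster),
         "clusters_rna.csv",
         function(x, f) utils::write.csv(x, f, row.names = FALSE))
    emit(data.frame(gene = names(km_protein$cluster),
                    cluster = km_protein$cluster),
         "clusters_protein.csv",
         function(x, f) utils::write.csv(x, f, row.names = FALSE))
    emit(data.frame(cluster = rownames(km_rna$centroids),
                    km_rna$centroids, check.names = FALSE),
         "centroids_rna.csv",
         function(x, f) utils::write.csv(x, f, row.names = FALSE))
    emit(data.frame(cluster = rownames(km_protein$centroids),
                    km_protein$centroids, check.names = FALSE),
         "centroids_protein.csv",
         function(x, f) utils::write.csv(x, f, row.names = FALSE))
  }

  ## -- manifest -----------------------------------------------------------
  manifest <- list(
    package = "decurve",
    version = as.character(utils::packageVersion("decurve")),
    seed = config$seed,
    stages = config$stages,
    parameters = list(min_total = config$min_total,
                      fold_change = config$fold_change,
                      alpha = config$alpha, k_rna = config$k_rna,
                      k_protein = config$k_protein,
                      agreement_min = config$agreement_min,
                      rho_threshold = config$rho_threshold,
                      flat_threshold = config$flat_threshold,
                      de = unclass(config$de)),
    synthetic = if (!is.null(config$synthetic))
      unclass(config$synthetic) else NULL,
    inputs = config$inputs,
    gene_counts = counts_log)
  out$manifest <- manifest
  if (!is.null(odir))
    jsonlite::write_json(manifest, file.path(odir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

# Depth scale for the fold-change denominator floor: roughly one count.
config_depth <- function(config, protein_counts) {
  if (!is.null(config$synthetic)) return(config$synthetic$depth)
  stats::median(apply(protein_counts$counts, c(2L, 3L), sum))
}
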