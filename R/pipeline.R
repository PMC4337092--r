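# Pipeline orchestration: simulate -> chip -> rna -> associate -> de ->
# arrange/classify -> report, with one master seed fanned out per stage.

#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline in one validated,
#' YAML-serialisable list: the background multiplier `k` (1.2 SD above the
#' mean of the ChIP:input ratios), the 300-bp anatomy flank, the 150-bp
#' end windows, the >3-fold association rule, the randomisation size, the
#' DE significance level, the 300-bp close/far boundary, the antisense
#' overlap minimum, the 7-quantile binning, and the 1e8-unit sense-strand
#' normalisation target.
#'
#' @param simulate a [sim_config()] describing the synthetic inputs.
#' @param seed master seed; each stage derives its own stream.
#' @param k background multiplier (default 1.2).
#' @param flank anatomy window half-width in bp (default 300).
#' @param window end-window size in bp (default 150).
#' @param fold_threshold association fold rule (default 3).
#' @param pseudocount fold-rule pseudocount (default 0.1).
#' @param iters randomisation iterations (default 1000).
#' @param alpha DE significance level (default 0.05).
#' @param close_threshold close/far gap boundary in bp (default 300).
#' @param min_overlap antisense assignment overlap minimum (default 0.5).
#' @param k_quantiles occupancy-level bins (default 7).
#' @param rna_target sense-strand normalisation target (default 1e8).
#' @param cluster_max cluster occupancy vectors only when the catalogue has
#'   at most this many genes (dendrograms on thousands of genes are
#'   memory-heavy and rarely inspected; default 1200).
#' @param n_clusters clusters to cut when clustering runs (default 4).
#' @return validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(simulate = sim_config(), seed = 1,
                            k = 1.2, flank = 300, window = 150,
                            fold_threshold = 3, pseudocount = 0.1,
                            iters = 1000, alpha = 0.05,
                            close_threshold = 300, min_overlap = 0.5,
                            k_quantiles = 7, rna_target = 1e8,
                            cluster_max = 1200, n_clusters = 4) {
  cfg <- as.list(environment())
  stopifnot(cfg$k >= 0, cfg$flank > 0, cfg$window > 0,
            cfg$fold_threshold > 0, cfg$pseudocount > 0, cfg$iters >= 1,
            cfg$alpha > 0, cfg$alpha < 1, cfg$close_threshold > 0,
            cfg$min_overlap > 0, cfg$min_overlap <= 1,
            cfg$k_quantiles >= 2, cfg$rna_target > 0)
  structure(cfg, class = "PipelineConfig")
}

#' Serialise / restore a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @param path YAML file.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  simc <- do.call(sim_config, lapply(raw$simulate, function(x)
    if (is.list(x)) unlist(x) else x))
  raw$simulate <- NULL
  do.call(pipeline_config, c(list(simulate = simc), raw))
}

#' Run the full pipeline on a simulated dataset
#'
#' Stages, in dependency order: (1) simulate the catalogue, ground truth,
#' ChIP/input coverage and stranded two-condition counts; (2) process the
#' ChIP pair (RPM, background subtraction), partition the signal by gene
#' anatomy, compute metagene profiles, quantify and classify 5'/3' end
#' enrichment (and cluster occupancy vectors on small catalogues);
#' (3) build condition-1 expression, normalise the strands, quantify
#' transcripts, assign antisense hosts, and apply the fold rule at 3'
#' windows; (4) cross-tabulate high-vs-none 3' occupancy against antisense
#' and run the randomisation null; (5) test differential expression on the
#' merged sense+antisense count matrix; (6) classify gene arrangement and
#' 5'/3' occupancy patterns and summarise sense fold changes per class;
#' (7) assemble the report (plus replicate-correlation QC and provenance).
#' Reruns with the same config are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every tabular output is
#'   written as TSV/JSON with stable schemas.
#' @return a `ReportBundle` list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(is(config, "PipelineConfig"))
  seed <- config$seed
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ## 1. simulate
  sim <- stage("simulate", function() simulate_genome(config$simulate, seed))
  catalog <- sim$catalog; truth <- sim$truth
  chip <- stage("simulate", function()
    simulate_chip(catalog, truth, config$simulate, seed))
  rna <- stage("simulate", function()
    simulate_rna(catalog, truth, config$simulate, seed))
  ## 2. chip
  chipres <- stage("chip", function() {
    signal <- subtract_background(normalize_rpm(chip$chip),
                                  normalize_rpm(chip$input), k = config$k)
    ee <- add_occupancy_calls(
      quantify_end_enrichment(signal, catalog, window = config$window))
    part <- partition_signal(signal, catalog, flank = config$flank)
    prof_tss <- metagene_profile(signal, catalog, "tss_aligned",
                                 span = config$flank)
    prof_tes <- metagene_profile(signal, catalog, "tes_aligned",
                                 span = config$flank)
    clusters <- NULL
    if (config$simulate$n_genes <= config$cluster_max) {
      fv <- feature_vectors(signal, catalog)
      clusters <- cluster_profiles(fv, config$n_clusters)$labels
    }
    list(signal = signal, end_enrichment = ee, partition = part,
         profile_tss = prof_tss, profile_tes = prof_tes,
         clusters = clusters)
  })
  ee <- chipres$end_enrichment
  ## 3. rna
  rnares <- stage("rna", function() {
    cond1 <- rna$col_data$sample[rna$col_data$condition ==
                                   rna$col_data$condition[1]]
    pooled <- rowMeans(rna$counts[, cond1, drop = FALSE])
    expr <- expression_from_counts(catalog, pooled,
                                   condition = rna$col_data$condition[1],
                                   replicate = "pooled")
    expr <- normalize_stranded(expr, catalog, target = config$rna_target)
    levels <- quantify_transcripts(expr, catalog)
    as_set <- classify_antisense(catalog, min_overlap = config$min_overlap)
    links <- associate_three_prime_peaks(catalog, expr,
                                         window = config$window,
                                         fold_threshold = config$fold_threshold,
                                         pseudocount = config$pseudocount)
    list(expr = expr, levels = levels, antisense = as_set, links = links)
  })
  ## 4. association
  assoc <- stage("associate", function() {
    cont <- overlap_contingency(ee, rnares$antisense, "high_vs_none")
    high <- ee$id[ee$three_call == "high"]
    rand <- randomization_test(catalog, rnares$antisense, high,
                               width = config$window, iters = config$iters,
                               seed = seed + 4L)
    list(contingency = cont, randomization = rand)
  })
  ## 5. differential expression
  de <- stage("de", function() {
    kinds <- catalog$transcripts[rownames(rna$counts), "kind"]
    test_differential(rna$counts, rna$col_data$condition,
                      alpha = config$alpha,
                      class = ifelse(kinds == "coding", "sense", "antisense"))
  })
  ## 6. arrangement and occupancy classes
  arr <- stage("arrange", function() {
    calls <- classify_arrangement(catalog,
                                  close_threshold = config$close_threshold)
    csig <- category_signal(ee, calls)
    down_as <- de$id[de$class == "antisense" & de$call == "down"]
    down_hosts <- rnares$antisense$host[
      rnares$antisense$id %in% down_as & !rnares$antisense$excluded_convergent]
    cenr <- if (length(down_hosts) > 0)
      category_enrichment(down_hosts, calls) else NULL
    with_as <- unique(rnares$antisense$host[
      !rnares$antisense$excluded_convergent])
    pat <- classify_htz_pattern(ee, universe = with_as)
    sense_de <- de[de$class == "sense", , drop = FALSE]
    cmp <- class_fold_change_comparison(pat, sense_de)
    hosts3 <- ee$three_prime_level[match(rnares$antisense$host,
                                         ee$id)]
    bins <- if (length(hosts3) >= config$k_quantiles)
      quantile_bins(hosts3, config$k_quantiles) else NULL
    list(arrangement = calls, category_signal = csig,
         category_enrichment = cenr, pattern = pat, class_comparison = cmp,
         occupancy_bins = if (!is.null(bins))
           data.frame(as_id = rnares$antisense$id,
                      host = rnares$antisense$host,
                      three_prime_level = hosts3, bin = bins) else NULL)
  })
  ## 7. report
  cor_qc <- stage("report", function() {
    cd <- rna$col_data
    vapply(unique(cd$condition), function(cc) {
      cols <- cd$sample[cd$condition == cc][1:2]
      cor(rna$counts[, cols[1]], rna$counts[, cols[2]])
    }, 0)
  })
  bundle <- list(
    catalog = catalog, truth = truth,
    partition = chipres$partition,
    end_enrichment = ee,
    profile_tss = chipres$profile_tss,
    profile_tes = chipres$profile_tes,
    clusters = chipres$clusters,
    levels = rnares$levels,
    antisense = rnares$antisense,
    links = rnares$links,
    contingency = assoc$contingency,
    randomization = assoc$randomization,
    de = de,
    arrangement = arr$arrangement,
    category_signal = arr$category_signal,
    category_enrichment = arr$category_enrichment,
    pattern = arr$pattern,
    class_comparison = arr$class_comparison,
    occupancy_bins = arr$occupancy_bins,
    replicate_correlation = cor_qc,
    provenance = list(seed = seed,
                      config = yaml::as.yaml(unclass(config))))
  class(bundle) <- "ReportBundle"
  if (!is.null(out_dir)) write_report(bundle, out_dir)
  bundle
}

#' Write a report bundle to disk
#'
#' Tabular outputs as TSV with headers, scalar summaries as JSON; the
#' provenance block records the seed and the full serialised
#' configuration.
#'
#' @param bundle a `ReportBundle` from [run_pipeline()].
#' @param out_dir output directory (created if absent).
#' @export
write_report <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    write.table(as.data.frame(df), file.path(out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  tsv(bundle$partition, "partition.tsv")
  tsv(bundle$end_enrichment, "end_enrichment.tsv")
  tsv(bundle$profile_tss, "metagene_tss.tsv")
  tsv(bundle$profile_tes, "metagene_tes.tsv")
  tsv(bundle$levels, "levels.tsv")
  tsv(bundle$antisense, "antisense.tsv")
  tsv(bundle$links, "links.tsv")
  tsv(bundle$de, "de.tsv")
  tsv(bundle$arrangement, "arrangement.tsv")
  tsv(bundle$category_signal, "category_signal.tsv")
  if (!is.null(bundle$category_enrichment))
    tsv(bundle$category_enrichment, "category_enrichment.tsv")
  tsv(bundle$pattern, "pattern_classes.tsv")
  tsv(bundle$class_comparison$summary, "class_fold_changes.tsv")
  if (!is.null(bundle$occupancy_bins))
    tsv(bundle$occupancy_bins, "occupancy_bins.tsv")
  tsv(data.frame(iteration = seq_along(bundle$randomization$null_counts),
                 count = bundle$randomization$null_counts),
      "randomization_null.tsv")
  cont <- bundle$contingency
  summary <- list(
    contingency = list(table = as.vector(cont$table),
                       expected = as.vector(cont$expected),
                       p_value = cont$p_value,
                       odds_ratio = cont$odds_ratio),
    randomization = list(observed = bundle$randomization$observed_count,
                         null_mean = mean(bundle$randomization$null_counts),
                         empirical_p = bundle$randomization$empirical_p,
                         seed = bundle$randomization$seed),
    replicate_correlation = as.list(bundle$replicate_correlation),
    provenance = bundle$provenance)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
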