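#' Build a pipeline run configuration
#'
#' Collects input paths and thresholds for [run_pipeline()]. Defaults are
#' the study thresholds: raw p < 0.05 with fold change > 2 or < 0.5 for
#' DEGs, enrichment alpha 0.05, hub degree strictly > 30, a stratified 50/50
#' train/test split, and tenfold cross-validation.
#'
#' @param counts,labels paths to the count and label TSVs
#'   (see [read_count_matrix()]).
#' @param kgml_dir directory of KGML `.xml` pathway files.
#' @param id_map optional KEGG-id-to-symbol TSV (see [read_id_map()]).
#' @param gmt optional GMT file for the enrichment stage.
#' @param literature optional text file of literature-confirmed symbols.
#' @param out_dir directory for all written artifacts.
#' @param p_thresh,fc_up,fc_down DEG filter thresholds.
#' @param alpha enrichment significance cutoff.
#' @param min_degree hub threshold (degree strictly greater).
#' @param split_fraction,folds,C classifier settings.
#' @param normalization `"libsize"` or `"tmm"`.
#' @param dispersion optional fixed NB dispersion; estimated when `NULL`.
#' @param restrict_to_significant build the network only from pathways the
#'   enrichment stage called significant (requires `gmt`; pathway ids must
#'   match the GMT set ids). Off by default: all KGML files are used.
#' @param resubstitution evaluate the training set by refitting on all of it
#'   instead of pooled cross-validation predictions.
#' @param seed integer seed driving the split and fold assignment.
#' @return A `RunConfig` list.
#' @export
pipeline_config <- function(counts, labels, kgml_dir, id_map = NULL,
                            gmt = NULL, literature = NULL,
                            out_dir = tempfile("pathmarker_run"),
                            p_thresh = 0.05, fc_up = 2, fc_down = 0.5,
                            alpha = 0.05, min_degree = 30,
                            split_fraction = 0.5, folds = 10, C = 1,
                            normalization = "libsize", dispersion = NULL,
                            restrict_to_significant = FALSE,
                            resubstitution = FALSE, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(p_thresh > 0, fc_up > 0, fc_down > 0, alpha > 0,
            min_degree >= 0, C > 0)
  class(cfg) <- "RunConfig"
  cfg
}

stage_msg <- function(...) message("[pathmarker] ", sprintf(...))

#' Run the full marker-discovery pipeline
#'
#' Executes, in order: count loading, differential expression (NB exact
#' test + FC/p filter), gene-set enrichment of the DEG list (if a GMT is
#' configured), KGML parsing and edge extraction, network merging with
#' degree/power-law analysis, hub extraction, DEG-hub intersection into the
#' candidate marker set, and linear-SVM training/evaluation on the marker
#' expression submatrix (log2(x+1) normalized expression): tenfold
#' cross-validation pooled over folds on the training half, and held-out
#' evaluation on the test half. Every stage writes its artifact under
#' `config$out_dir` and the run report is serialized as `report.json`.
#'
#' An empty marker set halts the run before classification with an error.
#' The run is fully reproducible from the inputs and `config$seed`.
#'
#' @param config a `RunConfig` from [pipeline_config()].
#' @return A `RunReport` list: stage counts, thresholds, the marker table,
#'   power-law diagnostic, and `EvalReport`s for cross-validation and the
#'   held-out test set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(f) file.path(config$out_dir, f)

  ## stage: counts
  cm <- read_count_matrix(config$counts, config$labels)
  stage_msg("counts: %d genes x %d samples (%d tumor / %d normal)",
            nrow(cm$counts), ncol(cm$counts),
            sum(cm$labels == "tumor"), sum(cm$labels == "normal"))

  ## stage: differential expression
  stage_msg("differential expression: normalization=%s, p<%g, FC>%g or FC<%g",
            config$normalization, config$p_thresh, config$fc_up, config$fc_down)
  det <- de_table(cm, method = config$normalization,
                  dispersion = config$dispersion,
                  p_thresh = config$p_thresh, fc_up = config$fc_up,
                  fc_down = config$fc_down)
  deg_call <- call_degs(det, config$p_thresh, config$fc_up, config$fc_down)
  write.table(det, art("deg_table.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  stage_msg("DEGs: %d (%d up, %d down)", nrow(deg_call$degs),
            deg_call$n_up, deg_call$n_down)

  ## stage: enrichment
  enr <- NULL
  significant_sets <- NULL
  if (!is.null(config$gmt)) {
    sets <- read_gmt(config$gmt)
    enr <- enrich(deg_call$degs$gene, sets, universe = rownames(cm$counts),
                  alpha = config$alpha)
    significant_sets <- enr$set_id[enr$significant]
    write.table(enr, art("enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    stage_msg("enrichment: %d / %d sets significant at p < %g",
              length(significant_sets), nrow(enr), config$alpha)
  }

  ## stage: KGML parsing and edge extraction
  files <- sort(list.files(config$kgml_dir, pattern = "\\.xml$",
                           full.names = TRUE))
  if (!length(files)) stop("no KGML .xml files found in ", config$kgml_dir)
  id_map <- if (!is.null(config$id_map)) read_id_map(config$id_map)
  docs <- lapply(files, parse_kgml)
  if (config$restrict_to_significant) {
    if (is.null(significant_sets)) {
      stop("restrict_to_significant requires a GMT-based enrichment stage")
    }
    docs <- Filter(function(d) d$pathway_id %in% significant_sets, docs)
    if (!length(docs)) stop("no KGML pathway matches a significant gene set")
  }
  edge_lists <- lapply(docs, pathway_edges, id_map = id_map)
  stage_msg("KGML: %d pathway files -> %d raw edges", length(docs),
            sum(vapply(edge_lists, nrow, integer(1))))

  ## stage: network, degrees, hubs
  net <- merge_networks(edge_lists)
  deg <- degree_table(net)
  pl <- powerlaw_diagnostic(deg)
  hubs <- hub_genes(deg, min_degree = config$min_degree)
  write_edge_list(net, art("network_edges.tsv"))
  write.table(deg, art("node_degrees.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  stage_msg("network: %d nodes, %d edges; %d hubs with degree > %g",
            length(net$nodes), nrow(net$edges), length(hubs),
            config$min_degree)

  ## stage: markers
  markers <- intersect_markers(deg_call$degs, hubs, deg)
  if (!is.null(config$literature)) {
    markers <- annotate_literature(markers, readLines(config$literature))
  }
  write_markers(markers, art("markers.tsv"))
  stage_msg("markers: %d genes in DEG-hub intersection", nrow(markers))
  if (nrow(markers) == 0) {
    stop("empty marker set: the DEG list and hub set do not overlap; ",
         "halting before classification")
  }

  ## stage: classification
  sf <- normalize_factors(cm, config$normalization)
  expr <- log2(sweep(cm$counts, 2, sf, "/") + 1)
  x <- t(expr[markers$gene, , drop = FALSE])
  y <- ifelse(cm$labels == "tumor", 1, -1)
  split <- stratified_split(cm$labels, config$split_fraction, config$seed)
  stage_msg("split: %d training / %d test samples (fraction %g, seed %d)",
            length(split$train), length(split$test), config$split_fraction,
            config$seed)

  if (config$resubstitution) {
    model_tr <- train_svm(x[split$train, , drop = FALSE], y[split$train],
                          C = config$C)
    train_eval <- evaluate_scores(
      y[split$train], decision_values(model_tr, x[split$train, , drop = FALSE]))
  } else {
    train_eval <- cross_validate(x[split$train, , drop = FALSE],
                                 y[split$train], k = config$folds,
                                 seed = config$seed, C = config$C)
  }
  model <- train_svm(x[split$train, , drop = FALSE], y[split$train],
                     C = config$C)
  test_eval <- evaluate_scores(
    y[split$test], decision_values(model, x[split$test, , drop = FALSE]))
  write_svm_model(model, art("svm_model.json"))
  write_eval_report(train_eval, art("train_eval.json"), art("train_roc.tsv"))
  write_eval_report(test_eval, art("test_eval.json"), art("test_roc.tsv"))
  stage_msg("training (%s): accuracy %.3f, AUC %.3f | test: accuracy %.3f, AUC %.3f",
            if (config$resubstitution) "resubstitution" else "pooled CV",
            train_eval$accuracy, train_eval$auc,
            test_eval$accuracy, test_eval$auc)

  report <- list(
    parameters = list(
      p_thresh = config$p_thresh, fc_up = config$fc_up,
      fc_down = config$fc_down, alpha = config$alpha,
      min_degree = config$min_degree,
      split_fraction = config$split_fraction, folds = config$folds,
      C = config$C, normalization = config$normalization,
      seed = config$seed
    ),
    counts = list(n_genes = nrow(cm$counts), n_samples = ncol(cm$counts),
                  n_tumor = sum(cm$labels == "tumor"),
                  n_normal = sum(cm$labels == "normal")),
    degs = list(n = nrow(deg_call$degs), n_up = deg_call$n_up,
                n_down = deg_call$n_down),
    enrichment = if (!is.null(enr)) {
      list(n_sets = nrow(enr), n_significant = length(significant_sets))
    },
    network = list(n_pathways = length(docs), n_nodes = length(net$nodes),
                   n_edges = nrow(net$edges),
                   powerlaw_exponent = pl$exponent,
                   powerlaw_r_squared = pl$r_squared),
    hubs = list(n = length(hubs), genes = hubs),
    markers = list(n = nrow(markers), genes = markers$gene),
    train_eval = list(confusion = as.list(train_eval$confusion),
                      accuracy = train_eval$accuracy,
                      sensitivity = train_eval$sensitivity,
                      specificity = train_eval$specificity,
                      auc = train_eval$auc),
    test_eval = list(confusion = as.list(test_eval$confusion),
                     accuracy = test_eval$accuracy,
                     sensitivity = test_eval$sensitivity,
                     specificity = test_eval$specificity,
                     auc = test_eval$auc)
  )
  jsonlite::write_json(report, art("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  report$markers_table <- markers
  report$model <- model
  class(report) <- "RunReport"
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat(sprintf(
    paste0("RunReport: %d DEGs (%d up / %d down); network %d nodes / %d ",
           "edges; %d hubs; %d markers\n  training AUC %.3f, test AUC %.3f\n"),
    x$degs$n, x$degs$n_up, x$degs$n_down, x$network$n_nodes,
    x$network$n_edges, x$hubs$n, x$markers$n,
    x$train_eval$auc, x$test_eval$auc
  ))
  invisible(x)
}
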