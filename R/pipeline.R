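# End-to-end orchestration: load -> fingerprint -> matrix -> threshold ->
# build -> classify -> predict -> export, with a run manifest.

#' Assemble and validate a pipeline configuration
#'
#' @param compounds,enzymes,annotation input TSV paths (annotation may be
#'   `NULL`).
#' @param out_dir output directory for run artifacts.
#' @param theta similarity threshold fraction in `[0, 1]` (default 0.65).
#' @param inclusive include pairs exactly at the threshold (default TRUE).
#' @param fingerprint an [fp_config()].
#' @param top_k optional integer; keep only each PDCC's `k` most similar
#'   LDCC.
#' @param strict abort on any invalid input row (default) instead of
#'   dropping with warnings.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(compounds, enzymes, annotation = NULL, out_dir,
                            theta = 0.65, inclusive = TRUE,
                            fingerprint = fp_config(), top_k = NULL,
                            strict = TRUE) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta < 0 || theta > 1)
    stop("theta must be a fraction in [0, 1]")
  stopifnot(inherits(fingerprint, "fp_config"))
  structure(list(compounds = compounds, enzymes = enzymes,
                 annotation = annotation, out_dir = out_dir, theta = theta,
                 inclusive = isTRUE(inclusive), fingerprint = fingerprint,
                 top_k = top_k, strict = isTRUE(strict)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `compounds`, `enzymes`, `annotation`, `out_dir`,
#' `theta`, `inclusive`, `top_k`, `strict`, and a `fingerprint` block with
#' the [fp_config()] fields.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  fp <- do.call(fp_config, y$fingerprint %||% list())
  pipeline_config(
    compounds = y$compounds, enzymes = y$enzymes,
    annotation = y$annotation, out_dir = y$out_dir,
    theta = y$theta %||% 0.65, inclusive = y$inclusive %||% TRUE,
    fingerprint = fp, top_k = y$top_k, strict = y$strict %||% TRUE)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full similarity-to-prediction pipeline
#'
#' Executes the stages load, fingerprint+matrix, threshold, build,
#' classify, predict, export, writing six artifacts into
#' `cfg$out_dir`: `similarity_matrix.tsv`, `edges.tsv`, `network.graphml`,
#' `case_report.tsv`, `predictions.tsv` and `manifest.json` (config,
#' package version, input checksums, per-stage row counts). Identical
#' configuration and inputs produce byte-identical artifacts apart from
#' the manifest's timestamp.
#'
#' @param cfg a `pipeline_config`.
#' @return Invisibly, a list with the in-memory results (`catalog`,
#'   `enzymes`, `annotation`, `matrix`, `edges`, `graph`, `cases`,
#'   `predictions`, `artifact_paths`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  catalog <- .stage("load", {
    if (!file.exists(cfg$compounds))
      stop("compounds file not found: ", cfg$compounds)
    load_compound_catalog(cfg$compounds, strict = cfg$strict)
  })
  enzymes <- .stage("load", {
    if (!file.exists(cfg$enzymes))
      stop("enzymes file not found: ", cfg$enzymes)
    load_enzyme_map(cfg$enzymes, catalog, strict = cfg$strict)
  })
  annotation <- .stage("load", {
    if (is.null(cfg$annotation)) NULL
    else {
      if (!file.exists(cfg$annotation))
        stop("annotation file not found: ", cfg$annotation)
      load_genome_annotation(cfg$annotation)
    }
  })

  mat <- .stage("matrix",
                similarity_matrix(catalog, catalog, cfg$fingerprint))
  edges <- .stage("threshold",
                  threshold_edges(mat, cfg$theta, cfg$inclusive))
  graph <- .stage("build",
                  build_tripartite(edges, enzymes, annotation,
                                   compounds = catalog, top_k = cfg$top_k))
  cases <- .stage("classify", classify_cases(graph))
  predictions <- .stage("predict", {
    part <- igraph::vertex_attr(graph$graph, "partition")
    pdcc <- igraph::V(graph$graph)$name[part == "PDCC"]
    preds <- lapply(pdcc, predict_enzymes, g = graph)
    if (length(preds) == 0L) data.frame()
    else {
      cols <- unique(unlist(lapply(preds, names)))
      preds <- lapply(preds, function(df) {
        for (cn in setdiff(cols, names(df)))
          df[[cn]] <- if (startsWith(cn, "genes_")) integer(nrow(df))
                      else character(nrow(df))
        df[, cols, drop = FALSE]
      })
      do.call(rbind, preds)
    }
  })

  paths <- .stage("export", {
    p_mat <- file.path(cfg$out_dir, "similarity_matrix.tsv")
    write_similarity_tsv(mat, p_mat)
    p_edges <- file.path(cfg$out_dir, "edges.tsv")
    utils::write.table(
      transform(edges, similarity = sprintf("%.6f", similarity)),
      p_edges, sep = "\t", quote = FALSE, row.names = FALSE)
    p_graph <- file.path(cfg$out_dir, "network.graphml")
    export_graph(graph, p_graph, "graphml")
    p_cases <- file.path(cfg$out_dir, "case_report.tsv")
    cases_df <- data.frame(
      pdcc_id = names(cases$labels),
      labels = vapply(cases$labels, paste, character(1), collapse = ","),
      stringsAsFactors = FALSE)
    utils::write.table(cases_df, p_cases, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p_pred <- file.path(cfg$out_dir, "predictions.tsv")
    pred_out <- predictions
    if (nrow(pred_out) > 0L)
      pred_out$similarity <- sprintf("%.6f", pred_out$similarity)
    utils::write.table(pred_out, p_pred, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    c(similarity_matrix = p_mat, edges = p_edges, graph = p_graph,
      cases = p_cases, predictions = p_pred)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("lignoplast")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = list(
      compounds = cfg$compounds, enzymes = cfg$enzymes,
      annotation = cfg$annotation, theta = cfg$theta,
      inclusive = cfg$inclusive, top_k = cfg$top_k, strict = cfg$strict,
      fingerprint = unclass(cfg$fingerprint)),
    input_checksums = as.list(tools::md5sum(
      stats::na.omit(c(cfg$compounds, cfg$enzymes,
                       if (!is.null(cfg$annotation)) cfg$annotation)))),
    stage_counts = list(
      compounds = nrow(catalog), enzymes = nrow(enzymes),
      annotation_rows = if (is.null(annotation)) 0L else nrow(annotation),
      matrix_cells = length(mat$values), edges = nrow(edges),
      graph_nodes = igraph::vcount(graph$graph),
      graph_edges = igraph::ecount(graph$graph),
      predictions = nrow(predictions))
  )
  p_manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, p_manifest, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)

  invisible(list(catalog = catalog, enzymes = enzymes,
                 annotation = annotation, matrix = mat, edges = edges,
                 graph = graph, cases = cases, predictions = predictions,
                 artifact_paths = c(paths, manifest = p_manifest)))
}
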