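# The compound-compound-enzyme tripartite graph: construction from
# thresholded similarity edges plus the enzyme-substrate map, case
# classification, per-PDCC enzyme ranking, and GraphML/TSV export.
#
# Backed by igraph.  Graph semantics are unweighted (no weighted
# algorithms are applied); the similarity fraction is retained as an edge
# attribute because it is what ranks competing enzyme predictions.

#' Build the PDCC-LDCC-enzyme tripartite graph
#'
#' Nodes fall into three partitions: plastic-derived compounds (PDCC),
#' lignin-derived compounds (LDCC) and enzymes (ENZ). Similarity edges
#' (PDCC-LDCC) come from [threshold_edges()]; catalysis edges (LDCC-ENZ)
#' from the enzyme-substrate map. No other edge type exists. LDCC nodes
#' are the union of similarity-edge endpoints and enzyme substrates;
#' enzymes with at least one retained substrate become ENZ nodes. PDCC
#' with no surviving similarity edge are excluded by default (a network
#' display conventionally shows only connected compounds) but can be kept
#' with `drop_isolated = FALSE` when `compounds` is supplied. Node order
#' is deterministic: partitions PDCC, LDCC, ENZ, each sorted
#' lexicographically.
#'
#' A PDCC is connected to every LDCC meeting the threshold, not only its
#' single best match; `top_k` restricts each PDCC to its `k` most similar
#' LDCC (ties broken by LDCC id) for the stricter reading.
#'
#' @param edges data frame from [threshold_edges()] (`pdcc_id`, `ldcc_id`,
#'   `similarity`).
#' @param enzymes an `enzyme_map`.
#' @param annotation optional `genome_annotation`; per-genome gene counts
#'   are attached to every ENZ node (0 where unlisted). Annotation rows
#'   for unknown enzymes produce a warning, not an error.
#' @param compounds optional `compound_catalog` used to attach names/SMILES
#'   and, with `drop_isolated = FALSE`, to include edge-less PDCC.
#' @param drop_isolated exclude PDCC without similarity edges (default).
#' @param top_k optional integer; keep only the `k` highest-similarity
#'   edges per PDCC.
#' @return A `tripartite_graph` wrapping an undirected igraph object with
#'   vertex attributes `partition`, `label`, `smiles`, `ec`, `ko`,
#'   `gene_counts` (serialized `"genome:count;..."`) and edge attributes
#'   `type` (`similarity`/`catalysis`) and `weight` (NA for catalysis).
#' @export
build_tripartite <- function(edges, enzymes, annotation = NULL,
                             compounds = NULL, drop_isolated = TRUE,
                             top_k = NULL) {
  stopifnot(is.data.frame(edges),
            all(c("pdcc_id", "ldcc_id", "similarity") %in% names(edges)),
            inherits(enzymes, "enzyme_map"))
  if (!is.null(top_k)) {
    top_k <- as.integer(top_k)
    if (is.na(top_k) || top_k < 1L) stop("top_k must be a positive integer")
    keep <- unlist(lapply(split(seq_len(nrow(edges)), edges$pdcc_id),
                          function(ii) {
                            ord <- order(-edges$similarity[ii], edges$ldcc_id[ii])
                            ii[ord][seq_len(min(top_k, length(ii)))]
                          }), use.names = FALSE)
    edges <- edges[sort(keep), , drop = FALSE]
  }

  if (!is.null(compounds)) {
    stopifnot(inherits(compounds, "compound_catalog"))
    unknown <- setdiff(c(edges$pdcc_id, edges$ldcc_id), compounds$id)
    if (length(unknown) > 0L)
      stop("edge compound id(s) not in catalog: ",
           paste(unknown, collapse = ", "))
  }

  pdcc_ids <- sort(unique(edges$pdcc_id))
  if (!drop_isolated) {
    if (is.null(compounds))
      stop("drop_isolated = FALSE requires the compound catalog")
    pdcc_ids <- sort(compounds$id[compounds$partition == "PDCC"])
  }
  enz_subs <- enzymes$substrates
  ldcc_ids <- sort(unique(c(edges$ldcc_id, unlist(enz_subs))))
  has_sub <- vapply(enz_subs, function(s) length(intersect(s, ldcc_ids)) > 0L,
                    logical(1))
  enz_ids <- sort(enzymes$id[has_sub])

  overlap <- intersect(intersect(pdcc_ids, ldcc_ids), enz_ids)
  if (length(c(intersect(pdcc_ids, ldcc_ids), intersect(ldcc_ids, enz_ids),
               intersect(pdcc_ids, enz_ids))) > 0L)
    stop("node ids must be unique across partitions")

  ids <- c(pdcc_ids, ldcc_ids, enz_ids)
  partition <- c(rep("PDCC", length(pdcc_ids)), rep("LDCC", length(ldcc_ids)),
                 rep("ENZ", length(enz_ids)))

  label <- ids
  smiles <- rep("", length(ids))
  if (!is.null(compounds)) {
    hit <- match(ids, compounds$id)
    label[!is.na(hit)] <- compounds$name[hit[!is.na(hit)]]
    smiles[!is.na(hit)] <- compounds$smiles[hit[!is.na(hit)]]
  }
  ec <- rep("", length(ids))
  ko <- rep("", length(ids))
  ehit <- match(ids, enzymes$id)
  label[!is.na(ehit)] <- enzymes$name[ehit[!is.na(ehit)]]
  ec[!is.na(ehit)] <- enzymes$ec[ehit[!is.na(ehit)]]
  ko[!is.na(ehit)] <- enzymes$ko[ehit[!is.na(ehit)]]

  gene_counts <- rep("", length(ids))
  if (!is.null(annotation)) {
    stopifnot(inherits(annotation, "genome_annotation"))
    unknown_enz <- setdiff(unique(annotation$enzyme_id), enzymes$id)
    if (length(unknown_enz) > 0L)
      warning("annotation references unknown enzyme(s): ",
              paste(unknown_enz, collapse = ", "))
    genomes <- sort(unique(annotation$genome_id))
    for (k in which(partition == "ENZ")) {
      counts <- vapply(genomes, function(g)
        gene_count(annotation, g, ids[k], warn = FALSE), integer(1))
      gene_counts[k] <- paste(genomes, counts, sep = ":", collapse = ";")
    }
  }

  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  g <- igraph::set_vertex_attr(g, "partition", value = partition)
  g <- igraph::set_vertex_attr(g, "label", value = label)
  g <- igraph::set_vertex_attr(g, "smiles", value = smiles)
  g <- igraph::set_vertex_attr(g, "ec", value = ec)
  g <- igraph::set_vertex_attr(g, "ko", value = ko)
  g <- igraph::set_vertex_attr(g, "gene_counts", value = gene_counts)

  sim_edges <- edges[edges$pdcc_id %in% pdcc_ids, , drop = FALSE]
  ev <- character(0); etype <- character(0); ew <- numeric(0)
  if (nrow(sim_edges) > 0L) {
    ev <- c(ev, rbind(sim_edges$pdcc_id, sim_edges$ldcc_id))
    etype <- c(etype, rep("similarity", nrow(sim_edges)))
    ew <- c(ew, sim_edges$similarity)
  }
  for (i in which(has_sub)) {
    for (s in sort(intersect(enz_subs[[i]], ldcc_ids))) {
      ev <- c(ev, s, enzymes$id[i])
      etype <- c(etype, "catalysis")
      ew <- c(ew, NA_real_)
    }
  }
  if (length(ev) > 0L)
    g <- igraph::add_edges(g, ev, type = etype, weight = ew)

  out <- structure(list(graph = g), class = "tripartite_graph")
  probs <- check_tripartite(out)
  if (length(probs) > 0L)
    stop("constructed graph violates tripartiteness: ",
         paste(probs, collapse = "; "))
  out
}

#' Check the tripartite edge constraints of a graph
#'
#' Verifies that the graph is undirected and loop-free, that similarity
#' edges connect only PDCC-LDCC, catalysis edges only LDCC-ENZ, and that
#' no intra-partition or PDCC-ENZ edges exist.
#'
#' @param g a `tripartite_graph`.
#' @return Character vector of violations; `character(0)` when valid.
#' @export
check_tripartite <- function(g) {
  stopifnot(inherits(g, "tripartite_graph"))
  ig <- g$graph
  probs <- character(0)
  if (igraph::is_directed(ig)) probs <- c(probs, "graph is directed")
  if (any(igraph::which_loop(ig))) probs <- c(probs, "graph has self-loops")
  if (igraph::ecount(ig) == 0L) return(probs)
  part <- igraph::vertex_attr(ig, "partition")
  ends <- igraph::ends(ig, igraph::E(ig), names = FALSE)
  p1 <- part[ends[, 1L]]; p2 <- part[ends[, 2L]]
  type <- igraph::edge_attr(ig, "type")
  pair <- paste(pmin(p1, p2), pmax(p1, p2))
  bad_sim <- type == "similarity" & pair != "LDCC PDCC"
  bad_cat <- type == "catalysis" & pair != "ENZ LDCC"
  bad_type <- !(type %in% c("similarity", "catalysis"))
  if (any(bad_sim))
    probs <- c(probs, sprintf("similarity edge %d joins %s-%s",
                              which(bad_sim), p1[bad_sim], p2[bad_sim]))
  if (any(bad_cat))
    probs <- c(probs, sprintf("catalysis edge %d joins %s-%s",
                              which(bad_cat), p1[bad_cat], p2[bad_cat]))
  if (any(bad_type))
    probs <- c(probs, sprintf("edge %d has unknown type '%s'",
                              which(bad_type), type[bad_type]))
  probs
}

.neighbors_by_type <- function(ig, vname, etype) {
  v <- which(igraph::V(ig)$name == vname)
  inc <- as.integer(igraph::incident(ig, v))
  inc <- inc[igraph::edge_attr(ig, "type", inc) == etype]
  if (length(inc) == 0L) return(character(0))
  e <- igraph::ends(ig, inc, names = TRUE)
  setdiff(as.vector(e), vname)
}

#' Classify plastic compounds into the three network cases
#'
#' For PDCC `p` with LDCC neighborhood `L(p)` and per-LDCC enzyme sets
#' `E(l)`, labels (a PDCC may hold several):
#' * `case_i`: similar to exactly one LDCC, which is catabolized by a
#'   single enzyme;
#' * `case_ii`: similar to two or more LDCC whose enzymes differ (union
#'   of enzyme sets has at least two members);
#' * `case_iii_member`: shares an LDCC having at least two PDCC neighbors
#'   and exactly one enzyme (two plastics funneled through one enzyme);
#' * `unclassified`: none of the above.
#'
#' An LDCC is flagged a hub when it has two or more PDCC neighbors and
#' exactly one enzyme.
#'
#' @param g a `tripartite_graph`.
#' @return A `case_report`: list with `labels` (named list per PDCC),
#'   `hubs` (named logical per LDCC), `counts` (table of label tallies).
#' @export
classify_cases <- function(g) {
  stopifnot(inherits(g, "tripartite_graph"))
  ig <- g$graph
  part <- igraph::vertex_attr(ig, "partition")
  names(part) <- igraph::V(ig)$name
  pdcc <- names(part)[part == "PDCC"]
  ldcc <- names(part)[part == "LDCC"]

  Lp <- lapply(pdcc, .neighbors_by_type, ig = ig, etype = "similarity")
  names(Lp) <- pdcc
  El <- lapply(ldcc, .neighbors_by_type, ig = ig, etype = "catalysis")
  names(El) <- ldcc
  Pl <- lapply(ldcc, .neighbors_by_type, ig = ig, etype = "similarity")
  names(Pl) <- ldcc

  labels <- lapply(pdcc, function(p) {
    L <- Lp[[p]]
    lab <- character(0)
    if (length(L) == 1L && length(El[[L]]) == 1L) lab <- c(lab, "case_i")
    if (length(L) >= 2L && length(unique(unlist(El[L]))) >= 2L)
      lab <- c(lab, "case_ii")
    if (any(vapply(L, function(l) length(Pl[[l]]) >= 2L &&
                     length(El[[l]]) == 1L, logical(1))))
      lab <- c(lab, "case_iii_member")
    if (length(lab) == 0L) lab <- "unclassified"
    lab
  })
  names(labels) <- pdcc
  hubs <- vapply(ldcc, function(l) length(Pl[[l]]) >= 2L &&
                   length(El[[l]]) == 1L, logical(1))
  counts <- table(factor(unlist(labels),
                         levels = c("case_i", "case_ii", "case_iii_member",
                                    "unclassified")))
  structure(list(labels = labels, hubs = hubs, counts = counts),
            class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat("<case_report>\n")
  print(x$counts)
  invisible(x)
}

#' Rank candidate enzymes for a plastic-derived compound
#'
#' Walks every similarity edge of `pdcc_id` to its LDCC neighbors and on
#' to their enzymes. Each reachable enzyme yields one prediction through
#' its best-supporting LDCC (highest similarity; ties broken by LDCC id).
#' Predictions are ranked by similarity descending with ties broken by
#' enzyme id, and carry the per-genome gene counts stored on the enzyme
#' node.
#'
#' @param g a `tripartite_graph`.
#' @param pdcc_id id of a PDCC node.
#' @return Data frame with columns `pdcc_id`, `enzyme_id`,
#'   `supporting_ldcc_id`, `similarity`, `ec`, and one `genes_<genome>`
#'   column per annotated genome. Zero rows when no enzyme is reachable.
#' @export
predict_enzymes <- function(g, pdcc_id) {
  stopifnot(inherits(g, "tripartite_graph"))
  ig <- g$graph
  vn <- igraph::V(ig)$name
  if (!(pdcc_id %in% vn)) stop("unknown node id: ", pdcc_id)
  if (igraph::vertex_attr(ig, "partition", which(vn == pdcc_id)) != "PDCC")
    stop("node '", pdcc_id, "' is not a PDCC")

  v <- which(vn == pdcc_id)
  inc <- as.integer(igraph::incident(ig, v))
  inc <- inc[igraph::edge_attr(ig, "type", inc) == "similarity"]
  empty <- data.frame(pdcc_id = character(0), enzyme_id = character(0),
                      supporting_ldcc_id = character(0),
                      similarity = numeric(0), ec = character(0),
                      stringsAsFactors = FALSE)
  if (length(inc) == 0L) return(empty)
  lends <- igraph::ends(ig, inc, names = TRUE)
  ldcc <- apply(lends, 1L, function(r) setdiff(r, pdcc_id)[1L])
  sim <- igraph::edge_attr(ig, "weight", inc)

  rows <- list()
  for (k in order(-sim, ldcc)) {
    for (e in sort(.neighbors_by_type(ig, ldcc[k], "catalysis"))) {
      if (!is.null(rows[[e]])) next  # best supporting LDCC already found
      rows[[e]] <- data.frame(pdcc_id = pdcc_id, enzyme_id = e,
                              supporting_ldcc_id = ldcc[k],
                              similarity = sim[k],
                              ec = igraph::vertex_attr(ig, "ec",
                                                       which(vn == e)),
                              stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$similarity, out$enzyme_id), , drop = FALSE]
  rownames(out) <- NULL

  gc <- igraph::vertex_attr(ig, "gene_counts", match(out$enzyme_id, vn))
  if (any(nzchar(gc))) {
    parsed <- lapply(gc, .parse_gene_counts)
    genomes <- sort(unique(unlist(lapply(parsed, names))))
    for (gm in genomes) {
      out[[paste0("genes_", gm)]] <-
        vapply(parsed, function(p) if (gm %in% names(p)) p[[gm]] else 0L,
               integer(1))
    }
  }
  out
}

.parse_gene_counts <- function(s) {
  if (!nzchar(s)) return(integer(0))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  counts <- vapply(kv, function(x) as.integer(x[2L]), integer(1))
  names(counts) <- vapply(kv, `[[`, character(1), 1L)
  counts
}

#' Export a tripartite graph
#'
#' `format = "graphml"` writes standard GraphML (re-importable with
#' [import_graph()] into an isomorphic attributed graph). `format =
#' "edge_tsv"` writes `<path>_nodes.tsv` (id, partition, label, smiles,
#' ec, ko, gene_counts) and `<path>_edges.tsv` (from, to, type, weight;
#' weight empty for catalysis edges).
#'
#' @param g a `tripartite_graph`.
#' @param path output file path (for `edge_tsv`, a prefix).
#' @param format `"graphml"` or `"edge_tsv"`.
#' @return The path(s) written, invisibly.
#' @export
export_graph <- function(g, path, format = c("graphml", "edge_tsv")) {
  stopifnot(inherits(g, "tripartite_graph"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(g$graph, path, format = "graphml")
    return(invisible(path))
  }
  ig <- g$graph
  nodes <- data.frame(
    id = igraph::V(ig)$name,
    partition = igraph::vertex_attr(ig, "partition"),
    label = igraph::vertex_attr(ig, "label"),
    smiles = igraph::vertex_attr(ig, "smiles"),
    ec = igraph::vertex_attr(ig, "ec"),
    ko = igraph::vertex_attr(ig, "ko"),
    gene_counts = igraph::vertex_attr(ig, "gene_counts"),
    stringsAsFactors = FALSE
  )
  ends <- igraph::ends(ig, igraph::E(ig), names = TRUE)
  w <- igraph::edge_attr(ig, "weight")
  edges <- data.frame(
    from = if (igraph::ecount(ig)) ends[, 1L] else character(0),
    to = if (igraph::ecount(ig)) ends[, 2L] else character(0),
    type = igraph::edge_attr(ig, "type") %||% character(0),
    weight = if (igraph::ecount(ig))
      ifelse(is.na(w), "", sprintf("%.6f", w)) else character(0),
    stringsAsFactors = FALSE
  )
  npath <- paste0(path, "_nodes.tsv")
  epath <- paste0(path, "_edges.tsv")
  utils::write.table(nodes, npath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(edges, epath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(npath, epath))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Re-import a GraphML tripartite graph
#'
#' @param path GraphML file written by [export_graph()].
#' @return A `tripartite_graph`.
#' @export
import_graph <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  # igraph serializes NA as NaN in GraphML; restore NA on catalysis edges
  if (igraph::ecount(ig) > 0L) {
    w <- igraph::edge_attr(ig, "weight")
    if (!is.null(w)) {
      w[is.nan(w)] <- NA_real_
      ig <- igraph::set_edge_attr(ig, "weight", value = w)
    }
  }
  out <- structure(list(graph = ig), class = "tripartite_graph")
  probs <- check_tripartite(out)
  if (length(probs) > 0L)
    stop("imported graph violates tripartiteness: ",
         paste(probs, collapse = "; "))
  out
}

#' @export
print.tripartite_graph <- function(x, ...) {
  ig <- x$graph
  part <- igraph::vertex_attr(ig, "partition")
  type <- igraph::edge_attr(ig, "type")
  cat(sprintf(paste0("<tripartite_graph> %d PDCC, %d LDCC, %d ENZ; ",
                     "%d similarity + %d catalysis edges\n"),
              sum(part == "PDCC"), sum(part == "LDCC"), sum(part == "ENZ"),
              sum(type == "similarity"), sum(type == "catalysis")))
  invisible(x)
}

#' @export
summary.tripartite_graph <- function(object, ...) {
  ig <- object$graph
  part <- igraph::vertex_attr(ig, "partition")
  type <- igraph::edge_attr(ig, "type")
  rep <- classify_cases(object)
  out <- list(
    n_pdcc = sum(part == "PDCC"), n_ldcc = sum(part == "LDCC"),
    n_enz = sum(part == "ENZ"),
    n_similarity_edges = sum(type == "similarity"),
    n_catalysis_edges = sum(type == "catalysis"),
    case_counts = rep$counts
  )
  class(out) <- "summary.tripartite_graph"
  out
}

#' @export
print.summary.tripartite_graph <- function(x, ...) {
  cat(sprintf("Nodes: %d PDCC, %d LDCC, %d ENZ\n", x$n_pdcc, x$n_ldcc, x$n_enz))
  cat(sprintf("Edges: %d similarity, %d catalysis\n",
              x$n_similarity_edges, x$n_catalysis_edges))
  cat("Case tallies:\n")
  print(x$case_counts)
  invisible(x)
}
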