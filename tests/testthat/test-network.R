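# Tripartite graph construction, case classification, enzyme ranking,
# and export round-trips.

test_that("a minimal edge plus one enzyme builds a 3-node graph", {
  edges <- toy_sim_edges(c("p1", "l1", "0.8"))
  enz <- toy_enzyme_map(list(list(id = "e1", name = "E1", substrates = "l1")))
  g <- build_tripartite(edges, enz)
  ig <- g$graph
  expect_equal(igraph::vcount(ig), 3L)
  types <- igraph::edge_attr(ig, "type")
  expect_equal(sort(types), c("catalysis", "similarity"))
  expect_identical(check_tripartite(g), character(0))
})

test_that("an empty edge list leaves only the catalysis structure", {
  edges <- toy_sim_edges()[0, ]
  edges <- data.frame(pdcc_id = character(0), ldcc_id = character(0),
                      similarity = numeric(0))
  enz <- toy_enzyme_map(list(list(id = "e1", name = "E1",
                                  substrates = c("l1", "l2"))))
  g <- build_tripartite(edges, enz)
  part <- igraph::vertex_attr(g$graph, "partition")
  expect_equal(sum(part == "PDCC"), 0L)
  expect_equal(sum(part == "LDCC"), 2L)
  expect_equal(sum(part == "ENZ"), 1L)
  expect_equal(sum(igraph::edge_attr(g$graph, "type") == "catalysis"), 2L)
})

test_that("gene counts from the annotation land on enzyme nodes", {
  edges <- toy_sim_edges(c("p1", "l1", "0.9"))
  enz <- toy_enzyme_map(list(list(id = "e1", name = "E1", substrates = "l1")))
  ann <- structure(
    data.frame(genome_id = c("MAG1", "MAG4"), enzyme_id = "e1",
               gene_count = c(2L, 0L), stringsAsFactors = FALSE),
    class = c("genome_annotation", "data.frame"))
  g <- build_tripartite(edges, enz, ann)
  gc <- igraph::vertex_attr(g$graph, "gene_counts",
                            which(igraph::V(g$graph)$name == "e1"))
  expect_equal(gc, "MAG1:2;MAG4:0")
  # unknown enzyme in annotation warns but does not abort
  ann2 <- structure(
    data.frame(genome_id = "MAG1", enzyme_id = "ghost", gene_count = 1L,
               stringsAsFactors = FALSE),
    class = c("genome_annotation", "data.frame"))
  expect_warning(build_tripartite(edges, enz, ann2), "unknown enzyme")
})

test_that("case classification reproduces the three hand-built motifs", {
  enz1 <- toy_enzyme_map(list(list(id = "e1", name = "E1", substrates = "l1")))
  # motif (i): one PDCC - one LDCC - one enzyme
  g1 <- build_tripartite(toy_sim_edges(c("p1", "l1", "0.8")), enz1)
  expect_equal(classify_cases(g1)$labels$p1, "case_i")

  # motif (ii): one PDCC - two LDCC with different enzymes
  enz2 <- toy_enzyme_map(list(
    list(id = "e1", name = "E1", substrates = "l1"),
    list(id = "e2", name = "E2", substrates = "l2")))
  g2 <- build_tripartite(toy_sim_edges(c("p1", "l1", "0.8"),
                                       c("p1", "l2", "0.7")), enz2)
  expect_equal(classify_cases(g2)$labels$p1, "case_ii")

  # motif (iii): two PDCC sharing one LDCC with a single enzyme
  g3 <- build_tripartite(toy_sim_edges(c("p1", "l1", "0.8"),
                                       c("p2", "l1", "0.7")), enz1)
  cr3 <- classify_cases(g3)
  expect_true("case_iii_member" %in% cr3$labels$p1)
  expect_true("case_iii_member" %in% cr3$labels$p2)
  expect_true(cr3$hubs[["l1"]])

  # a PDCC whose only LDCC has no enzyme stays unclassified
  enz4 <- toy_enzyme_map(list(list(id = "e1", name = "E1", substrates = "l9")))
  g4 <- build_tripartite(toy_sim_edges(c("p1", "l1", "0.8")), enz4)
  expect_equal(classify_cases(g4)$labels$p1, "unclassified")
})

test_that("classification depends on topology only, not on node names", {
  enz <- toy_enzyme_map(list(
    list(id = "zz_enzyme", name = "E", substrates = "mm_l")))
  g <- build_tripartite(toy_sim_edges(c("aa_p", "mm_l", "0.9"),
                                      c("bb_p", "mm_l", "0.8")), enz)
  cr <- classify_cases(g)
  counts <- as.vector(cr$counts)
  enzB <- toy_enzyme_map(list(
    list(id = "a_enzyme", name = "E", substrates = "z_l")))
  gB <- build_tripartite(toy_sim_edges(c("q_p", "z_l", "0.9"),
                                       c("r_p", "z_l", "0.8")), enzB)
  expect_equal(as.vector(classify_cases(gB)$counts), counts)
})

test_that("every PDCC receives at least one label", {
  fx <- builtin_fixture()
  mat <- similarity_matrix(fx$compounds, fx$compounds, fp_config("path"))
  g <- build_tripartite(threshold_edges(mat, 0.3), fx$enzymes,
                        compounds = fx$compounds)
  cr <- classify_cases(g)
  expect_true(all(lengths(cr$labels) >= 1L))
})

test_that("predict_enzymes ranks by similarity with deterministic ties", {
  enz <- toy_enzyme_map(list(
    list(id = "e1", name = "E1", substrates = "l1"),
    list(id = "e2", name = "E2", substrates = "l2")))
  g <- build_tripartite(toy_sim_edges(c("p1", "l1", "0.8"),
                                      c("p1", "l2", "0.7")), enz)
  pr <- predict_enzymes(g, "p1")
  expect_equal(pr$enzyme_id, c("e1", "e2"))
  expect_equal(pr$supporting_ldcc_id, c("l1", "l2"))
  expect_equal(pr$similarity, c(0.8, 0.7))

  # tie on similarity -> enzyme id lexicographic
  gt <- build_tripartite(toy_sim_edges(c("p1", "l1", "0.7"),
                                       c("p1", "l2", "0.7")), enz)
  expect_equal(predict_enzymes(gt, "p1")$enzyme_id, c("e1", "e2"))

  # one enzyme reachable through two LDCC -> best supporting LDCC kept
  enzS <- toy_enzyme_map(list(
    list(id = "e1", name = "E1", substrates = c("l1", "l2"))))
  gs <- build_tripartite(toy_sim_edges(c("p1", "l1", "0.7"),
                                       c("p1", "l2", "0.9")), enzS)
  prs <- predict_enzymes(gs, "p1")
  expect_equal(nrow(prs), 1L)
  expect_equal(prs$supporting_ldcc_id, "l2")
  expect_equal(prs$similarity, 0.9)
})

test_that("predict_enzymes handles unknown ids and empty reach", {
  enz <- toy_enzyme_map(list(list(id = "e1", name = "E1", substrates = "l9")))
  g <- build_tripartite(toy_sim_edges(c("p1", "l1", "0.8")), enz)
  expect_equal(nrow(predict_enzymes(g, "p1")), 0L)
  expect_error(predict_enzymes(g, "nope"), "unknown node")
  expect_error(predict_enzymes(g, "l1"), "not a PDCC")
})

test_that("prediction similarities sit at or above the build threshold", {
  fx <- builtin_fixture()
  mat <- similarity_matrix(fx$compounds, fx$compounds, fp_config("path"))
  theta <- 0.4
  g <- build_tripartite(threshold_edges(mat, theta), fx$enzymes,
                        compounds = fx$compounds)
  part <- igraph::vertex_attr(g$graph, "partition")
  for (p in igraph::V(g$graph)$name[part == "PDCC"]) {
    pr <- predict_enzymes(g, p)
    if (nrow(pr) > 0L) expect_true(all(pr$similarity >= theta))
    expect_false(anyDuplicated(pr$enzyme_id) > 0L)
  }
})

test_that("top_k restricts each PDCC to its best-matching LDCC", {
  enz <- toy_enzyme_map(list(
    list(id = "e1", name = "E1", substrates = "l1"),
    list(id = "e2", name = "E2", substrates = "l2")))
  g <- build_tripartite(toy_sim_edges(c("p1", "l1", "0.9"),
                                      c("p1", "l2", "0.7")), enz, top_k = 1)
  expect_equal(sum(igraph::edge_attr(g$graph, "type") == "similarity"), 1L)
  expect_equal(predict_enzymes(g, "p1")$enzyme_id, "e1")
})

test_that("GraphML export round-trips an isomorphic attributed graph", {
  fx <- builtin_fixture()
  mat <- similarity_matrix(fx$compounds, fx$compounds, fp_config("path"))
  g <- build_tripartite(threshold_edges(mat, 0.4), fx$enzymes, fx$annotation,
                        compounds = fx$compounds)
  f <- tempfile(fileext = ".graphml")
  export_graph(g, f, "graphml")
  g2 <- import_graph(f)
  expect_identical(check_tripartite(g2), character(0))
  expect_equal(igraph::vcount(g2$graph), igraph::vcount(g$graph))
  expect_equal(igraph::ecount(g2$graph), igraph::ecount(g$graph))
  for (at in c("name", "partition", "label", "smiles", "ec", "gene_counts")) {
    expect_equal(sort(igraph::vertex_attr(g2$graph, at)),
                 sort(igraph::vertex_attr(g$graph, at)))
  }
  expect_true(igraph::isomorphic(g$graph, g2$graph))
  # prediction results identical after round-trip
  expect_equal(predict_enzymes(g2, "terephthalate"),
               predict_enzymes(g, "terephthalate"))
})

test_that("edge TSV export writes nodes and edges tables", {
  edges <- toy_sim_edges(c("p1", "l1", "0.8"))
  enz <- toy_enzyme_map(list(list(id = "e1", name = "E1", substrates = "l1")))
  g <- build_tripartite(edges, enz)
  prefix <- tempfile()
  export_graph(g, prefix, "edge_tsv")
  nodes <- read.delim(paste0(prefix, "_nodes.tsv"))
  eds <- read.delim(paste0(prefix, "_edges.tsv"), colClasses = "character")
  expect_equal(nrow(nodes), 3L)
  expect_equal(nrow(eds), 2L)
  sim_row <- eds[eds$type == "similarity", ]
  cat_row <- eds[eds$type == "catalysis", ]
  expect_match(sim_row$weight, "^0\\.8")
  expect_equal(cat_row$weight, "")
})

test_that("an empty graph still exports valid files with headers", {
  edges <- data.frame(pdcc_id = character(0), ldcc_id = character(0),
                      similarity = numeric(0))
  enz <- toy_enzyme_map(list(list(id = "e1", name = "E1",
                                  substrates = character(0))))
  g <- build_tripartite(edges, enz)
  prefix <- tempfile()
  export_graph(g, prefix, "edge_tsv")
  expect_equal(nrow(read.delim(paste0(prefix, "_edges.tsv"))), 0L)
})
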