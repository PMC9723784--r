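# Tanimoto coefficient, similarity matrix, and threshold edge selection.

make_fp <- function(bits, name = "x", cfg = fp_config("path")) {
  lignoplast:::new_fingerprint(bits, cfg$n_bits, cfg, name)
}

test_that("tanimoto matches hand arithmetic and conventions", {
  expect_equal(tanimoto(make_fp(c(1, 3, 5)), make_fp(c(3, 5, 7))), 0.5)
  f <- make_fp(c(0, 10, 100))
  expect_equal(tanimoto(f, f), 1)
  expect_equal(tanimoto(make_fp(c(1, 2)), make_fp(c(3, 4))), 0)
  expect_warning(z <- tanimoto(make_fp(integer(0)), make_fp(integer(0))),
                 "both fingerprints empty")
  expect_equal(z, 0)
})

test_that("tanimoto rejects mismatched configurations", {
  a <- make_fp(1:3, cfg = fp_config("path"))
  b <- make_fp(1:3, cfg = fp_config("morgan"))
  expect_error(tanimoto(a, b), "configuration mismatch")
  d <- make_fp(1:3, cfg = fp_config("path", n_bits = 1024L))
  expect_error(tanimoto(a, d), "configuration mismatch")
})

test_that("tanimoto equals the brute-force membership-array oracle", {
  set.seed(7)
  cfg <- fp_config("path", n_bits = 256L)
  for (i in 1:200) {
    na <- sample(0:40, 1); nb <- sample(0:40, 1)
    ba <- sort(sample(0:255, na)); bb <- sort(sample(0:255, nb))
    a <- make_fp(ba, cfg = cfg); b <- make_fp(bb, cfg = cfg)
    expected <- tanimoto_oracle(ba, bb, 256L)
    got <- if (na == 0 && nb == 0) suppressWarnings(tanimoto(a, b))
           else tanimoto(a, b)
    expect_identical(got, expected)
    expect_identical(suppressWarnings(tanimoto(b, a)), expected)  # symmetry
    expect_gte(got, 0); expect_lte(got, 1)
  }
})

test_that("similarity_matrix covers all pairs with values in [0,1]", {
  pd <- list(p1 = parse_smiles("CCO"), p2 = parse_smiles("CCC"))
  ld <- list(l1 = parse_smiles("CCN"), l2 = parse_smiles("CCCC"),
             l3 = parse_smiles("c1ccccc1"))
  m <- similarity_matrix(pd, ld, fp_config("path"))
  expect_equal(dim(m$values), c(2L, 3L))
  expect_true(all(m$values >= 0 & m$values <= 1))
  # swapping a shared pair across the two lists transposes its value
  m2 <- similarity_matrix(list(p1 = ld$l1), list(l1 = pd$p1), fp_config("path"))
  expect_equal(m2$values[1, 1], m$values["p1", "l1"])
})

test_that("identical compounds give similarity exactly 1", {
  m <- similarity_matrix(list(a = parse_smiles("CCO")),
                         list(b = parse_smiles("OCC")), fp_config("path"))
  expect_equal(unname(m$values[1, 1]), 1)
})

test_that("duplicate ids across lists are fatal", {
  expect_error(
    similarity_matrix(list(x = parse_smiles("CCO")),
                      list(x = parse_smiles("CCC"))),
    "duplicate compound id")
})

test_that("threshold_edges honors boundary and inclusivity semantics", {
  vals <- matrix(c(0.64, 0.65), 1, 2,
                 dimnames = list("p", c("l1", "l2")))
  m <- structure(list(values = vals, row_ids = "p", col_ids = c("l1", "l2"),
                      fp_config = fp_config("path")),
                 class = "similarity_matrix")
  e <- threshold_edges(m, 0.65)
  expect_equal(nrow(e), 1L)
  expect_equal(e$ldcc_id, "l2")
  expect_equal(nrow(threshold_edges(m, 0.65, inclusive = FALSE)), 0L)
  expect_equal(nrow(threshold_edges(m, 0)), 2L)
  one <- structure(list(values = matrix(1, 1, 1, dimnames = list("p", "l")),
                        row_ids = "p", col_ids = "l",
                        fp_config = fp_config("path")),
                   class = "similarity_matrix")
  expect_equal(nrow(threshold_edges(one, 1)), 1L)
  expect_error(threshold_edges(m, 1.01), "fraction")
})

test_that("edge sets shrink monotonically as the threshold rises", {
  set.seed(11)
  vals <- matrix(runif(30), 5, 6,
                 dimnames = list(paste0("p", 1:5), paste0("l", 1:6)))
  m <- structure(list(values = vals, row_ids = rownames(vals),
                      col_ids = colnames(vals), fp_config = fp_config("path")),
                 class = "similarity_matrix")
  thetas <- sort(runif(6))
  prev <- threshold_edges(m, thetas[1])
  for (th in thetas[-1]) {
    cur <- threshold_edges(m, th)
    expect_lte(nrow(cur), nrow(prev))
    key <- function(df) paste(df$pdcc_id, df$ldcc_id)
    expect_true(all(key(cur) %in% key(prev)))
    prev <- cur
  }
})

test_that("edge order is deterministic row-major", {
  vals <- matrix(1, 2, 2, dimnames = list(c("pB", "pA"), c("lB", "lA")))
  m <- structure(list(values = vals, row_ids = c("pB", "pA"),
                      col_ids = c("lB", "lA"), fp_config = fp_config("path")),
                 class = "similarity_matrix")
  e <- threshold_edges(m, 0)
  expect_equal(e$pdcc_id, c("pB", "pB", "pA", "pA"))
  expect_equal(e$ldcc_id, c("lB", "lA", "lB", "lA"))
})

test_that("similarity matrix TSV round-trips shape and 4-decimal values", {
  pd <- list(p1 = parse_smiles("CCO"), p2 = parse_smiles("CCC"))
  ld <- list(l1 = parse_smiles("CCN"), l2 = parse_smiles("CCCC"))
  m <- similarity_matrix(pd, ld, fp_config("path"))
  f <- tempfile(fileext = ".tsv")
  write_similarity_tsv(m, f)
  m2 <- read_similarity_tsv(f)
  expect_equal(m2$row_ids, m$row_ids)
  expect_equal(m2$col_ids, m$col_ids)
  expect_equal(m2$values, round(m$values, 4), tolerance = 1e-12)
})
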