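# Path and Morgan fingerprint schemes and their hash foundation.

test_that("the FNV-1a 64-bit hash matches an independent limb-arithmetic oracle", {
  strings <- c("", "a", "C-C", "C-C-O", "c:c", "A|C|2|0|0|1",
               "terephthalic acid", "élément")
  expect_identical(lignoplast:::fnv1a64_hex(strings),
                   vapply(strings, fnv1a64_oracle, character(1),
                          USE.NAMES = FALSE))
  set.seed(42)
  rand <- vapply(1:50, function(i)
    paste(sample(c(letters, "-", "=", ":", "#"), sample(1:20, 1),
                 replace = TRUE), collapse = ""), character(1))
  for (nb in c(64L, 2048L, 1000L)) {
    expect_identical(lignoplast:::fnv1a64_mod(rand, nb),
                     vapply(rand, fnv1a64_mod_oracle, integer(1),
                            n_bits = nb, USE.NAMES = FALSE))
  }
})

test_that("enumerate_paths returns canonical deduplicated path strings", {
  expect_equal(enumerate_paths(parse_smiles("CCO", "ethanol"), 2),
               sort(c("C-C", "C-O", "C-C-O")))
  expect_equal(enumerate_paths(parse_smiles("c1ccccc1", "benzene"), 1),
               "c:c")
  expect_equal(enumerate_paths(parse_smiles("CCC", "propane"), 7),
               sort(c("C-C", "C-C-C")))
  # charged atoms carry their charge in the token
  expect_equal(enumerate_paths(parse_smiles("C[N+](C)(C)C", "tetramethylammonium"), 1),
               "C-N+1")
})

test_that("path fingerprints hash each distinct path to one bit", {
  cfg <- fp_config("path", n_bits = 2048L)
  fp <- path_fingerprint(parse_smiles("CCC", "propane"), cfg)
  expected <- unique(vapply(c("C-C", "C-C-C"), fnv1a64_mod_oracle,
                            integer(1), n_bits = 2048L, USE.NAMES = FALSE))
  expect_setequal(fp$bits, expected)
  expect_length(fp$bits, 2L)  # the two hashes do not collide at 2048 bits
})

test_that("single-atom molecules cannot be path-fingerprinted", {
  expect_error(path_fingerprint(parse_smiles("O", "water")), "single-atom")
})

test_that("Kekule and aromatic spellings fingerprint identically", {
  a <- parse_smiles("c1ccccc1", "benzene")
  k <- kekule_aromatize(parse_smiles("C1=CC=CC=C1", "benzene"))
  for (cfg in list(fp_config("path"), fp_config("morgan"))) {
    fa <- compute_fingerprint(a, cfg)
    fk <- compute_fingerprint(k, cfg)
    expect_identical(fa$bits, fk$bits)
  }
  # also with substituents
  a2 <- parse_smiles("OC(=O)c1ccccc1", "benzoic acid")
  k2 <- kekule_aromatize(parse_smiles("OC(=O)C1=CC=CC=C1", "benzoic acid"))
  expect_identical(path_fingerprint(a2)$bits, path_fingerprint(k2)$bits)
})

test_that("path bits are monotone in max_path_len", {
  mols <- list(parse_smiles("OC(=O)c1ccc(cc1)C(=O)O", "terephthalic acid"),
               parse_smiles("COc1cc(ccc1O)C(=O)O", "vanillate"),
               parse_smiles("CCC(O)CC(=O)O", "3-hydroxyvalerate"))
  for (m in mols) {
    for (k in 1:6) {
      b1 <- path_fingerprint(m, fp_config("path", max_path_len = k))$bits
      b2 <- path_fingerprint(m, fp_config("path", max_path_len = k + 1L))$bits
      expect_true(all(b1 %in% b2))
    }
  }
})

test_that("morgan fingerprints hit the identifier-count bounds", {
  cfg0 <- fp_config("morgan", radius = 0L)
  expect_length(morgan_fingerprint(parse_smiles("C", "methane"), cfg0)$bits, 1L)

  cfg1 <- fp_config("morgan", radius = 1L)
  nb <- length(morgan_fingerprint(parse_smiles("CCO", "ethanol"), cfg1)$bits)
  expect_gte(nb, 3L)  # three distinct round-0 invariants
  expect_lte(nb, 6L)

  cfg2 <- fp_config("morgan", radius = 2L)
  benz <- morgan_fingerprint(parse_smiles("c1ccccc1", "benzene"), cfg2)
  expect_lte(length(benz$bits), 18L)  # <= 6 atoms x 3 rounds
})

test_that("morgan fingerprints are invariant to atom input order", {
  spellings <- list(
    ethanol = c("CCO", "OCC", "C(O)C"),
    vanillate = c("COc1cc(ccc1O)C(=O)O", "OC(=O)c1ccc(O)c(OC)c1"),
    tpa = c("OC(=O)c1ccc(cc1)C(=O)O", "O=C(O)c1ccc(C(=O)O)cc1")
  )
  for (cfg in list(fp_config("morgan"), fp_config("path"))) {
    for (sp in spellings) {
      fps <- lapply(sp, function(s) compute_fingerprint(parse_smiles(s), cfg))
      for (i in seq_along(fps)[-1])
        expect_identical(fps[[i]]$bits, fps[[1]]$bits)
    }
  }
})

test_that("fingerprints are deterministic across repeated computation", {
  m <- parse_smiles("COc1cc(ccc1O)C(=O)O", "vanillate")
  for (cfg in list(fp_config("path"), fp_config("morgan"))) {
    expect_identical(compute_fingerprint(m, cfg)$bits,
                     compute_fingerprint(m, cfg)$bits)
  }
})

test_that("shared substructure yields heavily overlapping path bits", {
  cfg <- fp_config("path")
  ba <- path_fingerprint(parse_smiles("OC(=O)c1ccccc1", "benzoic acid"), cfg)
  tpa <- path_fingerprint(parse_smiles("OC(=O)c1ccc(cc1)C(=O)O",
                                       "terephthalic acid"), cfg)
  shared <- length(intersect(ba$bits, tpa$bits))
  expect_gt(shared / length(ba$bits), 0.5)
})

test_that("compute_fingerprint rejects unknown schemes and missing backends", {
  m <- parse_smiles("CCO", "ethanol")
  cfg <- fp_config("path")
  cfg$scheme <- "bogus"
  expect_error(compute_fingerprint(m, cfg), "unknown fingerprint scheme")
  # a backend that cannot exist -> capability error naming the backend
  withr_opts <- options(lignoplast.python = "/nonexistent/python-binary")
  on.exit(options(withr_opts), add = TRUE)
  expect_error(compute_fingerprint(m, fp_config("toolkit_default")),
               "RDKit")
})

test_that("fingerprint TSV export writes one row per molecule", {
  fps <- list(path_fingerprint(parse_smiles("CCO", "ethanol")),
              path_fingerprint(parse_smiles("CCC", "propane")))
  f <- tempfile(fileext = ".tsv")
  write_fingerprints_tsv(fps, f)
  df <- read.delim(f)
  expect_equal(nrow(df), 2L)
  expect_equal(df$n_bits, c(2048L, 2048L))
  expect_equal(strsplit(df$bits[2], ",")[[1]],
               as.character(sort(fps[[2]]$bits)))
})
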