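# Synthetic compound-family benchmark with known ground truth.
#
# Families are built by decorating a shared scaffold with random
# substituents, so within-family pairs stay structurally close while
# cross-family pairs (different scaffolds) stay apart.  Each family gets
# LDCC members, PDCC members and one enzyme whose substrates are exactly
# the family's LDCC; the truth table maps every PDCC to its family enzyme.
# The scaffold and substituent libraries are fixed in code so published
# test values stay reproducible.

.SCAFFOLDS <- list(
  benzene = list(fmt = "c1c%sc%sc%scc1", n_slots = 3L),
  phenol  = list(fmt = "Oc1c%sc%sc%scc1", n_slots = 3L),
  c4_acid = list(fmt = "OC(=O)C%sC%sC%s", n_slots = 3L),
  furan   = list(fmt = "c1c%sc%sc%so1", n_slots = 3L)
)

.SUBSTITUENTS <- c(methyl = "C", hydroxyl = "O", carboxyl = "C(=O)O",
                   methoxy = "OC", amino = "N")

#' Names of the built-in scaffolds
#' @return Character vector of scaffold ids.
#' @export
scaffold_library <- function() names(.SCAFFOLDS)

#' Generate one compound family by scaffold decoration
#'
#' Each member is the scaffold with every substitution slot independently
#' decorated with probability `decoration_rate` by a substituent drawn
#' uniformly from methyl, hydroxyl, carboxyl, methoxy, amino. Members are
#' deduplicated by resampling on collision within a bounded retry budget.
#' Draws consume the current R random stream, so callers control
#' reproducibility by seeding.
#'
#' @param scaffold_id one of [scaffold_library()].
#' @param n_members number of distinct molecules to produce.
#' @param decoration_rate per-slot decoration probability in `[0, 1]`.
#' @param max_retries retry budget for the whole family.
#' @return Character vector of `n_members` distinct SMILES, all parseable
#'   by [parse_smiles()].
#' @export
generate_family <- function(scaffold_id, n_members, decoration_rate,
                            max_retries = 100L * n_members) {
  sc <- .SCAFFOLDS[[scaffold_id]]
  if (is.null(sc)) stop("unknown scaffold: ", scaffold_id)
  n_members <- as.integer(n_members)
  if (is.na(n_members) || n_members < 1L) stop("n_members must be >= 1")
  if (!is.numeric(decoration_rate) || decoration_rate < 0 ||
      decoration_rate > 1)
    stop("decoration_rate must be in [0, 1]")
  if (decoration_rate == 0 && n_members > 1L)
    stop("decoration_rate 0 cannot yield ", n_members,
         " distinct molecules (all members identical)")

  out <- character(0)
  tries <- 0L
  while (length(out) < n_members) {
    if (tries >= max_retries)
      stop("could not produce ", n_members, " distinct members of scaffold '",
           scaffold_id, "' within ", max_retries, " attempts")
    tries <- tries + 1L
    slots <- vapply(seq_len(sc$n_slots), function(k) {
      if (stats::runif(1) < decoration_rate)
        sprintf("(%s)", .SUBSTITUENTS[[sample(length(.SUBSTITUENTS), 1L)]])
      else ""
    }, character(1))
    smi <- do.call(sprintf, c(list(sc$fmt), as.list(slots)))
    if (!(smi %in% out)) out <- c(out, smi)
  }
  for (smi in out) parse_smiles(smi)  # generator contract: all must parse
  out
}

#' Default benchmark parameters
#'
#' @param n_families number of compound families (>= 2).
#' @param ldcc_per_family,pdcc_per_family members per partition per family.
#' @param decoration_rate per-slot decoration probability.
#' @param seed integer seed for the benchmark's random stream.
#' @return A named list of generator parameters.
#' @export
benchmark_params <- function(n_families = 4L, ldcc_per_family = 4L,
                             pdcc_per_family = 4L, decoration_rate = 0.3,
                             seed = 1L) {
  list(n_families = as.integer(n_families),
       ldcc_per_family = as.integer(ldcc_per_family),
       pdcc_per_family = as.integer(pdcc_per_family),
       decoration_rate = decoration_rate, seed = as.integer(seed))
}

#' Generate a synthetic benchmark with known ground truth
#'
#' Assigns scaffolds to families round-robin, generates
#' `ldcc_per_family + pdcc_per_family` distinct members per family, one
#' enzyme per family with substrates = the family's LDCC, and a genome
#' annotation drawing each enzyme's gene count uniformly from 1--4 in each
#' of three synthetic genomes. All draws consume a single stream seeded
#' from `params$seed` (the caller's RNG state is preserved), so identical
#' parameters regenerate identical benchmarks.
#'
#' @param params list from [benchmark_params()].
#' @return A `synthetic_benchmark`: list with `compounds`
#'   (`compound_catalog`-shaped data frame), `enzymes` (`enzyme_map`),
#'   `annotation` (`genome_annotation`), `truth` (data frame `pdcc_id`,
#'   `family`, `enzyme_id`) and `params`.
#' @export
generate_benchmark <- function(params = benchmark_params()) {
  p <- params
  if (p$n_families < 2L) stop("n_families must be >= 2")
  if (p$ldcc_per_family < 1L || p$pdcc_per_family < 1L)
    stop("ldcc_per_family and pdcc_per_family must be >= 1")

  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(p$seed)

  scaffolds <- rep(scaffold_library(), length.out = p$n_families)
  comp <- list(); enz <- list(); truth <- list()
  for (f in seq_len(p$n_families)) {
    fam <- sprintf("fam%d", f)
    n_tot <- p$ldcc_per_family + p$pdcc_per_family
    smis <- generate_family(scaffolds[f], n_tot, p$decoration_rate)
    ldcc_ids <- sprintf("%s_ldcc%d", fam, seq_len(p$ldcc_per_family))
    pdcc_ids <- sprintf("%s_pdcc%d", fam, seq_len(p$pdcc_per_family))
    ids <- c(ldcc_ids, pdcc_ids)
    comp[[f]] <- data.frame(
      id = ids, name = ids, smiles = smis,
      partition = c(rep("LDCC", p$ldcc_per_family),
                    rep("PDCC", p$pdcc_per_family)),
      xref = "", stringsAsFactors = FALSE)
    enz_id <- sprintf("enz_%s", fam)
    enz[[f]] <- list(id = enz_id, name = sprintf("synthetic enzyme %s", fam),
                     ec = "", ko = "", substrates = ldcc_ids)
    truth[[f]] <- data.frame(pdcc_id = pdcc_ids, family = fam,
                             enzyme_id = enz_id, stringsAsFactors = FALSE)
  }
  compounds <- do.call(rbind, comp)
  mols <- lapply(seq_len(nrow(compounds)),
                 function(i) parse_smiles(compounds$smiles[i],
                                          compounds$name[i]))
  names(mols) <- compounds$id
  compounds <- structure(compounds, molecules = mols,
                         class = c("compound_catalog", "data.frame"))

  enzymes <- data.frame(
    id = vapply(enz, `[[`, character(1), "id"),
    name = vapply(enz, `[[`, character(1), "name"),
    ec = "", ko = "", stringsAsFactors = FALSE)
  enzymes$substrates <- lapply(enz, `[[`, "substrates")
  enzymes <- structure(enzymes, class = c("enzyme_map", "data.frame"))

  genomes <- sprintf("G%d", 1:3)
  ann <- expand.grid(genome_id = genomes, enzyme_id = enzymes$id,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ann <- ann[order(ann$genome_id, ann$enzyme_id), , drop = FALSE]
  rownames(ann) <- NULL
  ann$gene_count <- sample(1:4, nrow(ann), replace = TRUE)
  annotation <- structure(ann, class = c("genome_annotation", "data.frame"))

  structure(list(compounds = compounds, enzymes = enzymes,
                 annotation = annotation, truth = do.call(rbind, truth),
                 params = p),
            class = "synthetic_benchmark")
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_benchmark> %d families, %d compounds, ",
                     "%d enzymes (seed %d)\n"),
              x$params$n_families, nrow(x$compounds), nrow(x$enzymes),
              x$params$seed))
  invisible(x)
}

#' Write a benchmark as the standard TSV inputs plus the truth table
#'
#' Writes `compounds.tsv`, `enzymes.tsv`, `annotation.tsv` (the three
#' pipeline input schemas) and `truth.tsv` (`pdcc_id`, `family`,
#' `enzyme_id`) into `dir`. Output is byte-identical for identical
#' parameters.
#'
#' @param bench a `synthetic_benchmark`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  stopifnot(inherits(bench, "synthetic_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(as.data.frame(bench$compounds), "compounds.tsv")
  edf <- bench$enzymes
  edf$substrates <- vapply(edf$substrates, paste, character(1), collapse = ",")
  wt(as.data.frame(edf), "enzymes.tsv")
  wt(as.data.frame(bench$annotation), "annotation.tsv")
  wt(bench$truth, "truth.tsv")
  invisible(dir)
}

#' Score enzyme-recovery accuracy against ground truth
#'
#' @param predictions named list, PDCC id -> ordered character vector of
#'   predicted enzyme ids (may be empty).
#' @param truth data frame (`pdcc_id`, `family`, `enzyme_id`) covering all
#'   scored PDCC; a prediction for a PDCC absent from truth is an error.
#' @return A `recovery_report`: list with `top1_accuracy` (fraction of
#'   PDCC whose first-ranked enzyme is the true one; empty lists count as
#'   failures), `per_family` (named accuracy vector), `n_unpredicted`,
#'   `n_scored`.
#' @export
score_recovery <- function(predictions, truth) {
  stopifnot(is.list(predictions), is.data.frame(truth),
            all(c("pdcc_id", "family", "enzyme_id") %in% names(truth)))
  unknown <- setdiff(names(predictions), truth$pdcc_id)
  if (length(unknown) > 0L)
    stop("prediction(s) for PDCC absent from truth: ",
         paste(unknown, collapse = ", "))
  scored <- truth$pdcc_id
  correct <- logical(length(scored))
  unpred <- 0L
  for (i in seq_along(scored)) {
    p <- predictions[[scored[i]]]
    if (is.null(p) || length(p) == 0L) {
      unpred <- unpred + 1L
      next
    }
    correct[i] <- identical(p[1L], truth$enzyme_id[i])
  }
  per_family <- tapply(correct, truth$family, mean)
  structure(list(top1_accuracy = mean(correct),
                 per_family = per_family,
                 n_unpredicted = unpred,
                 n_scored = length(scored)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> top-1 accuracy %.3f (%d scored, %d unpredicted)\n",
              x$top1_accuracy, x$n_scored, x$n_unpredicted))
  invisible(x)
}
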