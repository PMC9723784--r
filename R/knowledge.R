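# Ingest of the three tabular inputs: compound catalogs, the
# enzyme-substrate map, and per-genome gene counts.  All three are
# UTF-8 tab-delimited files; lines starting with '#' are comments.

.read_tsv <- function(path, required, optional = character(0)) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE, na.strings = NULL,
                          colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("missing column(s) ", paste(missing, collapse = ", "), " in ", path)
  for (col in optional) if (!(col %in% names(df))) df[[col]] <- ""
  df
}

#' Load a compound catalog
#'
#' Reads a TSV with columns `id`, `name`, `smiles`, `partition` (one of
#' `LDCC`, `PDCC`) and optional `xref`, validating every SMILES with
#' [parse_smiles()]. Duplicate ids are always fatal. In strict mode
#' (default) any invalid row aborts the load; in lenient mode bad rows are
#' dropped with one warning each.
#'
#' @param path TSV file path.
#' @param strict abort on any invalid row (default) instead of dropping it.
#' @return A `compound_catalog`: data frame with the columns above plus a
#'   `"molecules"` attribute holding the parsed [parse_smiles()] graphs,
#'   named by id.
#' @export
load_compound_catalog <- function(path, strict = TRUE) {
  df <- .read_tsv(path, c("id", "name", "smiles", "partition"), "xref")
  if (anyDuplicated(df$id))
    stop("duplicate compound id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  bad_part <- !(df$partition %in% c("LDCC", "PDCC"))
  if (any(bad_part)) {
    msg <- paste0("invalid partition for id(s): ",
                  paste(df$id[bad_part], collapse = ", "))
    if (strict) stop(msg)
    warning(msg, "; rows dropped")
    df <- df[!bad_part, , drop = FALSE]
  }
  mols <- vector("list", nrow(df))
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    mols[[i]] <- tryCatch(parse_smiles(df$smiles[i], df$name[i]),
                          error = function(e) e)
    if (inherits(mols[[i]], "error")) {
      msg <- paste0("compound '", df$id[i], "': ",
                    conditionMessage(mols[[i]]))
      if (strict) stop(msg)
      warning(msg, "; row dropped")
      keep[i] <- FALSE
    }
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  mols <- mols[keep]
  names(mols) <- df$id
  structure(df, molecules = mols, class = c("compound_catalog", "data.frame"))
}

#' Load the enzyme-substrate map
#'
#' Reads a TSV with columns `id`, `name`, `ec`, `ko`, `substrates`
#' (comma-separated LDCC compound ids). `ec` and `ko` may be empty.
#' Substrate ids are resolved against the catalog: ids that are missing or
#' belong to the PDCC partition are reported, and an enzyme left with zero
#' resolvable substrates is fatal in strict mode (dropped with a warning
#' otherwise).
#'
#' @param path TSV file path.
#' @param catalog a `compound_catalog` to resolve substrate ids against.
#' @param strict abort on an enzyme with zero resolvable substrates.
#' @return An `enzyme_map`: data frame with columns `id`, `name`, `ec`,
#'   `ko` and a list-column `substrates` of resolved LDCC ids.
#' @export
load_enzyme_map <- function(path, catalog, strict = TRUE) {
  stopifnot(inherits(catalog, "compound_catalog"))
  df <- .read_tsv(path, c("id", "name", "ec", "ko", "substrates"))
  if (anyDuplicated(df$id))
    stop("duplicate enzyme id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  ldcc_ids <- catalog$id[catalog$partition == "LDCC"]
  subs <- vector("list", nrow(df))
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    raw <- trimws(strsplit(df$substrates[i], ",", fixed = TRUE)[[1]])
    raw <- raw[nzchar(raw)]
    unresolved <- setdiff(raw, ldcc_ids)
    if (length(unresolved) > 0L)
      warning("enzyme '", df$id[i], "': unresolved substrate id(s) ",
              paste(unresolved, collapse = ", "),
              " (not in the LDCC partition)")
    resolved <- intersect(raw, ldcc_ids)
    if (length(resolved) == 0L) {
      msg <- paste0("enzyme '", df$id[i], "' has zero resolvable substrates")
      if (strict) stop(msg)
      warning(msg, "; row dropped")
      keep[i] <- FALSE
    }
    subs[[i]] <- resolved
  }
  out <- data.frame(id = df$id, name = df$name, ec = df$ec, ko = df$ko,
                    stringsAsFactors = FALSE)
  out$substrates <- subs
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enzyme_map", "data.frame"))
}

#' Load per-genome enzyme gene counts
#'
#' Reads a TSV with columns `genome_id`, `enzyme_id`, `gene_count`
#' (non-negative integers). Enzymes absent for a genome default to count 0
#' at query time (see [gene_count()]).
#'
#' @param path TSV file path.
#' @return A `genome_annotation`: data frame with the three columns.
#' @export
load_genome_annotation <- function(path) {
  df <- .read_tsv(path, c("genome_id", "enzyme_id", "gene_count"))
  counts <- suppressWarnings(as.numeric(df$gene_count))
  bad <- is.na(counts) | counts < 0 | counts != floor(counts)
  if (any(bad))
    stop("invalid gene_count (must be a non-negative integer) in row(s): ",
         paste(which(bad), collapse = ", "))
  df$gene_count <- as.integer(counts)
  if (anyDuplicated(df[c("genome_id", "enzyme_id")]))
    stop("duplicate (genome_id, enzyme_id) pair in ", path)
  structure(df, class = c("genome_annotation", "data.frame"))
}

#' Look up a gene count, defaulting to zero
#'
#' @param annotation a `genome_annotation`.
#' @param genome_id,enzyme_id identifiers to look up.
#' @param warn warn when the pair is not listed (default TRUE).
#' @return Integer gene count; 0 with a warning for unlisted pairs.
#' @export
gene_count <- function(annotation, genome_id, enzyme_id, warn = TRUE) {
  stopifnot(inherits(annotation, "genome_annotation"))
  hit <- annotation$genome_id == genome_id & annotation$enzyme_id == enzyme_id
  if (!any(hit)) {
    if (warn)
      warning("no annotation for (", genome_id, ", ", enzyme_id,
              "); returning 0")
    return(0L)
  }
  annotation$gene_count[hit][1L]
}

#' Packaged worked-example fixture
#'
#' Loads the small compound/enzyme/genome tables shipped with the package:
#' the plastic-derived compounds (monomethyl phthalate,
#' 3,4-dihydroxyphthalate, terephthalic acid, 3-hydroxybutyric acid,
#' 3-hydroxyvalerate), the lignin-derived compounds of the aerobic aromatic
#' funnel (vanillate, cis,cis-muconic acid, benzoic acid, catechol,
#' protocatechuate, 4-hydroxybenzoate, salicylate, 3-oxoadipate), and the
#' enzymes that catabolize them with their EC/KO anchors (e.g. muconate
#' cycloisomerase EC 5.5.1.1, benzoate 1,2-dioxygenase EC 1.14.12.10,
#' vanillate monooxygenase EC 1.14.13.82). SMILES were transcribed from
#' each compound's standard structure. The per-genome gene counts for
#' MAG1/MAG4/MAG5 are illustrative toy values for the worked example, not
#' measurements.
#'
#' @return List with elements `compounds` (`compound_catalog`), `enzymes`
#'   (`enzyme_map`) and `annotation` (`genome_annotation`).
#' @export
builtin_fixture <- function() {
  dir <- system.file("extdata", package = "lignoplast", mustWork = TRUE)
  compounds <- load_compound_catalog(file.path(dir, "fixture_compounds.tsv"))
  enzymes <- load_enzyme_map(file.path(dir, "fixture_enzymes.tsv"), compounds)
  annotation <- load_genome_annotation(file.path(dir, "fixture_annotation.tsv"))
  list(compounds = compounds, enzymes = enzymes, annotation = annotation)
}
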