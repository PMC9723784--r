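# Tanimoto similarity, the PDCC x LDCC similarity matrix, and thresholded
# edge lists.

#' Tanimoto coefficient between two fingerprints
#'
#' `|A intersect B| / |A union B|` over the on-bit sets. Both fingerprints
#' must have been produced under an identical configuration. When both bit
#' sets are empty the coefficient is defined as 0 and a warning is issued
#' (the common toolkit convention; it avoids spurious similarity between
#' featureless inputs).
#'
#' @param a,b `fingerprint` objects.
#' @return A fraction in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (!identical(a$config, b$config) || a$n_bits != b$n_bits)
    stop("fingerprint configuration mismatch between '", a$molecule_name,
         "' and '", b$molecule_name, "'")
  if (length(a$bits) == 0L && length(b$bits) == 0L) {
    warning("both fingerprints empty (", a$molecule_name, ", ",
            b$molecule_name, "); Tanimoto defined as 0")
    return(0)
  }
  inter <- length(intersect(a$bits, b$bits))
  inter / (length(a$bits) + length(b$bits) - inter)
}

#' Pairwise PDCC x LDCC Tanimoto similarity matrix
#'
#' Fingerprints every molecule once under `cfg` (for the toolkit backend,
#' in a single batched subprocess call) and fills the full rectangular
#' matrix of Tanimoto values, rows = PDCC, columns = LDCC.
#'
#' @param pdcc,ldcc named lists of `molecule` objects (names are compound
#'   ids) or `compound_catalog` data frames, in which case the respective
#'   partition is taken.
#' @param cfg an [fp_config()].
#' @return A `similarity_matrix`: list with `values` (numeric matrix in
#'   `[0,1]` with dimnames), `row_ids`, `col_ids`, `fp_config`.
#' @export
similarity_matrix <- function(pdcc, ldcc, cfg = fp_config()) {
  pdcc <- .as_molecule_list(pdcc, "PDCC")
  ldcc <- .as_molecule_list(ldcc, "LDCC")
  if (length(pdcc) == 0L || length(ldcc) == 0L)
    stop("both compound lists must be non-empty")
  ids <- c(names(pdcc), names(ldcc))
  if (is.null(names(pdcc)) || is.null(names(ldcc)) || any(!nzchar(ids)))
    stop("molecule lists must be named by compound id")
  if (anyDuplicated(ids))
    stop("duplicate compound id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  mols <- c(pdcc, ldcc)
  for (i in seq_along(mols)) mols[[i]]$name <- ids[i]
  fps <- if (cfg$scheme == "toolkit_default") {
    toolkit_fingerprints(mols, cfg)
  } else {
    failed <- character(0)
    out <- vector("list", length(mols))
    for (i in seq_along(mols)) {
      out[[i]] <- tryCatch(compute_fingerprint(mols[[i]], cfg),
                           error = function(e) {
                             failed <<- c(failed, ids[i]); NULL
                           })
    }
    if (length(failed) > 0L)
      stop("fingerprinting failed for compound(s): ",
           paste(failed, collapse = ", "))
    out
  }
  names(fps) <- ids

  nr <- length(pdcc); nc <- length(ldcc)
  vals <- matrix(NA_real_, nr, nc,
                 dimnames = list(names(pdcc), names(ldcc)))
  for (i in seq_len(nr)) {
    fa <- fps[[i]]
    for (j in seq_len(nc)) vals[i, j] <- tanimoto(fa, fps[[nr + j]])
  }
  structure(list(values = vals, row_ids = names(pdcc), col_ids = names(ldcc),
                 fp_config = cfg),
            class = "similarity_matrix")
}

.as_molecule_list <- function(x, what) {
  if (inherits(x, "compound_catalog")) {
    x <- x[x$partition == what, , drop = FALSE]
    mols <- attr(x, "molecules")[x$id]
    if (is.null(mols) || any(vapply(mols, is.null, logical(1))))
      mols <- lapply(seq_len(nrow(x)),
                     function(i) parse_smiles(x$smiles[i], x$name[i]))
    names(mols) <- x$id
    return(mols)
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "molecule"))) return(x)
  stop(what, " must be a named list of molecules or a compound_catalog")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d PDCC x %d LDCC (%s fingerprints)\n",
              length(x$row_ids), length(x$col_ids), x$fp_config$scheme))
  invisible(x)
}

#' Select compound pairs at or above a similarity threshold
#'
#' Returns the similarity edges of the tripartite graph: all (PDCC, LDCC)
#' pairs whose unrounded Tanimoto fraction is `>= theta` (or `> theta`
#' when `inclusive = FALSE`), in deterministic row-major order. The
#' default threshold is 0.65, i.e. 65% structural similarity.
#'
#' @param m a `similarity_matrix`.
#' @param theta threshold fraction in `[0, 1]`.
#' @param inclusive include pairs exactly at the threshold (default TRUE).
#' @return Data frame with columns `pdcc_id`, `ldcc_id`, `similarity`.
#' @export
threshold_edges <- function(m, theta = 0.65, inclusive = TRUE) {
  stopifnot(inherits(m, "similarity_matrix"))
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta < 0 || theta > 1)
    stop("theta must be a fraction in [0, 1]")
  keep <- if (inclusive) m$values >= theta else m$values > theta
  idx <- which(t(keep))  # row-major order
  if (length(idx) == 0L)
    return(data.frame(pdcc_id = character(0), ldcc_id = character(0),
                      similarity = numeric(0), stringsAsFactors = FALSE))
  nc <- length(m$col_ids)
  rows <- (idx - 1L) %/% nc + 1L
  cols <- (idx - 1L) %% nc + 1L
  data.frame(pdcc_id = m$row_ids[rows], ldcc_id = m$col_ids[cols],
             similarity = m$values[cbind(rows, cols)],
             stringsAsFactors = FALSE)
}

#' Write a similarity matrix as TSV
#'
#' First row holds the LDCC ids, first column the PDCC ids; cells are
#' fractions printed with 4 decimals. Note the printed file is for
#' presentation/exchange; thresholding inside the pipeline always uses the
#' unrounded fractions.
#'
#' @param m a `similarity_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(m, path) {
  stopifnot(inherits(m, "similarity_matrix"))
  df <- as.data.frame(matrix(sprintf("%.4f", m$values),
                             nrow = length(m$row_ids)),
                      stringsAsFactors = FALSE)
  names(df) <- m$col_ids
  df <- cbind(pdcc_id = m$row_ids, df, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity matrix written by [write_similarity_tsv()]
#'
#' @param path TSV file path.
#' @param fp_config optionally, the configuration the values were computed
#'   under (not recoverable from the file itself).
#' @return A `similarity_matrix`.
#' @export
read_similarity_tsv <- function(path, fp_config = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  row_ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  dimnames(vals) <- list(row_ids, names(df)[-1L])
  structure(list(values = vals, row_ids = row_ids, col_ids = names(df)[-1L],
                 fp_config = fp_config),
            class = "similarity_matrix")
}
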