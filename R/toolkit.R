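# Literature-compatibility fingerprint backend.
#
# The self-contained path/morgan schemes are bit-reproducible but do not
# reproduce published similarity values computed with RDKit.  The
# "toolkit_default" scheme shells out to a Python interpreter with RDKit
# installed (the interpreter is found via option "lignoplast.python", env
# var LIGNOPLAST_PYTHON, or plain "python" on the PATH) and computes either
# MACCS structural keys (the default; 166 keys) or RDKit's default
# path-based topological fingerprint with n_bits honored.

.python_cmd <- function() {
  opt <- getOption("lignoplast.python", "")
  if (nzchar(opt)) return(opt)
  env <- Sys.getenv("LIGNOPLAST_PYTHON", "")
  if (nzchar(env)) return(env)
  "python"
}

#' Is the RDKit fingerprint backend available?
#'
#' Checks that a Python interpreter can be launched and that it can import
#' RDKit. The interpreter is taken from `getOption("lignoplast.python")`,
#' the `LIGNOPLAST_PYTHON` environment variable, or `python` on the PATH.
#'
#' @return `TRUE` or `FALSE`.
#' @export
rdkit_available <- function() {
  py <- .python_cmd()
  status <- tryCatch(
    suppressWarnings(system2(py, c("-c", shQuote("import rdkit")),
                             stdout = FALSE, stderr = FALSE)),
    error = function(e) 127L)
  identical(status, 0L)
}

#' Compute toolkit-backend fingerprints for a batch of molecules
#'
#' Delegates to RDKit through an external Python process. With
#' `cfg$toolkit_fp = "maccs"` (the default) the backend computes MACCS
#' structural keys, the convention that reproduces the published percent
#' similarities; with `"topological"` it computes RDKit's default
#' path-based fingerprint at `cfg$n_bits` bits. All molecules are
#' fingerprinted in a single subprocess call. Raises a capability error
#' naming the missing backend when no RDKit-capable interpreter is found.
#'
#' @param molecules list of `molecule` objects (their source SMILES are
#'   passed to the backend).
#' @param cfg an [fp_config()] with `scheme = "toolkit_default"`.
#' @return List of `fingerprint` objects, in input order.
#' @export
toolkit_fingerprints <- function(molecules, cfg = fp_config("toolkit_default")) {
  stopifnot(inherits(cfg, "fp_config"))
  if (cfg$scheme != "toolkit_default")
    stop("cfg$scheme must be 'toolkit_default'")
  if (!rdkit_available())
    stop("fingerprint scheme 'toolkit_default' requires the RDKit backend: ",
         "no Python interpreter with an importable 'rdkit' module was found ",
         "(looked for '", .python_cmd(), "'); install RDKit or use the ",
         "self-contained 'path'/'morgan' schemes")
  for (m in molecules) {
    if (!inherits(m, "molecule")) stop("toolkit_fingerprints expects molecules")
  }
  names_ <- unname(vapply(molecules, `[[`, character(1), "name"))
  smiles <- unname(vapply(molecules, `[[`, character(1), "smiles"))
  if (anyDuplicated(names_)) stop("duplicate molecule names in batch")

  script <- system.file("python", "rdkit_fp.py", package = "lignoplast",
                        mustWork = TRUE)
  infile <- tempfile(fileext = ".tsv")
  outfile <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(c("name\tsmiles", paste(names_, smiles, sep = "\t")), infile)
  err <- tempfile()
  status <- system2(.python_cmd(),
                    c(shQuote(script), "--fptype", cfg$toolkit_fp,
                      "--nbits", cfg$n_bits, shQuote(infile), shQuote(outfile)),
                    stdout = FALSE, stderr = err)
  if (!identical(status, 0L)) {
    msg <- tryCatch(paste(readLines(err), collapse = "; "),
                    error = function(e) "")
    stop("RDKit backend failed (exit ", status, "): ", msg)
  }
  res <- utils::read.delim(outfile, stringsAsFactors = FALSE,
                           colClasses = c("character", "integer", "character"))
  if (!identical(res$name, names_))
    stop("RDKit backend returned unexpected molecule set")
  lapply(seq_len(nrow(res)), function(i) {
    bits <- if (nzchar(res$bits[i]))
      as.integer(strsplit(res$bits[i], ",", fixed = TRUE)[[1]]) else integer(0)
    new_fingerprint(bits, res$n_bits[i], cfg, res$name[i])
  })
}
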