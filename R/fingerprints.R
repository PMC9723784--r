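# Fixed-length bit-set fingerprints of molecular graphs.
#
# Two self-contained schemes (linear-path hashing and Morgan/circular) are
# fully specified here, bit-reproducible from the FNV-1a 64-bit hash alone.
# A third scheme, "toolkit_default", delegates to an external RDKit backend
# (see toolkit.R) for similarity values comparable with published analyses.

#' Fingerprint configuration
#'
#' Bundles the scheme and its parameters so every fingerprint carries the
#' exact recipe that produced it; Tanimoto comparison requires identical
#' configurations.
#'
#' @param scheme `"path"` (linear atom-bond paths up to `max_path_len`
#'   bonds), `"morgan"` (circular environments up to `radius`), or
#'   `"toolkit_default"` (external RDKit backend; see
#'   [toolkit_fingerprints()]).
#' @param n_bits fingerprint length in bits (default 2048). A power of two
#'   is recommended but any positive value is accepted. Ignored by the
#'   MACCS toolkit backend, which has a fixed key set.
#' @param max_path_len maximum path length in bonds, 1--7 (path scheme).
#' @param radius neighborhood radius in bonds (morgan scheme).
#' @param hash_name identifier of the feature hash; only `"fnv1a64"`
#'   (FNV-1a, 64-bit, over the UTF-8 feature string) is implemented.
#' @param toolkit_fp which backend fingerprint the `toolkit_default`
#'   scheme requests: `"maccs"` (166 structural keys; reproduces the
#'   published similarity values) or `"topological"` (RDKit's default
#'   path-based fingerprint, `n_bits` honored).
#' @return An `fp_config` object.
#' @export
fp_config <- function(scheme = c("path", "morgan", "toolkit_default"),
                      n_bits = 2048L, max_path_len = 7L, radius = 2L,
                      hash_name = "fnv1a64",
                      toolkit_fp = c("maccs", "topological")) {
  scheme <- match.arg(scheme)
  toolkit_fp <- match.arg(toolkit_fp)
  n_bits <- as.integer(n_bits)
  if (is.na(n_bits) || n_bits < 1L) stop("n_bits must be a positive integer")
  max_path_len <- as.integer(max_path_len)
  if (is.na(max_path_len) || max_path_len < 1L || max_path_len > 7L)
    stop("max_path_len must be between 1 and 7 bonds")
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 0L) stop("radius must be a non-negative integer")
  if (!identical(hash_name, "fnv1a64"))
    stop("unsupported hash: ", hash_name, " (only 'fnv1a64' is implemented)")
  structure(list(scheme = scheme, n_bits = n_bits,
                 max_path_len = max_path_len, radius = radius,
                 hash_name = hash_name, toolkit_fp = toolkit_fp),
            class = "fp_config")
}

new_fingerprint <- function(bits, n_bits, config, molecule_name) {
  bits <- sort(unique(as.integer(bits)))
  stopifnot(all(bits >= 0L), all(bits < n_bits))
  structure(list(bits = bits, n_bits = as.integer(n_bits), config = config,
                 molecule_name = molecule_name),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> %s: %d/%d bits set (%s)\n",
              x$molecule_name, length(x$bits), x$n_bits, x$config$scheme))
  invisible(x)
}

# Token for an atom in a path string: element symbol, lowercased when
# aromatic, with "+n"/"-n" appended when charged.
.atom_token <- function(element, aromatic, charge) {
  tok <- ifelse(aromatic, tolower(element), element)
  ifelse(charge > 0L, paste0(tok, "+", charge),
         ifelse(charge < 0L, paste0(tok, "-", abs(charge)), tok))
}

.BOND_TOKEN <- c(single = "-", double = "=", triple = "#", aromatic = ":")

#' Enumerate canonical linear path strings of a molecule
#'
#' Finds all simple paths (no repeated atom) of 1 to `max_path_len` bonds,
#' serializes each in both directions as alternating atom and bond tokens,
#' keeps the lexicographically smaller string, and returns the distinct
#' strings sorted. Atom tokens are element symbols, lowercased when
#' aromatic, with `+n`/`-n` appended for formal charges; bond tokens are
#' `-`, `=`, `#`, `:`.
#'
#' @param m a `molecule`.
#' @param max_path_len maximum path length in bonds (at least 1).
#' @return Sorted character vector of distinct canonical path strings.
#' @examples
#' enumerate_paths(parse_smiles("CCO", "ethanol"), 2)  # "C-C" "C-C-O" "C-O"
#' @export
enumerate_paths <- function(m, max_path_len = 7L) {
  stopifnot(inherits(m, "molecule"), max_path_len >= 1L)
  n <- nrow(m$atoms)
  atok <- .atom_token(m$atoms$element, m$atoms$aromatic, m$atoms$charge)
  nb <- nrow(m$bonds)
  if (nb == 0L) return(character(0))
  # adjacency with bond tokens
  adj <- vector("list", n)
  for (k in seq_len(nb)) {
    a <- m$bonds$a[k]; b <- m$bonds$b[k]
    tok <- .BOND_TOKEN[[m$bonds$order[k]]]
    adj[[a]] <- rbind(adj[[a]], c(b, tok))
    adj[[b]] <- rbind(adj[[b]], c(a, tok))
  }
  out <- new.env(parent = emptyenv())
  dfs <- function(path, fwd) {
    last <- path[length(path)]
    edges <- adj[[last]]
    for (r in seq_len(nrow(edges))) {
      nxt <- as.integer(edges[r, 1L]); btok <- edges[r, 2L]
      if (nxt %in% path) next
      f <- paste0(fwd, btok, atok[nxt])
      p2 <- c(path, nxt)
      assign(f, TRUE, envir = out)
      if (length(p2) - 1L < max_path_len) dfs(p2, f)
    }
  }
  # Generate all directed path strings, then canonicalize by min(fwd, rev).
  # Directed generation from every start atom yields each undirected path
  # in both orientations, so pairing is done at collection time.
  for (v in seq_len(n)) dfs(v, atok[v])
  strings <- ls(out)
  # pair each string with its reversal: reparse tokens
  canon <- vapply(strings, function(sstr) {
    toks <- .split_path_tokens(sstr)
    rev_s <- paste(rev(toks), collapse = "")
    if (rev_s < sstr) rev_s else sstr
  }, character(1), USE.NAMES = FALSE)
  sort(unique(canon))
}

# Split a serialized path string back into tokens (atom and bond alternating).
.split_path_tokens <- function(s) {
  regmatches(s, gregexpr("[A-Za-z][a-z]?(?:[+-][0-9]+)?|[-=#:]", s))[[1]]
}

#' Path (topological) fingerprint
#'
#' Hashes each distinct canonical path string from [enumerate_paths()] to
#' one bit: index = FNV-1a 64-bit hash of the string, modulo `n_bits`.
#' Deterministic across runs and platforms. A single-atom molecule has no
#' paths of one or more bonds and is an error rather than a silently empty
#' fingerprint (which would make every Tanimoto value 0).
#'
#' @param m a `molecule`.
#' @param cfg an [fp_config()] with `scheme = "path"`.
#' @return A `fingerprint`.
#' @export
path_fingerprint <- function(m, cfg = fp_config("path")) {
  stopifnot(inherits(m, "molecule"), inherits(cfg, "fp_config"))
  if (cfg$scheme != "path") stop("cfg$scheme must be 'path'")
  if (nrow(m$atoms) == 0L) stop("empty molecule: ", m$name)
  paths <- enumerate_paths(m, cfg$max_path_len)
  if (length(paths) == 0L)
    stop("no paths of >= 1 bond in '", m$name,
         "' (single-atom molecules cannot be path-fingerprinted)")
  new_fingerprint(fnv1a64_mod(paths, cfg$n_bits), cfg$n_bits, cfg, m$name)
}

#' Morgan (circular, ECFP-style) fingerprint
#'
#' The initial invariant of each atom is the hash of its element, heavy-atom
#' degree, formal charge, aromatic flag and implicit hydrogen count. For
#' each round `r = 1..radius`, an atom's identifier is rehashed from its own
#' previous identifier together with the sorted (bond-order token, neighbor
#' previous identifier) pairs. Every identifier from every round sets the
#' bit `hash(identifier) mod n_bits`; duplicate environments are not
#' suppressed. Identifiers depend only on local structure, so atom input
#' order cannot change the result.
#'
#' @param m a `molecule`.
#' @param cfg an [fp_config()] with `scheme = "morgan"`.
#' @return A `fingerprint`.
#' @export
morgan_fingerprint <- function(m, cfg = fp_config("morgan")) {
  stopifnot(inherits(m, "molecule"), inherits(cfg, "fp_config"))
  if (cfg$scheme != "morgan") stop("cfg$scheme must be 'morgan'")
  n <- nrow(m$atoms)
  if (n == 0L) stop("empty molecule: ", m$name)
  adj <- vector("list", n)
  for (k in seq_len(nrow(m$bonds))) {
    a <- m$bonds$a[k]; b <- m$bonds$b[k]
    tok <- .BOND_TOKEN[[m$bonds$order[k]]]
    adj[[a]] <- rbind(adj[[a]], c(b, tok))
    adj[[b]] <- rbind(adj[[b]], c(a, tok))
  }
  degree <- vapply(adj, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  ids <- fnv1a64_hex(sprintf("A|%s|%d|%d|%d|%d",
                             m$atoms$element, degree, m$atoms$charge,
                             as.integer(m$atoms$aromatic),
                             m$atoms$implicit_h))
  all_ids <- ids
  r <- 0L
  while (r < cfg$radius) {
    new_ids <- character(n)
    for (i in seq_len(n)) {
      pairs <- if (degree[i] == 0L) character(0) else {
        e <- adj[[i]]
        sort(paste0(e[, 2L], "|", ids[as.integer(e[, 1L])]))
      }
      new_ids[i] <- fnv1a64_hex(paste(c(ids[i], pairs), collapse = "|"))
    }
    ids <- new_ids
    all_ids <- c(all_ids, ids)
    r <- r + 1L
  }
  new_fingerprint(fnv1a64_mod(unique(all_ids), cfg$n_bits),
                  cfg$n_bits, cfg, m$name)
}

#' Compute a fingerprint under any configured scheme
#'
#' Dispatches on `cfg$scheme`: `"path"` and `"morgan"` use the
#' self-contained schemes; `"toolkit_default"` delegates to the external
#' RDKit backend and raises a capability error naming the missing backend
#' when none is available.
#'
#' @param m a `molecule`.
#' @param cfg an [fp_config()].
#' @return A `fingerprint`.
#' @export
compute_fingerprint <- function(m, cfg = fp_config()) {
  stopifnot(inherits(cfg, "fp_config"))
  switch(cfg$scheme,
    path = path_fingerprint(m, cfg),
    morgan = morgan_fingerprint(m, cfg),
    toolkit_default = toolkit_fingerprints(list(m), cfg)[[1L]],
    stop("unknown fingerprint scheme: ", cfg$scheme)
  )
}

#' Export fingerprints as TSV
#'
#' One row per fingerprint: `molecule_name`, `n_bits`, comma-separated
#' sorted bit indices.
#'
#' @param fps list of `fingerprint` objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fingerprints_tsv <- function(fps, path) {
  df <- data.frame(
    molecule_name = vapply(fps, `[[`, character(1), "molecule_name"),
    n_bits = vapply(fps, `[[`, integer(1), "n_bits"),
    bits = vapply(fps, function(f) paste(f$bits, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
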