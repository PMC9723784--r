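# Molecular graphs parsed from a practical subset of SMILES.
#
# Supported: the elements B, C, N, O, P, S, F, Cl, Br, I; aromatic lowercase
# b, c, n, o, p, s; branches; ring closures (digits and %nn); bond symbols
# - = # : and the stereo bonds / \ (read as single); bracket atoms with
# isotope, @/@@ stereo (ignored), explicit H count and formal charge.
# Stereochemistry and isotopes are accepted and discarded: similarity here
# is 2-D fingerprint based.

.ELEMENTS <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_ELEMENTS <- c("b", "c", "n", "o", "p", "s")

# Allowed valences per element; a formal charge shifts each allowed value
# by its sign (e.g. N+ -> 4, O- -> 1).
.ALLOWED_VALENCE <- list(
  B = 3L, C = 4L, N = 3L, O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L
)

.BOND_ORDERS <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)

.bond_from_symbol <- function(sym) {
  switch(sym,
    "-" = "single", "=" = "double", "#" = "triple", ":" = "aromatic",
    "/" = "single", "\\" = "single",
    stop("unknown bond symbol: ", sym)
  )
}

new_molecule <- function(name, smiles, atoms, bonds) {
  structure(list(name = name, smiles = smiles, atoms = atoms, bonds = bonds),
            class = "molecule")
}

#' Parse a SMILES string into a molecular graph
#'
#' Parses a practical subset of SMILES (organic subset elements, aromatic
#' lowercase atoms, branches, ring closures including `%nn`, bracket atoms
#' with charge and explicit hydrogen counts) into a validated molecular
#' graph. Stereo markers (`/`, `\`, `@`) and isotope labels are accepted
#' and ignored. Multi-component input (`.`) is an error unless
#' `largest_component = TRUE`, in which case the fragment with the most
#' atoms is kept.
#'
#' Implicit hydrogen counts are filled in from standard default valences
#' (B 3; C 4; N 3; O 2; P 3 or 5; S 2, 4 or 6, smallest feasible;
#' halogens 1), shifted by the formal charge. An aromatic bond contributes
#' 1.5 to an atom's bond-order sum (1 at aromatic O/S and at bracket atoms
#' with an explicit H count, where the ring pi system is lone-pair
#' donated), and the sum is rounded to the nearest integer. A valence
#' violation is an error.
#'
#' @param s SMILES string (non-empty).
#' @param name molecule display name; defaults to the SMILES string itself.
#' @param largest_component keep the largest fragment of a multi-component
#'   input instead of raising an error.
#' @return A `molecule` object: a list with `name`, `smiles`, an `atoms`
#'   data frame (`element`, `aromatic`, `charge`, `explicit_h`,
#'   `implicit_h`) in left-to-right source order, and a `bonds` data frame
#'   (`a`, `b`, `order`) with 1-based atom indices.
#' @examples
#' m <- parse_smiles("OC(=O)c1ccc(cc1)C(=O)O", "terephthalic acid")
#' nrow(m$atoms)  # 12 heavy atoms
#' @export
parse_smiles <- function(s, name = s, largest_component = FALSE) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s))
    stop("SMILES must be a single non-empty string")

  parts <- .split_components(s)
  if (length(parts) > 1L) {
    if (!largest_component)
      stop("multi-component SMILES (contains '.'): ", s,
           "; use largest_component = TRUE to keep the biggest fragment")
    mols <- lapply(parts, parse_smiles, name = name)
    sizes <- vapply(mols, function(m) nrow(m$atoms), integer(1))
    m <- mols[[which.max(sizes)]]
    m$smiles <- s
    return(m)
  }

  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)

  atoms <- list()   # each: list(element, aromatic, charge, explicit_h)
  bonds <- list()   # each: list(a, b, order)
  prev <- NA_integer_
  stack <- integer(0)
  pending <- NULL   # unconsumed bond symbol
  rings <- list()   # ring-closure number -> list(atom, sym)

  add_bond <- function(a, b, order) {
    if (a == b) stop("self-bond at atom ", a, " in: ", s)
    for (bd in bonds) {
      if ((bd$a == a && bd$b == b) || (bd$a == b && bd$b == a))
        stop("duplicate bond between atoms ", a, " and ", b, " in: ", s)
    }
    bonds[[length(bonds) + 1L]] <<- list(a = a, b = b, order = order)
  }

  add_atom <- function(element, aromatic, charge = 0L, explicit_h = NA_integer_) {
    atoms[[length(atoms) + 1L]] <<- list(element = element, aromatic = aromatic,
                                         charge = charge, explicit_h = explicit_h)
    idx <- length(atoms)
    if (!is.na(prev)) {
      order <- if (is.null(pending)) {
        if (aromatic && atoms[[prev]]$aromatic) "aromatic" else "single"
      } else .bond_from_symbol(pending)
      add_bond(prev, idx, order)
    }
    pending <<- NULL
    prev <<- idx
  }

  close_ring <- function(key) {
    if (is.na(prev)) stop("ring-closure digit before any atom in: ", s)
    if (!is.null(rings[[key]])) {
      open <- rings[[key]]
      sym <- NULL
      if (!is.null(open$sym) && !is.null(pending) &&
          !identical(open$sym, pending))
        stop("conflicting bond symbols on ring closure ", key, " in: ", s)
      if (!is.null(open$sym)) sym <- open$sym
      if (!is.null(pending)) sym <- pending
      order <- if (is.null(sym)) {
        if (atoms[[open$atom]]$aromatic && atoms[[prev]]$aromatic)
          "aromatic" else "single"
      } else .bond_from_symbol(sym)
      add_bond(open$atom, prev, order)
      rings[[key]] <<- NULL
    } else {
      rings[[key]] <<- list(atom = prev, sym = pending)
    }
    pending <<- NULL
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (is.na(prev)) stop("branch before any atom in: ", s)
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced parentheses in: ", s)
      if (!is.null(pending)) stop("dangling bond symbol before ')' in: ", s)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      if (!is.null(pending)) stop("two consecutive bond symbols in: ", s)
      pending <- ch
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      close_ring(ch)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9][0-9]$", paste0(chars[i + 1L], chars[i + 2L])))
        stop("'%' ring closure needs two digits in: ", s)
      close_ring(paste0(chars[i + 1L], chars[i + 2L]))
      i <- i + 3L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated bracket atom in: ", s)
      at <- .parse_bracket(paste(chars[(i + 1L):(j - 1L)], collapse = ""), s)
      add_atom(at$element, at$aromatic, at$charge, at$explicit_h)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r")) {
      two <- paste0(ch, chars[i + 1L])
      if (two %in% .ELEMENTS) {
        add_atom(two, FALSE)
        i <- i + 2L
      } else stop("unsupported atom symbol '", two, "' in: ", s)
    } else if (ch %in% .ELEMENTS) {
      add_atom(ch, FALSE)
      i <- i + 1L
    } else if (ch %in% .AROMATIC_ELEMENTS) {
      add_atom(toupper(ch), TRUE)
      i <- i + 1L
    } else {
      stop("unsupported atom symbol or character '", ch, "' in: ", s)
    }
  }

  if (length(stack) > 0L) stop("unbalanced parentheses in: ", s)
  if (!is.null(pending)) stop("dangling bond symbol at end of: ", s)
  if (length(rings) > 0L)
    stop("unpaired ring closure (", paste(names(rings), collapse = ", "),
         ") in: ", s)
  if (length(atoms) == 0L) stop("no atoms parsed from: ", s)

  atoms_df <- data.frame(
    element = vapply(atoms, `[[`, character(1), "element"),
    aromatic = vapply(atoms, `[[`, logical(1), "aromatic"),
    charge = vapply(atoms, `[[`, integer(1), "charge"),
    explicit_h = vapply(atoms, `[[`, integer(1), "explicit_h"),
    stringsAsFactors = FALSE
  )
  bonds_df <- if (length(bonds) == 0L) {
    data.frame(a = integer(0), b = integer(0), order = character(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      a = vapply(bonds, `[[`, integer(1), "a"),
      b = vapply(bonds, `[[`, integer(1), "b"),
      order = vapply(bonds, `[[`, character(1), "order"),
      stringsAsFactors = FALSE
    )
  }

  m <- new_molecule(name, s, atoms_df, bonds_df)
  if (!.is_connected(m))
    stop("molecule is not a single connected component: ", s)
  m$atoms$implicit_h <- .implicit_hydrogens(m, error = TRUE)
  m
}

.split_components <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  cuts <- integer(0)
  in_bracket <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "[") in_bracket <- TRUE
    else if (ch == "]") in_bracket <- FALSE
    else if (!in_bracket && ch == "(") depth <- depth + 1L
    else if (!in_bracket && ch == ")") depth <- depth - 1L
    else if (!in_bracket && ch == ".") {
      if (depth != 0L)
        stop("'.' inside parentheses is not supported: ", s)
      cuts <- c(cuts, i)
    }
  }
  if (length(cuts) == 0L) return(s)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  vapply(seq_along(starts), function(k) {
    if (starts[k] > ends[k]) stop("empty component in: ", s)
    paste(chars[starts[k]:ends[k]], collapse = "")
  }, character(1))
}

.parse_bracket <- function(content, s) {
  m <- regexec(
    "^([0-9]+)?([A-Za-z][a-z]?)(@@|@)?(H[0-9]*)?(\\+[0-9]+|-[0-9]+|\\++|-+)?$",
    content)
  g <- regmatches(content, m)[[1]]
  if (length(g) == 0L) stop("cannot parse bracket atom [", content, "] in: ", s)
  sym <- g[3]
  if (sym %in% .ELEMENTS) {
    element <- sym; aromatic <- FALSE
  } else if (sym %in% .AROMATIC_ELEMENTS) {
    element <- toupper(sym); aromatic <- TRUE
  } else {
    stop("unsupported atom symbol '", sym, "' in bracket [", content, "]")
  }
  hspec <- g[5]
  explicit_h <- if (!nzchar(hspec)) 0L
                else if (hspec == "H") 1L
                else as.integer(substring(hspec, 2L))
  cspec <- g[6]
  charge <- 0L
  if (nzchar(cspec)) {
    if (grepl("^\\++$", cspec)) charge <- nchar(cspec)
    else if (grepl("^-+$", cspec)) charge <- -nchar(cspec)
    else charge <- as.integer(cspec)  # "+2" / "-3"
    charge <- as.integer(charge)
  }
  list(element = element, aromatic = aromatic, charge = charge,
       explicit_h = explicit_h)
}

.adjacency <- function(m) {
  n <- nrow(m$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(m$bonds))) {
    a <- m$bonds$a[k]; b <- m$bonds$b[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

.is_connected <- function(m) {
  n <- nrow(m$atoms)
  if (n <= 1L) return(TRUE)
  adj <- .adjacency(m)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (nb in adj[[v]]) if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
  }
  all(seen)
}

# Bond-order sum per atom under the aromatic-valence convention described
# in ?parse_smiles.
.bond_order_sums <- function(m) {
  n <- nrow(m$atoms)
  sums <- numeric(n)
  for (k in seq_len(nrow(m$bonds))) {
    a <- m$bonds$a[k]; b <- m$bonds$b[k]; ord <- m$bonds$order[k]
    for (idx in c(a, b)) {
      unit <- if (ord == "aromatic") {
        at <- m$atoms[idx, ]
        if (!is.na(at$explicit_h) || at$element %in% c("O", "S")) 1 else 1.5
      } else .BOND_ORDERS[[ord]]
      sums[idx] <- sums[idx] + unit
    }
  }
  # Round half to even: a ring-fusion aromatic carbon has three aromatic
  # bonds (sum 4.5) and must land on valence 4, not 5.
  round(sums)
}

# Returns implicit H counts, or raises/collects valence violations.
.implicit_hydrogens <- function(m, error = TRUE, violations = NULL) {
  n <- nrow(m$atoms)
  bsum <- .bond_order_sums(m)
  out <- integer(n)
  probs <- character(0)
  for (i in seq_len(n)) {
    at <- m$atoms[i, ]
    allowed <- .ALLOWED_VALENCE[[at$element]] + at$charge
    allowed <- allowed[allowed >= 0L]
    if (!is.na(at$explicit_h)) {
      total <- bsum[i] + at$explicit_h
      if (!(total %in% allowed))
        probs <- c(probs, sprintf(
          "atom %d (%s%+d): valence %d not allowed", i, at$element,
          at$charge, total))
      out[i] <- at$explicit_h
    } else {
      feasible <- allowed[allowed >= bsum[i]]
      if (length(feasible) == 0L) {
        probs <- c(probs, sprintf(
          "atom %d (%s%+d): bond-order sum %d exceeds allowed valence",
          i, at$element, at$charge, bsum[i]))
        out[i] <- 0L
      } else {
        out[i] <- as.integer(min(feasible) - bsum[i])
      }
    }
  }
  if (length(probs) > 0L && error)
    stop("valence violation in ", m$smiles, ": ", paste(probs, collapse = "; "))
  if (!is.null(violations)) return(list(implicit_h = out, violations = probs))
  out
}

#' Relabel alternating six-membered carbocycles as aromatic
#'
#' Normalizes Kekule spellings so that `C1=CC=CC=C1` and `c1ccccc1`
#' fingerprint identically: every six-membered all-carbon ring written
#' with alternating single/double bonds has its atoms and ring bonds
#' relabeled aromatic. Lowercase (already aromatic) input is unchanged;
#' rings that do not match the pattern are left untouched. Idempotent.
#' No general Hueckel perception is attempted.
#'
#' @param m a `molecule`.
#' @return The normalized `molecule`.
#' @export
kekule_aromatize <- function(m) {
  stopifnot(inherits(m, "molecule"))
  rings <- .find_six_rings(m)
  if (length(rings) == 0L) return(m)
  bond_key <- paste(pmin(m$bonds$a, m$bonds$b), pmax(m$bonds$a, m$bonds$b))
  mark_atoms <- integer(0)
  mark_bonds <- integer(0)
  for (ring in rings) {
    ats <- m$atoms[ring, ]
    if (!all(ats$element == "C") || any(ats$aromatic)) next
    nxt <- c(ring[-1L], ring[1L])
    keys <- paste(pmin(ring, nxt), pmax(ring, nxt))
    bidx <- match(keys, bond_key)
    if (anyNA(bidx)) next
    orders <- m$bonds$order[bidx]
    alternating <- all(orders[c(1, 3, 5)] == orders[1]) &&
      all(orders[c(2, 4, 6)] == orders[2]) &&
      setequal(unique(orders), c("single", "double"))
    if (!alternating) next
    mark_atoms <- union(mark_atoms, ring)
    mark_bonds <- union(mark_bonds, bidx)
  }
  if (length(mark_atoms) == 0L) return(m)
  m$atoms$aromatic[mark_atoms] <- TRUE
  m$bonds$order[mark_bonds] <- "aromatic"
  m$atoms$implicit_h <- .implicit_hydrogens(m, error = TRUE)
  m
}

# All simple 6-cycles, each as an atom-index sequence, deduplicated.
.find_six_rings <- function(m) {
  adj <- .adjacency(m)
  n <- nrow(m$atoms)
  found <- list()
  seen_keys <- character(0)
  dfs <- function(start, path) {
    last <- path[length(path)]
    if (length(path) == 6L) {
      if (start %in% adj[[last]]) {
        key <- paste(sort(path), collapse = ",")
        if (!(key %in% seen_keys)) {
          seen_keys <<- c(seen_keys, key)
          found[[length(found) + 1L]] <<- path
        }
      }
      return(invisible())
    }
    for (nb in adj[[last]]) {
      if (nb > start && !(nb %in% path)) dfs(start, c(path, nb))
    }
  }
  for (v in seq_len(n)) dfs(v, v)
  found
}

#' Validate a molecule object without raising errors
#'
#' Checks valence rules, connectivity and bond-index sanity, returning all
#' violations as a character vector (empty when the molecule is valid).
#' Unlike [parse_smiles()], which raises on the first problem, this never
#' throws and never mutates its input, so it can be applied to hand-built
#' or deserialized molecule-shaped values.
#'
#' @param m a `molecule` (or molecule-shaped list).
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
validate_molecule <- function(m) {
  probs <- character(0)
  if (!is.list(m) || is.null(m$atoms) || is.null(m$bonds))
    return("not a molecule: missing atoms or bonds")
  n <- nrow(m$atoms)
  if (n == 0L) probs <- c(probs, "molecule has no atoms")
  bad_elem <- !(m$atoms$element %in% .ELEMENTS)
  if (any(bad_elem))
    probs <- c(probs, sprintf("atom %d: unsupported element '%s'",
                              which(bad_elem), m$atoms$element[bad_elem]))
  if (nrow(m$bonds) > 0L) {
    out_of_range <- m$bonds$a < 1L | m$bonds$a > n | m$bonds$b < 1L | m$bonds$b > n
    if (any(out_of_range)) {
      probs <- c(probs, sprintf("bond %d: atom index out of range",
                                which(out_of_range)))
      return(probs)  # later checks would index out of bounds
    }
    selfs <- m$bonds$a == m$bonds$b
    if (any(selfs))
      probs <- c(probs, sprintf("bond %d: self-loop", which(selfs)))
    key <- paste(pmin(m$bonds$a, m$bonds$b), pmax(m$bonds$a, m$bonds$b))
    if (anyDuplicated(key))
      probs <- c(probs, "duplicate bond between the same atom pair")
  }
  if (length(probs) > 0L) return(probs)
  if (!.is_connected(m)) probs <- c(probs, "molecule is not connected")
  res <- .implicit_hydrogens(m, error = FALSE, violations = TRUE)
  c(probs, res$violations)
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s (%s): %d atoms, %d bonds\n",
              x$name, x$smiles, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

#' @export
format.molecule <- function(x, ...) {
  sprintf("%s [%d atoms, %d bonds]", x$name, nrow(x$atoms), nrow(x$bonds))
}
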