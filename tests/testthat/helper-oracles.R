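# Independent oracles used to cross-check the package's primitives.

# Pure-R FNV-1a 64-bit, computed on 16-bit limbs so every product stays
# exactly representable in doubles. Returns the zero-padded hex string.
fnv1a64_oracle <- function(s) {
  bytes <- as.integer(charToRaw(s))
  # little-endian 16-bit limbs of the state and the FNV prime 2^40 + 0x1b3
  h <- c(0x2325, 0x8422, 0x9ce4, 0xcbf2)
  prime <- c(0x01b3, 0x0000, 0x0100, 0x0000)
  mul64 <- function(a, b) {
    out <- numeric(4)
    for (i in 1:4) {
      for (j in 1:4) {
        k <- i + j - 1L
        if (k <= 4L) out[k] <- out[k] + a[i] * b[j]
      }
    }
    carry <- 0
    for (k in 1:4) {
      v <- out[k] + carry
      out[k] <- v %% 65536
      carry <- floor(v / 65536)
    }
    out
  }
  for (b in bytes) {
    h[1] <- bitwXor(as.integer(h[1]), b)
    h <- mul64(h, prime)
  }
  paste0(sprintf("%04x", h[4]), sprintf("%04x", h[3]),
         sprintf("%04x", h[2]), sprintf("%04x", h[1]))
}

# Residue of the oracle hash modulo n_bits, via the limb representation
# (2^16 mod n composed stepwise to avoid forming the 64-bit value).
fnv1a64_mod_oracle <- function(s, n_bits) {
  hex <- fnv1a64_oracle(s)
  limbs <- strtoi(substring(hex, c(1, 5, 9, 13), c(4, 8, 12, 16)), 16L)
  r <- 0
  for (limb in limbs) r <- (r * 65536 + limb) %% n_bits
  as.integer(r)
}

# Brute-force Tanimoto over explicit membership arrays.
tanimoto_oracle <- function(bits_a, bits_b, n_bits) {
  av <- rep(FALSE, n_bits); av[bits_a + 1L] <- TRUE
  bv <- rep(FALSE, n_bits); bv[bits_b + 1L] <- TRUE
  if (!any(av) && !any(bv)) return(0)
  sum(av & bv) / sum(av | bv)
}

# A tiny two-family world used by several network tests.
toy_enzyme_map <- function(rows) {
  # rows: list of list(id, name, ec, ko, substrates)
  df <- data.frame(
    id = vapply(rows, `[[`, character(1), "id"),
    name = vapply(rows, `[[`, character(1), "name"),
    ec = vapply(rows, function(r) r$ec %||% "", character(1)),
    ko = vapply(rows, function(r) r$ko %||% "", character(1)),
    stringsAsFactors = FALSE)
  df$substrates <- lapply(rows, `[[`, "substrates")
  structure(df, class = c("enzyme_map", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_sim_edges <- function(...) {
  # ... : vectors c(pdcc, ldcc, similarity)
  rows <- list(...)
  data.frame(
    pdcc_id = vapply(rows, `[[`, character(1), 1L),
    ldcc_id = vapply(rows, `[[`, character(1), 2L),
    similarity = as.numeric(vapply(rows, `[[`, character(1), 3L)),
    stringsAsFactors = FALSE)
}
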