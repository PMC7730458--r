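#' Hashed path-based fingerprint
#'
#' Enumerates all simple heavy-atom paths of 1..`max_len` atoms, labels
#' each by its element / bond-order sequence (direction-canonicalized),
#' and hashes every label onto a fixed-length bit vector.  Deterministic
#' for a given topology, so duplicate structures always collide to
#' Tanimoto 1.
#'
#' @param mol A `ligand_mol`.
#' @param n_bits Fingerprint length (default 2048).
#' @param max_len Maximum path length in atoms (default 7).
#' @return Logical vector of length `n_bits`.
#' @export
path_fingerprint <- function(mol, n_bits = 2048L, max_len = 7L) {
  el <- mol$atoms$element
  heavy <- which(el != "H")
  bits <- logical(n_bits)
  if (!length(heavy)) return(bits)
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  ord <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]; o <- mol$bonds$order[k]
    if (el[i] == "H" || el[j] == "H") next
    adj[[i]] <- c(adj[[i]], j); ord[[i]] <- c(ord[[i]], o)
    adj[[j]] <- c(adj[[j]], i); ord[[j]] <- c(ord[[j]], o)
  }
  labels <- character(0)
  walk <- function(path, bonds_so_far) {
    tip <- path[length(path)]
    fwd <- paste(c(rbind(el[path],
                         c(as.character(bonds_so_far), ""))), collapse = "")
    rev_lab <- paste(c(rbind(el[rev(path)],
                             c(as.character(rev(bonds_so_far)), ""))),
                     collapse = "")
    labels[[length(labels) + 1L]] <<- min(fwd, rev_lab)
    if (length(path) == max_len) return()
    nbrs <- adj[[tip]]
    for (m in seq_along(nbrs)) {
      w <- nbrs[m]
      if (w %in% path) next
      walk(c(path, w), c(bonds_so_far, ord[[tip]][m]))
    }
  }
  for (a in heavy) walk(a, integer(0))
  idx <- unique(vapply(labels, hash_string, integer(1),
                       modulus = n_bits, USE.NAMES = FALSE)) + 1L
  bits[idx] <- TRUE
  bits
}

# deterministic polynomial string hash
hash_string <- function(s, modulus) {
  b <- utf8ToInt(s)
  h <- 0
  for (x in b) h <- (h * 131 + x) %% modulus
  as.integer(h)
}

#' Tanimoto similarity of two bit vectors
#'
#' `|A & B| / |A | B|`; two empty fingerprints count as similarity 0.
#'
#' @param a,b Logical vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}
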