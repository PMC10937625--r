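# Circular (Morgan-style) fingerprints and Tanimoto similarity.
#
# Each atom starts from an invariant built from its element, aromaticity,
# charge, hydrogen count and degree; the invariant is then updated for
# `radius` rounds by hashing the sorted (bond order, neighbour invariant)
# multiset.  Every invariant from every round sets one bit in a fixed-width
# bit vector (default 2048 bits, radius 2: the community-standard settings
# for reagent/product similarity screening).

hash_string <- function(s) {
  # deterministic 31-polynomial string hash folded into [0, 2^31)
  x <- utf8ToInt(s)
  h <- 0
  for (v in x) h <- (h * 31 + v) %% 2147483647
  h
}

#' Circular fingerprint of a molecule
#'
#' @param mol a `mol_graph`.
#' @param radius neighbourhood radius (number of update rounds).
#' @param nbits fingerprint width.
#' @return integer vector of set bit positions (1-based, sorted).
#' @keywords internal
circular_fingerprint <- function(mol, radius = 2L, nbits = 2048L) {
  na <- n_atoms(mol)
  if (na == 0L) return(integer(0))
  adj <- vector("list", na)
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]; o <- mol$bonds$order[k]
      adj[[a]] <- rbind(adj[[a]], c(b, o))
      adj[[b]] <- rbind(adj[[b]], c(a, o))
    }
  }
  deg <- vapply(adj, function(m) if (is.null(m)) 0L else nrow(m), integer(1))
  inv <- vapply(seq_len(na), function(i) {
    hash_string(paste(mol$atoms$element[i], mol$atoms$aromatic[i],
                      mol$atoms$charge[i], mol$atoms$hcount[i], deg[i],
                      sep = "/"))
  }, numeric(1))
  bits <- inv
  for (r in seq_len(radius)) {
    inv <- vapply(seq_len(na), function(i) {
      m <- adj[[i]]
      if (is.null(m)) return(hash_string(paste0("r", r, ":", inv[i])))
      parts <- sort(sprintf("%s:%.0f", format(m[, 2]), inv[m[, 1]]))
      hash_string(paste0("r", r, ":", inv[i], "|",
                         paste(parts, collapse = ",")))
    }, numeric(1))
    bits <- c(bits, inv)
  }
  sort(unique(as.integer(bits %% nbits) + 1L))
}

#' Tanimoto similarity between two molecules
#'
#' Jaccard coefficient of the molecules' circular fingerprints, used to flag
#' spectator reactants that are suspiciously similar to a product.
#'
#' @param mol_a,mol_b `mol_graph` objects.
#' @param radius,nbits fingerprint parameters (defaults: radius 2,
#'   2048 bits).
#' @return similarity in `[0, 1]`.
#' @export
tanimoto_similarity <- function(mol_a, mol_b, radius = 2L, nbits = 2048L) {
  fa <- circular_fingerprint(mol_a, radius, nbits)
  fb <- circular_fingerprint(mol_b, radius, nbits)
  if (length(fa) == 0L && length(fb) == 0L) return(1)
  length(intersect(fa, fb)) / length(union(fa, fb))
}
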