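# Molecular-graph featurization for the mapper network.

#' Feature schema configuration
#'
#' Atom features: element one-hot over a fixed vocabulary (plus an
#' "unknown" slot), degree, formal charge, an approximate hybridization
#' (sp/sp2/sp3 from incident bond orders), aromaticity flag, implicit
#' hydrogen count, and ring membership.  Bond features: bond-order one-hot
#' (single/double/triple/aromatic), conjugation flag, ring membership.
#' The schema carries a version string; checkpoints record it and refuse to
#' load under a different version.
#'
#' @param elements element vocabulary for the one-hot encoding.
#' @return a `feature_config` list with entries `elements`, `max_degree`,
#'   `charges`, `max_h`, `version`, `atom_dim`, `bond_dim`.
#' @export
feature_config <- function(elements = c("C", "N", "O", "S", "F", "Cl", "Br",
                                        "I", "P", "B")) {
  max_degree <- 5L
  charges <- -2:2
  max_h <- 4L
  atom_dim <- (length(elements) + 1L) + (max_degree + 1L) +
    length(charges) + 3L + 1L + (max_h + 1L) + 1L
  structure(
    list(elements = elements, max_degree = max_degree, charges = charges,
         max_h = max_h, version = "rxnmapr-features-1",
         atom_dim = atom_dim, bond_dim = 6L),
    class = "feature_config"
  )
}

one_hot <- function(idx, n) {
  m <- matrix(0, length(idx), n)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

# featurize one merged molecule graph; returns dense atom features X, the
# directed edge list (src, tgt) and per-directed-edge bond features
featurize_mol <- function(mol, cfg) {
  na <- n_atoms(mol)
  deg <- integer(na)
  maxord <- numeric(na)
  if (nrow(mol$bonds) > 0L) {
    tab <- table(c(mol$bonds$a1, mol$bonds$a2))
    deg[as.integer(names(tab))] <- as.integer(tab)
    for (k in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds$order[k]
      maxord[mol$bonds$a1[k]] <- max(maxord[mol$bonds$a1[k]], o)
      maxord[mol$bonds$a2[k]] <- max(maxord[mol$bonds$a2[k]], o)
    }
  }
  el_idx <- match(mol$atoms$element, cfg$elements)
  unknown <- is.na(el_idx)
  if (any(unknown)) {
    warning(sprintf("element(s) outside vocabulary mapped to 'unknown': %s",
                    paste(unique(mol$atoms$element[unknown]), collapse = ", ")))
    el_idx[unknown] <- length(cfg$elements) + 1L
  }
  hyb <- ifelse(maxord >= 3, 1L, ifelse(maxord >= 1.5 | mol$atoms$aromatic,
                                        2L, 3L))  # sp / sp2 / sp3
  in_ring <- ring_membership(mol)
  X <- cbind(
    one_hot(el_idx, length(cfg$elements) + 1L),
    one_hot(pmin(deg, cfg$max_degree) + 1L, cfg$max_degree + 1L),
    one_hot(match(pmin(pmax(mol$atoms$charge, min(cfg$charges)),
                       max(cfg$charges)), cfg$charges), length(cfg$charges)),
    one_hot(hyb, 3L),
    as.numeric(mol$atoms$aromatic),
    one_hot(pmin(mol$atoms$hcount, cfg$max_h) + 1L, cfg$max_h + 1L),
    as.numeric(in_ring)
  )

  nb <- nrow(mol$bonds)
  if (nb > 0L) {
    ring_bond <- logical(nb)
    for (k in seq_len(nb)) {
      reduced <- mol$bonds[-k, , drop = FALSE]
      comp <- connected_components(na, reduced)
      ring_bond[k] <- comp[mol$bonds$a1[k]] == comp[mol$bonds$a2[k]]
    }
    sp2ish <- hyb <= 2L
    conj <- sp2ish[mol$bonds$a1] & sp2ish[mol$bonds$a2]
    ord_idx <- match(mol$bonds$order, c(1, 2, 3, 1.5))
    Eb1 <- cbind(one_hot(ord_idx, 4L), as.numeric(conj),
                 as.numeric(ring_bond))
    src <- c(mol$bonds$a1, mol$bonds$a2)
    tgt <- c(mol$bonds$a2, mol$bonds$a1)
    Eb <- rbind(Eb1, Eb1)
  } else {
    src <- integer(0); tgt <- integer(0)
    Eb <- matrix(0, 0, cfg$bond_dim)
  }
  list(X = X, src = src, tgt = tgt, Eb = Eb,
       elements = mol$atoms$element)
}

#' Featurize a reaction record
#'
#' Builds the merged reactant graph and merged product graph feature sets;
#' atom order equals the parsed atom order (stable indexing) and no bonds
#' cross molecules.
#'
#' @param record a `rxn_record`.
#' @param cfg a [feature_config()].
#' @return list with elements `reactant` and `product`, each holding atom
#'   features `X`, directed edges `src`/`tgt`, bond features `Eb`, and
#'   `elements`.
#' @export
featurize_reaction <- function(record, cfg = feature_config()) {
  list(
    reactant = featurize_mol(record$reactants, cfg),
    product = featurize_mol(record$products, cfg),
    version = cfg$version
  )
}
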