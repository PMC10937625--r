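# Canonical labelling of vertex- and edge-labelled graphs.
#
# Used for molecule equality, condensed-graph-of-reaction equivalence, and
# reaction-template canonicalization.  The algorithm is iterative partition
# refinement (Morgan-style) with individualization on ties: every atom of
# the first non-singleton cell is individualized in turn, the refinement
# re-run, and the lexicographically smallest certificate kept, so the result
# is invariant under any input vertex permutation.

# refine an integer colouring until the partition stops splitting; the
# returned labels are the deterministic rank-by-key of the stable partition
refine_partition <- function(classes, adj) {
  n <- length(classes)
  repeat {
    keys <- vapply(seq_len(n), function(i) {
      nb <- adj[[i]]
      if (is.null(nb) || nrow(nb) == 0L) {
        nbkey <- ""
      } else {
        parts <- sprintf("%s~%04d", nb[, "elabel"],
                         classes[as.integer(nb[, "nbr"])])
        nbkey <- paste(sort(parts), collapse = "|")
      }
      sprintf("%04d#%s", classes[i], nbkey)
    }, character(1))
    new_classes <- match(keys, sort(unique(keys)))
    if (length(unique(new_classes)) == length(unique(classes))) {
      return(new_classes)
    }
    classes <- new_classes
  }
}

canon_adjacency <- function(n, bonds_a1, bonds_a2, elabels) {
  adj <- vector("list", n)
  for (k in seq_along(bonds_a1)) {
    a <- bonds_a1[k]; b <- bonds_a2[k]; e <- elabels[k]
    adj[[a]] <- rbind(adj[[a]], cbind(nbr = b, elabel = e))
    adj[[b]] <- rbind(adj[[b]], cbind(nbr = a, elabel = e))
  }
  for (i in seq_len(n)) {
    if (!is.null(adj[[i]])) {
      adj[[i]] <- matrix(adj[[i]], ncol = 2,
                         dimnames = list(NULL, c("nbr", "elabel")))
    }
  }
  adj
}

certificate_for_order <- function(ord, labels, bonds_a1, bonds_a2, elabels) {
  rank <- integer(length(ord)); rank[ord] <- seq_along(ord)
  atom_part <- paste(labels[ord], collapse = ";")
  if (length(bonds_a1) > 0L) {
    r1 <- pmin(rank[bonds_a1], rank[bonds_a2])
    r2 <- pmax(rank[bonds_a1], rank[bonds_a2])
    eb <- paste0(r1, "-", r2, ":", elabels)
    bond_part <- paste(sort(eb), collapse = ";")
  } else bond_part <- ""
  paste0(atom_part, "||", bond_part)
}

#' Canonical order and certificate of a labelled graph
#'
#' @param labels character vector of vertex labels.
#' @param bonds_a1,bonds_a2 integer endpoints of undirected edges.
#' @param elabels character edge labels.
#' @return list with `order` (vertices in canonical sequence) and
#'   `certificate` (a string equal for isomorphic labelled graphs).
#' @keywords internal
canon_graph <- function(labels, bonds_a1, bonds_a2, elabels) {
  n <- length(labels)
  if (n == 0L) return(list(order = integer(0), certificate = ""))
  adj <- canon_adjacency(n, bonds_a1, bonds_a2, elabels)
  init <- match(labels, sort(unique(labels)))

  best <- NULL

  search <- function(classes) {
    classes <- refine_partition(classes, adj)
    tab <- table(classes)
    nonsingle <- as.integer(names(tab)[tab > 1L])
    if (length(nonsingle) == 0L) {
      ord <- order(classes)
      cert <- certificate_for_order(ord, labels, bonds_a1, bonds_a2, elabels)
      if (is.null(best) || cert < best$certificate) {
        best <<- list(order = ord, certificate = cert)
      }
      return(invisible(NULL))
    }
    cell <- which(classes == min(nonsingle))
    seen <- character(0)
    for (a in cell) {
      cl2 <- classes * 2L
      cl2[a] <- cl2[a] - 1L
      cl2 <- match(cl2, sort(unique(cl2)))
      key <- paste(refine_partition(cl2, adj), collapse = ",")
      if (key %in% seen) next   # same refined partition: same subtree
      seen <- c(seen, key)
      search(cl2)
    }
    invisible(NULL)
  }
  search(init)
  best
}

# canonical certificate of a mol_graph; atom labels carry element, aromatic
# flag, charge and (optionally) hydrogen count
mol_certificate <- function(mol, use_hcount = TRUE) {
  labels <- paste0(
    mol$atoms$element,
    ifelse(mol$atoms$aromatic, ":ar", ""),
    ifelse(mol$atoms$charge != 0L, paste0("c", mol$atoms$charge), ""),
    if (use_hcount) paste0("H", mol$atoms$hcount) else ""
  )
  canon_graph(labels, mol$bonds$a1, mol$bonds$a2,
              as.character(mol$bonds$order))$certificate
}

# find a non-identity transposition automorphism of mol, i.e. two atoms with
# identical labels whose neighbourhoods outside the pair coincide; returns
# c(i, j) or NULL
find_transposition_automorphism <- function(mol, candidates = NULL) {
  na <- n_atoms(mol)
  if (na < 2L) return(NULL)
  labels <- paste0(mol$atoms$element, mol$atoms$aromatic, mol$atoms$charge,
                   mol$atoms$hcount)
  adj <- vector("list", na)
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]; o <- mol$bonds$order[k]
      adj[[a]] <- rbind(adj[[a]], c(b, o))
      adj[[b]] <- rbind(adj[[b]], c(a, o))
    }
  }
  nb_key <- function(i, exclude) {
    m <- adj[[i]]
    if (is.null(m)) return("")
    keep <- !(m[, 1] %in% exclude)
    paste(sort(paste0(m[keep, 1], ":", m[keep, 2])), collapse = "|")
  }
  pool <- if (is.null(candidates)) seq_len(na) else candidates
  for (i in pool) {
    for (j in pool[pool > i]) {
      if (labels[i] != labels[j]) next
      # neighbourhoods must agree exactly once the pair itself is excluded,
      # and any mutual bond is automatically symmetric
      if (nb_key(i, c(i, j)) == nb_key(j, c(i, j))) return(c(i, j))
    }
  }
  NULL
}
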