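# Molecular graphs and SMILES input/output.
#
# Molecules are light-weight graphs: a data frame of heavy atoms (element,
# aromatic flag, formal charge, implicit hydrogen count, atom-map number,
# component id) plus a data frame of bonds (endpoints and bond order, with
# 1.5 denoting aromatic bonds).  Hydrogens are implicit throughout; stereo
# descriptors are parsed over but not retained.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_SUBSET <- c("b", "c", "n", "o", "p", "s")

# default valence sets used for implicit-H assignment
DEFAULT_VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1, Si = 4, Se = c(2, 4, 6), Sn = 4
)

new_mol_graph <- function(atoms, bonds) {
  structure(list(atoms = atoms, bonds = bonds), class = "mol_graph")
}

n_atoms <- function(mol) nrow(mol$atoms)

empty_atoms <- function() {
  data.frame(
    element = character(), aromatic = logical(), charge = integer(),
    hcount = integer(), map = integer(), mol = integer(),
    stringsAsFactors = FALSE
  )
}

#' Parse a single-molecule (or multi-component) SMILES string
#'
#' Supports the organic subset, aromatic lowercase atoms, bracket atoms with
#' isotope/charge/explicit H/atom-map fields, branches, ring closures
#' (including `%nn`), and dot-separated components.  Stereo markers
#' (`@`, `@@`, `/`, `\`) are accepted and discarded; isotopes are discarded.
#'
#' @param text a SMILES string.
#' @return a `mol_graph`: list with `atoms` and `bonds` data frames.
#' @keywords internal
parse_smiles <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)

  element <- character(0); aromatic <- logical(0)
  charge <- integer(0); hcount <- integer(0); map <- integer(0)
  b1 <- integer(0); b2 <- integer(0); border <- numeric(0)

  prev <- NA_integer_
  stack <- integer(0)
  pending <- NA_real_          # explicit bond order awaiting the next atom
  rings <- list()              # open ring closures: number -> (atom, order)

  fail <- function(msg) {
    stop(sprintf("invalid SMILES '%s': %s", text, msg), call. = FALSE)
  }

  add_atom <- function(el, arom, chg, hc, mp) {
    element[length(element) + 1L] <<- el
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- chg
    hcount[length(hcount) + 1L] <<- hc
    map[length(map) + 1L] <<- mp
    idx <- length(element)
    if (!is.na(prev)) {
      ord <- pending
      if (is.na(ord)) ord <- if (aromatic[prev] && arom) 1.5 else 1
      b1[length(b1) + 1L] <<- prev
      b2[length(b2) + 1L] <<- idx
      border[length(border) + 1L] <<- ord
    }
    pending <<- NA_real_
    prev <<- idx
  }

  close_ring <- function(num) {
    key <- as.character(num)
    if (is.na(prev)) fail("ring-closure digit before any atom")
    if (!is.null(rings[[key]])) {
      entry <- rings[[key]]
      ord <- pending
      if (is.na(ord)) ord <- entry$order
      if (is.na(ord)) {
        ord <- if (aromatic[entry$atom] && aromatic[prev]) 1.5 else 1
      }
      if (entry$atom == prev) fail("ring closure to the same atom")
      b1[length(b1) + 1L] <<- entry$atom
      b2[length(b2) + 1L] <<- prev
      border[length(border) + 1L] <<- ord
      rings[[key]] <<- NULL
    } else {
      rings[[key]] <- list(atom = prev, order = pending)
      rings <<- rings
    }
    pending <<- NA_real_
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    nxt <- if (i < n) chars[i + 1L] else ""
    if (ch == "(") {
      if (is.na(prev)) fail("branch before any atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) fail("unbalanced ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- NA_real_; i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pending <- 1; i <- i + 1L
    } else if (ch == "=") {
      pending <- 2; i <- i + 1L
    } else if (ch == "#") {
      pending <- 3; i <- i + 1L
    } else if (ch == ":") {
      pending <- 1.5; i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9][0-9]$", paste0(chars[i + 1L], chars[i + 2L])))
        fail("'%' must be followed by two digits")
      close_ring(as.integer(paste0(chars[i + 1L], chars[i + 2L])))
      i <- i + 3L
    } else if (grepl("^[0-9]$", ch)) {
      close_ring(as.integer(ch)); i <- i + 1L
    } else if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) fail("unclosed bracket atom")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Z][a-z]?|[a-z]{1,2})(@{0,2})(H[0-9]*)?(\\+{1,3}|-{1,3}|\\+[0-9]+|-[0-9]+)?(:[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0L) fail(sprintf("bad bracket atom '[%s]'", body))
      sym <- m[3]
      arom <- sym %in% c(AROMATIC_SUBSET, "se", "as")
      el <- if (arom) {
        paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, 10))
      } else sym
      hc <- if (m[5] == "") 0L else if (m[5] == "H") 1L else
        as.integer(substring(m[5], 2))
      chg <- 0L
      if (m[6] != "") {
        sign <- if (substr(m[6], 1, 1) == "+") 1L else -1L
        rest <- substring(m[6], 2)
        chg <- if (rest == "") sign else if (grepl("^[0-9]+$", rest))
          sign * as.integer(rest) else sign * (nchar(rest) + 1L)
      }
      mp <- if (m[7] == "") 0L else as.integer(substring(m[7], 2))
      if (mp < 0L) fail("atom-map numbers must be positive")
      add_atom(el, arom, chg, hc, mp)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && nxt %in% c("l", "r") &&
               paste0(ch, nxt) %in% c("Cl", "Br")) {
      add_atom(paste0(ch, nxt), FALSE, 0L, NA_integer_, 0L); i <- i + 2L
    } else if (ch %in% ORGANIC_SUBSET) {
      add_atom(ch, FALSE, 0L, NA_integer_, 0L); i <- i + 1L
    } else if (ch %in% AROMATIC_SUBSET) {
      add_atom(toupper(ch), TRUE, 0L, NA_integer_, 0L); i <- i + 1L
    } else {
      fail(sprintf("unexpected character '%s' at position %d", ch, i))
    }
  }
  if (length(stack) > 0L) fail("unbalanced '('")
  if (length(rings) > 0L) fail("unclosed ring bond")
  if (length(element) == 0L) fail("no atoms")

  atoms <- data.frame(
    element = element, aromatic = aromatic, charge = charge,
    hcount = hcount, map = map, mol = 0L, stringsAsFactors = FALSE
  )
  bonds <- data.frame(a1 = b1, a2 = b2, order = border)
  mol <- new_mol_graph(atoms, bonds)
  mol$atoms$mol <- connected_components(nrow(atoms), bonds)
  mol$atoms$hcount <- ifelse(
    is.na(mol$atoms$hcount),
    implicit_hydrogens(mol),
    mol$atoms$hcount
  )
  mol
}

# component id per atom (1-based, in order of first atom)
connected_components <- function(n, bonds) {
  comp <- integer(n)
  adj <- adjacency_list(n, bonds)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0L) {
      a <- queue[1L]; queue <- queue[-1L]
      for (b in adj[[a]]) {
        if (comp[b] == 0L) { comp[b] <- cid; queue <- c(queue, b) }
      }
    }
  }
  comp
}

adjacency_list <- function(n, bonds) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a1[k]; b <- bonds$a2[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# sum of bond orders incident to each atom (aromatic bonds count 1.5)
bond_order_sums <- function(mol) {
  s <- numeric(n_atoms(mol))
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      s[mol$bonds$a1[k]] <- s[mol$bonds$a1[k]] + mol$bonds$order[k]
      s[mol$bonds$a2[k]] <- s[mol$bonds$a2[k]] + mol$bonds$order[k]
    }
  }
  s
}

# implicit hydrogen counts for organic-subset atoms (standard SMILES rules)
implicit_hydrogens <- function(mol) {
  sums <- bond_order_sums(mol)
  vapply(seq_len(n_atoms(mol)), function(i) {
    el <- mol$atoms$element[i]
    vals <- DEFAULT_VALENCES[[el]]
    if (is.null(vals)) return(0L)
    need <- ceiling(sums[i] - 1e-9)
    v <- vals[vals >= need]
    if (length(v) == 0L) return(0L)
    as.integer(v[1L] - need)
  }, integer(1))
}

#' Write a molecule graph as SMILES
#'
#' Deterministic depth-first writer.  Atoms whose charge, atom-map number or
#' hydrogen count cannot be expressed implicitly are written in bracket form.
#' Round-trips through [parse_smiles()] to an identical graph up to atom
#' order.
#'
#' @param mol a `mol_graph`.
#' @param map optional integer vector of atom-map numbers to write
#'   (0 or `NA` = none); defaults to the graph's own `map` column.
#' @return a SMILES string.
#' @keywords internal
write_smiles <- function(mol, map = NULL) {
  na <- n_atoms(mol)
  if (is.null(map)) map <- mol$atoms$map
  map[is.na(map)] <- 0L
  bonds <- mol$bonds
  adj <- vector("list", na)          # list of (neighbor, bond index)
  if (nrow(bonds) > 0L) {
    for (k in seq_len(nrow(bonds))) {
      a <- bonds$a1[k]; b <- bonds$a2[k]
      adj[[a]] <- rbind(adj[[a]], c(b, k))
      adj[[b]] <- rbind(adj[[b]], c(a, k))
    }
  }

  implicit <- implicit_hydrogens(mol)

  visited <- logical(na)
  used_bond <- logical(max(1L, nrow(bonds)))
  ring_digit_of_bond <- integer(max(1L, nrow(bonds)))
  ring_digits_at <- vector("list", na)   # atom -> ring digits to emit
  next_digit <- 0L
  free_digits <- integer(0)

  # first pass: DFS partitioning bonds into tree bonds and ring closures;
  # a bond is marked used either as the tree bond of a first visit or as a
  # ring closure discovered from an already-visited endpoint
  assign_rings <- function(start) {
    stack_local <- list(list(atom = start, from_bond = 0L))
    while (length(stack_local) > 0L) {
      fr <- stack_local[[length(stack_local)]]
      stack_local[[length(stack_local)]] <- NULL
      a <- fr$atom
      if (visited[a]) next
      visited[a] <<- TRUE
      if (fr$from_bond > 0L) used_bond[fr$from_bond] <<- TRUE
      nb <- adj[[a]]
      if (!is.null(nb)) {
        for (r in rev(seq_len(nrow(nb)))) {
          b <- nb[r, 1L]; k <- nb[r, 2L]
          if (used_bond[k] || k == fr$from_bond) next
          if (visited[b]) {
            used_bond[k] <<- TRUE
            next_digit <<- next_digit + 1L
            ring_digit_of_bond[k] <<- next_digit
            ring_digits_at[[a]] <<- c(ring_digits_at[[a]], k)
            ring_digits_at[[b]] <<- c(ring_digits_at[[b]], k)
          } else {
            stack_local[[length(stack_local) + 1L]] <-
              list(atom = b, from_bond = k)
          }
        }
      }
    }
    invisible(NULL)
  }

  atom_token <- function(i) {
    el <- mol$atoms$element[i]
    arom <- mol$atoms$aromatic[i]
    sym <- if (arom) tolower(el) else el
    chg <- mol$atoms$charge[i]
    hc <- mol$atoms$hcount[i]
    mp <- map[i]
    plain_ok <- el %in% ORGANIC_SUBSET && chg == 0L && mp == 0L &&
      hc == implicit[i] && (!arom || tolower(el) %in% AROMATIC_SUBSET)
    if (plain_ok) return(sym)
    h <- if (hc == 0L) "" else if (hc == 1L) "H" else paste0("H", hc)
    c_str <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-"
      else if (chg > 0L) paste0("+", chg) else paste0("-", abs(chg))
    m_str <- if (mp > 0L) paste0(":", mp) else ""
    paste0("[", sym, h, c_str, m_str, "]")
  }

  bond_token <- function(k, a, b) {
    o <- bonds$order[k]
    if (o == 2) return("=")
    if (o == 3) return("#")
    both_arom <- mol$atoms$aromatic[a] && mol$atoms$aromatic[b]
    if (o == 1.5) return(if (both_arom) "" else ":")
    if (both_arom) return("-")   # explicit single bond between aromatic atoms
    ""
  }

  # recursive writer over the DFS tree
  tree_children <- vector("list", na)
  parent_bond <- integer(na)

  emit <- function(a, from_bond) {
    out <- character(0)
    if (from_bond > 0L) {
      other <- if (bonds$a1[from_bond] == a) bonds$a2[from_bond] else
        bonds$a1[from_bond]
      out <- c(out, bond_token(from_bond, other, a))
    }
    out <- c(out, atom_token(a))
    for (k in ring_digits_at[[a]]) {
      d <- ring_digit_of_bond[k]
      other <- if (bonds$a1[k] == a) bonds$a2[k] else bonds$a1[k]
      tok <- bond_token(k, a, other)
      dd <- if (d > 9L) paste0("%", d) else as.character(d)
      # write the bond symbol only at the first-encountered endpoint
      key <- as.character(k)
      if (!isTRUE(get0(key, envir = emitted_ring, inherits = FALSE))) {
        assign(key, TRUE, envir = emitted_ring)
        out <- c(out, tok, dd)
      } else {
        out <- c(out, dd)
      }
    }
    kids <- tree_children[[a]]
    if (!is.null(kids)) {
      for (idx in seq_along(kids)) {
        child <- kids[[idx]]
        sub <- emit(child$atom, child$bond)
        if (idx < length(kids)) {
          out <- c(out, "(", sub, ")")
        } else {
          out <- c(out, sub)
        }
      }
    }
    out
  }

  # rebuild the DFS tree explicitly (children in neighbor order)
  visited2 <- logical(na)
  build_tree <- function(start) {
    stack_local <- list(list(atom = start, bond = 0L, parent = 0L))
    root <- start
    while (length(stack_local) > 0L) {
      fr <- stack_local[[length(stack_local)]]
      stack_local[[length(stack_local)]] <- NULL
      a <- fr$atom
      if (visited2[a]) next
      visited2[a] <<- TRUE
      if (fr$parent > 0L) {
        tree_children[[fr$parent]] <<- c(
          tree_children[[fr$parent]], list(list(atom = a, bond = fr$bond)))
      }
      nb <- adj[[a]]
      if (!is.null(nb)) {
        for (r in rev(seq_len(nrow(nb)))) {
          b <- nb[r, 1L]; k <- nb[r, 2L]
          if (!visited2[b] && ring_digit_of_bond[k] == 0L) {
            stack_local[[length(stack_local) + 1L]] <-
              list(atom = b, bond = k, parent = a)
          }
        }
      }
    }
    root
  }

  emitted_ring <- new.env(parent = emptyenv())
  parts <- character(0)
  for (s in seq_len(na)) {
    if (visited[s]) next
    assign_rings(s)
    build_tree(s)
    parts <- c(parts, paste(emit(s, 0L), collapse = ""))
  }
  paste(parts, collapse = ".")
}

# apply an atom permutation: atom j of the result is atom perm[j] of mol
permute_mol <- function(mol, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  atoms <- mol$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol$bonds
  if (nrow(bonds) > 0L) {
    bonds$a1 <- inv[bonds$a1]
    bonds$a2 <- inv[bonds$a2]
  }
  out <- new_mol_graph(atoms, bonds)
  out$atoms$mol <- connected_components(nrow(atoms), bonds)
  out
}

# merge a list of mol_graphs into one graph with no cross-molecule bonds
merge_mols <- function(mols) {
  atoms <- empty_atoms(); bonds <- data.frame(a1 = integer(), a2 = integer(),
                                              order = numeric())
  offset <- 0L
  mol_id <- 0L
  for (m in mols) {
    a <- m$atoms
    ncomp <- max(a$mol)
    a$mol <- a$mol + mol_id
    mol_id <- mol_id + ncomp
    b <- m$bonds
    if (nrow(b) > 0L) { b$a1 <- b$a1 + offset; b$a2 <- b$a2 + offset }
    atoms <- rbind(atoms, a)
    bonds <- rbind(bonds, b)
    offset <- offset + nrow(a)
  }
  rownames(atoms) <- NULL
  new_mol_graph(atoms, bonds)
}

# split a merged graph back into per-component mol_graphs
split_mol <- function(mol) {
  comps <- sort(unique(mol$atoms$mol))
  lapply(comps, function(cid) {
    idx <- which(mol$atoms$mol == cid)
    lookup <- integer(n_atoms(mol)); lookup[idx] <- seq_along(idx)
    atoms <- mol$atoms[idx, , drop = FALSE]
    atoms$mol <- 1L
    rownames(atoms) <- NULL
    keep <- mol$bonds$a1 %in% idx & mol$bonds$a2 %in% idx
    bonds <- mol$bonds[keep, , drop = FALSE]
    if (nrow(bonds) > 0L) {
      bonds$a1 <- lookup[bonds$a1]; bonds$a2 <- lookup[bonds$a2]
    }
    rownames(bonds) <- NULL
    new_mol_graph(atoms, bonds)
  })
}

# TRUE for each atom lying on a cycle
ring_membership <- function(mol) {
  nb <- nrow(mol$bonds)
  in_ring_bond <- logical(nb)
  if (nb > 0L) {
    for (k in seq_len(nb)) {
      reduced <- mol$bonds[-k, , drop = FALSE]
      comp <- connected_components(n_atoms(mol), reduced)
      in_ring_bond[k] <- comp[mol$bonds$a1[k]] == comp[mol$bonds$a2[k]]
    }
  }
  out <- logical(n_atoms(mol))
  if (nb > 0L) {
    ra <- c(mol$bonds$a1[in_ring_bond], mol$bonds$a2[in_ring_bond])
    out[unique(ra)] <- TRUE
  }
  out
}
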