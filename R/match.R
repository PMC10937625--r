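# Substructure matching for the functional-group catalogue.
#
# Patterns are written in a restricted SMARTS-like subset: organic-subset
# atoms, aromatic lowercase atoms, bracket atoms carrying optional charge and
# an optional explicit H count (e.g. [OH1], [N+], [O-]), bond symbols
# - = # :, branches, and ring closures.  A bracket H count or charge is a
# constraint; atoms written without them match any H count / neutral charge
# behaviour as follows: H is unconstrained unless written, charge must equal
# the written value (0 if absent in a bracket, unconstrained for plain
# atoms).  This subset covers carbonyl, nitrile, nitro, acetal and the other
# catalogue groups; it is not a general SMARTS engine.

.pattern_cache <- new.env(parent = emptyenv())

parse_group_pattern_cached <- function(pattern) {
  hit <- get0(pattern, envir = .pattern_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  out <- parse_group_pattern(pattern)
  assign(pattern, out, envir = .pattern_cache)
  out
}

parse_group_pattern <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  n <- length(chars)
  element <- character(0); aromatic <- logical(0)
  charge <- integer(0); hreq <- integer(0)   # NA = unconstrained
  b1 <- integer(0); b2 <- integer(0); border <- numeric(0)
  prev <- NA_integer_; stack <- integer(0); pending <- NA_real_
  rings <- list()

  add_atom <- function(el, arom, chg, h) {
    element[length(element) + 1L] <<- el
    aromatic[length(aromatic) + 1L] <<- arom
    charge[length(charge) + 1L] <<- chg
    hreq[length(hreq) + 1L] <<- h
    idx <- length(element)
    if (!is.na(prev)) {
      ord <- pending
      if (is.na(ord)) ord <- if (aromatic[prev] && arom) 1.5 else 1
      b1[length(b1) + 1L] <<- prev; b2[length(b2) + 1L] <<- idx
      border[length(border) + 1L] <<- ord
    }
    pending <<- NA_real_; prev <<- idx
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    nxt <- if (i < n) chars[i + 1L] else ""
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L }
    else if (ch == ")") {
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    }
    else if (ch == "-") { pending <- 1; i <- i + 1L }
    else if (ch == "=") { pending <- 2; i <- i + 1L }
    else if (ch == "#") { pending <- 3; i <- i + 1L }
    else if (ch == ":") { pending <- 1.5; i <- i + 1L }
    else if (grepl("^[0-9]$", ch)) {
      key <- ch
      if (!is.null(rings[[key]])) {
        entry <- rings[[key]]
        ord <- if (!is.na(pending)) pending else
          if (!is.na(entry$order)) entry$order else
            if (aromatic[entry$atom] && aromatic[prev]) 1.5 else 1
        b1[length(b1) + 1L] <- entry$atom; b2[length(b2) + 1L] <- prev
        border[length(border) + 1L] <- ord
        rings[[key]] <- NULL
      } else rings[[key]] <- list(atom = prev, order = pending)
      pending <- NA_real_
      i <- i + 1L
    }
    else if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([A-Z][a-z]?|[a-z])?(H[0-9]?)?(\\+|-)?$", body))[[1]]
      if (length(m) == 0L || m[2] == "")
        stop(sprintf("bad group pattern atom '[%s]'", body), call. = FALSE)
      sym <- m[2]
      arom <- sym %in% AROMATIC_SUBSET
      el <- if (arom) toupper(sym) else sym
      h <- if (m[3] == "") NA_integer_ else if (m[3] == "H") 1L else
        as.integer(substring(m[3], 2))
      chg <- if (m[4] == "") 0L else if (m[4] == "+") 1L else -1L
      add_atom(el, arom, chg, h)
      i <- j + 1L
    }
    else if (ch %in% c("C", "B") && paste0(ch, nxt) %in% c("Cl", "Br")) {
      add_atom(paste0(ch, nxt), FALSE, NA_integer_, NA_integer_); i <- i + 2L
    }
    else if (ch %in% ORGANIC_SUBSET) {
      add_atom(ch, FALSE, NA_integer_, NA_integer_); i <- i + 1L
    }
    else if (ch %in% AROMATIC_SUBSET) {
      add_atom(toupper(ch), TRUE, NA_integer_, NA_integer_); i <- i + 1L
    }
    else if (ch == "*") {
      add_atom("*", NA, NA_integer_, NA_integer_); i <- i + 1L
    }
    else stop(sprintf("unexpected '%s' in group pattern '%s'", ch, pattern),
              call. = FALSE)
  }
  list(
    atoms = data.frame(element = element, aromatic = aromatic,
                       charge = charge, hreq = hreq,
                       stringsAsFactors = FALSE),
    bonds = data.frame(a1 = b1, a2 = b2, order = border)
  )
}

# all matches of a parsed pattern in a mol_graph; returns a list of integer
# vectors (pattern atom i -> molecule atom), deduplicated as atom sets
match_pattern <- function(pattern, mol) {
  np <- nrow(pattern$atoms)
  na <- n_atoms(mol)
  if (np == 0L || na < np) return(list())

  # molecule adjacency with orders
  madj <- vector("list", na)
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]; o <- mol$bonds$order[k]
      madj[[a]] <- rbind(madj[[a]], c(b, o))
      madj[[b]] <- rbind(madj[[b]], c(a, o))
    }
  }
  bond_order <- function(a, b) {
    m <- madj[[a]]
    if (is.null(m)) return(0)
    hit <- m[m[, 1] == b, 2]
    if (length(hit) == 0L) 0 else hit[1]
  }

  # precompute the admissible molecule atoms per pattern atom
  m_el <- mol$atoms$element; m_ar <- mol$atoms$aromatic
  m_ch <- mol$atoms$charge; m_h <- mol$atoms$hcount
  cand <- lapply(seq_len(np), function(p) {
    pa <- pattern$atoms[p, ]
    ok <- rep(TRUE, na)
    if (pa$element != "*") {
      ok <- ok & m_el == pa$element
      if (!is.na(pa$aromatic)) ok <- ok & m_ar == pa$aromatic
    }
    if (!is.na(pa$charge)) ok <- ok & m_ch == pa$charge
    if (!is.na(pa$hreq)) ok <- ok & m_h == pa$hreq
    which(ok)
  })
  if (any(lengths(cand) == 0L)) return(list())

  # pattern adjacency (constraints among already-assigned atoms)
  pb <- pattern$bonds
  results <- list()
  seen_sets <- character(0)
  assign_vec <- integer(np)

  bt <- function(p) {
    if (p > np) {
      key <- paste(sort(assign_vec), collapse = ",")
      if (!(key %in% seen_sets)) {
        seen_sets <<- c(seen_sets, key)
        results[[length(results) + 1L]] <<- assign_vec
      }
      return(invisible(NULL))
    }
    for (a in cand[[p]]) {
      if (a %in% assign_vec[seq_len(p - 1L)]) next
      ok <- TRUE
      if (nrow(pb) > 0L) {
        for (k in seq_len(nrow(pb))) {
          q1 <- pb$a1[k]; q2 <- pb$a2[k]
          if (q1 == p && q2 < p) {
            if (bond_order(a, assign_vec[q2]) != pb$order[k]) { ok <- FALSE; break }
          } else if (q2 == p && q1 < p) {
            if (bond_order(a, assign_vec[q1]) != pb$order[k]) { ok <- FALSE; break }
          }
        }
      }
      if (!ok) next
      assign_vec[p] <<- a
      bt(p + 1L)
    }
    invisible(NULL)
  }
  bt(1L)
  results
}
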