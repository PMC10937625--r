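# Greedy decoding of the mapping probability matrix into an atom mapping.

#' Decode an atom mapping greedily, highest probability first
#'
#' All (product atom, reactant atom) cells are visited in order of
#' decreasing probability (ties broken by product index, then reactant
#' index, ascending); a cell is accepted when neither of its atoms is
#' assigned yet, and — with element enforcement, the default — when the two
#' atoms share the same element.  Decoding terminates once every product
#' atom is assigned; spectator reactant atoms stay unmapped.
#'
#' @param P numeric matrix: rows = product atoms, columns = reactant atoms,
#'   each row a probability distribution.
#' @param product_elements,reactant_elements element symbols per atom;
#'   required when `enforce_element_match` is `TRUE`.
#' @param enforce_element_match require identical elements in an accepted
#'   pair (default `TRUE`; chemically invalid cross-element maps would
#'   poison template extraction).
#' @return an `atom_mapping` total over product atoms.
#' @export
decode_greedy <- function(P, product_elements = NULL,
                          reactant_elements = NULL,
                          enforce_element_match = TRUE) {
  np <- nrow(P); nr <- ncol(P)
  if (np == 0L || nr == 0L) stop("empty probability matrix", call. = FALSE)
  if (enforce_element_match &&
      (is.null(product_elements) || is.null(reactant_elements))) {
    stop("element vectors are required when enforcing element match",
         call. = FALSE)
  }
  pi_idx <- rep(seq_len(np), times = nr)
  ri_idx <- rep(seq_len(nr), each = np)
  admissible <- if (enforce_element_match) {
    product_elements[pi_idx] == reactant_elements[ri_idx]
  } else rep(TRUE, np * nr)
  ord <- order(-as.vector(P), pi_idx, ri_idx)
  ord <- ord[admissible[ord]]

  p_used <- logical(np); r_used <- logical(nr)
  out_p <- integer(0); out_r <- integer(0)
  for (cell in ord) {
    p <- pi_idx[cell]; r <- ri_idx[cell]
    if (p_used[p] || r_used[r]) next
    p_used[p] <- TRUE; r_used[r] <- TRUE
    out_p <- c(out_p, p); out_r <- c(out_r, r)
    if (length(out_p) == np) break
  }
  if (length(out_p) < np) {
    missing <- which(!p_used)[1L]
    stop(sprintf(
      "product atom %d (%s) has no admissible unassigned reactant atom",
      missing,
      if (is.null(product_elements)) "?" else product_elements[missing]),
      call. = FALSE)
  }
  atom_mapping(out_p, out_r)
}

#' Decode an atom mapping with neighbour-consistency propagation
#'
#' Highest-first greedy decoding with one refinement: after each accepted
#' pair, candidate cells whose atoms are adjacent (in product and reactant
#' respectively) to already-accepted pairs are preferred, by scoring cells
#' as `probability * (1 + n_consistent_neighbours)`.  Homotopic atoms —
#' e.g. the two ortho carbons of a para-substituted arene — provably
#' receive identical network probabilities, so plain greedy resolves each
#' tied pair independently and can mix the two ring orientations into a
#' chemically wrong mapping; neighbour propagation keeps the assignment
#' orientation-consistent.  With no ties and a confident matrix the result
#' coincides with [decode_greedy()].
#'
#' @param P numeric probability matrix (rows = product atoms).
#' @param record the `rxn_record` the matrix was predicted for (provides
#'   the two bond graphs and element symbols).
#' @param enforce_element_match require identical elements in a pair.
#' @param seed_margin probability advantage a frontier-detached candidate
#'   needs over the best frontier candidate to be accepted (default 0.1).
#' @param tie_eps when a region seed has alternative reactant atoms within
#'   `tie_eps` probability, the alternatives are decoded too and the
#'   mapping with the fewest bond changes wins (minimal-chemical-distance
#'   tie resolution, needed for products whose own symmetry makes the
#'   per-atom probabilities exactly ambiguous).  Set to 0 to disable.
#' @return an `atom_mapping` total over product atoms.
#' @export
decode_consistent <- function(P, record, enforce_element_match = TRUE,
                              seed_margin = 0.1, tie_eps = 0.05) {
  np <- nrow(P); nr <- ncol(P)
  pel <- record$products$atoms$element
  rel <- record$reactants$atoms$element
  padj <- adjacency_list(np, record$products$bonds)
  radj <- adjacency_list(nr, record$reactants$bonds)
  admissible <- if (enforce_element_match) {
    outer(pel, rel, `==`)
  } else matrix(TRUE, np, nr)

  base <- decode_grow(P, admissible, padj, radj, pel, seed_margin,
                      tie_eps = tie_eps)
  if (tie_eps <= 0 || length(base$seeds) == 0L) {
    return(atom_mapping(seq_len(np), base$assignment))
  }
  # minimal-chemical-distance resolution of ambiguous seeds: re-decode
  # with each near-tied seed forced to its alternative and keep the
  # mapping inducing the fewest bond changes
  best_map <- atom_mapping(seq_len(np), base$assignment)
  best_changes <- count_bond_changes(build_cgr(record, best_map))
  for (seed in base$seeds) {
    alts <- setdiff(seed$alts, seed$r)
    for (alt in alts[seq_len(min(3L, length(alts)))]) {
      cand <- decode_grow(P, admissible, padj, radj, pel, seed_margin,
                          forced = list(p = seed$p, r = alt))
      cand_map <- atom_mapping(seq_len(np), cand$assignment)
      changes <- count_bond_changes(build_cgr(record, cand_map))
      if (changes < best_changes) {
        best_map <- cand_map
        best_changes <- changes
      }
    }
  }
  best_map
}

# core region-growing pass; returns the assignment plus the seed decisions
# (each with the near-tied alternative reactant atoms observed at pick
# time)
decode_grow <- function(P, admissible, padj, radj, pel, seed_margin,
                        forced = NULL, tie_eps = 0.05) {
  np <- nrow(P); nr <- ncol(P)

  # region-growing with a seed margin.  Candidates touching the assigned
  # frontier (product atom adjacent to an assigned product atom AND
  # reactant atom adjacent to that atom's partner) are scored
  # probability * (1 + consistent neighbours) and preferred, so two
  # locally identical rings can never swap wholesale: each ring is entered
  # through its attachment atom, which pins ring identity and orientation.
  # A detached candidate (no frontier contact) is taken only when its raw
  # probability beats the best frontier score by `seed_margin`; this keeps
  # cross-molecule provenance decisions — e.g. a hydrolysis oxygen coming
  # from water rather than from the leaving group — with the network,
  # which is the only place that information lives.
  assigned_r_of_p <- integer(np)
  r_used <- logical(nr)
  seeds <- list()
  if (!is.null(forced)) {
    assigned_r_of_p[forced$p] <- forced$r
    r_used[forced$r] <- TRUE
  }
  while (any(assigned_r_of_p == 0L)) {
    open_p <- which(assigned_r_of_p == 0L)
    best_frontier <- NULL
    best_seed <- NULL
    for (p in open_p) {
      for (r in which(admissible[p, ] & !r_used)) {
        boost <- 0L
        for (pn in padj[[p]]) {
          ra <- assigned_r_of_p[pn]
          if (ra > 0L && r %in% radj[[ra]]) boost <- boost + 1L
        }
        if (boost > 0L) {
          score <- P[p, r] * (1 + boost)
          if (is.null(best_frontier) || score > best_frontier$score + 1e-15) {
            best_frontier <- list(p = p, r = r, score = score)
          }
        } else if (is.null(best_seed) || P[p, r] > best_seed$score + 1e-15) {
          best_seed <- list(p = p, r = r, score = P[p, r])
        }
      }
    }
    took_seed <- is.null(best_frontier) ||
      (!is.null(best_seed) &&
         best_seed$score > best_frontier$score + seed_margin)
    best <- if (took_seed) best_seed else best_frontier
    if (is.null(best)) {
      stop(sprintf(
        "product atom %d (%s) has no admissible unassigned reactant atom",
        open_p[1L], pel[open_p[1L]]), call. = FALSE)
    }
    if (took_seed) {
      alts <- which(admissible[best$p, ] & !r_used &
                      P[best$p, ] >= P[best$p, best$r] - tie_eps)
      if (length(alts) > 1L) {
        seeds[[length(seeds) + 1L]] <-
          list(p = best$p, r = best$r, alts = alts)
      }
    }
    assigned_r_of_p[best$p] <- best$r
    r_used[best$r] <- TRUE
  }
  list(assignment = assigned_r_of_p, seeds = seeds)
}

#' Probability-product confidence of a decoded mapping
#'
#' Product of the accepted cells' probabilities — the parameter-based
#' confidence diagnostic; it is not the knowledge-based (template library)
#' confidence used for active learning.
#'
#' @param P the probability matrix the mapping was decoded from.
#' @param mapping an `atom_mapping`.
#' @return a value in `[0, 1]`; equals 1 only if every accepted cell is 1.
#' @export
confidence_score <- function(P, mapping) {
  prod(P[cbind(mapping$product, mapping$reactant)])
}
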