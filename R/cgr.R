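# Condensed graphs of reaction (CGR): construction, equivalence, bond-change
# counting, and the accuracy metrics built on them.
#
# A CGR superposes the reactant and product graphs through an atom mapping.
# Every atom carries (element, charge before/after, implicit H before/after)
# and every bond carries (order before, order after), order 0 meaning the
# bond is absent on that side.  Two mappings of the same reaction are
# equivalent iff their CGRs are isomorphic as labelled graphs, which is
# decided by canonical certificate comparison, so symmetry-related and
# renumbered mappings compare equal.

#' Build the condensed graph of reaction
#'
#' @param record a `rxn_record`.
#' @param mapping an `atom_mapping` total over product heavy atoms and
#'   injective (enforced by [atom_mapping()]).
#' @return a `cgr` object: list with `atoms` (element, charge_before,
#'   charge_after, h_before, h_after, spectator) and `bonds` (a1, a2,
#'   order_before, order_after).  Spectator reactant atoms (not hit by the
#'   mapping) carry `NA` "after" attributes; bonds from a mapped atom to a
#'   spectator have `order_after` 0, bonds between two spectators `NA`.
#' @export
build_cgr <- function(record, mapping) {
  np <- n_atoms(record$products)
  nr <- n_atoms(record$reactants)
  if (!setequal(mapping$product, seq_len(np))) {
    stop("mapping must be total over product atoms", call. = FALSE)
  }
  if (any(mapping$reactant > nr)) {
    stop("mapping references reactant atoms outside the record", call. = FALSE)
  }
  # CGR atom i corresponds to reactant atom i (reactant indexing keeps
  # spectators addressable); product attributes arrive through the mapping
  p_of_r <- integer(nr)
  p_of_r[mapping$reactant] <- mapping$product
  ratoms <- record$reactants$atoms
  patoms <- record$products$atoms
  mapped <- p_of_r > 0L
  mismatch <- which(mapped &
                      ratoms$element != patoms$element[pmax(p_of_r, 1L)])
  if (length(mismatch) > 0L) {
    warning(sprintf("%d cross-element atom pair(s) in mapping",
                    length(mismatch)))
  }
  atoms <- data.frame(
    element = ratoms$element,
    aromatic = ratoms$aromatic,
    charge_before = ratoms$charge,
    charge_after = ifelse(mapped, patoms$charge[pmax(p_of_r, 1L)], NA_integer_),
    h_before = ratoms$hcount,
    h_after = ifelse(mapped, patoms$hcount[pmax(p_of_r, 1L)], NA_integer_),
    spectator = !mapped,
    stringsAsFactors = FALSE
  )

  key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
  rb <- record$reactants$bonds
  pb <- record$products$bonds
  # product bonds expressed in reactant (CGR) indices
  r_of_p <- integer(np)
  r_of_p[mapping$product] <- mapping$reactant
  bonds <- list()
  if (nrow(rb) > 0L) {
    for (k in seq_len(nrow(rb))) {
      bonds[[key(rb$a1[k], rb$a2[k])]] <-
        list(a1 = rb$a1[k], a2 = rb$a2[k], before = rb$order[k], after = 0)
    }
  }
  if (nrow(pb) > 0L) {
    for (k in seq_len(nrow(pb))) {
      a <- r_of_p[pb$a1[k]]; b <- r_of_p[pb$a2[k]]
      kk <- key(a, b)
      if (is.null(bonds[[kk]])) {
        bonds[[kk]] <- list(a1 = a, a2 = b, before = 0, after = pb$order[k])
      } else {
        bonds[[kk]]$after <- pb$order[k]
      }
    }
  }
  bdf <- if (length(bonds) == 0L) {
    data.frame(a1 = integer(), a2 = integer(),
               order_before = numeric(), order_after = numeric())
  } else {
    data.frame(
      a1 = vapply(bonds, function(x) x$a1, integer(1)),
      a2 = vapply(bonds, function(x) x$a2, integer(1)),
      order_before = vapply(bonds, function(x) x$before, numeric(1)),
      order_after = vapply(bonds, function(x) x$after, numeric(1)),
      row.names = NULL
    )
  }
  # bonds between two spectator atoms belong to untracked molecules: no
  # "after" information exists for them
  both_spec <- atoms$spectator[bdf$a1] & atoms$spectator[bdf$a2]
  bdf$order_after[both_spec] <- NA_real_
  structure(list(atoms = atoms, bonds = bdf), class = "cgr")
}

#' @export
print.cgr <- function(x, ...) {
  cat(sprintf("<cgr: %d atoms (%d spectator), %d bonds, %d bond change(s)>\n",
              nrow(x$atoms), sum(x$atoms$spectator), nrow(x$bonds),
              count_bond_changes(x)))
  invisible(x)
}

#' Count changed bonds in a CGR
#'
#' A bond counts as changed when its before/after orders differ.  Bonds
#' between two spectator atoms (no "after" information) and pure
#' hydrogen-count or charge changes on atoms do not count.
#'
#' @param cgr a `cgr`.
#' @return non-negative integer.
#' @export
count_bond_changes <- function(cgr) {
  b <- cgr$bonds
  if (nrow(b) == 0L) return(0L)
  sum(!is.na(b$order_after) & b$order_before != b$order_after)
}

# canonical certificate of a CGR; by default restricted to mapped atoms
# (the evaluation compares the provenance of product atoms)
cgr_certificate <- function(cgr, include_spectators = FALSE,
                            use_hcount = TRUE) {
  keep <- if (include_spectators) seq_len(nrow(cgr$atoms)) else
    which(!cgr$atoms$spectator)
  lookup <- integer(nrow(cgr$atoms)); lookup[keep] <- seq_along(keep)
  a <- cgr$atoms[keep, , drop = FALSE]
  fmt <- function(v) ifelse(is.na(v), ".", as.character(v))
  labels <- paste0(a$element, "|", fmt(a$charge_before), ">",
                   fmt(a$charge_after),
                   if (use_hcount) paste0("|", fmt(a$h_before), ">",
                                          fmt(a$h_after)) else "")
  bsel <- cgr$bonds$a1 %in% keep & cgr$bonds$a2 %in% keep
  b <- cgr$bonds[bsel, , drop = FALSE]
  elabels <- paste0(fmt(b$order_before), ">", fmt(b$order_after))
  canon_graph(labels, lookup[b$a1], lookup[b$a2], elabels)$certificate
}

#' Are two atom mappings equivalent?
#'
#' Two mappings of the same reaction are equivalent iff the condensed graphs
#' of reaction they induce are isomorphic respecting atom element, charge
#' and hydrogen-count labels and bond before/after orders.  Map-number
#' relabelling and symmetry-related (homotopic) re-assignments therefore
#' compare equal, while chemically different atom provenances do not.
#'
#' @param mapping_a,mapping_b `atom_mapping`s, each total over the product
#'   atoms of `record`.
#' @param record the shared `rxn_record`.
#' @param include_spectators include unmapped reactant atoms in the
#'   comparison (default `FALSE`: the evaluation compares mappings of
#'   product atoms).
#' @param use_hcount label atoms with implicit hydrogen counts
#'   (default `TRUE`).
#' @return logical.
#' @export
aam_equivalent <- function(mapping_a, mapping_b, record,
                           include_spectators = FALSE, use_hcount = TRUE) {
  ca <- cgr_certificate(build_cgr(record, mapping_a),
                        include_spectators, use_hcount)
  cb <- cgr_certificate(build_cgr(record, mapping_b),
                        include_spectators, use_hcount)
  identical(ca, cb)
}

#' Calibrated accuracy from dataset- and manually-derived accuracies
#'
#' The dataset-based accuracy of unconfident predictions is backed out of
#' the overall and confident-subset dataset accuracies,
#' \deqn{A_{unconf} = (A_{overall} - A_{conf} r) / (1 - r),}
#' clamped into `[0, 1]` with a warning if inconsistent inputs push it
#' outside, and then recombined with the manually verified confident
#' accuracy, \deqn{A_{cal} = A_{unconf} (1 - r) + A_{manual} r,}
#' where `r` is the confident-prediction ratio.
#'
#' @param acc_overall_dataset overall accuracy against the dataset mapping.
#' @param acc_conf_dataset dataset accuracy of the confident subset.
#' @param ratio_conf fraction of predictions that are confident.
#' @param acc_conf_manual manually verified accuracy of the confident
#'   subset.
#' @return a one-row tibble (the accuracy report) with fields
#'   `acc_overall_dataset`, `acc_conf_dataset`, `acc_conf_manual`,
#'   `ratio_conf`, `ratio_unconf`, `acc_unconf_dataset`, `acc_calibrated`.
#' @export
#' @examples
#' calibrated_accuracy(0.915, 0.928, 0.970, 1.000)$acc_calibrated  # 0.985
calibrated_accuracy <- function(acc_overall_dataset, acc_conf_dataset,
                                ratio_conf, acc_conf_manual) {
  stopifnot(
    acc_overall_dataset >= 0, acc_overall_dataset <= 1,
    acc_conf_dataset >= 0, acc_conf_dataset <= 1,
    ratio_conf >= 0, ratio_conf <= 1,
    acc_conf_manual >= 0, acc_conf_manual <= 1
  )
  ratio_unconf <- 1 - ratio_conf
  if (ratio_unconf <= 0) {
    acc_unconf <- 0  # weight-zero term
  } else {
    acc_unconf <- (acc_overall_dataset - acc_conf_dataset * ratio_conf) /
      ratio_unconf
    if (acc_unconf < 0 || acc_unconf > 1) {
      warning(sprintf(
        "unconfident accuracy %.4f outside [0, 1]; clamped (inconsistent inputs)",
        acc_unconf))
      acc_unconf <- min(1, max(0, acc_unconf))
    }
  }
  acc_cal <- acc_unconf * ratio_unconf + acc_conf_manual * ratio_conf
  tibble::tibble(
    acc_overall_dataset = acc_overall_dataset,
    acc_conf_dataset = acc_conf_dataset,
    acc_conf_manual = acc_conf_manual,
    ratio_conf = ratio_conf,
    ratio_unconf = ratio_unconf,
    acc_unconf_dataset = acc_unconf,
    acc_calibrated = acc_cal
  )
}

#' Evaluate predicted mappings against gold mappings
#'
#' Per-reaction correctness is CGR equivalence ([aam_equivalent()]);
#' aggregates cover overall accuracy, confident-subset accuracy, and the
#' confident ratio.  When `acc_conf_manual` is supplied, the calibrated
#' accuracy is computed as well.  Undefined ratios on empty subsets are
#' reported as `NA`, never coerced to 0.
#'
#' @param tbl a tibble with list-columns `record`, `prediction`, `gold`
#'   (each `atom_mapping`) and a logical column `confident`.
#' @param acc_conf_manual optional manually verified confident accuracy.
#' @return an `aam_eval` object; `tidy()` gives per-reaction verdicts,
#'   `glance()` the accuracy report.
#' @export
evaluate_mappings <- function(tbl, acc_conf_manual = NULL) {
  stopifnot(all(c("record", "prediction", "gold", "confident") %in% names(tbl)))
  correct <- purrr::pmap_lgl(
    list(tbl$record, tbl$prediction, tbl$gold),
    function(rec, pred, gold) {
      if (is.null(pred)) return(FALSE)
      aam_equivalent(pred, gold, rec)
    })
  verdicts <- tibble::tibble(
    id = if ("id" %in% names(tbl)) tbl$id else
      purrr::map_chr(tbl$record, "id"),
    confident = tbl$confident,
    correct = correct
  )
  n <- nrow(verdicts)
  nconf <- sum(verdicts$confident)
  report <- tibble::tibble(
    n = n,
    acc_overall_dataset = mean(verdicts$correct),
    acc_conf_dataset = if (nconf > 0L)
      mean(verdicts$correct[verdicts$confident]) else NA_real_,
    acc_unconf_dataset = if (nconf < n)
      mean(verdicts$correct[!verdicts$confident]) else NA_real_,
    ratio_conf = nconf / n,
    ratio_unconf = 1 - nconf / n,
    acc_calibrated = NA_real_
  )
  if (!is.null(acc_conf_manual) && nconf > 0L) {
    report$acc_calibrated <- calibrated_accuracy(
      report$acc_overall_dataset, report$acc_conf_dataset,
      report$ratio_conf, acc_conf_manual)$acc_calibrated
  }
  structure(list(verdicts = verdicts, report = report), class = "aam_eval")
}

#' @export
print.aam_eval <- function(x, ...) {
  cat(sprintf("<aam_eval: %d reactions, overall accuracy %.3f, confident ratio %.3f>\n",
              x$report$n, x$report$acc_overall_dataset, x$report$ratio_conf))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname evaluate_mappings
#' @param x an `aam_eval` object.
#' @param ... unused.
#' @export
tidy.aam_eval <- function(x, ...) x$verdicts

#' @rdname evaluate_mappings
#' @export
glance.aam_eval <- function(x, ...) x$report
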