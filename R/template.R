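# Extended-local reaction templates (ELRT) and the verified-template
# library that backs knowledge-based prediction confidence.
#
# The template of a mapped reaction is the sub-CGR induced by the reaction
# center (every atom whose bonds, charge or hydrogen count change) extended
# with the atoms of catalogue functional groups that touch the center.
# Center atoms keep their full before/after labels; extension atoms are
# generalized to element + aromaticity.  The pattern string is written from
# the canonical order of this labelled graph, so it is identical for the
# same chemistry regardless of input atom order or map renumbering.

#' The default functional-group catalogue
#'
#' Read from the package's `functional_groups.tsv` configuration file
#' (columns `name`, `pattern`); patterns use the restricted SMARTS subset
#' documented in the methods vignette.  The shipped catalogue covers
#' carbonyl, carboxylic acid, ester, amide, nitrile, nitro,
#' acetal/hemiacetal, imine, sulfonyl, boronic acid/ester, organohalides and
#' aromatic ring heteroatoms.
#'
#' @param path optional path to an alternative catalogue file.
#' @return a tibble with columns `name`, `pattern`.
#' @export
default_group_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "functional_groups.tsv",
                        package = "rxnmapr", mustWork = TRUE)
  }
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Extract the extended-local reaction template of a mapped reaction
#'
#' @param record a `rxn_record`.
#' @param mapping an `atom_mapping` total over product atoms.
#' @param groups functional-group catalogue (tibble with `name`,
#'   `pattern`); defaults to [default_group_catalog()].
#' @return a `rxn_template`: list with `canonical_pattern` (canonical
#'   string), `center_size` (number of changed atoms) and
#'   `extension_groups` (catalogue groups that contributed atoms).
#' @export
extract_elrt <- function(record, mapping, groups = default_group_catalog()) {
  cgr <- build_cgr(record, mapping)
  a <- cgr$atoms; b <- cgr$bonds

  changed_bond <- !is.na(b$order_after) & b$order_before != b$order_after
  center <- unique(c(
    b$a1[changed_bond], b$a2[changed_bond],
    which(!a$spectator &
            (a$charge_before != a$charge_after |
               a$h_before != a$h_after))
  ))
  if (length(center) == 0L) {
    stop("null reaction: no bond, charge or hydrogen change under the mapping",
         call. = FALSE)
  }

  # functional-group extension: group atoms (in reactant/CGR indexing) of
  # matches that share an atom with the center or touch it through a bond
  r_of_p <- integer(n_atoms(record$products))
  r_of_p[mapping$product] <- mapping$reactant
  neighbor_sets <- function(mol, translate = NULL) {
    adj <- adjacency_list(n_atoms(mol), mol$bonds)
    if (is.null(translate)) adj else
      lapply(adj, function(v) translate[v])
  }
  radj <- neighbor_sets(record$reactants)
  padj <- neighbor_sets(record$products, translate = r_of_p)

  ext <- integer(0); ext_groups <- character(0)
  for (gi in seq_len(nrow(groups))) {
    pat <- parse_group_pattern_cached(groups$pattern[gi])
    hits <- c(
      lapply(match_pattern(pat, record$reactants), function(m) {
        list(atoms = m, adj = radj)
      }),
      lapply(match_pattern(pat, record$products), function(m) {
        list(atoms = r_of_p[m], adj = padj)
      })
    )
    for (h in hits) {
      matoms <- h$atoms
      touches <- any(matoms %in% center) ||
        any(unlist(h$adj[matoms]) %in% center)
      if (touches) {
        ext <- union(ext, matoms)
        ext_groups <- union(ext_groups, groups$name[gi])
      }
    }
  }
  ext <- setdiff(ext, center)

  keep <- sort(c(center, ext))
  lookup <- integer(nrow(a)); lookup[keep] <- seq_along(keep)
  is_center <- keep %in% center
  fmt <- function(v) ifelse(is.na(v), ".", as.character(v))
  sub_a <- a[keep, , drop = FALSE]
  labels <- ifelse(
    is_center,
    paste0("C[", sub_a$element, ifelse(sub_a$aromatic, ":ar", ""), ";",
           fmt(sub_a$charge_before), ">", fmt(sub_a$charge_after), ";H",
           fmt(sub_a$h_before), ">", fmt(sub_a$h_after), "]"),
    paste0("X[", sub_a$element, ifelse(sub_a$aromatic, ":ar", ""), "]")
  )
  bsel <- b$a1 %in% keep & b$a2 %in% keep
  sb <- b[bsel, , drop = FALSE]
  elabels <- paste0(fmt(sb$order_before), ">", fmt(sb$order_after))
  cg <- canon_graph(labels, lookup[sb$a1], lookup[sb$a2], elabels)

  # human-readable canonical pattern: atoms in canonical order, then bonds
  rank <- integer(length(keep)); rank[cg$order] <- seq_along(cg$order)
  atom_str <- paste(labels[cg$order], collapse = "")
  if (nrow(sb) > 0L) {
    r1 <- pmin(rank[lookup[sb$a1]], rank[lookup[sb$a2]])
    r2 <- pmax(rank[lookup[sb$a1]], rank[lookup[sb$a2]])
    bond_str <- paste(sort(paste0(r1, "-", r2, ":", elabels)),
                      collapse = ",")
  } else bond_str <- ""
  pattern <- paste0(atom_str, "|", bond_str)

  structure(
    list(
      canonical_pattern = pattern,
      center_size = length(center),
      extension_groups = sort(ext_groups)
    ),
    class = "rxn_template"
  )
}

#' @export
print.rxn_template <- function(x, ...) {
  cat(sprintf("<rxn_template: center %d atom(s); extensions: %s>\n  %s\n",
              x$center_size,
              if (length(x$extension_groups)) paste(x$extension_groups, collapse = ", ")
              else "none",
              x$canonical_pattern))
  invisible(x)
}

#' Create an empty template library
#'
#' The library is the confidence authority: a prediction is confident iff
#' its extracted template is present here with `verified = TRUE`.
#'
#' @return a `template_library` tibble with columns `canonical_pattern`,
#'   `verified`, `reaction_count`, `first_seen_iteration`, `provenance`.
#' @export
template_library <- function() {
  structure(
    tibble::tibble(
      canonical_pattern = character(),
      verified = logical(),
      reaction_count = integer(),
      first_seen_iteration = integer(),
      provenance = character()
    ),
    class = c("template_library", class(tibble::tibble()))
  )
}

#' Update a template library
#'
#' Counts are incremented for known patterns, new patterns appended, and the
#' verified flag is monotone: once a pattern is verified it stays verified.
#'
#' @param library a `template_library`.
#' @param templates a `rxn_template` or list of them.
#' @param verified logical, recycled along `templates`.
#' @param iteration active-learning iteration recorded for new entries.
#' @param labeler provenance string for new entries.
#' @return list with `library` (new state) and `delta` (tibble of patterns
#'   with `new_entry` and `newly_verified` flags).
#' @export
update_library <- function(library, templates, verified = TRUE,
                           iteration = NA_integer_, labeler = "oracle") {
  if (inherits(templates, "rxn_template")) templates <- list(templates)
  verified <- rep_len(verified, length(templates))
  delta <- tibble::tibble(canonical_pattern = character(),
                          new_entry = logical(), newly_verified = logical())
  for (i in seq_along(templates)) {
    pat <- templates[[i]]$canonical_pattern
    row <- which(library$canonical_pattern == pat)
    if (length(row) == 0L) {
      library <- tibble::add_row(
        library, canonical_pattern = pat, verified = verified[i],
        reaction_count = 1L, first_seen_iteration = as.integer(iteration),
        provenance = labeler)
      delta <- tibble::add_row(delta, canonical_pattern = pat,
                               new_entry = TRUE, newly_verified = verified[i])
    } else {
      library$reaction_count[row] <- library$reaction_count[row] + 1L
      newly <- verified[i] && !library$verified[row]
      library$verified[row] <- library$verified[row] || verified[i]
      delta <- tibble::add_row(delta, canonical_pattern = pat,
                               new_entry = FALSE, newly_verified = newly)
    }
  }
  class(library) <- c("template_library", class(tibble::tibble()))
  list(library = library, delta = delta)
}

#' Classify prediction confidence from the template library
#'
#' A prediction is `confident` iff the template extracted from its mapping
#' is already present and human-verified in the library; templates that are
#' absent, or present but unverified, are `uncertain`.  Pure lookup, no
#' side effects.
#'
#' @param template a `rxn_template`.
#' @param library a `template_library`.
#' @return `"confident"` or `"uncertain"`.
#' @export
classify_confidence <- function(template, library) {
  row <- which(library$canonical_pattern == template$canonical_pattern)
  if (length(row) == 1L && library$verified[row]) "confident" else "uncertain"
}

#' Read / write a template library as tab-separated text
#'
#' @param path file path.
#' @export
read_template_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lib <- tibble::as_tibble(df)
  lib$verified <- as.logical(lib$verified)
  lib$reaction_count <- as.integer(lib$reaction_count)
  lib$first_seen_iteration <- as.integer(lib$first_seen_iteration)
  class(lib) <- c("template_library", class(tibble::tibble()))
  lib
}

#' @rdname read_template_library
#' @param library a `template_library`.
#' @export
write_template_library <- function(library, path) {
  utils::write.table(library, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
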