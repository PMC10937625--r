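# Reaction records, atom mappings, dataset filters and serialization.

#' Construct an atom mapping
#'
#' An atom mapping assigns each product heavy atom (by index into the merged
#' product graph) to the reactant heavy atom it originated from.  Both sides
#' must be duplicate-free (the mapping is injective in both directions).
#'
#' @param product,reactant integer atom indices of equal length.
#' @return an `atom_mapping` data frame with columns `product`, `reactant`.
#' @export
atom_mapping <- function(product, reactant) {
  stopifnot(length(product) == length(reactant))
  product <- as.integer(product); reactant <- as.integer(reactant)
  if (anyDuplicated(product) || anyDuplicated(reactant)) {
    stop("atom mapping must be injective on both sides", call. = FALSE)
  }
  if (length(product) > 0L && (any(product < 1L) || any(reactant < 1L))) {
    stop("atom indices must be positive", call. = FALSE)
  }
  structure(
    data.frame(product = product, reactant = reactant),
    class = c("atom_mapping", "data.frame")
  )
}

new_rxn_record <- function(id, reactants, products, raw_text,
                           given_mapping = NULL, agent_components = integer(0)) {
  structure(
    list(
      id = id, reactants = reactants, products = products,
      raw_text = raw_text, given_mapping = given_mapping,
      agent_components = agent_components
    ),
    class = "rxn_record"
  )
}

#' @export
print.rxn_record <- function(x, ...) {
  cat(sprintf(
    "<rxn_record %s: %d reactant atoms (%d molecules), %d product atoms (%d molecules)%s>\n",
    x$id, n_atoms(x$reactants), max(x$reactants$atoms$mol),
    n_atoms(x$products), max(x$products$atoms$mol),
    if (is.null(x$given_mapping)) "" else ", mapped"
  ))
  invisible(x)
}

#' Parse a reaction SMILES into a reaction record
#'
#' The input must have the `reactants>agents>products` structure (the agent
#' field may be empty, i.e. `reactants>>products`).  Agents are merged into
#' the reactant graph but remembered as agent components: they may donate
#' atoms to the product (water in a hydrolysis is a legitimate mapped
#' reactant) but are never required to map.  If the input carries atom-map
#' numbers, a given mapping is extracted from every map number present
#' exactly once on each side.
#'
#' @param text a reaction SMILES string.
#' @param id an identifier stored on the record.
#' @return a `rxn_record`.
#' @export
#' @examples
#' r <- parse_rxn_smiles("CCO>>CC=O")
#' r <- parse_rxn_smiles("[CH3:1][OH:2]>>[CH3:1][O:2]C")
parse_rxn_smiles <- function(text, id = "rxn") {
  fields <- strsplit(text, ">", fixed = TRUE)[[1]]
  if (length(fields) == 2L) fields <- c(fields[1L], "", fields[2L])
  if (length(fields) != 3L) {
    stop(sprintf("'%s' is not a reaction SMILES (expected 'reactants>agents>products')",
                 text), call. = FALSE)
  }
  if (fields[1L] == "" || fields[3L] == "") {
    stop("reaction needs at least one reactant and one product", call. = FALSE)
  }
  reactant_mol <- parse_smiles(fields[1L])
  n_reactant_components <- max(reactant_mol$atoms$mol)
  agent_components <- integer(0)
  if (fields[2L] != "") {
    agent_mol <- parse_smiles(fields[2L])
    merged <- merge_mols(list(reactant_mol, agent_mol))
    agent_components <- seq.int(n_reactant_components + 1L,
                                max(merged$atoms$mol))
    reactant_mol <- merged
  }
  product_mol <- parse_smiles(fields[3L])
  if (any(reactant_mol$atoms$map < 0L) || any(product_mol$atoms$map < 0L)) {
    stop("atom-map numbers must be positive integers", call. = FALSE)
  }
  given <- NULL
  pmaps <- product_mol$atoms$map
  rmaps <- reactant_mol$atoms$map
  mapped_p <- which(pmaps > 0L)
  if (length(mapped_p) > 0L) {
    pairs_p <- integer(0); pairs_r <- integer(0)
    for (i in mapped_p) {
      hit_r <- which(rmaps == pmaps[i])
      dup_p <- sum(pmaps == pmaps[i])
      if (length(hit_r) == 1L && dup_p == 1L) {
        pairs_p <- c(pairs_p, i); pairs_r <- c(pairs_r, hit_r)
      }
    }
    if (length(pairs_p) > 0L) given <- atom_mapping(pairs_p, pairs_r)
  }
  new_rxn_record(id, reactant_mol, product_mol, text, given,
                 agent_components)
}

filter_verdict <- function(keep, reason) {
  tibble::tibble(keep = keep, reason = reason)
}

#' Dataset filter: invalid product mapping
#'
#' Judges a dataset's given mapping: a reaction is excluded when its product
#' shows repeating atom-map numbers or atoms without an atom-map number.
#'
#' @param record a `rxn_record` parsed from a pre-mapped reaction SMILES.
#' @return a one-row tibble with `keep` and `reason`
#'   (`clean` or `invalid_product_mapping`).
#' @export
check_product_mapping <- function(record) {
  maps <- record$products$atoms$map
  bad <- any(maps == 0L) || anyDuplicated(maps[maps > 0L]) > 0L
  if (bad) filter_verdict(FALSE, "invalid_product_mapping")
  else filter_verdict(TRUE, "clean")
}

#' Dataset filter: confusing reagents
#'
#' A reaction is excluded when some reactant molecule contributes no mapped
#' atom to the product yet is structurally similar (Tanimoto similarity of
#' circular fingerprints >= `threshold`) to any product molecule.
#' Participation exempts a reactant regardless of similarity.
#'
#' @param record a `rxn_record`.
#' @param mapping the mapping identifying participating reactants; defaults
#'   to the record's given mapping.
#' @param threshold similarity threshold (default 0.5).
#' @return a one-row tibble with `keep` and `reason`
#'   (`clean` or `confusing_reagent`).
#' @export
check_confusing_reagents <- function(record, mapping = NULL,
                                     threshold = 0.5) {
  if (is.null(mapping)) mapping <- record$given_mapping
  mapped_reactant_atoms <- if (is.null(mapping)) integer(0) else
    mapping$reactant
  rmols <- split_mol(record$reactants)
  pmols <- split_mol(record$products)
  comp_of_atom <- record$reactants$atoms$mol
  pfps <- lapply(pmols, circular_fingerprint)
  for (cid in seq_along(rmols)) {
    atoms_in <- which(comp_of_atom == cid)
    if (any(atoms_in %in% mapped_reactant_atoms)) next  # participates
    rfp <- circular_fingerprint(rmols[[cid]])
    for (fp in pfps) {
      denom <- length(union(rfp, fp))
      sim <- if (denom == 0L) 1 else length(intersect(rfp, fp)) / denom
      if (sim >= threshold) return(filter_verdict(FALSE, "confusing_reagent"))
    }
  }
  filter_verdict(TRUE, "clean")
}

#' Serialize a mapped reaction as reaction SMILES
#'
#' Writes shared positive atom-map numbers on every mapped atom pair;
#' spectator reactant atoms carry none.  The mapping must cover every
#' product heavy atom and reference valid atoms.
#'
#' @param record a `rxn_record`.
#' @param mapping an `atom_mapping` total over product atoms.
#' @return a reaction SMILES string (`reactants>>products`).
#' @export
write_mapped_rxn_smiles <- function(record, mapping) {
  np <- n_atoms(record$products); nr <- n_atoms(record$reactants)
  if (any(mapping$product > np) || any(mapping$reactant > nr)) {
    stop("mapping references atoms outside the reaction", call. = FALSE)
  }
  if (!setequal(mapping$product, seq_len(np))) {
    stop("mapping must cover every product heavy atom", call. = FALSE)
  }
  # map numbers follow the mapping's row order, so permuting rows renumbers
  # the serialization without changing the mapping itself
  rmap <- integer(nr); pmap <- integer(np)
  nums <- seq_len(nrow(mapping))
  pmap[mapping$product] <- nums
  rmap[mapping$reactant] <- nums
  paste0(write_smiles(record$reactants, map = rmap), ">>",
         write_smiles(record$products, map = pmap))
}

#' Parse a table (or vector) of reaction SMILES
#'
#' @param x a character vector of reaction SMILES, or a data frame with
#'   columns `id` and `rxn_smiles`.
#' @return a tibble with columns `id`, `rxn_smiles`, `record` (list of
#'   `rxn_record`, `NULL` where unparseable), `parsed`, `parse_error`.
#' @export
parse_reactions <- function(x) {
  if (is.character(x)) {
    x <- tibble::tibble(id = paste0("rxn", seq_along(x)), rxn_smiles = x)
  }
  stopifnot(all(c("id", "rxn_smiles") %in% names(x)))
  out <- purrr::map2(x$rxn_smiles, x$id, function(s, id) {
    tryCatch(list(record = parse_rxn_smiles(s, id = id), error = NA_character_),
             error = function(e) list(record = NULL, error = conditionMessage(e)))
  })
  tibble::tibble(
    id = x$id,
    rxn_smiles = x$rxn_smiles,
    record = purrr::map(out, "record"),
    parsed = purrr::map_lgl(out, ~ is.null(.x$error) || is.na(.x$error)),
    parse_error = purrr::map_chr(out, "error")
  )
}

#' Apply the dataset-cleaning filters to parsed reactions
#'
#' Attaches a verdict per reaction: `unparseable`, `invalid_product_mapping`,
#' `confusing_reagent`, or `clean`.  The two mapping filters judge the
#' dataset's given mapping, so they only fire on records parsed from
#' pre-mapped reaction SMILES.  Filters are order-independent: each rule is
#' evaluated on the parsed record alone, and the reported reason is the
#' first violated rule in the fixed order above.
#'
#' @param tbl output of [parse_reactions()].
#' @param threshold Tanimoto threshold for the confusing-reagent rule.
#' @return `tbl` with `keep` (logical) and `reason` (character) columns.
#' @export
filter_reactions <- function(tbl, threshold = 0.5) {
  verdicts <- purrr::map2(tbl$record, tbl$parsed, function(rec, ok) {
    if (!ok || is.null(rec)) return(filter_verdict(FALSE, "unparseable"))
    v1 <- check_product_mapping(rec)
    if (!v1$keep) return(v1)
    v2 <- check_confusing_reagents(rec, threshold = threshold)
    if (!v2$keep) return(v2)
    filter_verdict(TRUE, "clean")
  })
  tbl$keep <- purrr::map_lgl(verdicts, "keep")
  tbl$reason <- purrr::map_chr(verdicts, "reason")
  tbl
}

#' Read reactions from disk
#'
#' Accepts either plain text (one reaction SMILES per line) or CSV with
#' columns `id,rxn_smiles`, decided by the file extension (`.csv`).
#'
#' @param path input file.
#' @return a tibble with columns `id`, `rxn_smiles`.
#' @export
read_reactions <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(c("id", "rxn_smiles") %in% names(df)))
    tibble::as_tibble(df[, c("id", "rxn_smiles")])
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    tibble::tibble(id = paste0("rxn", seq_along(lines)), rxn_smiles = lines)
  }
}

#' Write reactions to disk
#'
#' @param tbl a tibble with columns `id`, `rxn_smiles`.
#' @param path output file; `.csv` writes `id,rxn_smiles`, anything else one
#'   SMILES per line.
#' @export
write_reactions <- function(tbl, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(tbl[, c("id", "rxn_smiles")], path, row.names = FALSE,
                     quote = FALSE)
  } else {
    writeLines(tbl$rxn_smiles, path)
  }
  invisible(path)
}
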