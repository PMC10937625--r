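# Synthetic mapped reactions with ground truth known by construction.
#
# Eight hand-coded reaction classes (ester hydrolysis, esterification, SN2
# halide substitution, amide coupling, nitro reduction, acetal hydrolysis,
# Suzuki-type biaryl coupling, imine condensation) are instantiated with
# randomly sampled substituents from a small valence-checked vocabulary.
# Each instance carries its ground-truth atom mapping as explicit atom-index
# pairs (independent of map numbers, so relabelling tests are meaningful),
# and atom orders are shuffled per record to prevent positional leakage.
# Controlled corruptions generate mappings that are deliberately wrong
# (wrong atom provenance) or deliberately equivalent (homotopic relabels,
# renumbered serializations).

# substituent vocabulary; every fragment attaches through its first atom and
# uses ring digit 9 so skeleton ring digits 1-2 never collide
synth_fragments <- function() {
  tibble::tibble(
    name = c("methyl", "ethyl", "n_propyl", "isopropyl", "n_butyl",
             "isobutyl", "allyl", "phenyl", "p_tolyl", "benzyl"),
    smiles = c("C", "CC", "CCC", "C(C)C", "CCCC", "CC(C)C", "CC=C",
               "c9ccccc9", "c9ccc(C)cc9", "Cc9ccccc9")
  )
}

# each builder returns list(rsmi, psmi, pairs) with pairs = cbind(product,
# reactant) atom indices under the written atom order
synth_builders <- function() {
  frag_n <- function(f) n_atoms(parse_smiles(f))
  list(
    ester_hydrolysis = function(f1, f2) {
      n1 <- frag_n(f1); n2 <- frag_n(f2)
      list(
        rsmi = paste0("C(", f1, ")(=O)O", f2, ".O"),
        psmi = paste0("C(", f1, ")(=O)O.O", f2),
        pairs = rbind(
          c(1L, 1L),
          cbind(1L + seq_len(n1), 1L + seq_len(n1)),
          c(2L + n1, 2L + n1),                 # carbonyl O
          c(3L + n1, 4L + n1 + n2),            # acid OH O <- water O
          c(4L + n1, 3L + n1),                 # alcohol O <- ester bridge O
          cbind(4L + n1 + seq_len(n2), 3L + n1 + seq_len(n2))
        )
      )
    },
    esterification = function(f1, f2) {
      n1 <- frag_n(f1); n2 <- frag_n(f2)
      list(
        rsmi = paste0("C(", f1, ")(=O)O.O", f2),
        psmi = paste0("C(", f1, ")(=O)O", f2, ".O"),
        pairs = rbind(
          c(1L, 1L),
          cbind(1L + seq_len(n1), 1L + seq_len(n1)),
          c(2L + n1, 2L + n1),
          c(3L + n1, 4L + n1),                 # ester bridge O <- alcohol O
          cbind(3L + n1 + seq_len(n2), 4L + n1 + seq_len(n2)),
          c(4L + n1 + n2, 3L + n1)             # water O <- acid OH O
        )
      )
    },
    sn2_halide = function(f1, f2) {
      n1 <- frag_n(f1)
      list(
        rsmi = paste0("BrC", f1, ".[I-]"),
        psmi = paste0("IC", f1),
        pairs = rbind(
          c(1L, 3L + n1),                      # product I <- iodide
          c(2L, 2L),
          cbind(2L + seq_len(n1), 2L + seq_len(n1))
        )
      )
    },
    amide_coupling = function(f1, f2) {
      n1 <- frag_n(f1); n2 <- frag_n(f2)
      list(
        rsmi = paste0("C(", f1, ")(=O)O.N", f2),
        psmi = paste0("C(", f1, ")(=O)N", f2, ".O"),
        pairs = rbind(
          c(1L, 1L),
          cbind(1L + seq_len(n1), 1L + seq_len(n1)),
          c(2L + n1, 2L + n1),
          c(3L + n1, 4L + n1),                 # amide N <- amine N
          cbind(3L + n1 + seq_len(n2), 4L + n1 + seq_len(n2)),
          c(4L + n1 + n2, 3L + n1)             # water O <- acid OH O
        )
      )
    },
    nitro_reduction = function(f1, f2) {
      n1 <- frag_n(f1)
      list(
        rsmi = paste0("[O-][N+](=O)", f1),
        psmi = paste0("N", f1),
        pairs = rbind(
          c(1L, 2L),                           # amine N <- nitro N
          cbind(1L + seq_len(n1), 3L + seq_len(n1))
        )
      )
    },
    acetal_hydrolysis = function(f1, f2) {
      n1 <- frag_n(f1)
      list(
        rsmi = paste0("C(", f1, ")(OC)OC.O"),
        psmi = paste0("C(", f1, ")=O.OC.OC"),
        pairs = rbind(
          c(1L, 1L),
          cbind(1L + seq_len(n1), 1L + seq_len(n1)),
          c(2L + n1, 6L + n1),                 # aldehyde O <- water O
          c(3L + n1, 2L + n1),                 # methanol-1 O <- acetal O1
          c(4L + n1, 3L + n1),
          c(5L + n1, 4L + n1),                 # methanol-2 O <- acetal O2
          c(6L + n1, 5L + n1)
        )
      )
    },
    suzuki_coupling = function(f1, f2) {
      n1 <- frag_n(f1); n2 <- frag_n(f2)
      # reactants: O B O [a1 c c c_para f1 c c] Br [b1 c c c_para f2 c c]
      list(
        rsmi = paste0("OB(O)c1ccc(", f1, ")cc1.Brc1ccc(", f2, ")cc1"),
        psmi = paste0("c1(-c2ccc(", f2, ")cc2)ccc(", f1, ")cc1"),
        pairs = rbind(
          c(1L, 4L),                                        # biaryl C (B side)
          cbind(1L + seq_len(6L + n2), 10L + n1 + seq_len(6L + n2)),
          cbind(7L + n2 + seq_len(5L + n1), 4L + seq_len(5L + n1))
        )
      )
    },
    imine_condensation = function(f1, f2) {
      n1 <- frag_n(f1); n2 <- frag_n(f2)
      list(
        rsmi = paste0("C(", f1, ")=O.N", f2),
        psmi = paste0("C(", f1, ")=N", f2),
        pairs = rbind(
          c(1L, 1L),
          cbind(1L + seq_len(n1), 1L + seq_len(n1)),
          c(2L + n1, 3L + n1),                 # imine N <- amine N
          cbind(2L + n1 + seq_len(n2), 3L + n1 + seq_len(n2))
        )
      )
    }
  )
}

#' Names of the built-in synthetic reaction templates
#'
#' @return character vector of the eight reaction-class names.
#' @export
synthetic_templates <- function() names(synth_builders())

#' Generate synthetic mapped reactions
#'
#' Reactions are sampled uniformly over (template, substituent) choices,
#' atom orders are shuffled per record, and every record passes the dataset
#' filters by construction.  Deterministic given `seed`.
#'
#' @param n number of reactions.
#' @param templates subset of [synthetic_templates()] to draw from.
#' @param seed RNG seed.
#' @param shuffle_atoms randomly permute atom orders (default `TRUE`).
#' @return a tibble with columns `id`, `template`, `rxn_smiles` (mapped),
#'   and list-columns `record` (`rxn_record`) and `gold` (`atom_mapping`).
#' @export
generate_reactions <- function(n, templates = synthetic_templates(),
                               seed = 1L, shuffle_atoms = TRUE) {
  stopifnot(n >= 1L)
  builders <- synth_builders()
  stopifnot(all(templates %in% names(builders)))
  frags <- synth_fragments()
  withr::local_seed(seed)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tname <- sample(templates, 1L)
    f1 <- sample(frags$smiles, 1L)
    f2 <- sample(frags$smiles, 1L)
    built <- builders[[tname]](f1, f2)
    rec <- tryCatch(
      parse_rxn_smiles(paste0(built$rsmi, ">>", built$psmi),
                       id = sprintf("synth%05d", i)),
      error = function(e) NULL)
    if (is.null(rec)) {
      warning(sprintf("skipping invalid %s instance (%s, %s)",
                      tname, f1, f2))
      next
    }
    gold <- atom_mapping(built$pairs[, 1L], built$pairs[, 2L])
    if (shuffle_atoms) {
      nr <- n_atoms(rec$reactants); np <- n_atoms(rec$products)
      perm_r <- sample.int(nr); perm_p <- sample.int(np)
      inv_r <- integer(nr); inv_r[perm_r] <- seq_len(nr)
      inv_p <- integer(np); inv_p[perm_p] <- seq_len(np)
      rec$reactants <- permute_mol(rec$reactants, perm_r)
      rec$products <- permute_mol(rec$products, perm_p)
      gold <- atom_mapping(inv_p[gold$product], inv_r[gold$reactant])
    }
    rec$raw_text <- write_mapped_rxn_smiles(rec, gold)
    rows[[i]] <- tibble::tibble(
      id = rec$id, template = tname, rxn_smiles = rec$raw_text,
      record = list(rec), gold = list(gold))
  }
  dplyr::bind_rows(rows)
}

#' Corrupt a mapped reaction in a controlled way
#'
#' `wrong_atom_source` re-routes the provenance of same-element product
#' atoms (a swap or a 3-cycle of their reactant sources) so that the result
#' is not CGR-equivalent to the truth, preferring corruptions that increase
#' the bond-change count — the error class of mis-attributed oxygen sources
#' in hydrolysis reactions.  `equivalent_relabel` redirects the mapping
#' through a transposition automorphism of the reactant graph (homotopic
#' atoms) when one exists and renumbers; `shuffled_numbers` renumbers the
#' serialized map labels only.  The latter two are always CGR-equivalent to
#' the input.
#'
#' @param record a `rxn_record`.
#' @param mapping the ground-truth `atom_mapping`.
#' @param mode one of `"wrong_atom_source"`, `"equivalent_relabel"`,
#'   `"shuffled_numbers"`.
#' @param seed RNG seed for the renumbering permutations.
#' @return list with `record` (raw text re-serialized) and `mapping`.
#' @export
corrupt_mapping <- function(record, mapping,
                            mode = c("wrong_atom_source",
                                     "equivalent_relabel",
                                     "shuffled_numbers"),
                            seed = 1L) {
  mode <- match.arg(mode)
  withr::local_seed(seed)
  out_mapping <- switch(
    mode,
    shuffled_numbers = {
      perm <- sample.int(nrow(mapping))
      atom_mapping(mapping$product[perm], mapping$reactant[perm])
    },
    equivalent_relabel = {
      sw <- find_transposition_automorphism(record$reactants)
      m <- mapping
      if (!is.null(sw)) {
        r <- m$reactant
        r[m$reactant == sw[1L]] <- sw[2L]
        r[mapping$reactant == sw[2L]] <- sw[1L]
        m <- atom_mapping(m$product, r)
      }
      perm <- sample.int(nrow(m))
      atom_mapping(m$product[perm], m$reactant[perm])
    },
    wrong_atom_source = {
      gold_cgr <- build_cgr(record, mapping)
      gold_changes <- count_bond_changes(gold_cgr)
      elements <- record$products$atoms$element
      n <- nrow(mapping)
      candidates <- list()
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          if (elements[mapping$product[i]] != elements[mapping$product[j]])
            next
          candidates[[length(candidates) + 1L]] <- c(i, j)
        }
      }
      # 3-cycles among same-element triples
      if (n >= 3L) {
        for (i in seq_len(n - 2L)) {
          for (j in (i + 1L):(n - 1L)) {
            for (k in (j + 1L):n) {
              el <- elements[mapping$product[c(i, j, k)]]
              if (length(unique(el)) == 1L) {
                candidates[[length(candidates) + 1L]] <- c(i, j, k)
              }
            }
          }
        }
      }
      best <- NULL; best_strict <- FALSE
      for (cand in candidates) {
        r <- mapping$reactant
        r[cand] <- r[c(cand[-1L], cand[1L])]   # rotate sources
        m2 <- atom_mapping(mapping$product, r)
        if (aam_equivalent(m2, mapping, record)) next
        changes <- count_bond_changes(build_cgr(record, m2))
        if (changes > gold_changes) { best <- m2; best_strict <- TRUE; break }
        if (changes >= gold_changes && is.null(best)) best <- m2
      }
      if (is.null(best)) {
        stop("wrong_atom_source inapplicable: no same-element re-routing changes the CGR",
             call. = FALSE)
      }
      best
    }
  )
  record$raw_text <- write_mapped_rxn_smiles(record, out_mapping)
  list(record = record, mapping = out_mapping)
}
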