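# Shared fixtures, built in code at test time.

fixture_groups <- function() default_group_catalog()

# ester hydrolysis CC(=O)OC + H2O -> CC(=O)O + CH3OH with known atom order:
# reactants: C1 C2 O3(=O) O4(bridge) C5(methyl) O6(water)
# products:  C1 C2 O3(=O) O4(acid OH) O5(alcohol) C6(methyl)
ester_fixture <- function() {
  rec <- parse_rxn_smiles("CC(=O)OC.O>>CC(=O)O.OC", id = "ester")
  list(
    record = rec,
    gold = atom_mapping(product = 1:6, reactant = c(1, 2, 3, 6, 4, 5)),
    # dataset-style error: acid OH oxygen attributed to the leaving group
    wrong = atom_mapping(product = 1:6, reactant = c(1, 2, 3, 4, 6, 5))
  )
}

# small labeled set for network tests
tiny_training_set <- function(n = 12, seed = 404,
                              templates = c("sn2_halide",
                                            "nitro_reduction")) {
  tb <- generate_reactions(n, templates = templates, seed = seed)
  tibble::tibble(record = tb$record, mapping = tb$gold)
}

expect_mapping_equal <- function(a, b) {
  expect_setequal(paste(a$product, a$reactant),
                  paste(b$product, b$reactant))
}

# independent brute-force greedy decoder: explicit sort of all cells and a
# linear scan with used sets (kept deliberately separate from the package
# implementation)
oracle_greedy <- function(P, pel = NULL, rel = NULL, enforce = FALSE) {
  cells <- data.frame(
    p = rep(seq_len(nrow(P)), ncol(P)),
    r = rep(seq_len(ncol(P)), each = nrow(P))
  )
  cells$prob <- P[cbind(cells$p, cells$r)]
  cells <- cells[order(-cells$prob, cells$p, cells$r), ]
  used_p <- rep(FALSE, nrow(P)); used_r <- rep(FALSE, ncol(P))
  res_p <- integer(0); res_r <- integer(0)
  for (i in seq_len(nrow(cells))) {
    p <- cells$p[i]; r <- cells$r[i]
    if (used_p[p] || used_r[r]) next
    if (enforce && pel[p] != rel[r]) next
    used_p[p] <- TRUE; used_r[r] <- TRUE
    res_p <- c(res_p, p); res_r <- c(res_r, r)
  }
  list(product = res_p, reactant = res_r)
}

random_prob_matrix <- function(np, nr) {
  m <- matrix(stats::rexp(np * nr), np, nr)
  m / rowSums(m)
}
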