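test_that("CGR construction and bond-change counting match manual counts", {
  # identity reaction: no changes
  ident <- parse_rxn_smiles("CCO>>CCO")
  cgr0 <- build_cgr(ident, atom_mapping(1:3, 1:3))
  expect_equal(count_bond_changes(cgr0), 0L)

  # SN2: C-Br broken, C-I formed
  sn2 <- parse_rxn_smiles("[CH3:1][Br:2].[I-:3]>>[CH3:1][I:3]")
  cgr1 <- build_cgr(sn2, sn2$given_mapping)
  expect_equal(count_bond_changes(cgr1), 2L)
  # the iodide loses its charge across the reaction
  i_row <- which(cgr1$atoms$element == "I")
  expect_equal(cgr1$atoms$charge_before[i_row], -1L)
  expect_equal(cgr1$atoms$charge_after[i_row], 0L)

  # ester hydrolysis with water-oxygen mapping: broken C-O(ester),
  # formed C-O(water)
  fx <- ester_fixture()
  expect_equal(count_bond_changes(build_cgr(fx$record, fx$gold)), 2L)
})

test_that("spectator atoms keep before-side info but no after-side info", {
  sn2 <- parse_rxn_smiles("[CH3:1][Br:2].[I-:3]>>[CH3:1][I:3]")
  cgr <- build_cgr(sn2, sn2$given_mapping)
  br <- which(cgr$atoms$element == "Br")
  expect_true(cgr$atoms$spectator[br])
  expect_true(is.na(cgr$atoms$h_after[br]))
})

test_that("water- vs leaving-group-oxygen provenances are NOT equivalent", {
  fx <- ester_fixture()
  expect_false(aam_equivalent(fx$gold, fx$wrong, fx$record))
  expect_true(aam_equivalent(fx$gold, fx$gold, fx$record))
})

test_that("equivalence is invariant to map renumbering and symmetry", {
  fx <- ester_fixture()
  # permuted pair order (renumbered serialization)
  perm <- sample(6)
  renum <- atom_mapping(fx$gold$product[perm], fx$gold$reactant[perm])
  expect_true(aam_equivalent(fx$gold, renum, fx$record))

  # homotopic methyls on a symmetric substrate: either assignment works
  sym <- parse_rxn_smiles("CC(C)O>>CC(C)=O")
  m1 <- atom_mapping(1:4, 1:4)
  m2 <- atom_mapping(1:4, c(3, 2, 1, 4))
  expect_true(aam_equivalent(m1, m2, sym))
  # but a methyl-for-oxygen style misassignment would differ
  asym <- parse_rxn_smiles("CC(C)Br.[I-]>>CC(C)I")
  a1 <- atom_mapping(1:4, c(1, 2, 3, 5))
  a2 <- atom_mapping(1:4, c(3, 2, 1, 5))
  expect_true(aam_equivalent(a1, a2, asym))
})

test_that("aam_equivalent is an equivalence relation on fixture mappings", {
  tb <- generate_reactions(12, seed = 21)
  for (i in seq_len(nrow(tb))) {
    rec <- tb$record[[i]]; gold <- tb$gold[[i]]
    a <- gold
    b <- corrupt_mapping(rec, gold, "shuffled_numbers", seed = i)$mapping
    c <- corrupt_mapping(rec, gold, "equivalent_relabel", seed = i)$mapping
    # reflexive, symmetric, transitive on {a, b, c}
    expect_true(aam_equivalent(a, a, rec))
    expect_equal(aam_equivalent(a, b, rec), aam_equivalent(b, a, rec))
    if (aam_equivalent(a, b, rec) && aam_equivalent(b, c, rec)) {
      expect_true(aam_equivalent(a, c, rec))
    }
  }
})

test_that("equivalent mappings have identical bond-change counts", {
  tb <- generate_reactions(10, seed = 77)
  for (i in seq_len(nrow(tb))) {
    rec <- tb$record[[i]]; gold <- tb$gold[[i]]
    eq <- corrupt_mapping(rec, gold, "equivalent_relabel", seed = i)$mapping
    expect_true(aam_equivalent(gold, eq, rec))
    expect_equal(count_bond_changes(build_cgr(rec, eq)),
                 count_bond_changes(build_cgr(rec, gold)))
  }
})

test_that("calibrated accuracy reproduces the reference arithmetic", {
  expect_equal(
    round(calibrated_accuracy(0.915, 0.928, 0.970, 1.000)$acc_calibrated, 3),
    0.985)
  expect_equal(
    round(calibrated_accuracy(0.981, 0.997, 0.309, 0.936)$acc_calibrated, 3),
    0.962)
  # no confident predictions: calibrated reduces to the overall accuracy
  r0 <- calibrated_accuracy(0.8, 0.9, 0, 1)
  expect_equal(r0$acc_calibrated, 0.8)
  # all confident: the unconfident term has zero weight
  r1 <- calibrated_accuracy(0.9, 0.9, 1, 0.95)
  expect_equal(r1$acc_calibrated, 0.95)
  # inconsistent inputs are clamped with a warning
  expect_warning(calibrated_accuracy(0.99, 0.5, 0.9, 0.9), "clamped")
  # linear in the manual accuracy with slope ratio_conf
  r <- 0.7
  y1 <- calibrated_accuracy(0.9, 0.92, r, 0.5)$acc_calibrated
  y2 <- calibrated_accuracy(0.9, 0.92, r, 0.9)$acc_calibrated
  expect_equal((y2 - y1) / 0.4, r)
  expect_equal(r1$ratio_conf + r1$ratio_unconf, 1)
})

test_that("evaluate_mappings aggregates verdicts correctly", {
  tb <- generate_reactions(4, templates = "sn2_halide", seed = 55)
  # 3 of 4 correct (one wrong source), 2 confident (both correct)
  preds <- tb$gold
  preds[[4]] <- corrupt_mapping(tb$record[[4]], tb$gold[[4]],
                                "wrong_atom_source")$mapping
  ev <- evaluate_mappings(tibble::tibble(
    id = tb$id, record = tb$record, prediction = preds, gold = tb$gold,
    confident = c(TRUE, TRUE, FALSE, FALSE)))
  g <- glance(ev)
  expect_equal(g$acc_overall_dataset, 0.75)
  expect_equal(g$acc_conf_dataset, 1)
  expect_equal(g$ratio_conf, 0.5)
  expect_equal(nrow(tidy(ev)), 4L)

  # empty confident subset: reported as NA, not 0
  ev2 <- evaluate_mappings(tibble::tibble(
    id = tb$id, record = tb$record, prediction = preds, gold = tb$gold,
    confident = rep(FALSE, 4)))
  expect_true(is.na(glance(ev2)$acc_conf_dataset))
})
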