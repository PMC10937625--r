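test_that("reaction centers are the changed atoms", {
  sn2 <- parse_rxn_smiles("[CH3:1][Br:2].[I-:3]>>[CH3:1][I:3]")
  t1 <- extract_elrt(sn2, sn2$given_mapping, fixture_groups())
  expect_equal(t1$center_size, 3L)  # C, Br, I

  # identity mapping is a null reaction
  ident <- parse_rxn_smiles("CCO>>CCO")
  expect_error(extract_elrt(ident, atom_mapping(1:3, 1:3),
                            fixture_groups()),
               "null reaction")

  # hydrogen-count changes alone count as a change
  red <- parse_rxn_smiles("[CH2:1]=[CH2:2]>>[CH3:1][CH3:2]")
  t2 <- extract_elrt(red, red$given_mapping, fixture_groups())
  expect_gte(t2$center_size, 2L)
})

test_that("ester hydrolysis includes the carbonyl-group extension", {
  fx <- ester_fixture()
  t <- extract_elrt(fx$record, fx$gold, fixture_groups())
  expect_true("carbonyl" %in% t$extension_groups)
  # the wrong-oxygen mapping extracts a different template
  tw <- extract_elrt(fx$record, fx$wrong, fixture_groups())
  expect_false(identical(t$canonical_pattern, tw$canonical_pattern))
})

test_that("canonical patterns are invariant to atom order and renumbering", {
  withr::local_seed(123)
  tb <- generate_reactions(20, seed = 9)
  for (i in seq_len(nrow(tb))) {
    rec <- tb$record[[i]]; gold <- tb$gold[[i]]
    ref <- extract_elrt(rec, gold, fixture_groups())$canonical_pattern
    for (rep in 1:3) {
      nr <- rxnmapr:::n_atoms(rec$reactants)
      np <- rxnmapr:::n_atoms(rec$products)
      pr <- sample(nr); pp <- sample(np)
      inv_r <- integer(nr); inv_r[pr] <- seq_len(nr)
      inv_p <- integer(np); inv_p[pp] <- seq_len(np)
      rec2 <- rec
      rec2$reactants <- rxnmapr:::permute_mol(rec$reactants, pr)
      rec2$products <- rxnmapr:::permute_mol(rec$products, pp)
      g2 <- atom_mapping(inv_p[gold$product], inv_r[gold$reactant])
      expect_identical(
        extract_elrt(rec2, g2, fixture_groups())$canonical_pattern, ref)
    }
  }
})

test_that("one synthetic class gives one pattern; classes are distinct", {
  tb <- generate_reactions(64, seed = 14)
  pats <- purrr::map2_chr(tb$record, tb$gold,
                          ~ extract_elrt(.x, .y, fixture_groups())$canonical_pattern)
  per_class <- tapply(pats, tb$template, function(x) length(unique(x)))
  expect_true(all(per_class == 1L))
  first_per_class <- tapply(pats, tb$template, function(x) x[[1]])
  expect_equal(length(unique(first_per_class)), length(first_per_class))
})

test_that("library updates count, append, and keep verification monotone", {
  fx <- ester_fixture()
  t <- extract_elrt(fx$record, fx$gold, fixture_groups())
  lib <- template_library()

  u1 <- update_library(lib, t, verified = FALSE, iteration = 1L)
  expect_equal(nrow(u1$library), 1L)
  expect_true(u1$delta$new_entry)
  expect_equal(classify_confidence(t, u1$library), "uncertain")

  u2 <- update_library(u1$library, t, verified = TRUE, iteration = 2L)
  expect_equal(nrow(u2$library), 1L)
  expect_equal(u2$library$reaction_count, 2L)
  expect_true(u2$library$verified)
  expect_equal(classify_confidence(t, u2$library), "confident")

  # once verified, stays verified
  u3 <- update_library(u2$library, t, verified = FALSE, iteration = 3L)
  expect_true(u3$library$verified)
  expect_equal(u3$library$reaction_count, 3L)

  # absent template is uncertain
  sn2 <- parse_rxn_smiles("[CH3:1][Br:2].[I-:3]>>[CH3:1][I:3]")
  t2 <- extract_elrt(sn2, sn2$given_mapping, fixture_groups())
  expect_equal(classify_confidence(t2, u3$library), "uncertain")
})

test_that("template libraries round trip through TSV", {
  fx <- ester_fixture()
  t <- extract_elrt(fx$record, fx$gold, fixture_groups())
  lib <- update_library(template_library(), t, verified = TRUE,
                        iteration = 1L)$library
  path <- withr::local_tempfile(fileext = ".tsv")
  write_template_library(lib, path)
  lib2 <- read_template_library(path)
  expect_equal(lib2$canonical_pattern, lib$canonical_pattern)
  expect_equal(lib2$verified, lib$verified)
  expect_equal(lib2$reaction_count, lib$reaction_count)
})

test_that("templates of verified classes classify every instance confident", {
  tb <- generate_reactions(40, seed = 33)
  lib <- template_library()
  # verify one instance of each class
  firsts <- tb[!duplicated(tb$template), ]
  for (i in seq_len(nrow(firsts))) {
    t <- extract_elrt(firsts$record[[i]], firsts$gold[[i]], fixture_groups())
    lib <- update_library(lib, t, verified = TRUE, iteration = 1L)$library
  }
  for (i in seq_len(nrow(tb))) {
    t <- extract_elrt(tb$record[[i]], tb$gold[[i]], fixture_groups())
    expect_equal(classify_confidence(t, lib), "confident")
  }
})
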