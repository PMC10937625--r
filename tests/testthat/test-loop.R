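test_that("random sampling is uniform, exact and seed-deterministic", {
  pool <- tibble::tibble(id = letters[1:10], record = as.list(1:10))
  expect_equal(nrow(random_sample_reactions(pool, 10, seed = 1)), 10L)
  s1 <- random_sample_reactions(pool, 3, seed = 2)
  s2 <- random_sample_reactions(pool, 3, seed = 2)
  expect_identical(s1$id, s2$id)
  expect_error(random_sample_reactions(pool, 11), "exceeds pool size")

  # frequency over repeated draws of k=1 is uniform within 3 SE
  draws <- vapply(1:4000, function(s) {
    random_sample_reactions(pool, 1, seed = s)$id
  }, character(1))
  freq <- table(factor(draws, levels = pool$id)) / 4000
  se <- sqrt(0.1 * 0.9 / 4000)
  expect_true(all(abs(freq - 0.1) < 3.5 * se))
})

test_that("active sampling ranks templates by popularity and wraps", {
  uncertain <- tibble::tibble(
    id = paste0("r", 1:85),
    pattern = rep(c("T1", "T2", "T3"), c(50, 30, 5))
  )
  s <- active_sample_reactions(uncertain, 2, seed = 1)
  expect_equal(sort(s$pattern), c("T1", "T2"))

  # k larger than the number of unique templates: second pass repeats the
  # rank order
  s2 <- active_sample_reactions(uncertain, 5, seed = 1)
  expect_equal(table(s2$pattern)[["T1"]], 2L)
  expect_equal(table(s2$pattern)[["T2"]], 2L)
  expect_equal(table(s2$pattern)[["T3"]], 1L)

  # empty uncertain set gives an empty sample
  expect_equal(nrow(active_sample_reactions(uncertain[0, ], 3)), 0L)

  # exhaustion: k beyond the pool returns everything
  small <- uncertain[c(1, 51, 81), ]
  expect_equal(nrow(active_sample_reactions(small, 10)), 3L)
})

test_that("augmentation samples per verified template and splits 9:1", {
  lib <- template_library()
  lib <- update_library(lib, structure(list(canonical_pattern = "T1",
                                            center_size = 1L,
                                            extension_groups = character(0)),
                                       class = "rxn_template"),
                        verified = TRUE, iteration = 1L)$library
  pool <- tibble::tibble(
    id = paste0("r", 1:260),
    record = as.list(1:260),
    prediction = as.list(1:260),
    confident = c(rep(TRUE, 250), rep(FALSE, 10)),
    pattern = c(rep("T1", 250), rep("T2", 10))
  )
  labeled <- tibble::tibble(id = character(), record = list(),
                            mapping = list())
  sets <- augment_training_set(pool, lib, labeled, per_template = 100,
                               seed = 3)
  expect_equal(nrow(sets$train) + nrow(sets$validation), 100L)
  expect_equal(nrow(sets$train), 90L)
  expect_equal(nrow(sets$validation), 10L)

  # fewer confident reactions than the cap: all used, 36/4
  pool40 <- pool[c(1:40, 251:260), ]
  sets40 <- augment_training_set(pool40, lib, labeled, per_template = 100,
                                 seed = 3)
  expect_equal(nrow(sets40$train), 36L)
  expect_equal(nrow(sets40$validation), 4L)

  # no confident predictions: training set is the labeled set only
  pool0 <- pool; pool0$confident <- FALSE
  labeled1 <- tibble::tibble(id = "h1", record = list(1),
                             mapping = list(1))
  sets0 <- augment_training_set(pool0, lib, labeled1, seed = 3)
  expect_equal(sets0$train$id, "h1")
  expect_equal(nrow(sets0$validation), 0L)

  # human-labeled reactions are never displaced into validation
  labeled2 <- tibble::tibble(id = paste0("r", 1:5),
                             record = pool$record[1:5],
                             mapping = pool$prediction[1:5])
  sets2 <- augment_training_set(pool, lib, labeled2, per_template = 100,
                                seed = 3)
  expect_true(all(labeled2$id %in% sets2$train$id))
  expect_false(any(labeled2$id %in% sets2$validation$id))
})

test_that("a small active-learning run satisfies the loop invariants", {
  tb <- generate_reactions(60, templates = c("ester_hydrolysis",
                                             "sn2_halide",
                                             "nitro_reduction"),
                           seed = 5)
  loop <- run_active_loop(
    tb[, c("id", "record")], oracle_from_truth(tb), k = 10, iterations = 2,
    net_cfg = mapper_net_config(hidden_dim = 32L, heads = 4L),
    train_cfg = train_config(epochs = 15L),
    seed = 2)
  st <- tidy(loop)
  expect_equal(nrow(st), 2L)
  # labeled set grows by exactly k per iteration
  expect_equal(st$n_labeled, c(10L, 20L))
  # verified template count is non-decreasing
  expect_true(all(diff(st$verified_templates) >= 0))
  # coverage is non-decreasing when the oracle verifies every template
  expect_true(all(diff(st$coverage) >= -1e-9))
  # every confident prediction is CGR-equivalent correct
  pool <- loop$pool
  gold_by_id <- stats::setNames(tb$gold, tb$id)
  for (i in which(pool$confident)) {
    expect_true(aam_equivalent(pool$prediction[[i]],
                               gold_by_id[[pool$id[i]]],
                               pool$record[[i]]))
  }
  expect_equal(glance(loop)$pool_size, 60L)
})

test_that("the truth oracle validates ids and the loop rejects bad labels", {
  tb <- generate_reactions(4, seed = 91)
  oracle <- oracle_from_truth(tb)
  lab <- oracle(tb$record[[2]])
  expect_true(lab$verified)
  expect_mapping_equal(lab$mapping, tb$gold[[2]])
  stranger <- parse_rxn_smiles("CCO>>CC=O", id = "nope")
  expect_error(oracle(stranger), "no ground truth")
})
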