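test_that("featurization counts atoms and bonds and merges molecules", {
  cfg <- feature_config()
  f1 <- featurize_reaction(parse_rxn_smiles("C>>C"), cfg)
  expect_equal(nrow(f1$reactant$X), 1L)
  expect_equal(length(f1$reactant$src), 0L)

  f2 <- featurize_reaction(parse_rxn_smiles("CCO>>CC=O"), cfg)
  expect_equal(nrow(f2$reactant$X), 3L)
  expect_equal(length(f2$reactant$src), 4L)  # 2 bonds, both directions

  # two-reactant merge: 5 + 1 atoms, 4 + 0 bonds, no cross-molecule bond
  f3 <- featurize_reaction(parse_rxn_smiles("CC(=O)OC.O>>CC(=O)O.OC"), cfg)
  expect_equal(nrow(f3$reactant$X), 6L)
  expect_equal(length(f3$reactant$src), 8L)
  expect_equal(ncol(f3$reactant$X), cfg$atom_dim)
})

test_that("unknown elements fall back to the unknown slot with a warning", {
  cfg <- feature_config()
  expect_warning(
    featurize_reaction(parse_rxn_smiles("[Se]C>>C"), cfg),
    "unknown")
})

test_that("one MPNN layer matches an independent hand-computed oracle", {
  # 3-atom path a-b-c with hand-set weights, hidden width 2
  d <- 2L; fb <- 3L
  H <- rbind(c(1, 0), c(0, 1), c(1, 1))
  src <- c(1L, 2L, 2L, 3L)
  tgt <- c(2L, 1L, 3L, 2L)
  Eb <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 1, 0))
  Wm <- matrix(seq(0.1, 1.0, length.out = (d + fb) * d), d + fb, d)
  bm <- c(0.05, -0.05)
  Wu <- matrix(seq(-0.5, 0.5, length.out = 2 * d * d), 2 * d, d)
  bu <- c(0.1, 0.2)

  out <- rxnmapr:::mpnn_layer_forward(H, src, tgt, Eb, Wm, bm, Wu, bu)

  # oracle: explicit loops, no shared code with the layer implementation
  relu0 <- function(x) ifelse(x > 0, x, 0)
  msgs <- matrix(0, 4, d)
  for (e in 1:4) {
    inp <- c(H[src[e], ], Eb[e, ])
    for (j in 1:d) msgs[e, j] <- relu0(sum(inp * Wm[, j]) + bm[j])
  }
  expected <- matrix(0, 3, d)
  for (v in 1:3) {
    agg <- rep(0, d)
    for (e in which(tgt == v)) agg <- agg + msgs[e, ]
    inp <- c(H[v, ], agg)
    for (j in 1:d) expected[v, j] <- relu0(sum(inp * Wu[, j]) + bu[j])
  }
  expect_equal(out$H, expected, tolerance = 1e-10)
})

test_that("a single attention head matches hand-computed softmax(QK/s)V", {
  # 2 product atoms x 3 reactant atoms, hidden width 2
  Hp <- rbind(c(0.5, -1), c(1, 2))
  Hr <- rbind(c(1, 0), c(0, 1), c(-1, 1))
  Wq <- rbind(c(0.2, -0.1), c(0.4, 0.3))
  Wk <- rbind(c(-0.3, 0.5), c(0.1, 0.2))
  Wv <- rbind(c(1, 0.5), c(-0.5, 1))
  scale <- sqrt(2)
  out <- rxnmapr:::attention_head_forward(Hp, Hr, Wq, Wk, Wv, scale)

  expected <- matrix(0, 2, 2)
  for (u in 1:2) {
    q <- as.vector(Hp[u, ] %*% Wq)
    scores <- numeric(3)
    for (v in 1:3) scores[v] <- sum(q * as.vector(Hr[v, ] %*% Wk)) / scale
    w <- exp(scores - max(scores)); w <- w / sum(w)
    acc <- c(0, 0)
    for (v in 1:3) acc <- acc + w[v] * as.vector(Hr[v, ] %*% Wv)
    expected[u, ] <- acc
  }
  expect_equal(out$O, expected, tolerance = 1e-10)
})

test_that("attention degenerates correctly on singletons and duplicates", {
  cfg <- feature_config()
  nc <- mapper_net_config(hidden_dim = 8L, heads = 2L, dropout = 0)
  params <- rxnmapr:::init_mapper_params(nc, cfg, seed = 1L)
  # one product atom, one reactant atom: the probability matrix is [[1]]
  fx <- featurize_reaction(parse_rxn_smiles("O>>O"), cfg)
  P <- rxnmapr:::mapper_forward(params, fx, nc)$P
  expect_equal(dim(P), c(1L, 1L))
  expect_equal(P[1, 1], 1)
  # duplicate identical reactant atoms receive identical probability
  fx2 <- featurize_reaction(parse_rxn_smiles("O.O>>O"), cfg)
  P2 <- rxnmapr:::mapper_forward(params, fx2, nc)$P
  expect_equal(P2[1, 1], P2[1, 2], tolerance = 1e-12)
})

test_that("probability rows sum to one for arbitrary inputs", {
  cfg <- feature_config()
  nc <- mapper_net_config(hidden_dim = 16L, heads = 4L)
  params <- rxnmapr:::init_mapper_params(nc, cfg, seed = 2L)
  for (s in c("CC(=O)OC.O>>CC(=O)O.OC", "BrCCC.[I-]>>ICCC",
              "c1ccccc1>>c1ccccc1")) {
    fx <- featurize_reaction(parse_rxn_smiles(s), cfg)
    P <- rxnmapr:::mapper_forward(params, fx, nc)$P
    expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-6)
  }
})

test_that("the network is permutation-equivariant", {
  withr::local_seed(11)
  cfg <- feature_config()
  nc <- mapper_net_config(hidden_dim = 16L, heads = 4L, dropout = 0)
  params <- rxnmapr:::init_mapper_params(nc, cfg, seed = 3L)
  rec <- parse_rxn_smiles("CC(=O)OC.O>>CC(=O)O.OC")
  P <- rxnmapr:::mapper_forward(params, featurize_reaction(rec, cfg), nc)$P
  for (r in 1:5) {
    pr <- sample(6); pp <- sample(6)
    rec2 <- rec
    rec2$reactants <- rxnmapr:::permute_mol(rec$reactants, pr)
    rec2$products <- rxnmapr:::permute_mol(rec$products, pp)
    P2 <- rxnmapr:::mapper_forward(params, featurize_reaction(rec2, cfg),
                                   nc)$P
    # row i of P2 is product atom pp[i]; column j is reactant atom pr[j]
    expect_equal(P2, P[pp, pr], tolerance = 1e-10)
  }
})

test_that("analytic gradients agree with finite differences", {
  withr::local_seed(42)
  cfg <- feature_config()
  nc <- mapper_net_config(hidden_dim = 8L, heads = 2L, mpnn_layers = 2L,
                          attention_blocks = 2L, dropout = 0)
  rec <- parse_rxn_smiles("CC(=O)OC.O>>CC(=O)O.OC")
  fx <- featurize_reaction(rec, cfg)
  gold <- atom_mapping(1:6, c(1, 2, 3, 6, 4, 5))
  params <- rxnmapr:::init_mapper_params(nc, cfg, seed = 3L)
  res <- rxnmapr:::mapper_loss_grads(params, fx, gold, nc, training = FALSE)
  h <- 1e-5
  for (nm in c("Win", "Wm1", "Wu2", "Wq1", "Wk2", "Wv1", "Wg2", "Wf11",
               "Wf22", "ga11", "be22", "Wcq", "Wck")) {
    x <- params[[nm]]
    for (i in sample(length(x), 2)) {
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + h
      lp <- rxnmapr:::mapper_loss_grads(p2, fx, gold, nc,
                                        training = FALSE)$loss
      p2[[nm]][i] <- p2[[nm]][i] - 2 * h
      lm <- rxnmapr:::mapper_loss_grads(p2, fx, gold, nc,
                                        training = FALSE)$loss
      num <- (lp - lm) / (2 * h)
      expect_equal(res$grads[[nm]][i], num, tolerance = 1e-3,
                   label = paste("grad", nm))
    }
  }
})

test_that("untrained uniform rows give cross-entropy log(n_reactant)", {
  # with all-zero classifier weights the scores are 0 and P is uniform
  cfg <- feature_config()
  nc <- mapper_net_config(hidden_dim = 8L, heads = 2L, dropout = 0)
  params <- rxnmapr:::init_mapper_params(nc, cfg, seed = 4L)
  params$Wcq[] <- 0
  rec <- parse_rxn_smiles("CC(=O)OC.O>>CC(=O)O.OC")
  fx <- featurize_reaction(rec, cfg)
  gold <- atom_mapping(1:6, c(1, 2, 3, 6, 4, 5))
  res <- rxnmapr:::mapper_loss_grads(params, fx, gold, nc, training = FALSE)
  expect_equal(res$loss, log(6), tolerance = 1e-6)
})

test_that("training is deterministic given a seed and rejects bad labels", {
  exs <- tiny_training_set(6, seed = 71)
  nc <- mapper_net_config(hidden_dim = 16L, heads = 4L)
  tc <- train_config(epochs = 3L, seed = 5L)
  f1 <- train_mapper(exs, nc, tc)
  f2 <- train_mapper(exs, nc, tc)
  expect_identical(f1$log$loss, f2$log$loss)
  expect_identical(f1$params$Win, f2$params$Win)

  bad <- exs
  bad$mapping[[1]] <- atom_mapping(1L, 1L)
  expect_error(train_mapper(bad, nc, tc), "cover every product")
})

test_that("dropout is the only difference between train and eval modes", {
  cfg <- feature_config()
  rec <- parse_rxn_smiles("CCO>>CC=O")
  fx <- featurize_reaction(rec, cfg)
  nc0 <- mapper_net_config(hidden_dim = 8L, heads = 2L, dropout = 0)
  params <- rxnmapr:::init_mapper_params(nc0, cfg, seed = 6L)
  withr::with_seed(1, {
    P_train <- rxnmapr:::mapper_forward(params, fx, nc0, training = TRUE)$P
  })
  P_eval <- rxnmapr:::mapper_forward(params, fx, nc0, training = FALSE)$P
  expect_equal(P_train, P_eval)  # no dropout: modes agree exactly

  nc1 <- mapper_net_config(hidden_dim = 8L, heads = 2L, dropout = 0.5)
  withr::with_seed(1, {
    P_drop <- rxnmapr:::mapper_forward(params, fx, nc1, training = TRUE)$P
  })
  expect_false(isTRUE(all.equal(P_drop, P_eval)))
  # eval mode ignores the dropout rate entirely
  expect_equal(rxnmapr:::mapper_forward(params, fx, nc1,
                                        training = FALSE)$P, P_eval)
})

test_that("a small model overfits a small labeled set to perfect mapping", {
  tb <- generate_reactions(20, templates = c("sn2_halide",
                                             "nitro_reduction"),
                           seed = 88)
  exs <- tibble::tibble(record = tb$record, mapping = tb$gold)
  fit <- train_mapper(
    exs,
    net_cfg = mapper_net_config(hidden_dim = 64L),
    train_cfg = train_config(epochs = 60L, seed = 7L))
  preds <- predict_mappings(fit, tibble::tibble(id = tb$id,
                                                record = tb$record))
  correct <- purrr::pmap_lgl(
    list(preds$prediction, tb$gold, tb$record),
    function(p, g, r) !is.null(p) && aam_equivalent(p, g, r))
  expect_equal(mean(correct), 1)
  # training loss decreased substantially
  expect_lt(fit$log$loss[nrow(fit$log)], fit$log$loss[1] / 5)
})
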