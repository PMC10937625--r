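# Training the mapper network and predicting mappings.

normalize_examples <- function(examples) {
  if (is.data.frame(examples)) {
    stopifnot(all(c("record", "mapping") %in% names(examples)))
    examples <- purrr::map2(examples$record, examples$mapping,
                            function(r, m) list(record = r, mapping = m))
  }
  for (ex in examples) {
    np <- n_atoms(ex$record$products)
    if (!setequal(ex$mapping$product, seq_len(np))) {
      stop(sprintf(
        "labeled mapping for '%s' does not cover every product atom",
        ex$record$id), call. = FALSE)
    }
  }
  examples
}

#' Train the atom-mapping network
#'
#' Minimizes the mean negative log probability of the gold atom pairs
#' (cross-entropy over the rows of the mapping probability matrix) with
#' Adam, honoring the batch size, weight decay, gradient clipping and
#' plateau learning-rate schedule in `train_cfg`.  Two runs with the same
#' seed produce identical fits.
#'
#' @param examples labeled reactions: a tibble with list-columns `record`
#'   and `mapping`, or a list of `list(record, mapping)`.  Every mapping
#'   must cover all product heavy atoms.
#' @param net_cfg a [mapper_net_config()].
#' @param train_cfg a [train_config()].
#' @param validation optional labeled reactions in the same format; drives
#'   the plateau schedule (training loss is used when absent).
#' @param feat_cfg a [feature_config()].
#' @param verbose print per-epoch losses.
#' @return a `mapper_fit` with elements `params`, `net_cfg`, `feat_cfg`,
#'   `train_cfg`, `log` (per-epoch tibble), `seed`.  `tidy()` returns the
#'   log, `glance()` a one-row summary.
#' @export
train_mapper <- function(examples, net_cfg = mapper_net_config(),
                         train_cfg = train_config(), validation = NULL,
                         feat_cfg = feature_config(), verbose = FALSE) {
  examples <- normalize_examples(examples)
  if (!is.null(validation) &&
      (is.data.frame(validation) && nrow(validation) == 0L)) {
    validation <- NULL
  }
  if (!is.null(validation)) validation <- normalize_examples(validation)

  withr::local_seed(train_cfg$seed)
  fxs <- lapply(examples, function(ex) {
    list(fx = featurize_reaction(ex$record, feat_cfg), gold = ex$mapping)
  })
  vxs <- if (is.null(validation)) NULL else lapply(validation, function(ex) {
    list(fx = featurize_reaction(ex$record, feat_cfg), gold = ex$mapping)
  })

  params <- init_mapper_params(net_cfg, feat_cfg,
                               seed = stats::runif(1, 1, 2^30))
  adam_m <- lapply(params, function(x) x * 0)
  adam_v <- lapply(params, function(x) x * 0)
  beta1 <- 0.9; beta2 <- 0.999; aeps <- 1e-8
  step <- 0L
  lr <- train_cfg$learning_rate
  best_monitor <- Inf
  stale <- 0L
  n <- length(fxs)
  log <- vector("list", train_cfg$epochs)

  eval_loss <- function(set) {
    mean(vapply(set, function(e) {
      fw <- mapper_forward(params, e$fx, net_cfg, training = FALSE)
      idx <- cbind(e$gold$product, e$gold$reactant)
      -mean(log(fw$P[idx] + 1e-12))
    }, numeric(1)))
  }

  for (epoch in seq_len(train_cfg$epochs)) {
    ord <- sample.int(n)
    batch_losses <- numeric(0)
    for (start in seq(1L, n, by = train_cfg$batch_size)) {
      batch <- ord[start:min(start + train_cfg$batch_size - 1L, n)]
      grads <- lapply(params, function(x) x * 0)
      bl <- 0
      for (i in batch) {
        res <- mapper_loss_grads(params, fxs[[i]]$fx, fxs[[i]]$gold,
                                 net_cfg, training = TRUE)
        bl <- bl + res$loss
        for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + res$grads[[nm]]
      }
      nb <- length(batch)
      for (nm in names(grads)) {
        grads[[nm]] <- grads[[nm]] / nb +
          train_cfg$weight_decay * params[[nm]]
      }
      gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
      if (gn > train_cfg$grad_clip_norm) {
        sc <- train_cfg$grad_clip_norm / gn
        grads <- lapply(grads, function(g) g * sc)
      }
      step <- step + 1L
      bc1 <- 1 - beta1^step; bc2 <- 1 - beta2^step
      for (nm in names(params)) {
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * grads[[nm]]
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * grads[[nm]]^2
        params[[nm]] <- params[[nm]] -
          lr * (adam_m[[nm]] / bc1) / (sqrt(adam_v[[nm]] / bc2) + aeps)
      }
      batch_losses <- c(batch_losses, bl / nb)
    }
    train_loss <- mean(batch_losses)
    # the plateau monitor is evaluated without dropout so the schedule
    # reacts to the model, not to dropout noise; validation loss when a
    # validation set exists, else the training set itself
    val_loss <- if (is.null(vxs)) NA_real_ else eval_loss(vxs)
    monitor <- if (is.null(vxs)) eval_loss(fxs) else val_loss
    if (monitor < best_monitor - 1e-8) {
      best_monitor <- monitor
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= train_cfg$patience) {
        lr <- lr * train_cfg$lr_decay_factor
        stale <- 0L
      }
    }
    log[[epoch]] <- tibble::tibble(epoch = epoch, loss = train_loss,
                                   val_loss = val_loss, lr = lr)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val %.4f  lr %.2e",
                      epoch, train_loss, val_loss, lr))
    }
  }
  structure(
    list(params = params, net_cfg = net_cfg, feat_cfg = feat_cfg,
         train_cfg = train_cfg, log = dplyr::bind_rows(log),
         seed = train_cfg$seed),
    class = "mapper_fit"
  )
}

#' @export
print.mapper_fit <- function(x, ...) {
  cat(sprintf(
    "<mapper_fit: d=%d, %d epochs, final loss %.4f (seed %d)>\n",
    x$net_cfg$hidden_dim, nrow(x$log), x$log$loss[nrow(x$log)], x$seed))
  invisible(x)
}

#' @rdname train_mapper
#' @param x a `mapper_fit`.
#' @param ... unused.
#' @export
tidy.mapper_fit <- function(x, ...) x$log

#' @rdname train_mapper
#' @export
glance.mapper_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$log),
    final_loss = x$log$loss[nrow(x$log)],
    final_val_loss = x$log$val_loss[nrow(x$log)],
    final_lr = x$log$lr[nrow(x$log)],
    hidden_dim = x$net_cfg$hidden_dim,
    seed = x$seed
  )
}

#' Predict the mapping probability matrix for one reaction
#'
#' @param fit a `mapper_fit`.
#' @param record a `rxn_record`.
#' @return the probability matrix (rows = product atoms, columns = reactant
#'   atoms; rows sum to 1) with element vectors attached as attributes
#'   `product_elements` / `reactant_elements`.
#' @export
predict_mapping_matrix <- function(fit, record) {
  fx <- featurize_reaction(record, fit$feat_cfg)
  P <- mapper_forward(fit$params, fx, fit$net_cfg, training = FALSE)$P
  attr(P, "product_elements") <- fx$product$elements
  attr(P, "reactant_elements") <- fx$reactant$elements
  P
}

#' Predict atom mappings for a table of reactions
#'
#' Runs the network and the greedy decoder on every record.
#'
#' @param fit a `mapper_fit`.
#' @param tbl a tibble with a `record` list-column (e.g. from
#'   [parse_reactions()]), or a list of `rxn_record`s.
#' @param enforce_element_match require identical elements in accepted
#'   pairs.
#' @param decoder `"consistent"` (default; [decode_consistent()], which
#'   keeps symmetry-tied assignments orientation-consistent) or `"greedy"`
#'   (plain highest-first, [decode_greedy()]).
#' @return `tbl` with list-column `prediction` (`atom_mapping`, or `NULL`
#'   when decoding fails) and numeric `prob_confidence` (probability-product
#'   diagnostic).
#' @export
predict_mappings <- function(fit, tbl, enforce_element_match = TRUE,
                             decoder = c("consistent", "greedy")) {
  decoder <- match.arg(decoder)
  if (!is.data.frame(tbl)) {
    tbl <- tibble::tibble(
      id = purrr::map_chr(tbl, "id"),
      record = tbl
    )
  }
  out <- purrr::map(tbl$record, function(rec) {
    P <- predict_mapping_matrix(fit, rec)
    m <- tryCatch(
      if (decoder == "consistent") {
        decode_consistent(P, rec,
                          enforce_element_match = enforce_element_match)
      } else {
        decode_greedy(P, attr(P, "product_elements"),
                      attr(P, "reactant_elements"),
                      enforce_element_match = enforce_element_match)
      },
      error = function(e) NULL)
    list(mapping = m,
         conf = if (is.null(m)) NA_real_ else confidence_score(P, m))
  })
  tbl$prediction <- purrr::map(out, "mapping")
  tbl$prob_confidence <- purrr::map_dbl(out, "conf")
  tbl
}

#' Save / load a mapper checkpoint
#'
#' A checkpoint is a single archive holding the feature-schema version, the
#' network configuration and the weights; loading refuses a checkpoint
#' whose feature-schema version differs from the current one.
#'
#' @param fit a `mapper_fit`.
#' @param path file path.
#' @export
write_mapper_checkpoint <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname write_mapper_checkpoint
#' @export
read_mapper_checkpoint <- function(path) {
  fit <- readRDS(path)
  current <- feature_config()$version
  if (!identical(fit$feat_cfg$version, current)) {
    stop(sprintf(
      "checkpoint feature schema '%s' does not match current '%s'",
      fit$feat_cfg$version, current), call. = FALSE)
  }
  fit
}
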