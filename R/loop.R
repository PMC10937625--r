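# The human-in-the-loop active-learning workflow:
# sample -> label -> update template library -> train -> predict the pool ->
# classify confidence -> actively sample the next batch from uncertain
# predictions, with semi-supervised augmentation from confident predictions
# starting at the second iteration.

#' Labeling oracles
#'
#' An oracle is a function taking a `rxn_record` and returning
#' `list(mapping = <atom_mapping>, verified = <logical>)` — the mapping for
#' the reaction and whether the expert verified the extracted template.
#' `oracle_from_truth()` replays the ground truth carried by a synthetic
#' reaction table; `oracle_interactive()` prompts on the console for a
#' mapped reaction SMILES, re-parses and validates it.
#'
#' @param truth a tibble with columns `id` and list-column `gold`
#'   (e.g. from [generate_reactions()]).
#' @return a labeling oracle function.
#' @export
oracle_from_truth <- function(truth) {
  lookup <- stats::setNames(truth$gold, truth$id)
  function(record) {
    m <- lookup[[record$id]]
    if (is.null(m)) stop(sprintf("no ground truth for '%s'", record$id),
                         call. = FALSE)
    list(mapping = m, verified = TRUE)
  }
}

#' @rdname oracle_from_truth
#' @export
oracle_interactive <- function() {
  function(record) {
    cat("Reaction:", record$raw_text, "\n")
    ans <- readline("Mapped reaction SMILES (empty to skip): ")
    if (!nzchar(ans)) return(NULL)
    rec2 <- parse_rxn_smiles(ans, id = record$id)
    if (is.null(rec2$given_mapping)) {
      stop("input carries no usable atom-map numbers", call. = FALSE)
    }
    list(mapping = rec2$given_mapping, verified = TRUE)
  }
}

#' Random seed sampling from the pool
#'
#' Uniform sampling without replacement; deterministic given `seed`.
#'
#' @param pool a tibble of reactions.
#' @param k number of rows to sample (`k <= nrow(pool)`).
#' @param seed RNG seed.
#' @return the sampled rows.
#' @export
random_sample_reactions <- function(pool, k, seed = 1L) {
  if (k > nrow(pool)) {
    stop(sprintf("k = %d exceeds pool size %d", k, nrow(pool)),
         call. = FALSE)
  }
  withr::local_seed(seed)
  pool[sample.int(nrow(pool), k), , drop = FALSE]
}

#' Active sampling from uncertain predictions
#'
#' Templates extracted from uncertain predictions are ranked by how many
#' reactions share them (descending, ties by pattern string); one reaction
#' is taken per template in rank order, and if the templates are exhausted
#' before `k` reactions are collected, further passes take a second (third,
#' ...) reaction per template in the same order.  Within a template the
#' reaction order is deterministic given `seed`.
#'
#' @param uncertain a tibble with a `pattern` column (extracted template
#'   pattern) — typically the uncertain subset of a classified pool.
#' @param k number of reactions wanted.
#' @param seed RNG seed.
#' @return up to `k` rows of `uncertain`.
#' @export
active_sample_reactions <- function(uncertain, k, seed = 1L) {
  if (nrow(uncertain) == 0L || k <= 0L) {
    return(uncertain[integer(0), , drop = FALSE])
  }
  withr::local_seed(seed)
  counts <- sort(table(uncertain$pattern), decreasing = TRUE)
  # stable rank: count descending, pattern string ascending on ties
  pats <- names(counts)
  ord <- order(-as.integer(counts), pats)
  pats <- pats[ord]
  per_template <- lapply(pats, function(p) {
    rows <- which(uncertain$pattern == p)
    rows[sample.int(length(rows))]
  })
  picked <- integer(0)
  pass <- 1L
  while (length(picked) < k) {
    added <- FALSE
    for (rows in per_template) {
      if (length(rows) >= pass) {
        picked <- c(picked, rows[pass])
        added <- TRUE
        if (length(picked) == k) break
      }
    }
    if (!added) break   # everything exhausted
    pass <- pass + 1L
  }
  uncertain[picked, , drop = FALSE]
}

#' Semi-supervised training-set augmentation
#'
#' For every verified template in the library, up to `per_template`
#' confident predictions are sampled from the pool (all of them if fewer)
#' and added, with their predicted mappings as pseudo-labels, to the
#' human-labeled set.  The augmented reactions are split into training and
#' validation sets by `split_ratio`; human-labeled pairs always stay in
#' training.
#'
#' @param pool classified pool (columns `id`, `record`, `prediction`,
#'   `confident`, `pattern`).
#' @param library the `template_library`.
#' @param labeled tibble of human-labeled pairs (`record`, `mapping`).
#' @param per_template confident reactions sampled per verified template
#'   (default 100).
#' @param split_ratio training fraction of the augmented data (default 0.9,
#'   i.e. a 9:1 split).
#' @param seed RNG seed.
#' @return list with `train` and `validation` tibbles (`record`, `mapping`).
#' @export
augment_training_set <- function(pool, library, labeled,
                                 per_template = 100L, split_ratio = 0.9,
                                 seed = 1L) {
  withr::local_seed(seed)
  verified <- library$canonical_pattern[library$verified]
  pick <- integer(0)
  eligible <- pool$confident & !is.na(pool$pattern) &
    !(pool$id %in% labeled$id)
  for (pat in verified) {
    rows <- which(eligible & pool$pattern == pat)
    if (length(rows) == 0L) next
    take <- min(per_template, length(rows))
    pick <- c(pick, rows[sample.int(length(rows), take)])
  }
  aug <- tibble::tibble(
    id = pool$id[pick],
    record = pool$record[pick],
    mapping = pool$prediction[pick]
  )
  if (nrow(aug) > 0L) {
    n_train <- floor(split_ratio * nrow(aug))
    ord <- sample.int(nrow(aug))
    train_aug <- aug[ord[seq_len(n_train)], , drop = FALSE]
    val <- aug[ord[-seq_len(n_train)], , drop = FALSE]
  } else {
    train_aug <- aug
    val <- aug
  }
  train <- dplyr::bind_rows(
    tibble::tibble(id = labeled$id, record = labeled$record,
                   mapping = labeled$mapping),
    train_aug
  )
  list(train = train, validation = val)
}

# predict the whole pool with a fit, extract templates, classify confidence
classify_pool <- function(fit, pool, library, groups) {
  pool <- predict_mappings(fit, pool)
  pool$pattern <- purrr::map2_chr(pool$record, pool$prediction,
                                  function(rec, m) {
    if (is.null(m)) return(NA_character_)
    tryCatch(extract_elrt(rec, m, groups)$canonical_pattern,
             error = function(e) NA_character_)
  })
  verified <- library$canonical_pattern[library$verified]
  pool$confident <- !is.na(pool$pattern) & pool$pattern %in% verified
  pool
}

#' Run the human-in-the-loop active-learning workflow
#'
#' Executes `iterations` rounds of: sample `k` reactions (randomly at the
#' first iteration, by uncertainty-driven active sampling afterwards), label
#' them through `oracle`, update the verified-template library, train the
#' mapper from scratch (with confident-prediction augmentation from the
#' second iteration on), predict the whole pool, and classify every
#' prediction as confident or uncertain against the library.
#'
#' @param pool a tibble with columns `id`, `record` (e.g. from
#'   [generate_reactions()] or [parse_reactions()]).
#' @param oracle a labeling oracle (see [oracle_from_truth()]).
#' @param k reactions labeled per iteration.
#' @param iterations number of iterations.
#' @param net_cfg,train_cfg,feat_cfg network, training and feature
#'   configurations.
#' @param groups functional-group catalogue for template extraction.
#' @param per_template,split_ratio augmentation settings
#'   (see [augment_training_set()]).
#' @param seed master seed; all per-iteration seeds derive from it.
#' @param verbose print progress.
#' @return an `aam_loop` object: list with `pool` (final classified pool),
#'   `labeled`, `library`, `fit` (final model) and `stats` (per-iteration
#'   tibble: `iteration`, `n_labeled`, `verified_templates`, `coverage`).
#'   `tidy()` returns `stats`; `glance()` a one-row summary.
#' @export
run_active_loop <- function(pool, oracle, k, iterations,
                            net_cfg = mapper_net_config(hidden_dim = 64L),
                            train_cfg = train_config(epochs = 30L),
                            feat_cfg = feature_config(),
                            groups = default_group_catalog(),
                            per_template = 100L, split_ratio = 0.9,
                            seed = 1L, verbose = FALSE) {
  stopifnot(all(c("id", "record") %in% names(pool)))
  labeled <- tibble::tibble(id = character(), record = list(),
                            mapping = list())
  library <- template_library()
  fit <- NULL
  stats <- vector("list", iterations)

  for (it in seq_len(iterations)) {
    it_seed <- (seed * 1000L + it) %% .Machine$integer.max
    # 1. sample
    candidates <- pool[!(pool$id %in% labeled$id), , drop = FALSE]
    kk <- min(k, nrow(candidates))
    batch <- if (it == 1L || is.null(fit)) {
      random_sample_reactions(candidates, kk, seed = it_seed)
    } else {
      uncertain <- candidates[
        !candidates$confident & !is.na(candidates$pattern), , drop = FALSE]
      b <- active_sample_reactions(uncertain, kk, seed = it_seed)
      if (nrow(b) < kk) {
        # top up from the remaining unlabeled reactions (no usable
        # template or none uncertain left)
        rest <- candidates[!(candidates$id %in% b$id), , drop = FALSE]
        extra <- random_sample_reactions(rest, min(kk - nrow(b), nrow(rest)),
                                         seed = it_seed + 1L)
        b <- dplyr::bind_rows(b, extra)
      }
      b
    }
    # 2. oracle labels + library update
    for (ri in seq_len(nrow(batch))) {
      rec <- batch$record[[ri]]
      lab <- tryCatch(oracle(rec), error = function(e) NULL)
      if (is.null(lab)) next
      ok <- tryCatch({
        stopifnot(setequal(lab$mapping$product,
                           seq_len(n_atoms(rec$products))))
        TRUE
      }, error = function(e) FALSE)
      if (!ok) {
        warning(sprintf("oracle mapping for '%s' rejected; record re-queued",
                        rec$id))
        next
      }
      tmpl <- tryCatch(extract_elrt(rec, lab$mapping, groups),
                       error = function(e) NULL)
      if (!is.null(tmpl)) {
        library <- update_library(library, tmpl,
                                  verified = isTRUE(lab$verified),
                                  iteration = it)$library
      }
      labeled <- tibble::add_row(labeled, id = rec$id, record = list(rec),
                                 mapping = list(lab$mapping))
    }
    # 3. train (augmented from iteration 2 on)
    if (it >= 2L && !is.null(fit)) {
      sets <- augment_training_set(pool, library, labeled,
                                   per_template = per_template,
                                   split_ratio = split_ratio,
                                   seed = it_seed + 2L)
    } else {
      sets <- list(train = labeled, validation = labeled[integer(0), ])
    }
    tc <- train_cfg
    tc$seed <- as.integer(it_seed + 3L)
    fit <- train_mapper(sets$train, net_cfg = net_cfg, train_cfg = tc,
                        validation = if (nrow(sets$validation) > 0L)
                          sets$validation else NULL,
                        feat_cfg = feat_cfg)
    # 4-5. predict pool + classify confidence
    pool <- classify_pool(fit, pool, library, groups)
    stats[[it]] <- tibble::tibble(
      iteration = it,
      n_labeled = nrow(labeled),
      verified_templates = sum(library$verified),
      coverage = mean(pool$confident)
    )
    if (verbose) {
      message(sprintf(
        "iteration %d: %d labeled, %d verified templates, coverage %.3f",
        it, nrow(labeled), sum(library$verified), mean(pool$confident)))
    }
  }
  structure(
    list(pool = pool, labeled = labeled, library = library, fit = fit,
         stats = dplyr::bind_rows(stats), seed = seed),
    class = "aam_loop"
  )
}

#' @export
print.aam_loop <- function(x, ...) {
  last <- x$stats[nrow(x$stats), ]
  cat(sprintf(
    "<aam_loop: %d iteration(s), %d labeled, %d verified templates, coverage %.3f>\n",
    last$iteration, last$n_labeled, last$verified_templates, last$coverage))
  invisible(x)
}

#' @rdname run_active_loop
#' @param x an `aam_loop`.
#' @param ... unused.
#' @export
tidy.aam_loop <- function(x, ...) x$stats

#' @rdname run_active_loop
#' @export
glance.aam_loop <- function(x, ...) {
  last <- x$stats[nrow(x$stats), ]
  tibble::tibble(
    iterations = last$iteration,
    n_labeled = last$n_labeled,
    verified_templates = last$verified_templates,
    coverage = last$coverage,
    pool_size = nrow(x$pool)
  )
}
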