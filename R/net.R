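# The atom-mapping network: MPNN encoder, reactant-product cross-attention,
# and the single-head attention classifier, with hand-written
# backpropagation on base-R matrices.
#
# Architecture.  Atom features are projected to the hidden dimension d and
# updated by `mpnn_layers` message-passing rounds: each directed edge
# (u -> v) builds a message relu(W_m [h_u ; e_uv] + b_m), messages are
# summed at the target atom and combined through relu(W_u [h_v ; m_v] + b_u)
# (isolated atoms pass through with a zero message).  Product atom features
# are then refined by `attention_blocks` cross-attention blocks over all
# reactant atoms: n heads with scores Q K^T / sqrt(d/n), concatenated, a
# gated residual update g = sigmoid(W_g [h ; o] + b_g), layer norm, then a
# two-layer feed-forward net with its own residual and layer norm
# (the gated transform and the feed-forward net carry distinct parameter
# sets).  Reactant features are not cross-attended; they enter the
# classifier straight from the MPNN.  The classifier is one more attention
# head whose scores (H_p W_q)(H_r W_k)^T / sqrt(d) are row-softmaxed into
# the mapping probability matrix P[u_p, u_r] = p(u_r | u_p).

#' Mapper network configuration
#'
#' @param hidden_dim hidden width `d` (must be divisible by `heads`).
#' @param mpnn_layers message-passing rounds (default 3).
#' @param attention_blocks cross-attention blocks (default 3).
#' @param heads attention heads per block (default 8).
#' @param dropout dropout rate, active only in training mode (default 0.1).
#' @param ffn_mult feed-forward inner width as a multiple of `hidden_dim`.
#' @return a `mapper_net_config` list.
#' @export
mapper_net_config <- function(hidden_dim = 320L, mpnn_layers = 3L,
                              attention_blocks = 3L, heads = 8L,
                              dropout = 0.1, ffn_mult = 2L) {
  stopifnot(hidden_dim %% heads == 0L, mpnn_layers >= 1L,
            attention_blocks >= 1L, dropout >= 0, dropout < 1)
  structure(
    list(hidden_dim = as.integer(hidden_dim),
         mpnn_layers = as.integer(mpnn_layers),
         attention_blocks = as.integer(attention_blocks),
         heads = as.integer(heads), dropout = dropout,
         ffn_mult = as.integer(ffn_mult)),
    class = "mapper_net_config"
  )
}

#' Training configuration
#'
#' Defaults follow the mapper's reference regimen: Adam, learning rate
#' 1e-3, weight decay 1e-6, batch size 16, 100 epochs, learning rate halved
#' when the validation loss fails to decrease after an epoch, gradients
#' clipped at global norm 20.
#'
#' @param epochs,batch_size,learning_rate,weight_decay,lr_decay_factor,patience,grad_clip_norm,seed
#'   scalars as described above; `seed` controls initialization, shuffling
#'   and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 100L, batch_size = 16L,
                         learning_rate = 1e-3, weight_decay = 1e-6,
                         lr_decay_factor = 0.5, patience = 1L,
                         grad_clip_norm = 20, seed = 1L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            weight_decay >= 0, lr_decay_factor > 0, lr_decay_factor < 1,
            grad_clip_norm > 0)
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, weight_decay = weight_decay,
         lr_decay_factor = lr_decay_factor, patience = as.integer(patience),
         grad_clip_norm = grad_clip_norm, seed = as.integer(seed)),
    class = "train_config"
  )
}

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

# initialize all trainable parameters (named list of matrices/vectors)
init_mapper_params <- function(net_cfg, feat_cfg, seed = 1L) {
  withr::local_seed(seed)
  d <- net_cfg$hidden_dim
  fa <- feat_cfg$atom_dim; fb <- feat_cfg$bond_dim
  fd <- d * net_cfg$ffn_mult
  p <- list(Win = glorot(fa, d), bin = numeric(d))
  for (t in seq_len(net_cfg$mpnn_layers)) {
    p[[paste0("Wm", t)]] <- glorot(d + fb, d)
    p[[paste0("bm", t)]] <- numeric(d)
    p[[paste0("Wu", t)]] <- glorot(2 * d, d)
    p[[paste0("bu", t)]] <- numeric(d)
  }
  for (b in seq_len(net_cfg$attention_blocks)) {
    p[[paste0("Wq", b)]] <- glorot(d, d)
    p[[paste0("Wk", b)]] <- glorot(d, d)
    p[[paste0("Wv", b)]] <- glorot(d, d)
    p[[paste0("Wg", b)]] <- glorot(2 * d, d)
    p[[paste0("bg", b)]] <- numeric(d)
    p[[paste0("Wf1", b)]] <- glorot(d, fd)
    p[[paste0("bf1", b)]] <- numeric(fd)
    p[[paste0("Wf2", b)]] <- glorot(fd, d)
    p[[paste0("bf2", b)]] <- numeric(d)
    p[[paste0("ga1", b)]] <- rep(1, d)
    p[[paste0("be1", b)]] <- numeric(d)
    p[[paste0("ga2", b)]] <- rep(1, d)
    p[[paste0("be2", b)]] <- numeric(d)
  }
  p$Wcq <- glorot(d, d)
  p$Wck <- glorot(d, d)
  p
}

relu <- function(x) pmax(x, 0)

# fast column-wise bias add / scale (vector recycled along rows)
addb <- function(X, b) X + rep(b, each = nrow(X))
mulb <- function(X, b) X * rep(b, each = nrow(X))

softmax_rows <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

# row-wise layer normalization
ln_forward <- function(X, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- mulb(xhat, gamma)
  Y <- addb(Y, beta)
  list(Y = Y, xhat = xhat, inv = inv, gamma = gamma)
}

ln_backward <- function(dY, cache) {
  d <- ncol(dY)
  dxhat <- mulb(dY, cache$gamma)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  rs <- rowSums(dxhat)
  rs2 <- rowSums(dxhat * cache$xhat)
  dX <- cache$inv * (dxhat - rs / d - cache$xhat * rs2 / d)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# sum messages into target atoms
aggregate_rows <- function(M, tgt, n_atoms_out) {
  out <- matrix(0, n_atoms_out, ncol(M))
  if (length(tgt) > 0L) {
    rs <- rowsum(M, group = tgt)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

# one MPNN layer; returns output and a cache for backprop
mpnn_layer_forward <- function(H, src, tgt, Eb, Wm, bm, Wu, bu) {
  n <- nrow(H)
  if (length(src) > 0L) {
    cat_in <- cbind(H[src, , drop = FALSE], Eb)
    pre_m <- addb(cat_in %*% Wm, bm)
    M <- relu(pre_m)
    agg <- aggregate_rows(M, tgt, n)
  } else {
    cat_in <- NULL; pre_m <- NULL; M <- NULL
    agg <- matrix(0, n, length(bm))
  }
  upd_in <- cbind(H, agg)
  pre_u <- addb(upd_in %*% Wu, bu)
  Hout <- relu(pre_u)
  list(H = Hout, cache = list(Hin = H, src = src, tgt = tgt, cat_in = cat_in,
                              pre_m = pre_m, M = M, agg = agg,
                              upd_in = upd_in, pre_u = pre_u))
}

mpnn_layer_backward <- function(dH, cache, Wm, Wu) {
  dpre_u <- dH * (cache$pre_u > 0)
  dWu <- crossprod(cache$upd_in, dpre_u)
  dbu <- colSums(dpre_u)
  dupd_in <- tcrossprod(dpre_u, Wu)
  d <- ncol(dH)
  dHin <- dupd_in[, seq_len(d), drop = FALSE]
  dagg <- dupd_in[, d + seq_len(d), drop = FALSE]
  if (length(cache$src) > 0L) {
    dM <- dagg[cache$tgt, , drop = FALSE]
    dpre_m <- dM * (cache$pre_m > 0)
    dWm <- crossprod(cache$cat_in, dpre_m)
    dbm <- colSums(dpre_m)
    dcat <- tcrossprod(dpre_m, Wm)
    dHsrc <- dcat[, seq_len(d), drop = FALSE]
    dHin <- dHin + aggregate_rows(dHsrc, cache$src, nrow(dHin))
  } else {
    dWm <- matrix(0, nrow(Wm), ncol(Wm)); dbm <- numeric(ncol(Wm))
  }
  list(dHin = dHin, dWm = dWm, dbm = dbm, dWu = dWu, dbu = dbu)
}

# encode one molecule side through input projection + MPNN stack
encode_side_forward <- function(params, fx, net_cfg) {
  pre0 <- addb(fx$X %*% params$Win, params$bin)
  H <- relu(pre0)
  layer_caches <- vector("list", net_cfg$mpnn_layers)
  for (t in seq_len(net_cfg$mpnn_layers)) {
    out <- mpnn_layer_forward(H, fx$src, fx$tgt, fx$Eb,
                              params[[paste0("Wm", t)]],
                              params[[paste0("bm", t)]],
                              params[[paste0("Wu", t)]],
                              params[[paste0("bu", t)]])
    H <- out$H
    layer_caches[[t]] <- out$cache
  }
  list(H = H, cache = list(X = fx$X, pre0 = pre0, layers = layer_caches))
}

encode_side_backward <- function(dH, cache, params, net_cfg, grads) {
  for (t in rev(seq_len(net_cfg$mpnn_layers))) {
    bk <- mpnn_layer_backward(dH, cache$layers[[t]],
                              params[[paste0("Wm", t)]],
                              params[[paste0("Wu", t)]])
    grads[[paste0("Wm", t)]] <- grads[[paste0("Wm", t)]] + bk$dWm
    grads[[paste0("bm", t)]] <- grads[[paste0("bm", t)]] + bk$dbm
    grads[[paste0("Wu", t)]] <- grads[[paste0("Wu", t)]] + bk$dWu
    grads[[paste0("bu", t)]] <- grads[[paste0("bu", t)]] + bk$dbu
    dH <- bk$dHin
  }
  dpre0 <- dH * (cache$pre0 > 0)
  grads$Win <- grads$Win + crossprod(cache$X, dpre0)
  grads$bin <- grads$bin + colSums(dpre0)
  grads
}

# multi-head cross attention of product atoms over reactant atoms
attention_head_forward <- function(Hp, Hr, Wq, Wk, Wv, scale) {
  Q <- Hp %*% Wq
  K <- Hr %*% Wk
  V <- Hr %*% Wv
  S <- tcrossprod(Q, K) / scale
  A <- softmax_rows(S)
  O <- A %*% V
  list(O = O, cache = list(Q = Q, K = K, V = V, A = A, scale = scale))
}

cross_block_forward <- function(params, b, Hp, Hr, net_cfg, training,
                                masks = NULL) {
  d <- net_cfg$hidden_dim
  nh <- net_cfg$heads
  dk <- d %/% nh
  scale <- sqrt(dk)
  Q <- Hp %*% params[[paste0("Wq", b)]]
  K <- Hr %*% params[[paste0("Wk", b)]]
  V <- Hr %*% params[[paste0("Wv", b)]]
  heads <- vector("list", nh)
  O <- matrix(0, nrow(Hp), d)
  for (h in seq_len(nh)) {
    cols <- (h - 1L) * dk + seq_len(dk)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / scale
    A <- softmax_rows(S)
    O[, cols] <- A %*% V[, cols, drop = FALSE]
    heads[[h]] <- list(A = A, cols = cols)
  }
  maskO <- if (training && net_cfg$dropout > 0) {
    if (is.null(masks)) {
      matrix((stats::runif(length(O)) >= net_cfg$dropout) /
               (1 - net_cfg$dropout), nrow(O), ncol(O))
    } else masks$O
  } else NULL
  Od <- if (is.null(maskO)) O else O * maskO
  gate_in <- cbind(Hp, Od)
  gpre <- sweep(gate_in %*% params[[paste0("Wg", b)]], 2L,
                params[[paste0("bg", b)]], `+`)
  G <- 1 / (1 + exp(-gpre))
  Zpre <- Hp + G * Od
  ln1 <- ln_forward(Zpre, params[[paste0("ga1", b)]],
                    params[[paste0("be1", b)]])
  Z <- ln1$Y
  f1pre <- sweep(Z %*% params[[paste0("Wf1", b)]], 2L,
                 params[[paste0("bf1", b)]], `+`)
  F1 <- relu(f1pre)
  F2 <- sweep(F1 %*% params[[paste0("Wf2", b)]], 2L,
              params[[paste0("bf2", b)]], `+`)
  maskF <- if (training && net_cfg$dropout > 0) {
    if (is.null(masks)) {
      matrix((stats::runif(length(F2)) >= net_cfg$dropout) /
               (1 - net_cfg$dropout), nrow(F2), ncol(F2))
    } else masks$F
  } else NULL
  F2d <- if (is.null(maskF)) F2 else F2 * maskF
  ln2 <- ln_forward(Z + F2d, params[[paste0("ga2", b)]],
                    params[[paste0("be2", b)]])
  list(H = ln2$Y,
       cache = list(Hp = Hp, Hr = Hr, Q = Q, K = K, V = V, heads = heads,
                    O = O, maskO = maskO, Od = Od, gate_in = gate_in,
                    G = G, ln1 = ln1, Z = Z, f1pre = f1pre, F1 = F1,
                    maskF = maskF, ln2 = ln2, scale = scale, dk = dk))
}

cross_block_backward <- function(dHout, cache, params, b, net_cfg, grads) {
  d <- net_cfg$hidden_dim
  bk2 <- ln_backward(dHout, cache$ln2)
  grads[[paste0("ga2", b)]] <- grads[[paste0("ga2", b)]] + bk2$dgamma
  grads[[paste0("be2", b)]] <- grads[[paste0("be2", b)]] + bk2$dbeta
  dZ <- bk2$dX
  dF2d <- bk2$dX
  dF2 <- if (is.null(cache$maskF)) dF2d else dF2d * cache$maskF
  grads[[paste0("Wf2", b)]] <- grads[[paste0("Wf2", b)]] +
    crossprod(cache$F1, dF2)
  grads[[paste0("bf2", b)]] <- grads[[paste0("bf2", b)]] + colSums(dF2)
  dF1 <- tcrossprod(dF2, params[[paste0("Wf2", b)]])
  df1pre <- dF1 * (cache$f1pre > 0)
  grads[[paste0("Wf1", b)]] <- grads[[paste0("Wf1", b)]] +
    crossprod(cache$Z, df1pre)
  grads[[paste0("bf1", b)]] <- grads[[paste0("bf1", b)]] + colSums(df1pre)
  dZ <- dZ + tcrossprod(df1pre, params[[paste0("Wf1", b)]])

  bk1 <- ln_backward(dZ, cache$ln1)
  grads[[paste0("ga1", b)]] <- grads[[paste0("ga1", b)]] + bk1$dgamma
  grads[[paste0("be1", b)]] <- grads[[paste0("be1", b)]] + bk1$dbeta
  dZpre <- bk1$dX
  dHp <- dZpre
  dG <- dZpre * cache$Od
  dOd <- dZpre * cache$G
  dgpre <- dG * cache$G * (1 - cache$G)
  grads[[paste0("Wg", b)]] <- grads[[paste0("Wg", b)]] +
    crossprod(cache$gate_in, dgpre)
  grads[[paste0("bg", b)]] <- grads[[paste0("bg", b)]] + colSums(dgpre)
  dgate_in <- tcrossprod(dgpre, params[[paste0("Wg", b)]])
  dHp <- dHp + dgate_in[, seq_len(d), drop = FALSE]
  dOd <- dOd + dgate_in[, d + seq_len(d), drop = FALSE]
  dO <- if (is.null(cache$maskO)) dOd else dOd * cache$maskO

  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dV <- matrix(0, nrow(cache$V), ncol(cache$V))
  for (h in seq_along(cache$heads)) {
    hd <- cache$heads[[h]]
    cols <- hd$cols
    A <- hd$A
    dOh <- dO[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dA <- tcrossprod(dOh, Vh)
    dV[, cols] <- dV[, cols, drop = FALSE] + crossprod(A, dOh)
    dS <- A * (dA - rowSums(dA * A))
    dQ[, cols] <- (dS %*% cache$K[, cols, drop = FALSE]) / cache$scale
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE]) / cache$scale
  }
  grads[[paste0("Wq", b)]] <- grads[[paste0("Wq", b)]] +
    crossprod(cache$Hp, dQ)
  grads[[paste0("Wk", b)]] <- grads[[paste0("Wk", b)]] +
    crossprod(cache$Hr, dK)
  grads[[paste0("Wv", b)]] <- grads[[paste0("Wv", b)]] +
    crossprod(cache$Hr, dV)
  dHp <- dHp + tcrossprod(dQ, params[[paste0("Wq", b)]])
  dHr <- tcrossprod(dK, params[[paste0("Wk", b)]]) +
    tcrossprod(dV, params[[paste0("Wv", b)]])
  list(dHp = dHp, dHr = dHr, grads = grads)
}

#' Forward pass of the mapper network
#'
#' @param params parameter list from `init_mapper_params()` or a fit.
#' @param fx featurized reaction from [featurize_reaction()].
#' @param net_cfg a [mapper_net_config()].
#' @param training enable dropout (draws from the R RNG).
#' @return list with `P` (the mapping probability matrix, rows = product
#'   atoms softmax-normalized over reactant atoms) and `cache` for
#'   backpropagation.
#' @keywords internal
mapper_forward <- function(params, fx, net_cfg, training = FALSE) {
  if (nrow(fx$reactant$X) == 0L) stop("empty reactant set", call. = FALSE)
  encR <- encode_side_forward(params, fx$reactant, net_cfg)
  encP <- encode_side_forward(params, fx$product, net_cfg)
  Hp <- encP$H
  blocks <- vector("list", net_cfg$attention_blocks)
  for (b in seq_len(net_cfg$attention_blocks)) {
    out <- cross_block_forward(params, b, Hp, encR$H, net_cfg, training)
    Hp <- out$H
    blocks[[b]] <- out$cache
  }
  d <- net_cfg$hidden_dim
  Qc <- Hp %*% params$Wcq
  Kc <- encR$H %*% params$Wck
  S <- tcrossprod(Qc, Kc) / sqrt(d)
  P <- softmax_rows(S)
  list(P = P,
       cache = list(encR = encR, encP = encP, blocks = blocks,
                    Hp_final = Hp, Qc = Qc, Kc = Kc, P = P, d = d))
}

# cross-entropy loss over gold pairs and full parameter gradients
mapper_loss_grads <- function(params, fx, gold, net_cfg, training = TRUE) {
  fw <- mapper_forward(params, fx, net_cfg, training = training)
  P <- fw$P
  idx <- cbind(gold$product, gold$reactant)
  eps <- 1e-12
  loss <- -mean(log(P[idx] + eps))

  grads <- lapply(params, function(x) {
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
  })
  n_pairs <- nrow(gold)
  dS <- P / n_pairs
  dS[idx] <- dS[idx] - 1 / n_pairs
  # rows without a gold pair contribute nothing
  has_gold <- seq_len(nrow(P)) %in% gold$product
  if (!all(has_gold)) dS[!has_gold, ] <- 0

  cache <- fw$cache
  sc <- sqrt(cache$d)
  dQc <- (dS %*% cache$Kc) / sc
  dKc <- crossprod(dS, cache$Qc) / sc
  grads$Wcq <- grads$Wcq + crossprod(cache$Hp_final, dQc)
  grads$Wck <- grads$Wck + crossprod(cache$encR$H, dKc)
  dHp <- tcrossprod(dQc, params$Wcq)
  dHr <- tcrossprod(dKc, params$Wck)

  for (b in rev(seq_len(net_cfg$attention_blocks))) {
    bk <- cross_block_backward(dHp, cache$blocks[[b]], params, b, net_cfg,
                               grads)
    grads <- bk$grads
    dHp <- bk$dHp
    dHr <- dHr + bk$dHr
  }
  grads <- encode_side_backward(dHp, cache$encP$cache, params, net_cfg, grads)
  grads <- encode_side_backward(dHr, cache$encR$cache, params, net_cfg, grads)
  list(loss = loss, grads = grads, P = P)
}
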