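# Conditional (and unconditional) encoder-decoder transformer over SMILES
# token sequences.
#
# The architecture is the original post-norm transformer: learned token
# embeddings scaled by sqrt(d) plus sinusoidal positions, multi-head
# self/cross attention, position-wise feed-forward blocks with rectifier
# activation, residual connections and layer normalization. Conditioning is
# a single reaction-template token prefixed to the encoder input only; the
# decoder never sees it. Forward and backward passes are hand-written
# (R/nn.R) and finite-difference-checked in the tests.

#' Transformer hyperparameter set
#'
#' The `"toy"` preset is the package default used with the bundled reaction
#' grammar; `"full"` mirrors the original-architecture values used at
#' patent-corpus scale (model dimension 512, 6+6 layers, 8 heads,
#' feed-forward 2048, dropout 0.1, batch 128).
#'
#' @param preset `"toy"` or `"full"`.
#' @param d_model Model dimension (must be divisible by `n_heads`).
#' @param n_enc,n_dec Encoder/decoder layer counts.
#' @param n_heads Attention heads.
#' @param d_ff Feed-forward width.
#' @param dropout Dropout probability.
#' @param batch_size Training batch size.
#' @param lr Adam learning rate.
#' @param lr_halflife Halve the learning rate every this many epochs
#'   (simple step decay; `Inf` keeps it constant).
#' @param epochs Maximum training epochs.
#' @param target_accuracy Stop early once validation perfect accuracy
#'   reaches this value.
#' @param val_fraction Fraction of pairs held out for the curves when no
#'   validation set is supplied.
#' @return A list of class `transformer_config`.
#' @export
transformer_config <- function(preset = c("toy", "full"),
                               d_model = NULL, n_enc = NULL, n_dec = NULL,
                               n_heads = NULL, d_ff = NULL, dropout = NULL,
                               batch_size = NULL, lr = 2e-3,
                               lr_halflife = 80, epochs = 60,
                               target_accuracy = 0.97, val_fraction = 0.1) {
  preset <- match.arg(preset)
  def <- if (preset == "full") {
    list(d_model = 512, n_enc = 6, n_dec = 6, n_heads = 8, d_ff = 2048,
         dropout = 0.1, batch_size = 128)
  } else {
    list(d_model = 64, n_enc = 1, n_dec = 1, n_heads = 4, d_ff = 128,
         dropout = 0.1, batch_size = 16)
  }
  cfg <- list(
    d_model = d_model %||% def$d_model,
    n_enc = n_enc %||% def$n_enc, n_dec = n_dec %||% def$n_dec,
    n_heads = n_heads %||% def$n_heads, d_ff = d_ff %||% def$d_ff,
    dropout = dropout %||% def$dropout,
    batch_size = batch_size %||% def$batch_size,
    lr = lr, lr_halflife = lr_halflife, epochs = epochs,
    target_accuracy = target_accuracy, val_fraction = val_fraction)
  stopifnot(cfg$d_model %% cfg$n_heads == 0)
  structure(cfg, class = "transformer_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- parameter initialization ----------------------------------------------

t_init_params <- function(cfg, vocab_size) {
  d <- cfg$d_model
  p <- list(emb = xavier_init(vocab_size, d),
            out_W = xavier_init(d, vocab_size),
            out_b = rep(0, vocab_size))
  attn <- function(prefix) {
    out <- list()
    for (w in c("Wq", "Wk", "Wv", "Wo")) {
      out[[paste0(prefix, "_", w)]] <- xavier_init(d, d)
    }
    out
  }
  block <- function(prefix, n_ln) {
    out <- list()
    out[[paste0(prefix, "_ff_W1")]] <- xavier_init(d, cfg$d_ff)
    out[[paste0(prefix, "_ff_b1")]] <- rep(0, cfg$d_ff)
    out[[paste0(prefix, "_ff_W2")]] <- xavier_init(cfg$d_ff, d)
    out[[paste0(prefix, "_ff_b2")]] <- rep(0, d)
    for (j in seq_len(n_ln)) {
      out[[paste0(prefix, "_ln", j, "_g")]] <- rep(1, d)
      out[[paste0(prefix, "_ln", j, "_b")]] <- rep(0, d)
    }
    out
  }
  for (i in seq_len(cfg$n_enc)) {
    p <- c(p, attn(paste0("enc", i, "_attn")), block(paste0("enc", i), 2))
  }
  for (i in seq_len(cfg$n_dec)) {
    p <- c(p, attn(paste0("dec", i, "_sa")), attn(paste0("dec", i, "_ca")),
           block(paste0("dec", i), 3))
  }
  p
}

# --- forward / backward -----------------------------------------------------

# inverted-dropout mask; NULL when not training or p = 0
make_drop <- function(n, d, p) {
  if (p <= 0) return(NULL)
  matrix(stats::rbinom(n * d, 1, 1 - p), n, d) / (1 - p)
}

drop_apply <- function(x, mask) {
  if (is.null(mask)) x else x * mask
}

# ids: B x L matrix -> (B*L) x d embedding + positions, b-major rows
t_embed <- function(p, cfg, ids, pe, pdrop = 0) {
  idx <- as.vector(t(ids))
  L <- ncol(ids)
  X <- p$emb[idx, , drop = FALSE] * sqrt(cfg$d_model) +
    pe[rep(seq_len(L), times = nrow(ids)), , drop = FALSE]
  mask <- make_drop(nrow(X), ncol(X), pdrop)
  list(X = drop_apply(X, mask), idx = idx, mask = mask)
}

t_encode <- function(p, cfg, src, smask, pe, pdrop = 0) {
  B <- nrow(src)
  Ls <- ncol(src)
  emb <- t_embed(p, cfg, src, pe, pdrop)
  X <- emb$X
  layers <- vector("list", cfg$n_enc)
  for (i in seq_len(cfg$n_enc)) {
    pre <- paste0("enc", i)
    at <- mha_fwd(X, X, p[[paste0(pre, "_attn_Wq")]],
                  p[[paste0(pre, "_attn_Wk")]], p[[paste0(pre, "_attn_Wv")]],
                  p[[paste0(pre, "_attn_Wo")]], cfg$n_heads, B, Ls, Ls, smask)
    m1 <- make_drop(nrow(X), ncol(X), pdrop)
    l1 <- layernorm_fwd(X + drop_apply(at$out, m1),
                        p[[paste0(pre, "_ln1_g")]],
                        p[[paste0(pre, "_ln1_b")]])
    ff <- ffn_fwd(l1$y, p[[paste0(pre, "_ff_W1")]], p[[paste0(pre, "_ff_b1")]],
                  p[[paste0(pre, "_ff_W2")]], p[[paste0(pre, "_ff_b2")]])
    m2 <- make_drop(nrow(X), ncol(X), pdrop)
    l2 <- layernorm_fwd(l1$y + drop_apply(ff$y, m2),
                        p[[paste0(pre, "_ln2_g")]],
                        p[[paste0(pre, "_ln2_b")]])
    layers[[i]] <- list(at = at, l1 = l1, ff = ff, l2 = l2, m1 = m1, m2 = m2)
    X <- l2$y
  }
  list(M = X, layers = layers, emb = emb, B = B, Ls = Ls)
}

t_decode_stack <- function(p, cfg, tgt_in, tmask, enc, smask, pe, pdrop = 0) {
  B <- nrow(tgt_in)
  Lt <- ncol(tgt_in)
  emb <- t_embed(p, cfg, tgt_in, pe, pdrop)
  X <- emb$X
  layers <- vector("list", cfg$n_dec)
  for (i in seq_len(cfg$n_dec)) {
    pre <- paste0("dec", i)
    sa <- mha_fwd(X, X, p[[paste0(pre, "_sa_Wq")]], p[[paste0(pre, "_sa_Wk")]],
                  p[[paste0(pre, "_sa_Wv")]], p[[paste0(pre, "_sa_Wo")]],
                  cfg$n_heads, B, Lt, Lt, tmask, causal = TRUE)
    m1 <- make_drop(nrow(X), ncol(X), pdrop)
    l1 <- layernorm_fwd(X + drop_apply(sa$out, m1),
                        p[[paste0(pre, "_ln1_g")]],
                        p[[paste0(pre, "_ln1_b")]])
    ca <- mha_fwd(l1$y, enc$M, p[[paste0(pre, "_ca_Wq")]],
                  p[[paste0(pre, "_ca_Wk")]], p[[paste0(pre, "_ca_Wv")]],
                  p[[paste0(pre, "_ca_Wo")]], cfg$n_heads, B, Lt, enc$Ls,
                  smask)
    m2 <- make_drop(nrow(X), ncol(X), pdrop)
    l2 <- layernorm_fwd(l1$y + drop_apply(ca$out, m2),
                        p[[paste0(pre, "_ln2_g")]],
                        p[[paste0(pre, "_ln2_b")]])
    ff <- ffn_fwd(l2$y, p[[paste0(pre, "_ff_W1")]], p[[paste0(pre, "_ff_b1")]],
                  p[[paste0(pre, "_ff_W2")]], p[[paste0(pre, "_ff_b2")]])
    m3 <- make_drop(nrow(X), ncol(X), pdrop)
    l3 <- layernorm_fwd(l2$y + drop_apply(ff$y, m3),
                        p[[paste0(pre, "_ln3_g")]],
                        p[[paste0(pre, "_ln3_b")]])
    layers[[i]] <- list(sa = sa, l1 = l1, ca = ca, l2 = l2, ff = ff, l3 = l3,
                        m1 = m1, m2 = m2, m3 = m3)
    X <- l3$y
  }
  logits <- X %*% p$out_W + rep(p$out_b, each = nrow(X))
  list(logits = logits, layers = layers, emb = emb, X_last = X,
       B = B, Lt = Lt)
}

t_forward <- function(p, cfg, src, smask, tgt_in, tmask, pe, pdrop = 0) {
  enc <- t_encode(p, cfg, src, smask, pe, pdrop)
  dec <- t_decode_stack(p, cfg, tgt_in, tmask, enc, smask, pe, pdrop)
  list(enc = enc, dec = dec)
}

# cross-entropy over non-pad target positions; tgt_out as (B*Lt) vector
t_loss <- function(logits, tgt_out_vec, weight_vec) {
  P <- softmax_rows(logits)
  n <- sum(weight_vec)
  picked <- P[cbind(seq_along(tgt_out_vec), tgt_out_vec)]
  loss <- -sum(log(pmax(picked, 1e-12)) * weight_vec) / n
  dlogits <- P
  dlogits[cbind(seq_along(tgt_out_vec), tgt_out_vec)] <-
    picked - 1
  dlogits <- dlogits * (weight_vec / n)
  list(loss = loss, dlogits = dlogits, probs = P)
}

t_backward <- function(p, cfg, fw, dlogits, vocab_size) {
  grads <- list()
  dec <- fw$dec
  enc <- fw$enc
  # output projection
  grads <- acc_grad(grads, "out_W", crossprod(dec$X_last, dlogits))
  grads <- acc_grad(grads, "out_b", colSums(dlogits))
  dX <- dlogits %*% t(p$out_W)
  dM <- matrix(0, nrow(enc$M), cfg$d_model)
  for (i in rev(seq_len(cfg$n_dec))) {
    pre <- paste0("dec", i)
    ly <- dec$layers[[i]]
    b3 <- layernorm_bwd(dX, ly$l3$cache)
    grads <- acc_grad(grads, paste0(pre, "_ln3_g"), b3$dg)
    grads <- acc_grad(grads, paste0(pre, "_ln3_b"), b3$db)
    bf <- ffn_bwd(drop_apply(b3$dx, ly$m3), ly$ff$cache)
    for (nm in c("W1", "b1", "W2", "b2")) {
      grads <- acc_grad(grads, paste0(pre, "_ff_", nm), bf[[paste0("d", nm)]])
    }
    dX <- b3$dx + bf$dx
    b2 <- layernorm_bwd(dX, ly$l2$cache)
    grads <- acc_grad(grads, paste0(pre, "_ln2_g"), b2$dg)
    grads <- acc_grad(grads, paste0(pre, "_ln2_b"), b2$db)
    bc <- mha_bwd(drop_apply(b2$dx, ly$m2), ly$ca$cache)
    for (nm in c("Wq", "Wk", "Wv", "Wo")) {
      grads <- acc_grad(grads, paste0(pre, "_ca_", nm), bc[[paste0("d", nm)]])
    }
    dM <- dM + bc$dXkv
    dX <- b2$dx + bc$dXq
    b1 <- layernorm_bwd(dX, ly$l1$cache)
    grads <- acc_grad(grads, paste0(pre, "_ln1_g"), b1$dg)
    grads <- acc_grad(grads, paste0(pre, "_ln1_b"), b1$db)
    bs <- mha_bwd(drop_apply(b1$dx, ly$m1), ly$sa$cache)
    for (nm in c("Wq", "Wk", "Wv", "Wo")) {
      grads <- acc_grad(grads, paste0(pre, "_sa_", nm), bs[[paste0("d", nm)]])
    }
    dX <- b1$dx + bs$dXq + bs$dXkv
  }
  demb <- matrix(0, vocab_size, cfg$d_model)
  part <- rowsum(drop_apply(dX, dec$emb$mask) * sqrt(cfg$d_model),
                 group = dec$emb$idx)
  iu <- as.integer(rownames(part))
  demb[iu, ] <- demb[iu, ] + part
  # encoder stack
  dX <- dM
  for (i in rev(seq_len(cfg$n_enc))) {
    pre <- paste0("enc", i)
    ly <- enc$layers[[i]]
    b2 <- layernorm_bwd(dX, ly$l2$cache)
    grads <- acc_grad(grads, paste0(pre, "_ln2_g"), b2$dg)
    grads <- acc_grad(grads, paste0(pre, "_ln2_b"), b2$db)
    bf <- ffn_bwd(drop_apply(b2$dx, ly$m2), ly$ff$cache)
    for (nm in c("W1", "b1", "W2", "b2")) {
      grads <- acc_grad(grads, paste0(pre, "_ff_", nm), bf[[paste0("d", nm)]])
    }
    dX <- b2$dx + bf$dx
    b1 <- layernorm_bwd(dX, ly$l1$cache)
    grads <- acc_grad(grads, paste0(pre, "_ln1_g"), b1$dg)
    grads <- acc_grad(grads, paste0(pre, "_ln1_b"), b1$db)
    ba <- mha_bwd(drop_apply(b1$dx, ly$m1), ly$at$cache)
    for (nm in c("Wq", "Wk", "Wv", "Wo")) {
      grads <- acc_grad(grads, paste0(pre, "_attn_", nm),
                        ba[[paste0("d", nm)]])
    }
    dX <- b1$dx + ba$dXq + ba$dXkv
  }
  part <- rowsum(drop_apply(dX, enc$emb$mask) * sqrt(cfg$d_model),
                 group = enc$emb$idx)
  iu <- as.integer(rownames(part))
  demb[iu, ] <- demb[iu, ] + part
  grads <- acc_grad(grads, "emb", demb)
  grads
}

# --- batching ---------------------------------------------------------------

pad_ids <- function(id_list, pad, L = NULL) {
  L <- L %||% max(lengths(id_list))
  out <- matrix(pad, length(id_list), L)
  for (i in seq_along(id_list)) {
    out[i, seq_along(id_list[[i]])] <- id_list[[i]]
  }
  out
}

# encode a pairs tibble into id lists; strips condition tokens if requested
encode_pairs <- function(pairs, vocab, conditioned) {
  src <- lapply(pairs$source, function(tk) {
    if (!conditioned && grepl("^<t_", tk[1])) tk <- tk[-1]
    encode_tokens(vocab, tk, strict = TRUE)
  })
  tgt <- lapply(pairs$target, encode_tokens, vocab = vocab, strict = TRUE)
  list(src = src, tgt = tgt)
}

make_batches <- function(enc, vocab, batch_size) {
  ord <- order(lengths(enc$tgt), lengths(enc$src))
  idx_chunks <- split(ord, ceiling(seq_along(ord) / batch_size))
  lapply(idx_chunks, function(ix) {
    src <- pad_ids(enc$src[ix], vocab$pad)
    tin <- pad_ids(lapply(enc$tgt[ix], function(t) c(vocab$bos, t)), vocab$pad)
    tout <- pad_ids(lapply(enc$tgt[ix], function(t) c(t, vocab$eos)),
                    vocab$pad)
    list(src = src, smask = src != vocab$pad,
         tgt_in = tin, tmask = tin != vocab$pad,
         tgt_out = tout, wt = as.numeric(t(tout) != vocab$pad),
         tgt_out_vec = as.vector(t(tout)))
  })
}

# --- training ---------------------------------------------------------------

#' Train the sequence-to-sequence product predictor
#'
#' Teacher-forced cross-entropy training with Adam; per-epoch partial
#' accuracy (per token) and perfect accuracy (per molecule, greedy decode,
#' canonicalized comparison) are recorded on held-out pairs, mirroring how
#' conditional and unconditional twins are compared.
#'
#' @param pairs Tibble with list-columns `source`, `target` (token vectors,
#'   sources carrying condition tokens as built by [prepare_reactions()]).
#' @param vocab An `rxn_vocab` covering every token.
#' @param cfg A [transformer_config()].
#' @param conditioned Keep the condition prefix? When `FALSE` the prefix is
#'   stripped, giving the unconditional twin of the same data.
#' @param seed Integer seed controlling initialization and shuffling.
#' @param val_pairs Optional validation tibble; defaults to an internal
#'   split of `cfg$val_fraction`.
#' @param quiet Suppress per-epoch messages?
#' @return An object of class `seq2seq_transformer` with elements `params`,
#'   `cfg`, `vocab`, `curves` (tibble: epoch, loss, partial, perfect).
#' @export
train_seq2seq <- function(pairs, vocab, cfg = transformer_config(),
                          conditioned = TRUE, seed = 1L, val_pairs = NULL,
                          quiet = FALSE) {
  stopifnot(nrow(pairs) > 0)
  if (is.null(val_pairs)) {
    sp <- split_dataset(pairs, c(train = 1 - cfg$val_fraction,
                                 val = cfg$val_fraction), seed = seed)
    pairs <- sp$train
    val_pairs <- sp$val
  }
  enc <- encode_pairs(pairs, vocab, conditioned)  # errors on unknown tokens
  venc <- encode_pairs(val_pairs, vocab, conditioned)
  V <- length(vocab$symbols)
  max_tgt <- max(lengths(enc$tgt))
  max_len <- max(lengths(enc$src), max_tgt) + 2L
  pe <- positional_encoding(ceiling(1.5 * max_len) + 8L, cfg$d_model)
  params <- withr::with_seed(seed, t_init_params(cfg, V))
  state <- adam_init(params)
  curves <- list()
  model <- NULL
  withr::with_seed(seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(length(enc$src))
      enc_sh <- list(src = enc$src[ord], tgt = enc$tgt[ord])
      batches <- make_batches(enc_sh, vocab, cfg$batch_size)
      tot_loss <- 0
      for (ba in batches) {
        fw <- t_forward(params, cfg, ba$src, ba$smask, ba$tgt_in, ba$tmask,
                        pe, pdrop = cfg$dropout)
        ls <- t_loss(fw$dec$logits, ba$tgt_out_vec, ba$wt)
        grads <- t_backward(params, cfg, fw, ls$dlogits, V)
        up <- adam_step(params, grads, state,
                        lr = cfg$lr * 0.5^((epoch - 1) %/% cfg$lr_halflife))
        params <- up$params
        state <- up$state
        tot_loss <- tot_loss + ls$loss * sum(ba$wt)
      }
      model <- structure(
        list(params = params, cfg = cfg, vocab = vocab,
             conditioned = conditioned, pe = pe,
             max_decode = ceiling(1.5 * max_tgt) + 8L,
             cache = new.env(parent = emptyenv())),
        class = "seq2seq_transformer")
      pa <- partial_accuracy_ids(model, venc)
      # greedy decoding dominates validation cost: refresh the molecule-level
      # curve only periodically once tokens mostly match, or at the end
      if ((pa >= 0.93 && epoch %% 2 == 0) || epoch == cfg$epochs) {
        nval <- length(venc$src)
        sub <- if (nval > 48) sort(sample(nval, 48)) else seq_len(nval)
        pf <- perfect_accuracy_ids(model, list(src = venc$src[sub],
                                               tgt = venc$tgt[sub]))
      } else {
        pf <- if (epoch > 1) curves[[epoch - 1]]$perfect else 0
      }
      curves[[epoch]] <- tibble::tibble(
        epoch = epoch,
        loss = tot_loss / sum(vapply(batches, function(b) sum(b$wt), 0)),
        partial = pa, perfect = pf)
      if (!quiet) {
        message(sprintf("epoch %3d  loss %.4f  partial %.3f  perfect %.3f",
                        epoch, curves[[epoch]]$loss, pa, pf))
      }
      if (pf >= cfg$target_accuracy) break
    }
  })
  model$curves <- dplyr::bind_rows(curves)
  model$val_pairs <- val_pairs
  model
}

#' @export
print.seq2seq_transformer <- function(x, ...) {
  last <- utils::tail(x$curves, 1)
  cat(sprintf(
    "<seq2seq_transformer> %s, d=%d, %d+%d layers; final val partial %.3f perfect %.3f\n",
    if (x$conditioned) "conditional" else "unconditional",
    x$cfg$d_model, x$cfg$n_enc, x$cfg$n_dec, last$partial, last$perfect))
  invisible(x)
}

# --- accuracy metrics -------------------------------------------------------

partial_accuracy_ids <- function(model, enc) {
  vocab <- model$vocab
  batches <- make_batches(enc, vocab, model$cfg$batch_size)
  hits <- 0
  n <- 0
  for (ba in batches) {
    fw <- t_forward(model$params, model$cfg, ba$src, ba$smask,
                    ba$tgt_in, ba$tmask, model$pe)
    pred <- max.col(fw$dec$logits, ties.method = "first")
    w <- ba$wt > 0
    hits <- hits + sum(pred[w] == ba$tgt_out_vec[w])
    n <- n + sum(w)
  }
  hits / n
}

#' Token-level (partial) accuracy under teacher forcing
#'
#' Fraction of non-padding target positions whose argmax prediction equals
#' the target token.
#'
#' @param model A `seq2seq_transformer`.
#' @param pairs Tibble with `source`/`target` token list-columns.
#' @return Fraction in `[0, 1]`.
#' @export
partial_accuracy <- function(model, pairs) {
  if (nrow(pairs) == 0) stop("no pairs supplied")
  partial_accuracy_ids(
    model, encode_pairs(pairs, model$vocab, model$conditioned))
}

perfect_accuracy_ids <- function(model, enc) {
  tgt_smiles <- vapply(enc$tgt, function(ids) {
    detokenize(decode_ids(model$vocab, ids))
  }, character(1))
  # batch in chunks so padding stays close to each group's length
  ord <- order(lengths(enc$src))
  pred <- character(length(enc$src))
  for (chunk in split(ord, ceiling(seq_along(ord) / 64))) {
    outs <- greedy_decode_batch(model, enc$src[chunk])
    pred[chunk] <- vapply(outs, function(ids) {
      detokenize(decode_ids(model$vocab, ids))
    }, character(1))
  }
  mean(!is.na(canonical_smiles(pred)) &
         canonical_smiles(pred) == canonical_smiles(tgt_smiles))
}

#' Molecule-level (perfect) accuracy
#'
#' Fraction of pairs whose greedy decode, canonicalized, equals the
#' canonical target product.
#'
#' @inheritParams partial_accuracy
#' @return Fraction in `[0, 1]`.
#' @export
perfect_accuracy <- function(model, pairs) {
  if (nrow(pairs) == 0) stop("no pairs supplied")
  perfect_accuracy_ids(
    model, encode_pairs(pairs, model$vocab, model$conditioned))
}

# --- decoding ---------------------------------------------------------------

# --- incremental decoding -------------------------------------------------
# One decoder step per emitted token with cached keys/values: cross-attention
# K/V are projected once per decode; self-attention K/V grow by one row per
# hypothesis per step. Hypothesis state is kept per beam so pruning and
# reordering are list operations. The stacked reference implementation
# (beam_search_ids_ref) recomputes the full decoder each step; tests assert
# both paths emit identical hypotheses.

dec_init_state <- function(model, src_ids) {
  p <- model$params
  cfg <- model$cfg
  vocab <- model$vocab
  src <- matrix(src_ids, 1)
  smask_vec <- src_ids != vocab$pad
  enc <- t_encode(p, cfg, src, matrix(smask_vec, 1), model$pe)
  ca <- vector("list", cfg$n_dec)
  for (i in seq_len(cfg$n_dec)) {
    pre <- paste0("dec", i)
    ca[[i]] <- list(K = enc$M %*% p[[paste0(pre, "_ca_Wk")]],
                    V = enc$M %*% p[[paste0(pre, "_ca_Wv")]])
  }
  list(ca = ca, smask = smask_vec, Ls = enc$Ls)
}

# state per hypothesis: list of per-layer K/V matrices (t x d)
new_hyp_state <- function(cfg) {
  lapply(seq_len(cfg$n_dec), function(i) list(K = NULL, V = NULL))
}

# advance a set of hypotheses one token; ids_new: integer vector (one per
# hypothesis); states: list of hypothesis states; pos: current position
dec_step <- function(model, shared, states, ids_new, pos) {
  p <- model$params
  cfg <- model$cfg
  d <- cfg$d_model
  h <- cfg$n_heads
  dk <- d / h
  B <- length(ids_new)
  x <- p$emb[ids_new, , drop = FALSE] * sqrt(d) +
    matrix(model$pe[pos, ], B, d, byrow = TRUE)
  maskcol <- which(!shared$smask)
  for (i in seq_len(cfg$n_dec)) {
    pre <- paste0("dec", i)
    q <- x %*% p[[paste0(pre, "_sa_Wq")]]
    k_new <- x %*% p[[paste0(pre, "_sa_Wk")]]
    v_new <- x %*% p[[paste0(pre, "_sa_Wv")]]
    o <- matrix(0, B, d)
    for (b in seq_len(B)) {
      states[[b]][[i]]$K <- rbind(states[[b]][[i]]$K, k_new[b, ])
      states[[b]][[i]]$V <- rbind(states[[b]][[i]]$V, v_new[b, ])
      K <- states[[b]][[i]]$K
      V <- states[[b]][[i]]$V
      for (hh in seq_len(h)) {
        cols <- (hh - 1L) * dk + seq_len(dk)
        s <- drop(K[, cols, drop = FALSE] %*% q[b, cols]) / sqrt(dk)
        w <- exp(s - max(s))
        w <- w / sum(w)
        o[b, cols] <- drop(crossprod(V[, cols, drop = FALSE], w))
      }
    }
    sa_out <- o %*% p[[paste0(pre, "_sa_Wo")]]
    l1 <- layernorm_fwd(x + sa_out, p[[paste0(pre, "_ln1_g")]],
                        p[[paste0(pre, "_ln1_b")]])$y
    qc <- l1 %*% p[[paste0(pre, "_ca_Wq")]]
    Kc <- shared$ca[[i]]$K
    Vc <- shared$ca[[i]]$V
    oc <- matrix(0, B, d)
    for (hh in seq_len(h)) {
      cols <- (hh - 1L) * dk + seq_len(dk)
      s <- qc[, cols, drop = FALSE] %*% t(Kc[, cols, drop = FALSE]) / sqrt(dk)
      if (length(maskcol)) s[, maskcol] <- -Inf
      P <- softmax_rows(s)
      oc[, cols] <- P %*% Vc[, cols, drop = FALSE]
    }
    ca_out <- oc %*% p[[paste0(pre, "_ca_Wo")]]
    l2 <- layernorm_fwd(l1 + ca_out, p[[paste0(pre, "_ln2_g")]],
                        p[[paste0(pre, "_ln2_b")]])$y
    ff <- ffn_fwd(l2, p[[paste0(pre, "_ff_W1")]], p[[paste0(pre, "_ff_b1")]],
                  p[[paste0(pre, "_ff_W2")]], p[[paste0(pre, "_ff_b2")]])$y
    x <- layernorm_fwd(l2 + ff, p[[paste0(pre, "_ln3_g")]],
                       p[[paste0(pre, "_ln3_b")]])$y
  }
  list(logits = x %*% p$out_W + rep(p$out_b, each = B), states = states)
}

# beam search over id sequences with incremental decoding; returns finished
# hypotheses ranked by length-normalized log-probability
beam_search_ids <- function(model, src_ids, width) {
  stopifnot(width >= 1)
  vocab <- model$vocab
  cfg <- model$cfg
  shared <- dec_init_state(model, src_ids)
  beams <- list(list(ids = vocab$bos, lp = 0,
                     state = new_hyp_state(cfg)))
  done <- list()
  full_for <- 0L
  for (step in seq_len(model$max_decode)) {
    B <- length(beams)
    st <- dec_step(model, shared,
                   lapply(beams, `[[`, "state"),
                   vapply(beams, function(b) utils::tail(b$ids, 1), 0L),
                   step)
    cand <- list()
    for (b in seq_len(B)) {
      lg <- st$logits[b, ]
      lp <- lg - max(lg) - log(sum(exp(lg - max(lg))))
      top <- order(lp, decreasing = TRUE)[seq_len(min(width, length(lp)))]
      for (tk in top) {
        cand[[length(cand) + 1L]] <-
          list(ids = c(beams[[b]]$ids, tk), lp = beams[[b]]$lp + lp[tk],
               state = st$states[[b]])
      }
    }
    scores <- vapply(cand, function(c) c$lp / (length(c$ids) - 1), 0)
    top <- cand[utils::head(order(scores, decreasing = TRUE), width)]
    beams <- list()
    for (c in top) {
      if (utils::tail(c$ids, 1) == vocab$eos) {
        done[[length(done) + 1L]] <- c
      } else {
        beams[[length(beams) + 1L]] <- c
      }
    }
    full_for <- if (length(done) >= width) full_for + 1L else 0L
    if (beam_stop(beams, done, width, full_for)) break
  }
  if (length(done) == 0) done <- beams  # length cap hit: emit unfinished
  norm <- vapply(done, function(c) c$lp / (length(c$ids) - 1), 0)
  done <- done[utils::head(order(norm, decreasing = TRUE), width)]
  lapply(done, function(c) {
    ids <- c$ids[-1]
    ids <- ids[ids != vocab$eos]
    list(ids = ids, score = c$lp / max(length(c$ids) - 1, 1))
  })
}

# stop once enough hypotheses are finished and no active one can still beat
# the retained finished set: future tokens have log-probability <= 0, so an
# active hypothesis of cumulative lp and length n ends with mean at best
# lp / n (one more token, the end marker)
beam_stop <- function(beams, done, width, full_for = 0L) {
  if (length(beams) == 0) return(TRUE)
  if (length(done) < width) return(FALSE)
  if (full_for >= 8L) return(TRUE)  # patience once the finished set is full
  dnorm <- sort(vapply(done, function(c) c$lp / (length(c$ids) - 1), 0),
                decreasing = TRUE)
  bound <- max(vapply(beams, function(c) c$lp / length(c$ids), 0))
  bound <= dnorm[width]
}

# stacked (non-incremental) reference used by the equality tests
beam_search_ids_ref <- function(model, src_ids, width) {
  stopifnot(width >= 1)
  vocab <- model$vocab
  cfg <- model$cfg
  src <- matrix(src_ids, 1)
  enc <- t_encode(model$params, cfg, src, src != vocab$pad, model$pe)
  beams <- list(list(ids = vocab$bos, lp = 0))
  done <- list()
  full_for <- 0L
  for (step in seq_len(model$max_decode)) {
    B <- length(beams)
    Lt <- max(vapply(beams, function(b) length(b$ids), 0L))
    tin <- pad_ids(lapply(beams, `[[`, "ids"), vocab$pad, Lt)
    # replicate encoder memory across active beams
    encB <- list(M = enc$M[rep(seq_len(enc$Ls), B), , drop = FALSE],
                 Ls = enc$Ls, B = B)
    smaskB <- matrix(src_ids != vocab$pad, B, enc$Ls, byrow = TRUE)
    dec <- t_decode_stack(model$params, cfg, tin, tin != vocab$pad,
                          encB, smaskB, model$pe)
    cand <- list()
    for (b in seq_len(B)) {
      pos <- length(beams[[b]]$ids)
      row <- (b - 1L) * Lt + pos
      lg <- dec$logits[row, ]
      lp <- lg - max(lg) - log(sum(exp(lg - max(lg))))
      top <- order(lp, decreasing = TRUE)[seq_len(min(width, length(lp)))]
      for (tk in top) {
        cand[[length(cand) + 1L]] <-
          list(ids = c(beams[[b]]$ids, tk), lp = beams[[b]]$lp + lp[tk])
      }
    }
    scores <- vapply(cand, function(c) c$lp / (length(c$ids) - 1), 0)
    # only the top `width` candidates overall survive the step; the
    # finished ones among them retire to `done`
    top <- cand[utils::head(order(scores, decreasing = TRUE), width)]
    beams <- list()
    for (c in top) {
      if (utils::tail(c$ids, 1) == vocab$eos) {
        done[[length(done) + 1L]] <- c
      } else {
        beams[[length(beams) + 1L]] <- c
      }
    }
    full_for <- if (length(done) >= width) full_for + 1L else 0L
    if (beam_stop(beams, done, width, full_for)) break
  }
  if (length(done) == 0) done <- beams  # length cap hit: emit unfinished
  norm <- vapply(done, function(c) c$lp / (length(c$ids) - 1), 0)
  done <- done[utils::head(order(norm, decreasing = TRUE), width)]
  lapply(done, function(c) {
    ids <- c$ids[-1]
    ids <- ids[ids != vocab$eos]
    list(ids = ids, score = c$lp / max(length(c$ids) - 1, 1))
  })
}

# decode many sources at once under argmax; one batched decoder pass per
# step instead of one per sequence per step
greedy_decode_batch <- function(model, src_ids_list) {
  vocab <- model$vocab
  cfg <- model$cfg
  B <- length(src_ids_list)
  src <- pad_ids(src_ids_list, vocab$pad)
  smask <- src != vocab$pad
  enc <- t_encode(model$params, cfg, src, smask, model$pe)
  ids <- matrix(vocab$bos, B, 1)
  done <- rep(FALSE, B)
  for (step in seq_len(model$max_decode)) {
    dec <- t_decode_stack(model$params, cfg, ids, ids != vocab$pad,
                          enc, smask, model$pe)
    rows <- seq_len(B) * ncol(ids)
    nxt <- max.col(dec$logits[rows, , drop = FALSE], ties.method = "first")
    nxt[done] <- vocab$pad
    ids <- cbind(ids, nxt)
    done <- done | nxt == vocab$eos
    if (all(done)) break
  }
  lapply(seq_len(B), function(b) {
    seq <- ids[b, -1]
    stop_at <- which(seq == vocab$eos)[1]
    if (!is.na(stop_at)) seq[seq_len(stop_at - 1)] else seq[seq != vocab$pad]
  })
}

greedy_decode_ids <- function(model, src_ids) {
  key <- paste0("g:", paste(src_ids, collapse = ","))
  hit <- model$cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- beam_search_ids(model, src_ids, 1L)
  s <- detokenize(decode_ids(model$vocab, out[[1]]$ids))
  model$cache[[key]] <- s
  s
}

#' Greedy decode of a source token sequence
#'
#' @param model A `seq2seq_transformer`.
#' @param source Character vector of source tokens (with condition prefix if
#'   the model is conditional).
#' @return The decoded string (not validity-checked).
#' @export
greedy_decode <- function(model, source) {
  greedy_decode_ids(model, encode_tokens(model$vocab, source, strict = TRUE))
}

#' Beam-search decode to candidate products
#'
#' Standard beam search with length-normalized log-probability scoring.
#' Decodes that do not parse as molecules are dropped and duplicates (by
#' canonical SMILES) merged keeping the best rank; the removed counts are
#' attached as attributes `n_invalid` and `n_duplicate`.
#'
#' @param model A `seq2seq_transformer`.
#' @param source Character vector of source tokens.
#' @param width Beam width (>= 1).
#' @return Tibble `smiles` (canonical), `score`, `rank`, at most `width`
#'   rows, scores non-increasing.
#' @export
beam_decode <- function(model, source, width = 10) {
  stopifnot(width >= 1)
  ids <- encode_tokens(model$vocab, source, strict = TRUE)
  key <- paste0("b:", width, ":", paste(ids, collapse = ","))
  hit <- model$cache[[key]]
  if (!is.null(hit)) return(hit)
  raw <- beam_search_ids(model, ids, width)
  smiles <- vapply(raw, function(r) {
    detokenize(decode_ids(model$vocab, r$ids))
  }, character(1))
  can <- canonical_smiles(smiles)
  score <- vapply(raw, `[[`, 0, "score")
  valid <- !is.na(can)
  tb <- tibble::tibble(smiles = can[valid], score = score[valid])
  n_dup <- 0L
  if (nrow(tb) > 0) {
    tb <- dplyr::slice_max(dplyr::group_by(tb, .data$smiles), .data$score,
                           n = 1, with_ties = FALSE)
    tb <- dplyr::arrange(dplyr::ungroup(tb), dplyr::desc(.data$score))
    n_dup <- sum(valid) - nrow(tb)
  }
  tb$rank <- seq_len(nrow(tb))
  attr(tb, "n_invalid") <- sum(!valid)
  attr(tb, "n_duplicate") <- n_dup
  model$cache[[key]] <- tb
  tb
}

#' Top-n accuracy under beam search
#'
#' Fraction of pairs whose canonical target appears among the top `n` beam
#' candidates.
#'
#' @param model A `seq2seq_transformer`.
#' @param pairs Tibble with `source`/`target` token list-columns.
#' @param n Top-n cut (<= `width`).
#' @param width Beam width.
#' @return Fraction in `[0, 1]`.
#' @export
top_n_accuracy <- function(model, pairs, n = 1, width = 10) {
  stopifnot(n <= width, nrow(pairs) > 0)
  hit <- purrr::map2_lgl(pairs$source, pairs$target, function(src, tgt) {
    if (!model$conditioned && grepl("^<t_", src[1])) src <- src[-1]
    out <- beam_decode(model, src, width)
    target <- canonical_smiles(detokenize(tgt))
    target %in% utils::head(out$smiles, n)
  })
  mean(hit)
}

#' Enumerate single-step products across templates
#'
#' For each proposed template, decodes with the condition token prefixed to
#' the reactant; templates annotated single-product contribute only their
#' rank-1 decode. Products are validity-filtered, canonicalized and
#' deduplicated across templates keeping the best (template, rank)
#' provenance by score.
#'
#' @param model A conditional `seq2seq_transformer`.
#' @param smiles Reactant SMILES.
#' @param templates Tibble with columns `template` and (optionally)
#'   `single_product` — e.g. a filtered [templates_table()] or a
#'   [predict_templates()] ranking joined to it.
#' @param width Beam width per template.
#' @param per_template_cap Keep at most this many products per template.
#' @return Tibble `product`, `template`, `rank`, `score`.
#' @export
enumerate_products <- function(model, smiles, templates, width = 10,
                               per_template_cap = NULL) {
  if (nrow(templates) == 0) {
    return(tibble::tibble(product = character(0), template = integer(0),
                          rank = integer(0), score = numeric(0)))
  }
  src_tokens <- tokenize_smiles(canonical_smiles(smiles))
  if (!all(src_tokens %in% model$vocab$symbols)) {
    # decoded chemistry can drift outside the training alphabet (new ring
    # labels etc.); such molecules have no virtual reactions available
    return(tibble::tibble(product = character(0), template = integer(0),
                          rank = integer(0), score = numeric(0)))
  }
  single <- templates$single_product %||% rep(FALSE, nrow(templates))
  out <- purrr::map2_dfr(templates$template, single, function(ti, sp) {
    res <- beam_decode(model, c(condition_token(ti), src_tokens), width)
    if (sp) res <- utils::head(res, 1)
    if (!is.null(per_template_cap)) res <- utils::head(res, per_template_cap)
    if (nrow(res) == 0) return(NULL)
    tibble::tibble(product = res$smiles, template = ti, rank = res$rank,
                   score = res$score)
  })
  if (nrow(out) == 0) return(tibble::tibble(product = character(0),
                                            template = integer(0),
                                            rank = integer(0),
                                            score = numeric(0)))
  out <- dplyr::slice_max(dplyr::group_by(out, .data$product), .data$score,
                          n = 1, with_ties = FALSE)
  dplyr::arrange(dplyr::ungroup(out), dplyr::desc(.data$score))
}
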