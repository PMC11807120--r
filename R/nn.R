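# Neural-network primitives with hand-written backward passes.
#
# No deep-learning framework is assumed: parameters live in flat named lists
# of base-R matrices/vectors, forward passes cache what the backward pass
# needs, and optimization is plain Adam. Gradients are verified against
# finite differences in the test suite.

xavier_init <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

zeros_like <- function(params) {
  lapply(params, function(p) p * 0)
}

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# accumulate gradient contributions into a flat list
acc_grad <- function(grads, nm, g) {
  if (is.null(grads[[nm]])) grads[[nm]] <- g else grads[[nm]] <- grads[[nm]] + g
  grads
}

relu <- function(x) {
  x * (x > 0)
}

# row-wise softmax, tolerating -Inf entries (fully masked rows forbidden)
softmax_rows <- function(x) {
  m <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - m)
  e[is.na(e)] <- 0  # -Inf - -Inf
  e / pmax(rowSums(e), .Machine$double.xmin)
}

# --- layer norm -------------------------------------------------------------

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  n <- nrow(x)
  list(y = xhat * rep(g, each = n) + rep(b, each = n),
       cache = list(xhat = xhat, inv = inv, g = g))
}

layernorm_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  inv <- cache$inv
  d <- ncol(dy)
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- dy * rep(cache$g, each = nrow(dy))
  # dx = inv * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) per row
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

# --- multi-head attention ---------------------------------------------------

# Xq: (B*Lq) x d, Xkv: (B*Lk) x d, rows grouped per sequence (b-major).
# kmask: B x Lk logical, TRUE where the key position is real; the first key
# of every sequence must be real so no softmax row is fully masked.
# The compiled path (src/mha.cpp) carries the training load; the pure-R
# implementation below is the reference both are checked against.
mha_fwd <- function(Xq, Xkv, Wq, Wk, Wv, Wo, n_heads, B, Lq, Lk, kmask,
                    causal = FALSE) {
  fw <- mha_fwd_cpp(Xq, Xkv, Wq, Wk, Wv, Wo, n_heads, B, Lq, Lk,
                    matrix(as.integer(kmask), nrow(kmask)), causal)
  list(out = fw$out,
       cache = list(Xq = Xq, Xkv = Xkv, Q = fw$Q, K = fw$K, V = fw$V,
                    O = fw$O, P = fw$P, n_heads = n_heads, B = B, Lq = Lq,
                    Lk = Lk, Wq = Wq, Wk = Wk, Wv = Wv, Wo = Wo))
}

mha_bwd <- function(dout, cache) {
  with(cache, mha_bwd_cpp(dout, Xq, Xkv, Q, K, V, O, P, Wq, Wk, Wv, Wo,
                          n_heads, B, Lq, Lk))
}

mha_fwd_ref <- function(Xq, Xkv, Wq, Wk, Wv, Wo, n_heads, B, Lq, Lk, kmask,
                        causal = FALSE) {
  d <- ncol(Wq)
  dk <- d / n_heads
  Q <- Xq %*% Wq
  K <- Xkv %*% Wk
  V <- Xkv %*% Wv
  O <- matrix(0, nrow(Xq), d)
  P_list <- vector("list", B * n_heads)
  for (b in seq_len(B)) {
    qr <- (b - 1L) * Lq + seq_len(Lq)
    kr <- (b - 1L) * Lk + seq_len(Lk)
    maskcol <- !kmask[b, ]
    for (h in seq_len(n_heads)) {
      cols <- (h - 1L) * dk + seq_len(dk)
      S <- tcrossprod(Q[qr, cols, drop = FALSE],
                      K[kr, cols, drop = FALSE]) / sqrt(dk)
      if (any(maskcol)) S[, maskcol] <- -Inf
      if (causal) S[upper.tri(S)] <- -Inf
      P <- softmax_rows(S)
      P_list[[(b - 1L) * n_heads + h]] <- P
      O[qr, cols] <- P %*% V[kr, cols, drop = FALSE]
    }
  }
  out <- O %*% Wo
  list(out = out,
       cache = list(Xq = Xq, Xkv = Xkv, Q = Q, K = K, V = V, O = O,
                    P_list = P_list, n_heads = n_heads, B = B, Lq = Lq,
                    Lk = Lk, Wq = Wq, Wk = Wk, Wv = Wv, Wo = Wo))
}

mha_bwd_ref <- function(dout, cache) {
  with(cache, {
    d <- ncol(Wq)
    dk <- d / n_heads
    dO <- dout %*% t(Wo)
    dWo <- crossprod(O, dout)
    dQ <- matrix(0, nrow(Q), d)
    dK <- matrix(0, nrow(K), d)
    dV <- matrix(0, nrow(V), d)
    for (b in seq_len(B)) {
      qr <- (b - 1L) * Lq + seq_len(Lq)
      kr <- (b - 1L) * Lk + seq_len(Lk)
      for (h in seq_len(n_heads)) {
        cols <- (h - 1L) * dk + seq_len(dk)
        P <- P_list[[(b - 1L) * n_heads + h]]
        dOb <- dO[qr, cols, drop = FALSE]
        Vb <- V[kr, cols, drop = FALSE]
        dV[kr, cols] <- dV[kr, cols] + crossprod(P, dOb)
        dP <- tcrossprod(dOb, Vb)
        dS <- P * (dP - rowSums(dP * P))
        dS <- dS / sqrt(dk)
        dQ[qr, cols] <- dQ[qr, cols] +
          dS %*% K[kr, cols, drop = FALSE]
        dK[kr, cols] <- dK[kr, cols] +
          crossprod(dS, Q[qr, cols, drop = FALSE])
      }
    }
    list(dXq = dQ %*% t(Wq),
         dXkv = dK %*% t(Wk) + dV %*% t(Wv),
         dWq = crossprod(Xq, dQ),
         dWk = crossprod(Xkv, dK),
         dWv = crossprod(Xkv, dV),
         dWo = dWo)
  })
}

# --- position-wise feed-forward ---------------------------------------------

ffn_fwd <- function(x, W1, b1, W2, b2) {
  a <- x %*% W1 + rep(b1, each = nrow(x))
  h <- relu(a)
  list(y = h %*% W2 + rep(b2, each = nrow(x)),
       cache = list(x = x, a = a, h = h, W1 = W1, W2 = W2))
}

ffn_bwd <- function(dy, cache) {
  with(cache, {
    dh <- dy %*% t(W2)
    da <- dh * (a > 0)
    list(dx = da %*% t(W1),
         dW1 = crossprod(x, da), db1 = colSums(da),
         dW2 = crossprod(h, dy), db2 = colSums(dy))
  })
}

# sinusoidal positional encoding, L x d
positional_encoding <- function(L, d) {
  pos <- seq_len(L) - 1
  i <- seq_len(d) - 1
  angle <- outer(pos, 10000^(-(i %/% 2 * 2) / d))
  pe <- matrix(0, L, d)
  even <- (i %% 2) == 0
  pe[, even] <- sin(angle[, even, drop = FALSE])
  pe[, !even] <- cos(angle[, !even, drop = FALSE])
  pe
}
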