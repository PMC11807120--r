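# Graph convolutional reaction-template classifier.
#
# A molecule is encoded as per-bond-type adjacency indicators A^(t),
# t in {single, double, triple, aromatic}, plus a node-feature matrix F.
# One graph-convolution step computes X' = sigma(sum_t A~^(t) X W_t) with
# A~^(t) = D_t^{-1}(A^(t) + I) (row-normalized with self-loops per type);
# node states are then sum-aggregated into a graph vector and passed through
# dense rectifier layers to template logits. Defaults follow the selected
# values of the hyperparameter search at full scale: hidden dimension 256,
# one convolution layer, three dense layers, learning rate 4e-4.

.gcn_elements <- c("C", "N", "O", "S", "F", "Cl", "Br", "I")

#' Featurize a molecule for the graph network
#'
#' @param smiles A single SMILES string.
#' @return List of class `molecule_graph`: `n` (heavy atoms), `A`
#'   (n x n x 4 bond-type indicator array, symmetric, zero diagonal), `F`
#'   (n x d node features: element one-hot, degree one-hot, formal charge,
#'   aromatic flag, ring flag).
#' @export
featurize <- function(smiles) {
  g <- mol_graph(smiles)
  n <- g$n
  A <- array(0, c(n, n, 4))
  if (nrow(g$bonds) > 0) {
    type <- ifelse(g$bonds$aromatic, 4L, pmin(g$bonds$order, 3L))
    for (i in seq_len(nrow(g$bonds))) {
      A[g$bonds$a1[i], g$bonds$a2[i], type[i]] <- 1
      A[g$bonds$a2[i], g$bonds$a1[i], type[i]] <- 1
    }
  }
  el <- match(g$atoms$symbol, .gcn_elements)
  el[is.na(el)] <- length(.gcn_elements) + 1L
  Fm <- matrix(0, n, length(.gcn_elements) + 1L + 5L + 3L)
  Fm[cbind(seq_len(n), el)] <- 1
  off <- length(.gcn_elements) + 1L
  Fm[cbind(seq_len(n), off + pmin(g$atoms$degree, 4L) + 1L)] <- 1
  Fm[, off + 6L] <- g$atoms$charge
  Fm[, off + 7L] <- as.numeric(g$atoms$aromatic)
  Fm[, off + 8L] <- as.numeric(g$atoms$in_ring)
  structure(list(n = n, A = A, F = Fm), class = "molecule_graph")
}

gcn_feature_dim <- function() length(.gcn_elements) + 9L

#' Normalize per-bond-type adjacency
#'
#' \eqn{\tilde A^{(t)} = D_t^{-1}(A^{(t)} + I)} — self-loops added per bond
#' type, then row normalization.
#'
#' @param A n x n x T indicator array.
#' @return Array of the same shape.
#' @export
normalize_adjacency <- function(A) {
  n <- dim(A)[1]
  out <- A
  for (t in seq_len(dim(A)[3])) {
    At <- A[, , t] + diag(n)
    out[, , t] <- At / rowSums(At)
  }
  out
}

#' One graph-convolution step
#'
#' \eqn{X' = \sigma(\sum_t \tilde A^{(t)} X W_t)} with a rectifier
#' nonlinearity.
#'
#' @param X n x h input node-state matrix.
#' @param A_norm normalized n x n x T adjacency array.
#' @param W_list List of T weight matrices (h x h').
#' @return n x h' matrix.
#' @export
graph_convolution <- function(X, A_norm, W_list) {
  stopifnot(length(W_list) == dim(A_norm)[3])
  acc <- 0
  for (t in seq_along(W_list)) {
    acc <- acc + A_norm[, , t] %*% X %*% W_list[[t]]
  }
  relu(acc)
}

#' Sum aggregation of node states
#'
#' Column sums of the node-state matrix: a permutation-invariant graph-level
#' readout.
#'
#' @param X n x h matrix.
#' @return Numeric vector of length h.
#' @export
sum_aggregate <- function(X) {
  colSums(X)
}

#' GCN hyperparameter set
#'
#' @param dim Hidden dimension (default 256, the selected full-scale value).
#' @param n_conv Number of convolution layers (default 1).
#' @param n_dense Number of dense layers including the output projection
#'   (default 3).
#' @param lr Adam learning rate (default 4e-4).
#' @param epochs Maximum epochs.
#' @param patience Early-stopping patience on validation top-1 accuracy.
#' @param seed Integer seed.
#' @return List of class `gcn_config`.
#' @export
gcn_config <- function(dim = 256, n_conv = 1, n_dense = 3, lr = 4e-4,
                       epochs = 60, patience = 8, seed = 1L) {
  structure(list(dim = dim, n_conv = n_conv, n_dense = n_dense, lr = lr,
                 epochs = epochs, patience = patience,
                 seed = as.integer(seed)),
            class = "gcn_config")
}

gcn_init_params <- function(cfg, d_in, n_templates) {
  p <- list()
  for (l in seq_len(cfg$n_conv)) {
    din <- if (l == 1) d_in else cfg$dim
    for (t in 1:4) {
      p[[paste0("conv", l, "_W", t)]] <- xavier_init(din, cfg$dim)
    }
  }
  for (l in seq_len(cfg$n_dense)) {
    dout <- if (l == cfg$n_dense) n_templates else cfg$dim
    p[[paste0("dense", l, "_W")]] <- xavier_init(cfg$dim, dout)
    p[[paste0("dense", l, "_b")]] <- rep(0, dout)
  }
  p
}

# forward for one featurized molecule; returns caches for backprop
gcn_forward_one <- function(p, cfg, graph, A_norm) {
  Xs <- list(graph$F)
  for (l in seq_len(cfg$n_conv)) {
    W <- lapply(1:4, function(t) p[[paste0("conv", l, "_W", t)]])
    pre <- 0
    for (t in 1:4) pre <- pre + A_norm[, , t] %*% Xs[[l]] %*% W[[t]]
    Xs[[l + 1]] <- relu(pre)
  }
  g <- sum_aggregate(Xs[[cfg$n_conv + 1]])
  hs <- list(g)
  as <- list()
  for (l in seq_len(cfg$n_dense)) {
    a <- drop(hs[[l]] %*% p[[paste0("dense", l, "_W")]]) +
      p[[paste0("dense", l, "_b")]]
    as[[l]] <- a
    hs[[l + 1]] <- if (l < cfg$n_dense) relu(a) else a
  }
  list(logits = hs[[cfg$n_dense + 1]], Xs = Xs, hs = hs, as = as)
}

gcn_backward_one <- function(p, cfg, graph, A_norm, fw, dlogits, grads) {
  dh <- dlogits
  for (l in rev(seq_len(cfg$n_dense))) {
    if (l < cfg$n_dense) dh <- dh * (fw$as[[l]] > 0)
    grads <- acc_grad(grads, paste0("dense", l, "_W"),
                      outer(fw$hs[[l]], dh))
    grads <- acc_grad(grads, paste0("dense", l, "_b"), dh)
    dh <- drop(p[[paste0("dense", l, "_W")]] %*% dh)
  }
  # through sum aggregation: broadcast to every node
  dX <- matrix(dh, graph$n, length(dh), byrow = TRUE)
  for (l in rev(seq_len(cfg$n_conv))) {
    X <- fw$Xs[[l]]
    Xout <- fw$Xs[[l + 1]]
    dpre <- dX * (Xout > 0)
    for (t in 1:4) {
      AtX <- A_norm[, , t] %*% X
      grads <- acc_grad(grads, paste0("conv", l, "_W", t),
                        crossprod(AtX, dpre))
    }
    if (l > 1) {
      dXnew <- 0
      for (t in 1:4) {
        W <- p[[paste0("conv", l, "_W", t)]]
        dXnew <- dXnew + t(A_norm[, , t]) %*% dpre %*% t(W)
      }
      dX <- dXnew
    }
  }
  grads
}

#' Train the template classifier
#'
#' Cross-entropy training with Adam over (reactant, template) records; the
#' held-out report carries top-1/5/10 accuracy, the quantities used to judge
#' template proposal quality.
#'
#' @param records Tibble with columns `reactant` (SMILES) and `template`
#'   (0-based integer labels).
#' @param n_templates Number of template classes `T` (default
#'   `max(template) + 1`).
#' @param cfg A [gcn_config()].
#' @param seed Integer seed (overrides `cfg$seed`).
#' @param quiet Suppress progress messages?
#' @return Object of class `gcn_model` with `params`, `cfg`, `report`
#'   (tibble: top1, top5, top10 on the test split), `n_templates`.
#' @export
train_gcn <- function(records, n_templates = NULL, cfg = gcn_config(),
                      seed = cfg$seed, quiet = FALSE) {
  stopifnot(nrow(records) > 0)
  if (is.null(n_templates)) n_templates <- max(records$template) + 1L
  if (length(unique(records$template)) < 2) {
    stop("need at least two template classes to train")
  }
  sp <- split_dataset(records, c(train = 0.8, val = 0.1, test = 0.1),
                      seed = seed)
  feats <- new.env(parent = emptyenv())
  get_feat <- function(s) {
    hit <- feats[[s]]
    if (is.null(hit)) {
      gr <- featurize(s)
      hit <- list(graph = gr, A_norm = normalize_adjacency(gr$A))
      feats[[s]] <- hit
    }
    hit
  }
  params <- withr::with_seed(
    seed, gcn_init_params(cfg, gcn_feature_dim(), n_templates))
  state <- adam_init(params)
  topk_eval <- function(p, data, ks = c(1, 5, 10)) {
    hits <- matrix(FALSE, nrow(data), length(ks))
    for (i in seq_len(nrow(data))) {
      ft <- get_feat(data$reactant[i])
      lg <- gcn_forward_one(p, cfg, ft$graph, ft$A_norm)$logits
      ord <- order(-lg, seq_along(lg))  # deterministic tie-break by index
      pos <- which(ord == data$template[i] + 1L)
      hits[i, ] <- pos <= ks
    }
    colMeans(hits)
  }
  best <- list(acc = -1, params = params, epoch = 0)
  wait <- 0
  withr::with_seed(seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(nrow(sp$train))
      grads <- list()
      nb <- 0
      for (i in ord) {
        ft <- get_feat(sp$train$reactant[i])
        fw <- gcn_forward_one(params, cfg, ft$graph, ft$A_norm)
        pr <- exp(fw$logits - max(fw$logits))
        pr <- pr / sum(pr)
        dlogits <- pr
        y <- sp$train$template[i] + 1L
        dlogits[y] <- dlogits[y] - 1
        grads <- gcn_backward_one(params, cfg, ft$graph, ft$A_norm, fw,
                                  dlogits, grads)
        nb <- nb + 1
        if (nb == 16 || i == ord[length(ord)]) {
          grads <- lapply(grads, function(g) g / nb)
          up <- adam_step(params, grads, state, lr = cfg$lr)
          params <- up$params
          state <- up$state
          grads <- list()
          nb <- 0
        }
      }
      val <- topk_eval(params, sp$val, 1)
      if (!quiet) message(sprintf("gcn epoch %3d  val top-1 %.3f", epoch, val))
      if (val > best$acc + 1e-9) {
        best <- list(acc = val, params = params, epoch = epoch)
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= cfg$patience) break
      }
    }
  })
  ks <- c(1, 5, min(10, n_templates))
  acc <- topk_eval(best$params, sp$test, ks)
  structure(
    list(params = best$params, cfg = cfg, n_templates = n_templates,
         report = tibble::tibble(top1 = acc[1], top5 = acc[2],
                                 top10 = acc[3]),
         best_epoch = best$epoch,
         feat_cache = feats),
    class = "gcn_model")
}

#' @export
print.gcn_model <- function(x, ...) {
  cat(sprintf(
    "<gcn_model> %d templates; held-out top-1 %.3f top-5 %.3f top-10 %.3f\n",
    x$n_templates, x$report$top1, x$report$top5, x$report$top10))
  invisible(x)
}

#' Rank reaction templates for a reactant
#'
#' @param model A `gcn_model`.
#' @param smiles Reactant SMILES.
#' @param k Number of templates to return (capped at `T`).
#' @return Tibble of class-ranked rows: `template` (0-based), `score`
#'   (softmax probability), scores non-increasing, ties broken by index.
#' @export
predict_templates <- function(model, smiles, k = 10) {
  gr <- featurize(canonical_smiles(smiles))
  fw <- gcn_forward_one(model$params, model$cfg, gr, normalize_adjacency(gr$A))
  pr <- exp(fw$logits - max(fw$logits))
  pr <- pr / sum(pr)
  ord <- order(-pr, seq_along(pr))
  top <- utils::head(ord, min(k, model$n_templates))
  tibble::tibble(template = top - 1L, score = pr[top])
}

#' Filter a template ranking by substructure match
#'
#' Keeps only templates whose reactant-side SMARTS matches the molecule;
#' the order of the ranking is preserved. Every ranked template must carry a
#' pattern.
#'
#' @param smiles Reactant SMILES.
#' @param ranking Tibble from [predict_templates()].
#' @param templates Template metadata with columns `template` and `smarts`
#'   (e.g. [templates_table()]).
#' @return The surviving subsequence of `ranking`, joined with the
#'   templates' `smarts` and `single_product` columns when present.
#' @export
filter_matching_templates <- function(smiles, ranking, templates) {
  if (nrow(ranking) == 0) return(ranking)
  meta <- templates[match(ranking$template, templates$template), ,
                    drop = FALSE]
  if (anyNA(meta$template) || anyNA(meta$smarts)) {
    stop("ranked template lacks a reactant-side SMARTS pattern")
  }
  ok <- vapply(meta$smarts, function(pt) smarts_count(smiles, pt) > 0,
               logical(1))
  out <- ranking[ok, , drop = FALSE]
  extra <- setdiff(intersect(c("smarts", "single_product"), names(meta)),
                   names(out))
  for (cl in extra) out[[cl]] <- meta[[cl]][ok]
  out
}
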