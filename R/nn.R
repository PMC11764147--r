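# The dual-channel graph network and its hand-derived reverse-mode
# gradients. One channel is a stack of multi-head graph-attention (GAT)
# layers with ReLU attention logits and post-concatenation layer norm; the
# other is a single symmetric-normalised graph convolution (GCN). Each
# channel is globally max-pooled and the pooled vectors are concatenated and
# classified by four affine layers with a sigmoid output. All tensors are
# dense base-R matrices: peptides have at most a few dozen residues, so
# sparse machinery would cost more than it saves.

LN_EPS <- 1e-5

#' Model configuration
#'
#' @param input_dim Node-feature width (70 for the full featurization).
#' @param hidden Hidden/output width of both channels; default 64. Must be
#'   divisible by `heads`.
#' @param heads Number of attention heads per GAT layer; default 8.
#' @param gat_layers Number of stacked GAT layers; default 3.
#' @param dropout Dropout rate applied after pooling and after each hidden
#'   classifier layer during training; default 0.5.
#' @param threshold Decision threshold on the sigmoid probability (strict
#'   `>`); default 0.35.
#' @param pos_weight Loss weight multiplying positive-sample terms;
#'   default 10 (10:1 positive:negative).
#' @param activation Attention-logit activation: `"relu"` (default) or
#'   `"leakyrelu"` (slope 0.2). With ReLU a row of all-zero logits is
#'   legitimate and yields uniform attention over the neighbourhood.
#' @param use_gat,use_gcn Channel toggles for ablations; at least one must
#'   remain enabled.
#' @return A named list of class `il6gnn_config`.
#' @export
model_config <- function(input_dim = 70L, hidden = 64L, heads = 8L,
                         gat_layers = 3L, dropout = 0.5, threshold = 0.35,
                         pos_weight = 10, activation = c("relu", "leakyrelu"),
                         use_gat = TRUE, use_gcn = TRUE) {
  activation <- match.arg(activation)
  if (!use_gat && !use_gcn)
    stop("at least one channel (GAT or GCN) must be enabled", call. = FALSE)
  if (use_gat && hidden %% heads != 0L)
    stop("hidden width ", hidden, " not divisible by ", heads, " heads",
         call. = FALSE)
  structure(list(input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden), heads = as.integer(heads),
                 gat_layers = as.integer(gat_layers), gcn_layers = 1L,
                 dropout = dropout, threshold = threshold,
                 pos_weight = pos_weight, activation = activation,
                 use_gat = use_gat, use_gcn = use_gcn),
            class = "il6gnn_config")
}

act_fun <- function(x, kind) {
  if (kind == "relu") pmax(x, 0) else ifelse(x > 0, x, 0.2 * x)
}
act_grad <- function(x, kind) {
  if (kind == "relu") (x > 0) * 1 else ifelse(x > 0, 1, 0.2)
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialise model parameters
#'
#' Glorot-uniform weights drawn from the current RNG stream; layer-norm
#' gains start at 1, all biases at 0. The classifier head is four affine
#' maps F -> F -> F/2 -> F/4 -> 1 where F is the fused width (128 with both
#' channels at hidden width 64).
#'
#' @param config An `il6gnn_config`.
#' @return A `model_params` list: `gat` (per-layer `W`, `a_src`, `a_dst`,
#'   `ln_gain`, `ln_bias`), `gcn` (`W`), `cls` (`W1..b4`).
#' @export
init_model_params <- function(config) {
  H <- config$hidden
  dh <- if (config$use_gat) H %/% config$heads else 0L
  gat <- list()
  if (config$use_gat) {
    din <- config$input_dim
    for (l in seq_len(config$gat_layers)) {
      gat[[l]] <- list(W = glorot(din, H),
                       a_src = matrix(stats::runif(dh * config$heads,
                                                   -0.1, 0.1), dh),
                       a_dst = matrix(stats::runif(dh * config$heads,
                                                   -0.1, 0.1), dh),
                       ln_gain = rep(1, H), ln_bias = rep(0, H))
      din <- H
    }
  }
  gcn <- if (config$use_gcn) list(W = glorot(config$input_dim, H)) else NULL
  fw <- fused_width(config)
  dims <- c(fw, fw, fw %/% 2L, fw %/% 4L, 1L)
  cls <- list()
  for (i in 1:4) {
    cls[[paste0("W", i)]] <- glorot(dims[i], dims[i + 1])
    cls[[paste0("b", i)]] <- rep(0, dims[i + 1])
  }
  structure(list(gat = gat, gcn = gcn, cls = cls), class = "model_params")
}

fused_width <- function(config) {
  config$hidden * (as.integer(config$use_gat) + as.integer(config$use_gcn))
}

check_params_shapes <- function(params, config) {
  config <- as_model_config(config)
  if (config$use_gat) {
    if (length(params$gat) != config$gat_layers)
      stop("checkpoint has ", length(params$gat), " GAT layers; config says ",
           config$gat_layers, call. = FALSE)
    din <- config$input_dim
    for (l in seq_along(params$gat)) {
      W <- params$gat[[l]]$W
      if (nrow(W) != din || ncol(W) != config$hidden)
        stop("GAT layer ", l, " weight is ", nrow(W), " x ", ncol(W),
             "; expected ", din, " x ", config$hidden, call. = FALSE)
      din <- config$hidden
    }
  }
  if (config$use_gcn && !identical(dim(params$gcn$W),
                                   c(config$input_dim, config$hidden)))
    stop("GCN weight shape mismatch with config", call. = FALSE)
  fw <- fused_width(config)
  if (nrow(params$cls$W1) != fw)
    stop("classifier input width ", nrow(params$cls$W1),
         " != fused width ", fw, call. = FALSE)
  invisible(params)
}

as_model_config <- function(x) {
  # always rebuild through the constructor so invariants are re-checked
  do.call(model_config, x[intersect(names(x), names(formals(model_config)))])
}

# ---- attention -------------------------------------------------------------

#' Attention coefficients of one GAT head
#'
#' For head `k`, computes the softmax-normalised attention matrix
#' `alpha[i, j]` over each node's neighbourhood (self-loops included):
#' logits are `g(a^T [W h_i || W h_j])` with `g` the configured activation,
#' masked to the adjacency support before the softmax. Each defined row sums
#' to 1; entries off the support are exactly 0.
#'
#' @param H L x D input feature matrix.
#' @param adj Binary symmetric adjacency with self-loops.
#' @param layer One element of `params$gat` (fields `W`, `a_src`, `a_dst`).
#' @param head Head index in 1..K.
#' @param activation `"relu"` or `"leakyrelu"`.
#' @return L x L attention matrix.
#' @export
gat_attention <- function(H, adj, layer, head, activation = "relu") {
  dh <- nrow(layer$a_src)
  cols <- ((head - 1L) * dh + 1L):(head * dh)
  U <- H %*% layer$W[, cols, drop = FALSE]
  s <- drop(U %*% layer$a_src[, head])
  t_ <- drop(U %*% layer$a_dst[, head])
  logits <- act_fun(outer(s, rep(1, length(t_))) +
                    outer(rep(1, length(s)), t_), activation)
  masked_softmax(logits, adj)
}

masked_softmax <- function(logits, adj) {
  neg <- ifelse(adj > 0, logits, -Inf)
  mx <- apply(neg, 1, max)
  w <- exp(neg - mx)
  w[adj == 0] <- 0
  w / rowSums(w)
}

# Forward pass of one GAT layer with cache for backprop.
gat_layer_fwd <- function(H, adj, layer, activation) {
  L <- nrow(H); K <- ncol(layer$a_src); dh <- nrow(layer$a_src)
  U <- H %*% layer$W                       # L x hidden, head-blocked
  P <- matrix(0, L, K * dh)
  cache_heads <- vector("list", K)
  ones <- rep(1, L)
  for (k in seq_len(K)) {
    cols <- ((k - 1L) * dh + 1L):(k * dh)
    Uk <- U[, cols, drop = FALSE]
    s <- drop(Uk %*% layer$a_src[, k])
    t_ <- drop(Uk %*% layer$a_dst[, k])
    E <- outer(s, ones) + outer(ones, t_)
    G <- act_fun(E, activation)
    alpha <- masked_softmax(G, adj)
    M <- alpha %*% Uk
    P[, cols] <- pmax(M, 0)                # per-head ReLU (Eq-level sigma)
    cache_heads[[k]] <- list(Uk = Uk, E = E, alpha = alpha, M = M)
  }
  # layer norm over the concatenated feature axis, per node
  mu <- rowMeans(P)
  xc <- P - mu
  v <- rowMeans(xc^2)
  invstd <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * invstd
  out <- sweep(xhat, 2, layer$ln_gain, `*`)
  out <- sweep(out, 2, layer$ln_bias, `+`)
  list(out = out,
       cache = list(H = H, U = U, heads = cache_heads, P = P, xhat = xhat,
                    invstd = invstd, adj = adj))
}

gat_layer_bwd <- function(dout, layer, cache, activation) {
  K <- ncol(layer$a_src); dh <- nrow(layer$a_src)
  L <- nrow(dout); Hdim <- K * dh
  # layer-norm backward (population variance, per row)
  dgain <- colSums(dout * cache$xhat)
  dbias <- colSums(dout)
  dxhat <- sweep(dout, 2, layer$ln_gain, `*`)
  rs1 <- rowSums(dxhat)
  rs2 <- rowSums(dxhat * cache$xhat)
  dP <- cache$invstd / Hdim * (Hdim * dxhat - rs1 - cache$xhat * rs2)
  dU <- matrix(0, L, Hdim)
  da_src <- matrix(0, dh, K); da_dst <- matrix(0, dh, K)
  for (k in seq_len(K)) {
    cols <- ((k - 1L) * dh + 1L):(k * dh)
    ch <- cache$heads[[k]]
    dM <- dP[, cols, drop = FALSE] * (ch$M > 0)
    dalpha <- dM %*% t(ch$Uk)
    dUk <- t(ch$alpha) %*% dM
    # softmax backward: rows; off-support alpha = 0 kills those entries
    dG <- ch$alpha * (dalpha - rowSums(ch$alpha * dalpha))
    dE <- dG * act_grad(ch$E, activation)
    ds <- rowSums(dE)
    dt <- colSums(dE)
    dUk <- dUk + outer(ds, layer$a_src[, k]) + outer(dt, layer$a_dst[, k])
    da_src[, k] <- drop(crossprod(ch$Uk, ds))
    da_dst[, k] <- drop(crossprod(ch$Uk, dt))
    dU[, cols] <- dUk
  }
  dW <- crossprod(cache$H, dU)
  dH <- tcrossprod(dU, layer$W)
  list(dH = dH,
       grads = list(W = dW, a_src = da_src, a_dst = da_dst,
                    ln_gain = dgain, ln_bias = dbias))
}

#' Forward pass of one multi-head GAT layer
#'
#' Attention-weighted aggregation per head (see [gat_attention()]), per-head
#' ReLU, concatenation of the `K` head outputs to the hidden width, then
#' layer normalisation with learned gain/offset.
#'
#' @inheritParams gat_attention
#' @param K Number of heads (taken from the layer parameters).
#' @return L x hidden output feature matrix.
#' @export
gat_layer_forward <- function(H, adj, layer, K = ncol(layer$a_src),
                              activation = "relu") {
  gat_layer_fwd(H, adj, layer, activation)$out
}

#' Forward pass of the GCN layer
#'
#' Symmetric degree-normalised aggregation
#' `relu(D^-1/2 A D^-1/2 H W)` where `A` already carries self-loops (no
#' second self-loop is added) and `D` is its degree matrix.
#'
#' @param H L x D input feature matrix.
#' @param adj Binary symmetric adjacency with self-loops.
#' @param layer List with field `W`.
#' @return L x hidden output matrix.
#' @export
gcn_layer_forward <- function(H, adj, layer) {
  gcn_layer_fwd(H, adj, layer)$out
}

gcn_norm <- function(adj) {
  dinv <- 1 / sqrt(rowSums(adj))
  adj * outer(dinv, dinv)
}

gcn_layer_fwd <- function(H, adj, layer) {
  S <- gcn_norm(adj)
  T_ <- S %*% H
  pre <- T_ %*% layer$W
  list(out = pmax(pre, 0), cache = list(S = S, T_ = T_, pre = pre))
}

gcn_layer_bwd <- function(dout, layer, cache) {
  dpre <- dout * (cache$pre > 0)
  dW <- crossprod(cache$T_, dpre)
  dH <- cache$S %*% tcrossprod(dpre, layer$W)   # S symmetric
  list(dH = dH, grads = list(W = dW))
}

#' Global max pooling
#'
#' Column-wise maximum over the node axis; invariant to node order.
#'
#' @param H L x D node-feature matrix with L >= 1.
#' @return Length-D vector.
#' @export
global_max_pool <- function(H) {
  if (is.null(dim(H)) || nrow(H) < 1L)
    stop("cannot pool an empty graph", call. = FALSE)
  apply(H, 2, max)
}

pool_fwd <- function(H) {
  idx <- max.col(t(H), ties.method = "first")
  list(out = H[cbind(idx, seq_len(ncol(H)))], idx = idx)
}

# ---- whole-model forward / backward ---------------------------------------

dropout_mask <- function(n, rate) {
  if (rate <= 0) rep(1, n)
  else (stats::runif(n) >= rate) / (1 - rate)   # inverted dropout
}

#' Forward pass of the full dual-channel model
#'
#' GAT channel: the stacked attention layers followed by global max pooling;
#' GCN channel: one convolution followed by global max pooling. The pooled
#' vectors are concatenated (GAT features first, positions 1..hidden; GCN
#' features after) and passed through the four-layer classifier; the final
#' scalar goes through a sigmoid. Dropout (after pooling and after each
#' hidden classifier layer) is active only when `training = TRUE`; with it
#' off the forward pass is deterministic.
#'
#' @param graph A `peptide_graph` (see [build_graph()]).
#' @param params A `model_params`.
#' @param config The matching `il6gnn_config`.
#' @param training Logical; enables dropout (drawing from the current RNG).
#' @return List with `logit` and `prob`.
#' @export
forward <- function(graph, params, config, training = FALSE) {
  fw <- forward_graph(graph$X, graph$adj, params, config, training)
  list(logit = fw$logit, prob = fw$prob)
}

forward_graph <- function(X, adj, params, config, training = FALSE) {
  caches <- list()
  pooled <- NULL
  if (config$use_gat) {
    H <- X
    gcaches <- vector("list", config$gat_layers)
    for (l in seq_len(config$gat_layers)) {
      r <- gat_layer_fwd(H, adj, params$gat[[l]], config$activation)
      gcaches[[l]] <- r$cache
      H <- r$out
    }
    pg <- pool_fwd(H)
    caches$gat <- gcaches
    caches$gat_pool <- pg
    pooled <- pg$out
  }
  if (config$use_gcn) {
    r <- gcn_layer_fwd(X, adj, params$gcn)
    pc <- pool_fwd(r$out)
    caches$gcn <- r$cache
    caches$gcn_pool <- pc
    pooled <- c(pooled, pc$out)
  }
  x0 <- pooled
  m0 <- if (training) dropout_mask(length(x0), config$dropout)
        else rep(1, length(x0))
  a <- x0 * m0
  caches$x0 <- x0; caches$m0 <- m0
  acts <- list(); masks <- list(); pres <- list()
  for (i in 1:3) {
    pre <- drop(a %*% params$cls[[paste0("W", i)]]) +
      params$cls[[paste0("b", i)]]
    h <- pmax(pre, 0)
    m <- if (training) dropout_mask(length(h), config$dropout)
         else rep(1, length(h))
    pres[[i]] <- pre; acts[[i]] <- a; masks[[i]] <- m
    a <- h * m
  }
  logit <- drop(a %*% params$cls$W4) + params$cls$b4
  caches$cls <- list(pres = pres, acts = acts, masks = masks, a_last = a)
  list(logit = logit, prob = stats::plogis(logit), caches = caches)
}

backward_graph <- function(dlogit, fw, params, config) {
  ch <- fw$caches
  g_cls <- list()
  da <- dlogit * drop(params$cls$W4)
  g_cls$W4 <- matrix(ch$cls$a_last * dlogit, ncol = 1)
  g_cls$b4 <- dlogit
  for (i in 3:1) {
    dh <- da * ch$cls$masks[[i]]
    dpre <- dh * (ch$cls$pres[[i]] > 0)
    Wi <- params$cls[[paste0("W", i)]]
    g_cls[[paste0("W", i)]] <- outer(ch$cls$acts[[i]], dpre)
    g_cls[[paste0("b", i)]] <- dpre
    da <- drop(Wi %*% dpre)
  }
  dx0 <- da * ch$m0
  g_cls <- g_cls[names(params$cls)]   # align with parameter-tree order
  grads <- list(gat = list(), gcn = NULL, cls = g_cls)
  if (config$use_gat) {
    Hw <- config$hidden
    dpool <- dx0[seq_len(Hw)]
    L <- nrow(ch$gat[[1]]$H)
    dH <- matrix(0, L, Hw)
    dH[cbind(ch$gat_pool$idx, seq_len(Hw))] <- dpool
    ggat <- vector("list", config$gat_layers)
    for (l in config$gat_layers:1) {
      b <- gat_layer_bwd(dH, params$gat[[l]], ch$gat[[l]], config$activation)
      ggat[[l]] <- b$grads
      dH <- b$dH
    }
    grads$gat <- ggat
    off <- Hw
  } else off <- 0L
  if (config$use_gcn) {
    Hw <- config$hidden
    dpool <- dx0[off + seq_len(Hw)]
    L <- nrow(ch$gcn$T_)
    dG <- matrix(0, L, Hw)
    dG[cbind(ch$gcn_pool$idx, seq_len(Hw))] <- dpool
    grads$gcn <- gcn_layer_bwd(dG, params$gcn, ch$gcn)$grads
  }
  grads
}

#' Decide a class label from a probability
#'
#' Strictly greater than the decision threshold; a probability exactly at
#' the threshold is classified negative.
#'
#' @param probability Numeric vector of probabilities in \[0, 1\].
#' @param threshold Decision threshold; default 0.35.
#' @return Integer vector of 0/1 labels.
#' @export
predict_label <- function(probability, threshold = 0.35) {
  as.integer(probability > threshold)
}

#' Class-weighted binary cross-entropy on logits
#'
#' Mean over samples of
#' `-(w_pos * y * log(sigmoid(p)) + (1 - y) * log(1 - sigmoid(p)))`,
#' evaluated in the numerically stable softplus form (never materialising
#' the sigmoid), with `w_pos` multiplying the positive-sample terms.
#'
#' @param logits Numeric vector of pre-sigmoid scores.
#' @param labels Binary 0/1 vector of the same length.
#' @param pos_weight Positive-class weight; default 10.
#' @return Scalar loss.
#' @export
weighted_bce_loss <- function(logits, labels, pos_weight = 10) {
  stopifnot(length(logits) == length(labels), all(labels %in% c(0, 1)))
  sp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))   # softplus, stable
  per <- pos_weight * labels * sp(-logits) + (1 - labels) * sp(logits)
  mean(per)
}

# d loss_i / d logit_i (per-sample, before the 1/N of the batch mean)
bce_logit_grad <- function(logit, label, pos_weight) {
  if (label == 1) pos_weight * (stats::plogis(logit) - 1)
  else stats::plogis(logit)
}

# ---- generic parameter-tree utilities -------------------------------------

params_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- Map(function(x, y) params_map2(f, x, y), a, b)
    attributes(out) <- attributes(a)
    out
  } else if (is.null(a)) NULL else f(a, b)
}

params_zero <- function(p) {
  if (is.list(p)) {
    out <- lapply(p, params_zero)
    attributes(out) <- attributes(p)
    out
  } else if (is.null(p)) NULL else p * 0
}

params_flatten <- function(p) {
  if (is.list(p)) unlist(lapply(p, params_flatten), use.names = FALSE)
  else if (is.null(p)) numeric(0) else as.vector(p)
}

params_unflatten <- function(p, vec) {
  i <- 0L
  fill <- function(x) {
    if (is.list(x)) {
      out <- lapply(x, fill)
      attributes(out) <- attributes(x)
      out
    } else if (is.null(x)) NULL else {
      n <- length(x)
      v <- vec[(i + 1L):(i + n)]
      i <<- i + n
      if (is.null(dim(x))) v else array(v, dim = dim(x))
    }
  }
  out <- fill(p)
  stopifnot(i == length(vec))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
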