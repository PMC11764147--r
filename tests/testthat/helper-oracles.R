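# Independent oracles and small fixture builders shared across tests. The
# oracles are deliberately written as plain loops, independent of the
# package's vectorised implementations.

# subset an il6_data bundle by row index
subset_bundle <- function(d, idx) subset_data(d, idx)

# random valid contact tensor (symmetric, rows of bins sum to 1)
random_contact_tensor <- function(L) {
  tens <- array(0, dim = c(L, L, 37))
  for (a in 1:L) for (b in a:L) {
    d <- stats::rgamma(37, shape = 0.5)
    d <- d / sum(d)
    tens[a, b, ] <- d
    tens[b, a, ] <- d
  }
  tens
}

# random connected-ish small graph: symmetric binary adjacency + self-loops
random_small_graph <- function(L, D) {
  adj <- matrix(stats::rbinom(L * L, 1, 0.5), L, L)
  adj <- pmax(adj, t(adj))
  diag(adj) <- 1
  list(adj = adj, X = matrix(stats::rnorm(L * D), L, D))
}

# parameters at a generic point (fresh inits sit exactly on ReLU kinks for
# "dead" nodes, where the loss is not differentiable)
generic_params <- function(config, jitter = 0.3) {
  p <- init_model_params(config)
  th <- il6gnn:::params_flatten(p)
  il6gnn:::params_unflatten(p, th + stats::rnorm(length(th), sd = jitter))
}

relu <- function(x) pmax(x, 0)

# brute-force single-head attention: explicit loops over i, j
oracle_attention <- function(H, adj, W_head, a_src, a_dst) {
  L <- nrow(H)
  alpha <- matrix(0, L, L)
  for (i in 1:L) {
    nb <- which(adj[i, ] == 1)
    logits <- sapply(nb, function(j) {
      relu(sum(a_src * drop(H[i, ] %*% W_head)) +
           sum(a_dst * drop(H[j, ] %*% W_head)))
    })
    e <- exp(logits - max(logits))
    alpha[i, nb] <- e / sum(e)
  }
  alpha
}

# brute-force full GAT layer: heads, per-head ReLU, concat, layer norm
oracle_gat_layer <- function(H, adj, layer) {
  K <- ncol(layer$a_src); dh <- nrow(layer$a_src); L <- nrow(H)
  out <- NULL
  for (k in 1:K) {
    cols <- ((k - 1) * dh + 1):(k * dh)
    Wk <- layer$W[, cols, drop = FALSE]
    alpha <- oracle_attention(H, adj, Wk, layer$a_src[, k], layer$a_dst[, k])
    M <- matrix(0, L, dh)
    for (i in 1:L) for (j in 1:L)
      M[i, ] <- M[i, ] + alpha[i, j] * drop(H[j, ] %*% Wk)
    out <- cbind(out, relu(M))
  }
  for (i in 1:L) {
    mu <- mean(out[i, ]); v <- mean((out[i, ] - mu)^2)
    out[i, ] <- (out[i, ] - mu) / sqrt(v + 1e-5) * layer$ln_gain +
      layer$ln_bias
  }
  out
}

# brute-force GCN layer
oracle_gcn_layer <- function(H, adj, W) {
  deg <- rowSums(adj)
  Dm <- diag(1 / sqrt(deg), nrow(adj))
  relu(Dm %*% adj %*% Dm %*% H %*% W)
}

# exhaustive pairwise AUC: wins + half ties over P * N
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# independent confusion-matrix metrics
oracle_metrics <- function(scores, labels, threshold) {
  pred <- ifelse(scores > threshold, 1, 0)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  sn <- tp / (tp + fn); sp <- tn / (tn + fp)
  den <- sqrt(as.numeric(tp + fp)) * sqrt(tp + fn) * sqrt(tn + fp) *
    sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
  list(tp = tp, fp = fp, tn = tn, fn = fn, sn = sn, sp = sp,
       bacc = (sn + sp) / 2, mcc = mcc)
}
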