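# The dual-channel network: attention, layer forwards, pooling, the full
# forward pass, the weighted loss, and the analytic gradients.

test_that("attention is a masked softmax over the neighbourhood", {
  set.seed(51)
  cfg <- model_config(input_dim = 6, hidden = 8, heads = 2, gat_layers = 1)
  p <- generic_params(cfg)
  layer <- p$gat[[1]]

  # a node whose only neighbour is itself gets alpha_ii = 1
  H1 <- matrix(rnorm(6), 1, 6)
  a1 <- gat_attention(H1, matrix(1, 1, 1), layer, head = 1)
  expect_equal(a1[1, 1], 1)

  # two fully connected nodes with identical features split 0.5 / 0.5
  H2 <- rbind(H1, H1)
  a2 <- gat_attention(H2, matrix(1, 2, 2), layer, head = 2)
  expect_equal(as.vector(a2), rep(0.5, 4))

  # random graphs match the exhaustive loop oracle; rows sum to 1
  for (rep in 1:10) {
    g <- random_small_graph(5, 6)
    for (k in 1:2) {
      a <- gat_attention(g$X, g$adj, layer, head = k)
      cols <- ((k - 1) * 4 + 1):(k * 4)
      ora <- oracle_attention(g$X, g$adj, layer$W[, cols, drop = FALSE],
                              layer$a_src[, k], layer$a_dst[, k])
      expect_equal(a, ora, tolerance = 1e-12)
      expect_equal(unname(rowSums(a)), rep(1, 5))
      expect_true(all(a[g$adj == 0] == 0))
    }
  }
})

test_that("GAT layer forward equals the dense oracle and is equivariant", {
  set.seed(52)
  cfg <- model_config(input_dim = 5, hidden = 8, heads = 4, gat_layers = 1)
  p <- generic_params(cfg)
  layer <- p$gat[[1]]

  # 4-node path graph against the explicit oracle
  adj <- diag(4)
  for (i in 1:3) adj[i, i + 1] <- adj[i + 1, i] <- 1
  H <- matrix(rnorm(20), 4, 5)
  expect_equal(gat_layer_forward(H, adj, layer),
               oracle_gat_layer(H, adj, layer), tolerance = 1e-10)

  # single self-looped node: layernorm(relu(W' h)) per head
  H1 <- matrix(rnorm(5), 1, 5)
  out1 <- gat_layer_forward(H1, matrix(1, 1, 1), layer)
  expect_equal(out1, oracle_gat_layer(H1, matrix(1, 1, 1), layer),
               tolerance = 1e-10)

  # node permutation permutes the output rows identically
  for (rep in 1:5) {
    g <- random_small_graph(6, 5)
    perm <- sample(6)
    out <- gat_layer_forward(g$X, g$adj, layer)
    out_p <- gat_layer_forward(g$X[perm, ], g$adj[perm, perm], layer)
    expect_equal(out_p, out[perm, ], tolerance = 1e-10)
  }
})

test_that("GCN layer matches the normalised-adjacency oracle", {
  set.seed(53)
  cfg <- model_config(input_dim = 4, hidden = 6, heads = 2, use_gat = FALSE)
  p <- generic_params(cfg)

  # single self-looped node with identity weight: relu(H)
  pI <- p; pI$gcn$W <- diag(4)[, c(1:4, 1, 2)]   # 4 x 6 pseudo-identity
  H1 <- matrix(c(-1, 2, -3, 4), 1, 4)
  expect_equal(gcn_layer_forward(H1, matrix(1, 1, 1), pI$gcn),
               pmax(H1 %*% pI$gcn$W, 0))

  # two identical fully connected nodes give identical rows
  H2 <- matrix(rnorm(4), 2, 4, byrow = TRUE)
  H2[2, ] <- H2[1, ]
  out2 <- gcn_layer_forward(H2, matrix(1, 2, 2), p$gcn)
  expect_equal(out2[1, ], out2[2, ])

  # random 6-node graphs against the explicit dense oracle
  for (rep in 1:10) {
    g <- random_small_graph(6, 4)
    expect_equal(gcn_layer_forward(g$X, g$adj, p$gcn),
                 oracle_gcn_layer(g$X, g$adj, p$gcn$W), tolerance = 1e-10)
  }
})

test_that("global max pooling is columnwise and order-invariant", {
  expect_equal(global_max_pool(matrix(c(1, 3, 5, 2), 2, 2)), c(3, 5))
  H <- matrix(rnorm(12), 4, 3)
  expect_equal(global_max_pool(H[sample(4), ]), global_max_pool(H))
  expect_equal(global_max_pool(H[2, , drop = FALSE]), H[2, ])
  expect_error(global_max_pool(H[0, , drop = FALSE]), "empty")
})

test_that("full forward is deterministic, saturates, and matches a scripted oracle", {
  set.seed(54)
  cfg <- model_config(input_dim = 5, hidden = 8, heads = 2, gat_layers = 2,
                      dropout = 0.5)
  p <- generic_params(cfg)
  g <- random_small_graph(3, 5)
  pg <- structure(list(id = "t", X = g$X, adj = g$adj, label = 1L),
                  class = "peptide_graph")

  # no dropout at inference: bit-identical repeated outputs
  o1 <- forward(pg, p, cfg, training = FALSE)
  o2 <- forward(pg, p, cfg, training = FALSE)
  expect_identical(o1, o2)

  # huge final bias saturates the sigmoid
  psat <- p; psat$cls$b4 <- 1e4
  expect_equal(forward(pg, psat, cfg)$prob, 1)
  psat$cls$b4 <- -1e4
  expect_equal(forward(pg, psat, cfg)$prob, 0)

  # straight-line scripted recomputation of the whole pipeline
  H <- g$X
  for (l in 1:2) H <- oracle_gat_layer(H, g$adj, p$gat[[l]])
  x0 <- c(apply(H, 2, max),
          apply(oracle_gcn_layer(g$X, g$adj, p$gcn$W), 2, max))
  a <- x0
  for (i in 1:3)
    a <- pmax(drop(a %*% p$cls[[paste0("W", i)]]) + p$cls[[paste0("b", i)]],
              0)
  logit <- drop(a %*% p$cls$W4) + p$cls$b4
  expect_equal(o1$logit, logit, tolerance = 1e-10)
  expect_equal(o1$prob, 1 / (1 + exp(-logit)), tolerance = 1e-10)
})

test_that("the whole-graph logit is invariant under node permutation", {
  set.seed(55)
  cfg <- model_config(input_dim = 6, hidden = 8, heads = 2, gat_layers = 3)
  p <- generic_params(cfg)
  for (rep in 1:8) {
    L <- sample(2:7, 1)
    g <- random_small_graph(L, 6)
    perm <- sample(L)
    f0 <- il6gnn:::forward_graph(g$X, g$adj, p, cfg)$logit
    f1 <- il6gnn:::forward_graph(g$X[perm, , drop = FALSE],
                                 g$adj[perm, perm, drop = FALSE], p,
                                 cfg)$logit
    expect_equal(f1, f0, tolerance = 1e-10)
  }
})

test_that("channel ablations shrink the fused vector", {
  set.seed(56)
  g <- random_small_graph(4, 6)
  for (spec in list(list(gat = TRUE, gcn = FALSE),
                    list(gat = FALSE, gcn = TRUE))) {
    cfg <- model_config(input_dim = 6, hidden = 8, heads = 2,
                        use_gat = spec$gat, use_gcn = spec$gcn)
    p <- generic_params(cfg)
    fw <- il6gnn:::forward_graph(g$X, g$adj, p, cfg)
    expect_length(fw$caches$x0, 8)
    expect_equal(nrow(p$cls$W1), 8)
  }
  expect_error(model_config(use_gat = FALSE, use_gcn = FALSE),
               "at least one channel")
})

test_that("weighted BCE matches closed forms and is stable", {
  # sigma(p) = 0.5 at logit 0
  expect_equal(weighted_bce_loss(0, 0), log(2))
  expect_equal(weighted_bce_loss(0, 1, pos_weight = 10), 10 * log(2))
  # saturation: confident correct prediction -> loss ~ 0
  expect_lt(weighted_bce_loss(40, 1), 1e-10)
  expect_lt(weighted_bce_loss(-40, 0), 1e-10)
  # extreme logits stay finite (log-sum-exp form)
  expect_true(is.finite(weighted_bce_loss(-1000, 1)))
  expect_true(is.finite(weighted_bce_loss(1000, 0)))
  # mean over a batch, weight only on positives
  expect_equal(weighted_bce_loss(c(0, 0), c(1, 0), pos_weight = 10),
               (10 * log(2) + log(2)) / 2)
  expect_gte(weighted_bce_loss(rnorm(5), rbinom(5, 1, 0.5)), 0)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(57)
  cfg <- model_config(input_dim = 5, hidden = 8, heads = 2, gat_layers = 2,
                      dropout = 0)
  p <- generic_params(cfg)
  g <- random_small_graph(4, 5)
  theta <- il6gnn:::params_flatten(p)
  for (y in c(0, 1)) {
    loss_fn <- function(th) {
      pp <- il6gnn:::params_unflatten(p, th)
      fw <- il6gnn:::forward_graph(g$X, g$adj, pp, cfg)
      weighted_bce_loss(fw$logit, y, cfg$pos_weight)
    }
    fw <- il6gnn:::forward_graph(g$X, g$adj, p, cfg)
    dlogit <- il6gnn:::bce_logit_grad(fw$logit, y, cfg$pos_weight)
    ana <- il6gnn:::params_flatten(
      il6gnn:::backward_graph(dlogit, fw, p, cfg))
    idx <- sample(length(theta), 80)
    eps <- 1e-6
    num <- vapply(idx, function(i) {
      t1 <- theta; t2 <- theta
      t1[i] <- t1[i] + eps; t2[i] <- t2[i] - eps
      (loss_fn(t1) - loss_fn(t2)) / (2 * eps)
    }, 1.0)
    expect_equal(ana[idx], num, tolerance = 1e-4)
  }
})

test_that("label prediction uses a strict threshold", {
  expect_equal(predict_label(0.36), 1L)
  expect_equal(predict_label(0.35), 0L)   # boundary is negative
  expect_equal(predict_label(0.34), 0L)
  expect_equal(predict_label(c(0.9, 0.1), threshold = 0.5), c(1L, 0L))
})
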