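# Training loop, metrics, cross-validation, grid search, feature export.

make_toy_graphs <- function(n = 16, seed = 61, sep = 3) {
  # tiny linearly separable graph set: class encoded in the feature mean
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    lab <- as.integer(i <= n / 2)
    L <- sample(3:5, 1)
    g <- random_small_graph(L, 10)
    g$X <- g$X + if (lab == 1) sep else -sep
    structure(list(id = paste0("t", i), X = g$X, adj = g$adj, label = lab),
              class = "peptide_graph")
  })
}

test_that("the learning-rate schedule follows its closed form", {
  tc <- train_config()
  expect_equal(learning_rate_at(10, tc), 0.001 * 0.95^2)
  expect_equal(learning_rate_at(1, tc), 0.001)
  expect_equal(learning_rate_at(4, tc), 0.001)
  expect_equal(learning_rate_at(5, tc), 0.001 * 0.95)
  expect_equal(learning_rate_at(40, tc), 0.001 * 0.95^8)
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(lr = -1), "positive")
})

test_that("training is seed-deterministic and can overfit a toy set", {
  graphs <- make_toy_graphs()
  cfg <- model_config(input_dim = 10, dropout = 0)
  tc <- train_config(epochs = 50, batch_size = 4, seed = 99)   # 200 steps
  r1 <- train_model(graphs, cfg, tc)
  r2 <- train_model(graphs, cfg, tc)
  expect_identical(r1$params, r2$params)
  expect_identical(r1$history, r2$history)
  # loss collapses well below its initial value (trainability)
  expect_lt(tail(r1$history$loss, 1), 0.1 * r1$history$loss[1])
  # and the RNG state of the session is not disturbed
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(train_model(graphs, cfg,
                                     train_config(epochs = 1, seed = 2)))
  expect_identical(rnorm(1), before)

  expect_error(train_model(list(), cfg, tc), "empty")
  one_class <- graphs[1:8]
  expect_warning(train_model(one_class, cfg,
                             train_config(epochs = 1, seed = 1)),
                 "single class")
})

test_that("metrics reproduce closed-form and oracle values", {
  # printed-table identity: BACC is the mean of SN and SP
  expect_equal(round_half_up((0.876 + 0.799) / 2), 0.838)

  # perfect separation
  r <- compute_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(r$sn, 1); expect_equal(r$sp, 1)
  expect_equal(r$bacc, 1); expect_equal(r$mcc, 1); expect_equal(r$auc, 1)

  # TP=3, FP=1, TN=5, FN=1 -> MCC = 14/24
  scores <- c(rep(0.9, 3), 0.1, rep(0.1, 5), 0.9)
  labels <- c(rep(1, 3), 1, rep(0, 5), 0)
  r2 <- compute_metrics(scores, labels, threshold = 0.5)
  expect_equal(unname(r2$counts), c(3L, 1L, 5L, 1L))
  expect_equal(r2$mcc, (3 * 5 - 1 * 1) / sqrt(4 * 4 * 6 * 6))
  expect_equal(r2$mcc, 14 / 24)

  # all-one-sided predictions give MCC 0 by convention
  r3 <- compute_metrics(c(0.9, 0.9), c(1, 0), threshold = 0.5)
  expect_equal(r3$mcc, 0)

  expect_error(compute_metrics(numeric(0), numeric(0)), "empty")
})

test_that("metrics agree with an independent confusion oracle", {
  set.seed(62)
  for (rep in 1:200) {
    n <- sample(5:40, 1)
    scores <- runif(n)
    labels <- rbinom(n, 1, 0.5)
    th <- runif(1)
    r <- compute_metrics(scores, labels, threshold = th)
    o <- oracle_metrics(scores, labels, th)
    expect_equal(unname(r$counts), c(o$tp, o$fp, o$tn, o$fn))
    expect_equal(r$mcc, o$mcc)
    if (!is.nan(r$bacc)) {
      expect_equal(r$bacc, o$bacc)
      expect_equal(r$bacc, (r$sn + r$sp) / 2)   # identity always holds
    }
  }
})

test_that("AUC is the midrank Mann-Whitney statistic", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_score(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auc_score(c(0.1, 0.2), c(1, 1)), "both classes")
  set.seed(63)
  for (rep in 1:50) {
    n <- sample(4:30, 1)
    scores <- round(runif(n), 1)   # force ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(auc_score(scores, labels), oracle_auc(scores, labels))
  }
  # independent library cross-check (trapezoidal ROC equals midrank MW)
  set.seed(64)
  scores <- runif(40); labels <- rbinom(40, 1, 0.4)
  expect_equal(auc_score(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              levels = c(0, 1),
                                              direction = "<",
                                              quiet = TRUE))))
})

test_that("cross-validation folds are stratified, disjoint and exhaustive", {
  graphs <- make_toy_graphs(n = 50, seed = 64)
  cfg <- model_config(input_dim = 10, hidden = 8, heads = 2)
  tc <- train_config(epochs = 1, batch_size = 16, seed = 7)
  cv <- cross_validate(graphs, k = 5, config = cfg, tconfig = tc)
  labels <- vapply(graphs, `[[`, 1L, "label")
  expect_length(cv$folds, 5)
  # each fold tests exactly 10 of the 50
  expect_equal(as.integer(table(cv$assignments)), rep(10L, 5))
  # fold label proportions within one sample of the global proportion
  for (f in 1:5)
    expect_lte(abs(sum(labels[cv$assignments == f]) - 5), 1)
  # metrics averaged over folds
  expect_equal(cv$mean$auc,
               mean(vapply(cv$folds, `[[`, 1.0, "auc")))
  expect_error(cross_validate(graphs, k = 30, config = cfg, tconfig = tc),
               "smaller class")
})

test_that("grid search picks the dominant configuration, first on ties", {
  graphs <- make_toy_graphs(n = 24, seed = 65)
  cfg <- model_config(input_dim = 10, hidden = 8, heads = 2, dropout = 0)
  tc <- train_config(epochs = 8, batch_size = 8, seed = 11)
  # an effectively frozen model (lr ~ 0) cannot beat a trained one on a
  # separable set
  gs <- grid_search(graphs, list(list(lr = 1e-12), list(lr = 0.005)),
                    config = cfg, tconfig = tc, k = 2)
  expect_equal(gs$best_index, 2L)
  expect_gt(gs$auc[2], gs$auc[1])
  # identical configs tie; the earlier one is returned
  gs2 <- grid_search(graphs, list(list(lr = 0.005), list(lr = 0.005)),
                     config = cfg, tconfig = tc, k = 2)
  expect_equal(gs2$best_index, 1L)
  expect_equal(gs2$auc[1], gs2$auc[2])
  # single-entry grid returns that entry
  gs3 <- grid_search(graphs, list(list(epochs = 1)), config = cfg,
                     tconfig = tc, k = 2)
  expect_equal(gs3$best_index, 1L)
  expect_error(grid_search(graphs, list(), cfg, tc), "empty grid")
})

test_that("threshold selection maximises balanced accuracy", {
  scores <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  labels <- c(0, 0, 0, 1, 1, 1)
  th <- select_threshold(scores, labels)
  expect_equal(compute_metrics(scores, labels, th)$bacc, 1)
  expect_lt(th, 0.7); expect_gte(th, 0.3)
})

test_that("fused-feature export is normalised and labelled by channel", {
  set.seed(66)
  cfg <- model_config(input_dim = 6, hidden = 8, heads = 2, gat_layers = 1)
  p <- generic_params(cfg)
  graphs <- lapply(1:5, function(i) {
    g <- random_small_graph(4, 6)
    structure(list(id = paste0("g", i), X = g$X, adj = g$adj, label = 0L),
              class = "peptide_graph")
  })
  feats <- export_fused_features(p, cfg, graphs)
  expect_equal(dim(feats), c(5L, 16L))
  expect_equal(attr(feats, "channel"), rep(c("GAT", "GCN"), each = 8))
  expect_equal(colnames(feats)[1], "gat_0")
  expect_equal(colnames(feats)[16], "gcn_15")
  expect_true(all(feats >= 0 & feats <= 1))
  # every non-constant column attains both 0 and 1 after min-max scaling
  spans <- apply(feats, 2, function(x) diff(range(x)))
  expect_true(all(abs(apply(feats[, spans > 0, drop = FALSE], 2, min)) <
                    1e-12))
})

test_that("ablation widths and guards are enforced", {
  expect_equal(il6gnn:::feature_width(feature_config(onehot = FALSE)), 50L)
  expect_equal(il6gnn:::feature_width(feature_config(embedding = FALSE)),
               40L)
  expect_equal(il6gnn:::fused_width(model_config(use_gat = FALSE)), 64L)
  expect_error(feature_config(FALSE, FALSE, FALSE), "at least one")
})

test_that("reporting rounds half away from zero", {
  expect_equal(round_half_up(0.8375), 0.838)
  expect_equal(round_half_up(0.8125), 0.813)
  expect_equal(round_half_up(-0.8375), -0.838)
  expect_equal(round_half_up(0.77149999), 0.771)
})
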