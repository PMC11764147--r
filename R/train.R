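# Training loop (Adam, stepped learning-rate decay, class-weighted loss),
# imbalance-aware metrics, stratified cross-validation, grid search and
# fused-feature export.

#' Training configuration
#'
#' Defaults follow the published protocol: Adam, initial learning rate
#' 0.001 reduced by 5 percent every 5 epochs, 40 epochs, batch size 256,
#' positive-class loss weight 10.
#'
#' @param lr Initial learning rate.
#' @param lr_decay Multiplicative decay factor; default 0.95.
#' @param decay_every Epoch interval between decays; default 5.
#' @param epochs Number of epochs (>= 1); default 40.
#' @param batch_size Graphs per gradient step; default 256.
#' @param seed RNG seed controlling initialisation, shuffling and dropout.
#' @return A list of class `il6gnn_train_config`.
#' @export
train_config <- function(lr = 0.001, lr_decay = 0.95, decay_every = 5L,
                         epochs = 40L, batch_size = 256L, seed = 1L) {
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (lr <= 0 || lr_decay <= 0 || batch_size < 1L || decay_every < 1L)
    stop("training config values must be positive", call. = FALSE)
  structure(list(lr = lr, lr_decay = lr_decay,
                 decay_every = as.integer(decay_every),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "il6gnn_train_config")
}

#' Learning rate at a given epoch
#'
#' Closed form of the stepped schedule:
#' `lr * lr_decay^floor(epoch / decay_every)` with 1-based epochs, so the
#' rate at epoch 10 under the defaults is `0.001 * 0.95^2`.
#'
#' @param epoch Epoch number (1-based).
#' @param config An `il6gnn_train_config`.
#' @return The learning rate in effect during that epoch.
#' @export
learning_rate_at <- function(epoch, config = train_config()) {
  config$lr * config$lr_decay^(epoch %/% config$decay_every)
}

with_preserved_seed <- function(expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  expr
}

#' Train the dual-channel model
#'
#' Mini-batch Adam with the stepped learning-rate schedule and the
#' class-weighted binary cross-entropy of [weighted_bce_loss()]. Dropout is
#' active during training. Fully reproducible from `tconfig$seed`.
#'
#' @param graphs List of labelled `peptide_graph`s.
#' @param config An `il6gnn_config` matching the graph feature width.
#' @param tconfig An `il6gnn_train_config`.
#' @param params Optional warm-start parameters; fresh Glorot init otherwise.
#' @param verbose Print per-epoch loss.
#' @return List with `params` (trained `model_params`) and `history`
#'   (data.frame of epoch, learning rate, mean training loss).
#' @export
train_model <- function(graphs, config, tconfig = train_config(),
                        params = NULL, verbose = FALSE) {
  if (length(graphs) == 0L) stop("empty training set", call. = FALSE)
  labels <- vapply(graphs, function(g) as.integer(g$label), 1L)
  if (anyNA(labels)) stop("all training graphs need labels", call. = FALSE)
  if (length(unique(labels)) < 2L)
    warning("training set contains a single class", call. = FALSE)
  with_preserved_seed({
    set.seed(tconfig$seed)
    if (is.null(params)) params <- init_model_params(config)
    check_params_shapes(params, config)
    theta <- params_flatten(params)
    m <- numeric(length(theta)); v <- numeric(length(theta))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0L
    n <- length(graphs)
    history <- data.frame(epoch = integer(), lr = numeric(),
                          loss = numeric())
    for (epoch in seq_len(tconfig$epochs)) {
      lr <- learning_rate_at(epoch, tconfig)
      ord <- sample.int(n)
      starts <- seq(1L, n, by = tconfig$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + tconfig$batch_size - 1L, n)]
        bs <- length(idx)
        acc <- NULL
        batch_loss <- 0
        for (gi in idx) {
          g <- graphs[[gi]]
          fw <- forward_graph(g$X, g$adj, params, config, training = TRUE)
          batch_loss <- batch_loss +
            weighted_bce_loss(fw$logit, g$label, config$pos_weight)
          dlogit <- bce_logit_grad(fw$logit, g$label, config$pos_weight) / bs
          gr <- backward_graph(dlogit, fw, params, config)
          acc <- if (is.null(acc)) gr
                 else params_map2(`+`, acc, gr)
        }
        epoch_loss <- epoch_loss + batch_loss
        gvec <- params_flatten(acc)
        step <- step + 1L
        m <- b1 * m + (1 - b1) * gvec
        v <- b2 * v + (1 - b2) * gvec^2
        mhat <- m / (1 - b1^step)
        vhat <- v / (1 - b2^step)
        theta <- theta - lr * mhat / (sqrt(vhat) + eps)
        params <- params_unflatten(params, theta)
      }
      mean_loss <- epoch_loss / n
      history <- rbind(history,
                       data.frame(epoch = epoch, lr = lr, loss = mean_loss))
      if (verbose)
        message(sprintf("epoch %3d  lr %.6f  loss %.5f", epoch, lr,
                        mean_loss))
    }
    list(params = params, history = history)
  })
}

#' Score graphs with a trained model
#'
#' Deterministic forward passes (dropout off).
#'
#' @param graphs List of `peptide_graph`s.
#' @param params Trained `model_params`.
#' @param config Matching `il6gnn_config`.
#' @return Numeric vector of positive-class probabilities, named by id.
#' @export
score_graphs <- function(graphs, params, config) {
  p <- vapply(graphs,
              function(g) forward_graph(g$X, g$adj, params, config)$prob,
              1.0)
  names(p) <- vapply(graphs, `[[`, "", "id")
  p
}

# ---- metrics ---------------------------------------------------------------

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic with
#' midrank handling of ties (a tied positive/negative pair counts one half).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0L || N == 0L)
    stop("AUC needs both classes present", call. = FALSE)
  r <- rank(scores)   # midranks
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Confusion-based performance metrics
#'
#' Classifies each score with the strict-\code{>} decision threshold, then
#' reports sensitivity SN = TP/(TP+FN), specificity SP = TN/(TN+FP),
#' balanced accuracy BACC = (SN+SP)/2, the Matthews correlation coefficient
#' (0 when any factor of its denominator vanishes) and the rank-based AUC.
#'
#' @param scores Numeric probabilities/scores.
#' @param labels Binary 0/1 ground-truth labels.
#' @param threshold Decision threshold; default 0.35.
#' @return A `metrics_report`: list with `bacc`, `sn`, `sp`, `mcc`, `auc`
#'   and `counts` (TP, FP, TN, FN).
#' @export
compute_metrics <- function(scores, labels, threshold = 0.35) {
  if (length(scores) == 0L) stop("empty input", call. = FALSE)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  pred <- predict_label(scores, threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  sn <- if (tp + fn > 0) tp / (tp + fn) else NaN
  sp <- if (tn + fp > 0) tn / (tn + fp) else NaN
  denom2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 == 0) 0
         else (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom2)
  auc <- if (length(unique(labels)) == 2L) auc_score(scores, labels)
         else NA_real_
  structure(list(bacc = (sn + sp) / 2, sn = sn, sp = sp, mcc = mcc,
                 auc = auc,
                 counts = c(TP = tp, FP = fp, TN = tn, FN = fn)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat(sprintf("BACC %.*f  SN %.*f  SP %.*f  MCC %.*f  AUC %s\n",
              digits, x$bacc, digits, x$sn, digits, x$sp, digits, x$mcc,
              if (is.na(x$auc)) "NA" else sprintf("%.*f", digits, x$auc)))
  cat(sprintf("counts: TP %d  FP %d  TN %d  FN %d\n",
              x$counts["TP"], x$counts["FP"], x$counts["TN"],
              x$counts["FN"]))
  invisible(x)
}

#' Round metric values for reporting
#'
#' Half-away-from-zero rounding to `digits` decimals, the convention used
#' for printed benchmark tables.
#'
#' @param x Numeric vector.
#' @param digits Decimal places; default 3.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Select a decision threshold by balanced accuracy
#'
#' Scans a threshold grid and returns the value maximising BACC on the
#' supplied scores (typically cross-validated or validation-set scores);
#' ties go to the smallest threshold. This mirrors how a deployment
#' threshold is chosen on imbalanced data rather than defaulting to 0.5.
#'
#' @param scores Numeric scores.
#' @param labels Binary 0/1 labels.
#' @param grid Candidate thresholds; default `seq(0.05, 0.95, by = 0.05)`.
#' @return The selected threshold (scalar).
#' @export
select_threshold <- function(scores, labels,
                             grid = seq(0.05, 0.95, by = 0.05)) {
  baccs <- vapply(grid, function(th) {
    r <- compute_metrics(scores, labels, threshold = th)
    if (is.nan(r$bacc)) -Inf else r$bacc
  }, 1.0)
  grid[which.max(baccs)]
}

# ---- cross-validation / grid search ---------------------------------------

stratified_folds <- function(labels, k, seed) {
  counts <- table(labels)
  if (k > min(counts))
    stop("k = ", k, " exceeds the size of the smaller class (",
         min(counts), ")", call. = FALSE)
  fold <- integer(length(labels))
  with_preserved_seed({
    set.seed(seed)
    for (cl in names(counts)) {
      idx <- sample(which(labels == as.integer(cl)))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation
#'
#' Seeded, label-stratified folds; every graph is tested exactly once.
#'
#' @param graphs List of labelled `peptide_graph`s (both classes present).
#' @param k Number of folds; default 5.
#' @param config Model configuration.
#' @param tconfig Training configuration (its seed also controls the fold
#'   assignment).
#' @return List with `folds` (per-fold `metrics_report`s), `mean` (averaged
#'   metric values), and `assignments` (fold index per graph).
#' @export
cross_validate <- function(graphs, k = 5L, config, tconfig = train_config()) {
  labels <- vapply(graphs, function(g) as.integer(g$label), 1L)
  fold <- stratified_folds(labels, k, tconfig$seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- graphs[fold != f]
    te <- graphs[fold == f]
    fit <- train_model(tr, config, tconfig)
    sc <- score_graphs(te, fit$params, config)
    reports[[f]] <- compute_metrics(sc, labels[fold == f],
                                    config$threshold)
  }
  keys <- c("bacc", "sn", "sp", "mcc", "auc")
  avg <- vapply(keys, function(kk)
    mean(vapply(reports, `[[`, 1.0, kk)), 1.0)
  list(folds = reports, mean = as.list(avg), assignments = fold)
}

#' Grid search over configuration overrides
#'
#' Evaluates every candidate by cross-validated mean AUC under an identical
#' seed and returns the best; ties go to the earlier grid entry.
#'
#' @param graphs Labelled graphs.
#' @param grid A list of named lists; each entry overrides fields of
#'   `config` and/or `tconfig` (e.g. `list(heads = 4, lr = 0.01)`).
#' @param config,tconfig Baseline configurations.
#' @param k Folds per evaluation; default 3.
#' @return List with `best` (the winning overrides), `best_index`,
#'   `auc` (vector of mean AUCs in grid order) and `results`.
#' @export
grid_search <- function(graphs, grid, config, tconfig = train_config(),
                        k = 3L) {
  if (length(grid) == 0L) stop("empty grid", call. = FALSE)
  results <- vector("list", length(grid))
  aucs <- numeric(length(grid))
  for (i in seq_along(grid)) {
    ov <- grid[[i]]
    cfg <- utils::modifyList(config, ov[names(ov) %in% names(config)])
    cfg <- as_model_config(cfg)
    tcf <- utils::modifyList(tconfig, ov[names(ov) %in% names(tconfig)])
    class(tcf) <- class(tconfig)
    cv <- cross_validate(graphs, k = k, config = cfg, tconfig = tcf)
    results[[i]] <- cv
    aucs[i] <- cv$mean$auc
  }
  best <- which.max(aucs)   # first maximum wins ties
  list(best = grid[[best]], best_index = best, auc = aucs,
       results = results)
}

# ---- fused-feature export --------------------------------------------------

#' Export fused dual-channel features
#'
#' Runs each graph through the trained channels and returns the fused
#' pre-classifier vector (GAT features first, then GCN features), min-max
#' normalised per column across the peptide set; a constant column maps to
#' 0. The `"channel"` attribute labels each column's provenance.
#'
#' @param params Trained `model_params`.
#' @param config Matching `il6gnn_config`.
#' @param graphs List of `peptide_graph`s.
#' @return N x F numeric matrix (F = 128 with both channels), rows named by
#'   peptide id, with attribute `channel`.
#' @export
export_fused_features <- function(params, config, graphs) {
  feats <- t(vapply(graphs, function(g)
    forward_graph(g$X, g$adj, params, config)$caches$x0,
    numeric(fused_width(config))))
  rownames(feats) <- vapply(graphs, `[[`, "", "id")
  rng <- apply(feats, 2, range)
  span <- rng[2, ] - rng[1, ]
  norm <- sweep(feats, 2, rng[1, ])
  norm <- sweep(norm, 2, ifelse(span > 0, span, 1), `/`)
  norm[, span == 0] <- 0
  channel <- character(0)
  if (config$use_gat) channel <- rep("GAT", config$hidden)
  if (config$use_gcn) channel <- c(channel, rep("GCN", config$hidden))
  colnames(norm) <- paste0(tolower(channel), "_",
                           seq_along(channel) - 1L)
  attr(norm, "channel") <- channel
  norm
}
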