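# The modelling front-end: one fitting function returning a classed object
# with the usual method set. Everything it does is a composition of the
# exported pipeline pieces (build_graphs / train_model / score_graphs), so
# power users can drop down a level at any point.

#' Fit the dual-channel graph classifier
#'
#' Builds peptide graphs from the bundle (thresholded contact maps, fused
#' node features; the embedding PCA is fitted on this training bundle
#' only), then trains the dual-channel GAT + GCN network with class-weighted
#' binary cross-entropy under the stepped Adam schedule.
#'
#' @param data An [il6_data()] bundle with labels on every peptide, or a
#'   list of prebuilt labelled `peptide_graph`s.
#' @param fconfig Feature-block configuration; see [feature_config()].
#' @param config Model configuration; see [model_config()]. Its
#'   `input_dim` is aligned with the feature width automatically.
#' @param tconfig Training configuration; see [train_config()].
#' @param contact_threshold Contact threshold for adjacency; default 0.8.
#' @param bin_range Short-range distance-bin window; default `c(1, 13)`.
#' @param verbose Print per-epoch loss.
#' @return An object of class `il6gnn`: the trained parameters, the fitted
#'   PCA projection, all configuration, the training history, and the
#'   training-set scores.
#' @examples
#' cfg <- synthetic_config(n_peptides = 24, embedding_dim = 40, seed = 7)
#' d <- generate_dataset(cfg)
#' fit <- il6gnn(d, tconfig = train_config(epochs = 2, batch_size = 8,
#'                                         seed = 7))
#' predict(fit, d, type = "label")
#' @export
il6gnn <- function(data, fconfig = feature_config(),
                   config = model_config(), tconfig = train_config(),
                   contact_threshold = 0.8, bin_range = c(1L, 13L),
                   verbose = FALSE) {
  cl <- match.call()
  if (inherits(data, "il6_data")) {
    if (anyNA(data$manifest$label))
      stop("every peptide needs a label for fitting", call. = FALSE)
    built <- build_graphs(data, fconfig, contact_threshold, bin_range)
    graphs <- built$graphs
    pca <- built$pca
    input_dim <- built$input_dim
  } else if (is.list(data) && all(vapply(data, inherits, TRUE,
                                         "peptide_graph"))) {
    graphs <- data
    pca <- NULL
    input_dim <- ncol(graphs[[1]]$X)
  } else stop("data must be an il6_data bundle or a list of peptide_graphs",
              call. = FALSE)
  config$input_dim <- input_dim
  config <- as_model_config(config)
  trained <- train_model(graphs, config, tconfig, verbose = verbose)
  scores <- score_graphs(graphs, trained$params, config)
  labels <- vapply(graphs, function(g) as.integer(g$label), 1L)
  structure(list(params = trained$params, config = config,
                 tconfig = tconfig, fconfig = fconfig, pca = pca,
                 contact_threshold = contact_threshold,
                 bin_range = bin_range, history = trained$history,
                 fitted_scores = scores, labels = labels, call = cl),
            class = "il6gnn")
}

graphs_from_newdata <- function(object, newdata) {
  if (inherits(newdata, "il6_data")) {
    if (object$fconfig$embedding && is.null(object$pca))
      stop("model was fitted on prebuilt graphs; supply peptide_graphs",
           call. = FALSE)
    build_graphs(newdata, object$fconfig, object$contact_threshold,
                 object$bin_range, pca = object$pca)$graphs
  } else if (is.list(newdata) && all(vapply(newdata, inherits, TRUE,
                                            "peptide_graph"))) {
    newdata
  } else stop("newdata must be an il6_data bundle or peptide_graphs",
              call. = FALSE)
}

#' Predict from a fitted classifier
#'
#' @param object An `il6gnn` fit.
#' @param newdata An `il6_data` bundle or list of `peptide_graph`s; the
#'   training scores are reused when omitted.
#' @param type `"prob"` (sigmoid probabilities, default), `"label"`
#'   (strict-`>` thresholding at the configured decision threshold),
#'   `"logit"`, or `"fused"` (the 128-dimensional pre-classifier feature
#'   matrix via [export_fused_features()]).
#' @param ... Unused.
#' @return Named numeric/integer vector, or a matrix for `type = "fused"`.
#' @export
predict.il6gnn <- function(object, newdata = NULL,
                           type = c("prob", "label", "logit", "fused"),
                           ...) {
  type <- match.arg(type)
  if (is.null(newdata) && type == "prob") return(object$fitted_scores)
  graphs <- if (is.null(newdata)) NULL else
    graphs_from_newdata(object, newdata)
  if (type == "fused") {
    if (is.null(graphs)) stop("type = 'fused' needs newdata", call. = FALSE)
    return(export_fused_features(object$params, object$config, graphs))
  }
  probs <- if (is.null(graphs)) object$fitted_scores
           else score_graphs(graphs, object$params, object$config)
  switch(type,
         prob = probs,
         label = stats::setNames(predict_label(probs,
                                               object$config$threshold),
                                 names(probs)),
         logit = stats::qlogis(probs))
}

#' @export
print.il6gnn <- function(x, ...) {
  cfg <- x$config
  cat("Dual-channel graph classifier of IL-6-inducing peptides\n")
  cat(sprintf("  channels: %s (fused width %d)\n",
              paste(c(if (cfg$use_gat)
                        sprintf("%d-layer %d-head GAT", cfg$gat_layers,
                                cfg$heads),
                      if (cfg$use_gcn) "1-layer GCN"), collapse = " + "),
              fused_width(cfg)))
  cat(sprintf("  node features: %d-dim; decision threshold %.2f\n",
              cfg$input_dim, cfg$threshold))
  cat(sprintf("  trained %d epochs on %d peptides (%d positive); final loss %.4f\n",
              nrow(x$history), length(x$labels), sum(x$labels),
              utils::tail(x$history$loss, 1)))
  invisible(x)
}

#' @export
summary.il6gnn <- function(object, ...) {
  rep <- compute_metrics(object$fitted_scores, object$labels,
                         object$config$threshold)
  out <- list(fit = object, train_metrics = rep,
              n_params = length(params_flatten(object$params)))
  class(out) <- "summary.il6gnn"
  out
}

#' @export
print.summary.il6gnn <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  learnable parameters: %d\n", x$n_params))
  cat("  training-set metrics (resubstitution, optimistic):\n  ")
  print(x$train_metrics)
  invisible(x)
}

#' @export
coef.il6gnn <- function(object, ...) {
  object$params
}

#' Training-loss curve
#'
#' @param x An `il6gnn` fit.
#' @param ... Passed to [plot()].
#' @export
plot.il6gnn <- function(x, ...) {
  plot(x$history$epoch, x$history$loss, type = "b", pch = 16,
       xlab = "epoch", ylab = "mean weighted BCE loss",
       main = "Training loss", ...)
  invisible(x)
}

#' @export
residuals.il6gnn <- function(object, ...) {
  object$labels - object$fitted_scores
}

#' Simulate labels from the fitted class probabilities
#'
#' @param object An `il6gnn` fit.
#' @param nsim Number of simulated label vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return data.frame with `nsim` columns of Bernoulli draws.
#' @export
simulate.il6gnn <- function(object, nsim = 1, seed = NULL, ...) {
  with_preserved_seed({
    if (!is.null(seed)) set.seed(seed)
    p <- object$fitted_scores
    as.data.frame(replicate(nsim, stats::rbinom(length(p), 1, p)),
                  col.names = paste0("sim_", seq_len(nsim)))
  })
}

#' Save / restore a fitted classifier
#'
#' Thin wrappers over [save_checkpoint()] storing the whole fit (weights,
#' configs, PCA projection) with a bit-exact round trip.
#'
#' @param object An `il6gnn` fit.
#' @param path Checkpoint path.
#' @return `path` invisibly; `load_il6gnn()` returns the restored fit.
#' @export
save_il6gnn <- function(object, path) {
  stopifnot(inherits(object, "il6gnn"))
  save_checkpoint(object$params, object$config, path,
                  extra = object[setdiff(names(object),
                                         c("params", "config"))])
  invisible(path)
}

#' @rdname save_il6gnn
#' @export
load_il6gnn <- function(path) {
  ck <- load_checkpoint(path)
  obj <- c(list(params = ck$params, config = ck$config), ck$extra)
  class(obj) <- "il6gnn"
  obj
}
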