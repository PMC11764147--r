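# Glue between raw inputs and model-ready graphs: bundle a manifest with
# its per-peptide contact tensors and embeddings, build node features
# (fitting the PCA on the bundle when it is the training set), and run the
# feature/channel ablation harness.

#' Bundle a dataset: manifest + contact tensors + embeddings
#'
#' @param manifest An `il6_manifest` (see [read_manifest()]).
#' @param tensors Named list of L x L x 37 contact tensors, one per peptide
#'   id.
#' @param embeddings Named list of L x E embedding matrices, one per id
#'   (may be `NULL` when the embedding feature block is disabled).
#' @return An `il6_data` object.
#' @export
il6_data <- function(manifest, tensors, embeddings = NULL) {
  ids <- manifest$id
  miss <- setdiff(ids, names(tensors))
  if (length(miss) > 0L)
    stop("missing contact tensors for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.null(embeddings)) {
    miss <- setdiff(ids, names(embeddings))
    if (length(miss) > 0L)
      stop("missing embeddings for: ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  for (i in seq_along(ids)) {
    L <- nchar(manifest$sequence[i])
    validate_contact_tensor(tensors[[ids[i]]], expected_length = L)
    if (!is.null(embeddings) && nrow(embeddings[[ids[i]]]) != L)
      stop("embedding rows != length for peptide ", ids[i], call. = FALSE)
  }
  structure(list(manifest = manifest, tensors = tensors[ids],
                 embeddings = if (is.null(embeddings)) NULL
                              else embeddings[ids]),
            class = "il6_data")
}

#' @export
print.il6_data <- function(x, ...) {
  n <- nrow(x$manifest)
  npos <- sum(x$manifest$label == 1, na.rm = TRUE)
  cat("il6_data:", n, "peptides (", npos, "positive ),",
      if (is.null(x$embeddings)) "no embeddings"
      else paste0("E = ", ncol(x$embeddings[[1]])), "\n")
  invisible(x)
}

#' Subset a dataset bundle
#'
#' Row-subsets the manifest and the matching tensors/embeddings — the
#' usual way to carve train/test splits out of one bundle.
#'
#' @param data An `il6_data` bundle.
#' @param idx Integer or logical row index into the manifest.
#' @return An `il6_data` bundle with the selected peptides.
#' @export
subset_data <- function(data, idx) {
  stopifnot(inherits(data, "il6_data"))
  man <- data$manifest
  il6_data(new_manifest(man$id[idx], man$sequence[idx], man$label[idx],
                        attr(man, "split_tag")),
           data$tensors[man$id[idx]],
           if (is.null(data$embeddings)) NULL
           else data$embeddings[man$id[idx]])
}

#' Feature-block configuration
#'
#' @param onehot,position,embedding Logical toggles for the three node
#'   feature blocks (widths 20, 20 and `pca_dim`).
#' @param pca_dim Reduced embedding width; default 30.
#' @return Named list.
#' @export
feature_config <- function(onehot = TRUE, position = TRUE, embedding = TRUE,
                           pca_dim = 30L) {
  if (!onehot && !position && !embedding)
    stop("at least one feature block must be enabled", call. = FALSE)
  list(onehot = onehot, position = position, embedding = embedding,
       pca_dim = as.integer(pca_dim))
}

feature_width <- function(fc) {
  20L * fc$onehot + 20L * fc$position + fc$pca_dim * fc$embedding
}

#' Build model-ready graphs from a dataset bundle
#'
#' Converts every peptide's contact tensor into a thresholded adjacency and
#' assembles the node-feature matrix from the enabled blocks. When the
#' embedding block is enabled and `pca` is `NULL`, the PCA projection is
#' fitted on the pooled residue embeddings of *this* bundle (so pass the
#' training bundle first and reuse the returned projection for held-out
#' data — the projection never sees test residues).
#'
#' @param data An `il6_data` bundle.
#' @param fconfig A [feature_config()].
#' @param contact_threshold Contact-probability threshold; default 0.8.
#' @param bin_range Short-range bin window for [contact_probability()].
#' @param pca A fitted `pca_projection`, or `NULL` to fit here.
#' @return List with `graphs` (list of `peptide_graph`), `pca` (the
#'   projection used, or `NULL`) and `input_dim`.
#' @export
build_graphs <- function(data, fconfig = feature_config(),
                         contact_threshold = 0.8, bin_range = c(1L, 13L),
                         pca = NULL) {
  stopifnot(inherits(data, "il6_data"))
  man <- data$manifest
  if (fconfig$embedding) {
    if (is.null(data$embeddings))
      stop("embedding block enabled but bundle has no embeddings",
           call. = FALSE)
    if (is.null(pca)) {
      pooled <- do.call(rbind, data$embeddings)
      pca <- fit_pca(pooled, k = fconfig$pca_dim)
    }
  }
  graphs <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    rec <- list(id = man$id[i], sequence = man$sequence[i],
                label = man$label[i])
    L <- nchar(rec$sequence)
    cmap <- contact_probability(data$tensors[[rec$id]], bin_range)
    adj <- build_adjacency(cmap, contact_threshold)
    oh <- if (fconfig$onehot) one_hot_encode(rec$sequence) else NULL
    pe <- if (fconfig$position) position_encode(L) else NULL
    eb <- if (fconfig$embedding)
      reduce_embedding(data$embeddings[[rec$id]], pca) else NULL
    X <- fuse_features(onehot = oh, position = pe, embedding = eb)
    graphs[[i]] <- build_graph(rec, X, adj)
  }
  list(graphs = graphs, pca = pca, input_dim = feature_width(fconfig))
}

#' Feature and channel ablation harness
#'
#' Retrains the model under each requested toggle with identical seeds and
#' identical data, evaluating on the held-out bundle. Feature toggles
#' (`no_onehot`, `no_position`, `no_embedding`) rebuild the node features
#' with the block removed; channel toggles (`no_gat`, `no_gcn`) drop one
#' extraction channel, shrinking the fused width to 64. The untouched model
#' is always included as `"full"`.
#'
#' @param train_data,test_data `il6_data` bundles with labels.
#' @param toggles Character vector drawn from `no_onehot`, `no_position`,
#'   `no_embedding`, `no_gat`, `no_gcn`.
#' @param config Baseline `il6gnn_config` (its `input_dim` is recomputed
#'   per toggle).
#' @param tconfig Training configuration; the same seed is used for every
#'   variant.
#' @param fconfig Baseline feature configuration.
#' @param contact_threshold,bin_range Graph-construction settings.
#' @return Named list of `metrics_report`s (one per variant, plus
#'   `"full"`), with the per-variant AUC also in the `"auc"` attribute.
#' @export
ablation_run <- function(train_data, test_data, toggles,
                         config = model_config(),
                         tconfig = train_config(),
                         fconfig = feature_config(),
                         contact_threshold = 0.8, bin_range = c(1L, 13L)) {
  allowed <- c("no_onehot", "no_position", "no_embedding", "no_gat",
               "no_gcn")
  bad <- setdiff(toggles, allowed)
  if (length(bad) > 0L)
    stop("unknown toggle(s): ", paste(bad, collapse = ", "), call. = FALSE)
  variants <- c("full", toggles)
  out <- vector("list", length(variants))
  names(out) <- variants
  for (vn in variants) {
    fc <- fconfig
    cfg <- config
    if (vn == "no_onehot") fc$onehot <- FALSE
    if (vn == "no_position") fc$position <- FALSE
    if (vn == "no_embedding") fc$embedding <- FALSE
    if (vn == "no_gat") cfg$use_gat <- FALSE
    if (vn == "no_gcn") cfg$use_gcn <- FALSE
    if (!fc$onehot && !fc$position && !fc$embedding)
      stop("ablation removes every feature block", call. = FALSE)
    if (!cfg$use_gat && !cfg$use_gcn)
      stop("ablation disables both channels", call. = FALSE)
    cfg$input_dim <- feature_width(fc)
    cfg <- as_model_config(cfg)
    tr <- build_graphs(train_data, fc, contact_threshold, bin_range)
    te <- build_graphs(test_data, fc, contact_threshold, bin_range,
                       pca = tr$pca)
    fit <- train_model(tr$graphs, cfg, tconfig)
    sc <- score_graphs(te$graphs, fit$params, cfg)
    out[[vn]] <- compute_metrics(sc,
                                 vapply(te$graphs,
                                        function(g) as.integer(g$label), 1L),
                                 cfg$threshold)
  }
  attr(out, "auc") <- vapply(out, `[[`, 1.0, "auc")
  out
}
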