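# Contact-map and adjacency construction: collapse the per-pair distance-bin
# distributions into a contact probability, threshold into a binary
# symmetric adjacency with forced self-loops, and bundle with node features
# into a peptide graph.

#' Contact probability from a distance-bin tensor
#'
#' Sums, for every residue pair, the probability mass of the short-range
#' distance bins. With the default `bin_range = c(1, 13)` these are the 13
#' bins starting at 2 Angstroms (distance-bin index 1 corresponds to 2 A at
#' 0.5 A per bin); the "no contact" bin (index 0) is never included. The bin
#' range is exposed because the short-range window is a modelling choice.
#'
#' @param tens An L x L x 37 `contact_tensor` (see [read_contact_archive()]).
#' @param bin_range Integer vector `c(first, last)` of distance-bin indices
#'   (1-based over the 36 distance bins) to sum.
#' @return An L x L symmetric matrix of contact probabilities in \[0, 1\].
#' @export
contact_probability <- function(tens, bin_range = c(1L, 13L)) {
  stopifnot(length(dim(tens)) == 3L, dim(tens)[3] == N_DIST_BINS)
  lo <- as.integer(bin_range[1]); hi <- as.integer(bin_range[2])
  if (lo < 1L || hi > N_DIST_BINS - 1L || lo > hi)
    stop("bin_range must lie within 1..", N_DIST_BINS - 1L, call. = FALSE)
  # distance bin n lives at array slice n + 1 (slice 1 = no-contact bin)
  prob <- apply(tens[, , (lo + 1L):(hi + 1L), drop = FALSE], c(1, 2), sum)
  (prob + t(prob)) / 2
}

#' Binary adjacency from a contact-probability map
#'
#' An edge is placed wherever the contact probability reaches the threshold
#' (inclusive), and every node receives a self-loop regardless of its
#' probability. Output is symmetric with a unit diagonal.
#'
#' @param cmap L x L contact-probability matrix.
#' @param threshold Contact threshold in (0, 1); default 0.8.
#' @return L x L binary matrix.
#' @export
build_adjacency <- function(cmap, threshold = 0.8) {
  stopifnot(is.matrix(cmap), nrow(cmap) == ncol(cmap))
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must lie in (0, 1)", call. = FALSE)
  adj <- (cmap >= threshold) * 1
  adj <- pmax(adj, t(adj))
  diag(adj) <- 1
  adj
}

#' Bundle features and adjacency into a peptide graph
#'
#' @param record A peptide record (list with `id`, `sequence`, `label`).
#' @param features L x D node-feature matrix (see [fuse_features()]).
#' @param adj L x L binary adjacency with self-loops.
#' @return A `peptide_graph`: list with `id`, `sequence`, `label`, `X`
#'   (features), `adj`, and the feature `blocks` attribute carried over.
#' @export
build_graph <- function(record, features, adj) {
  L <- nchar(record$sequence)
  if (nrow(features) != L)
    stop("feature rows (", nrow(features), ") != sequence length (", L, ")",
         call. = FALSE)
  if (nrow(adj) != L || ncol(adj) != L)
    stop("adjacency is ", nrow(adj), " x ", ncol(adj),
         "; expected ", L, " x ", L, call. = FALSE)
  if (any(diag(adj) != 1))
    stop("adjacency must carry self-loops", call. = FALSE)
  structure(list(id = record$id, sequence = record$sequence,
                 label = record$label, X = features, adj = adj,
                 blocks = attr(features, "blocks")),
            class = "peptide_graph")
}

#' Export an adjacency matrix as an edge list
#'
#' Upper-triangle edges (excluding self-loops) as a data.frame for
#' inspection or TSV export.
#'
#' @param adj Binary adjacency matrix.
#' @return data.frame with integer columns `i`, `j` (i < j).
#' @export
adjacency_edge_list <- function(adj) {
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  data.frame(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]))
}
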