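# Node featurization: one-hot residue identity (20), sinusoidal position
# encoding (20), PCA-reduced language-model embedding (30), concatenated in
# that fixed order into the L x 70 node-feature matrix. Each block can be
# toggled off for ablations.

#' One-hot encode a peptide sequence
#'
#' Columns follow the fixed alphabetical residue order of [aa_alphabet()]
#' ('A' in column 1). Each row contains exactly one 1.
#'
#' @param sequence Peptide string over the 20 standard residues.
#' @return L x 20 numeric matrix.
#' @export
one_hot_encode <- function(sequence) {
  validate_sequence(sequence)
  chars <- strsplit(sequence, "")[[1]]
  idx <- match(chars, aa_alphabet())
  m <- matrix(0, nrow = length(chars), ncol = 20L,
              dimnames = list(NULL, aa_alphabet()))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Sinusoidal residue position encoding
#'
#' Position `pos` (0-based) maps to a `d`-dimensional vector whose even
#' columns (0-based index 2i) hold `sin(pos / b^(2i/d))` and odd columns
#' (2i+1) hold `cos(pos / b^(2i/d))`, with `b = 1000` and `d = 20`.
#'
#' @param L Sequence length (>= 1).
#' @param b Frequency base; default 1000.
#' @param d Encoding width (even); default 20.
#' @return L x d numeric matrix; values lie in \[-1, 1\].
#' @export
position_encode <- function(L, b = 1000, d = 20L) {
  stopifnot(L >= 1L, d %% 2L == 0L)
  pos <- 0:(L - 1L)
  i <- 0:(d / 2L - 1L)
  freq <- b^(-(2 * i) / d)                     # 1 / b^(2i/d)
  ang <- outer(pos, freq)                      # L x d/2
  m <- matrix(0, nrow = L, ncol = d)
  m[, 2 * i + 1L] <- sin(ang)                  # 0-based even columns
  m[, 2 * i + 2L] <- cos(ang)                  # 0-based odd columns
  m
}

#' Fit a PCA projection on pooled training-residue embeddings
#'
#' Mean-centred projection onto the top-`k` variance directions of the
#' stacked per-residue embedding rows of the *training* peptides only
#' (fitting on training rows and applying to held-out rows avoids test
#' leakage). Component signs are fixed deterministically: the
#' largest-magnitude loading of each component is made positive, so
#' checkpoints are reproducible across platforms.
#'
#' @param train_rows N x E matrix of stacked residue embeddings.
#' @param k Target dimension; default 30.
#' @return A `pca_projection`: list with `mean` (E), `components` (E x k,
#'   orthonormal columns), `sdev` (k) and `k`.
#' @export
fit_pca <- function(train_rows, k = 30L) {
  stopifnot(is.matrix(train_rows))
  E <- ncol(train_rows)
  if (k > E) stop("k (", k, ") exceeds embedding width (", E, ")",
                  call. = FALSE)
  if (nrow(train_rows) <= k)
    stop("need more than k = ", k, " rows to fit the projection",
         call. = FALSE)
  pc <- stats::prcomp(train_rows, center = TRUE, scale. = FALSE)
  if (sum(pc$sdev > 1e-10) < k)
    stop("rank-deficient input: fewer than k = ", k,
         " informative directions", call. = FALSE)
  comp <- pc$rotation[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(k)) {
    lead <- which.max(abs(comp[, j]))
    if (comp[lead, j] < 0) comp[, j] <- -comp[, j]
  }
  structure(list(mean = pc$center, components = unname(comp),
                 sdev = pc$sdev[seq_len(k)], k = as.integer(k)),
            class = "pca_projection")
}

#' Project an embedding matrix through a fitted PCA
#'
#' @param emb L x E embedding matrix.
#' @param proj A `pca_projection` from [fit_pca()].
#' @return L x k reduced block.
#' @export
reduce_embedding <- function(emb, proj) {
  stopifnot(inherits(proj, "pca_projection"))
  if (ncol(emb) != length(proj$mean))
    stop("embedding width ", ncol(emb), " != projection input width ",
         length(proj$mean), call. = FALSE)
  sweep(emb, 2, proj$mean) %*% proj$components
}

#' Fuse feature blocks into a node-feature matrix
#'
#' Horizontal concatenation in the fixed order one-hot | position |
#' embedding; absent blocks (ablations) are simply skipped. The block layout
#' is recorded in the `"blocks"` attribute as named column spans.
#'
#' @param onehot Optional L x 20 one-hot block.
#' @param position Optional L x 20 position block.
#' @param embedding Optional L x k reduced-embedding block.
#' @return L x D matrix with a `blocks` attribute; full model D = 70.
#' @export
fuse_features <- function(onehot = NULL, position = NULL, embedding = NULL) {
  blocks <- Filter(Negate(is.null),
                   list(onehot = onehot, position = position,
                        embedding = embedding))
  if (length(blocks) == 0L)
    stop("at least one feature block is required", call. = FALSE)
  n <- vapply(blocks, nrow, 1L)
  if (length(unique(n)) != 1L)
    stop("feature blocks disagree on row count: ",
         paste(n, collapse = ", "), call. = FALSE)
  X <- do.call(cbind, lapply(blocks, unname))
  widths <- vapply(blocks, ncol, 1L)
  ends <- cumsum(widths)
  spans <- Map(function(s, e) c(start = s, end = e),
               c(1L, utils::head(ends, -1) + 1L), ends)
  names(spans) <- names(blocks)
  attr(X, "blocks") <- spans
  X
}

# ---- embedding providers ---------------------------------------------------

#' Embedding providers
#'
#' An embedding provider is a function `provider(sequence, id)` returning an
#' L x E per-residue embedding matrix. Real protein language models (e.g.
#' ESM-1b, E = 1280) plug in through this interface;
#' `file_embedding_provider` serves matrices from files on disk, and the
#' synthetic generator in [generate_dataset()] produces class-conditioned
#' Gaussian embeddings for testing.
#'
#' @param dir Directory holding one `<id>.tsv` embedding file per peptide.
#' @return A provider function.
#' @export
file_embedding_provider <- function(dir) {
  force(dir)
  function(sequence, id) {
    path <- file.path(dir, paste0(id, ".tsv"))
    read_embedding(path, expected_length = nchar(sequence))
  }
}
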