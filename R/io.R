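# Readers and writers for every external representation the pipeline touches:
# peptide sequences (FASTA), labelled manifests (TSV), residue-pair
# distance-bin tensors (trRosetta-style NPZ or plain-text dump), per-residue
# embedding matrices, run configs (JSON/YAML) and model checkpoints.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter residue codes in alphabetical order. This fixed
#' ordering defines the one-hot column layout everywhere in the package.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Number of distance bins per residue pair: index 1 (R) = "no contact",
# indices 2..37 = 0.5 A bins covering 2--20 A.
N_DIST_BINS <- 37L

validate_sequence <- function(seq, id = "<unnamed>") {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) < 1L)
    stop("peptide '", id, "': sequence must be a non-empty string",
         call. = FALSE)
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% aa_alphabet())
  if (length(bad) > 0L)
    stop("peptide '", id, "': non-standard residue '", chars[bad[1]],
         "' at position ", bad[1], call. = FALSE)
  invisible(seq)
}

new_peptide_record <- function(id, sequence, label = NA_integer_) {
  if (!nzchar(id)) stop("peptide id must be non-empty", call. = FALSE)
  sequence <- toupper(sequence)
  validate_sequence(sequence, id)
  if (!is.na(label) && !label %in% c(0L, 1L))
    stop("peptide '", id, "': label must be 0 or 1", call. = FALSE)
  list(id = id, sequence = sequence, label = as.integer(label))
}

check_unique_ids <- function(ids) {
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate peptide id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  invisible(ids)
}

#' Read peptide sequences from a FASTA file
#'
#' Sequences are uppercased and validated against the 20 standard residues;
#' non-standard characters (including X/B/Z/U) are rejected with the
#' offending id and position, since the featurization has no column for them.
#'
#' @param path Path to a FASTA file.
#' @return A list of peptide records, each a list with elements `id`,
#'   `sequence` and `label` (always `NA` for FASTA input).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(list())
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  ids <- names(seqs)
  check_unique_ids(ids)
  recs <- mapply(function(id, s) new_peptide_record(id, as.character(s)),
                 ids, seqs, SIMPLIFY = FALSE)
  unname(recs)
}

#' Write peptide records to a FASTA file
#'
#' @param records List of peptide records (see [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqinr::write.fasta(lapply(records, `[[`, "sequence"),
                      names = vapply(records, `[[`, "", "id"),
                      file.out = path, as.string = TRUE)
  invisible(path)
}

#' Read a labelled dataset manifest (TSV)
#'
#' The manifest is a tab-separated file with columns `id`, `sequence` and
#' `label` (1 = IL-6-inducing, 0 = non-inducing). Row order is preserved.
#'
#' @param path Path to the TSV file.
#' @param split_tag One of `"train"`, `"test"`, `"unsplit"`; recorded on the
#'   returned object.
#' @return A `data.frame` of class `il6_manifest` with character columns
#'   `id`, `sequence` and integer `label`.
#' @export
read_manifest <- function(path, split_tag = c("unsplit", "train", "test")) {
  split_tag <- match.arg(split_tag)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("id", "sequence", "label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("manifest missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L)
    return(new_manifest(character(), character(), integer(), split_tag))
  if (!all(df$label %in% c("0", "1")))
    stop("manifest labels must be 0 or 1; got: ",
         paste(unique(df$label[!df$label %in% c("0", "1")]), collapse = ", "),
         call. = FALSE)
  new_manifest(df$id, toupper(df$sequence), as.integer(df$label), split_tag)
}

new_manifest <- function(id, sequence, label, split_tag = "unsplit") {
  check_unique_ids(id)
  if (length(sequence) > 0L) mapply(validate_sequence, sequence, id)
  stopifnot(length(label) == length(id))
  df <- data.frame(id = as.character(id), sequence = as.character(sequence),
                   label = as.integer(label), stringsAsFactors = FALSE)
  attr(df, "split_tag") <- split_tag
  class(df) <- c("il6_manifest", "data.frame")
  df
}

#' Write a dataset manifest as TSV
#'
#' @param manifest An `il6_manifest` (or data.frame with id/sequence/label).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest[, c("id", "sequence", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- contact-bin tensor archives ------------------------------------------

validate_contact_tensor <- function(tens, expected_length = NULL,
                                    tol_sum = 1e-3, tol_sym = 1e-6) {
  d <- dim(tens)
  if (length(d) != 3L || d[1] != d[2] || d[3] != N_DIST_BINS)
    stop("contact tensor must be L x L x ", N_DIST_BINS, "; got ",
         paste(d, collapse = " x "), call. = FALSE)
  L <- d[1]
  if (!is.null(expected_length) && L != expected_length)
    stop("contact tensor length ", L, " does not match expected length ",
         expected_length, call. = FALSE)
  if (any(!is.finite(tens)) || any(tens < 0))
    stop("contact tensor entries must be finite and non-negative",
         call. = FALSE)
  sums <- apply(tens, c(1, 2), sum)
  if (any(abs(sums - 1) > tol_sum))
    stop("malformed contact archive: per-pair bin sums deviate from 1 ",
         "by up to ", format(max(abs(sums - 1))), call. = FALSE)
  asym <- max(abs(tens - aperm(tens, c(2, 1, 3))))
  if (asym > tol_sym)
    stop("contact tensor not symmetric in residue indices (max deviation ",
         format(asym), ")", call. = FALSE)
  invisible(tens)
}

#' Read a residue-pair distance-bin probability tensor
#'
#' Accepts two dialects: a trRosetta-style NPZ archive whose `dist` entry is
#' an L x L x 37 float array, or a plain-text dump (first line `L`, then the
#' flattened tensor, whitespace-delimited, bin index fastest). Bin 1 is the
#' "no contact" bin; bins 2..37 cover 2--20 Angstroms in 0.5 A increments.
#' The per-pair distributions must each sum to 1 within `1e-3` and the tensor
#' must be symmetric in its residue indices.
#'
#' @param path Path to the archive.
#' @param expected_length Sequence length to validate against, or `NULL`.
#' @return An L x L x 37 array of class `contact_tensor`.
#' @export
read_contact_archive <- function(path, expected_length = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  magic <- readBin(path, "raw", n = 4L)
  tens <- if (length(magic) >= 4L &&
              identical(magic[1:2], as.raw(c(0x50, 0x4b)))) {
    read_npz_dist(path)
  } else {
    read_text_tensor(path)
  }
  validate_contact_tensor(tens, expected_length)
  structure(tens, class = "contact_tensor")
}

#' Write a contact tensor as a plain-text dump
#'
#' The portable dialect read back by [read_contact_archive()]: first line the
#' sequence length, then the flattened tensor in bin-fastest order.
#'
#' @param tens An L x L x 37 array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_archive <- function(tens, path) {
  L <- dim(tens)[1]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(L), con)
  # bin-fastest: t(matrix) rows are (i,j) pairs in row-major pair order
  flat <- as.vector(aperm(tens, c(3, 2, 1)))
  writeLines(paste(format(flat, digits = 10, trim = TRUE, scientific = TRUE),
                   collapse = " "), con)
  invisible(path)
}

read_text_tensor <- function(path) {
  vals <- scan(path, what = numeric(), quiet = TRUE)
  if (length(vals) < 1L) stop("empty tensor file: ", path, call. = FALSE)
  L <- as.integer(vals[1])
  body <- vals[-1]
  if (length(body) != L * L * N_DIST_BINS)
    stop("tensor dump for L=", L, " should hold ", L * L * N_DIST_BINS,
         " values; found ", length(body), call. = FALSE)
  aperm(array(body, dim = c(N_DIST_BINS, L, L)), c(3, 2, 1))
}

# Minimal NPY v1.x parser (little-endian f4/f8, C order) for the `dist`
# member of an NPZ zip; enough for trRosetta-style distance archives.
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 6L)
  if (!identical(magic, c(as.raw(0x93), charToRaw("NUMPY"))))
    stop("not an NPY file: ", path, call. = FALSE)
  ver <- readBin(con, "raw", n = 2L)
  hlen <- if (as.integer(ver[1]) >= 2L) {
    readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  } else {
    readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
            endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", n = hlen))
  descr <- sub(".*'descr'\\s*:\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order'\\s*:\\s*True", header)
  shape_str <- sub(".*'shape'\\s*:\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  shape <- shape[!is.na(shape)]
  size <- switch(descr, "<f4" = 4L, "<f8" = 8L,
                 stop("unsupported NPY dtype: ", descr, call. = FALSE))
  n <- prod(shape)
  vals <- readBin(con, "double", n = n, size = size, endian = "little")
  if (length(vals) != n)
    stop("truncated NPY payload in ", path, call. = FALSE)
  if (fortran) array(vals, dim = shape)
  else aperm(array(vals, dim = rev(shape)), length(shape):1)
}

read_npz_dist <- function(path) {
  listing <- utils::unzip(path, list = TRUE)
  member <- if ("dist.npy" %in% listing$Name) "dist.npy"
  else if (any(grepl("\\.npy$", listing$Name))) {
    grep("\\.npy$", listing$Name, value = TRUE)[1]
  } else {
    stop("NPZ archive has no .npy member: ", path, call. = FALSE)
  }
  tmp <- tempfile()
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  utils::unzip(path, files = member, exdir = tmp)
  read_npy(file.path(tmp, member))
}

#' Read a per-residue embedding matrix
#'
#' A whitespace-delimited numeric table, one row per residue.
#'
#' @param path Path to the file.
#' @param expected_length Optional sequence length to validate against.
#' @return An L x E numeric matrix.
#' @export
read_embedding <- function(path, expected_length = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  if (!is.null(expected_length) && nrow(m) != expected_length)
    stop("embedding has ", nrow(m), " rows; expected ", expected_length,
         call. = FALSE)
  if (any(!is.finite(m))) stop("embedding contains non-finite values",
                               call. = FALSE)
  m
}

#' Write a per-residue embedding matrix
#' @param emb L x E numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path) {
  utils::write.table(emb, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a run configuration (JSON or YAML)
#' @param path Path ending in .json, .yml or .yaml.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint stores the learnable weights together with the model
#' configuration (and any PCA projection) so that a load reproduces every
#' weight bit-exactly and validates shapes against the embedded config.
#'
#' @param params A `model_params` object (see [init_model_params()]).
#' @param config The model configuration list the params were built from.
#' @param path Output path.
#' @param extra Optional named list of additional objects (e.g. the fitted
#'   PCA projection) stored alongside.
#' @return `path`, invisibly (for `save_checkpoint`); a list with elements
#'   `params`, `config` and `extra` (for `load_checkpoint`).
#' @export
save_checkpoint <- function(params, config, path, extra = list()) {
  check_params_shapes(params, config)
  saveRDS(list(format = "il6gnn-checkpoint-1", params = params,
               config = config, extra = extra),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- readRDS(path)
  if (!identical(obj$format, "il6gnn-checkpoint-1"))
    stop("not an il6gnn checkpoint: ", path, call. = FALSE)
  check_params_shapes(obj$params, obj$config)
  obj[c("params", "config", "extra")]
}
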