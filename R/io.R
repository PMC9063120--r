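# File formats: label CSVs (column `smiles`, then one column per target
# with 0 / 1 / empty cell for missing), plain SMILES text files (one per
# line), and dense fingerprint matrices as CSV.

#' Write a labeled pool to CSV
#'
#' @param smiles Character vector of SMILES.
#' @param labels Matrix over {0, 1, NA}; NA is written as an empty cell.
#' @param path Output file.
#' @export
write_label_csv <- function(smiles, labels, path) {
  stopifnot(length(smiles) == nrow(labels))
  df <- data.frame(smiles = smiles, labels, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a labeled pool from CSV
#'
#' @param path CSV with a `smiles` column and one 0/1/empty column per
#'   target.
#' @return List with `smiles` and integer `labels` matrix (NA = missing).
#' @export
read_label_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (!"smiles" %in% names(df)) stop("no `smiles` column in ", path)
  lab_cols <- setdiff(names(df), "smiles")
  labels <- as.matrix(df[lab_cols])
  storage.mode(labels) <- "integer"
  if (!all(labels %in% c(0L, 1L) | is.na(labels))) {
    stop("label cells must be 0, 1 or empty in ", path)
  }
  list(smiles = df$smiles, labels = labels)
}

#' Read / write plain SMILES files (one molecule per line)
#'
#' @param smiles Character vector (for writing).
#' @param path File path.
#' @export
write_smiles_file <- function(smiles, path) {
  writeLines(smiles, path)
  invisible(path)
}

#' @rdname write_smiles_file
#' @export
read_smiles_file <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x))]
}

#' Write a synthetic dataset to a directory
#'
#' Produces `labeled.csv`, `partial.csv` (label CSV dialect) and
#' `unlabeled.smi` under `dir`.
#'
#' @param dataset A `gp_synth_dataset`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "gp_synth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_label_csv(dataset$fully_labeled$smiles, dataset$fully_labeled$labels,
                  file.path(dir, "labeled.csv"))
  write_label_csv(dataset$partially_labeled$smiles,
                  dataset$partially_labeled$labels,
                  file.path(dir, "partial.csv"))
  write_smiles_file(dataset$unlabeled, file.path(dir, "unlabeled.smi"))
  invisible(dir)
}

#' Write a feature matrix as CSV
#'
#' Dense 0/1 (or continuous) matrix with a header row; fingerprint columns
#' are named by bit index.
#'
#' @param m Matrix.
#' @param path Output file.
#' @param prefix Column-name prefix when `m` has no column names.
#' @export
write_feature_csv <- function(m, path, prefix = "bit_") {
  if (is.null(colnames(m))) {
    colnames(m) <- paste0(prefix, seq_len(ncol(m)) - 1L)
  }
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' Standardize a continuous feature matrix
#'
#' Column-wise z-scoring (zero-variance columns are left centered at 0).
#' Continuous embeddings such as GINFPs should be standardized before MLP
#' training; the attributes `center` and `scale` let new rows be placed on
#' the same scale.
#'
#' @param x Numeric matrix.
#' @param center,scale Optional precomputed statistics (e.g. from the
#'   matrix the model was trained on).
#' @return Standardized matrix with attributes `center` and `scale`.
#' @export
standardize_features <- function(x, center = NULL, scale = NULL) {
  center <- center %||% colMeans(x)
  scale <- scale %||% apply(x, 2L, stats::sd)
  scale[scale < 1e-12] <- 1
  out <- sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Build a PLANS bundle from a synthetic dataset
#'
#' Featurizes the three pools with either ECFP bits or GINFP embeddings
#' and assembles a [plans_bundle()].
#'
#' @param dataset A `gp_synth_dataset`.
#' @param features `"ecfp"` or `"ginfp"`.
#' @param gin_model A `gp_gin` (required for `features = "ginfp"`).
#' @param radius,n_bits ECFP parameters (used for `features = "ecfp"`).
#' @return A `gp_bundle`.
#' @export
bundle_from_synthetic <- function(dataset, features = c("ecfp", "ginfp"),
                                  gin_model = NULL, radius = 4L,
                                  n_bits = 2048L) {
  features <- match.arg(features)
  stopifnot(inherits(dataset, "gp_synth_dataset"))
  featurize <- function(smiles) {
    if (length(smiles) == 0L) return(NULL)
    if (features == "ecfp") {
      ecfp_matrix(smiles, radius = radius, n_bits = n_bits, quiet = TRUE)
    } else {
      if (is.null(gin_model)) stop("features = 'ginfp' needs a gin_model")
      embed_dataset(smiles, gin_model, quiet = TRUE)
    }
  }
  f_full <- featurize(dataset$fully_labeled$smiles)
  f_part <- featurize(dataset$partially_labeled$smiles)
  f_unlab <- featurize(dataset$unlabeled)
  if (features == "ginfp") {
    # continuous embeddings: one joint z-scoring across all pools
    all_f <- rbind(f_full, f_part, f_unlab)
    std <- standardize_features(all_f)
    n1 <- nrow(f_full %||% matrix(numeric(0), ncol = 1))
    n2 <- if (is.null(f_part)) 0L else nrow(f_part)
    f_full <- std[seq_len(n1), , drop = FALSE]
    if (n2 > 0L) f_part <- std[n1 + seq_len(n2), , drop = FALSE]
    if (!is.null(f_unlab) && nrow(f_unlab)) {
      f_unlab <- std[(n1 + n2 + 1L):nrow(std), , drop = FALSE]
    }
  }
  plans_bundle(
    features_full = f_full,
    labels_full = dataset$fully_labeled$labels,
    features_partial = f_part,
    labels_partial = dataset$partially_labeled$labels,
    features_unlabeled = f_unlab,
    feature_kind = toupper(features)
  )
}
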