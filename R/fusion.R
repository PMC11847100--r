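# The N x d deep-feature container, serial (column-wise) fusion of the two
# stream feature matrices, and entropy-based column ranking.

#' Deep-feature matrix
#'
#' An `N x d` numeric matrix with aligned row labels and a per-column
#' provenance tag (`"residual"`, `"inverted_residual"`, `"fused"`, ...).
#'
#' @param values Numeric matrix, no NaN/Inf.
#' @param labels Optional length-N labels (coerced to factor).
#' @param origin Per-column provenance; scalar values are recycled.
#' @param row_ids Optional record identifiers used to check row alignment
#'   when fusing.
#' @return A `feature_matrix`.
#' @export
feature_matrix <- function(values, labels = NULL, origin = "unknown",
                           row_ids = NULL) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("feature values must be finite", call. = FALSE)
  if (!is.null(labels)) {
    if (length(labels) != nrow(values))
      stop("labels must align with rows", call. = FALSE)
    labels <- as.factor(labels)
  }
  if (length(origin) == 1L) origin <- rep(origin, ncol(values))
  if (length(origin) != ncol(values))
    stop("origin must have one tag per column", call. = FALSE)
  if (!is.null(row_ids) && length(row_ids) != nrow(values))
    stop("row_ids must align with rows", call. = FALSE)
  structure(list(values = values, labels = labels, origin = origin,
                 row_ids = row_ids),
            class = "feature_matrix")
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d x %d (%s)\n", nrow(x$values), ncol(x$values),
              paste(unique(x$origin), collapse = "+")))
  if (!is.null(x$labels))
    cat(sprintf("  labels: %d classes\n", nlevels(x$labels)))
  invisible(x)
}

#' Column subset of a feature matrix
#' @param m A [feature_matrix].
#' @param cols Column indices (or logical mask) to keep.
#' @return A [feature_matrix] with the selected columns.
#' @export
subset_features <- function(m, cols) {
  if (is.logical(cols)) cols <- which(cols)
  feature_matrix(m$values[, cols, drop = FALSE], labels = m$labels,
                 origin = m$origin[cols], row_ids = m$row_ids)
}

#' Serial feature fusion
#'
#' Column-wise concatenation of two feature matrices from the same
#' observations: an `N x k1` and an `N x k2` input give an `N x (k1 + k2)`
#' output with columns `[1, k1]` from `a` and `(k1, k1+k2]` from `b`, origin
#' tags preserved. Rows must be aligned; a row-count or record-id mismatch is
#' an error, never a silent truncation.
#'
#' @param a,b [feature_matrix] objects with equal row counts.
#' @return The fused [feature_matrix].
#' @export
serial_fuse <- function(a, b) {
  stopifnot(inherits(a, "feature_matrix"), inherits(b, "feature_matrix"))
  if (nrow(a$values) != nrow(b$values))
    stop(sprintf("row mismatch: %d vs %d observations",
                 nrow(a$values), nrow(b$values)), call. = FALSE)
  if (!is.null(a$row_ids) && !is.null(b$row_ids) &&
      !identical(a$row_ids, b$row_ids))
    stop("record ids disagree between the two streams", call. = FALSE)
  if (!is.null(a$labels) && !is.null(b$labels) &&
      !identical(as.character(a$labels), as.character(b$labels)))
    stop("labels disagree between the two streams", call. = FALSE)
  feature_matrix(cbind(a$values, b$values),
                 labels = if (!is.null(a$labels)) a$labels else b$labels,
                 origin = c(a$origin, b$origin),
                 row_ids = if (!is.null(a$row_ids)) a$row_ids else b$row_ids)
}

#' Shannon entropy of each feature column
#'
#' Each column is min-max normalized to `[0, 1]` and binned into `bins`
#' equal-width bins; the entropy of the resulting histogram is returned in
#' bits. Constant columns have entropy 0; a column uniform over `B` occupied
#' bins has entropy `log2(B)`.
#'
#' @param values Numeric matrix.
#' @param bins Number of histogram bins (>= 2).
#' @return Numeric vector of per-column entropies in `[0, log2(bins)]`.
#' @export
column_entropy <- function(values, bins = 256L) {
  stopifnot(bins >= 2L)
  apply(as.matrix(values), 2, function(v) {
    rng <- range(v)
    if (rng[1] == rng[2]) return(0)
    u <- (v - rng[1]) / (rng[2] - rng[1])
    bin <- pmin(floor(u * bins) + 1L, bins)
    p <- tabulate(bin, nbins = bins) / length(v)
    p <- p[p > 0]
    -sum(p * log2(p))
  })
}

#' Rank fused columns by entropy and keep the best
#'
#' Retains the `keep` columns with the highest histogram entropy (ties broken
#' by lower column index), preserving the original column order among the
#' retained ones. The selected indices are recorded in
#' `attr(result, "selected_idx")`.
#'
#' @param m A [feature_matrix].
#' @param keep Number of columns to retain (`<= ncol`); default keeps all.
#' @param bins Histogram bins for the entropy estimate (default 256).
#' @return A [feature_matrix] with `keep` columns.
#' @export
entropy_rank <- function(m, keep = ncol(m$values), bins = 256L) {
  stopifnot(inherits(m, "feature_matrix"))
  if (keep > ncol(m$values)) stop("keep exceeds the number of columns", call. = FALSE)
  if (keep < 1L) stop("keep must be >= 1", call. = FALSE)
  ent <- column_entropy(m$values, bins)
  ranked <- order(-ent, seq_along(ent))       # ties -> lower index first
  sel <- sort(ranked[seq_len(keep)])
  out <- subset_features(m, sel)
  attr(out, "selected_idx") <- sel
  attr(out, "entropy") <- ent
  out
}

#' Persist / load a feature matrix
#'
#' CSV for the values plus a JSON sidecar for labels, origins and any
#' selected-index log.
#'
#' @param m A [feature_matrix].
#' @param path Output CSV path (the sidecar gets extension `.json`).
#' @export
write_features <- function(m, path) {
  utils::write.csv(m$values, path, row.names = FALSE)
  side <- list(labels = if (is.null(m$labels)) NULL else as.character(m$labels),
               origin = m$origin,
               row_ids = m$row_ids,
               selected_idx = attr(m, "selected_idx"))
  jsonlite::write_json(side[!vapply(side, is.null, logical(1))],
                       sub("\\.csv$", ".json", path), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  vals <- as.matrix(utils::read.csv(path))
  side <- jsonlite::read_json(sub("\\.csv$", ".json", path), simplifyVector = TRUE)
  m <- feature_matrix(vals, labels = side$labels, origin = side$origin,
                      row_ids = side$row_ids)
  if (!is.null(side$selected_idx)) attr(m, "selected_idx") <- side$selected_idx
  m
}
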