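#' Construct a labelled distance matrix
#'
#' Thin wrapper around a symmetric, zero-diagonal matrix of non-negative
#' reals with unique sample labels and a metric name; the shared currency of
#' all pairwise statistics in the package (Bray-Curtis, geographic km,
#' standardized environmental Euclidean, beta-deviation).
#'
#' @param values Square numeric matrix, symmetric within 1e-12, zero
#'   diagonal. A `dist` object is also accepted.
#' @param labels Character labels (defaults to `rownames(values)`).
#' @param metric_name Short name of the metric.
#' @return An object of class `dist_matrix`.
#' @export
dist_matrix <- function(values, labels = rownames(values),
                        metric_name = "distance") {
  if (inherits(values, "dist")) {
    labels <- labels %||% attr(values, "Labels")
    values <- as.matrix(values)
  }
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (is.null(labels)) labels <- paste0("S", seq_len(nrow(values)))
  labels <- as.character(labels)
  if (length(labels) != nrow(values))
    stop("labels length does not match matrix size")
  if (anyDuplicated(labels)) stop("duplicate labels in distance matrix")
  if (max(abs(values - t(values))) > 1e-12)
    stop("matrix not symmetric (tolerance 1e-12)")
  if (any(abs(diag(values)) > 1e-12)) stop("diagonal not zero")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = labels,
                 metric_name = metric_name),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("dist_matrix (", x$metric_name, "): ", length(x$labels),
      " x ", length(x$labels), ", range [",
      signif(min(x$values[upper.tri(x$values)]), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.dist_matrix <- function(x, ...) x$values

#' Extract the upper-triangle pair vector of a distance matrix
#' @param dm A [dist_matrix].
#' @return Numeric vector of the n(n-1)/2 unordered pair values (column-major
#'   upper triangle).
#' @export
pair_vector <- function(dm) upper_vec(dm$values)

check_same_labels <- function(a, b) {
  if (!identical(a$labels, b$labels)) {
    extra <- setdiff(a$labels, b$labels)
    miss <- setdiff(b$labels, a$labels)
    stop("distance matrices have mismatched labels",
         if (length(extra)) paste0("; only in first: ",
                                   paste(extra, collapse = ", ")),
         if (length(miss)) paste0("; only in second: ",
                                  paste(miss, collapse = ", ")),
         if (!length(extra) && !length(miss)) " (same set, different order)")
  }
  invisible(TRUE)
}

#' Write a distance matrix as labelled square TSV
#' @param dm A [dist_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(dm, path) {
  df <- data.frame(sample_id = dm$labels, dm$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labelled square TSV distance matrix
#' @param path Path written by [write_dist_matrix].
#' @param metric_name Metric name to attach.
#' @return A [dist_matrix].
#' @export
read_dist_matrix <- function(path, metric_name = "distance") {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  dist_matrix(m, labels = df[[1]], metric_name = metric_name)
}
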