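#' Construct an OTU table
#'
#' The central data container of the package: a non-negative integer count
#' matrix with samples as rows and OTUs as columns, plus optional taxonomy
#' strings per OTU.
#'
#' @param counts Numeric matrix of non-negative integers, samples x OTUs.
#' @param sample_ids Character vector of unique sample labels (defaults to
#'   `rownames(counts)`).
#' @param otu_ids Character vector of unique OTU labels (defaults to
#'   `colnames(counts)`).
#' @param taxonomy Optional named character vector mapping OTU ids to lineage
#'   strings.
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts), taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(counts)))
  if (is.null(otu_ids)) otu_ids <- paste0("OTU", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  otu_ids <- as.character(otu_ids)
  if (length(sample_ids) != nrow(counts))
    stop("sample_ids length (", length(sample_ids),
         ") does not match number of rows (", nrow(counts), ")")
  if (length(otu_ids) != ncol(counts))
    stop("otu_ids length (", length(otu_ids),
         ") does not match number of columns (", ncol(counts), ")")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(otu_ids))
    stop("duplicate OTU ids: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  if (anyNA(counts)) stop("counts contain NA")
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("negative count at sample '", sample_ids[bad[1, 1]], "', OTU '",
         otu_ids[bad[1, 2]], "'")
  frac <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(frac) > 0)
    stop("non-integer count at sample '", sample_ids[frac[1, 1]], "', OTU '",
         otu_ids[frac[1, 2]], "': ", counts[frac[1, , drop = FALSE]])
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, otu_ids)
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[otu_ids]
    names(taxonomy) <- otu_ids
  }
  structure(list(counts = counts, sample_ids = sample_ids, otu_ids = otu_ids,
                 taxonomy = taxonomy),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat("otu_table: ", nrow(x$counts), " samples x ", ncol(x$counts),
      " OTUs, total reads ", sum(as.numeric(x$counts)),
      if (!is.null(x$taxonomy)) ", with taxonomy" else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

sample_totals <- function(table) rowSums(table$counts)
otu_totals <- function(table) colSums(table$counts)

#' Read an OTU table from a QIIME-classic TSV file
#'
#' On disk OTUs are rows (first header field `#OTU ID`, QIIME classic
#' convention) and an optional trailing `taxonomy` column carries lineage
#' strings (`format = "biom_tsv"`). Lines starting with `#` are treated as
#' comments, except the `#OTU ID` header itself. In memory the table is
#' transposed to samples x OTUs.
#'
#' @param path Path to a tab-separated file.
#' @param format `"tsv"` (counts only) or `"biom_tsv"` (last column is
#'   taxonomy).
#' @return An [otu_table].
#' @export
read_otu_table <- function(path, format = c("tsv", "biom_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#") & !startsWith(lines, "#OTU ID")
  lines <- lines[!is_comment & nzchar(lines)]
  if (length(lines) < 2) stop("no data rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  body <- fields[-1]
  has_tax <- format == "biom_tsv" ||
    identical(tolower(header[length(header)]), "taxonomy")
  n_col <- length(header)
  sample_ids <- header[-1]
  taxonomy <- NULL
  if (has_tax) {
    sample_ids <- header[2:(n_col - 1)]
  }
  otu_ids <- vapply(body, `[`, character(1), 1L)
  count_cols <- if (has_tax) 2:(n_col - 1) else 2:n_col
  mat <- matrix(0, nrow = length(body), ncol = length(count_cols))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != n_col)
      stop("row for OTU '", otu_ids[i], "' has ", length(row),
           " fields, expected ", n_col)
    vals <- suppressWarnings(as.numeric(row[count_cols]))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1]
      stop("non-numeric count for OTU '", otu_ids[i], "', sample '",
           sample_ids[j], "': '", row[count_cols[j]], "'")
    }
    mat[i, ] <- vals
  }
  if (has_tax)
    taxonomy <- stats::setNames(vapply(body, `[`, character(1), n_col), otu_ids)
  otu_table(t(mat), sample_ids = sample_ids, otu_ids = otu_ids,
            taxonomy = taxonomy)
}

#' Write an OTU table in QIIME-classic TSV
#'
#' Inverse of [read_otu_table]: OTUs as rows, `#OTU ID` header, taxonomy as
#' trailing column when present.
#'
#' @param table An [otu_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  m <- t(table$counts)
  header <- c("#OTU ID", table$sample_ids)
  rows <- paste(table$otu_ids,
                apply(m, 1, paste, collapse = "\t"), sep = "\t")
  if (!is.null(table$taxonomy)) {
    header <- c(header, "taxonomy")
    rows <- paste(rows, table$taxonomy[table$otu_ids], sep = "\t")
  }
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  invisible(path)
}

#' Discard OTUs with few reads across the whole dataset
#'
#' Removes OTUs whose total count over all samples is below `min_reads`
#' (default 20 reads: totals of exactly 20 are kept), guarding rare-taxon
#' identification against sequencing noise.
#'
#' @param table An [otu_table].
#' @param min_reads Minimum dataset-wide total for an OTU to be retained.
#' @return Filtered [otu_table]; sample order unchanged.
#' @export
filter_low_count_otus <- function(table, min_reads = 20L) {
  stopifnot(min_reads >= 0)
  keep <- otu_totals(table) >= min_reads
  if (!any(keep)) stop("all OTUs removed at min_reads = ", min_reads)
  otu_table(table$counts[, keep, drop = FALSE],
            sample_ids = table$sample_ids,
            otu_ids = table$otu_ids[keep],
            taxonomy = if (!is.null(table$taxonomy)) table$taxonomy[keep])
}

#' Rarefy an OTU table to equal depth
#'
#' Subsamples each sample without replacement (a multivariate hypergeometric
#' draw per sample) down to `depth` reads, removing depth differences before
#' diversity analyses. Deterministic given `seed`.
#'
#' @param table An [otu_table].
#' @param depth Target reads per sample; every sample must have at least this
#'   many.
#' @param seed Integer RNG seed.
#' @return Rarefied [otu_table] with every sample total equal to `depth`.
#'   OTU columns are kept even if they drop to zero total.
#' @export
rarefy <- function(table, depth, seed) {
  depth <- as.integer(depth)
  stopifnot(depth > 0)
  tot <- sample_totals(table)
  low <- tot < depth
  if (any(low))
    stop("samples below depth ", depth, ": ",
         paste(sprintf("%s (%d)", table$sample_ids[low], tot[low]),
               collapse = ", "))
  n_otu <- ncol(table$counts)
  out <- with_seed(seed, {
    res <- matrix(0L, nrow = nrow(table$counts), ncol = n_otu)
    for (k in seq_len(nrow(table$counts))) {
      cnt <- table$counts[k, ]
      pool <- rep.int(seq_len(n_otu), cnt)
      drawn <- pool[sample.int(length(pool), depth)]
      res[k, ] <- tabulate(drawn, nbins = n_otu)
    }
    res
  })
  otu_table(out, sample_ids = table$sample_ids, otu_ids = table$otu_ids,
            taxonomy = table$taxonomy)
}
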