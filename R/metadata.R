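#' Read a sample-metadata table
#'
#' Tab-separated file with a header row; first column must be `sample_id`.
#' Expected columns (all optional beyond `sample_id`): `latitude`,
#' `longitude`, `altitude` (m), `MAT` (degrees C), `MAP` (mm), `PET` (mm),
#' `AI` (dimensionless, MAP/PET), `SM` (%), `pH`, `TSN`, `TSP`, `TOC`
#' (g/kg), `AN` (mg/kg), `CN`, `NP` (ratios).
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` with one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  names(meta)[1] <- sub("^#", "", names(meta)[1])
  if (names(meta)[1] != "sample_id")
    stop("first metadata column must be 'sample_id', got '",
         names(meta)[1], "'")
  validate_metadata(meta)
  meta
}

#' Write a sample-metadata table
#' @param meta Metadata `data.frame` (first column `sample_id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_metadata <- function(meta) {
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  if ("pH" %in% names(meta) &&
      any(meta$pH <= 0 | meta$pH >= 14, na.rm = TRUE))
    stop("pH outside (0, 14)")
  if (all(c("AI", "MAP", "PET") %in% names(meta))) {
    ok <- is.na(meta$AI) | is.na(meta$MAP) | is.na(meta$PET) |
      abs(meta$AI - meta$MAP / meta$PET) < 1e-9
    if (!all(ok))
      stop("AI inconsistent with MAP/PET for: ",
           paste(meta$sample_id[!ok], collapse = ", "))
  }
  invisible(meta)
}

#' Derive the aridity index AI = MAP/PET
#'
#' @param meta Metadata `data.frame` with `MAP` and `PET` columns.
#' @return `meta` with the `AI` column (re)populated.
#' @export
derive_aridity_index <- function(meta) {
  if (!all(c("MAP", "PET") %in% names(meta)))
    stop("metadata must contain MAP and PET")
  if (any(meta$PET == 0, na.rm = TRUE))
    stop("PET is zero for: ",
         paste(meta$sample_id[which(meta$PET == 0)], collapse = ", "))
  meta$AI <- meta$MAP / meta$PET
  meta
}

#' Screen environmental variables for collinearity
#'
#' Pairs of variables with absolute Pearson correlation above `threshold`
#' are considered collinear. By default a greedy rule is applied: repeatedly
#' drop, among variables involved in a violating pair, the one with the
#' highest mean absolute correlation against all remaining variables (ties
#' broken by later column order), until no violating pair remains.
#' `drop_override` instead drops exactly the named variables (after checking
#' each takes part in at least one violating pair; a warning is issued when
#' one does not).
#'
#' @param meta Metadata `data.frame`.
#' @param variables Character vector of column names to screen (>= 2).
#' @param threshold Absolute Pearson correlation above which a pair violates
#'   (default 0.7, strict).
#' @param drop_override Optional character vector of variables to drop
#'   instead of the greedy rule.
#' @return Character vector of retained variable names, in input order.
#' @export
collinearity_screen <- function(meta, variables, threshold = 0.7,
                                drop_override = NULL) {
  stopifnot(length(variables) >= 2, nrow(meta) >= 3)
  missing_vars <- setdiff(variables, names(meta))
  if (length(missing_vars))
    stop("variables absent from metadata: ",
         paste(missing_vars, collapse = ", "))
  x <- as.matrix(meta[, variables, drop = FALSE])
  r <- stats::cor(x)
  viol <- abs(r) > threshold & upper.tri(r)
  if (!is.null(drop_override)) {
    for (v in drop_override) {
      i <- match(v, variables)
      if (is.na(i)) stop("drop_override variable not screened: ", v)
      in_pair <- any(abs(r[i, -i]) > threshold)
      if (!in_pair)
        warning("drop_override variable '", v,
                "' has no correlation above ", threshold)
    }
    return(setdiff(variables, drop_override))
  }
  keep <- variables
  repeat {
    rr <- stats::cor(as.matrix(meta[, keep, drop = FALSE]))
    diag(rr) <- 0
    if (all(abs(rr) <= threshold)) break
    involved <- which(apply(abs(rr) > threshold, 1, any))
    mean_abs <- rowMeans(abs(rr))[involved]
    # ties to the later column
    worst <- involved[which(mean_abs >= max(mean_abs) - 1e-12)]
    drop_i <- max(worst)
    keep <- keep[-drop_i]
    if (length(keep) < 2) break
  }
  keep
}
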