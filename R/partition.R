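#' Classify OTUs into abundant, intermediate and rare sub-communities
#'
#' Classification uses each OTU's share of the dataset grand total: strictly
#' above `abundant_min_frac` (default 0.1%) is abundant, strictly below
#' `rare_max_frac` (default 0.01%) is rare, anything else (boundaries
#' included) is intermediate. With `basis = "per_sample_mean"` the mean of
#' per-sample relative abundances is used instead, a convention some studies
#' prefer.
#'
#' @param table An [otu_table].
#' @param abundant_min_frac Strict lower relative-abundance bound for the
#'   abundant class.
#' @param rare_max_frac Strict upper bound for the rare class.
#' @param basis `"total"` (share of grand total, default) or
#'   `"per_sample_mean"`.
#' @return A `partition_result`: `class_of` (named character vector over
#'   OTUs), `thresholds`, and `summary` (per-class OTU counts, OTU fraction,
#'   reads, read fraction — fractions as percentages).
#' @export
classify_otus <- function(table, abundant_min_frac = 0.001,
                          rare_max_frac = 0.0001,
                          basis = c("total", "per_sample_mean")) {
  basis <- match.arg(basis)
  stopifnot(abundant_min_frac > 0, abundant_min_frac < 1,
            rare_max_frac > 0, rare_max_frac < 1,
            abundant_min_frac > rare_max_frac,
            ncol(table$counts) > 0)
  totals <- as.numeric(otu_totals(table))
  frac <- switch(basis,
    total = totals / sum(totals),
    per_sample_mean = colMeans(table$counts / rowSums(table$counts)))
  cls <- ifelse(frac > abundant_min_frac, "abundant",
                ifelse(frac < rare_max_frac, "rare", "intermediate"))
  names(cls) <- table$otu_ids
  summ <- partition_summary(cls, totals)
  structure(list(class_of = cls,
                 thresholds = c(abundant_min_frac = abundant_min_frac,
                                rare_max_frac = rare_max_frac),
                 basis = basis,
                 summary = summ),
            class = "partition_result")
}

# Per-class bookkeeping: OTU counts and read totals with their percentage
# shares of the whole table.
partition_summary <- function(class_of, totals) {
  lv <- c("abundant", "intermediate", "rare")
  n <- vapply(lv, function(l) sum(class_of == l), numeric(1))
  reads <- vapply(lv, function(l) sum(totals[class_of == l]), numeric(1))
  data.frame(class = lv,
             n_otus = as.integer(n),
             pct_otus = 100 * n / length(class_of),
             reads = reads,
             pct_reads = 100 * reads / sum(totals),
             row.names = NULL)
}

#' @export
print.partition_result <- function(x, ...) {
  cat("partition_result (abundant > ",
      100 * x$thresholds[["abundant_min_frac"]], "%, rare < ",
      100 * x$thresholds[["rare_max_frac"]], "% of total reads)\n", sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Restrict an OTU table to one abundance class
#'
#' @param table An [otu_table].
#' @param part A `partition_result` from [classify_otus].
#' @param cls `"abundant"`, `"intermediate"` or `"rare"`.
#' @return [otu_table] with only the OTUs of that class. Samples whose total
#'   drops to zero are retained (with a log message), so labels stay aligned
#'   across sub-communities.
#' @export
subset_by_class <- function(table, part, cls) {
  cls <- match.arg(cls, c("abundant", "intermediate", "rare"))
  keep <- names(part$class_of)[part$class_of == cls]
  if (!length(keep)) stop("no OTUs in class '", cls, "'")
  idx <- match(keep, table$otu_ids)
  if (anyNA(idx)) stop("partition refers to OTUs absent from the table")
  sub <- otu_table(table$counts[, idx, drop = FALSE],
                   sample_ids = table$sample_ids, otu_ids = keep,
                   taxonomy = if (!is.null(table$taxonomy))
                     table$taxonomy[keep])
  empty <- sample_totals(sub) == 0
  if (any(empty))
    ra_log("WARN", "samples with zero '", cls, "' reads retained: ",
           paste(sub$sample_ids[empty], collapse = ", "))
  sub
}

#' Occupancy and mean relative abundance per OTU
#'
#' Occupancy is the fraction of samples in which an OTU has a non-zero
#' count; mean relative abundance is averaged over per-sample proportions.
#'
#' @param table An [otu_table].
#' @return An `occupancy_profile`: named vectors `occupancy` and
#'   `mean_relative_abundance` over OTUs, and `n_samples`.
#' @export
occupancy_profile <- function(table) {
  n <- nrow(table$counts)
  occ <- colSums(table$counts > 0) / n
  rel <- table$counts / rowSums(table$counts)
  structure(list(occupancy = stats::setNames(occ, table$otu_ids),
                 mean_relative_abundance =
                   stats::setNames(colMeans(rel), table$otu_ids),
                 n_samples = n),
            class = "occupancy_profile")
}

#' Fraction of OTUs occupying more than a given share of samples
#'
#' @param profile An [occupancy_profile].
#' @param otus OTU ids to consider (default all).
#' @param min_occupancy Strict occupancy threshold (default 0.5: an OTU in
#'   13 of 24 samples qualifies, one in 12 does not).
#' @return List with `n_qualifying`, `n_total` and `pct` (percentage).
#' @export
occupancy_above <- function(profile, otus = names(profile$occupancy),
                            min_occupancy = 0.5) {
  occ <- profile$occupancy[otus]
  q <- sum(occ > min_occupancy)
  list(n_qualifying = q, n_total = length(occ),
       pct = 100 * q / length(occ))
}

#' Abundance-occupancy regression
#'
#' Ordinary least squares of occupancy on log10 mean relative abundance over
#' a set of OTUs, the classical abundance-occupancy relationship.
#'
#' @param profile An [occupancy_profile].
#' @param otus OTU ids to fit over (default all); OTUs with zero mean
#'   abundance are excluded.
#' @return List with `slope`, `intercept`, `r` (Pearson), `p` (two-sided),
#'   `n_otus`.
#' @export
abundance_occupancy_fit <- function(profile, otus = names(profile$occupancy)) {
  x <- profile$mean_relative_abundance[otus]
  y <- profile$occupancy[otus]
  pos <- x > 0
  x <- log10(x[pos]); y <- y[pos]
  if (length(x) < 3) stop("need >= 3 OTUs with positive mean abundance")
  if (stats::sd(x) == 0) stop("zero variance in log10 abundance")
  fit <- stats::lm(y ~ x)
  if (stats::sd(y) == 0) {
    # flat occupancy: slope 0, correlation undefined
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(x, y)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = r, p = p, n_otus = length(x))
}

#' Write a per-OTU partition summary table
#'
#' Emits a TSV (otu_id, class, total_reads, rel_abund, occupancy) and a JSON
#' block with the per-class summary.
#'
#' @param table An [otu_table].
#' @param part A `partition_result`.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return The per-OTU `data.frame`, invisibly.
#' @export
write_partition_summary <- function(table, part, tsv_path = NULL,
                                    json_path = NULL) {
  totals <- otu_totals(table)
  prof <- occupancy_profile(table)
  df <- data.frame(otu_id = table$otu_ids,
                   class = unname(part$class_of[table$otu_ids]),
                   total_reads = as.integer(totals),
                   rel_abund = totals / sum(totals),
                   occupancy = unname(prof$occupancy[table$otu_ids]))
  if (!is.null(tsv_path))
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(thresholds = as.list(part$thresholds),
                              summary = part$summary),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(df)
}
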