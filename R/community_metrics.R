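#' Bray-Curtis dissimilarity between samples
#'
#' `BC(a, b) = 1 - 2 * sum_j min(a_j, b_j) / (sum_j a_j + sum_j b_j)`,
#' computed on counts. On a rarefied table (equal depth) this equals the
#' proportion-based form up to scaling.
#'
#' @param table An [otu_table] with at least two samples and no all-zero
#'   sample.
#' @return A [dist_matrix] with values in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  x <- table$counts
  if (nrow(x) < 2) stop("need >= 2 samples")
  tot <- rowSums(x)
  if (any(tot == 0))
    stop("all-zero samples: ",
         paste(table$sample_ids[tot == 0], collapse = ", "))
  bc_from_matrix(x, table$sample_ids)
}

# Core on a plain count matrix; reused on null realizations where building
# a full otu_table per draw would dominate run time.
bc_from_matrix <- function(x, labels = rownames(x)) {
  n <- nrow(x)
  tot <- rowSums(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    xi <- x[i, ]
    for (j in (i + 1):n) {
      s <- sum(pmin(xi, x[j, ]))
      d[i, j] <- d[j, i] <- 1 - 2 * s / (tot[i] + tot[j])
    }
  }
  dist_matrix(d, labels = labels, metric_name = "bray_curtis")
}

#' Great-circle geographic distances between samples
#'
#' Haversine distance in kilometres on a sphere of radius 6371.0088 km.
#'
#' @param meta Metadata `data.frame` with `latitude` and `longitude` in
#'   decimal degrees.
#' @return A [dist_matrix] in km.
#' @export
geographic_distance <- function(meta) {
  if (!all(c("latitude", "longitude") %in% names(meta)))
    stop("metadata must contain latitude and longitude")
  lat <- meta$latitude; lon <- meta$longitude
  if (anyNA(lat) || anyNA(lon))
    stop("missing coordinates for: ",
         paste(meta$sample_id[is.na(lat) | is.na(lon)], collapse = ", "))
  stopifnot(all(abs(lat) <= 90), all(abs(lon) <= 180))
  R <- 6371.0088
  phi <- lat * pi / 180; lam <- lon * pi / 180
  n <- length(phi)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    a <- sin((phi[j] - phi[i]) / 2)^2 +
      cos(phi[i]) * cos(phi[j]) * sin((lam[j] - lam[i]) / 2)^2
    dij <- 2 * R * asin(pmin(1, sqrt(a)))
    d[i, j] <- dij; d[j, i] <- dij
  }
  dist_matrix(d, labels = meta$sample_id, metric_name = "geographic_km")
}

#' Standardized environmental Euclidean distances
#'
#' Each variable is z-scored (mean 0, sd 1 with denominator n-1) before
#' computing Euclidean distances, so variables on different scales
#' contribute comparably.
#'
#' @param meta Metadata `data.frame`.
#' @param variables Character vector of column names to include.
#' @return A [dist_matrix].
#' @export
environmental_distance <- function(meta, variables) {
  missing_vars <- setdiff(variables, names(meta))
  if (length(missing_vars))
    stop("variables absent from metadata: ",
         paste(missing_vars, collapse = ", "))
  x <- as.matrix(meta[, variables, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance variable(s): ",
         paste(variables[sds == 0], collapse = ", "))
  z <- scale(x)
  dist_matrix(as.matrix(stats::dist(z)), labels = meta$sample_id,
              metric_name = paste0("env_euclid[",
                                   paste(variables, collapse = ","), "]"))
}

#' Per-variable absolute-difference distance matrix
#'
#' `|x_i - x_j|` for a single metadata variable; the form environmental
#' candidates take in Mantel / MRM tables that list variables individually.
#'
#' @param meta Metadata `data.frame`.
#' @param variable Column name.
#' @return A [dist_matrix].
#' @export
variable_difference <- function(meta, variable) {
  if (!variable %in% names(meta)) stop("no such variable: ", variable)
  v <- meta[[variable]]
  dist_matrix(abs(outer(v, v, "-")), labels = meta$sample_id,
              metric_name = paste0("abs_diff[", variable, "]"))
}

#' Distance-decay regression of community similarity on geographic distance
#'
#' Ordinary least squares of similarity (`1 - dissimilarity`) on geographic
#' distance over all unordered sample pairs. Because pairs sharing a sample
#' are not independent, significance is assessed by permuting sample labels
#' of the community matrix (default 999 permutations, two-sided on the
#' slope) rather than by the naive OLS t-test.
#'
#' @param community_dist Community dissimilarity [dist_matrix].
#' @param geo_dist Geographic [dist_matrix] with identical labels.
#' @param n_perm Number of label permutations for the p-value.
#' @param seed RNG seed.
#' @return A `ddr_fit`: `slope` (similarity per km), `intercept`,
#'   `r_squared`, `p_value`, `n_pairs`, `n_perm`.
#' @export
distance_decay <- function(community_dist, geo_dist, n_perm = 999,
                           seed = NULL) {
  check_same_labels(community_dist, geo_dist)
  n <- length(community_dist$labels)
  if (n < 3) stop("need >= 3 samples")
  sim <- 1 - community_dist$values
  x <- upper_vec(geo_dist$values)
  y <- upper_vec(sim)
  if (stats::sd(x) == 0) stop("geographic distances are constant")
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 0
  p <- with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      pi <- sample.int(n)
      yp <- upper_vec(sim[pi, pi])
      sp <- stats::lm.fit(cbind(1, x), yp)$coefficients[2]
      if (abs(sp) >= abs(slope) - 1e-15) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_perm)
  })
  structure(list(slope = unname(slope),
                 intercept = unname(fit$coefficients[1]),
                 r_squared = r2, p_value = p,
                 n_pairs = length(y), n_perm = n_perm),
            class = "ddr_fit")
}

#' @export
print.ddr_fit <- function(x, ...) {
  cat(sprintf(
    "distance-decay: slope %.4g per 100 km (%.3g per km), R^2 %.3f, p %.4g (%d pairs)\n",
    100 * x$slope, x$slope, x$r_squared, x$p_value, x$n_pairs))
  invisible(x)
}

#' Levins niche breadth per OTU and abundance-weighted community breadth
#'
#' For OTU j with proportions `P_ij = count_ij / total_j` across samples i,
#' `B_j = 1 / sum_i P_ij^2` (inverse Simpson concentration across habitats;
#' 1 = confined to one sample, n_samples = perfectly even). The community
#' value `Bcom_k` is the abundance-weighted mean of `B_j` over OTUs present
#' in sample k, with weights `count_jk / N_k` (summing to one per sample).
#'
#' @param table An [otu_table] in which every OTU has a positive total.
#' @return A `niche_breadth_result`: `B` (named per OTU) and `Bcom` (named
#'   per sample).
#' @export
levins_breadth <- function(table) {
  tot <- otu_totals(table)
  if (any(tot == 0))
    stop("zero-total OTUs (filter first): ",
         paste(table$otu_ids[tot == 0], collapse = ", "))
  P <- sweep(table$counts, 2, tot, "/")
  B <- 1 / colSums(P^2)
  W <- table$counts / rowSums(table$counts)
  Bcom <- as.numeric(W %*% B)
  structure(list(B = stats::setNames(B, table$otu_ids),
                 Bcom = stats::setNames(Bcom, table$sample_ids)),
            class = "niche_breadth_result")
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided Mann-Whitney test with normal approximation and tie
#' correction, the convention used for comparing per-sample summaries (e.g.
#' Bcom) between sub-communities.
#'
#' @param values_a,values_b Numeric vectors (each length >= 2).
#' @return List with `statistic` (Mann-Whitney U of the first group), `p`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("both groups need >= 2 values")
  ht <- stats::wilcox.test(values_a, values_b, exact = FALSE,
                           correct = FALSE)
  list(statistic = unname(ht$statistic), p = ht$p.value)
}
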