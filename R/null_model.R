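#' Draw one abundance-constrained null community
#'
#' For each sample k with observed richness `S_k` and depth `N_k`, the null
#' sample (1) picks `S_k` distinct OTUs by weighted sampling without
#' replacement with weights equal to regional relative abundances (column
#' totals of the table), (2) seeds each picked OTU with one individual, and
#' (3) distributes the remaining `N_k - S_k` individuals multinomially over
#' the picked OTUs with renormalized regional weights. This preserves each
#' sample's richness and depth exactly while remaining
#' abundance-proportional.
#'
#' @param table An [otu_table] with no all-zero samples.
#' @param seed RNG seed (`NULL` to consume the current stream).
#' @return A null [otu_table] with the same labels.
#' @export
generate_null_community <- function(table, seed = NULL) {
  m <- with_seed(seed, null_counts(table$counts))
  otu_table(m, sample_ids = table$sample_ids, otu_ids = table$otu_ids,
            taxonomy = table$taxonomy)
}

# Matrix-level core consuming the current RNG stream; called once per null
# realization inside beta_deviation.
null_counts <- function(x) {
  regional <- colSums(x)
  pool <- which(regional > 0)
  w <- regional[pool] / sum(regional[pool])
  n_samp <- nrow(x)
  out <- matrix(0L, n_samp, ncol(x), dimnames = dimnames(x))
  S <- rowSums(x > 0)
  N <- rowSums(x)
  if (any(N == 0)) stop("all-zero sample in table")
  if (any(S > length(pool)))
    stop("sample richness exceeds regional pool size")
  for (k in seq_len(n_samp)) {
    picked <- if (S[k] == length(pool)) pool
              else pool[sample.int(length(pool), S[k], prob = w)]
    cnt <- rep(1L, S[k])
    extra <- N[k] - S[k]
    if (extra > 0) {
      pw <- regional[picked]
      cnt <- cnt + as.integer(stats::rmultinom(1, extra, pw / sum(pw)))
    }
    out[k, picked] <- cnt
  }
  out
}

#' Beta-deviation: standardized effect size of beta-diversity
#'
#' Bray-Curtis dissimilarity is computed on the observed table and on
#' `n_null` null realizations from [generate_null_community]; for each
#' sample pair, `beta_deviation = (obs - mean(null)) / sd(null)` with the
#' sd over nulls using denominator n-1. Pairs whose null sd is zero are set
#' to 0 with a warning (degenerate pools). Values well above zero indicate
#' more compositional turnover than expected from regional abundances alone
#' (dispersal limitation or heterogeneous selection); values well below
#' zero indicate homogenization.
#'
#' @param table An [otu_table].
#' @param n_null Number of null communities (default 999).
#' @param seed RNG seed; results are bit-identical for identical seeds.
#' @return A `beta_deviation_result`: `beta_dev`, `observed`, `null_mean`,
#'   `null_sd` (all [dist_matrix]), `n_null`, `seed`.
#' @export
beta_deviation <- function(table, n_null = 999, seed = NULL) {
  stopifnot(n_null >= 2)
  obs <- bray_curtis(table)
  n <- length(obs$labels)
  n_pairs <- n * (n - 1) / 2
  nulls <- with_seed(seed, {
    res <- matrix(0, n_pairs, n_null)
    for (b in seq_len(n_null)) {
      nb <- null_counts(table$counts)
      res[, b] <- upper_vec(bc_from_matrix(nb)$values)
    }
    res
  })
  mu <- rowMeans(nulls)
  sdv <- apply(nulls, 1, stats::sd)
  obs_v <- upper_vec(obs$values)
  dev <- (obs_v - mu) / sdv
  zero_sd <- sdv == 0
  if (any(zero_sd)) {
    warning(sum(zero_sd), " pair(s) with zero null sd set to 0")
    dev[zero_sd] <- 0
  }
  fold <- function(v) {
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- v
    m + t(m)
  }
  structure(list(
    beta_dev = dist_matrix(fold(dev), labels = obs$labels,
                           metric_name = "beta_deviation"),
    observed = obs,
    null_mean = dist_matrix(fold(mu), labels = obs$labels,
                            metric_name = "null_mean_bray_curtis"),
    null_sd = dist_matrix(fold(sdv), labels = obs$labels,
                          metric_name = "null_sd_bray_curtis"),
    n_null = n_null, seed = seed),
    class = "beta_deviation_result")
}

#' @export
print.beta_deviation_result <- function(x, ...) {
  v <- pair_vector(x$beta_dev)
  cat(sprintf(
    "beta_deviation over %d pairs (n_null = %d): mean %.3f, median %.3f, sd %.3f\n",
    length(v), x$n_null, mean(v), stats::median(v), stats::sd(v)))
  invisible(x)
}

#' Test whether beta-deviations differ from zero
#'
#' One-sample Wilcoxon signed-rank test of the pairwise beta-deviations
#' against zero, two-sided; direction is the sign of the median.
#'
#' @param result A `beta_deviation_result`.
#' @return List with `statistic` (V), `p`, `direction` (`"positive"`,
#'   `"negative"` or `"none"`), `median`.
#' @export
test_deviation_sign <- function(result) {
  v <- pair_vector(result$beta_dev)
  if (length(v) < 2) stop("need >= 2 pairs")
  if (all(v == 0))
    return(list(statistic = 0, p = 1, direction = "none", median = 0))
  ht <- suppressWarnings(stats::wilcox.test(v, mu = 0))
  med <- stats::median(v)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       direction = if (med > 0) "positive" else if (med < 0) "negative"
                   else "none",
       median = med)
}

#' Interpret a beta-deviation test as an assembly-process label
#'
#' At `alpha` (default 0.05): significantly positive beta-deviation points
#' to dispersal limitation or heterogeneous selection; significantly
#' negative to homogenizing dispersal or homogeneous selection; otherwise
#' stochastic processes dominate.
#'
#' @param result A `beta_deviation_result`.
#' @param test Output of [test_deviation_sign] (computed if missing).
#' @param alpha Significance level.
#' @return One of `"stochastic-dominated"`,
#'   `"dispersal-limitation-or-heterogeneous-selection"`,
#'   `"homogenizing-dispersal-or-homogeneous-selection"`.
#' @export
interpret_deviation <- function(result, test = test_deviation_sign(result),
                                alpha = 0.05) {
  if (test$p >= alpha || test$direction == "none")
    return("stochastic-dominated")
  if (test$direction == "positive")
    "dispersal-limitation-or-heterogeneous-selection"
  else
    "homogenizing-dispersal-or-homogeneous-selection"
}

#' Write beta-deviation outputs
#' @param result A `beta_deviation_result`.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisible vector of paths written.
#' @export
write_beta_deviation <- function(result, dir, prefix = "beta_deviation") {
  p1 <- file.path(dir, paste0(prefix, ".tsv"))
  write_dist_matrix(result$beta_dev, p1)
  p2 <- file.path(dir, paste0(prefix, "_params.json"))
  jsonlite::write_json(list(n_null = result$n_null,
                            seed = result$seed %||% NA),
                       p2, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2))
}
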