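#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle pair vectors, with a
#' permutation p-value obtained by jointly permuting rows and columns of
#' the second matrix. One-sided (positive association) by default, the
#' usual ecological convention; `alternative = "two.sided"` compares
#' absolute correlations instead.
#'
#' @param a,b [dist_matrix] objects with identical labels, >= 4 samples.
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A `mantel_result`: `r`, `p`, `n_perm`.
#' @export
mantel <- function(a, b, n_perm = 999, seed = NULL,
                   alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  check_same_labels(a, b)
  n <- length(a$labels)
  if (n < 4) stop("need >= 4 samples")
  av <- upper_vec(a$values)
  bm <- b$values
  bv <- upper_vec(bm)
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop("constant distance matrix")
  r_obs <- stats::cor(av, bv)
  stat <- function(r) if (alternative == "greater") r else abs(r)
  p <- with_seed(seed, {
    hits <- 0L
    for (k in seq_len(n_perm)) {
      pi <- sample.int(n)
      rp <- stats::cor(av, upper_vec(bm[pi, pi]))
      if (stat(rp) >= stat(r_obs) - 1e-15) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_perm)
  })
  structure(list(r = r_obs, p = p, n_perm = n_perm,
                 alternative = alternative),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.3f, p = %.4g (%d permutations, %s)\n",
              x$r, x$p, x$n_perm, x$alternative))
  invisible(x)
}

# OLS of a response pair vector on a set of predictor pair vectors;
# returns coefficients and R^2.
pair_ols <- function(y, X) {
  Xm <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(Xm)
  if (qrx$rank < ncol(Xm)) {
    dropped <- colnames(Xm)[qrx$pivot[(qrx$rank + 1):ncol(Xm)]]
    stop("rank-deficient predictor set (collinear): ",
         paste(dropped, collapse = ", "))
  }
  coefs <- qr.coef(qrx, y)
  res <- y - Xm %*% coefs
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 0
  list(coefficients = coefs, r_squared = r2, qr = qrx)
}

#' Multiple regression on distance matrices with forward selection
#'
#' Response and candidate matrices are unfolded to pair vectors. At each
#' step candidates are ranked by the R-squared increase their addition
#' yields; starting from the best, each is tested by a permutation test on
#' its coefficient (rows/columns of the response matrix permuted jointly,
#' model refit, comparison on absolute coefficients) and the first with
#' p < `alpha` enters. Selection stops when no remaining candidate
#' qualifies. The final model is refit with all selected predictors.
#'
#' @param response A [dist_matrix].
#' @param candidates Named list of candidate [dist_matrix] objects.
#' @param alpha Entry threshold on the permutation p-value (default 0.05).
#' @param n_perm Permutations per coefficient test (default 999).
#' @param seed RNG seed.
#' @return An `mrm_result`: `selected` (ordered names), `coefficients`
#'   (final refit, including intercept), `r_squared`, `p_values` (entry
#'   p per selected predictor), `n_perm`.
#' @export
mrm_forward_select <- function(response, candidates, alpha = 0.05,
                               n_perm = 999, seed = NULL) {
  stopifnot(length(candidates) >= 1)
  if (is.null(names(candidates)) || any(!nzchar(names(candidates))))
    stop("candidates must be a named list")
  for (cm in candidates) check_same_labels(response, cm)
  n <- length(response$labels)
  ym <- response$values
  X_all <- vapply(candidates, function(cm) upper_vec(cm$values),
                  numeric(n * (n - 1) / 2))
  y <- upper_vec(ym)
  selected <- character(0)
  entry_p <- numeric(0)
  with_seed(seed, {
    remaining <- names(candidates)
    while (length(remaining) > 0 && alpha > 0) {
      base_X <- X_all[, selected, drop = FALSE]
      gains <- vapply(remaining, function(v) {
        pair_ols(y, cbind(base_X, X_all[, v, drop = FALSE]))$r_squared
      }, numeric(1))
      added <- NULL
      for (v in names(sort(gains, decreasing = TRUE))) {
        Xv <- cbind(base_X, X_all[, v, drop = FALSE])
        colnames(Xv) <- c(selected, v)
        fit <- pair_ols(y, Xv)
        b_obs <- abs(fit$coefficients[[v]])
        hits <- 0L
        for (k in seq_len(n_perm)) {
          pi <- sample.int(n)
          yp <- upper_vec(ym[pi, pi])
          bp <- abs(qr.coef(fit$qr, yp)[[v]])
          if (bp >= b_obs - 1e-15) hits <- hits + 1L
        }
        pv <- (1 + hits) / (1 + n_perm)
        if (pv < alpha) {
          added <- v
          selected <- c(selected, v)
          entry_p <- c(entry_p, stats::setNames(pv, v))
          break
        }
      }
      if (is.null(added)) break
      remaining <- setdiff(remaining, selected)
    }
  })
  if (length(selected) > 0) {
    fit <- pair_ols(y, X_all[, selected, drop = FALSE])
    coefs <- fit$coefficients
    r2 <- fit$r_squared
  } else {
    coefs <- c(`(Intercept)` = mean(y))
    r2 <- 0
  }
  structure(list(selected = selected, coefficients = coefs,
                 r_squared = r2, p_values = entry_p, n_perm = n_perm),
            class = "mrm_result")
}

#' @export
print.mrm_result <- function(x, ...) {
  cat("MRM forward selection: ",
      if (length(x$selected)) paste(x$selected, collapse = " + ")
      else "(none)",
      sprintf(" | R^2 = %.3f\n", x$r_squared), sep = "")
  invisible(x)
}

#' Variation partitioning of a distance-matrix response
#'
#' Partitions the variance of a response pair vector (typically the
#' beta-deviation matrix) explained by environmental vs spatial predictor
#' matrices: with `R2_ES` from the joint model, `R2_E` (environment only)
#' and `R2_S` (space only), the pure fractions are
#' `env = R2_ES - R2_S`, `space = R2_ES - R2_E`,
#' `shared = R2_E + R2_S - R2_ES`, `residual = 1 - R2_ES`. Plain (not
#' adjusted) R-squared on pair vectors is used.
#'
#' @param response A [dist_matrix].
#' @param env Named list of environmental [dist_matrix] predictors.
#' @param space Named list of spatial [dist_matrix] predictors.
#' @return A `vpa_result`: `env_individual`, `space_individual`, `shared`,
#'   `residual` (fractions of 1), `r2_full`, and `esdr`.
#' @export
variation_partition <- function(response, env, space) {
  stopifnot(length(env) >= 1, length(space) >= 1)
  for (cm in c(env, space)) check_same_labels(response, cm)
  y <- upper_vec(response$values)
  unfold <- function(set) {
    X <- vapply(set, function(cm) upper_vec(cm$values), numeric(length(y)))
    colnames(X) <- names(set)
    X
  }
  Xe <- unfold(env); Xs <- unfold(space)
  r2_es <- pair_ols(y, cbind(Xe, Xs))$r_squared
  r2_e <- pair_ols(y, Xe)$r_squared
  r2_s <- pair_ols(y, Xs)$r_squared
  vpa_result(env_individual = r2_es - r2_s,
             space_individual = r2_es - r2_e,
             shared = r2_e + r2_s - r2_es,
             residual = 1 - r2_es)
}

#' Assemble a variation-partitioning result from its fractions
#'
#' Useful for ESDR arithmetic on fractions reported elsewhere; fractions
#' must sum to 1 (tolerance 1e-9).
#'
#' @param env_individual,space_individual,shared,residual Fractions of
#'   total variance.
#' @return A `vpa_result` with `esdr` populated (NA with a warning when
#'   `space_individual <= 0`).
#' @export
vpa_result <- function(env_individual, space_individual, shared, residual) {
  tot <- env_individual + space_individual + shared + residual
  if (abs(tot - 1) > 1e-9)
    stop("fractions must sum to 1, got ", format(tot, digits = 12))
  x <- structure(list(env_individual = env_individual,
                      space_individual = space_individual,
                      shared = shared, residual = residual,
                      r2_full = 1 - residual, esdr = NA_real_),
                 class = "vpa_result")
  x$esdr <- esdr(x)
  x
}

#' @export
print.vpa_result <- function(x, ...) {
  cat(sprintf(
    "VPA: env %.2f%% | shared %.2f%% | space %.2f%% | residual %.2f%% | ESDR %s\n",
    100 * x$env_individual, 100 * x$shared, 100 * x$space_individual,
    100 * x$residual,
    if (is.na(x$esdr)) "undefined" else sprintf("%.3f", x$esdr)))
  invisible(x)
}

#' Environmental-selection to dispersal-limitation ratio
#'
#' The ratio of the pure environmental fraction to the pure spatial
#' fraction of a variation partitioning; values below 1 indicate dispersal
#' limitation outweighs environmental selection.
#'
#' @param v A `vpa_result`.
#' @return `env_individual / space_individual`, or `NA` with a warning when
#'   `space_individual <= 0`.
#' @export
esdr <- function(v) {
  if (!is.finite(v$space_individual) || v$space_individual <= 0) {
    warning("space_individual <= 0: ESDR undefined")
    return(NA_real_)
  }
  v$env_individual / v$space_individual
}

#' Split beta-deviations along an environmental gradient
#'
#' Samples are divided into low/high groups of (near-)equal size at the
#' median of `variable` (odd counts put the extra sample in the low group).
#' A beta-deviation pair is assigned to a group only when both its samples
#' belong to it; the two within-group distributions are compared with a
#' Wilcoxon rank-sum test.
#'
#' @param result A `beta_deviation_result`.
#' @param meta Metadata `data.frame` covering all samples of `result`.
#' @param variable Metadata column to split on.
#' @return List with `low`, `high` (numeric beta-deviation vectors),
#'   `groups` (named factor), `test` (from [compare_groups]).
#' @export
gradient_split_deviation <- function(result, meta, variable) {
  labels <- result$beta_dev$labels
  idx <- match(labels, meta$sample_id)
  if (anyNA(idx))
    stop("metadata missing samples: ",
         paste(labels[is.na(idx)], collapse = ", "))
  v <- meta[[variable]][idx]
  if (is.null(v)) stop("no such variable: ", variable)
  if (length(unique(v)) < 2) stop("variable '", variable, "' is constant")
  n <- length(v)
  n_low <- ceiling(n / 2)
  ord <- order(v, seq_along(v))   # stable tie-break by sample order
  grp <- rep("high", n)
  grp[ord[seq_len(n_low)]] <- "low"
  if (min(table(grp)) < 2) stop("fewer than 2 samples in a group")
  m <- result$beta_dev$values
  pick <- function(g) {
    sel <- which(grp == g)
    upper_vec(m[sel, sel, drop = FALSE])
  }
  low <- pick("low"); high <- pick("high")
  list(low = low, high = high,
       groups = stats::setNames(factor(grp, levels = c("low", "high")),
                                labels),
       test = if (length(low) >= 2 && length(high) >= 2)
         compare_groups(low, high))
}
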