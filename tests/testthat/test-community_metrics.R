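test_that("bray_curtis handles canonical cases and matches the double loop", {
  counts <- rbind(a = c(1L, 1L, 0L), b = c(0L, 1L, 1L), c = c(1L, 1L, 0L))
  bc <- bray_curtis(otu_table(counts))
  m <- as.matrix(bc)
  expect_equal(m["a", "b"], 0.5)   # 1 - 2*1/4
  expect_equal(m["a", "c"], 0)     # identical samples
  disjoint <- otu_table(rbind(c(3L, 0L), c(0L, 7L)))
  expect_equal(as.matrix(bray_curtis(disjoint))[1, 2], 1)

  tab <- random_table(8, 30, depth = 500, seed = 21)
  got <- as.matrix(bray_curtis(tab))
  x <- tab$counts
  for (i in 1:7) for (j in (i + 1):8) {
    oracle <- 1 - 2 * sum(pmin(x[i, ], x[j, ])) /
      (sum(x[i, ]) + sum(x[j, ]))
    expect_equal(got[i, j], oracle)
  }
  expect_true(all(got >= 0 & got <= 1))
  zero <- tab; zero$counts[2, ] <- 0L
  expect_error(bray_curtis(zero), "all-zero")
})

test_that("bray_curtis agrees with vegan and is permutation-equivariant", {
  skip_if_not_installed("vegan")
  tab <- random_table(10, 40, depth = 700, seed = 22)
  got <- as.matrix(bray_curtis(tab))
  ref <- as.matrix(vegan::vegdist(tab$counts, method = "bray"))
  expect_equal(unname(got), unname(ref), tolerance = 1e-12)
  perm <- sample(10)
  tab2 <- otu_table(tab$counts[perm, ], sample_ids = tab$sample_ids[perm],
                    otu_ids = tab$otu_ids)
  expect_equal(as.matrix(bray_curtis(tab2)),
               as.matrix(bray_curtis(tab))[perm, perm])
})

test_that("geographic distance matches the spherical law of cosines", {
  meta <- data.frame(sample_id = c("p", "q"),
                     latitude = c(10, -10), longitude = c(20, -160))
  d <- geographic_distance(meta)
  expect_equal(as.matrix(d)[1, 2], pi * 6371.0088, tolerance = 1e-6)
  meta2 <- data.frame(sample_id = c("x", "x2"),
                      latitude = c(45, 45), longitude = c(7, 7))
  expect_equal(as.matrix(geographic_distance(meta2))[1, 2], 0)

  set.seed(23)
  meta3 <- data.frame(sample_id = paste0("s", 1:8),
                      latitude = runif(8, -60, 60),
                      longitude = runif(8, -180, 180))
  got <- as.matrix(geographic_distance(meta3))
  R <- 6371.0088
  phi <- meta3$latitude * pi / 180; lam <- meta3$longitude * pi / 180
  for (i in 1:7) for (j in (i + 1):8) {
    slc <- R * acos(pmin(1, sin(phi[i]) * sin(phi[j]) +
      cos(phi[i]) * cos(phi[j]) * cos(lam[i] - lam[j])))
    expect_lt(abs(got[i, j] - slc), 1e-3)  # < 1 m
  }
  meta3$latitude[2] <- NA
  expect_error(geographic_distance(meta3), "missing coordinates.*s2")
})

test_that("environmental distance z-scores then takes Euclidean norms", {
  meta <- tiny_meta(9, seed = 24)
  d <- environmental_distance(meta, c("pH", "TSP"))
  z <- scale(as.matrix(meta[, c("pH", "TSP")]))
  oracle <- as.matrix(dist(z))
  expect_equal(unname(as.matrix(d)), unname(oracle), tolerance = 1e-12)
  # duplicated variable scales all pairs by sqrt(2)
  meta$pH2 <- meta$pH
  d2 <- environmental_distance(meta, c("pH", "pH2"))
  d1 <- environmental_distance(meta, "pH")
  expect_equal(as.matrix(d2), sqrt(2) * as.matrix(d1), tolerance = 1e-12)
  meta$flat <- 1
  expect_error(environmental_distance(meta, c("pH", "flat")), "flat")
})

test_that("distance decay recovers the closed-form OLS line", {
  meta <- tiny_meta(10, seed = 25)
  tab <- random_table(10, 50, depth = 600, seed = 25)
  bc <- bray_curtis(tab)
  geo <- geographic_distance(meta)
  fit <- distance_decay(bc, geo, n_perm = 99, seed = 1)
  x <- as.matrix(geo)[upper.tri(as.matrix(geo))]
  y <- (1 - as.matrix(bc))[upper.tri(as.matrix(bc))]
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit$slope, sl, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(y) - sl * mean(x), tolerance = 1e-12)
  expect_equal(fit$n_pairs, 45)
  expect_equal(distance_decay(bc, geo, n_perm = 99, seed = 7)$p_value,
               distance_decay(bc, geo, n_perm = 99, seed = 7)$p_value)
})

test_that("constant community similarity gives slope zero", {
  n <- 6
  m <- matrix(0.4, n, n); diag(m) <- 0
  cd <- dist_matrix(m, labels = sprintf("S%02d", 1:n))
  geo <- random_dist(n, seed = 26)
  fit <- distance_decay(cd, geo, n_perm = 49, seed = 1)
  expect_equal(fit$slope, 0)
})

test_that("dispersal-structured data decays with distance", {
  cfg <- scenario_config(regime = "dispersal_limited", n_samples = 18,
                         n_otus = 150, depth = 1000, seed = 31)
  meta <- make_metadata(cfg)
  tab <- make_community(cfg, meta)
  fit <- distance_decay(bray_curtis(tab), geographic_distance(meta),
                        n_perm = 199, seed = 2)
  expect_lt(fit$slope, 0)
  expect_lte(fit$p_value, 0.05)
})

test_that("Levins breadth hits its closed forms and invariants", {
  # even spread over 4 samples -> B = 4; confined -> B = 1
  counts <- cbind(even = c(5L, 5L, 5L, 5L), one = c(8L, 0L, 0L, 0L),
                  half = c(6L, 6L, 0L, 0L))
  nb <- levins_breadth(otu_table(counts))
  expect_equal(unname(nb$B), c(4, 1, 2))
  # a sample containing only the P=(0.5,0.5,0) OTU has Bcom = that OTU's B
  counts2 <- rbind(c(0L, 0L, 4L), c(5L, 3L, 4L), c(2L, 0L, 0L))
  nb2 <- levins_breadth(otu_table(counts2))
  expect_equal(unname(nb2$Bcom[1]), unname(nb2$B[3]))
  # scale invariance of B_j
  tab <- random_table(8, 20, depth = 300, seed = 27)
  tab2 <- otu_table(tab$counts * 3L, sample_ids = tab$sample_ids,
                    otu_ids = tab$otu_ids)
  keep <- colSums(tab$counts) > 0
  expect_equal(levins_breadth(tab)$B[keep], levins_breadth(tab2)$B[keep])
  # Bcom bounded by the B range
  nb3 <- levins_breadth(tab)
  expect_true(all(nb3$Bcom >= min(nb3$B) - 1e-12))
  expect_true(all(nb3$Bcom <= max(nb3$B) + 1e-12))
  expect_error(levins_breadth(otu_table(cbind(c(1L, 1L), c(0L, 0L)))),
               "zero-total")
})

test_that("broadly distributed taxa have larger Bcom than clumped ones", {
  set.seed(28)
  n <- 12
  broad <- t(stats::rmultinom(n, 400, rep(1 / 30, 30)))
  clumped <- matrix(0L, n, 30)
  for (j in 1:30) clumped[sample.int(n, 2), j] <- 200L
  b_broad <- levins_breadth(otu_table(broad))
  b_clump <- levins_breadth(otu_table(clumped))
  expect_gt(mean(b_broad$Bcom), mean(b_clump$Bcom))
})

test_that("compare_groups matches a brute-force rank-sum and detects shifts", {
  a <- c(1.2, 3.4, 0.5, 2.2); b <- c(4.5, 6.1, 5.0)
  res <- compare_groups(a, b)
  # brute-force Mann-Whitney U: pairs where a beats b (+0.5 per tie)
  u <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  expect_equal(res$statistic, u)
  same <- c(1, 2, 3, 4, 5)
  expect_gt(compare_groups(same, same)$p, 0.95)
  set.seed(29)
  res2 <- compare_groups(rnorm(24), rnorm(24, mean = 3))
  expect_lt(res2$p, 0.001)
  expect_error(compare_groups(1, c(1, 2)), ">= 2 values")
})
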