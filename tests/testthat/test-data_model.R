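test_that("otu_table validates shape, labels and counts", {
  m <- matrix(1:6, 2, 3)
  t1 <- otu_table(m)
  expect_s3_class(t1, "otu_table")
  expect_equal(dim(t1), c(2L, 3L))
  expect_error(otu_table(m, sample_ids = c("a", "a")), "duplicate sample")
  expect_error(otu_table(m, otu_ids = c("x", "y", "x")), "duplicate OTU")
  m2 <- m; m2[2, 1] <- -1
  expect_error(otu_table(m2), "negative count")
  m3 <- matrix(c(1, 2.5, 3, 4), 2, 2)
  expect_error(otu_table(m3), "non-integer count")
})

test_that("TSV round-trip preserves counts, labels and taxonomy", {
  tab <- random_table(10, 20, seed = 1, taxonomy = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tab, path)
  back <- read_otu_table(path, format = "biom_tsv")
  expect_identical(back$counts, tab$counts)
  expect_identical(back$sample_ids, tab$sample_ids)
  expect_identical(back$otu_ids, tab$otu_ids)
  expect_identical(back$taxonomy, tab$taxonomy)
  # taxonomy auto-detected from the header even without biom_tsv
  expect_identical(read_otu_table(path)$taxonomy, tab$taxonomy)
  # comment lines are ignored
  lines <- readLines(path)
  writeLines(c("# Constructed from biom file", lines), path)
  expect_identical(read_otu_table(path)$counts, tab$counts)
})

test_that("read_otu_table rejects malformed tables", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\tS1\tS2", "o1\t3\t-2"), path)
  expect_error(read_otu_table(path), "negative")
  writeLines(c("#OTU ID\tS1\tS2", "o1\t3\tx"), path)
  expect_error(read_otu_table(path), "non-numeric.*o1.*S2")
  writeLines(c("#OTU ID\tS1\tS2", "o1\t3\t2", "o1\t1\t1"), path)
  expect_error(read_otu_table(path), "duplicate")
})

test_that("filter_low_count_otus applies a strict 'less than' threshold", {
  counts <- rbind(c(10, 10, 11), c(9, 10, 10))  # totals 19, 20, 21
  tab <- otu_table(counts, otu_ids = c("a", "b", "c"))
  kept <- filter_low_count_otus(tab, 20)
  expect_identical(kept$otu_ids, c("b", "c"))
  expect_identical(filter_low_count_otus(tab, 0)$counts, tab$counts)
  expect_error(filter_low_count_otus(tab, 100), "all OTUs removed")
})

test_that("filter matches brute-force column filter and is idempotent", {
  tab <- random_table(8, 30, depth = 60, seed = 4)
  f <- filter_low_count_otus(tab, 15)
  keep <- colSums(tab$counts) >= 15          # oracle
  expect_identical(f$counts, tab$counts[, keep])
  f2 <- filter_low_count_otus(f, 15)
  expect_identical(f2$counts, f$counts)
})

test_that("rarefy hits depth exactly, never inflates, and is seeded", {
  tab <- random_table(6, 25, depth = 400, seed = 2)
  r1 <- rarefy(tab, 150, seed = 11)
  expect_true(all(rowSums(r1$counts) == 150))
  expect_true(all(colSums(r1$counts) <= colSums(tab$counts)))
  r2 <- rarefy(tab, 150, seed = 11)
  expect_identical(r1$counts, r2$counts)
  expect_false(identical(rarefy(tab, 150, seed = 12)$counts, r1$counts))
  # depth == each total leaves counts unchanged
  expect_identical(rarefy(tab, 400, seed = 1)$counts, tab$counts)
  expect_error(rarefy(tab, 401, seed = 1), "below depth 401")
})

test_that("rarefaction cell means match the hypergeometric expectation", {
  tab <- random_table(4, 10, depth = 200, seed = 3)
  depth <- 80
  n_rep <- 1000
  acc <- matrix(0, 4, 10)
  for (s in seq_len(n_rep))
    acc <- acc + rarefy(tab, depth, seed = s)$counts
  means <- acc / n_rep
  N <- rowSums(tab$counts)
  expected <- depth * tab$counts / N
  # per-draw hypergeometric variance
  v <- depth * (tab$counts / N) * (1 - tab$counts / N) *
    ((N - depth) / (N - 1))
  se <- sqrt(v / n_rep)
  expect_true(all(abs(means - expected) <= 3 * se + 1e-9))
})

test_that("aridity index derivation matches direct division", {
  meta <- data.frame(sample_id = c("a", "b"), MAP = c(200, 500),
                     PET = c(1000, 500))
  out <- derive_aridity_index(meta)
  expect_equal(out$AI, c(0.2, 1.0))
  set.seed(8)
  meta2 <- data.frame(sample_id = paste0("s", 1:20),
                      MAP = runif(20, 50, 800), PET = runif(20, 500, 2000))
  expect_equal(derive_aridity_index(meta2)$AI, meta2$MAP / meta2$PET)
  meta$PET[1] <- 0
  expect_error(derive_aridity_index(meta), "PET is zero")
})

test_that("metadata round-trip and validation", {
  meta <- tiny_meta(6)
  meta <- derive_aridity_index(meta)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sample_metadata(meta, path)
  back <- read_sample_metadata(path)
  expect_equal(back$pH, meta$pH)
  expect_equal(back$AI, meta$AI)
  bad <- meta; bad$AI[2] <- bad$AI[2] + 1
  write_sample_metadata(bad, path)
  expect_error(read_sample_metadata(path), "AI inconsistent")
  bad2 <- meta; bad2$pH[1] <- 15
  write_sample_metadata(bad2, path)
  expect_error(read_sample_metadata(path), "pH outside")
})

test_that("collinearity screen drops violating variables", {
  set.seed(5)
  n <- 30
  x <- rnorm(n)
  meta <- data.frame(sample_id = paste0("s", 1:n),
                     a = x, b = x + rnorm(n, sd = 0.01),  # |r| ~ 1
                     c = rnorm(n))
  kept <- collinearity_screen(meta, c("a", "b", "c"))
  expect_length(intersect(kept, c("a", "b")), 1)
  expect_true("c" %in% kept)
  # all pairs below threshold: identity
  set.seed(6)
  meta2 <- data.frame(sample_id = paste0("s", 1:n),
                      u = rnorm(n), v = rnorm(n), w = rnorm(n))
  expect_identical(collinearity_screen(meta2, c("u", "v", "w")),
                   c("u", "v", "w"))
})

test_that("collinearity screen matches the greedy oracle on random sets", {
  greedy_oracle <- function(df, vars, thr) {
    repeat {
      r <- abs(stats::cor(df[, vars])); diag(r) <- 0
      if (all(r <= thr) || length(vars) < 2) return(vars)
      involved <- which(apply(r > thr, 1, any))
      ma <- rowMeans(r)[involved]
      worst <- involved[ma >= max(ma) - 1e-12]
      vars <- vars[-max(worst)]
    }
  }
  for (s in 1:5) {
    set.seed(100 + s)
    n <- 25
    base <- matrix(rnorm(n * 2), n, 2)
    mix <- base %*% matrix(rnorm(10), 2, 5) +
      matrix(rnorm(n * 5, sd = 0.6), n, 5)
    meta <- data.frame(sample_id = paste0("s", 1:n), mix)
    vars <- names(meta)[-1]
    expect_identical(collinearity_screen(meta, vars, 0.7),
                     greedy_oracle(meta, vars, 0.7))
  }
})

test_that("drop_override drops exactly the named variables", {
  set.seed(9)
  n <- 30
  x <- rnorm(n)
  meta <- data.frame(sample_id = paste0("s", 1:n),
                     a = x, b = x + rnorm(n, sd = 0.05), c = rnorm(n))
  expect_identical(collinearity_screen(meta, c("a", "b", "c"),
                                       drop_override = "b"), c("a", "c"))
  expect_warning(
    collinearity_screen(meta, c("a", "b", "c"), drop_override = "c"),
    "no correlation above")
})
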