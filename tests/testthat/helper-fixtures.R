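# Shared fixture builders: everything is generated in code, no data files.

# Random count table with a lognormal abundance profile.
random_table <- function(n_samples = 10, n_otus = 20, depth = 500,
                         seed = 1, taxonomy = FALSE) {
  set.seed(seed)
  mc <- rlnorm(n_otus, 0, 1.5)
  counts <- t(stats::rmultinom(n_samples, depth, mc / sum(mc)))
  tax <- if (taxonomy)
    stats::setNames(paste0("k__Fungi; p__Phylum", seq_len(n_otus) %% 5),
                    paste0("OTU", seq_len(n_otus)))
  otu_table(counts,
            sample_ids = sprintf("S%02d", seq_len(n_samples)),
            otu_ids = paste0("OTU", seq_len(n_otus)),
            taxonomy = tax)
}

# Random symmetric zero-diagonal matrix wrapped as dist_matrix.
random_dist <- function(n = 10, seed = 1, labels = sprintf("S%02d", 1:n)) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  dist_matrix(m + t(m), labels = labels)
}

# Minimal metadata frame for n samples.
tiny_meta <- function(n = 10, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("S%02d", seq_len(n)),
             latitude = runif(n, 43, 48),
             longitude = runif(n, 84, 92),
             pH = runif(n, 4.3, 7.5),
             TSP = runif(n, 0.36, 1.04),
             MAP = runif(n, 150, 500),
             PET = runif(n, 800, 1300))
}

# Build a beta_deviation_result-shaped object from a deviation matrix,
# for unit tests of the sign test / interpretation / gradient split.
fake_bdev <- function(values, labels = sprintf("S%02d", 1:nrow(values))) {
  structure(list(beta_dev = dist_matrix(values, labels = labels,
                                        metric_name = "beta_deviation"),
                 n_null = 999, seed = 0),
            class = "beta_deviation_result")
}
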