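#' Synthetic OTU table reproducing the survey-scale partition bookkeeping
#'
#' Deterministically constructs a 24-sample x 1,688-OTU count table whose
#' class structure matches the dryland montane forest soil survey that
#' motivates this package: 172 abundant OTUs carrying 398,367 reads, 969
#' rare OTUs carrying 23,647 reads (31 of them present in more than half
#' the samples), 547 intermediate OTUs carrying the remaining 82,994 reads,
#' and a grand total of 505,008 reads (24 x 21,042). The table is a
#' synthetic stand-in — individual counts are arbitrary within those
#' totals — built so that partition and occupancy bookkeeping can be
#' exercised at the published scale without the deposited sequence data.
#'
#' @return An [otu_table] (24 x 1688, total 505,008 reads).
#' @export
partition_design_table <- function() {
  n_samp <- 24L
  counts <- matrix(0L, n_samp, 1688L)
  # abundant: 172 OTUs, 398,367 reads, spread over all samples
  for (j in 1:172) {
    reads <- 2316L + (j <= 15L)
    base <- reads %/% n_samp
    rem <- reads %% n_samp
    counts[, j] <- base + (seq_len(n_samp) <= rem)
  }
  # intermediate: 547 OTUs, 82,994 reads, one sample each
  for (j in 173:719) {
    reads <- 151L + ((j - 172L) <= 397L)
    counts[(j - 173L) %% n_samp + 1L, j] <- reads
  }
  # rare: 969 OTUs, 23,647 reads; the first 31 occupy 13 samples,
  # the rest are confined to a single sample
  for (j in 720:1688) {
    reads <- 24L + ((j - 719L) <= 391L)
    if (j - 719L <= 31L) {
      counts[1:12, j] <- 1L
      counts[13L, j] <- reads - 12L
    } else {
      counts[(j - 720L) %% n_samp + 1L, j] <- reads
    }
  }
  otu_table(counts,
            sample_ids = sprintf("S%02d", seq_len(n_samp)),
            otu_ids = sprintf("OTU%04d", 1:1688))
}
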