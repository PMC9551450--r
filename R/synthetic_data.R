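#' Scenario configuration for the synthetic-data generator
#'
#' The defaults emulate the kind of dryland montane forest soil survey the
#' package targets: 24 sites over a ~600 km x 600 km region, equal
#' sequencing depth per sample, a soil pH gradient spanning 4.3-7.5 and a
#' total soil phosphorus (TSP) gradient spanning 0.36-1.04 g/kg. Community
#' sizes are scaled down (300 OTUs, depth 2,000) so a full pipeline with
#' 999 null communities runs in minutes; `paper_scale = TRUE` switches to a
#' survey-scale preset (1,688 OTUs, depth 21,042) for long runs.
#'
#' @param n_samples Number of sites (default 24).
#' @param n_otus Number of OTUs in the regional pool (default 300).
#' @param depth Reads per sample after rarefaction (default 2000).
#' @param regime One of `"neutral"`, `"dispersal_limited"`,
#'   `"env_filtered"`, `"mixed"`.
#' @param m Migration rate for the neutral regime (default 0.1).
#' @param kernel_scale Exponential dispersal-kernel scale in km
#'   (default 100).
#' @param env_strength Width (sd) of the Gaussian environmental response on
#'   each gradient variable, in that variable's units (default 0.5).
#' @param gradient_vars Metadata variables carrying the selective gradient
#'   (default `c("pH", "TSP")`).
#' @param seed Master RNG seed.
#' @param paper_scale Use survey-scale sizes (overrides `n_otus`, `depth`).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_samples = 24, n_otus = 300, depth = 2000,
                            regime = c("neutral", "dispersal_limited",
                                       "env_filtered", "mixed"),
                            m = 0.1, kernel_scale = 100, env_strength = 0.5,
                            gradient_vars = c("pH", "TSP"), seed = 1,
                            paper_scale = FALSE) {
  regime <- match.arg(regime)
  if (paper_scale) { n_otus <- 1688; depth <- 21042 }
  stopifnot(n_samples >= 2, n_otus >= 2, depth >= 1, m > 0, m <= 1,
            kernel_scale > 0, env_strength > 0)
  structure(list(n_samples = n_samples, n_otus = n_otus, depth = depth,
                 regime = regime, m = m, kernel_scale = kernel_scale,
                 env_strength = env_strength, gradient_vars = gradient_vars,
                 seed = seed),
            class = "scenario_config")
}

# Documented simulation ranges for non-gradient variables: arid/semi-arid
# montane values (MAT in degrees C, MAP/PET in mm, altitude in m, SM in %,
# TSN/TOC in g/kg, AN in mg/kg, CN and NP dimensionless).
meta_ranges <- list(
  altitude = c(800, 2600), MAT = c(-2, 9), MAP = c(150, 500),
  PET = c(800, 1300), SM = c(5, 35), TSN = c(0.4, 2.5),
  TOC = c(5, 45), AN = c(30, 220), CN = c(8, 20), NP = c(1, 6))

#' Generate synthetic site metadata
#'
#' Coordinates are uniform over a ~600 km x 600 km box (latitudes around
#' 43-48 N); pH is uniform on 4.3-7.5 and TSP on 0.36-1.04 g/kg; the other
#' climate and soil variables are uniform over documented arid-montane
#' ranges; AI is derived as MAP/PET. Deterministic per `config$seed`.
#'
#' @param config A [scenario_config].
#' @return Metadata `data.frame` (one row per sample).
#' @export
make_metadata <- function(config) {
  n <- config$n_samples
  with_seed(derive_seed(config$seed, "metadata"), {
    lat0 <- 43
    lat <- lat0 + stats::runif(n, 0, 600 / 110.574)
    lon <- 84 + stats::runif(n, 0, 600 / (111.320 * cos(lat0 * pi / 180)))
    meta <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                       latitude = lat, longitude = lon)
    for (v in names(meta_ranges))
      meta[[v]] <- stats::runif(n, meta_ranges[[v]][1], meta_ranges[[v]][2])
    meta$pH <- stats::runif(n, 4.3, 7.5)
    meta$TSP <- stats::runif(n, 0.36, 1.04)
    derive_aridity_index(meta)
  })
}

#' Generate a synthetic OTU table under a known assembly regime
#'
#' Metacommunity abundances are lognormal (`meanlog 0`, `sdlog 2`),
#' normalized. Per-sample multinomial sampling weights multiply the
#' metacommunity by, depending on regime:
#' * `dispersal_limited` — an exponential dispersal factor
#'   `exp(-dist(site, origin_j) / kernel_scale)`, each OTU having a latent
#'   origin point in the study box;
#' * `env_filtered` — a Gaussian response
#'   `exp(-(env_site - optimum_j)^2 / (2 * env_strength^2))` on each
#'   gradient variable, each OTU having latent optima uniform over the
#'   gradient range;
#' * `mixed` — both factors;
#' * `neutral` — delegates to [simulate_ncm] with migration rate
#'   `config$m` (no spatial or environmental structure).
#'
#' @param config A [scenario_config].
#' @param meta Metadata from [make_metadata] (must match `n_samples`).
#' @return An [otu_table] with attribute `truth`: a list of the latent
#'   metacommunity, OTU origin coordinates and environmental optima, for
#'   oracle tests.
#' @export
make_community <- function(config, meta) {
  stopifnot(nrow(meta) == config$n_samples)
  n <- config$n_samples; k <- config$n_otus
  with_seed(derive_seed(config$seed, "community"), {
    metacomm <- stats::rlnorm(k, meanlog = 0, sdlog = 2)
    metacomm <- metacomm / sum(metacomm)
    truth <- list(metacommunity = metacomm, regime = config$regime)
    if (config$regime == "neutral") {
      tab <- simulate_ncm(n, config$depth, config$m, metacomm,
                          seed = derive_seed(config$seed, "neutral_draw"))
      tab$sample_ids <- meta$sample_id
      rownames(tab$counts) <- meta$sample_id
      attr(tab, "truth") <- truth
      return(tab)
    }
    w <- matrix(metacomm, n, k, byrow = TRUE)
    if (config$regime %in% c("dispersal_limited", "mixed")) {
      or_lat <- stats::runif(k, min(meta$latitude), max(meta$latitude))
      or_lon <- stats::runif(k, min(meta$longitude), max(meta$longitude))
      dmat <- cross_haversine(meta$latitude, meta$longitude, or_lat, or_lon)
      w <- w * exp(-dmat / config$kernel_scale)
      truth$origin <- data.frame(latitude = or_lat, longitude = or_lon)
    }
    if (config$regime %in% c("env_filtered", "mixed")) {
      truth$optima <- list()
      for (v in config$gradient_vars) {
        env <- meta[[v]]
        opt <- stats::runif(k, min(env), max(env))
        w <- w * exp(-outer(env, opt, "-")^2 / (2 * config$env_strength^2))
        truth$optima[[v]] <- opt
      }
    }
    counts <- matrix(0L, n, k)
    for (i in seq_len(n)) {
      wi <- w[i, ]
      if (sum(wi) == 0) wi <- metacomm
      counts[i, ] <- as.integer(stats::rmultinom(1, config$depth,
                                                 wi / sum(wi)))
    }
    tab <- otu_table(counts, sample_ids = meta$sample_id,
                     otu_ids = sprintf("OTU%04d", seq_len(k)))
    attr(tab, "truth") <- truth
    tab
  })
}

# Haversine km between each site and each OTU origin point.
cross_haversine <- function(lat1, lon1, lat2, lon2) {
  R <- 6371.0088
  p1 <- lat1 * pi / 180; l1 <- lon1 * pi / 180
  p2 <- lat2 * pi / 180; l2 <- lon2 * pi / 180
  a <- outer(p1, p2, function(x, y) sin((y - x) / 2)^2) +
    outer(cos(p1), cos(p2)) *
      outer(l1, l2, function(x, y) sin((y - x) / 2)^2)
  2 * R * asin(pmin(1, sqrt(a)))
}

#' Write a complete synthetic scenario to disk
#'
#' Emits the OTU table and metadata in the package's TSV dialects, the
#' configuration as YAML, and the latent truth (metacommunity, origins,
#' optima) as a JSON sidecar.
#'
#' @param config A [scenario_config].
#' @param dir Output directory (created if needed).
#' @return Invisible named vector of paths.
#' @export
write_scenario <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- make_metadata(config)
  tab <- make_community(config, meta)
  paths <- c(otu = file.path(dir, "otu_table.tsv"),
             meta = file.path(dir, "metadata.tsv"),
             config = file.path(dir, "scenario.yaml"),
             truth = file.path(dir, "truth.json"))
  write_otu_table(tab, paths[["otu"]])
  write_sample_metadata(meta, paths[["meta"]])
  yaml::write_yaml(unclass(config), paths[["config"]])
  jsonlite::write_json(attr(tab, "truth"), paths[["truth"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
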