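#' Run the full abundant-vs-rare assembly analysis
#'
#' Orchestrates the pipeline: low-count filter, rarefaction, abundance
#' partition, then for each analyzed sub-community (whole, abundant, rare)
#' Bray-Curtis beta-diversity, distance-decay regression, Levins niche
#' breadth, the abundance-based null model with beta-deviation and its
#' interpretation, and the Sloan neutral model; followed by Mantel tests,
#' MRM forward selection, variation partitioning with ESDR and a gradient
#' split of the beta-deviations. All randomness derives from
#' `config$seed`, with independent sub-seeds per stage, so e.g. changing
#' `n_null` does not perturb the NCM fits.
#'
#' @param otu_path Path to a QIIME-classic OTU table TSV.
#' @param meta_path Path to a sample-metadata TSV.
#' @param config Named list of analysis settings; recognized entries (with
#'   defaults): `seed` (1), `n_null` (999), `n_perm` (999), `min_reads`
#'   (20), `rarefy_depth` (min sample total), `abundant_frac` (0.001),
#'   `rare_frac` (0.0001), `alpha` (0.05), `env_vars` (all numeric
#'   metadata columns except coordinates, screened at |r| > 0.7),
#'   `gradient_vars` (`c("pH", "TSP")`), `ncm_boot` (200),
#'   `filter_before_rarefy` (TRUE).
#' @param out_dir Optional directory for TSV/JSON artifacts and a Markdown
#'   report.
#' @return An `analysis_report` list; see its `print` method for a tour.
#' @export
run_pipeline <- function(otu_path, meta_path, config = list(),
                         out_dir = NULL) {
  cfg <- pipeline_defaults(config)
  table <- read_otu_table(otu_path)
  meta <- read_sample_metadata(meta_path)
  missing_meta <- setdiff(table$sample_ids, meta$sample_id)
  missing_tab <- setdiff(meta$sample_id, table$sample_ids)
  if (length(missing_meta) || length(missing_tab))
    stop("sample labels differ between table and metadata",
         if (length(missing_meta)) paste0("; missing from metadata: ",
           paste(missing_meta, collapse = ", ")),
         if (length(missing_tab)) paste0("; missing from table: ",
           paste(missing_tab, collapse = ", ")))
  meta <- meta[match(table$sample_ids, meta$sample_id), ]
  run_pipeline_obj(table, meta, cfg, out_dir)
}

pipeline_defaults <- function(config) {
  def <- list(seed = 1, n_null = 999, n_perm = 999, min_reads = 20,
              rarefy_depth = NULL, abundant_frac = 0.001,
              rare_frac = 0.0001, alpha = 0.05, env_vars = NULL,
              gradient_vars = c("pH", "TSP"), ncm_boot = 200,
              filter_before_rarefy = TRUE)
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  utils::modifyList(def, config)
}

# In-memory pipeline core (also the programmatic entry point).
run_pipeline_obj <- function(table, meta, cfg, out_dir = NULL) {
  cfg <- pipeline_defaults(cfg)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ra_log("INFO", "input: ", nrow(table$counts), " samples x ",
         ncol(table$counts), " OTUs")
  if (cfg$filter_before_rarefy)
    table <- filter_low_count_otus(table, cfg$min_reads)
  depth <- cfg$rarefy_depth %||% min(sample_totals(table))
  table <- rarefy(table, depth, seed = derive_seed(cfg$seed, "rarefy"))
  if (!cfg$filter_before_rarefy)
    table <- filter_low_count_otus(table, cfg$min_reads)
  keep <- otu_totals(table) > 0
  table <- otu_table(table$counts[, keep, drop = FALSE],
                     sample_ids = table$sample_ids,
                     otu_ids = table$otu_ids[keep],
                     taxonomy = if (!is.null(table$taxonomy))
                       table$taxonomy[keep])
  part <- classify_otus(table, cfg$abundant_frac, cfg$rare_frac)
  geo <- geographic_distance(meta)

  env_vars <- cfg$env_vars
  if (is.null(env_vars)) {
    num <- names(meta)[vapply(meta, is.numeric, logical(1))]
    env_vars <- setdiff(num, c("latitude", "longitude"))
  }
  if (length(env_vars) >= 2)
    env_vars <- collinearity_screen(meta, env_vars, threshold = 0.7)

  subcoms <- list(whole = table)
  for (cls in c("abundant", "rare")) {
    if (any(part$class_of == cls))
      subcoms[[cls]] <- subset_by_class(table, part, cls)
  }

  results <- list()
  for (nm in names(subcoms)) {
    sub <- subcoms[[nm]]
    ok <- sample_totals(sub) > 0
    if (!all(ok)) {
      ra_log("WARN", nm, ": dropping ", sum(!ok),
             " empty sample(s) for distance-based analyses")
      sub <- otu_table(sub$counts[ok, , drop = FALSE],
                       sample_ids = sub$sample_ids[ok],
                       otu_ids = sub$otu_ids)
    }
    meta_s <- meta[match(sub$sample_ids, meta$sample_id), ]
    geo_s <- geographic_distance(meta_s)
    bc <- bray_curtis(sub)
    ddr <- distance_decay(bc, geo_s, n_perm = cfg$n_perm,
                          seed = derive_seed(cfg$seed, paste0("ddr_", nm)))
    nb <- levins_breadth(sub)
    bdev <- beta_deviation(sub, n_null = cfg$n_null,
                           seed = derive_seed(cfg$seed,
                                              paste0("null_", nm)))
    sign_test <- test_deviation_sign(bdev)
    label <- interpret_deviation(bdev, sign_test, alpha = cfg$alpha)
    ncm <- fit_ncm(sub, n_boot = cfg$ncm_boot,
                   seed = derive_seed(cfg$seed, paste0("ncm_", nm)))
    cand <- c(stats::setNames(
                lapply(env_vars, function(v) variable_difference(meta_s, v)),
                env_vars),
              list(Space = geo_s))
    mantel_tab <- do.call(rbind, lapply(names(cand), function(v) {
      mt <- mantel(bdev$beta_dev, cand[[v]], n_perm = cfg$n_perm,
                   seed = derive_seed(cfg$seed,
                                      paste0("mantel_", nm, "_", v)))
      data.frame(variable = v, mantel_r = mt$r, p = mt$p)
    }))
    mrm <- mrm_forward_select(bdev$beta_dev, cand, alpha = cfg$alpha,
                              n_perm = cfg$n_perm,
                              seed = derive_seed(cfg$seed,
                                                 paste0("mrm_", nm)))
    env_sel <- setdiff(mrm$selected, "Space")
    if (!length(env_sel)) env_sel <- env_vars
    vpa <- variation_partition(bdev$beta_dev, cand[env_sel],
                               list(Space = geo_s))
    splits <- lapply(cfg$gradient_vars, function(v)
      tryCatch(gradient_split_deviation(bdev, meta_s, v),
               error = function(e) NULL))
    names(splits) <- cfg$gradient_vars
    results[[nm]] <- list(
      n_otus = ncol(sub$counts), bray_curtis = bc, ddr = ddr,
      mean_Bcom = mean(nb$Bcom), niche = nb,
      beta_deviation = bdev, deviation_test = sign_test,
      interpretation = label, ncm = ncm, mantel = mantel_tab,
      mrm = mrm, vpa = vpa, gradient_split = splits)
  }

  bcom_cmp <- NULL
  if (all(c("abundant", "rare") %in% names(results)))
    bcom_cmp <- compare_groups(results$abundant$niche$Bcom,
                               results$rare$niche$Bcom)

  report <- structure(list(
    partition = part,
    depth = depth,
    env_vars = env_vars,
    subcommunities = results,
    bcom_comparison = bcom_cmp,
    provenance = list(seed = cfg$seed, n_null = cfg$n_null,
                      n_perm = cfg$n_perm, alpha = cfg$alpha,
                      abundant_frac = cfg$abundant_frac,
                      rare_frac = cfg$rare_frac,
                      package_version =
                        as.character(utils::packageVersion("rareassembly")))),
    class = "analysis_report")
  if (!is.null(out_dir)) write_report(report, table, out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== abundance partition (depth ", x$depth, ") ==\n", sep = "")
  print(x$partition$summary, digits = 4)
  for (nm in names(x$subcommunities)) {
    r <- x$subcommunities[[nm]]
    cat("\n== ", nm, " (", r$n_otus, " OTUs) ==\n", sep = "")
    print(r$ddr)
    cat(sprintf("mean Bcom %.2f\n", r$mean_Bcom))
    print(r$beta_deviation)
    cat("interpretation: ", r$interpretation, "\n", sep = "")
    print(r$ncm)
    print(r$vpa)
  }
  invisible(x)
}

write_report <- function(report, table, out_dir) {
  write_partition_summary(table, report$partition,
                          file.path(out_dir, "partition.tsv"),
                          file.path(out_dir, "partition.json"))
  for (nm in names(report$subcommunities)) {
    r <- report$subcommunities[[nm]]
    write_dist_matrix(r$bray_curtis,
                      file.path(out_dir, paste0("bray_curtis_", nm, ".tsv")))
    write_beta_deviation(r$beta_deviation, out_dir,
                         paste0("beta_deviation_", nm))
    write_ncm_fit(r$ncm, file.path(out_dir, paste0("ncm_", nm, ".json")),
                  file.path(out_dir, paste0("ncm_", nm, ".tsv")))
    utils::write.table(r$mantel,
                       file.path(out_dir, paste0("mantel_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(env_individual = r$vpa$env_individual,
           space_individual = r$vpa$space_individual,
           shared = r$vpa$shared, residual = r$vpa$residual,
           esdr = r$vpa$esdr,
           mrm_selected = r$mrm$selected,
           interpretation = r$interpretation),
      file.path(out_dir, paste0("vpa_", nm, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  md <- c("# Assembly analysis report", "",
          paste0("Rarefaction depth: ", report$depth),
          paste0("Environmental variables (post-screen): ",
                 paste(report$env_vars, collapse = ", ")), "")
  for (nm in names(report$subcommunities)) {
    r <- report$subcommunities[[nm]]
    md <- c(md, paste0("## ", nm), "",
            sprintf("- OTUs: %d", r$n_otus),
            sprintf("- DDR slope: %.4g per 100 km (R^2 %.3f, p %.4g)",
                    100 * r$ddr$slope, r$ddr$r_squared, r$ddr$p_value),
            sprintf("- mean Bcom: %.2f", r$mean_Bcom),
            sprintf("- mean beta-deviation: %.3f (%s)",
                    mean(pair_vector(r$beta_deviation$beta_dev)),
                    r$interpretation),
            sprintf("- NCM: m = %.4f, R^2 = %.3f", r$ncm$m,
                    r$ncm$r_squared),
            sprintf("- VPA: env %.2f%%, space %.2f%%, ESDR %s",
                    100 * r$vpa$env_individual,
                    100 * r$vpa$space_individual,
                    if (is.na(r$vpa$esdr)) "undefined"
                    else sprintf("%.3f", r$vpa$esdr)),
            "")
  }
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
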