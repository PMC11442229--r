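# Readers, writers, run configuration and the end-to-end pipeline driver.

#' Read a QTL table
#'
#' Reads the shared QTL-table CSV (the schema produced by the scan stage and
#' accepted by the meta-QTL stage). Hand-entered rows transcribed from other
#' studies are welcome; the \code{population} and \code{study} columns keep
#' the sources apart.
#'
#' @param path CSV path.
#' @return data.frame in the shared schema.
#' @export
read_qtl_table <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(QTL_COLUMNS, names(tbl))
  if (length(miss))
    stop("QTL table ", path, " missing mandatory columns: ",
         paste(miss, collapse = ", "))
  tbl$linkage_group <- as.character(tbl$linkage_group)
  tbl[, QTL_COLUMNS]
}

#' Write a QTL table
#' @param hits QTL table data.frame.
#' @param path CSV path.
#' @export
write_qtl_table <- function(hits, path) {
  .check_hits(hits)
  utils::write.csv(hits[, QTL_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Write a meta-QTL table
#' @param metas meta-QTL data.frame.
#' @param path CSV path.
#' @export
write_meta_table <- function(metas, path) {
  utils::write.csv(metas, path, row.names = FALSE)
  invisible(path)
}

#' Read trait groups from YAML
#'
#' The YAML mirrors the published grouping tables: a list of groups, each
#' with \code{group_id}, \code{traits} and optional \code{filters} (each a
#' mapping with statistic, comparator, value).
#'
#' @param path YAML path.
#' @return list of \code{\link{trait_group}}s.
#' @export
read_trait_groups <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(g)
    trait_group(g$group_id, unlist(g$traits),
                if (is.null(g$filters)) list() else g$filters))
}

#' Validate a run configuration
#'
#' @param config named list; must contain an integer \code{seed}. Per-stage
#'   blocks (\code{map}, \code{cross}, \code{traits}, \code{prep},
#'   \code{scan}, \code{meta}) override the defaults.
#' @return the completed config.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must provide a seed")
  defaults <- list(
    map = list(n_lg = 5, markers_per_lg = 12, length_cm = 80),
    cross = list(n_progeny = 168),
    traits = list(years = c("2011", "2012", "2013"), uprights = 10),
    prep = list(alpha = 0.05, sd_cut = 3),
    scan = list(step = 2, n_perm = 1000, percentile = 80,
                stepwise_percentile = 95),
    meta = list(min_models = 3, min_r2 = 0.10))
  for (blk in names(defaults)) {
    if (is.null(config[[blk]])) config[[blk]] <- defaults[[blk]]
    else config[[blk]] <- utils::modifyList(defaults[[blk]], config[[blk]])
  }
  config
}

#' Run the whole pipeline on synthetic data
#'
#' Executes simulate -> prep -> blup -> scan -> metaqtl with one master seed
#' (stage seeds are derived from it), writing every intermediate CSV, a
#' machine-readable manifest and the summary tables under \code{out_dir}.
#'
#' @param config list (or YAML path) accepted by \code{\link{run_config}};
#'   must carry \code{seed}.
#' @param out_dir output directory (created if needed); NULL skips writing.
#' @param arch \code{\link{trait_architecture}} for the simulated trait;
#'   default: two QTL plus polygenic background and spatial trend.
#' @return invisible list with the main objects: map, geno, phenotypes,
#'   curated, means, blup fits, qtl table, meta table, manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL, arch = NULL) {
  cfg <- run_config(config)
  seed <- as.integer(cfg$seed)
  seeds <- seed + c(map = 0L, cross = 1L, traits = 2L, perm = 3L)

  map <- simulate_map(cfg$map$n_lg, cfg$map$markers_per_lg,
                      cfg$map$length_cm, seed = seeds["map"])
  geno <- simulate_cross(map, cfg$cross$n_progeny, seed = seeds["cross"])
  layout <- simulate_layout(rownames(geno), seed = seeds["cross"])
  if (is.null(arch)) {
    lgs <- unique(c(1, cfg$map$n_lg))
    k <- length(lgs)
    arch <- trait_architecture(
      qtl = data.frame(linkage_group = lgs,
                       position = (cfg$map$length_cm * c(0.5, 0.25))[1:k],
                       maternal = c(1, 0)[1:k], paternal = c(0.6, 0.8)[1:k],
                       interaction = rep(0, k)),
      polygenic_variance = 0.5, residual_variance = 1, gxy_variance = 0.2,
      spatial_amplitude = 0.5, mu = 10,
      year_effects = stats::setNames(seq_along(cfg$traits$years) - 1,
                                     cfg$traits$years))
  }
  A <- compute_A(fourway_dosage(geno))
  sim <- simulate_traits(geno, map, arch, layout, cfg$traits$years,
                         cfg$traits$uprights, seed = seeds["traits"],
                         polygenic_K = A)

  trimmed <- trim_outliers(sim$phenotypes, alpha = cfg$prep$alpha,
                           sd_cut = cfg$prep$sd_cut)
  means <- upright_means(trimmed$data)
  means <- merge(means, layout, by = "genotype")
  blup <- fit_blup_model(means[means$trait == means$trait[1], ], A,
                         model = "across")
  probs <- calc_genoprob(geno, map, step = cfg$scan$step)
  yb <- blup$blup[rownames(geno)]
  thr <- permutation_threshold(probs, yb, n_perm = cfg$scan$n_perm,
                               percentile = cfg$scan$percentile,
                               seed = seeds["perm"])
  hits <- scan_summary(probs, yb, thr$threshold, trait = "Y",
                       population = "SIM", study = "synthetic",
                       model = "all years")
  thr95 <- permutation_threshold(probs, yb, n_perm = cfg$scan$n_perm,
                                 percentile = cfg$scan$stepwise_percentile,
                                 seed = seeds["perm"])
  hits_sw <- stepwise_scan(probs, yb, thr95$threshold, trait = "Y",
                           population = "SIM", study = "synthetic",
                           model = "all years")
  qtl <- rbind(hits, hits_sw)
  metas <- meta_qtl(qtl)

  manifest <- list(
    seed = seed, stage_seeds = as.list(seeds),
    config = cfg,
    rows = list(map = nrow(map), genotypes = nrow(geno),
                phenotypes = nrow(sim$phenotypes),
                removed = nrow(trimmed$log), means = nrow(means),
                qtl = nrow(qtl), meta = nrow(metas)),
    h2 = blup$h2,
    threshold_80 = thr$threshold, threshold_95 = thr95$threshold)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(map, file.path(out_dir, "map.csv"), row.names = FALSE)
    utils::write.csv(data.frame(progeny = rownames(geno), geno,
                                check.names = FALSE),
                     file.path(out_dir, "genotypes.csv"), row.names = FALSE)
    utils::write.csv(sim$phenotypes, file.path(out_dir, "phenotypes.csv"),
                     row.names = FALSE)
    utils::write.csv(sim$truth$components, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    utils::write.csv(trimmed$log, file.path(out_dir, "removal_log.csv"),
                     row.names = FALSE)
    utils::write.csv(means, file.path(out_dir, "upright_means.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(genotype = names(blup$blup),
                                blup = unname(blup$blup),
                                se = unname(blup$blup_se)),
                     file.path(out_dir, "blups.csv"), row.names = FALSE)
    write_qtl_table(qtl, file.path(out_dir, "qtl.csv"))
    write_meta_table(metas, file.path(out_dir, "meta_qtl.csv"))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  invisible(list(map = map, geno = geno, layout = layout, sim = sim,
                 trimmed = trimmed, means = means, blup = blup, probs = probs,
                 threshold = thr, qtl = qtl, meta = metas,
                 manifest = manifest))
}
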