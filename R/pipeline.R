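# Pipeline orchestration: simulate / scan / report, driven by a YAML (or
# in-memory list) configuration. Results are written as TSV files; logging
# goes to stderr, never to stdout.

SIM_CONFIG_KEYS <- c("cancer_types", "samples_per_cancer", "n_genes",
                     "domains_per_gene", "domain_length_aa",
                     "linker_length_aa", "mu", "planted_smds",
                     "n_planted_smds", "planted_fold", "cross_cancer_fold",
                     "onco_fraction",
                     "hotspot_positions_h", "hotspot_mass_rho",
                     "functional_site_count", "p_hotspot_at_functional",
                     "nondamaging_fraction", "seed")

SCAN_CONFIG_KEYS <- c("mutations", "domains", "samples", "labels", "sites",
                      "gene_sets", "pairs", "background_genes", "seed",
                      "smd_alpha", "smd_fdr", "hotspot_alpha", "hotspot_fdr",
                      "evalue_cutoff", "damaging_categories", "min_cancers_shared",
                      "min_cancers_type_hotspot")

.log_msg <- function(verbose, ...) {
  if (verbose) message("[domainscape] ", ...)
}

.check_config_keys <- function(config, allowed) {
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    key <- unknown[1]
    dist <- utils::adist(key, allowed)
    hint <- if (min(dist) <= 3)
      sprintf(" (did you mean '%s'?)", allowed[which.min(dist)]) else ""
    .config_error(sprintf("unknown configuration key '%s'%s", key, hint))
  }
}

.load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      .config_error(sprintf("configuration file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) .config_error("configuration must be a list or a YAML file path")
  config
}

#' Simulate a cohort to disk
#'
#' Runs [generate_cohort()] under the supplied configuration and writes the
#' cohort tables, ground-truth tables, the gene-label and functional-site
#' inputs for a downstream scan, and the fully resolved configuration
#' (`config_used.yaml`).
#'
#' @param config A list of [sim_config()] arguments, or the path to a YAML
#'   file containing them. Unknown keys raise a configuration error naming
#'   the key (with a closest-match suggestion).
#' @param out_dir Output directory.
#' @param verbose Log progress to stderr.
#' @return Named character vector of the files written, invisibly.
#' @export
run_simulate <- function(config = list(), out_dir, verbose = FALSE) {
  config <- .load_config(config)
  .check_config_keys(config, SIM_CONFIG_KEYS)
  if (!is.null(config$planted_smds) && !is.data.frame(config$planted_smds))
    config$planted_smds <- as.data.frame(
      do.call(rbind, lapply(config$planted_smds, as.data.frame)))
  cfg <- do.call(sim_config, config)
  .log_msg(verbose, "generating cohort (seed ", cfg$seed, ")")
  gen <- generate_cohort(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_cohort(gen$dataset, out_dir)
  paths <- c(paths, write_truth(gen$truth, out_dir,
                                instances = gen$dataset$instances))
  lab_path <- file.path(out_dir, "gene_labels.tsv")
  .write_tsv(gen$truth$labels, lab_path)
  site_path <- file.path(out_dir, "functional_sites.tsv")
  sites <- gen$truth$functional_sites
  sites$site_category <- if (nrow(sites)) "functional" else character()
  .write_tsv(sites, site_path)
  cfg_out <- cfg[setdiff(names(cfg), "genes")]
  cfg_out$planted_smds <- if (nrow(cfg$planted_smds))
    lapply(seq_len(nrow(cfg$planted_smds)),
           function(i) as.list(cfg$planted_smds[i, ])) else list()
  class(cfg_out) <- NULL
  cfg_path <- file.path(out_dir, "config_used.yaml")
  yaml::write_yaml(cfg_out, cfg_path)
  .log_msg(verbose, nrow(gen$dataset$mutations), " mutations written")
  invisible(c(paths, gene_labels = lab_path, functional_sites = site_path,
              config = cfg_path))
}

.scan_thresholds <- function(config) {
  args <- config[intersect(names(config),
                           c("smd_alpha", "smd_fdr", "hotspot_alpha",
                             "hotspot_fdr", "evalue_cutoff",
                             "damaging_categories"))]
  do.call(thresholds, args)
}

#' Run the full scan pipeline
#'
#' Executes filter, mapping, density, SMD scan, hotspot scan, cross-cancer
#' sharing, domain-type pooling, co-occurrence, exclusivity, hotspot-ratio
#' profiling and — when the optional label / site / gene-set / pair inputs
#' are supplied — classification, gene-set enrichment, functional-site
#' overlap and the interacting-pair report. All result tables are written to
#' `out_dir` along with `manifest.yaml` recording stage counts, thresholds,
#' wall-clock time and package version.
#'
#' @param config A list (or YAML file path) with keys: `mutations`,
#'   `domains`, `samples` (paths; mandatory), optional `labels`, `sites`,
#'   `gene_sets` (named list of gene-set file paths), `pairs`,
#'   `background_genes` (integer universe size for enrichment; defaults to
#'   the number of distinct genes in the mutation table), threshold
#'   overrides (`smd_alpha`, `smd_fdr`, `hotspot_alpha`, `hotspot_fdr`,
#'   `evalue_cutoff`, `damaging_categories`) and `min_cancers_shared` /
#'   `min_cancers_type_hotspot`.
#' @param out_dir Output directory.
#' @param verbose Log progress to stderr.
#' @return The manifest list, invisibly.
#' @export
run_scan <- function(config, out_dir, verbose = FALSE) {
  t0 <- Sys.time()
  config <- .load_config(config)
  .check_config_keys(config, SCAN_CONFIG_KEYS)
  for (k in c("mutations", "domains", "samples")) {
    if (is.null(config[[k]]))
      .config_error(sprintf("mandatory input '%s' missing from configuration", k))
    if (!file.exists(config[[k]]))
      .config_error(sprintf("input file not found: %s", config[[k]]))
  }
  for (k in c("labels", "sites", "pairs"))
    if (!is.null(config[[k]]) && !file.exists(config[[k]]))
      .config_error(sprintf("input file not found: %s", config[[k]]))
  th <- .scan_thresholds(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  .log_msg(verbose, "reading inputs")
  mutations <- read_mutations(config$mutations)
  skip <- attr(mutations, "skip_report")
  instances <- read_domain_instances(config$domains, th$evalue_cutoff)
  samples <- .read_tsv(config$samples)
  damaging <- filter_damaging(mutations, th$damaging_categories)
  dataset <- cohort_dataset(damaging, instances, samples)

  .log_msg(verbose, "mapping ", nrow(damaging), " damaging mutations onto ",
           nrow(instances), " instances")
  mapped <- map_mutations(dataset)
  dens <- mutation_density(dataset, mapped)
  smd <- smd_scan(dataset, mapped, th)
  hot <- hotspot_scan(dataset, mapped, smd, th)
  shared <- shared_smds(smd, config$min_cancers_shared %||% 2)
  pooled <- shared_type_hotspots(hot, instances,
                                 config$min_cancers_type_hotspot %||% 3)
  cooc <- smd_cooccurrence(dataset, mapped, smd)
  excl <- hotspot_exclusivity(dataset, mapped, pooled)
  profiles <- hotspot_ratio(smd, hot)

  .write_tsv(dens, file.path(out_dir, "densities.tsv"))
  .write_tsv(smd, file.path(out_dir, "smd_results.tsv"))
  .write_tsv(hot, file.path(out_dir, "hotspot_results.tsv"))
  .write_tsv(shared, file.path(out_dir, "shared_smds.tsv"))
  .write_tsv(pooled, file.path(out_dir, "type_hotspots.tsv"))
  .write_tsv(cooc, file.path(out_dir, "cooccurrence.tsv"))
  .write_tsv(excl, file.path(out_dir, "exclusivity_violations.tsv"))
  .write_tsv(profiles, file.path(out_dir, "gene_profiles.tsv"))
  hm <- heatmap_matrix(smd)
  hm_df <- data.frame(instance_id = rownames(hm), hm, check.names = FALSE,
                      stringsAsFactors = FALSE)
  .write_tsv(hm_df, file.path(out_dir, "heatmap_matrix.tsv"))

  labels <- if (!is.null(config$labels)) read_gene_labels(config$labels)
  if (!is.null(labels) && nrow(profiles) &&
      any(labels$label == "oncogene") &&
      any(labels$label == "tumor_suppressor")) {
    cls <- tryCatch(classify_genes(profiles, labels),
                    error = function(e) NULL)
    if (!is.null(cls))
      .write_tsv(cls, file.path(out_dir, "classification.tsv"))
  }
  if (!is.null(config$sites) && !is.null(labels) && nrow(hot)) {
    sites <- read_site_annotations(config$sites)
    ov <- tryCatch(functional_site_overlap(hot, sites, labels),
                   error = function(e) NULL)
    if (!is.null(ov)) {
      ov_df <- data.frame(percent_onco = ov$percent_onco,
                          percent_tsg = ov$percent_tsg,
                          percent_onco_rounded = ov$percent_onco_rounded,
                          percent_tsg_rounded = ov$percent_tsg_rounded,
                          odds_ratio = ov$odds_ratio, p_value = ov$p_value)
      .write_tsv(ov_df, file.path(out_dir, "site_overlap.tsv"))
    }
  }
  if (!is.null(config$gene_sets)) {
    smd_genes <- unique(smd$gene[smd$is_smd])
    background <- config$background_genes %||%
      length(unique(mutations$gene))
    enr_rows <- lapply(names(config$gene_sets), function(nm) {
      ref <- read_gene_set(config$gene_sets[[nm]])
      e <- geneset_enrichment(smd_genes, ref, background)
      data.frame(gene_set = nm, fold = e$fold, p_value = e$p_value,
                 hits = e$hits, n_candidates = e$n_candidates,
                 n_reference = e$n_reference, background = e$background,
                 stringsAsFactors = FALSE)
    })
    .write_tsv(do.call(rbind, enr_rows), file.path(out_dir, "enrichment.tsv"))
  }
  if (!is.null(config$pairs)) {
    pairs <- .read_tsv(config$pairs)
    rep_df <- interacting_pair_report(smd, pairs)
    .write_tsv(rep_df, file.path(out_dir, "pair_report.tsv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("domainscape")),
    thresholds = unclass(th),
    counts = list(
      mutations_input = skip$n_input,
      mutations_parsed = skip$n_kept,
      mutations_skipped = skip$n_skipped,
      mutations_damaging = nrow(damaging),
      instances = nrow(instances),
      cancer_types = length(unique(samples$cancer_type)),
      samples = nrow(unique(samples[, c("cancer_type", "sample_id")])),
      smd_tests = nrow(smd),
      smds = sum(smd$is_smd),
      hotspot_tests = nrow(hot),
      hotspots = sum(hot$is_hotspot),
      shared_smds = nrow(shared),
      pooled_type_hotspots = nrow(pooled),
      exclusivity_violations = nrow(excl)),
    wall_clock_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  .log_msg(verbose, "scan complete: ", sum(smd$is_smd), " SMDs, ",
           sum(hot$is_hotspot), " hotspots")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarise a results directory
#'
#' Reads the scan outputs in `dir` and writes `summary.txt`: SMD counts per
#' cancer type, shared SMDs, and the top hotspots by p-value. Missing
#' artifacts are listed as an error.
#'
#' @param dir A directory produced by [run_scan()].
#' @param top_n Number of top hotspots to list.
#' @return Path to the summary file, invisibly.
#' @export
run_report <- function(dir, top_n = 10) {
  needed <- c("smd_results.tsv", "hotspot_results.tsv", "shared_smds.tsv")
  missing <- needed[!file.exists(file.path(dir, needed))]
  if (length(missing))
    .data_error(sprintf("results directory is missing: %s",
                        paste(missing, collapse = ", ")))
  smd <- .read_tsv(file.path(dir, "smd_results.tsv"))
  hot <- .read_tsv(file.path(dir, "hotspot_results.tsv"))
  shared <- .read_tsv(file.path(dir, "shared_smds.tsv"))
  lines <- c("domainscape scan summary", "========================", "")
  n_smd <- sum(smd$is_smd)
  lines <- c(lines, sprintf("SMD calls: %d (of %d tested instance-cancer cells)",
                            n_smd, nrow(smd)))
  if (n_smd > 0) {
    tab <- table(smd$cancer_type[smd$is_smd])
    lines <- c(lines, "", "SMDs per cancer type:")
    lines <- c(lines, sprintf("  %-32s %d", names(tab), as.integer(tab)))
  } else {
    lines <- c(lines, "No significantly mutated domain instances detected.")
  }
  lines <- c(lines, "", sprintf("Domain instances significant in >= 2 cancers: %d",
                                nrow(shared)))
  if (nrow(shared))
    lines <- c(lines, sprintf("  %s (%s)", shared$instance_id, shared$cancers))
  n_hot <- if (nrow(hot)) sum(hot$is_hotspot) else 0
  lines <- c(lines, "", sprintf("Hotspot calls: %d (of %d tested residues)",
                                n_hot, nrow(hot)))
  if (n_hot > 0) {
    top <- hot[hot$is_hotspot, ][seq_len(min(top_n, n_hot)), ]
    lines <- c(lines, sprintf("Top hotspots (by p-value, up to %d):", top_n),
               sprintf("  %s %s p.%d in %s (p=%.3g)", top$gene,
                       top$instance_id, top$position, top$cancer_type,
                       top$p_value))
  }
  path <- file.path(dir, "summary.txt")
  writeLines(lines, path)
  invisible(path)
}
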