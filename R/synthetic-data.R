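# Seeded synthetic cohort generator. Emits mutation/domain/sample tables in
# the exact dialect the readers consume, plus ground-truth tables of every
# planted signal, so the detection stack can be validated by recovery.

#' Synthetic cohort configuration
#'
#' Describes a cohort with a homogeneous per-residue, per-sample background
#' rate of damaging missense mutation, a set of planted cancer-type-specific
#' significantly mutated domain instances (SMDs) whose per-residue rate is
#' multiplied by a fold factor in one cancer type, and two within-domain
#' placement regimes: oncogene-like planted instances concentrate a fraction
#' `hotspot_mass_rho` of their mutations onto `hotspot_positions_h`
#' designated positions, while tumor-suppressor-like instances spread
#' mutations uniformly.
#'
#' Each gene encodes one protein laid out as alternating linkers and
#' domains; every domain instance has a distinct accession, so pooled
#' domain-type analyses on generated cohorts are trivially
#' instance-confined (cross-gene pooling is exercised with hand-built
#' fixtures instead).
#'
#' @param cancer_types Character vector of cancer-type labels.
#' @param samples_per_cancer Samples sequenced per cancer type.
#' @param n_genes Number of genes.
#' @param domains_per_gene Domain instances per gene.
#' @param domain_length_aa Length of each domain instance (aa).
#' @param linker_length_aa Length of inter-domain linkers (aa).
#' @param mu Background per-residue per-sample mutation probability.
#' @param planted_smds Data frame with columns `gene`, `instance_ordinal`,
#'   `cancer_type`, `fold` (all folds > 1), or `NULL` to auto-plant
#'   `n_planted_smds` cells at `planted_fold` cycling over genes, ordinals
#'   and cancers.
#' @param n_planted_smds,planted_fold Used only when `planted_smds` is NULL.
#' @param cross_cancer_fold Rate multiplier applied to planted instances in
#'   the cancers *other* than their planted cancer (default 1). Values > 1
#'   emulate the empirical pattern where the domains of driver genes are
#'   recurrently mutated across many cancer types while remaining
#'   significantly enriched in one; the cross-cancer mutation mass is what
#'   gives the within-domain hotspot contrast its comparison group.
#' @param onco_fraction Fraction of planted genes labeled oncogene
#'   (the rest are tumor suppressors).
#' @param hotspot_positions_h Hotspot positions per oncogene-like planted
#'   instance.
#' @param hotspot_mass_rho Probability that a mutation in an oncogene-like
#'   planted instance is redirected onto a hotspot position.
#' @param functional_site_count Annotated functional sites per instance.
#' @param p_hotspot_at_functional Probability that an oncogene-like hotspot
#'   position is annotated as a functional site.
#' @param nondamaging_fraction Fraction of emitted records assigned impact
#'   `none`/`unknown`.
#' @param seed Integer seed; the random stream is partitioned by
#'   (cancer, gene) so enlarging the cohort does not perturb existing
#'   blocks.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(cancer_types = c("breast", "lung", "colorectal",
                                        "endometrium"),
                       samples_per_cancer = 250,
                       n_genes = 50,
                       domains_per_gene = 3,
                       domain_length_aa = 150,
                       linker_length_aa = 20,
                       mu = 4e-5,
                       planted_smds = NULL,
                       n_planted_smds = 10,
                       planted_fold = 20,
                       cross_cancer_fold = 1,
                       onco_fraction = 0.5,
                       hotspot_positions_h = 2,
                       hotspot_mass_rho = 0.8,
                       functional_site_count = 3,
                       p_hotspot_at_functional = 0.8,
                       nondamaging_fraction = 0.2,
                       seed = 1L) {
  if (mu < 0 || mu >= 1) .config_error("mu must lie in [0, 1)")
  probs <- c(onco_fraction, hotspot_mass_rho, p_hotspot_at_functional,
             nondamaging_fraction)
  if (any(probs < 0) || any(probs > 1))
    .config_error("fractions and probabilities must lie in [0, 1]")
  if (hotspot_positions_h < 1)
    .config_error("hotspot_positions_h must be >= 1")
  if (hotspot_positions_h > domain_length_aa)
    .config_error("hotspot_positions_h exceeds the domain length")
  if (cross_cancer_fold <= 0)
    .config_error("cross_cancer_fold must be > 0")
  genes <- sprintf("G%03d", seq_len(n_genes))
  if (is.null(planted_smds)) {
    if (n_planted_smds > 0) {
      idx <- seq_len(n_planted_smds)
      planted_smds <- data.frame(
        gene = genes[((idx - 1) %% n_genes) + 1],
        instance_ordinal = ((idx - 1) %% domains_per_gene) + 1L,
        cancer_type = cancer_types[((idx - 1) %% length(cancer_types)) + 1],
        fold = planted_fold,
        stringsAsFactors = FALSE)
    } else {
      planted_smds <- data.frame(gene = character(),
                                 instance_ordinal = integer(),
                                 cancer_type = character(), fold = numeric())
    }
  }
  if (nrow(planted_smds)) {
    .require_columns(planted_smds,
                     c("gene", "instance_ordinal", "cancer_type", "fold"),
                     "planted_smds")
    if (any(planted_smds$fold <= 1))
      .config_error("planted folds must be > 1")
    bad_gene <- setdiff(planted_smds$gene, genes)
    if (length(bad_gene))
      .config_error(sprintf("planted SMD references unknown gene '%s'",
                            bad_gene[1]))
    if (any(planted_smds$instance_ordinal < 1 |
            planted_smds$instance_ordinal > domains_per_gene))
      .config_error("planted SMD references a nonexistent domain ordinal")
    bad_ct <- setdiff(planted_smds$cancer_type, cancer_types)
    if (length(bad_ct))
      .config_error(sprintf("planted SMD references unknown cancer type '%s'",
                            bad_ct[1]))
  }
  structure(list(cancer_types = cancer_types,
                 samples_per_cancer = samples_per_cancer,
                 n_genes = n_genes, genes = genes,
                 domains_per_gene = domains_per_gene,
                 domain_length_aa = domain_length_aa,
                 linker_length_aa = linker_length_aa,
                 mu = mu, planted_smds = planted_smds,
                 cross_cancer_fold = cross_cancer_fold,
                 onco_fraction = onco_fraction,
                 hotspot_positions_h = hotspot_positions_h,
                 hotspot_mass_rho = hotspot_mass_rho,
                 functional_site_count = functional_site_count,
                 p_hotspot_at_functional = p_hotspot_at_functional,
                 nondamaging_fraction = nondamaging_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# deterministic per-(cancer, gene) seed; exact in double arithmetic and
# below 2^31
.block_seed <- function(seed, ci, gi) {
  as.integer((((seed %% 100000) * 101 + ci) * 10007 + gi * 7) %% 2147483647)
}

.sim_instances <- function(config) {
  L <- config$domain_length_aa; lk <- config$linker_length_aa
  dp <- config$domains_per_gene
  rows <- expand.grid(ordinal = seq_len(dp), gene_i = seq_len(config$n_genes))
  gene <- config$genes[rows$gene_i]
  start <- lk + (rows$ordinal - 1L) * (L + lk) + 1L
  acc_i <- (rows$gene_i - 1L) * dp + rows$ordinal
  data.frame(gene = gene,
             protein_id = sub("^G", "P", gene),
             domain_acc = sprintf("PF9%04d", acc_i),
             domain_name = sprintf("SynDom%04d", acc_i),
             start = as.integer(start),
             end = as.integer(start + L - 1L),
             e_value = 1e-10,
             model_map = "",
             ordinal = rows$ordinal,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort under the configuration's generative model. For each
#' cancer, sample, gene and residue a damaging missense mutation occurs with
#' probability `mu`, multiplied by the planted fold when the residue lies in
#' a planted SMD for that (gene, cancer). Mutations landing in an
#' oncogene-like planted instance are redirected onto one of its designated
#' hotspot positions with probability `hotspot_mass_rho` (uniform over the
#' positions), otherwise placed uniformly over the instance;
#' tumor-suppressor-like planted instances keep the uniform per-residue
#' placement. At most one mutation is kept per (sample, residue). A fraction
#' `nondamaging_fraction` of records is independently downgraded to impact
#' `none`/`unknown`; the rest are `high`/`medium`/`low` uniformly. Output is
#' identical for identical configurations.
#'
#' @param config A [sim_config()].
#' @return A list with `dataset` (a [cohort_dataset()]) and `truth`, a list
#'   of data frames: `smds` (instance_id, cancer_type, fold), `hotspots`
#'   (instance_id, cancer_type, position — oncogene-like planted positions),
#'   `labels` (gene, label for planted genes) and `functional_sites`
#'   (gene, position).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  inst <- .sim_instances(config)
  L <- config$domain_length_aa; lk <- config$linker_length_aa
  protein_len <- lk + config$domains_per_gene * (L + lk)
  cancers <- config$cancer_types
  nsamp <- config$samples_per_cancer

  samples <- do.call(rbind, lapply(cancers, function(ct)
    data.frame(cancer_type = ct,
               sample_id = sprintf("%s_S%04d", ct, seq_len(nsamp)),
               stringsAsFactors = FALSE)))

  planted <- config$planted_smds
  planted_genes <- unique(planted$gene)
  n_onco <- ceiling(config$onco_fraction * length(planted_genes))
  labels <- if (length(planted_genes))
    data.frame(gene = planted_genes,
               label = c(rep("oncogene", n_onco),
                         rep("tumor_suppressor",
                             length(planted_genes) - n_onco)),
               stringsAsFactors = FALSE)
  else data.frame(gene = character(), label = character())

  inst_key <- paste(inst$gene, inst$ordinal)
  # setup draws (hotspot positions, functional sites) use their own stream
  set.seed(.block_seed(config$seed, 0L, 0L))
  truth_hot <- list(); site_rows <- list()
  hot_pos <- vector("list", nrow(inst))  # protein positions per instance
  names(hot_pos) <- inst_key
  for (j in seq_len(nrow(inst))) {
    g <- inst$gene[j]
    lab <- labels$label[match(g, labels$gene)]
    pl <- planted[planted$gene == g & planted$instance_ordinal == inst$ordinal[j], ,
                  drop = FALSE]
    is_onco_planted <- nrow(pl) > 0 && identical(lab, "oncogene")
    span <- inst$start[j]:inst$end[j]
    sites <- integer()
    if (is_onco_planted) {
      hp <- sort(sample(span, config$hotspot_positions_h))
      hot_pos[[j]] <- hp
      truth_hot[[length(truth_hot) + 1]] <- data.frame(
        instance_id = paste(inst$gene[j], inst$protein_id[j],
                            inst$domain_acc[j], inst$start[j], sep = "|"),
        cancer_type = rep(pl$cancer_type, each = length(hp)),
        position = rep(hp, times = nrow(pl)),
        stringsAsFactors = FALSE)
      keep <- hp[stats::runif(length(hp)) < config$p_hotspot_at_functional]
      sites <- keep
    }
    extra <- config$functional_site_count - length(sites)
    if (extra > 0)
      sites <- c(sites, sample(setdiff(span, sites), extra))
    if (length(sites))
      site_rows[[length(site_rows) + 1]] <-
        data.frame(gene = g, position = sort(sites), stringsAsFactors = FALSE)
  }

  impact_dmg <- c("high", "medium", "low")
  impact_non <- c("none", "unknown")

  mut_blocks <- list()
  for (ci in seq_along(cancers)) {
    ct <- cancers[ci]
    for (gi in seq_len(config$n_genes)) {
      set.seed(.block_seed(config$seed, ci, gi))
      g <- config$genes[gi]
      rate <- rep(config$mu, protein_len)
      rows_j <- which(inst$gene == g)
      pl_gene <- planted[planted$gene == g, , drop = FALSE]
      onco_spans <- list()
      for (ord in unique(pl_gene$instance_ordinal)) {
        j <- rows_j[ord]
        span <- inst$start[j]:inst$end[j]
        here <- pl_gene[pl_gene$instance_ordinal == ord &
                          pl_gene$cancer_type == ct, , drop = FALSE]
        if (nrow(here)) {
          rate[span] <- rate[span] * here$fold[1]
          # hotspot concentration applies only in the planted (focal) cancer
          if (!is.null(hot_pos[[j]]))
            onco_spans[[length(onco_spans) + 1]] <-
              list(span = span, hp = hot_pos[[j]])
        } else {
          rate[span] <- rate[span] * config$cross_cancer_fold
        }
      }
      occ <- which(matrix(stats::runif(nsamp * protein_len), nsamp) <
                     rep(rate, each = nsamp), arr.ind = TRUE)
      if (nrow(occ) == 0) next
      samp_i <- occ[, 1]; pos <- occ[, 2]
      # redirect mutations inside oncogene-like planted instances
      for (os in onco_spans) {
        in_span <- which(pos %in% os$span)
        if (!length(in_span)) next
        to_hot <- stats::runif(length(in_span)) < config$hotspot_mass_rho
        n_hot <- sum(to_hot)
        if (n_hot)
          pos[in_span[to_hot]] <- os$hp[sample.int(length(os$hp), n_hot,
                                                   replace = TRUE)]
        n_uni <- sum(!to_hot)
        if (n_uni)
          pos[in_span[!to_hot]] <- os$span[sample.int(length(os$span), n_uni,
                                                      replace = TRUE)]
      }
      dup <- duplicated(cbind(samp_i, pos))
      samp_i <- samp_i[!dup]; pos <- pos[!dup]
      o <- order(samp_i, pos)
      samp_i <- samp_i[o]; pos <- pos[o]
      nm <- length(pos)
      ref <- AA_ALPHABET[sample.int(20, nm, replace = TRUE)]
      shift <- sample.int(19, nm, replace = TRUE)
      alt <- AA_ALPHABET[((match(ref, AA_ALPHABET) - 1 + shift) %% 20) + 1]
      nondmg <- stats::runif(nm) < config$nondamaging_fraction
      impact <- ifelse(nondmg,
                       impact_non[sample.int(2, nm, replace = TRUE)],
                       impact_dmg[sample.int(3, nm, replace = TRUE)])
      mut_blocks[[length(mut_blocks) + 1]] <- data.frame(
        gene = g, protein_id = sub("^G", "P", g),
        sample_id = sprintf("%s_S%04d", ct, samp_i),
        cancer_type = ct, position = as.integer(pos),
        ref_aa = ref, alt_aa = alt, impact = impact,
        stringsAsFactors = FALSE)
    }
  }
  mutations <- if (length(mut_blocks)) do.call(rbind, mut_blocks) else
    data.frame(gene = character(), protein_id = character(),
               sample_id = character(), cancer_type = character(),
               position = integer(), ref_aa = character(),
               alt_aa = character(), impact = character())
  rownames(mutations) <- NULL

  instances <- inst[, c("gene", "protein_id", "domain_acc", "domain_name",
                        "start", "end", "e_value", "model_map")]
  instances$instance_id <- paste(instances$gene, instances$protein_id,
                                 instances$domain_acc, instances$start,
                                 sep = "|")
  instances$length_aa <- instances$end - instances$start + 1L
  instances <- instances[, c("instance_id", "gene", "protein_id",
                             "domain_acc", "domain_name", "start", "end",
                             "length_aa", "e_value", "model_map")]

  truth_smds <- if (nrow(planted)) {
    idx <- match(paste(planted$gene, planted$instance_ordinal), inst_key)
    data.frame(instance_id = instances$instance_id[idx],
               cancer_type = planted$cancer_type,
               fold = planted$fold, stringsAsFactors = FALSE)
  } else data.frame(instance_id = character(), cancer_type = character(),
                    fold = numeric())
  truth <- list(
    smds = truth_smds,
    hotspots = if (length(truth_hot)) do.call(rbind, truth_hot) else
      data.frame(instance_id = character(), cancer_type = character(),
                 position = integer()),
    labels = labels,
    functional_sites = if (length(site_rows)) do.call(rbind, site_rows) else
      data.frame(gene = character(), position = integer()))
  rownames(truth$hotspots) <- rownames(truth$functional_sites) <- NULL

  list(dataset = cohort_dataset(mutations, instances, samples),
       truth = truth)
}

#' Write a cohort to disk
#'
#' Emits `mutations.tsv`, `domains.tsv` and `samples.tsv` in the dialects
#' consumed by [read_mutations()] and [read_domain_instances()].
#'
#' @param dataset A `cohort_dataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_cohort <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mutations = file.path(dir, "mutations.tsv"),
             domains = file.path(dir, "domains.tsv"),
             samples = file.path(dir, "samples.tsv"))
  write_mutations(dataset$mutations, paths["mutations"])
  write_domain_instances(dataset$instances, paths["domains"])
  samples <- dataset$samples[order(dataset$samples$cancer_type,
                                   dataset$samples$sample_id), ]
  .write_tsv(samples, paths["samples"])
  invisible(paths)
}

#' Write ground-truth tables
#'
#' Emits `truth_smds.tsv`, `truth_hotspots.tsv`, `truth_labels.tsv` and
#' `truth_functional_sites.tsv`. Hotspot positions are checked against the
#' instance bounds encoded in their `instance_id` before writing.
#'
#' @param truth Truth list from [generate_cohort()].
#' @param dir Output directory.
#' @param instances Optional instance table used to validate hotspot bounds.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_truth <- function(truth, dir, instances = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(instances) && nrow(truth$hotspots)) {
    idx <- match(truth$hotspots$instance_id, instances$instance_id)
    if (any(is.na(idx)))
      .data_error("truth hotspot references an unknown instance")
    inside <- truth$hotspots$position >= instances$start[idx] &
      truth$hotspots$position <= instances$end[idx]
    if (any(!inside))
      .data_error("truth hotspot position falls outside its instance")
  }
  paths <- c(smds = file.path(dir, "truth_smds.tsv"),
             hotspots = file.path(dir, "truth_hotspots.tsv"),
             labels = file.path(dir, "truth_labels.tsv"),
             functional_sites = file.path(dir, "truth_functional_sites.tsv"))
  .write_tsv(truth$smds, paths["smds"])
  .write_tsv(truth$hotspots, paths["hotspots"])
  .write_tsv(truth$labels, paths["labels"])
  .write_tsv(truth$functional_sites, paths["functional_sites"])
  invisible(paths)
}

#' Read ground-truth tables written by [write_truth()]
#'
#' @param dir Directory containing the truth TSVs.
#' @return A truth list (`smds`, `hotspots`, `labels`, `functional_sites`).
#' @export
read_truth <- function(dir) {
  list(smds = .read_tsv(file.path(dir, "truth_smds.tsv")),
       hotspots = .read_tsv(file.path(dir, "truth_hotspots.tsv")),
       labels = .read_tsv(file.path(dir, "truth_labels.tsv")),
       functional_sites = .read_tsv(file.path(dir, "truth_functional_sites.tsv")))
}
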