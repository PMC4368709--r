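# The analytical core: mutation-to-instance mapping, density, the SMD and
# hotspot exact-test scans, cross-cancer sharing, domain-type pooling,
# co-occurrence and per-sample exclusivity.

#' Map mutations onto domain instances
#'
#' Matches every mutation to all domain instances on the same protein whose
#' `[start, end]` range contains its position (inclusive bounds). A mutation
#' overlapping k instances yields k rows; a mutation matching no instance is
#' retained with `instance_id = NA` so it still contributes to the
#' "outside this domain" cells of the contingency tables.
#'
#' Expects instances pre-filtered by E-value and mutations pre-filtered by
#' impact ([filter_damaging()]).
#'
#' @param dataset A [cohort_dataset()].
#' @return Data frame with one row per (mutation, matched instance) plus one
#'   row per unmatched mutation: columns `mut_id`, `gene`, `protein_id`,
#'   `sample_id`, `cancer_type`, `position`, `instance_id`.
#' @export
map_mutations <- function(dataset) {
  m <- dataset$mutations
  inst <- dataset$instances
  m$mut_id <- seq_len(nrow(m))
  base <- m[, c("mut_id", "gene", "protein_id", "sample_id", "cancer_type",
                "position")]
  if (nrow(base) == 0) {
    base$instance_id <- character()
    return(base)
  }
  hits <- merge(base, inst[, c("protein_id", "instance_id", "start", "end")],
                by = "protein_id")
  hits <- hits[hits$position >= hits$start & hits$position <= hits$end, ,
               drop = FALSE]
  matched <- hits[, c("mut_id", "gene", "protein_id", "sample_id",
                      "cancer_type", "position", "instance_id")]
  un <- base[!(base$mut_id %in% matched$mut_id), , drop = FALSE]
  if (nrow(un)) un$instance_id <- NA_character_
  out <- rbind(matched, un)
  out <- out[order(out$mut_id, out$instance_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-instance mutation density
#'
#' Mutations per megabase of domain-encoding DNA per sample:
#' `count * 1e6 / (3 * length_aa * n_samples)`, where the factor 3 converts
#' amino-acid length to coding nucleotides and `n_samples` is the number of
#' sequenced samples of that cancer type. Instances with zero mutations in a
#' cancer are omitted (only mutated domain instances are reported).
#'
#' @param dataset A [cohort_dataset()].
#' @param mapped Output of [map_mutations()].
#' @return Data frame with `instance_id`, `cancer_type`, `count`, `density`.
#' @export
mutation_density <- function(dataset, mapped) {
  nsamp <- .samples_per_cancer(dataset)
  if (any(nsamp == 0)) .data_error("cancer type with zero samples")
  hits <- mapped[!is.na(mapped$instance_id), , drop = FALSE]
  if (nrow(hits) == 0)
    return(data.frame(instance_id = character(), cancer_type = character(),
                      count = integer(), density = numeric()))
  agg <- stats::aggregate(list(count = hits$mut_id),
                          by = list(instance_id = hits$instance_id,
                                    cancer_type = hits$cancer_type),
                          FUN = length)
  len <- dataset$instances$length_aa[match(agg$instance_id,
                                           dataset$instances$instance_id)]
  ns <- nsamp[agg$cancer_type]
  if (any(is.na(ns))) .data_error("mutation cancer type missing from sample registry")
  agg$density <- agg$count * 1e6 / (3 * len * as.numeric(ns))
  agg <- agg[order(agg$instance_id, agg$cancer_type), ]
  rownames(agg) <- NULL
  agg
}

# totals of damaging mutations per cancer (each mutation counted once)
.totals_per_cancer <- function(mapped) {
  u <- unique(mapped[, c("mut_id", "cancer_type")])
  tab <- table(u$cancer_type)
  stats::setNames(as.integer(tab), names(tab))
}

#' Scan for significantly mutated domain instances (SMDs)
#'
#' For every (domain instance, cancer type) cell with at least one mapped
#' mutation, tests whether the instance's mutation share in the focal cancer
#' exceeds its share in all other cancers pooled, via a two-sided Fisher's
#' exact test on the 2x2 table: rows = focal cancer vs all other cancers,
#' columns = mutations inside vs outside the instance (counted over all
#' damaging mutations of the analyzed protein set, so regional differences
#' in mutation rate are implicitly controlled). Benjamini-Hochberg
#' adjustment is applied over the full family of executed tests. A cell is
#' called an SMD when `p_value < smd_alpha`, `p_adjusted < smd_fdr` and the
#' odds ratio exceeds 1 (enrichment only).
#'
#' @param dataset A [cohort_dataset()].
#' @param mapped Output of [map_mutations()].
#' @param thresholds A [thresholds()] object.
#' @return Data frame sorted by `p_value` with columns `instance_id`,
#'   `gene`, `domain_acc`, `cancer_type`, `a`, `b`, `c`, `d` (contingency
#'   counts), `odds_ratio`, `p_value`, `p_adjusted`, `density`, `is_smd`.
#' @export
smd_scan <- function(dataset, mapped, thresholds = domainscape::thresholds()) {
  cancers <- unique(dataset$samples$cancer_type)
  if (length(cancers) < 2)
    .data_error("cross-cancer contrast undefined: need >= 2 cancer types")
  totals <- .totals_per_cancer(mapped)
  N <- sum(totals)
  dens <- mutation_density(dataset, mapped)
  if (nrow(dens) == 0)
    return(data.frame(instance_id = character(), gene = character(),
                      domain_acc = character(), cancer_type = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), odds_ratio = numeric(),
                      p_value = numeric(), p_adjusted = numeric(),
                      density = numeric(), is_smd = logical()))
  # instance totals across all cancers
  inst_tot <- tapply(dens$count, dens$instance_id, sum)
  res <- dens
  res$a <- res$count
  res$b <- as.integer(totals[res$cancer_type] - res$a)
  res$c <- as.integer(inst_tot[res$instance_id] - res$a)
  res$d <- as.integer(N - totals[res$cancer_type] - res$c)
  ft <- mapply(function(a, b, c, d) {
    f <- fisher_exact(a, b, c, d, sided = "two_sided")
    c(f$p_value, f$estimate)
  }, res$a, res$b, res$c, res$d)
  res$p_value <- ft[1, ]
  res$odds_ratio <- ft[2, ]
  res$p_adjusted <- bh_adjust(res$p_value)
  res$is_smd <- res$p_value < thresholds$smd_alpha &
    res$p_adjusted < thresholds$smd_fdr &
    !is.nan(res$odds_ratio) & res$odds_ratio > 1
  idx <- match(res$instance_id, dataset$instances$instance_id)
  res$gene <- dataset$instances$gene[idx]
  res$domain_acc <- dataset$instances$domain_acc[idx]
  res <- res[order(res$p_value, res$instance_id, res$cancer_type),
             c("instance_id", "gene", "domain_acc", "cancer_type",
               "a", "b", "c", "d", "odds_ratio", "p_value", "p_adjusted",
               "density", "is_smd")]
  rownames(res) <- NULL
  res
}

#' Scan for within-instance mutational hotspots
#'
#' For every domain instance belonging to a gene with at least one SMD, and
#' every residue carrying at least one mutation in a focal cancer, tests the
#' 2x2 table (this residue vs the instance's other residues) x (focal cancer
#' vs all other cancers), restricted to mutations mapped to that instance.
#' Two-sided Fisher's exact test; BH adjustment over all executed hotspot
#' tests. A residue is called a hotspot when `p_value < hotspot_alpha`,
#' `p_adjusted < hotspot_fdr` and the direction is enrichment.
#'
#' @param dataset A [cohort_dataset()].
#' @param mapped Output of [map_mutations()].
#' @param smd_results Output of [smd_scan()].
#' @param thresholds A [thresholds()] object.
#' @return Data frame sorted by `p_value` with columns `instance_id`,
#'   `gene`, `cancer_type`, `position`, the four counts
#'   (`count_here_this_cancer`, `count_elsewhere_this_cancer`,
#'   `count_here_other_cancers`, `count_elsewhere_other_cancers`),
#'   `odds_ratio`, `p_value`, `p_adjusted`, `is_hotspot`.
#' @export
hotspot_scan <- function(dataset, mapped, smd_results,
                         thresholds = domainscape::thresholds()) {
  empty <- data.frame(instance_id = character(), gene = character(),
                      cancer_type = character(), position = integer(),
                      count_here_this_cancer = integer(),
                      count_elsewhere_this_cancer = integer(),
                      count_here_other_cancers = integer(),
                      count_elsewhere_other_cancers = integer(),
                      odds_ratio = numeric(), p_value = numeric(),
                      p_adjusted = numeric(), is_hotspot = logical())
  smd_genes <- unique(smd_results$gene[smd_results$is_smd])
  if (length(smd_genes) == 0) return(empty)
  keep_inst <- dataset$instances$instance_id[
    dataset$instances$gene %in% smd_genes]
  hits <- mapped[!is.na(mapped$instance_id) &
                   mapped$instance_id %in% keep_inst, , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  # counts per (instance, position, cancer) and marginals per instance
  cnt <- stats::aggregate(list(k = hits$mut_id),
                          by = list(instance_id = hits$instance_id,
                                    position = hits$position,
                                    cancer_type = hits$cancer_type),
                          FUN = length)
  tot_ic <- stats::aggregate(list(t = hits$mut_id),
                             by = list(instance_id = hits$instance_id,
                                       cancer_type = hits$cancer_type),
                             FUN = length)
  tot_i <- tapply(tot_ic$t, tot_ic$instance_id, sum)
  pos_tot <- stats::aggregate(list(kt = cnt$k),
                              by = list(instance_id = cnt$instance_id,
                                        position = cnt$position),
                              FUN = sum)
  key_ic <- function(i, c) paste(i, c, sep = "\r")
  key_ip <- function(i, p) paste(i, p, sep = "\r")
  t_ic <- stats::setNames(tot_ic$t, key_ic(tot_ic$instance_id, tot_ic$cancer_type))
  k_ip <- stats::setNames(pos_tot$kt, key_ip(pos_tot$instance_id, pos_tot$position))
  res <- cnt
  res$count_here_this_cancer <- res$k
  res$count_elsewhere_this_cancer <-
    as.integer(t_ic[key_ic(res$instance_id, res$cancer_type)] - res$k)
  res$count_here_other_cancers <-
    as.integer(k_ip[key_ip(res$instance_id, res$position)] - res$k)
  res$count_elsewhere_other_cancers <-
    as.integer(tot_i[res$instance_id] -
                 t_ic[key_ic(res$instance_id, res$cancer_type)] -
                 res$count_here_other_cancers)
  ft <- mapply(function(a, b, c, d) {
    f <- fisher_exact(a, b, c, d, sided = "two_sided")
    c(f$p_value, f$estimate)
  }, res$count_here_this_cancer, res$count_elsewhere_this_cancer,
     res$count_here_other_cancers, res$count_elsewhere_other_cancers)
  res$p_value <- ft[1, ]
  res$odds_ratio <- ft[2, ]
  res$p_adjusted <- bh_adjust(res$p_value)
  res$is_hotspot <- res$p_value < thresholds$hotspot_alpha &
    res$p_adjusted < thresholds$hotspot_fdr &
    !is.nan(res$odds_ratio) & res$odds_ratio > 1
  res$gene <- dataset$instances$gene[match(res$instance_id,
                                           dataset$instances$instance_id)]
  res <- res[order(res$p_value, res$instance_id, res$cancer_type,
                   res$position),
             c("instance_id", "gene", "cancer_type", "position",
               "count_here_this_cancer", "count_elsewhere_this_cancer",
               "count_here_other_cancers", "count_elsewhere_other_cancers",
               "odds_ratio", "p_value", "p_adjusted", "is_hotspot")]
  res$position <- as.integer(res$position)
  rownames(res) <- NULL
  res
}

#' Domain instances significantly mutated in several cancers
#'
#' @param smd_results Output of [smd_scan()].
#' @param min_cancers Minimum number of cancer types with an SMD call.
#' @return Data frame with `instance_id`, `gene`, `n_cancers` and a
#'   comma-separated `cancers` column.
#' @export
shared_smds <- function(smd_results, min_cancers = 2) {
  hits <- smd_results[smd_results$is_smd, , drop = FALSE]
  if (nrow(hits) == 0)
    return(data.frame(instance_id = character(), gene = character(),
                      n_cancers = integer(), cancers = character()))
  sp <- split(hits$cancer_type, hits$instance_id)
  out <- data.frame(instance_id = names(sp),
                    gene = hits$gene[match(names(sp), hits$instance_id)],
                    n_cancers = lengths(sp),
                    cancers = vapply(sp, function(x)
                      paste(sort(x), collapse = ","), ""),
                    stringsAsFactors = FALSE)
  out <- out[out$n_cancers >= min_cancers, , drop = FALSE]
  out <- out[order(-out$n_cancers, out$instance_id), ]
  rownames(out) <- NULL
  out
}

# model position for mapped rows: model_map when present, else linear offset
.model_position <- function(instance_id, position, instances) {
  idx <- match(instance_id, instances$instance_id)
  mp <- position - instances$start[idx] + 1L
  has_map <- which(instances$model_map[idx] != "")
  for (i in has_map) {
    mm <- parse_model_map(instances$model_map[idx[i]],
                          instances$start[idx[i]], instances$end[idx[i]])
    j <- match(position[i], mm$protein_position)
    mp[i] <- if (is.na(j)) NA_integer_ else mm$model_position[j]
  }
  mp
}

#' Per-residue mutation fractions in model coordinates
#'
#' For each (gene, cancer, instance) with at least one mapped mutation,
#' reports the fraction of the instance's mutations observed at each model
#' position, enabling pooling of equivalent residues across instances of the
#' same domain type. Model positions come from the instance's model map when
#' present, otherwise from the linear offset `position - start + 1`.
#'
#' @param dataset A [cohort_dataset()].
#' @param mapped Output of [map_mutations()].
#' @return Data frame with `domain_acc`, `gene`, `instance_id`,
#'   `cancer_type`, `model_position`, `count`, `fraction`.
#' @export
domain_type_profile <- function(dataset, mapped) {
  hits <- mapped[!is.na(mapped$instance_id), , drop = FALSE]
  if (nrow(hits) == 0)
    return(data.frame(domain_acc = character(), gene = character(),
                      instance_id = character(), cancer_type = character(),
                      model_position = integer(), count = integer(),
                      fraction = numeric()))
  cnt <- stats::aggregate(list(count = hits$mut_id),
                          by = list(instance_id = hits$instance_id,
                                    cancer_type = hits$cancer_type,
                                    position = hits$position),
                          FUN = length)
  cnt$model_position <- .model_position(cnt$instance_id, cnt$position,
                                        dataset$instances)
  tot <- stats::aggregate(list(total = cnt$count),
                          by = list(instance_id = cnt$instance_id,
                                    cancer_type = cnt$cancer_type),
                          FUN = sum)
  key <- function(i, c) paste(i, c, sep = "\r")
  tt <- stats::setNames(tot$total, key(tot$instance_id, tot$cancer_type))
  cnt$fraction <- cnt$count / tt[key(cnt$instance_id, cnt$cancer_type)]
  idx <- match(cnt$instance_id, dataset$instances$instance_id)
  cnt$domain_acc <- dataset$instances$domain_acc[idx]
  cnt$gene <- dataset$instances$gene[idx]
  out <- cnt[order(cnt$domain_acc, cnt$gene, cnt$cancer_type,
                   cnt$model_position),
             c("domain_acc", "gene", "instance_id", "cancer_type",
               "model_position", "count", "fraction")]
  rownames(out) <- NULL
  out
}

#' Hotspot positions shared across cancers within a domain type
#'
#' Pools hotspot calls across instances of the same domain type via model
#' positions, and reports pooled positions that are hotspots in at least
#' `min_cancers` distinct cancer types (union over genes).
#'
#' @param hotspot_results Output of [hotspot_scan()].
#' @param instances Domain-instance table (for accessions and model maps).
#' @param min_cancers Minimum number of distinct cancers (default 3).
#' @return Data frame with `domain_acc`, `model_position`, `n_cancers`,
#'   comma-separated `cancers` and `genes`.
#' @export
shared_type_hotspots <- function(hotspot_results, instances, min_cancers = 3) {
  hot <- hotspot_results[hotspot_results$is_hotspot, , drop = FALSE]
  empty <- data.frame(domain_acc = character(), model_position = integer(),
                      n_cancers = integer(), cancers = character(),
                      genes = character())
  if (nrow(hot) == 0) return(empty)
  hot$model_position <- .model_position(hot$instance_id, hot$position,
                                        instances)
  hot$domain_acc <- instances$domain_acc[match(hot$instance_id,
                                               instances$instance_id)]
  hot <- hot[!is.na(hot$model_position), , drop = FALSE]
  if (nrow(hot) == 0) return(empty)
  sp <- split(hot, paste(hot$domain_acc, hot$model_position, sep = "\r"))
  out <- do.call(rbind, lapply(sp, function(g) data.frame(
    domain_acc = g$domain_acc[1],
    model_position = as.integer(g$model_position[1]),
    n_cancers = length(unique(g$cancer_type)),
    cancers = paste(sort(unique(g$cancer_type)), collapse = ","),
    genes = paste(sort(unique(g$gene)), collapse = ","),
    stringsAsFactors = FALSE)))
  out <- out[out$n_cancers >= min_cancers, , drop = FALSE]
  out <- out[order(out$domain_acc, out$model_position), ]
  rownames(out) <- NULL
  out
}

#' SMD co-occurrence across patient samples
#'
#' For each unordered pair of SMDs within a cancer type, cross-classifies
#' that cancer's samples by whether they carry at least one mutation in each
#' instance, and tests association with a two-sided Fisher's exact test.
#'
#' @param dataset A [cohort_dataset()].
#' @param mapped Output of [map_mutations()].
#' @param smd_results Output of [smd_scan()].
#' @return Data frame with `cancer_type`, `instance_id_1`, `instance_id_2`,
#'   the four sample counts (`both`, `only_1`, `only_2`, `neither`),
#'   `odds_ratio`, `p_value`, `direction`.
#' @export
smd_cooccurrence <- function(dataset, mapped, smd_results) {
  empty <- data.frame(cancer_type = character(), instance_id_1 = character(),
                      instance_id_2 = character(), both = integer(),
                      only_1 = integer(), only_2 = integer(),
                      neither = integer(), odds_ratio = numeric(),
                      p_value = numeric(), direction = character())
  hits <- smd_results[smd_results$is_smd, , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  rows <- list()
  for (ct in unique(hits$cancer_type)) {
    insts <- sort(hits$instance_id[hits$cancer_type == ct])
    if (length(insts) < 2) next
    samp_all <- dataset$samples$sample_id[dataset$samples$cancer_type == ct]
    n_ct <- length(samp_all)
    carriers <- lapply(insts, function(i)
      unique(mapped$sample_id[!is.na(mapped$instance_id) &
                                mapped$instance_id == i &
                                mapped$cancer_type == ct]))
    names(carriers) <- insts
    for (i in seq_len(length(insts) - 1)) for (j in (i + 1):length(insts)) {
      x <- carriers[[i]]; y <- carriers[[j]]
      a <- length(intersect(x, y)); b <- length(setdiff(x, y))
      cc <- length(setdiff(y, x)); d <- n_ct - a - b - cc
      f <- fisher_exact(a, b, cc, d, sided = "two_sided")
      rows[[length(rows) + 1]] <- data.frame(
        cancer_type = ct, instance_id_1 = insts[i], instance_id_2 = insts[j],
        both = a, only_1 = b, only_2 = cc, neither = d,
        odds_ratio = f$estimate, p_value = f$p_value,
        direction = f$direction, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$cancer_type), ]
  rownames(out) <- NULL
  out
}

#' Per-sample exclusivity of pooled hotspots
#'
#' Checks whether any single tumor sample carries mutations at the same
#' pooled hotspot position in two or more instances of the same domain type.
#' An empty result asserts the exclusivity property: within one sample, a
#' functional hotspot of a domain type is mutated in at most one of the
#' type's instances.
#'
#' @param dataset A [cohort_dataset()].
#' @param mapped Output of [map_mutations()].
#' @param pooled Output of [shared_type_hotspots()].
#' @return Data frame of violations: `sample_id`, `domain_acc`,
#'   `model_position`, `n_instances`, comma-separated `instances`.
#' @export
hotspot_exclusivity <- function(dataset, mapped, pooled) {
  empty <- data.frame(sample_id = character(), domain_acc = character(),
                      model_position = integer(), n_instances = integer(),
                      instances = character())
  if (nrow(pooled) == 0) return(empty)
  hits <- mapped[!is.na(mapped$instance_id), , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  hits$model_position <- .model_position(hits$instance_id, hits$position,
                                         dataset$instances)
  hits$domain_acc <- dataset$instances$domain_acc[
    match(hits$instance_id, dataset$instances$instance_id)]
  key <- paste(hits$domain_acc, hits$model_position, sep = "\r")
  pooled_key <- paste(pooled$domain_acc, pooled$model_position, sep = "\r")
  hits <- hits[key %in% pooled_key, , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  grp <- paste(hits$sample_id, hits$domain_acc, hits$model_position,
               sep = "\r")
  rows <- lapply(split(hits, grp), function(g) {
    insts <- sort(unique(g$instance_id))
    if (length(insts) < 2) return(NULL)
    data.frame(sample_id = g$sample_id[1], domain_acc = g$domain_acc[1],
               model_position = as.integer(g$model_position[1]),
               n_instances = length(insts),
               instances = paste(insts, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$domain_acc, out$model_position), ]
  rownames(out) <- NULL
  out
}

#' Interaction-mediating domain pairs with SMD status
#'
#' Joins SMD calls onto a supplied table of interaction-mediating domain
#' instance pairs and reports, per cancer type, whether one or both members
#' of each pair are significantly mutated.
#'
#' @param smd_results Output of [smd_scan()].
#' @param pairs Data frame with columns `instance_id_1`, `instance_id_2`.
#' @return Data frame with `instance_id_1`, `instance_id_2`, `cancer_type`,
#'   `smd_1`, `smd_2`, `both_smd`, restricted to (pair, cancer) rows where
#'   at least one member is an SMD. Pairs referencing instances absent from
#'   the scan are skipped with a warning.
#' @export
interacting_pair_report <- function(smd_results, pairs) {
  empty <- data.frame(instance_id_1 = character(),
                      instance_id_2 = character(), cancer_type = character(),
                      smd_1 = logical(), smd_2 = logical(),
                      both_smd = logical())
  if (nrow(pairs) == 0) return(empty)
  .require_columns(pairs, c("instance_id_1", "instance_id_2"), "pairs")
  known <- unique(smd_results$instance_id)
  ok <- pairs$instance_id_1 %in% known & pairs$instance_id_2 %in% known
  if (any(!ok)) {
    warning(sprintf("%d pair(s) reference instances absent from the scan; skipped",
                    sum(!ok)))
    pairs <- pairs[ok, , drop = FALSE]
  }
  if (nrow(pairs) == 0) return(empty)
  key <- function(i, c) paste(i, c, sep = "\r")
  smd_set <- key(smd_results$instance_id[smd_results$is_smd],
                 smd_results$cancer_type[smd_results$is_smd])
  rows <- list()
  for (ct in unique(smd_results$cancer_type)) {
    s1 <- key(pairs$instance_id_1, ct) %in% smd_set
    s2 <- key(pairs$instance_id_2, ct) %in% smd_set
    keep <- s1 | s2
    if (!any(keep)) next
    rows[[length(rows) + 1]] <- data.frame(
      instance_id_1 = pairs$instance_id_1[keep],
      instance_id_2 = pairs$instance_id_2[keep],
      cancer_type = ct, smd_1 = s1[keep], smd_2 = s2[keep],
      both_smd = (s1 & s2)[keep], stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$cancer_type, out$instance_id_1, out$instance_id_2), ]
  rownames(out) <- NULL
  out
}

#' -log10 p-value matrix of the SMD scan
#'
#' Instances x cancers matrix of `-log10(p)` suitable for heat-map export.
#' P-values are clipped below at 1e-300 before the logarithm; untested cells
#' (no mutations) are 0.
#'
#' @param smd_results Output of [smd_scan()].
#' @return A numeric matrix with instance ids as row names and cancer types
#'   as column names.
#' @export
heatmap_matrix <- function(smd_results) {
  insts <- sort(unique(smd_results$instance_id))
  cancers <- sort(unique(smd_results$cancer_type))
  m <- matrix(0, length(insts), length(cancers),
              dimnames = list(insts, cancers))
  if (nrow(smd_results))
    m[cbind(match(smd_results$instance_id, insts),
            match(smd_results$cancer_type, cancers))] <-
      -log10(pmax(smd_results$p_value, 1e-300))
  m
}
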