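# Downstream interpretation: hotspot-ratio profiles, oncogene vs tumor
# suppressor comparison and classification, gene-set enrichment and
# functional-site overlap.

#' Hotspot-ratio profiles per (gene, cancer)
#'
#' For every (gene, cancer type) with at least one SMD, computes the number
#' of hotspot positions and the number of distinct mutated residues within
#' the gene's SMDs in that cancer, and their ratio. Oncogene-like genes
#' concentrate mutations on few recurrent residues (ratio near 1);
#' tumor-suppressor-like genes spread mutations across the domain (ratio
#' near 0). Mutated residues are counted per instance, over the residues
#' actually tested by [hotspot_scan()] (those with at least one mutation in
#' the focal cancer).
#'
#' @param smd_results Output of [smd_scan()].
#' @param hotspot_results Output of [hotspot_scan()].
#' @return Data frame with `gene`, `cancer_type`, `n_hotspot_positions`,
#'   `n_mutated_positions`, `hotspot_ratio`; profiles with zero mutated
#'   positions are excluded.
#' @export
hotspot_ratio <- function(smd_results, hotspot_results) {
  smd <- smd_results[smd_results$is_smd, , drop = FALSE]
  empty <- data.frame(gene = character(), cancer_type = character(),
                      n_hotspot_positions = integer(),
                      n_mutated_positions = integer(),
                      hotspot_ratio = numeric())
  if (nrow(smd) == 0 || nrow(hotspot_results) == 0) return(empty)
  key <- function(i, c) paste(i, c, sep = "\r")
  smd_cells <- key(smd$instance_id, smd$cancer_type)
  hr <- hotspot_results[key(hotspot_results$instance_id,
                            hotspot_results$cancer_type) %in% smd_cells, ,
                        drop = FALSE]
  if (nrow(hr) == 0) return(empty)
  grp <- paste(hr$gene, hr$cancer_type, sep = "\r")
  rows <- lapply(split(hr, grp), function(g) data.frame(
    gene = g$gene[1], cancer_type = g$cancer_type[1],
    n_hotspot_positions = length(unique(paste(g$instance_id,
                                              g$position)[g$is_hotspot])),
    n_mutated_positions = length(unique(paste(g$instance_id, g$position))),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[out$n_mutated_positions > 0, , drop = FALSE]
  out$hotspot_ratio <- out$n_hotspot_positions / out$n_mutated_positions
  out <- out[order(out$gene, out$cancer_type), ]
  rownames(out) <- NULL
  out
}

#' Compare hotspot ratios of oncogenes and tumor suppressors
#'
#' Two-sided Mann-Whitney U test on the hotspot-ratio values of
#' oncogene-labeled vs tumor-suppressor-labeled (gene, cancer) profiles.
#'
#' @param profiles Output of [hotspot_ratio()].
#' @param labels Gene-label data frame ([read_gene_labels()]).
#' @return A list with `U`, `p_value`, `median_oncogene`,
#'   `median_tumor_suppressor` and the two group sizes.
#' @export
compare_onco_tsg <- function(profiles, labels) {
  lab <- labels$label[match(profiles$gene, labels$gene)]
  x <- profiles$hotspot_ratio[!is.na(lab) & lab == "oncogene"]
  y <- profiles$hotspot_ratio[!is.na(lab) & lab == "tumor_suppressor"]
  if (length(x) == 0 || length(y) == 0)
    .data_error("need at least one labeled profile in each group")
  mw <- mann_whitney_u(x, y)
  list(U = mw$estimate, p_value = mw$p_value,
       median_oncogene = stats::median(x),
       median_tumor_suppressor = stats::median(y),
       n_oncogene = length(x), n_tumor_suppressor = length(y))
}

# threshold on hotspot_ratio minimising misclassification over labeled
# profiles, tie broken toward the midpoint of the optimal interval
.hotspot_ratio_threshold <- function(ratios, is_onco) {
  u <- sort(unique(ratios))
  # candidate decision regions: rule "ratio >= t" for t in
  # (u[j], u[j+1]] (j = 0..m), bounded to [0, 1] since ratios live there
  bounds <- c(0, u, 1)
  errs <- vapply(seq_len(length(u) + 1), function(j) {
    cut <- if (j <= length(u)) u[j] else Inf   # onco iff ratio >= cut
    pred_onco <- ratios >= cut
    sum(pred_onco != is_onco)
  }, 0)
  best <- which(errs == min(errs))
  # merge a contiguous run of tied-optimal regions into one interval
  run_start <- best[1]
  run_end <- run_start
  while (run_end + 1 <= length(errs) && (run_end + 1) %in% best)
    run_end <- run_end + 1
  lo <- bounds[run_start]
  hi <- bounds[run_end + 1]
  (lo + hi) / 2
}

#' Classify unlabeled genes by hotspot ratio
#'
#' Learns a decision threshold on the hotspot ratio that minimises the
#' misclassification count over labeled profiles (ties broken toward the
#' midpoint of the optimal threshold interval), then labels unlabeled
#' profiles: ratio at or above the threshold is oncogene-like, below is
#' tumor-suppressor-like. Profiles with fewer than `min_mutated` distinct
#' mutated residues are left `undetermined` (too sparse to judge a
#' distribution pattern).
#'
#' @param profiles Output of [hotspot_ratio()].
#' @param labels Gene-label data frame; both classes must be represented.
#' @param min_mutated Sparsity guard (default 3).
#' @return `profiles` with added columns `label` (training label or
#'   `unlabeled`) and `predicted_label`; the learned threshold is attached
#'   as attribute `"threshold"`.
#' @export
classify_genes <- function(profiles, labels, min_mutated = 3) {
  lab <- labels$label[match(profiles$gene, labels$gene)]
  lab[is.na(lab)] <- "unlabeled"
  labeled <- lab != "unlabeled"
  if (!any(lab == "oncogene") || !any(lab == "tumor_suppressor"))
    .data_error("labeled profiles must include both oncogenes and tumor suppressors")
  t_star <- .hotspot_ratio_threshold(profiles$hotspot_ratio[labeled],
                                     lab[labeled] == "oncogene")
  pred <- ifelse(profiles$hotspot_ratio >= t_star, "oncogene-like",
                 "tumor_suppressor-like")
  pred[profiles$n_mutated_positions < min_mutated] <- "undetermined"
  out <- profiles
  out$label <- lab
  out$predicted_label <- pred
  attr(out, "threshold") <- t_star
  out
}

#' Gene-set enrichment of SMD genes
#'
#' 2x2 Fisher's exact test and fold enrichment for the overlap between a
#' candidate gene set (e.g. genes encoding at least one SMD) and a reference
#' set (e.g. a cancer-gene census) within a background universe of genes.
#'
#' @param candidates Character vector of candidate genes.
#' @param reference Character vector of reference genes.
#' @param background Size of the background gene universe (integer).
#' @return A list with `fold`, `p_value`, `odds_ratio`, `direction` and the
#'   overlap counts (`hits`, `n_candidates`, `n_reference`, `background`).
#' @export
geneset_enrichment <- function(candidates, reference, background) {
  candidates <- unique(candidates); reference <- unique(reference)
  n_union <- length(union(candidates, reference))
  if (background < n_union)
    .data_error("background universe smaller than candidates + reference")
  hits <- length(intersect(candidates, reference))
  a <- hits
  b <- length(candidates) - hits
  cc <- length(reference) - hits
  d <- background - n_union + hits - a  # = background - |union|
  f <- fisher_exact(a, b, cc, d, sided = "two_sided")
  fold <- fold_enrichment(hits, length(candidates), length(reference),
                          background)
  list(fold = fold, p_value = f$p_value, odds_ratio = f$estimate,
       direction = f$direction, hits = hits,
       n_candidates = length(candidates), n_reference = length(reference),
       background = background)
}

.overlap_from_counts <- function(onco_at, onco_total, tsg_at, tsg_total) {
  a <- onco_at; b <- onco_total - onco_at
  cc <- tsg_at; d <- tsg_total - tsg_at
  f <- fisher_exact(a, b, cc, d, sided = "two_sided")
  p_on <- 100 * a / onco_total
  p_ts <- 100 * cc / tsg_total
  list(percent_onco = p_on, percent_tsg = p_ts,
       percent_onco_rounded = round(p_on), percent_tsg_rounded = round(p_ts),
       odds_ratio = f$estimate, p_value = f$p_value,
       counts = c(onco_at_site = a, onco_not_at_site = b,
                  tsg_at_site = cc, tsg_not_at_site = d))
}

#' Functional-site overlap of hotspots from explicit tallies
#'
#' Same statistic as [functional_site_overlap()], computed directly from
#' hotspot tallies (how many of each class's hotspots fall at functional
#' sites) rather than from result tables.
#'
#' @param onco_at,onco_total Oncoprotein hotspots at functional sites, and
#'   total oncoprotein hotspots.
#' @param tsg_at,tsg_total Same for tumor-suppressor proteins.
#' @return See [functional_site_overlap()].
#' @export
site_overlap_from_counts <- function(onco_at, onco_total, tsg_at, tsg_total) {
  if (onco_total == 0 || tsg_total == 0)
    .data_error("both classes need at least one hotspot")
  if (onco_at > onco_total || tsg_at > tsg_total)
    .data_error("at-site counts cannot exceed totals")
  .overlap_from_counts(onco_at, onco_total, tsg_at, tsg_total)
}

#' Overlap of mutational hotspots with functional sites
#'
#' Cross-classifies the hotspots of labeled genes by (oncogene vs tumor
#' suppressor) x (at an annotated functional site vs not) and reports row
#' percentages (unrounded and rounded to the nearest integer), the sample
#' odds ratio and the two-sided Fisher p-value. Hotspots are matched to
#' sites exactly on (gene, residue position), restricted to annotations of
#' category `functional`.
#'
#' @param hotspot_results Output of [hotspot_scan()].
#' @param sites Site-annotation data frame ([read_site_annotations()]).
#' @param labels Gene-label data frame ([read_gene_labels()]).
#' @return A list with `percent_onco`, `percent_tsg`,
#'   `percent_onco_rounded`, `percent_tsg_rounded`, `odds_ratio`, `p_value`
#'   and the four `counts`.
#' @export
functional_site_overlap <- function(hotspot_results, sites, labels) {
  hot <- unique(hotspot_results[hotspot_results$is_hotspot,
                                c("gene", "position")])
  hot$label <- labels$label[match(hot$gene, labels$gene)]
  hot <- hot[!is.na(hot$label), , drop = FALSE]
  if (nrow(hot) == 0) .data_error("no labeled hotspots")
  fs <- sites[sites$site_category == "functional", , drop = FALSE]
  at_site <- paste(hot$gene, hot$position) %in% paste(fs$gene, fs$position)
  onco <- hot$label == "oncogene"
  if (!any(onco) || all(onco))
    .data_error("labeled hotspots must include both classes")
  .overlap_from_counts(sum(at_site & onco), sum(onco),
                       sum(at_site & !onco), sum(!onco))
}
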