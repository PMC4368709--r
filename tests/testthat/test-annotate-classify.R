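mk_smd <- function(instance_id, gene, cancer_type, is_smd = TRUE) {
  data.frame(instance_id = instance_id, gene = gene,
             cancer_type = cancer_type, is_smd = is_smd)
}

mk_hot <- function(instance_id, gene, cancer_type, position, is_hotspot) {
  data.frame(instance_id = instance_id, gene = gene,
             cancer_type = cancer_type, position = position,
             is_hotspot = is_hotspot)
}

test_that("hotspot ratio is hotspot positions over mutated positions", {
  smd <- mk_smd("i1", "EGFR", "lung")
  hot <- mk_hot("i1", "EGFR", "lung", 1:16, c(rep(TRUE, 4), rep(FALSE, 12)))
  prof <- hotspot_ratio(smd, hot)
  expect_equal(prof$hotspot_ratio, 0.25)
  expect_equal(prof$n_mutated_positions, 16)
  # single mutated residue that is a hotspot: upper bound 1
  prof2 <- hotspot_ratio(mk_smd("i2", "AKT1", "breast"),
                         mk_hot("i2", "AKT1", "breast", 17L, TRUE))
  expect_equal(prof2$hotspot_ratio, 1)
  # residues outside SMD cells do not count
  hot_mixed <- rbind(hot, mk_hot("i1", "EGFR", "colon", 99L, TRUE))
  expect_equal(hotspot_ratio(smd, hot_mixed), prof)
})

test_that("concentrated breast vs dispersed endometrial profiles order correctly", {
  # FGFR2-style: one hotspot among few residues in breast; nine spread
  # residues, one hotspot, in endometrium
  smd <- mk_smd(c("kin", "kin"), "FGFR2", c("breast", "endometrium"))
  hot <- rbind(
    mk_hot("kin", "FGFR2", "breast", c(549L, 550L, 551L),
           c(TRUE, FALSE, FALSE)),
    mk_hot("kin", "FGFR2", "endometrium", c(549L, 311:318),
           c(TRUE, rep(FALSE, 8))))
  prof <- hotspot_ratio(smd, hot)
  expect_gt(prof$hotspot_ratio[prof$cancer_type == "breast"],
            prof$hotspot_ratio[prof$cancer_type == "endometrium"])
})

test_that("hotspot ratio stays in [0,1] and never drops when a residue turns hot", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    is_hot <- runif(n) < 0.3
    smd <- mk_smd("i", "G", "lung")
    prof <- hotspot_ratio(smd, mk_hot("i", "G", "lung", seq_len(n), is_hot))
    expect_gte(prof$hotspot_ratio, 0)
    expect_lte(prof$hotspot_ratio, 1)
    if (any(!is_hot)) {
      flip <- is_hot
      flip[which(!is_hot)[1]] <- TRUE
      prof2 <- hotspot_ratio(smd, mk_hot("i", "G", "lung", seq_len(n), flip))
      expect_gte(prof2$hotspot_ratio, prof$hotspot_ratio)
    }
  }
})

test_that("oncogene vs TSG ratio comparison matches the permutation oracle", {
  prof <- data.frame(gene = c("O1", "O2", "T1", "T2"),
                     cancer_type = "lung",
                     n_hotspot_positions = c(8, 9, 1, 2),
                     n_mutated_positions = 10,
                     hotspot_ratio = c(0.8, 0.9, 0.1, 0.2))
  labels <- data.frame(gene = c("O1", "O2", "T1", "T2"),
                       label = c("oncogene", "oncogene",
                                 "tumor_suppressor", "tumor_suppressor"))
  cmp <- compare_onco_tsg(prof, labels)
  expect_gt(cmp$median_oncogene, cmp$median_tumor_suppressor)
  expect_equal(cmp$p_value, mwu_exact_p(c(0.8, 0.9), c(0.1, 0.2)))
  # identical ratio multisets: no difference
  prof$hotspot_ratio <- c(0.4, 0.5, 0.4, 0.5)
  expect_equal(compare_onco_tsg(prof, labels)$p_value, 1)
  expect_error(compare_onco_tsg(prof, labels[1:2, ]), "each group")
})

test_that("classification thresholds separate labeled classes and guard sparsity", {
  prof <- data.frame(gene = c("O1", "O2", "T1", "T2", "X1", "X2"),
                     cancer_type = "lung",
                     n_hotspot_positions = c(6, 8, 1, 2, 7, 1),
                     n_mutated_positions = c(10, 10, 10, 10, 10, 2),
                     hotspot_ratio = c(0.6, 0.8, 0.1, 0.2, 0.7, 0.5))
  labels <- data.frame(gene = c("O1", "O2", "T1", "T2"),
                       label = c("oncogene", "oncogene",
                                 "tumor_suppressor", "tumor_suppressor"))
  cls <- classify_genes(prof, labels)
  expect_equal(cls$predicted_label[cls$gene == "X1"], "oncogene-like")
  expect_equal(cls$predicted_label[cls$gene == "X2"], "undetermined")
  t_star <- attr(cls, "threshold")
  expect_true(t_star > 0.2 && t_star <= 0.6)
  # perfectly separable labels: zero training misclassification
  train <- cls[cls$label != "unlabeled", ]
  expect_equal(sum((train$hotspot_ratio >= t_star) !=
                     (train$label == "oncogene")), 0)
  expect_error(classify_genes(prof, labels[1:2, ]), "both")
})

test_that("the learned threshold is minimal-error over an exhaustive sweep", {
  set.seed(17)
  for (i in 1:15) {
    n <- sample(4:20, 1)
    ratios <- round(runif(n), 2)
    onco <- runif(n) < 0.5
    if (!any(onco) || all(onco)) next
    prof <- data.frame(gene = paste0("g", seq_len(n)), cancer_type = "x",
                       n_hotspot_positions = 1, n_mutated_positions = 5,
                       hotspot_ratio = ratios)
    labels <- data.frame(gene = prof$gene,
                         label = ifelse(onco, "oncogene", "tumor_suppressor"))
    cls <- classify_genes(prof, labels)
    t_star <- attr(cls, "threshold")
    err <- function(t) sum((ratios >= t) != onco)
    sweep_best <- min(vapply(c(0, sort(unique(ratios)), 1.01), err, 0))
    expect_equal(err(t_star), sweep_best)
  }
})

test_that("gene-set enrichment computes fold and exact p over the universe", {
  cands <- paste0("c", 1:10)
  ref <- c(cands[1:5], paste0("r", 1:95))
  e <- geneset_enrichment(cands, ref, 1000)
  expect_equal(e$fold, 5)
  expect_equal(e$hits, 5)
  # enumeration oracle overflows at this N; cross-check with the reference
  # implementation instead
  expect_equal(e$p_value,
               stats::fisher.test(matrix(c(5, 5, 95, 895), 2,
                                         byrow = TRUE))$p.value,
               tolerance = 1e-7)
  # disjoint sets: depletion at fold 0
  e2 <- geneset_enrichment(paste0("c", 1:10), paste0("r", 1:100), 1000)
  expect_equal(e2$fold, 0)
  expect_equal(e2$direction, "depleted")
  # reference equals the whole universe: no enrichment possible
  e3 <- geneset_enrichment(paste0("g", 1:10), paste0("g", 1:50), 50)
  expect_equal(e3$fold, 1)
  expect_equal(e3$p_value, 1)
  expect_error(geneset_enrichment(paste0("g", 1:10), paste0("h", 1:10), 15),
               "universe")
})

test_that("functional-site overlap reproduces the printed contingency", {
  ov <- site_overlap_from_counts(15, 40, 3, 47)
  expect_equal(ov$percent_onco, 37.5)
  expect_equal(ov$percent_onco_rounded, 38)
  expect_equal(ov$percent_tsg, 100 * 3 / 47)
  expect_equal(ov$percent_tsg_rounded, 6)
  expect_equal(ov$odds_ratio, 660 / 75)
  expect_equal(ov$p_value, brute_force_fisher(15, 25, 3, 44),
               tolerance = 1e-9)
})

test_that("site overlap from result tables matches the count-based route", {
  # 4 oncoprotein hotspots (2 at functional sites), 3 TSG hotspots (0 at)
  hot <- rbind(
    mk_hot("i1", "KRAS", "lung", c(12L, 13L, 20L, 30L), TRUE),
    mk_hot("i2", "TP53", "lung", c(100L, 110L, 120L), TRUE),
    mk_hot("i1", "KRAS", "lung", 40L, FALSE))  # non-hotspot rows ignored
  sites <- data.frame(gene = c("KRAS", "KRAS", "TP53"),
                      position = c(12L, 13L, 500L),
                      site_category = c("functional", "functional",
                                        "interface"))
  labels <- data.frame(gene = c("KRAS", "TP53"),
                       label = c("oncogene", "tumor_suppressor"))
  ov <- functional_site_overlap(hot, sites, labels)
  expect_equal(unname(ov$counts), c(2, 2, 0, 3))
  expect_equal(ov$percent_onco, 50)
  expect_equal(ov$p_value, site_overlap_from_counts(2, 4, 0, 3)$p_value)
  expect_error(functional_site_overlap(hot, sites,
                                       data.frame(gene = "BRAF",
                                                  label = "oncogene")),
               "no labeled hotspots")
})
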