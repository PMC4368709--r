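# Mapping, density, the two exact-test scans and the downstream landscape
# summaries, checked on hand-built cohorts and on generated data.

two_cancer_cohort <- function() {
  # G1 has a domain [10, 100] and an overlapping one [40, 60]
  inst <- data.frame(gene = c("G1", "G1"), domain_acc = c("PFa", "PFb"),
                     start = c(10L, 40L), end = c(100L, 60L))
  mut <- data.frame(
    gene = "G1",
    sample_id = c("lung_s1", "lung_s2", "lung_s3", "colon_s1"),
    cancer_type = c("lung", "lung", "lung", "colon"),
    position = c(50L, 101L, 5L, 50L))
  make_toy_cohort(mut, inst, make_samples(c("lung", "colon"), 5))
}

test_that("mutations map to all covering instances, inclusively", {
  ds <- two_cancer_cohort()
  mapped <- map_mutations(ds)
  at50 <- mapped[mapped$position == 50 & mapped$cancer_type == "lung", ]
  expect_equal(sort(unlist(strsplit(at50$instance_id, "\\|"))[
    seq(3, 8, by = 4)]), c("PFa", "PFb"))  # both overlapping instances
  expect_equal(nrow(at50), 2)
  # position 101 is just past the inclusive end of [10, 100]
  expect_true(is.na(mapped$instance_id[mapped$position == 101]))
  expect_true(is.na(mapped$instance_id[mapped$position == 5]))
  # unmatched mutations are retained
  expect_equal(length(unique(mapped$mut_id)), 4)
})

test_that("density is mutations per megabase of coding DNA per sample", {
  inst <- data.frame(gene = "G1", domain_acc = "PFa", start = 1L, end = 200L)
  mut <- data.frame(gene = "G1",
                    sample_id = paste0("lung_s", 1:6),
                    cancer_type = "lung", position = c(3L, 9L, 20L, 20L, 50L, 77L))
  ds <- make_toy_cohort(mut, inst, make_samples(c("lung", "colon"), 1000))
  dens <- mutation_density(ds, map_mutations(ds))
  expect_equal(nrow(dens), 1)  # colon has zero mutations: omitted
  expect_equal(dens$density, 6 * 1e6 / (3 * 200 * 1000))
  expect_equal(dens$density, 10)
  # doubling the samples halves the density at fixed count
  ds2 <- make_toy_cohort(mut, inst, make_samples(c("lung", "colon"), 2000))
  expect_equal(mutation_density(ds2, map_mutations(ds2))$density, 5)
})

test_that("smd_scan assembles the cross-cancer contingency correctly", {
  # lung: 12 mutations, 9 in the domain; colon: 15 mutations, 2 in it
  inst <- data.frame(gene = "G1", domain_acc = "PFa", start = 10L, end = 50L)
  mut <- rbind(
    data.frame(gene = "G1", sample_id = paste0("lung_s", 1:12),
               cancer_type = "lung",
               position = c(rep(20L, 5), 21:24, 200L, 201L, 202L)),
    data.frame(gene = "G1", sample_id = paste0("colon_s", 1:15),
               cancer_type = "colon",
               position = c(30L, 31L, 150:162)))
  ds <- make_toy_cohort(mut, inst, make_samples(c("lung", "colon"), 20))
  smd <- smd_scan(ds, map_mutations(ds))
  lung <- smd[smd$cancer_type == "lung", ]
  expect_equal(c(lung$a, lung$b, lung$c, lung$d), c(9, 3, 2, 13))
  expect_equal(lung$p_value,
               brute_force_fisher(9, 3, 2, 13), tolerance = 1e-9)
  expect_true(lung$odds_ratio > 1)
})

test_that("identical per-cancer proportions give p = 1 and no SMD call", {
  inst <- data.frame(gene = "G1", domain_acc = "PFa", start = 1L, end = 50L)
  mut <- rbind(
    data.frame(gene = "G1", sample_id = paste0("lung_s", 1:10),
               cancer_type = "lung", position = c(rep(10L, 3), 101:107)),
    data.frame(gene = "G1", sample_id = paste0("colon_s", 1:10),
               cancer_type = "colon", position = c(rep(12L, 3), 111:117)))
  ds <- make_toy_cohort(mut, inst, make_samples(c("lung", "colon"), 12))
  smd <- smd_scan(ds, map_mutations(ds))
  expect_equal(smd$p_value, c(1, 1))
  expect_false(any(smd$is_smd))
})

test_that("a single cancer type is an error for the SMD scan", {
  inst <- data.frame(gene = "G1", domain_acc = "PFa", start = 1L, end = 50L)
  mut <- data.frame(gene = "G1", sample_id = "lung_s1",
                    cancer_type = "lung", position = 10L)
  ds <- make_toy_cohort(mut, inst, make_samples("lung", 5))
  expect_error(smd_scan(ds, map_mutations(ds)), "cross-cancer")
})

test_that("mapped counts are conserved per cancer type", {
  sim <- generate_and_map(sim_config(seed = 13, n_genes = 20,
                                     samples_per_cancer = 100))
  mapped <- sim$mapped
  totals <- table(sim$dataset$mutations$cancer_type)
  # single-match subset: each mutation appears exactly once
  once <- names(which(table(mapped$mut_id) == 1))
  single <- mapped[mapped$mut_id %in% once, ]
  for (ct in names(totals)) {
    in_dom <- sum(single$cancer_type == ct & !is.na(single$instance_id))
    out_dom <- sum(single$cancer_type == ct & is.na(single$instance_id))
    multi <- sum(sim$dataset$mutations$cancer_type == ct) -
      sum(single$cancer_type == ct)
    expect_equal(in_dom + out_dom + multi, as.integer(totals[[ct]]))
  }
})

test_that("label-permuted cohorts stay below the nominal SMD FDR", {
  cfg <- sim_config(seed = 31, n_genes = 20, samples_per_cancer = 100,
                    planted_fold = 10, n_planted_smds = 4)
  gen <- generate_cohort(cfg)
  damaging <- filter_damaging(gen$dataset$mutations)
  set.seed(99)
  frac_called <- vapply(1:20, function(i) {
    samples <- gen$dataset$samples
    perm <- samples
    perm$cancer_type <- sample(samples$cancer_type)
    key <- stats::setNames(perm$cancer_type, perm$sample_id)
    m <- damaging
    m$cancer_type <- unname(key[m$sample_id])
    ds <- cohort_dataset(m, gen$dataset$instances, perm)
    smd <- smd_scan(ds, map_mutations(ds))
    if (nrow(smd) == 0) 0 else mean(smd$is_smd)
  }, 0)
  expect_lte(mean(frac_called), 0.05)
})

test_that("every SMD call is an enrichment and hotspot cells never leak", {
  sim <- generate_and_map(sim_config(seed = 2))
  smd <- smd_scan(sim$dataset, sim$mapped)
  expect_true(all(smd$odds_ratio[smd$is_smd] > 1))
  hot <- hotspot_scan(sim$dataset, sim$mapped, smd)
  if (nrow(hot)) {
    # comparison cells are other cancers only: per instance, the focal and
    # comparison columns partition the instance's mutations
    inst_tot <- tapply(
      rep(1, sum(!is.na(sim$mapped$instance_id))),
      sim$mapped$instance_id[!is.na(sim$mapped$instance_id)], sum)
    expect_equal(hot$count_here_this_cancer + hot$count_elsewhere_this_cancer +
                   hot$count_here_other_cancers +
                   hot$count_elsewhere_other_cancers,
                 as.integer(inst_tot[hot$instance_id]),
                 ignore_attr = TRUE)
    focal <- tapply(hot$count_here_this_cancer + hot$count_elsewhere_this_cancer,
                    paste(hot$instance_id, hot$cancer_type), max)
    other <- tapply(hot$count_here_other_cancers + hot$count_elsewhere_other_cancers,
                    paste(hot$instance_id, hot$cancer_type), max)
    expect_true(all(focal + other == inst_tot[
      sub(" [^ ]+$", "", names(focal))]))
  }
})

test_that("a concentrated residue against a flat background is a hotspot", {
  # one residue holds 10 of lung's 12 instance mutations; other cancers
  # carry 15 instance mutations, none at that residue
  inst <- data.frame(gene = "G1", domain_acc = "PFa", start = 1L, end = 60L)
  mut <- rbind(
    data.frame(gene = "G1", sample_id = paste0("lung_s", 1:12),
               cancer_type = "lung", position = c(rep(30L, 10), 40L, 41L)),
    data.frame(gene = "G1", sample_id = paste0("colon_s", 1:15),
               cancer_type = "colon", position = as.integer(1:15)))
  ds <- make_toy_cohort(mut, inst, make_samples(c("lung", "colon"), 20))
  mapped <- map_mutations(ds)
  smd <- smd_scan(ds, mapped)
  smd$is_smd <- TRUE  # scan all instances of the gene
  hot <- hotspot_scan(ds, mapped, smd)
  h30 <- hot[hot$position == 30 & hot$cancer_type == "lung", ]
  expect_equal(c(h30$count_here_this_cancer, h30$count_elsewhere_this_cancer,
                 h30$count_here_other_cancers,
                 h30$count_elsewhere_other_cancers), c(10, 2, 0, 15))
  expect_lt(h30$p_value, 0.01)
  expect_equal(h30$p_value, brute_force_fisher(10, 2, 0, 15),
               tolerance = 1e-9)
  expect_true(h30$is_hotspot)
  # a uniform one-per-residue instance yields no hotspot
  flat <- hot[hot$cancer_type == "colon", ]
  expect_false(any(flat$is_hotspot))
})

test_that("shared SMDs are grouped by instance across cancers", {
  smd <- data.frame(instance_id = c("i1", "i1", "i2", "i3"),
                    gene = c("g1", "g1", "g2", "g3"),
                    cancer_type = c("lung", "colon", "lung", "breast"),
                    is_smd = c(TRUE, TRUE, TRUE, FALSE))
  sh <- shared_smds(smd, 2)
  expect_equal(sh$instance_id, "i1")
  expect_equal(sh$cancers, "colon,lung")
  expect_equal(nrow(shared_smds(smd, 1)), 2)  # all SMD instances
  expect_equal(nrow(shared_smds(smd[smd$is_smd == FALSE, ], 1)), 0)
})

test_that("domain-type profiles normalise per instance and pool by model position", {
  # two Ras-like instances whose model maps align different protein
  # positions onto model position 12
  inst <- data.frame(gene = c("KRAS", "NRAS"), domain_acc = "PF00071",
                     start = c(5L, 11L), end = c(14L, 20L),
                     model_map = c("5:3,6:4,10:12,14:20",
                                   "11:3,16:12,20:20"))
  mut <- rbind(
    data.frame(gene = "KRAS", sample_id = paste0("lung_s", 1:4),
               cancer_type = "lung", position = rep(10L, 4)),
    data.frame(gene = "NRAS", sample_id = paste0("colon_s", 1:2),
               cancer_type = "colon", position = c(16L, 20L)))
  ds <- make_toy_cohort(mut, inst, make_samples(c("lung", "colon"), 6))
  prof <- domain_type_profile(ds, map_mutations(ds))
  kras <- prof[prof$gene == "KRAS", ]
  expect_equal(kras$fraction, 1)           # all 4 mutations at one position
  expect_equal(kras$model_position, 12L)   # via the model map
  expect_equal(prof$model_position[prof$gene == "NRAS"], c(12L, 20L))
  # fractions sum to 1 within each (instance, cancer)
  sums <- tapply(prof$fraction, paste(prof$instance_id, prof$cancer_type), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("type-level pooling reports positions hot in enough cancers", {
  hot <- data.frame(
    instance_id = c("KRAS|P_KRAS|PF00071|5", "NRAS|P_NRAS|PF00071|11",
                    "KRAS|P_KRAS|PF00071|5", "KRAS|P_KRAS|PF00071|5"),
    gene = c("KRAS", "NRAS", "KRAS", "KRAS"),
    cancer_type = c("lung", "colon", "pancreas", "lung"),
    position = c(10L, 16L, 10L, 6L),
    is_hotspot = TRUE)
  inst <- data.frame(gene = c("KRAS", "NRAS"), domain_acc = "PF00071",
                     protein_id = c("P_KRAS", "P_NRAS"),
                     start = c(5L, 11L), end = c(14L, 20L),
                     model_map = c("5:3,6:4,10:12,14:20",
                                   "11:3,16:12,20:20"))
  inst$instance_id <- paste(inst$gene, inst$protein_id, inst$domain_acc,
                            inst$start, sep = "|")
  pooled <- shared_type_hotspots(hot, inst, min_cancers = 3)
  expect_equal(nrow(pooled), 1)
  expect_equal(pooled$model_position, 12L)
  expect_equal(pooled$n_cancers, 3)
  expect_equal(pooled$genes, "KRAS,NRAS")
  # a position hot in only 2 cancers is dropped at min_cancers = 3
  expect_equal(nrow(shared_type_hotspots(hot[-3, ], inst, 3)), 0)
})

test_that("co-occurrence classifies joint and disjoint SMD carriers", {
  inst <- data.frame(gene = c("G1", "G2"), domain_acc = c("PFa", "PFb"),
                     start = c(1L, 1L), end = c(50L, 50L))
  # identical carrier sets for both instances in lung
  mut <- rbind(
    data.frame(gene = "G1", sample_id = paste0("lung_s", 1:6),
               cancer_type = "lung", position = 10L),
    data.frame(gene = "G2", sample_id = paste0("lung_s", 1:6),
               cancer_type = "lung", position = 20L),
    data.frame(gene = "G1", sample_id = "colon_s1",
               cancer_type = "colon", position = 10L))
  ds <- make_toy_cohort(mut, inst, make_samples(c("lung", "colon"), 12))
  mapped <- map_mutations(ds)
  smd <- smd_scan(ds, mapped)
  smd$is_smd <- smd$cancer_type == "lung"
  co <- smd_cooccurrence(ds, mapped, smd)
  expect_equal(nrow(co), 1)
  expect_equal(co$direction, "enriched")
  expect_equal(c(co$both, co$only_1, co$only_2, co$neither), c(6, 0, 0, 6))
  expect_equal(co$p_value, brute_force_fisher(6, 0, 0, 6), tolerance = 1e-9)
  # fewer than 2 SMDs anywhere: empty table
  smd$is_smd <- FALSE
  expect_equal(nrow(smd_cooccurrence(ds, mapped, smd)), 0)
})

test_that("exclusivity flags a sample mutated at one pooled position in two instances", {
  inst <- data.frame(gene = c("KRAS", "NRAS"), domain_acc = "PF00071",
                     start = c(1L, 1L), end = c(30L, 30L))
  mut <- rbind(
    data.frame(gene = "KRAS", sample_id = "lung_s1",
               cancer_type = "lung", position = 12L),
    data.frame(gene = "NRAS", sample_id = "lung_s1",
               cancer_type = "lung", position = 12L),
    data.frame(gene = "KRAS", sample_id = "lung_s2",
               cancer_type = "lung", position = 12L))
  ds <- make_toy_cohort(mut, inst, make_samples(c("lung", "colon"), 4))
  mapped <- map_mutations(ds)
  pooled <- data.frame(domain_acc = "PF00071", model_position = 12L,
                       n_cancers = 3, cancers = "a,b,c", genes = "KRAS,NRAS")
  viol <- hotspot_exclusivity(ds, mapped, pooled)
  expect_equal(nrow(viol), 1)
  expect_equal(viol$sample_id, "lung_s1")
  expect_equal(viol$n_instances, 2)
  # without the double-carrier sample there is no violation
  ds2 <- make_toy_cohort(mut[-2, ], inst, make_samples(c("lung", "colon"), 4))
  expect_equal(nrow(hotspot_exclusivity(ds2, map_mutations(ds2), pooled)), 0)
})

test_that("interacting-pair report flags pairs with both members significant", {
  smd <- data.frame(instance_id = c("iA", "iB", "iC"),
                    gene = c("g", "g", "h"),
                    cancer_type = "colon",
                    is_smd = c(TRUE, TRUE, FALSE))
  pairs <- data.frame(instance_id_1 = c("iA", "iA"),
                      instance_id_2 = c("iB", "iC"))
  rep <- interacting_pair_report(smd, pairs)
  expect_equal(rep$both_smd, c(TRUE, FALSE))
  expect_warning(
    interacting_pair_report(smd, data.frame(instance_id_1 = "iA",
                                            instance_id_2 = "iZ")),
    "skipped")
  expect_equal(nrow(interacting_pair_report(
    smd, data.frame(instance_id_1 = character(),
                    instance_id_2 = character()))), 0)
})

test_that("heatmap matrix carries -log10 p-values", {
  smd <- data.frame(instance_id = c("i1", "i2", "i1"),
                    cancer_type = c("lung", "lung", "colon"),
                    p_value = c(1e-8, 0.5, 1e-320))
  m <- heatmap_matrix(smd)
  expect_equal(m["i1", "lung"], 8)
  expect_equal(m["i2", "colon"], 0)      # untested cell
  expect_equal(m["i1", "colon"], 300)    # clipped at 1e-300
})
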