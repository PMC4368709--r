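# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: probabilities come from factorial(), the BH
# oracle runs the raw step-up rule, and the Mann-Whitney oracle enumerates
# group assignments.

# Two-sided Fisher p by full enumeration of all 2x2 tables with the observed
# margins; each table's probability from the closed multinomial form.
brute_force_fisher <- function(a, b, c, d) {
  N <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  prob <- function(k) {
    (factorial(r1) / (factorial(k) * factorial(r1 - k))) *
      (factorial(r2) / (factorial(c1 - k) * factorial(r2 - c1 + k))) /
      (factorial(N) / (factorial(c1) * factorial(c2)))
  }
  ks <- max(0, c1 - r2):min(r1, c1)
  ps <- vapply(ks, prob, 0)
  p_obs <- ps[ks == a]
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# Direct Benjamini-Hochberg step-up: indices rejected at level alpha.
bh_stepup_rejections <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= alpha * seq_len(m) / m)
  if (!length(below)) return(integer())
  sort(o[seq_len(max(below))])
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments.
mwu_exact_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_stat <- function(xi) {
    r <- rank(pooled)
    sum(r[xi]) - nx * (nx + 1) / 2
  }
  obs <- u_stat(seq_len(nx))
  mu <- nx * length(y) / 2
  combos <- utils::combn(length(pooled), nx)
  us <- apply(combos, 2, u_stat)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# Small hand-buildable cohort: one protein per gene, explicit mutations.
make_toy_cohort <- function(mutations, instances, samples) {
  mutations$protein_id <- paste0("P_", mutations$gene)
  mutations$ref_aa <- "A"
  mutations$alt_aa <- "T"
  if (is.null(mutations$impact)) mutations$impact <- "high"
  instances$protein_id <- paste0("P_", instances$gene)
  instances$instance_id <- paste(instances$gene, instances$protein_id,
                                 instances$domain_acc, instances$start,
                                 sep = "|")
  instances$length_aa <- instances$end - instances$start + 1L
  if (is.null(instances$domain_name)) instances$domain_name <- instances$domain_acc
  if (is.null(instances$e_value)) instances$e_value <- 1e-10
  if (is.null(instances$model_map)) instances$model_map <- ""
  cohort_dataset(mutations, instances, samples)
}

# Sample registry with n samples per cancer, ids <cancer>_s<i>.
make_samples <- function(cancers, n) {
  do.call(rbind, lapply(cancers, function(ct)
    data.frame(cancer_type = ct, sample_id = paste0(ct, "_s", seq_len(n)),
               stringsAsFactors = FALSE)))
}

# Default-scale generated cohort, mapped and filtered, for reuse.
generate_and_map <- function(config) {
  gen <- generate_cohort(config)
  damaging <- filter_damaging(gen$dataset$mutations)
  ds <- cohort_dataset(damaging, gen$dataset$instances, gen$dataset$samples)
  list(gen = gen, dataset = ds, mapped = map_mutations(ds))
}
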