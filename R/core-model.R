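# Core domain types, readers/writers and shared filters.
#
# All protein coordinates are 1-based and ranges are inclusive, matching the
# p.X123Y protein-change notation used in COSMIC-style tables.

#' Standard single-letter amino-acid alphabet
#'
#' The twenty standard residues, used to validate protein-change strings and
#' by the synthetic cohort generator.
#'
#' @format A character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

IMPACT_LEVELS <- c("high", "medium", "low", "unknown", "none")

DAMAGING_DEFAULT <- c("high", "medium", "low")

.config_error <- function(msg) {
  stop(structure(class = c("domainscape_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.data_error <- function(msg) {
  stop(structure(class = c("domainscape_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Analysis thresholds
#'
#' Bundle of the significance and filtering thresholds used throughout the
#' scans. Defaults follow the study design this package implements: SMD calls
#' at a per-test alpha of 1e-7 with FDR < 0.05, per-residue hotspot calls at
#' alpha 0.01 with FDR < 0.05, and a domain-match E-value ceiling of 0.001.
#'
#' @param smd_alpha Per-test p-value threshold for SMD calls.
#' @param smd_fdr Benjamini-Hochberg FDR ceiling for SMD calls.
#' @param hotspot_alpha Per-residue p-value threshold for hotspot calls.
#' @param hotspot_fdr BH FDR ceiling for hotspot calls.
#' @param evalue_cutoff Domain instances with E-value >= this are dropped.
#' @param damaging_categories Impact categories retained as damaging.
#' @return An object of class `thresholds` (a validated list).
#' @export
thresholds <- function(smd_alpha = 1e-7,
                       smd_fdr = 0.05,
                       hotspot_alpha = 0.01,
                       hotspot_fdr = 0.05,
                       evalue_cutoff = 0.001,
                       damaging_categories = DAMAGING_DEFAULT) {
  probs <- c(smd_alpha = smd_alpha, smd_fdr = smd_fdr,
             hotspot_alpha = hotspot_alpha, hotspot_fdr = hotspot_fdr)
  if (any(!is.finite(probs)) || any(probs <= 0) || any(probs > 1))
    .config_error("all significance thresholds must lie in (0, 1]")
  if (!is.finite(evalue_cutoff) && !identical(evalue_cutoff, Inf))
    .config_error("evalue_cutoff must be a positive number (Inf allowed)")
  if (evalue_cutoff <= 0)
    .config_error("evalue_cutoff must be > 0")
  damaging_categories <- tolower(damaging_categories)
  bad <- setdiff(damaging_categories, IMPACT_LEVELS)
  if (length(bad))
    .config_error(sprintf("unknown impact categories: %s",
                          paste(bad, collapse = ", ")))
  structure(list(smd_alpha = smd_alpha, smd_fdr = smd_fdr,
                 hotspot_alpha = hotspot_alpha, hotspot_fdr = hotspot_fdr,
                 evalue_cutoff = evalue_cutoff,
                 damaging_categories = damaging_categories),
            class = "thresholds")
}

#' Column-name dialect for mutation tables
#'
#' COSMIC exports (and tables derived from them) name columns differently
#' across releases; a dialect maps the canonical field names used by this
#' package to the column names present in a given file.
#'
#' @param gene,protein_id,sample_id,cancer_type,protein_change,impact Column
#'   names in the input file for each canonical field.
#' @return A named character vector.
#' @export
mutation_dialect <- function(gene = "gene",
                             protein_id = "protein_id",
                             sample_id = "sample_id",
                             cancer_type = "cancer_type",
                             protein_change = "protein_change",
                             impact = "impact") {
  c(gene = gene, protein_id = protein_id, sample_id = sample_id,
    cancer_type = cancer_type, protein_change = protein_change,
    impact = impact)
}

# Non-throwing parser shared by parse_protein_change() and read_mutations().
.parse_pc <- function(text) {
  text <- as.character(text)
  n <- length(text)
  out <- data.frame(ref_aa = NA_character_, position = NA_integer_,
                    alt_aa = NA_character_, ok = FALSE,
                    reason = NA_character_, stringsAsFactors = FALSE)[rep(1, max(n, 1)), ]
  if (n == 0) return(out[0, ])
  rownames(out) <- NULL
  m <- regexec("^p\\.([A-Za-z])([0-9]+)([A-Za-z])$", text)
  parts <- regmatches(text, m)
  for (i in seq_len(n)) {
    p <- parts[[i]]
    if (length(p) != 4) {
      out$reason[i] <- sprintf("malformed protein change '%s'", text[i])
      next
    }
    ref <- toupper(p[2]); alt <- toupper(p[4])
    pos <- suppressWarnings(as.integer(p[3]))
    if (!(ref %in% AA_ALPHABET) || !(alt %in% AA_ALPHABET)) {
      out$reason[i] <- sprintf("invalid amino acid in '%s'", text[i])
    } else if (is.na(pos) || pos < 1) {
      out$reason[i] <- sprintf("invalid position in '%s'", text[i])
    } else if (ref == alt) {
      out$reason[i] <- sprintf("synonymous change '%s'", text[i])
    } else {
      out$ref_aa[i] <- ref; out$position[i] <- pos; out$alt_aa[i] <- alt
      out$ok[i] <- TRUE
    }
  }
  out
}

#' Parse a protein-change string
#'
#' Parses strings in the `p.<ref><position><alt>` notation (e.g. `"p.G12D"`)
#' into their components. Only missense changes with valid single-letter
#' amino acids and a positive residue position are accepted.
#'
#' @param text Character vector of protein-change strings.
#' @return A data frame with columns `ref_aa`, `position` (integer, 1-based)
#'   and `alt_aa`, one row per input element.
#' @examples
#' parse_protein_change("p.A289T")
#' @export
parse_protein_change <- function(text) {
  p <- .parse_pc(text)
  if (any(!p$ok)) .data_error(p$reason[which(!p$ok)[1]])
  p[, c("ref_aa", "position", "alt_aa")]
}

.read_tsv <- function(path) {
  if (!file.exists(path))
    .config_error(sprintf("input file not found: %s", path))
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}

# Generic TSV writer used by all output stages: header, tab-separated, no
# quoting; numeric columns keep full double precision (>= 6 significant
# digits guaranteed).
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    .config_error(sprintf("file '%s' is missing required column(s): %s",
                          path, paste(missing, collapse = ", ")))
}

#' Read a somatic missense mutation table
#'
#' Reads a COSMIC-like tab-separated mutation table. Rows whose protein
#' change is not a parsable missense substitution, or whose impact category
#' is not recognised, are skipped (never fatal) and tallied in the attached
#' skip report. Impact strings are case-insensitive and canonicalised to
#' lower case.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect A [mutation_dialect()] mapping canonical field names to the
#'   file's column names.
#' @return A data frame of mutation records with columns `gene`,
#'   `protein_id`, `sample_id`, `cancer_type`, `position`, `ref_aa`,
#'   `alt_aa`, `impact`, carrying a `skip_report` attribute: a list with
#'   `n_input`, `n_kept`, `n_skipped` and a `reasons` data frame.
#' @export
read_mutations <- function(path, dialect = mutation_dialect()) {
  raw <- .read_tsv(path)
  .require_columns(raw, unname(dialect), path)
  n_input <- nrow(raw)
  empty <- data.frame(gene = character(), protein_id = character(),
                      sample_id = character(), cancer_type = character(),
                      position = integer(), ref_aa = character(),
                      alt_aa = character(), impact = character(),
                      stringsAsFactors = FALSE)
  if (n_input == 0) {
    attr(empty, "skip_report") <- list(n_input = 0L, n_kept = 0L,
                                       n_skipped = 0L,
                                       reasons = data.frame(reason = character(),
                                                            n = integer()))
    return(empty)
  }
  pc <- .parse_pc(raw[[dialect[["protein_change"]]]])
  impact <- tolower(trimws(raw[[dialect[["impact"]]]]))
  bad_impact <- !(impact %in% IMPACT_LEVELS)
  cancer <- trimws(as.character(raw[[dialect[["cancer_type"]]]]))
  bad_cancer <- is.na(cancer) | cancer == ""
  reason <- pc$reason
  reason[pc$ok & bad_impact] <- "unrecognised impact category"
  reason[pc$ok & !bad_impact & bad_cancer] <- "empty cancer type"
  keep <- pc$ok & !bad_impact & !bad_cancer
  out <- data.frame(gene = as.character(raw[[dialect[["gene"]]]])[keep],
                    protein_id = as.character(raw[[dialect[["protein_id"]]]])[keep],
                    sample_id = as.character(raw[[dialect[["sample_id"]]]])[keep],
                    cancer_type = cancer[keep],
                    position = pc$position[keep],
                    ref_aa = pc$ref_aa[keep],
                    alt_aa = pc$alt_aa[keep],
                    impact = impact[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  skipped <- reason[!keep]
  reasons <- if (length(skipped)) {
    tab <- table(skipped)
    data.frame(reason = names(tab), n = as.integer(tab),
               stringsAsFactors = FALSE)
  } else data.frame(reason = character(), n = integer())
  attr(out, "skip_report") <- list(n_input = n_input, n_kept = nrow(out),
                                   n_skipped = n_input - nrow(out),
                                   reasons = reasons)
  out
}

#' Write a mutation table
#'
#' Inverse of [read_mutations()]: emits the canonical tab-separated dialect
#' with a `protein_change` column in `p.<ref><pos><alt>` notation. Rows are
#' sorted deterministically.
#'
#' @param mutations Mutation data frame as returned by [read_mutations()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mutations <- function(mutations, path) {
  df <- data.frame(gene = mutations$gene,
                   protein_id = mutations$protein_id,
                   sample_id = mutations$sample_id,
                   cancer_type = mutations$cancer_type,
                   protein_change = sprintf("p.%s%d%s", mutations$ref_aa,
                                            mutations$position,
                                            mutations$alt_aa),
                   impact = mutations$impact,
                   stringsAsFactors = FALSE)
  df <- df[order(df$cancer_type, df$gene, df$sample_id, df$protein_id,
                 mutations$position, df$protein_change), , drop = FALSE]
  .write_tsv(df, path)
}

#' Read a domain-instance coordinate table
#'
#' Reads precomputed domain-scan output (gene, protein, domain accession and
#' name, alignment start/end in 1-based inclusive protein coordinates,
#' E-value, optional protein-to-model position map) and applies the E-value
#' filter. Instance identifiers are assigned deterministically as
#' `gene|protein_id|domain_acc|start`.
#'
#' @param path Path to the tab-separated table.
#' @param evalue_cutoff Instances are retained only when
#'   `e_value < evalue_cutoff` (default 0.001; pass `Inf` to keep all).
#' @return Data frame with columns `instance_id`, `gene`, `protein_id`,
#'   `domain_acc`, `domain_name`, `start`, `end`, `length_aa`, `e_value`,
#'   `model_map` (character; `""` when absent).
#' @export
read_domain_instances <- function(path, evalue_cutoff = 0.001) {
  raw <- .read_tsv(path)
  .require_columns(raw, c("gene", "protein_id", "domain_acc", "domain_name",
                          "start", "end", "e_value"), path)
  start <- as.integer(raw$start); end <- as.integer(raw$end)
  bad <- which(is.na(start) | is.na(end) | start < 1 | start > end)
  if (length(bad))
    .data_error(sprintf("invalid domain coordinates at data row %d (start=%s, end=%s)",
                        bad[1], raw$start[bad[1]], raw$end[bad[1]]))
  ev <- as.numeric(raw$e_value)
  if (any(is.na(ev) | ev < 0))
    .data_error("e_value column must be nonnegative numbers")
  mm <- if ("model_map" %in% names(raw)) as.character(raw$model_map) else
    rep("", nrow(raw))
  mm[is.na(mm)] <- ""
  out <- data.frame(instance_id = paste(raw$gene, raw$protein_id,
                                        raw$domain_acc, start, sep = "|"),
                    gene = as.character(raw$gene),
                    protein_id = as.character(raw$protein_id),
                    domain_acc = as.character(raw$domain_acc),
                    domain_name = as.character(raw$domain_name),
                    start = start, end = end,
                    length_aa = end - start + 1L,
                    e_value = ev,
                    model_map = mm,
                    stringsAsFactors = FALSE)
  out <- out[out$e_value < evalue_cutoff, , drop = FALSE]
  rownames(out) <- NULL
  dup <- duplicated(out$instance_id)
  if (any(dup))
    .data_error(sprintf("duplicate domain instance id: %s",
                        out$instance_id[which(dup)[1]]))
  # validate model maps eagerly so malformed rows fail at load time
  for (i in which(out$model_map != ""))
    parse_model_map(out$model_map[i], out$start[i], out$end[i])
  out
}

#' Write a domain-instance table
#'
#' @param instances Data frame as returned by [read_domain_instances()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_domain_instances <- function(instances, path) {
  df <- instances[order(instances$gene, instances$protein_id,
                        instances$domain_acc, instances$start),
                  c("gene", "protein_id", "domain_acc", "domain_name",
                    "start", "end", "e_value", "model_map"), drop = FALSE]
  .write_tsv(df, path)
}

#' Parse a protein-to-model position map
#'
#' Model maps are serialised as `"p1:m1,p2:m2,..."`, pairing protein
#' positions with positions in the domain's profile model. The map must be
#' strictly increasing in both coordinates and confined to `[start, end]`.
#'
#' @param text The serialised map (a single string).
#' @param start,end Instance bounds used for validation.
#' @return A data frame with integer columns `protein_position` and
#'   `model_position`; zero rows when `text` is empty.
#' @export
parse_model_map <- function(text, start, end) {
  if (is.na(text) || !nzchar(text))
    return(data.frame(protein_position = integer(), model_position = integer()))
  pairs <- strsplit(strsplit(text, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  if (any(lengths(pairs) != 2))
    .data_error(sprintf("malformed model map '%s'", text))
  pp <- as.integer(vapply(pairs, `[`, "", 1))
  mp <- as.integer(vapply(pairs, `[`, "", 2))
  if (any(is.na(pp)) || any(is.na(mp)))
    .data_error(sprintf("non-integer entries in model map '%s'", text))
  if (any(diff(pp) <= 0) || any(diff(mp) <= 0))
    .data_error("model map must be strictly increasing in both coordinates")
  if (any(pp < start) || any(pp > end))
    .data_error("model map protein positions fall outside the instance")
  data.frame(protein_position = pp, model_position = mp)
}

#' Keep predicted-damaging mutations
#'
#' Retains exactly the records whose impact category belongs to `allowed`
#' (by default high/medium/low, i.e. excluding mutations predicted to have
#' no or unknown functional effect). Input order is preserved; the filter is
#' idempotent.
#'
#' @param mutations Mutation data frame.
#' @param allowed Character vector of retained impact categories.
#' @return The filtered data frame.
#' @export
filter_damaging <- function(mutations, allowed = DAMAGING_DEFAULT) {
  allowed <- tolower(allowed)
  out <- mutations[mutations$impact %in% allowed, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skip_report") <- NULL
  out
}

#' Read a gene-set file
#'
#' One gene symbol per line; blank lines are ignored.
#'
#' @param path Path to the file.
#' @return Character vector of unique gene symbols, in file order.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path))
    .config_error(sprintf("input file not found: %s", path))
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Read functional-site annotations
#'
#' Tab-separated table with columns `gene`, `position` and `site_category`
#' (one of `functional`, `interface`, `other`).
#'
#' @param path Path to the file.
#' @return Data frame with those three columns.
#' @export
read_site_annotations <- function(path) {
  raw <- .read_tsv(path)
  .require_columns(raw, c("gene", "position", "site_category"), path)
  cat_ok <- raw$site_category %in% c("functional", "interface", "other")
  if (any(!cat_ok))
    .data_error(sprintf("unknown site category '%s'",
                        raw$site_category[which(!cat_ok)[1]]))
  pos <- as.integer(raw$position)
  if (any(is.na(pos) | pos < 1))
    .data_error("site positions must be positive integers")
  data.frame(gene = as.character(raw$gene), position = pos,
             site_category = as.character(raw$site_category),
             stringsAsFactors = FALSE)
}

#' Read oncogene / tumor-suppressor labels
#'
#' Tab-separated table with columns `gene` and `label` (`oncogene` or
#' `tumor_suppressor`). A gene listed twice with conflicting labels is an
#' error; exact duplicates are collapsed.
#'
#' @param path Path to the file.
#' @return Data frame with columns `gene` and `label`.
#' @export
read_gene_labels <- function(path) {
  raw <- .read_tsv(path)
  .require_columns(raw, c("gene", "label"), path)
  lab_ok <- raw$label %in% c("oncogene", "tumor_suppressor")
  if (any(!lab_ok))
    .data_error(sprintf("unknown gene label '%s'", raw$label[which(!lab_ok)[1]]))
  df <- unique(data.frame(gene = as.character(raw$gene),
                          label = as.character(raw$label),
                          stringsAsFactors = FALSE))
  dup <- duplicated(df$gene)
  if (any(dup))
    .data_error(sprintf("gene '%s' carries conflicting labels",
                        df$gene[which(dup)[1]]))
  rownames(df) <- NULL
  df
}

#' Write a results table
#'
#' Generic writer for the pipeline's tab-separated outputs: header row,
#' stable column order, no quoting, full floating-point precision.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_results <- function(df, path) .write_tsv(df, path)

#' Assemble a cohort dataset
#'
#' Binds a mutation table, a domain-instance table and the sample registry
#' (which samples were sequenced per cancer type — the denominator of all
#' per-sample statistics) into one validated object.
#'
#' @param mutations Mutation data frame ([read_mutations()]).
#' @param instances Domain-instance data frame ([read_domain_instances()]).
#' @param samples Data frame with columns `cancer_type` and `sample_id`
#'   listing every sequenced sample.
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(mutations, instances, samples) {
  .require_columns(samples, c("cancer_type", "sample_id"), "samples")
  samples <- unique(samples[, c("cancer_type", "sample_id")])
  key <- function(ct, s) paste(ct, s, sep = "\r")
  reg <- key(samples$cancer_type, samples$sample_id)
  if (nrow(mutations)) {
    mk <- key(mutations$cancer_type, mutations$sample_id)
    bad <- !(mk %in% reg)
    if (any(bad))
      .data_error(sprintf(
        "mutation sample '%s' (%s) is absent from the sample registry",
        mutations$sample_id[which(bad)[1]], mutations$cancer_type[which(bad)[1]]))
  }
  structure(list(mutations = mutations, instances = instances,
                 samples = samples), class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("cohort_dataset:",
      nrow(x$mutations), "mutations,",
      nrow(x$instances), "domain instances,",
      nrow(x$samples), "samples in",
      length(unique(x$samples$cancer_type)), "cancer types\n")
  invisible(x)
}

# number of samples per cancer type, as a named integer vector
.samples_per_cancer <- function(dataset) {
  tab <- table(dataset$samples$cancer_type)
  stats::setNames(as.integer(tab), names(tab))
}
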