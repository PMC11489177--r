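#' Write a data.frame as TSV
#'
#' Deterministic tab-separated output (no quoting, no row names, full
#' precision) used for every pipeline table.
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, NA)
  df[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), NA_character_, vapply(v, format, "", digits = 15)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

.as_matrix_input <- function(x, sep = "\t") {
  if (is.character(x) && length(x) == 1) read_expression_matrix(x, sep = sep) else expression_matrix(unclass(as.matrix(x)))
}

.as_clinical_input <- function(x, sep = "\t") {
  if (is.character(x) && length(x) == 1) read_survival_table(x, sep = sep) else survival_table(x)
}

#' Run the full single-cohort recurrence analysis
#'
#' Normalize and impute both tissue matrices, screen recurrence-related
#' proteins per tissue, form the four direction sets, compute per-sample
#' enrichment and DFS scores, call tumor and NAT subtypes at their best
#' cut-points, integrate the four-group label, and test clinical covariates
#' across the NAT subtypes. All tables plus a reproducibility manifest are
#' written to `outdir`.
#'
#' @param config named list: `tumor`, `nat` (matrices or TSV paths),
#'   `clinical` (data.frame or path), `outdir`; optional `cohort_id`,
#'   `endpoint` ("dfs"), `alpha` (0.05), `minprop` (0.1), `ssgsea_exponent`
#'   (0.25), `impute_first` (FALSE = quantile-normalize then impute, the
#'   default order), `min_overlap` (20), `seed` (1).
#' @return invisibly, a list with every intermediate result and `outdir`.
#' @export
run_cohort_analysis <- function(config) {
  need <- c("tumor", "nat", "clinical", "outdir")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config is missing: ", paste(miss, collapse = ", "))
  cfg <- utils::modifyList(list(cohort_id = "cohort1", endpoint = "dfs",
                                alpha = 0.05, minprop = 0.1,
                                ssgsea_exponent = 0.25, impute_first = FALSE,
                                min_overlap = 20L, seed = 1L),
                           config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  clinical <- .as_clinical_input(cfg$clinical)
  prep <- function(x) {
    m <- .as_matrix_input(x)
    if (cfg$impute_first) quantile_normalize(impute_min(m))
    else impute_min(quantile_normalize(m))
  }
  tumor <- prep(cfg$tumor)
  nat <- prep(cfg$nat)

  rrp_t <- screen_rrps(tumor, clinical, endpoint = cfg$endpoint,
                       alpha = cfg$alpha, minprop = cfg$minprop,
                       tissue = "tumor", cohort_id = cfg$cohort_id,
                       min_overlap = cfg$min_overlap)
  rrp_n <- screen_rrps(nat, clinical, endpoint = cfg$endpoint,
                       alpha = cfg$alpha, minprop = cfg$minprop,
                       tissue = "nat", cohort_id = cfg$cohort_id,
                       min_overlap = cfg$min_overlap)
  sets <- build_direction_sets(rrp_t, rrp_n)

  scores_t <- score_samples(tumor, sets, "tumor_unfavorable", "tumor_favorable",
                            alpha = cfg$ssgsea_exponent)
  scores_n <- score_samples(nat, sets, "nat_unfavorable", "nat_favorable",
                            alpha = cfg$ssgsea_exponent)
  sub_t <- call_subtypes(scores_t, clinical, tissue = "tumor",
                         endpoint = cfg$endpoint, minprop = cfg$minprop)
  sub_n <- call_subtypes(scores_n, clinical, tissue = "nat",
                         endpoint = cfg$endpoint, minprop = cfg$minprop)
  subtypes <- integrate_subtypes(sub_t, sub_n)

  nat_labels <- data.frame(sample_id = sub_n$sample_id, label = sub_n$subtype,
                           stringsAsFactors = FALSE)
  feature_tests <- group_feature_tests(nat_labels, clinical)

  write_tsv(as.data.frame(rrp_t), file.path(cfg$outdir, "rrp_tumor.tsv"))
  write_tsv(as.data.frame(rrp_n), file.path(cfg$outdir, "rrp_nat.tsv"))
  write_gmt(sets, file.path(cfg$outdir, "direction_sets.gmt"))
  write_tsv(scores_t, file.path(cfg$outdir, "scores_tumor.tsv"))
  write_tsv(scores_n, file.path(cfg$outdir, "scores_nat.tsv"))
  write_tsv(subtypes, file.path(cfg$outdir, "subtypes.tsv"))
  write_tsv(feature_tests, file.path(cfg$outdir, "nat_subtype_feature_tests.tsv"))

  manifest <- list(
    tool = "natrecur",
    version = as.character(utils::packageVersion("natrecur")),
    cohort_id = cfg$cohort_id,
    parameters = cfg[c("endpoint", "alpha", "minprop", "ssgsea_exponent",
                       "impute_first", "min_overlap", "seed")],
    ties_policy = list(quantile_normalization = "average",
                       cox = "efron",
                       cutpoint = "balanced-then-smaller"),
    inputs = list(
      n_proteins = nrow(tumor), n_samples = ncol(tumor),
      tumor_md5 = .input_hash(cfg$tumor), nat_md5 = .input_hash(cfg$nat),
      clinical_md5 = .input_hash(cfg$clinical)),
    outputs = list.files(cfg$outdir, pattern = "\\.(tsv|gmt)$"),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(tumor = tumor, nat = nat, clinical = clinical,
                 rrp_tumor = rrp_t, rrp_nat = rrp_n, sets = sets,
                 scores_tumor = scores_t, scores_nat = scores_n,
                 subtype_tumor = sub_t, subtype_nat = sub_n,
                 subtypes = subtypes, feature_tests = feature_tests,
                 outdir = cfg$outdir))
}

.input_hash <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    unname(tools::md5sum(x))
  else unname(tools::md5sum(textConnection_digest(x)))
}

# Hash an in-memory object through its serialized text representation.
textConnection_digest <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  if (is.data.frame(x)) utils::write.csv(x, tf, row.names = FALSE)
  else utils::write.csv(as.data.frame(unclass(as.matrix(x))), tf)
  tf
}

#' Run the multi-cohort consensus analysis
#'
#' Runs [run_cohort_analysis()] on each cohort config, intersects the four
#' direction sets across cohorts, and applies the cross-cohort drug-target
#' filter (unfavorable-significant somewhere, favorable-significant
#' nowhere).
#'
#' @param configs list (>= 2) of single-cohort configs; each needs its own
#'   `outdir`.
#' @param outdir directory for the consensus outputs.
#' @return invisibly: `per_cohort` results, `consensus_sets`, `targets`.
#' @export
run_multicohort <- function(configs, outdir) {
  if (length(configs) < 2) stop("need >= 2 cohort configs")
  runs <- lapply(configs, run_cohort_analysis)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  consensus <- intersect_cohorts(lapply(runs, `[[`, "sets"))
  keep <- consensus[vapply(consensus, length, 0L) > 0]
  if (length(keep)) write_gmt(keep, file.path(outdir, "consensus_sets.gmt"))
  targets <- target_filter(unlist(lapply(runs, function(r)
    list(r$rrp_tumor, r$rrp_nat)), recursive = FALSE))
  write_tsv(data.frame(protein_id = targets, stringsAsFactors = FALSE),
            file.path(outdir, "target_proteins.tsv"))
  invisible(list(per_cohort = runs, consensus_sets = consensus,
                 targets = targets, outdir = outdir))
}
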