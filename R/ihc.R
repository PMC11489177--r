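#' Bin the percentage of positive cells
#'
#' Extent bins: 0% = 0, \[1, 25)% = 1, \[25, 50)% = 2, \[50, 75)% = 3,
#' \[75, 100\]% = 4. Two boundary cases the printed bins leave open are
#' closed deterministically: 100% maps to bin 4 and any positivity in
#' (0, 1)% maps to bin 1.
#'
#' @param extent_percent percent positive cells in \[0, 100\].
#' @return integer bin(s) 0-4.
#' @export
extent_bin <- function(extent_percent) {
  if (anyNA(extent_percent) || any(extent_percent < 0 | extent_percent > 100))
    stop("extent_percent must lie in [0, 100]")
  b <- integer(length(extent_percent))
  b[extent_percent > 0]  <- 1L
  b[extent_percent >= 25] <- 2L
  b[extent_percent >= 50] <- 3L
  b[extent_percent >= 75] <- 4L
  b
}

#' Composite immunohistochemistry score
#'
#' Staining intensity grade (0 = none, 1 = weak, 2 = moderate, 3 = strong)
#' multiplied by the extent bin (0-4); range 0 to 12. Only the products of
#' those grades are achievable: \{0, 1, 2, 3, 4, 6, 8, 9, 12\}.
#'
#' @param intensity integer 0-3.
#' @param extent integer extent bin 0-4.
#' @return integer score(s).
#' @export
composite_score <- function(intensity, extent) {
  if (anyNA(intensity) || !all(intensity %in% 0:3))
    stop("intensity must be an integer in 0..3")
  if (anyNA(extent) || !all(extent %in% 0:4))
    stop("extent bin must be an integer in 0..4")
  as.integer(intensity) * as.integer(extent)
}

#' Achievable composite IHC scores
#'
#' @return sorted integer vector of all products of intensity (0-3) and
#'   extent bin (0-4).
#' @export
achievable_ihc_scores <- function() {
  grid <- expand.grid(intensity = 0:3, extent = 0:4)
  sort(unique(composite_score(grid$intensity, grid$extent)))
}

#' Validate an IHC record table
#'
#' @param df data.frame with patient_id, tissue ("tumor"/"nat"), intensity,
#'   and either extent_percent or extent_bin; a `score` column is derived
#'   (and checked against the achievable set if supplied).
#' @return validated data.frame with `extent_bin` and `score` columns.
#' @export
ihc_records <- function(df) {
  need <- c("patient_id", "tissue", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing IHC columns: ", paste(miss, collapse = ", "))
  if (!all(df$tissue %in% c("tumor", "nat"))) stop("tissue must be 'tumor' or 'nat'")
  if (is.null(df$extent_bin)) {
    if (is.null(df$extent_percent)) stop("need extent_percent or extent_bin")
    df$extent_bin <- extent_bin(df$extent_percent)
  }
  sc <- composite_score(df$intensity, df$extent_bin)
  if (!is.null(df$score)) {
    if (!all(df$score %in% achievable_ihc_scores()))
      stop("score outside the achievable set {",
           paste(achievable_ihc_scores(), collapse = ","), "}")
    if (any(df$score != sc)) stop("supplied scores disagree with intensity x extent")
  }
  df$score <- sc
  df
}

#' Dual-tissue recurrence stratification from IHC scores
#'
#' Dichotomizes the tumor and NAT composite scores at their maximally
#' selected cut-points against the recurrence endpoint (or at a fixed
#' threshold), reports the per-tissue high-vs-low hazard ratio, and — for
#' patients with both tissues scored — the four-group tumor/NAT label.
#'
#' @param records IHC table (see [ihc_records()]); one row per patient and
#'   tissue.
#' @param clinical survival table keyed by `patient_id` = `sample_id`.
#' @param minprop minimum group proportion for the cut-point scan.
#' @param fixed_threshold optional named numeric (tumor, nat) to bypass the
#'   cut-point search.
#' @return list with per-tissue elements (`cutpoint`, `cox`, `logrank`,
#'   `labels`) and `four_group` (data.frame patient_id, tumor, nat, group)
#'   for paired patients; tissues absent from `records` are skipped.
#' @export
ihc_stratify <- function(records, clinical, minprop = 0.1, fixed_threshold = NULL) {
  records <- ihc_records(records)
  clinical <- survival_table(clinical)
  out <- list()
  labs <- list()
  for (tis in intersect(c("tumor", "nat"), unique(records$tissue))) {
    r <- records[records$tissue == tis, ]
    cl <- clinical[match(r$patient_id, clinical$sample_id), ]
    ok <- !is.na(cl$sample_id)
    r <- r[ok, ]; cl <- cl[ok, ]
    if (length(unique(r$score)) < 2) stop("all ", tis, " scores tied; cannot stratify")
    if (!is.null(fixed_threshold)) {
      thr <- unname(fixed_threshold[[tis]])
      cp <- list(threshold = thr, statistic = NA_real_, logrank_p = NA_real_,
                 n_low = sum(r$score <= thr), n_high = sum(r$score > thr))
    } else {
      cp <- best_cutpoint(r$score, cl$dfs_time, cl$dfs_event, minprop = minprop)
    }
    high <- r$score > cp$threshold
    lr <- logrank_test(cl$dfs_time, cl$dfs_event, ifelse(high, "high", "low"))
    fit <- tryCatch(cox_fit(matrix(as.numeric(high), dimnames = list(NULL, "high")),
                            cl$dfs_time, cl$dfs_event),
                    error = function(e) NULL)
    pre <- if (tis == "tumor") "T" else "NAT"
    labs[[tis]] <- data.frame(patient_id = r$patient_id,
                              lab = paste0(pre, ifelse(high, 2, 1)),
                              stringsAsFactors = FALSE)
    out[[tis]] <- list(cutpoint = cp,
                       cox = fit,
                       hr = if (is.null(fit)) NA_real_ else fit$coefficients$hr[1],
                       p = lr$p,
                       logrank = lr[c("chi_square", "p")],
                       km = list(low = km_estimate(cl$dfs_time[!high], cl$dfs_event[!high]),
                                 high = km_estimate(cl$dfs_time[high], cl$dfs_event[high])))
  }
  if (all(c("tumor", "nat") %in% names(labs))) {
    paired <- merge(labs$tumor, labs$nat, by = "patient_id",
                    suffixes = c("_tumor", "_nat"))
    out$four_group <- data.frame(patient_id = paired$patient_id,
                                 tumor = paired$lab_tumor, nat = paired$lab_nat,
                                 group = paste(paired$lab_tumor, paired$lab_nat, sep = "-"),
                                 stringsAsFactors = FALSE)
  } else {
    message("only one tissue present; four-group integration skipped")
  }
  out
}

#' Consensus of two independent IHC readers
#'
#' Per core, the consensus score is the mean of the two readers' composite
#' scores rounded half-up. Also reports the exact-agreement fraction and a
#' linearly weighted kappa over the achievable score scale.
#'
#' @param reader1,reader2 IHC tables (see [ihc_records()]) covering the same
#'   patient/tissue cores.
#' @return list: `records` (consensus table), `agreement` (exact fraction),
#'   `kappa` (linear weights).
#' @export
consensus_score <- function(reader1, reader2) {
  r1 <- ihc_records(reader1); r2 <- ihc_records(reader2)
  k1 <- paste(r1$patient_id, r1$tissue); k2 <- paste(r2$patient_id, r2$tissue)
  unmatched <- c(setdiff(k1, k2), setdiff(k2, k1))
  if (length(unmatched))
    stop("unmatched cores between readers: ", paste(unmatched, collapse = "; "))
  r2 <- r2[match(k1, k2), ]
  cons <- floor((r1$score + r2$score) / 2 + 0.5)   # mean, round half-up
  records <- data.frame(patient_id = r1$patient_id, tissue = r1$tissue,
                        score = as.integer(cons), stringsAsFactors = FALSE)
  agreement <- mean(r1$score == r2$score)
  list(records = records, agreement = agreement,
       kappa = .weighted_kappa(r1$score, r2$score, levels = 0:12))
}

# Linearly weighted Cohen's kappa on an ordinal scale.
.weighted_kappa <- function(a, b, levels) {
  k <- length(levels)
  tab <- table(factor(a, levels), factor(b, levels))
  p <- tab / sum(tab)
  w <- 1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  pe <- outer(rowSums(p), colSums(p))
  po_w <- sum(w * p); pe_w <- sum(w * pe)
  if (pe_w == 1) return(1)
  (po_w - pe_w) / (1 - pe_w)
}
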