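#' Classify the prognostic direction of a hazard ratio
#'
#' A hazard ratio above 1 marks the high-marker group as having a higher
#' recurrence hazard, hence "unfavorable"; any other positive value
#' (including exactly 1) is "favorable".
#'
#' @param hr positive hazard ratio(s).
#' @return character vector of "unfavorable"/"favorable".
#' @export
classify_direction <- function(hr) {
  if (anyNA(hr) || any(hr <= 0)) stop("hazard ratios must be positive")
  ifelse(hr > 1, "unfavorable", "favorable")
}

#' Screen recurrence-related proteins (RRPs)
#'
#' For each protein, finds the maximally selected log-rank cut-point of its
#' abundance against the chosen endpoint, dichotomizes samples at that
#' threshold, and estimates the high-vs-low hazard ratio with a two-group Cox
#' model. Proteins with log-rank p below `alpha` are flagged significant and
#' labelled unfavorable (HR > 1) or favorable. No multiplicity correction is
#' applied for set construction; a Benjamini-Hochberg column is reported for
#' reference only.
#'
#' @param m expression matrix (imputed; proteins x samples).
#' @param clinical survival table (see [survival_table()]).
#' @param endpoint "dfs" or "os".
#' @param alpha significance level for the RRP call. Default 0.05.
#' @param minprop minimum group proportion for the cut-point scan.
#' @param tissue label recorded on every record ("tumor" or "nat").
#' @param cohort_id label recorded on every record.
#' @param min_overlap minimum number of samples shared by matrix and clinical
#'   table. Default 20.
#' @return data.frame of class `rrp_table`, one row per screened protein,
#'   sorted by p: protein_id, tissue, cohort_id, cutpoint, hr, ci_low,
#'   ci_high, p, p_bh, direction, significant, frac_imputed_flag.
#' @export
screen_rrps <- function(m, clinical, endpoint = c("dfs", "os"), alpha = 0.05,
                        minprop = 0.1, tissue = "tumor", cohort_id = "cohort1",
                        min_overlap = 20L) {
  endpoint <- match.arg(endpoint)
  clinical <- survival_table(clinical)
  common <- intersect(colnames(m), clinical$sample_id)
  if (!length(common)) stop("no overlapping samples between matrix and clinical table")
  if (length(common) < min_overlap)
    stop("only ", length(common), " overlapping samples (< min_overlap = ", min_overlap, ")")
  cl <- clinical[match(common, clinical$sample_id), ]
  tm <- if (endpoint == "dfs") cl$dfs_time else cl$os_time
  ev <- if (endpoint == "dfs") cl$dfs_event else cl$os_event
  if (is.null(tm) || anyNA(tm)) stop("endpoint '", endpoint, "' not fully available")
  vals <- unclass(m)[, common, drop = FALSE]

  # proteins pinned at one value (e.g. all-imputed) cannot be dichotomized
  screenable <- apply(vals, 1, function(v) length(unique(v)) >= 2)
  if (!any(screenable)) stop("no protein has >= 2 distinct values")
  glob_min <- min(vals)
  rows <- lapply(rownames(vals)[screenable], function(pid) {
    v <- vals[pid, ]
    cp <- tryCatch(best_cutpoint(v, tm, ev, minprop = minprop),
                   error = function(e) NULL)
    if (is.null(cp)) return(NULL)
    high <- as.numeric(v > cp$threshold)
    hr <- ci_low <- ci_high <- NA_real_
    fit <- tryCatch(cox_fit(matrix(high, dimnames = list(NULL, "high")), tm, ev),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      hr <- fit$coefficients$hr[1]
      ci_low <- fit$coefficients$ci_low[1]
      ci_high <- fit$coefficients$ci_high[1]
    }
    data.frame(protein_id = pid, tissue = tissue, cohort_id = cohort_id,
               cutpoint = cp$threshold, hr = hr, ci_low = ci_low,
               ci_high = ci_high, p = cp$logrank_p,
               frac_imputed_flag = mean(v == glob_min) > 0.5,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, NA)])
  if (is.null(res) || !nrow(res)) stop("screening produced no usable records")
  res$p_bh <- stats::p.adjust(res$p, "BH")
  res$direction <- ifelse(is.na(res$hr), NA_character_, classify_direction(res$hr))
  res$significant <- res$p < alpha & !is.na(res$direction)
  res <- res[order(res$p, res$protein_id), ]
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  attr(res, "endpoint") <- endpoint
  attr(res, "minprop") <- minprop
  class(res) <- c("rrp_table", "data.frame")
  res
}

#' Build the four direction-labelled protein sets
#'
#' From tumor and NAT screening results of one cohort, collects the
#' significant proteins into four sets: tumor-unfavorable, tumor-favorable,
#' NAT-unfavorable, NAT-favorable.
#'
#' @param tumor_records,nat_records `rrp_table`s from [screen_rrps()] for the
#'   two compartments.
#' @return named list of four character vectors (`tumor_unfavorable`,
#'   `tumor_favorable`, `nat_unfavorable`, `nat_favorable`).
#' @export
build_direction_sets <- function(tumor_records, nat_records) {
  pick <- function(rec, dir)
    sort(rec$protein_id[rec$significant & rec$direction == dir & !is.na(rec$direction)])
  sets <- list(tumor_unfavorable = pick(tumor_records, "unfavorable"),
               tumor_favorable   = pick(tumor_records, "favorable"),
               nat_unfavorable   = pick(nat_records, "unfavorable"),
               nat_favorable     = pick(nat_records, "favorable"))
  empty <- names(sets)[vapply(sets, length, 0L) == 0]
  if (length(empty))
    stop("empty direction set(s): ", paste(empty, collapse = ", "),
         " - increase the cohort size or planted effect, or relax alpha")
  sets
}

#' Intersect direction sets across cohorts
#'
#' @param per_cohort_sets list (>= 2 cohorts) of named set lists as returned
#'   by [build_direction_sets()].
#' @return named list: per set name, the members shared by all cohorts.
#'   Empty intersections are allowed (with a warning).
#' @export
intersect_cohorts <- function(per_cohort_sets) {
  if (length(per_cohort_sets) < 2) stop("need >= 2 cohorts to intersect")
  nms <- Reduce(intersect, lapply(per_cohort_sets, names))
  out <- lapply(nms, function(nm)
    sort(Reduce(intersect, lapply(per_cohort_sets, `[[`, nm))))
  names(out) <- nms
  empty <- nms[vapply(out, length, 0L) == 0]
  if (length(empty))
    warning("empty cross-cohort intersection for: ", paste(empty, collapse = ", "))
  out
}

#' Filter candidate drug-target proteins across cohorts
#'
#' Keeps proteins that are significantly unfavorable in at least one cohort
#' and not significantly favorable in any cohort.
#'
#' @param records a single `rrp_table` or list of them (e.g. one per
#'   cohort/tissue); rows are pooled.
#' @return sorted character vector of protein IDs passing the predicate.
#' @export
target_filter <- function(records) {
  if (is.data.frame(records)) records <- list(records)
  all_rec <- do.call(rbind, lapply(records, function(r) as.data.frame(r)[
    c("protein_id", "direction", "significant")]))
  sig <- all_rec[all_rec$significant & !is.na(all_rec$direction), ]
  unf <- unique(sig$protein_id[sig$direction == "unfavorable"])
  fav <- unique(sig$protein_id[sig$direction == "favorable"])
  sort(setdiff(unf, fav))
}

#' Fraction of a query set covered by reference sets
#'
#' `|query intersect union(reference)| / |query|` — e.g. the fraction of
#' treatment-downregulated proteins that are recurrence-unfavorable.
#'
#' @param query nonempty character vector.
#' @param reference_sets list of character vectors (union is taken).
#' @return fraction in \[0, 1\].
#' @export
overlap_fraction <- function(query, reference_sets) {
  query <- unique(query)
  if (!length(query)) stop("empty query set")
  ref <- unique(unlist(reference_sets, use.names = FALSE))
  length(intersect(query, ref)) / length(query)
}
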