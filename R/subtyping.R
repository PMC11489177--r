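#' Call prognostic subtypes from DFS scores
#'
#' Dichotomizes per-sample DFS scores at their maximally selected log-rank
#' cut-point against the recurrence endpoint and labels the higher-hazard
#' side "2" (poor prognosis), the other "1" — so T2/NAT2 always mark the
#' poorer-prognosis group regardless of the score's sign convention.
#'
#' @param scores `sample_scores` table from [score_samples()] (or any
#'   data.frame with `sample_id` and `dfs_score`).
#' @param clinical survival table.
#' @param tissue "tumor" or "nat" (controls the label prefix T/NAT).
#' @param endpoint "dfs" or "os".
#' @param minprop minimum group proportion for the cut-point.
#' @return data.frame: sample_id, dfs_score, subtype (e.g. "T1"/"T2"),
#'   with attributes `cutpoint` (the [best_cutpoint()] result) and
#'   `high_side_label` recording which side of the threshold is label 2.
#' @export
call_subtypes <- function(scores, clinical, tissue = c("tumor", "nat"),
                          endpoint = c("dfs", "os"), minprop = 0.1) {
  tissue <- match.arg(tissue)
  endpoint <- match.arg(endpoint)
  clinical <- survival_table(clinical)
  common <- intersect(scores$sample_id, clinical$sample_id)
  if (length(common) < 2) stop("need >= 2 samples shared by scores and clinical table")
  sc <- scores[match(common, scores$sample_id), ]
  cl <- clinical[match(common, clinical$sample_id), ]
  tm <- if (endpoint == "dfs") cl$dfs_time else cl$os_time
  ev <- if (endpoint == "dfs") cl$dfs_event else cl$os_event
  if (length(unique(sc$dfs_score)) < 2) stop("constant DFS scores: cannot subtype")
  cp <- best_cutpoint(sc$dfs_score, tm, ev, minprop = minprop)
  high <- sc$dfs_score > cp$threshold
  # label 2 = the side with the higher event hazard
  uv <- .logrank_stat(.logrank_prep(tm, ev), high)
  high_is_poor <- uv["U"] >= 0                 # more events than expected in high group
  prefix <- if (tissue == "tumor") "T" else "NAT"
  lab <- ifelse(xor(high, !high_is_poor), paste0(prefix, "2"), paste0(prefix, "1"))
  out <- data.frame(sample_id = sc$sample_id, dfs_score = sc$dfs_score,
                    subtype = lab, stringsAsFactors = FALSE)
  attr(out, "cutpoint") <- cp
  attr(out, "high_side_label") <- if (high_is_poor) "2" else "1"
  attr(out, "tissue") <- tissue
  out
}

#' Integrate tumor and NAT subtype calls
#'
#' Joins the two per-tissue calls on sample ID into the four-level label
#' (T1-NAT1, T1-NAT2, T2-NAT1, T2-NAT2). Samples with only one tissue keep
#' their single-tissue call and get no integrated label.
#'
#' @param tumor_calls,nat_calls outputs of [call_subtypes()].
#' @return data.frame: sample_id, tumor_subtype, nat_subtype, integrated
#'   (NA when either tissue is missing).
#' @export
integrate_subtypes <- function(tumor_calls, nat_calls) {
  ids <- union(tumor_calls$sample_id, nat_calls$sample_id)
  tu <- tumor_calls$subtype[match(ids, tumor_calls$sample_id)]
  na_ <- nat_calls$subtype[match(ids, nat_calls$sample_id)]
  integrated <- ifelse(is.na(tu) | is.na(na_), NA_character_, paste(tu, na_, sep = "-"))
  n_drop <- sum(is.na(integrated))
  if (n_drop)
    message(n_drop, " sample(s) lack one tissue and get no integrated label")
  data.frame(sample_id = ids, tumor_subtype = tu, nat_subtype = na_,
             integrated = integrated, stringsAsFactors = FALSE)
}

#' Subtype survival contrast within clinical strata
#'
#' Within each level of a clinical stratifying variable, compares the two
#' subtype labels by Kaplan-Meier, log-rank and a two-group Cox hazard ratio
#' — the complementarity check that a tissue's subtype still separates
#' recurrence risk inside clinically defined risk groups.
#'
#' @param labels data.frame with `sample_id` and a two-level `label` column
#'   (e.g. NAT1/NAT2).
#' @param clinical survival table containing `stratum_variable`.
#' @param stratum_variable name of the clinical covariate to stratify on.
#' @param endpoint "dfs" or "os".
#' @return named list per stratum: `km` (per-label [km_estimate()] curves),
#'   `logrank` (chi-square, p), `hr`, `ci_low`, `ci_high`, `n`. Strata with a
#'   single label present are skipped with a warning.
#' @export
stratified_km <- function(labels, clinical, stratum_variable,
                          endpoint = c("dfs", "os")) {
  endpoint <- match.arg(endpoint)
  clinical <- survival_table(clinical)
  if (!stratum_variable %in% names(clinical))
    stop("stratum variable '", stratum_variable, "' not in clinical table")
  df <- merge(labels, clinical, by = "sample_id")
  tm_col <- if (endpoint == "dfs") "dfs_time" else "os_time"
  ev_col <- if (endpoint == "dfs") "dfs_event" else "os_event"
  lev2 <- sort(unique(df$label))
  if (length(lev2) != 2) stop("labels must have exactly 2 levels")
  out <- list()
  for (s in sort(unique(df[[stratum_variable]]))) {
    d <- df[df[[stratum_variable]] == s, ]
    if (length(unique(d$label)) < 2) {
      warning("stratum '", s, "' has a single label; skipped")
      next
    }
    lr <- logrank_test(d[[tm_col]], d[[ev_col]], d$label)
    ind <- as.numeric(d$label == lev2[2])
    fit <- tryCatch(cox_fit(matrix(ind, dimnames = list(NULL, lev2[2])),
                            d[[tm_col]], d[[ev_col]]),
                    error = function(e) NULL)
    out[[as.character(s)]] <- list(
      km = lapply(stats::setNames(lev2, lev2), function(l)
        km_estimate(d[[tm_col]][d$label == l], d[[ev_col]][d$label == l])),
      logrank = lr[c("chi_square", "p")],
      hr = if (is.null(fit)) NA_real_ else fit$coefficients$hr[1],
      ci_low = if (is.null(fit)) NA_real_ else fit$coefficients$ci_low[1],
      ci_high = if (is.null(fit)) NA_real_ else fit$coefficients$ci_high[1],
      n = nrow(d))
  }
  out
}

#' Compare clinical covariates between subtype groups
#'
#' Numeric covariates are compared with the Wilcoxon rank-sum test,
#' categorical ones with the chi-square test (continuity-corrected for 2x2
#' tables; Fisher's exact test replaces it when any expected cell count falls
#' below 5). Constant covariates get p = 1 with a warning.
#'
#' @param labels data.frame with `sample_id` and two-level `label`.
#' @param clinical survival table; every column other than the survival
#'   fields is tested.
#' @param covariates optional character vector restricting the columns tested.
#' @return data.frame: covariate, test, statistic, p.
#' @export
group_feature_tests <- function(labels, clinical, covariates = NULL) {
  clinical <- survival_table(clinical)
  df <- merge(labels, clinical, by = "sample_id")
  if (length(unique(df$label)) != 2) stop("labels must have exactly 2 levels")
  skip <- c("sample_id", "label", "dfs_time", "dfs_event", "os_time", "os_event")
  if (is.null(covariates)) covariates <- setdiff(names(df), skip)
  rows <- lapply(covariates, function(cv) {
    x <- df[[cv]]
    ok <- !is.na(x)
    x <- x[ok]; g <- df$label[ok]
    if (length(unique(x)) < 2) {
      warning("covariate '", cv, "' is constant; p set to 1")
      return(data.frame(covariate = cv, test = "none", statistic = NA_real_, p = 1))
    }
    if (is.numeric(x)) {
      wt <- stats::wilcox.test(x ~ g, exact = FALSE)
      data.frame(covariate = cv, test = "wilcoxon",
                 statistic = unname(wt$statistic), p = wt$p.value)
    } else {
      tab <- table(x, g)
      expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expd < 5)) {
        ft <- stats::fisher.test(tab)
        data.frame(covariate = cv, test = "fisher", statistic = NA_real_,
                   p = ft$p.value)
      } else {
        ct <- stats::chisq.test(tab, correct = all(dim(tab) == 2))
        data.frame(covariate = cv, test = "chisq",
                   statistic = unname(ct$statistic), p = ct$p.value)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
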