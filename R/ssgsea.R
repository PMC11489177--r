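#' Single-sample gene-set enrichment score
#'
#' Weighted Kolmogorov-Smirnov-like running-sum score for one sample. Genes
#' are walked in order of decreasing expression; at each in-set gene the sum
#' rises by that gene's weight (normalized over in-set weights), at each
#' out-of-set gene it falls by 1 / (number of out-of-set genes). The
#' enrichment score is the sum of the running-sum deviations over all steps
#' (the integrated form used by single-sample GSEA), or the maximum absolute
#' deviation in `"max"` mode.
#'
#' Weights are `|w|^alpha` where `w` is either the within-sample rank of the
#' expression value (ties averaged; default — making the score invariant to
#' any strictly increasing per-sample transform) or the raw expression value.
#'
#' @param expr named numeric vector of one sample's (complete) expression.
#' @param gene_set character vector of set members.
#' @param alpha weighting exponent. Default 0.25.
#' @param weight "rank" (default) or "value".
#' @param mode "integral" (default) or "max".
#' @return scalar enrichment score.
#' @export
ssgsea_sample <- function(expr, gene_set, alpha = 0.25,
                          weight = c("rank", "value"),
                          mode = c("integral", "max")) {
  weight <- match.arg(weight)
  mode <- match.arg(mode)
  if (is.null(names(expr))) stop("expression vector must be named by gene")
  if (anyNA(expr)) stop("missing expression values; impute before scoring")
  in_set <- names(expr) %in% gene_set
  if (!any(in_set)) stop("gene set has no overlap with the measured genes")
  if (all(in_set)) stop("gene set covers every measured gene (empty complement)")
  ord <- order(-expr, names(expr))             # descending; ID breaks ties
  in_s <- in_set[ord]
  w <- if (weight == "rank") rank(expr, ties.method = "average") else expr
  w <- abs(w[ord])^alpha
  n_out <- sum(!in_s)
  step_up <- ifelse(in_s, w, 0)
  sum_up <- sum(step_up)
  if (sum_up == 0) stop("in-set weights sum to zero; cannot normalize")
  rs <- unname(cumsum(step_up / sum_up) - cumsum(!in_s) / n_out)
  if (mode == "integral") sum(rs)
  else rs[which(abs(rs) >= max(abs(rs)) - 1e-12)[1]]  # first extreme on ties
}

#' Per-sample enrichment scores and the DFS score
#'
#' Scores every sample of an expression matrix against each gene set and
#' derives the DFS score as the unfavorable-set score minus the favorable-set
#' score. Scoring a tumor matrix uses the tumor-unfavorable/favorable sets;
#' a NAT matrix the NAT sets.
#'
#' @param m complete expression matrix (proteins x samples).
#' @param sets named list of gene sets (must include the two named below).
#' @param unfavor_name,favor_name names of the sets entering the DFS score.
#' @param normalize divide all scores by the overall score range across
#'   samples and sets (off by default; the DFS score is a within-sample
#'   difference and does not need it).
#' @inheritParams ssgsea_sample
#' @return data.frame of class `sample_scores`: sample_id, one ES column per
#'   set (`es_<name>`), `es_unfavor`, `es_favor`, `dfs_score`.
#' @export
score_samples <- function(m, sets, unfavor_name, favor_name,
                          alpha = 0.25, weight = "rank", mode = "integral",
                          normalize = FALSE) {
  missing_sets <- setdiff(c(unfavor_name, favor_name), names(sets))
  if (length(missing_sets))
    stop("set(s) not found: ", paste(missing_sets, collapse = ", "))
  if (anyNA(m)) stop("matrix has missing values; impute before scoring")
  es <- vapply(names(sets), function(nm)
    apply(unclass(m), 2, ssgsea_sample, gene_set = sets[[nm]],
          alpha = alpha, weight = weight, mode = mode),
    numeric(ncol(m)))
  es <- matrix(es, nrow = ncol(m), dimnames = list(colnames(m), names(sets)))
  if (normalize) {
    rng <- diff(range(es))
    if (rng > 0) es <- es / rng
  }
  out <- data.frame(sample_id = colnames(m), es,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[-1] <- paste0("es_", names(sets))
  out$es_unfavor <- es[, unfavor_name]
  out$es_favor <- es[, favor_name]
  out$dfs_score <- out$es_unfavor - out$es_favor
  rownames(out) <- NULL
  class(out) <- c("sample_scores", "data.frame")
  out
}
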