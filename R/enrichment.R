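#' Group-wise differential abundance
#'
#' Compares two sample groups per protein on log-scale abundances with
#' Welch's t-test (optionally a pooled-prior moderated variant), reports the
#' linear-scale fold change (ratio of geometric means) and classifies each
#' protein as up (FC > 1, p < alpha), down (FC < 1, p < alpha) or ns.
#'
#' @param m expression matrix of log-scale abundances (complete).
#' @param labels two-level group vector aligned to the columns; fold change
#'   is `ref_level` over the other level.
#' @param ref_level label of the numerator group (default: the treated /
#'   second sorted level).
#' @param alpha significance threshold for the class call. Default 0.05.
#' @param log_base base of the input log scale (2 for log2 data). Default 2.
#' @param moderate shrink per-protein variances toward the median
#'   across-protein variance (equal prior weight) before the t-test — a
#'   lightweight analogue of moderated test statistics. Default `FALSE`.
#' @return data.frame of class `diff_table`: protein_id, log_fc, fold_change,
#'   p, adjusted_p (Benjamini-Hochberg), class.
#' @export
groupwise_diff <- function(m, labels, ref_level = NULL, alpha = 0.05,
                           log_base = 2, moderate = FALSE) {
  if (length(labels) != ncol(m)) stop("labels must match the sample columns")
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2) stop("exactly two groups required")
  if (is.null(ref_level)) ref_level <- lev[2]
  if (!ref_level %in% lev) stop("ref_level not among the labels")
  other <- setdiff(lev, ref_level)
  i1 <- which(labels == ref_level); i2 <- which(labels == other)
  if (length(i1) < 2 || length(i2) < 2) stop("each group needs >= 2 samples")
  x <- unclass(m)
  if (anyNA(x)) stop("matrix has missing values; impute first")
  m1 <- rowMeans(x[, i1, drop = FALSE]); m2 <- rowMeans(x[, i2, drop = FALSE])
  v1 <- apply(x[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, i2, drop = FALSE], 1, stats::var)
  n1 <- length(i1); n2 <- length(i2)
  if (moderate) {
    v0 <- stats::median(c(v1, v2))
    v1 <- (v1 + v0) / 2
    v2 <- (v2 + v0) / 2
  }
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0] <- 1                          # identical constant groups
  log_fc <- m1 - m2
  fc <- log_base^log_fc
  cls <- rep("ns", length(p))
  cls[fc > 1 & p < alpha] <- "up"
  cls[fc < 1 & p < alpha] <- "down"
  out <- data.frame(protein_id = rownames(x), log_fc = log_fc, fold_change = fc,
                    p = p, adjusted_p = stats::p.adjust(p, "BH"), class = cls,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "ref_level") <- ref_level
  attr(out, "alpha") <- alpha
  class(out) <- c("diff_table", "data.frame")
  out
}

#' Over-representation (hypergeometric) test
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' overlap between a hit list and a gene set, both restricted to the
#' measurement universe.
#'
#' @param hits character vector of selected genes (subset of `universe`).
#' @param gene_set character vector.
#' @param universe character vector of all measurable genes.
#' @return list: set overlap counts (`n_overlap`, `n_set`, `n_hits`,
#'   `n_universe`), `p`, and the fold `enrichment` over expectation.
#' @export
ora_test <- function(hits, gene_set, universe) {
  hits <- unique(hits); universe <- unique(universe)
  if (!length(hits)) stop("empty hit list")
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  set_u <- intersect(unique(gene_set), universe)
  if (!length(set_u)) stop("gene set does not intersect the universe")
  k <- length(intersect(hits, set_u))
  K <- length(set_u); nh <- length(hits); N <- length(universe)
  # P(overlap >= k) summed over the achievable tail
  kmax <- min(K, nh)
  p <- sum(stats::dhyper(k:kmax, K, N - K, nh))
  p <- min(1, p)
  list(n_overlap = k, n_set = K, n_hits = nh, n_universe = N,
       p = p, enrichment = (k / nh) / (K / N))
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov enrichment on a ranked statistic
#' (weight `|stat|^1`), with the maximum-deviation enrichment score.
#' Significance and the normalized enrichment score come from gene-label
#' permutation: NES = ES divided by the mean |ES| of same-sign permuted
#' scores; p is the same-sign permutation tail with the +1 correction.
#'
#' @param stats_ranked named numeric vector of per-gene statistics (unique
#'   names; any order — ranking is internal).
#' @param gene_set character vector.
#' @param n_perm number of gene permutations. Default 1000.
#' @param seed RNG seed for the permutations.
#' @return list: `es`, `nes`, `p`, `n_overlap`, `n_set`, `n_universe`.
#' @export
preranked_gsea <- function(stats_ranked, gene_set, n_perm = 1000L, seed = 1L) {
  if (is.null(names(stats_ranked)) || anyDuplicated(names(stats_ranked)))
    stop("stats_ranked must have unique gene names")
  genes <- names(stats_ranked)
  in_set <- genes %in% gene_set
  if (!any(in_set)) stop("gene set does not overlap the ranking")
  if (all(in_set)) stop("gene set covers the whole ranking")
  es_fun <- function(in_s, st) {
    ord <- order(-st, names(st))
    hit <- in_s[ord]
    w <- abs(st[ord])
    sw <- sum(w[hit])
    inc <- if (sw > 0) ifelse(hit, w, 0) / sw else ifelse(hit, 1 / sum(hit), 0)
    rs <- cumsum(inc) - cumsum(!hit) / sum(!hit)
    rs[which(abs(rs) >= max(abs(rs)) - 1e-12)[1]]     # first extreme on ties
  }
  es <- es_fun(in_set, stats_ranked)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  k <- sum(in_set)
  perm <- vapply(seq_len(n_perm), function(b) {
    idx <- sample(length(genes), k)
    in_p <- logical(length(genes)); in_p[idx] <- TRUE
    es_fun(in_p, stats_ranked)
  }, 0)
  same_sign <- perm[sign(perm) == sign(es)]
  nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
  p <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
  list(es = unname(es), nes = unname(nes), p = p,
       n_overlap = k, n_set = length(unique(gene_set)),
       n_universe = length(genes))
}
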