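# Independent oracles used to cross-check the package implementations.
# These deliberately use different code paths (survival::survdiff, naive
# loops, closed forms) from the functions they verify.

# Brute-force maximally selected log-rank scan: every admissible midpoint
# threshold, chi-square from survival::survdiff, same tie-break rule
# (balanced groups, then smaller threshold).
oracle_cutpoint <- function(marker, times, events, minprop = 0.1) {
  sv <- sort(unique(marker))
  thr <- (sv[-length(sv)] + sv[-1]) / 2
  n <- length(marker)
  min_n <- ceiling(minprop * n)
  res <- lapply(thr, function(th) {
    lo <- marker <= th
    if (sum(lo) < min_n || sum(!lo) < min_n) return(NULL)
    chi <- if (sum(events) == 0) 0 else
      survival::survdiff(survival::Surv(times, events) ~ lo)$chisq
    data.frame(thr = th, chi = chi, n_low = sum(lo))
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(NULL)
  best <- which(res$chi >= max(res$chi) - 1e-12)
  if (length(best) > 1) {
    bal <- abs(res$n_low[best] - (n - res$n_low[best]))
    best <- best[bal == min(bal)]
    best <- best[which.min(res$thr[best])]
  }
  res[best, ]
}

# Step-by-step single-sample enrichment running sum, written as an explicit
# walk (no cumsum), integral and max-deviation forms.
oracle_ssgsea <- function(expr, gene_set, alpha = 0.25, weight = "rank",
                          mode = "integral") {
  ord <- order(-expr, names(expr))
  g <- names(expr)[ord]
  w_all <- if (weight == "rank") rank(expr, ties.method = "average") else expr
  w_all <- abs(w_all[ord])^alpha
  in_set <- g %in% gene_set
  denom_in <- sum(w_all[in_set])
  n_out <- sum(!in_set)
  rs <- 0; acc <- 0; best <- 0
  for (i in seq_along(g)) {
    if (in_set[i]) rs <- rs + w_all[i] / denom_in
    else rs <- rs - 1 / n_out
    acc <- acc + rs
    if (abs(rs) > abs(best) + 1e-12) best <- rs
  }
  unname(if (mode == "integral") acc else best)
}

# Closed-form hypergeometric upper tail by explicit enumeration with choose().
oracle_hyper_tail <- function(overlap, n_set, n_universe, n_hits) {
  ks <- overlap:min(n_set, n_hits)
  sum(choose(n_set, ks) * choose(n_universe - n_set, n_hits - ks)) /
    choose(n_universe, n_hits)
}

# Classic preranked enrichment running sum, explicit walk.
oracle_gsea_es <- function(stats_ranked, gene_set) {
  ord <- order(-stats_ranked, names(stats_ranked))
  g <- names(stats_ranked)[ord]
  w <- abs(stats_ranked[ord])
  hit <- g %in% gene_set
  denom <- sum(w[hit])
  rs <- 0; best <- 0
  for (i in seq_along(g)) {
    rs <- if (hit[i]) rs + w[i] / denom else rs - 1 / sum(!hit)
    if (abs(rs) > abs(best) + 1e-12) best <- rs
  }
  unname(best)
}

# Small right-censored survival dataset generator for property tests.
make_surv <- function(n, seed, event_rate = 0.05, cens_rate = 0.03) {
  set.seed(seed)
  t_ev <- rexp(n, event_rate)
  t_c <- rexp(n, cens_rate)
  list(times = pmax(pmin(t_ev, t_c), 1e-3), events = as.numeric(t_ev <= t_c))
}

# Tiny expression matrix fixture with named rows/columns.
make_expr <- function(p, n, seed, mean = 20, sd = 1) {
  set.seed(seed)
  expression_matrix(matrix(rnorm(p * n, mean, sd), p, n,
                           dimnames = list(sprintf("P%04d", seq_len(p)),
                                           sprintf("S%03d", seq_len(n)))))
}
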