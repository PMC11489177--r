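#' Kaplan-Meier product-limit estimate
#'
#' Right-censored survival curve. With no events the curve is identically 1.
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators (1 = event, 0 = censored).
#' @return object of class `km_curve`: `time` (distinct event times,
#'   increasing), `survival`, `at_risk`, `n_events`, `n`.
#' @export
km_estimate <- function(times, events) {
  .check_surv(times, events)
  ord <- order(times)
  t <- times[ord]; d <- events[ord]
  ut <- unique(t)
  f <- match(t, ut)
  n <- length(t)
  n_risk <- n - c(0, cumsum(tabulate(f, length(ut))))[seq_along(ut)]
  d_j <- as.vector(rowsum(d, f))
  keep <- d_j > 0
  surv <- cumprod(1 - d_j[keep] / n_risk[keep])
  structure(list(time = ut[keep], survival = surv, at_risk = n_risk[keep],
                 n_events = d_j[keep], n = n),
            class = "km_curve")
}

.check_surv <- function(times, events) {
  if (!length(times)) stop("empty survival input")
  if (length(times) != length(events)) stop("times and events differ in length")
  if (anyNA(times) || anyNA(events)) stop("missing values in survival input")
  if (any(times <= 0)) stop("survival times must be strictly positive")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
}

# Precompute the pooled risk-set structure reused across repeated two-group
# log-rank evaluations on the same (times, events), as in the cut-point scan.
.logrank_prep <- function(times, events) {
  ord <- order(times)
  t <- times[ord]; d <- events[ord]
  ut <- unique(t)
  f <- match(t, ut)
  k <- length(ut)
  n <- length(t)
  n_risk <- n - c(0, cumsum(tabulate(f, k)))[seq_len(k)]
  d_j <- as.vector(rowsum(d, f))
  keep <- which(d_j > 0)
  list(ord = ord, f = f, k = k, n = n, d_sorted = d,
       n_risk = n_risk, d_j = d_j, keep = keep)
}

# Two-group log-rank O-E statistic with hypergeometric variance, for a logical
# membership vector in original subject order.
.logrank_stat <- function(prep, in_group1) {
  g1 <- in_group1[prep$ord]
  n1_at <- tabulate(prep$f[g1], prep$k)
  n1_risk <- sum(g1) - c(0, cumsum(n1_at))[seq_len(prep$k)]
  d1_j <- as.vector(rowsum(prep$d_sorted * g1, prep$f))
  j <- prep$keep
  nj <- prep$n_risk[j]; dj <- prep$d_j[j]; n1j <- n1_risk[j]; d1j <- d1_j[j]
  U <- sum(d1j - dj * n1j / nj)
  ok <- nj > 1
  V <- sum((dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1))[ok])
  c(U = U, V = V)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected statistic with hypergeometric variance, referred to
#' a chi-square distribution with 1 degree of freedom. With no events at all
#' the statistic is 0 and p = 1 by convention.
#'
#' @param times,events follow-up data (see [km_estimate()]).
#' @param group vector with exactly two distinct values.
#' @return list with `chi_square`, `p`, `observed`, `expected` (per group),
#'   and the group labels.
#' @export
logrank_test <- function(times, events, group) {
  .check_surv(times, events)
  if (length(group) != length(times)) stop("group vector length mismatch")
  lev <- unique(group)
  if (length(lev) != 2) stop("log-rank test requires exactly 2 non-empty groups")
  if (sum(events) == 0) {
    message("no events: log-rank p set to 1 by convention")
    return(list(chi_square = 0, p = 1, observed = c(0, 0),
                expected = c(0, 0), groups = lev))
  }
  prep <- .logrank_prep(times, events)
  uv <- .logrank_stat(prep, group == lev[1])
  chi <- if (uv["V"] > 0) unname(uv["U"]^2 / uv["V"]) else 0
  o1 <- sum(events[group == lev[1]])
  e1 <- o1 - unname(uv["U"])
  list(chi_square = chi,
       p = if (uv["V"] > 0) stats::pchisq(chi, df = 1, lower.tail = FALSE) else 1,
       observed = c(o1, sum(events) - o1),
       expected = c(e1, sum(events) - e1),
       groups = lev)
}

#' Cox proportional-hazards regression
#'
#' Maximizes the partial likelihood by Newton-Raphson with the Efron
#' (default) or Breslow approximation for tied event times. Reports per-term
#' hazard ratios with Wald 95% confidence intervals and p-values.
#'
#' @param x covariate vector or n-by-p matrix (numeric; code factors upstream).
#' @param times,events follow-up data.
#' @param ties "efron" or "breslow".
#' @param max_iter,tol Newton-Raphson controls.
#' @return object of class `cox_fit` with elements `coefficients` (a
#'   data.frame: term, coef, hr, ci_low, ci_high, se, z, p), `loglik`
#'   (null, final), `n`, `n_events`, `iter`, `ties`.
#' @export
cox_fit <- function(x, times, events, ties = c("efron", "breslow"),
                    max_iter = 30L, tol = 1e-9) {
  ties <- match.arg(ties)
  .check_surv(times, events)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (nrow(x) != length(times)) stop("covariate rows must match times")
  if (anyNA(x)) stop("missing covariate values")
  const <- apply(x, 2, function(v) diff(range(v)) == 0)
  if (any(const)) stop("constant covariate: ", paste(colnames(x)[const], collapse = ", "))
  if (sum(events) < 1) stop("no events: Cox model is not identifiable")

  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  p <- ncol(xc)
  beta <- rep(0, p)
  trace <- list()
  ll_fun <- function(b) .cox_partial(xc, times, events, b, ties)
  fit0 <- ll_fun(beta)
  ll_null <- fit0$loglik
  ll_old <- ll_null
  fit <- fit0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    step <- solve(fit$info, fit$grad)
    b_new <- beta + step
    f_new <- ll_fun(b_new)
    halv <- 0
    while ((!is.finite(f_new$loglik) || f_new$loglik < ll_old - 1e-12) && halv < 20) {
      step <- step / 2
      b_new <- beta + step
      f_new <- ll_fun(b_new)
      halv <- halv + 1
    }
    beta <- b_new; fit <- f_new
    trace[[it]] <- c(iter = it, loglik = fit$loglik, beta)
    if (abs(fit$loglik - ll_old) < tol * (abs(ll_old) + tol)) { converged <- TRUE; break }
    ll_old <- fit$loglik
  }
  if (!converged || any(abs(beta) > 20)) {
    tr <- paste(vapply(trace, function(r) paste(signif(r, 6), collapse = " "), ""),
                collapse = "\n")
    stop("Cox partial likelihood did not converge; iteration trace:\n", tr)
  }
  se <- sqrt(diag(solve(fit$info)))
  z <- beta / se
  coefs <- data.frame(term = colnames(x), coef = beta, hr = exp(beta),
                      ci_low = exp(beta - stats::qnorm(0.975) * se),
                      ci_high = exp(beta + stats::qnorm(0.975) * se),
                      se = se, z = z,
                      p = 2 * stats::pnorm(-abs(z)),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, loglik = c(null = ll_null, final = fit$loglik),
                 n = length(times), n_events = sum(events),
                 iter = length(trace), ties = ties),
            class = "cox_fit")
}

# Partial log-likelihood, score and information at beta, handling ties.
.cox_partial <- function(x, times, events, beta, ties) {
  p <- ncol(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  ord <- order(times, decreasing = TRUE)
  t_s <- times[ord]; d_s <- events[ord]; x_s <- x[ord, , drop = FALSE]; w_s <- w[ord]
  n <- length(t_s)
  ll <- 0; grad <- rep(0, p); info <- matrix(0, p, p)
  S0 <- 0; S1 <- rep(0, p); S2 <- matrix(0, p, p)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j <= n && t_s[j] == t_s[i]) j <- j + 1L
    idx <- i:(j - 1L)
    for (k in idx) {
      S0 <- S0 + w_s[k]
      S1 <- S1 + w_s[k] * x_s[k, ]
      S2 <- S2 + w_s[k] * tcrossprod(x_s[k, ])
    }
    dk <- which(d_s[idx] == 1)
    m <- length(dk)
    if (m > 0) {
      di <- idx[dk]
      xd <- x_s[di, , drop = FALSE]
      wd <- w_s[di]
      ll <- ll + sum(eta[ord][di])
      if (ties == "breslow" || m == 1) {
        ll <- ll - m * log(S0)
        xbar <- S1 / S0
        grad <- grad + colSums(xd) - m * xbar
        info <- info + m * (S2 / S0 - tcrossprod(xbar))
      } else {
        S0d <- sum(wd)
        S1d <- colSums(wd * xd)
        S2d <- matrix(0, p, p)
        for (k in seq_len(m)) S2d <- S2d + wd[k] * tcrossprod(xd[k, ])
        grad <- grad + colSums(xd)
        for (l in seq_len(m) - 1) {
          a <- l / m
          s0 <- S0 - a * S0d
          s1 <- S1 - a * S1d
          s2 <- S2 - a * S2d
          ll <- ll - log(s0)
          grad <- grad - s1 / s0
          info <- info + s2 / s0 - tcrossprod(s1 / s0)
        }
      }
    }
    i <- j
  }
  list(loglik = ll, grad = grad, info = info)
}

# Score chi-square at beta = 0 (equals the log-rank statistic for a binary
# covariate without ties).
.cox_score_chisq <- function(x, times, events, ties = "efron") {
  x <- as.matrix(x)
  xc <- sweep(x, 2L, colMeans(x))
  f <- .cox_partial(xc, times, events, rep(0, ncol(xc)), ties)
  drop(crossprod(f$grad, solve(f$info, f$grad)))
}

#' Maximally selected log-rank cut-point
#'
#' Scans every threshold lying between consecutive distinct marker values
#' whose induced low/high split keeps both groups at or above
#' `ceiling(minprop * n)` subjects, and returns the threshold maximizing the
#' standardized log-rank statistic. The reported `logrank_p` is the naive
#' chi-square p-value at the selected threshold — the convention of best
#' cut-off survival screening — and is optimistic because the threshold was
#' optimized; an optional permutation p-value (`n_perm > 0`) refits the
#' cut-point on permuted markers for an honest selection-adjusted p.
#'
#' @param marker numeric marker values (>= 2 distinct).
#' @param times,events follow-up data.
#' @param minprop minimum group proportion, in (0, 0.5). Default 0.1.
#' @param n_perm number of marker permutations for the adjusted p; 0 = off.
#' @param seed RNG seed used only when `n_perm > 0`.
#' @return object of class `cutpoint`: `threshold`, `statistic` (standardized,
#'   i.e. sqrt of the chi-square), `chi_square`, `logrank_p`, `n_low`,
#'   `n_high`, `minprop`, and `perm_p` when requested.
#' @export
best_cutpoint <- function(marker, times, events, minprop = 0.1,
                          n_perm = 0L, seed = 1L) {
  .check_surv(times, events)
  if (length(marker) != length(times)) stop("marker length mismatch")
  if (anyNA(marker)) stop("missing marker values")
  if (!(minprop > 0 && minprop < 0.5)) stop("minprop must lie in (0, 0.5)")
  sv <- sort(unique(marker))
  if (length(sv) < 2) stop("constant marker: no cut-point exists")
  n <- length(marker)
  thr_all <- (sv[-length(sv)] + sv[-1]) / 2
  n_low_all <- vapply(thr_all, function(th) sum(marker <= th), 0L)
  min_n <- ceiling(minprop * n)
  adm <- n_low_all >= min_n & (n - n_low_all) >= min_n
  if (!any(adm)) stop("no admissible split under minprop = ", minprop)
  thr <- thr_all[adm]; n_low <- n_low_all[adm]

  prep <- .logrank_prep(times, events)
  scan <- function(mk) {
    chi <- vapply(thr, function(th) {
      uv <- .logrank_stat(prep, mk <= th)
      if (uv["V"] > 0) unname(uv["U"]^2 / uv["V"]) else 0
    }, 0)
    chi
  }
  chi <- scan(marker)
  best <- which(chi >= max(chi) - 1e-12)
  if (length(best) > 1) {                       # most balanced, then smallest
    bal <- abs(n_low[best] - (n - n_low[best]))
    best <- best[bal == min(bal)]
    best <- best[which.min(thr[best])]
  }
  chi_best <- chi[best]
  out <- list(threshold = thr[best],
              statistic = sqrt(chi_best),
              chi_square = chi_best,
              logrank_p = stats::pchisq(chi_best, 1, lower.tail = FALSE),
              n_low = n_low[best], n_high = n - n_low[best],
              minprop = minprop)
  if (n_perm > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    exceed <- vapply(seq_len(n_perm), function(b) {
      max(scan(sample(marker))) >= chi_best
    }, NA)
    out$perm_p <- (1 + sum(exceed)) / (n_perm + 1)
  }
  class(out) <- "cutpoint"
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (%s ties), n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
print.cutpoint <- function(x, ...) {
  cat(sprintf("best cut-point %.4g | standardized log-rank %.3f | p = %.3g | groups %d/%d\n",
              x$threshold, x$statistic, x$logrank_p, x$n_low, x$n_high))
  invisible(x)
}
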