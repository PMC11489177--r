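# small planted cohort reused by the subtype tests
.subtype_fixture <- function(seed = 9, n = 160) {
  spec <- cohort_spec(n_patients = n, n_proteins = 40,
                      planted_sets = list(
                        list(tissue = "tumor", direction = "unfavorable",
                             size = 8, log_hr_per_sd = log(3)),
                        list(tissue = "tumor", direction = "favorable",
                             size = 8, log_hr_per_sd = log(3)),
                        list(tissue = "nat", direction = "unfavorable",
                             size = 8, log_hr_per_sd = log(3)),
                        list(tissue = "nat", direction = "favorable",
                             size = 8, log_hr_per_sd = log(3))),
                      missing_fraction = 0, seed = seed)
  co <- generate_cohort(spec)
  sets <- split(co$truth$protein_id,
                paste(co$truth$tissue, co$truth$direction, sep = "_"))
  sc <- score_samples(co$tumor, sets, "tumor_unfavorable", "tumor_favorable")
  list(co = co, scores = sc, sets = sets)
}

test_that("label 2 marks the poorer-prognosis DFS-score group", {
  fx <- .subtype_fixture()
  sub <- call_subtypes(fx$scores, fx$co$clinical, tissue = "tumor")
  expect_setequal(unique(sub$subtype), c("T1", "T2"))
  # score separation between labels
  expect_gt(mean(sub$dfs_score[sub$subtype == "T2"]),
            mean(sub$dfs_score[sub$subtype == "T1"]))
  # label-2 KM lies at or below label-1 KM over the common horizon
  cl <- fx$co$clinical
  km <- lapply(c("T1", "T2"), function(l) {
    ids <- sub$sample_id[sub$subtype == l]
    i <- match(ids, cl$sample_id)
    km_estimate(cl$dfs_time[i], cl$dfs_event[i])
  })
  s_at <- function(km_, t) {
    i <- findInterval(t, km_$time)
    c(1, km_$survival)[i + 1]
  }
  grid <- seq(5, 55, by = 5)
  expect_true(all(s_at(km[[2]], grid) <= s_at(km[[1]], grid) + 1e-12))
  # label 2 has Cox HR >= 1 vs label 1 by construction
  i <- match(sub$sample_id, cl$sample_id)
  fit <- cox_fit(cbind(t2 = as.numeric(sub$subtype == "T2")),
                 cl$dfs_time[i], cl$dfs_event[i])
  expect_gte(fit$coefficients$hr, 1)
})

test_that("negating scores keeps label 2 on the poor-prognosis side", {
  fx <- .subtype_fixture(seed = 10)
  sub <- call_subtypes(fx$scores, fx$co$clinical, tissue = "tumor")
  neg <- fx$scores
  neg$dfs_score <- -neg$dfs_score
  sub_neg <- call_subtypes(neg, fx$co$clinical, tissue = "tumor")
  expect_equal(sub$subtype, sub_neg$subtype)  # same patients land in T2
})

test_that("constant scores cannot be subtyped", {
  fx <- .subtype_fixture(seed = 11)
  const <- fx$scores
  const$dfs_score <- 0
  expect_error(call_subtypes(const, fx$co$clinical, tissue = "tumor"),
               "constant")
})

test_that("integration is the product of the two calls", {
  tum <- data.frame(sample_id = c("a", "b", "c"),
                    subtype = c("T1", "T2", "T1"), stringsAsFactors = FALSE)
  nat <- data.frame(sample_id = c("a", "b", "d"),
                    subtype = c("NAT1", "NAT2", "NAT1"), stringsAsFactors = FALSE)
  expect_message(out <- integrate_subtypes(tum, nat), "lack one tissue")
  expect_equal(out$integrated[out$sample_id == "a"], "T1-NAT1")
  expect_equal(out$integrated[out$sample_id == "b"], "T2-NAT2")
  expect_true(is.na(out$integrated[out$sample_id == "c"]))  # tumor-only
  expect_true(is.na(out$integrated[out$sample_id == "d"]))  # NAT-only
  # marginal counts preserved
  expect_equal(sum(out$tumor_subtype == "T1", na.rm = TRUE), 2)
  expect_equal(sum(out$nat_subtype == "NAT1", na.rm = TRUE), 2)
})

test_that("NAT labels stratify risk inside independent clinical strata", {
  fx <- .subtype_fixture(seed = 12, n = 240)
  co <- fx$co
  scn <- score_samples(co$nat, fx$sets, "nat_unfavorable", "nat_favorable")
  sub <- call_subtypes(scn, co$clinical, tissue = "nat")
  labels <- data.frame(sample_id = sub$sample_id, label = sub$subtype,
                       stringsAsFactors = FALSE)
  res <- stratified_km(labels, co$clinical, "hbv_dna")  # independent stratum
  expect_setequal(names(res), c("negative", "positive"))
  for (s in res) {
    expect_gt(s$hr, 1)                  # NAT2 worse in both strata
    expect_s3_class(s$km$NAT1, "km_curve")
  }
})

test_that("single-label strata are skipped with a warning", {
  d <- make_surv(30, 2)
  labels <- data.frame(sample_id = sprintf("s%02d", 1:30),
                       label = rep(c("A", "B"), 15), stringsAsFactors = FALSE)
  cl <- data.frame(sample_id = labels$sample_id, dfs_time = d$times,
                   dfs_event = d$events,
                   stratum = c(rep("mixed", 28), "solo", "solo"),
                   stringsAsFactors = FALSE)
  cl$stratum[29:30] <- "solo"
  labels$label[29:30] <- "A"
  expect_warning(res <- stratified_km(labels, cl, "stratum"), "single label")
  expect_false("solo" %in% names(res))
})

test_that("feature tests pick the right test per covariate type", {
  set.seed(33)
  n <- 100
  labels <- data.frame(sample_id = sprintf("s%03d", 1:n),
                       label = rep(c("g1", "g2"), each = n / 2),
                       stringsAsFactors = FALSE)
  d <- make_surv(n, 4)
  cl <- data.frame(sample_id = labels$sample_id, dfs_time = d$times,
                   dfs_event = d$events,
                   shifted = rnorm(n) + 2 * (labels$label == "g2"),
                   same = rnorm(n),
                   cat = rep(c("x", "y"), n / 2),
                   stringsAsFactors = FALSE)
  res <- group_feature_tests(labels, cl)
  expect_equal(res$test[res$covariate == "shifted"], "wilcoxon")
  expect_lt(res$p[res$covariate == "shifted"], 0.01)   # 2 SD shift, n = 100
  expect_gt(res$p[res$covariate == "same"], 0.05)      # null covariate
})

test_that("2x2 chi-square matches the hand-computed corrected value", {
  labels <- data.frame(sample_id = sprintf("s%02d", 1:50),
                       label = rep(c("g1", "g2"), each = 25),
                       stringsAsFactors = FALSE)
  d <- make_surv(50, 5)
  cl <- data.frame(sample_id = labels$sample_id, dfs_time = d$times,
                   dfs_event = d$events,
                   feat = c(rep("a", 20), rep("b", 5), rep("a", 5), rep("b", 20)),
                   stringsAsFactors = FALSE)
  res <- group_feature_tests(labels, cl, covariates = "feat")
  # N (|ad - bc| - N/2)^2 / (r1 r2 c1 c2) = 50 * 350^2 / 25^4 = 15.68
  expect_equal(res$statistic, 15.68, tolerance = 1e-12)
  expect_equal(res$test, "chisq")
  # constant covariate: p = 1 with a warning
  cl$feat <- "a"
  expect_warning(res0 <- group_feature_tests(labels, cl, covariates = "feat"),
                 "constant")
  expect_equal(res0$p, 1)
})
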