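test_that("generators are pure functions of spec and seed", {
  a <- generate_cohort(cohort_spec(n_patients = 50, n_proteins = 30, seed = 3,
                                   planted_sets = list()))
  b <- generate_cohort(cohort_spec(n_patients = 50, n_proteins = 30, seed = 3,
                                   planted_sets = list()))
  expect_identical(unclass(a$tumor)[], unclass(b$tumor)[])
  expect_identical(a$clinical, b$clinical)
  c_ <- generate_cohort(cohort_spec(n_patients = 50, n_proteins = 30, seed = 4,
                                    planted_sets = list()))
  expect_false(identical(unclass(a$tumor)[], unclass(c_$tumor)[]))

  t1 <- generate_treatment_study(seed = 5)
  t2 <- generate_treatment_study(seed = 5)
  expect_identical(unclass(t1$matrix)[], unclass(t2$matrix)[])
  i1 <- generate_ihc_cohort(seed = 6)
  i2 <- generate_ihc_cohort(seed = 6)
  expect_identical(i1$records, i2$records)
  expect_identical(i1$clinical, i2$clinical)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_cohort(cohort_spec(n_patients = 25, n_proteins = 10,
                                        planted_sets = list(), seed = 1)))
  expect_identical(runif(1), before)
})

test_that("spec validation rejects infeasible cohorts", {
  expect_error(cohort_spec(n_proteins = 10, planted_sets = list(
    list(tissue = "tumor", direction = "unfavorable", size = 11,
         log_hr_per_sd = 1))), "exceed")
  expect_error(cohort_spec(pathway_block_correlation = 1), "correlation")
  expect_error(cohort_spec(missing_fraction = 1), "missing_fraction")
  expect_error(cohort_spec(baseline_hazard = 0), "positive")
  expect_error(cohort_spec(planted_sets = list(
    list(tissue = "plasma", direction = "unfavorable", size = 2,
         log_hr_per_sd = 1))), "tissue")
})

test_that("missingness and structure parameters are respected", {
  spec <- cohort_spec(n_patients = 100, missing_fraction = 0.1, seed = 8)
  co <- generate_cohort(spec)
  expect_equal(mean(is.na(co$tumor)), 0.1, tolerance = 0.002)
  expect_equal(sort(unique(co$truth$tissue)), c("nat", "tumor"))
  expect_equal(nrow(co$truth), 60)
  # planted block correlation raises within-set correlations
  co2 <- generate_cohort(cohort_spec(n_patients = 300, n_proteins = 40,
                                     planted_sets = list(
                                       list(tissue = "tumor",
                                            direction = "unfavorable",
                                            size = 10, log_hr_per_sd = 0.5)),
                                     pathway_block_correlation = 0.6,
                                     missing_fraction = 0, seed = 9))
  x <- unclass(co2$tumor)
  in_set <- rownames(x) %in% co2$truth$protein_id
  cors <- cor(t(x[in_set, ]))
  expect_equal(mean(cors[upper.tri(cors)]), 0.6, tolerance = 0.1)
  out_cors <- cor(t(x[!in_set, ][1:10, ]))
  expect_lt(abs(mean(out_cors[upper.tri(out_cors)])), 0.1)
})

test_that("censoring fraction matches the exponential race expectation", {
  spec <- cohort_spec(n_patients = 10000, n_proteins = 2,
                      planted_sets = list(), missing_fraction = 0, seed = 10)
  co <- generate_cohort(spec)
  h <- spec$baseline_hazard; c_ <- spec$censoring_rate; cap <- spec$follow_up_cap
  # P(event) = h/(h+c) * (1 - exp(-(h+c) * cap)); the rest is censoring
  p_event <- h / (h + c_) * (1 - exp(-(h + c_) * cap))
  se <- sqrt(p_event * (1 - p_event) / 10000)
  expect_lt(abs(mean(co$clinical$dfs_event) - p_event), 4 * se)
})

test_that("Cox on the oracle risk covariate recovers the planted log HR", {
  spec <- cohort_spec(n_patients = 2000, n_proteins = 20,
                      planted_sets = list(
                        list(tissue = "tumor", direction = "unfavorable",
                             size = 10, log_hr_per_sd = log(2))),
                      missing_fraction = 0, seed = 11)
  co <- generate_cohort(spec)
  x <- unclass(co$tumor)
  sm <- colMeans(x[co$truth$protein_id, ])
  z <- (sm - mean(sm)) / sqrt(spec$pathway_block_correlation +
                              (1 - spec$pathway_block_correlation) / 10)
  fit <- cox_fit(cbind(risk = z), co$clinical$dfs_time, co$clinical$dfs_event)
  expect_equal(fit$coefficients$coef, log(2), tolerance = 0.1 * log(2))
})

test_that("null screening shows the documented optimal-cutoff inflation", {
  spec <- cohort_spec(n_patients = 120, n_proteins = 120,
                      planted_sets = list(), missing_fraction = 0, seed = 12)
  co <- generate_cohort(spec)
  rrp <- screen_rrps(co$tumor, co$clinical, tissue = "tumor")
  expect_gte(mean(rrp$significant), 0.05)   # inflated well above nominal alpha
})

test_that("treatment simulation powers the down classification", {
  rates <- vapply(1:5, function(s) {
    st <- generate_treatment_study(n_proteins = 150, n_per_arm = 14,
                                   effect_sets = 50, log_fc = -1, seed = s)
    res <- groupwise_diff(st$matrix, st$labels, ref_level = "treated")
    mean(res$class[res$protein_id %in% st$truth] == "down")
  }, 0)
  expect_gte(mean(rates), 0.7)

  # no effect: class calls near the nominal rate
  st0 <- generate_treatment_study(n_proteins = 300, n_per_arm = 14,
                                  effect_sets = 50, log_fc = 0, seed = 20)
  res0 <- groupwise_diff(st0$matrix, st0$labels, ref_level = "treated")
  expect_lt(mean(res0$class != "ns"), 0.12)

  # permuting arm labels destroys the planted enrichment
  st <- generate_treatment_study(n_proteins = 150, n_per_arm = 14,
                                 effect_sets = 50, log_fc = -1, seed = 21)
  set.seed(1)
  perm <- sample(st$labels)
  resp <- groupwise_diff(st$matrix, perm, ref_level = "treated")
  down_p <- resp$protein_id[resp$class == "down"]
  expect_lt(length(intersect(down_p, st$truth)),
            length(st$truth) * 0.2)
})

test_that("IHC cohorts stain tumors more strongly than NATs", {
  means <- vapply(1:5, function(s) {
    sim <- generate_ihc_cohort(n = 80, seed = s)
    tapply(sim$records$score, sim$records$tissue, mean)[c("tumor", "nat")]
  }, numeric(2))
  expect_true(all(means["tumor", ] > means["nat", ]))
  expect_error(generate_ihc_cohort(n = 10), "n >= 20")
})
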