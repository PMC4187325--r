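test_that("time-window censoring follows the boundary rules exactly", {
  rec <- data.frame(time = c(3, 7, 10, 5), event = c(1, 1, 0, 1))
  late <- censor_late(rec, 5)
  expect_equal(late$event, c(0, 1, 0, 1))   # early event censored at 3
  expect_equal(late$time, rec$time)          # times never change
  early <- censor_early(rec, 5)
  expect_equal(early$event, c(1, 0, 0, 0))   # "at or after" includes 5 years
  expect_error(censor_late(data.frame(time = -1, event = 1)), "negative")
})

test_that("the two window transforms partition events and are idempotent", {
  set.seed(101)
  for (i in 1:20) {
    rec <- data.frame(time = stats::runif(50, 0, 15),
                      event = stats::rbinom(50, 1, 0.5))
    e <- censor_early(rec, 5); l <- censor_late(rec, 5)
    expect_equal(e$event + l$event, rec$event)            # partition
    expect_identical(censor_early(e, 5), e)               # idempotence
    expect_identical(censor_late(l, 5), l)
  }
})

test_that("the Cox coefficient matches a brute-force partial likelihood", {
  rec <- data.frame(time = 1:6, event = c(1, 1, 1, 0, 0, 0))
  x <- c(1, 0, 1, 0, 1, 0)
  fit <- cox_univariable(x, rec)
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, partial_loglik, numeric(1),
               time = rec$time, event = rec$event, x = x)
  expect_equal(fit$coef, grid[which.max(ll)], tolerance = 2e-4)
  # negating the covariate negates the coefficient, p unchanged
  fit_neg <- cox_univariable(-x, rec)
  expect_equal(fit_neg$coef, -fit$coef, tolerance = 1e-10)
  expect_equal(fit_neg$p, fit$p, tolerance = 1e-12)
})

test_that("degenerate Cox inputs are rejected", {
  rec <- data.frame(time = 1:6, event = c(1, 1, 1, 0, 0, 0))
  expect_error(cox_univariable(rep(2, 6), rec), "zero-variance")
  expect_error(cox_univariable(rnorm(6),
                               data.frame(time = 1:6, event = rep(0, 6))),
               "no events")
})

test_that("screen p-values are invariant under affine expression rescaling", {
  co <- generate_cohort(small_spec(seed = 6, samples_per_study = 80))
  x <- co$expression[co$truth$late_probes[1:5], ]
  scr1 <- screen_genome(x, co$clinical)
  x2 <- x; x2$values <- 3 * x2$values + 7
  scr2 <- screen_genome(x2, co$clinical)
  expect_equal(scr2$p_overall, scr1$p_overall, tolerance = 1e-8)
  expect_equal(scr2$coef_late, scr1$coef_late / 3, tolerance = 1e-6)
})

test_that("the three-scheme screen recovers planted late genes cleanly", {
  co <- generate_cohort(cohort_spec(seed = 5))  # 800 bulk samples
  x <- co$expression
  bulk <- which(x$samples$tissue == "bulk")
  scr <- screen_genome(x[, bulk], co$clinical, threshold = 0.001)
  late_hit <- scr$probe_id[!is.na(scr$p_late) & scr$p_late < 0.001]
  sens <- mean(co$truth$late_probes %in% late_hit)
  leak <- mean(co$truth$early_probes %in% late_hit)
  expect_gte(sens, 0.7)
  expect_lte(leak, 0.05)
  # null probes cross the threshold at about the nominal rate
  null_ids <- setdiff(scr$probe_id,
                      c(co$truth$early_probes, co$truth$late_probes,
                        co$truth$marker_probes, co$truth$subtype_probes))
  p_null <- scr$p_overall[scr$probe_id %in% null_ids]
  hits <- sum(p_null < 0.001, na.rm = TRUE)
  bounds <- stats::qbinom(c(0.005, 0.995), sum(!is.na(p_null)), 0.001)
  expect_gte(hits, bounds[1]); expect_lte(hits, bounds[2])
  # a zero threshold selects nothing
  scr0 <- screen_genome(x[co$truth$late_probes[1:3], bulk], co$clinical,
                        threshold = 0)
  expect_true(all(scr0$category == "neither"))
})

test_that("constant probes are reported as 'neither' with a reason", {
  co <- generate_cohort(small_spec(seed = 6, samples_per_study = 40))
  x <- co$expression[co$truth$late_probes[1:3], ]
  x$values[2, ] <- 5
  scr <- screen_genome(x, co$clinical)
  expect_identical(scr$category[2], "neither")
  expect_match(scr$note[2], "zero variance")
})

test_that("adjustment for constant covariates reduces to the univariable fit", {
  co <- generate_cohort(small_spec(seed = 14, samples_per_study = 70))
  cl <- co$clinical[co$clinical$tissue == "bulk", ]
  x <- co$expression$values[co$truth$early_probes[1],
                            match(cl$sample_id,
                                  co$expression$samples$sample_id)]
  rec <- data.frame(time = cl$rfs_years, event = cl$rfs_event)
  uni <- cox_univariable(x, rec)
  covs <- data.frame(size = rep(2, nrow(cl)), grade = rep(3, nrow(cl)))
  adj <- suppressWarnings(cox_adjusted(x, rec, covs))
  expect_equal(adj$p, uni$p, tolerance = 1e-8)
  expect_setequal(adj$dropped, c("size", "grade"))
  expect_error(cox_adjusted(x, rec, data.frame()), "empty covariate table")
})

test_that("adjusting for a real confounder weakens a spurious association", {
  set.seed(9)
  n <- 400
  grade <- stats::rbinom(n, 1, 0.5)
  expr <- grade + stats::rnorm(n, sd = 0.7)   # expression only via grade
  t <- stats::rexp(n, rate = 0.08 * exp(1.0 * grade))
  rec <- data.frame(time = pmin(t, 15), event = as.integer(t < 15))
  uni <- cox_univariable(expr, rec)
  adj <- cox_adjusted(expr, rec, data.frame(grade = grade))
  expect_gt(adj$p, uni$p)
})

test_that("clinical-parameter Cox estimates a known hazard ratio", {
  sim <- sim_two_group(1000, hr = 2, seed = 13)
  cl <- data.frame(sample_id = sprintf("s%04d", seq_len(nrow(sim))),
                   rfs_years = sim$time, rfs_event = sim$event,
                   size_cm = ifelse(sim$group == 1, 3, 1),
                   grade = 1, age = 60)
  est <- clinical_param_cox(cl, "size", scheme = "overall")
  expect_gt(est$hr, 1.7); expect_lt(est$hr, 2.35)
  expect_equal(est$n, 1000)
  # swapping the group labels inverts the HR and mirrors the CI
  cl2 <- cl; cl2$size_cm <- ifelse(sim$group == 1, 1, 3)
  inv <- clinical_param_cox(cl2, "size", scheme = "overall")
  expect_equal(inv$hr, 1 / est$hr, tolerance = 1e-8)
  expect_equal(sort(inv$ci), sort(1 / est$ci), tolerance = 1e-8)
})

test_that("a group-balanced outcome gives a hazard ratio near 1", {
  set.seed(77)
  t <- stats::rexp(300, 0.1)
  # both groups carry identical survival data (paired construction)
  cl <- data.frame(sample_id = sprintf("s%03d", 1:600),
                   rfs_years = rep(pmin(t, 15), 2),
                   rfs_event = rep(as.integer(t < 15), 2),
                   size_cm = rep(c(1, 3), each = 300), grade = 1, age = 60)
  est <- clinical_param_cox(cl, "size")
  expect_equal(est$hr, 1, tolerance = 1e-6)
  expect_error(clinical_param_cox(cl[1:300, ], "size"), "one-level")
})

test_that("the late screen keeps its nominal type-I rate", {
  co <- generate_cohort(cohort_spec(
    n_studies = 2, samples_per_study = 200, n_probes = 2300,
    n_control_probes = 5, n_batch_factors = 0, n_early_genes = 20,
    n_late_genes = 20, n_stromal_probes = 5, stroma_pairs = 0, seed = 8))
  x <- co$expression
  null_ids <- setdiff(x$probes$probe_id[!x$probes$is_control],
                      c(co$truth$early_probes, co$truth$late_probes,
                        co$truth$marker_probes, co$truth$subtype_probes))
  null_ids <- null_ids[seq_len(2000)]
  scr <- screen_genome(x[null_ids, ], co$clinical)
  rate <- mean(scr$p_late < 0.05, na.rm = TRUE)
  expect_gte(rate, 0.035); expect_lte(rate, 0.065)
})
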