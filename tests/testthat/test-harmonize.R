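test_that("platform intersection keeps common probes in first-input order", {
  m1 <- make_expr(matrix(1:12, 3, 4,
                         dimnames = list(c("A", "B", "C"), paste0("x", 1:4))))
  m2 <- make_expr(matrix(13:24, 3, 4,
                         dimnames = list(c("B", "C", "D"), paste0("y", 1:4))),
                  study = "s2")
  # identical probe sets: plain concatenation keeping every probe
  m1b <- make_expr(matrix(31:38, 2, 4,
                          dimnames = list(c("A", "B"), paste0("w", 1:4))),
                   study = "s4")
  m1a <- make_expr(matrix(1:8, 2, 4,
                          dimnames = list(c("A", "B"), paste0("v", 1:4))))
  same <- intersect_platforms(list(m1a, m1b))
  expect_identical(same$probes$probe_id, c("A", "B"))
  expect_equal(ncol(same$values), 8)
  out <- intersect_platforms(list(m1, m2))
  expect_identical(out$probes$probe_id, c("B", "C"))
  expect_equal(ncol(out$values), 8)
  expect_identical(out$values["B", "y1"], m2$values["B", "y1"])
  # three-way intersection against explicit set operations
  m3 <- make_expr(matrix(1:8, 2, 4,
                         dimnames = list(c("C", "B"), paste0("z", 1:4))),
                  study = "s3")
  out3 <- intersect_platforms(list(m1, m2, m3))
  brute <- intersect(intersect(c("A", "B", "C"), c("B", "C", "D")),
                     c("C", "B"))
  expect_setequal(out3$probes$probe_id, brute)
  expect_identical(out3$probes$probe_id, c("B", "C"))  # first-input order
  expect_error(intersect_platforms(list(m1, make_expr(
    matrix(1:4, 2, 2, dimnames = list(c("Y", "Z"), c("q1", "q2")))))),
    "empty probe intersection")
})

test_that("duplicate sample IDs across studies are rejected", {
  m1 <- make_expr(matrix(1:4, 2, 2,
                         dimnames = list(c("A", "B"), c("s1", "s2"))))
  expect_error(intersect_platforms(list(m1, m1)), "duplicate sample IDs")
})

test_that("a rank-1 control pattern is fully captured by one component", {
  pattern <- sin(seq_len(30))
  ctrl <- outer(rep(1, 10), pattern) + 5     # identical shape per probe
  bio <- matrix(rnorm(40 * 30), 40, 30)
  x <- make_expr(rbind(ctrl, bio), is_control = rep(c(TRUE, FALSE), c(10, 40)))
  model <- fit_control_structure(x, 1)
  pc <- stats::prcomp(t(x$values[1:10, ]), center = TRUE)
  expect_gte(pc$sdev[1]^2 / sum(pc$sdev^2), 1 - 1e-12)
  expect_equal(ncol(model$component_scores), 1)
})

test_that("control PCs recover the planted batch-factor subspace", {
  co <- generate_cohort(cohort_spec(seed = 11))
  x <- co$expression
  model <- fit_control_structure(x, 3)
  planted <- co$truth$batch_scores           # n x 3 per-sample factor scores
  planted <- sweep(planted, 2, colMeans(planted))
  # largest principal angle between the two 3-dim sample subspaces
  qs <- qr.Q(qr(model$component_scores))
  qp <- qr.Q(qr(planted))
  angles <- acos(pmin(1, svd(crossprod(qs, qp))$d)) * 180 / pi
  expect_lt(max(angles), 5)
})

test_that("structure removal leaves residuals orthogonal to the scores", {
  co <- generate_cohort(small_spec(seed = 13))
  x <- co$expression
  model <- fit_control_structure(x, 2)
  res <- remove_structure(x, model)
  cors <- stats::cor(t(res$values), model$component_scores)
  expect_lt(max(abs(cors)), 1e-8)
  # metadata and dimensions untouched
  expect_identical(res$probes, x$probes)
  expect_identical(res$samples, x$samples)
  expect_identical(dim(res$values), dim(x$values))
})

test_that("fit + remove is idempotent and a 0-component model is identity", {
  co <- generate_cohort(small_spec(seed = 13))
  x <- co$expression
  model <- fit_control_structure(x, 2)
  r1 <- remove_structure(x, model)
  r2 <- remove_structure(r1, model)
  rms <- sqrt(mean((r1$values - r2$values)^2))
  expect_lt(rms, 1e-10)
  m0 <- fit_control_structure(x, 0)
  expect_identical(remove_structure(x, m0)$values, x$values)
})

test_that("removal shrinks the leading control-probe variance share", {
  co <- generate_cohort(cohort_spec(seed = 11))
  x <- co$expression
  ctrl_frac <- function(m) {
    pc <- stats::prcomp(t(m$values[m$probes$is_control, ]), center = TRUE)
    pc$sdev[1]^2 / sum(pc$sdev^2)
  }
  before <- ctrl_frac(x)
  after <- ctrl_frac(remove_structure(x, fit_control_structure(x, 3)))
  expect_lt(after, 0.05 * before)
})

test_that("removal without planted batch structure barely touches the data", {
  co <- generate_cohort(small_spec(seed = 17, n_batch_factors = 0,
                                   samples_per_study = 100))
  x <- co$expression
  k <- 5
  res <- remove_structure(x, fit_control_structure(x, k))
  msq <- mean((res$values - x$values)^2)
  n <- ncol(x$values)
  # projecting noise onto k of n dimensions removes ~ var * k/n
  expect_lt(msq, 2 * 1^2 * k / n)
})

test_that("the mixing statistic detects and loses a planted study shift", {
  set.seed(3)
  base <- matrix(rnorm(200 * 90), 200, 90)
  ctrl <- matrix(rnorm(20 * 90, sd = 0.1), 20, 90)
  shift <- c(rep(0, 45), rep(5, 45))               # one study shifted by 5 SD
  vals <- rbind(ctrl + rep(shift, each = 20), base + rep(shift, each = 200))
  x <- make_expr(vals, is_control = rep(c(TRUE, FALSE), c(20, 200)),
                 study = rep(c("sA", "sB"), each = 45))
  mix_pre <- confirm_mixing(x)
  expect_gt(mix_pre$variance_ratio, 0.5)
  cleaned <- remove_structure(x, fit_control_structure(x, 2))
  mix_post <- confirm_mixing(cleaned)
  expect_lt(mix_post$variance_ratio, mix_pre$variance_ratio / 10)
})

test_that("identical study distributions sit inside the permutation band", {
  set.seed(42)
  vals <- matrix(rnorm(150 * 80), 150, 80)
  x <- make_expr(vals, study = rep(c("sA", "sB"), each = 40))
  mix <- confirm_mixing(x)
  perm <- replicate(999, variance_ratio(mix$embedding[, 1],
                                        sample(mix$study)))
  expect_lt(mix$variance_ratio, stats::quantile(perm, 0.995))
  expect_error(confirm_mixing(make_expr(vals)), "single study")
})

test_that("harmonization models serialize losslessly to tab files", {
  co <- generate_cohort(small_spec(seed = 23, samples_per_study = 30,
                                   n_probes = 100))
  model <- fit_control_structure(co$expression, 2)
  prefix <- file.path(withr::local_tempdir(), "model")
  write_harmonization_model(model, prefix)
  back <- read_harmonization_model(prefix)
  expect_equal(back$component_scores, model$component_scores)
  expect_equal(back$removal_coefficients, model$removal_coefficients,
               ignore_attr = TRUE)
})
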