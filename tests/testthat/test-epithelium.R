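# constructed cascade fixture: probes either have all three signature
# properties (stroma-score correlation, target upregulation, direct
# recurrence association) or exactly two of them
build_cascade_fixture <- function(seed = 41, n_pairs = 40, n_disc = 300) {
  set.seed(seed)
  v <- rnorm(n_pairs)                     # stromal activation score
  # subgroup labels independent of v, so each filter can fail on its own
  grp <- factor(ifelse(runif(n_pairs) < 0.3, "G4", "rest"),
                levels = c("G4", "rest"))
  risk <- rnorm(n_disc)                   # discovery-cohort hazard driver
  probes <- c(sprintf("all3_%02d", 1:30), sprintf("no_cox_%02d", 1:10),
              sprintf("no_de_%02d", 1:10), sprintf("no_r_%02d", 1:10))
  shift <- 3 * (grp == "G4")
  epi <- matrix(rnorm(60 * n_pairs, sd = 0.4), 60, n_pairs,
                dimnames = list(probes, sprintf("e%03d", 1:n_pairs)))
  disc <- matrix(rnorm(60 * n_disc, sd = 0.4), 60, n_disc,
                 dimnames = list(probes, sprintf("d%03d", 1:n_disc)))
  has_r <- !grepl("^no_r", probes)
  has_de <- !grepl("^no_de", probes)
  has_cox <- !grepl("^no_cox", probes)
  epi[has_r, ] <- epi[has_r, ] + rep(v, each = sum(has_r))
  # probes lacking the correlation property load negatively on v, so the
  # r > r_min filter fails deterministically rather than by chance
  epi[!has_r, ] <- epi[!has_r, ] - 0.5 * rep(v, each = sum(!has_r))
  epi[has_de, ] <- epi[has_de, ] + rep(shift, each = sum(has_de))
  disc[has_cox, ] <- disc[has_cox, ] + rep(risk, each = sum(has_cox))
  # probes lacking the survival property get an inverse association, so
  # the "direct" requirement fails deterministically rather than by chance
  disc[!has_cox, ] <- disc[!has_cox, ] - 0.8 * rep(risk, each = sum(!has_cox))
  t_ <- rexp(n_disc, rate = 0.15 * exp(1.2 * risk))
  clinical <- data.frame(sample_id = colnames(disc),
                         rfs_years = pmin(t_, 15),
                         rfs_event = as.integer(t_ < 15))
  epi_x <- make_expr(epi, tissue = "epithelium",
                     pair_id = sprintf("pp%03d", 1:n_pairs))
  str_x <- make_expr(matrix(rnorm(60 * n_pairs), 60, n_pairs,
                            dimnames = list(probes,
                                            sprintf("t%03d", 1:n_pairs))),
                     tissue = "stroma", pair_id = sprintf("pp%03d", 1:n_pairs))
  joint <- intersect_platforms(list(epi_x, str_x))
  pairs <- paired_compartments(joint)
  spc1 <- structure(list(name = "SPC1", probe_ids = character(0),
                         loadings = numeric(0),
                         scores = setNames(v, str_x$samples$sample_id),
                         var_explained = 1, sign_anchor = "fixture"),
                    class = "metagene_score")
  groups <- setNames(grp, epi_x$samples$sample_id)
  disc_x <- make_expr(disc)
  list(pairs = pairs, spc1 = spc1, groups = groups, disc_x = disc_x,
       clinical = clinical)
}

test_that("the cascade keeps exactly the probes with all three properties", {
  fx <- build_cascade_fixture(seed = 41)
  sig <- cascade_select(fx$pairs, fx$spc1, fx$groups, fx$disc_x,
                        fx$clinical)
  expect_setequal(sig$probe_id, sprintf("all3_%02d", 1:30))
  expect_true(all(diff(sig$r) <= 0))         # ordered by descending r
  # unattainable correlation threshold: empty signature with a warning
  expect_warning(
    empty <- cascade_select(fx$pairs, fx$spc1, fx$groups, fx$disc_x,
                            fx$clinical,
                            criteria = cascade_criteria(r_min = 0.999)),
    "no probe")
  expect_equal(nrow(empty), 0)
})

test_that("cascade selection is monotone in each threshold", {
  fx <- build_cascade_fixture(seed = 43)
  base <- cascade_select(fx$pairs, fx$spc1, fx$groups, fx$disc_x,
                         fx$clinical,
                         criteria = cascade_criteria(0.3, 0.02, 0.005))
  for (crit in list(cascade_criteria(0.25, 0.02, 0.005),
                    cascade_criteria(0.3, 0.05, 0.005),
                    cascade_criteria(0.3, 0.02, 0.01))) {
    relaxed <- cascade_select(fx$pairs, fx$spc1, fx$groups, fx$disc_x,
                              fx$clinical, criteria = crit)
    expect_true(all(base$probe_id %in% relaxed$probe_id))
  }
})

test_that("metastasis-timing groups follow the follow-up rules", {
  cl <- data.frame(sample_id = c("a", "b", "c", "d", "e"),
                   dmfs_years = c(16, 4, 9, 8, 5),
                   dmfs_event = c(0, 1, 1, 0, 1))
  tg <- timing_groups(cl)
  expect_identical(as.character(tg),
                   c("none", "early", "late", NA, "late"))
  # partition: nobody lands in two groups, short-follow-up excluded
  expect_equal(sum(!is.na(tg)), 4)
  expect_error(timing_groups(cl, boundary = -1), "positive")
  expect_error(timing_groups(data.frame(sample_id = "a")), "DMFS")
})

test_that("signature scores separate timing groups on planted cohorts", {
  co <- generate_cohort(cohort_spec(n_studies = 4, samples_per_study = 500,
                                    seed = 45))
  x <- co$expression
  tum <- which(x$samples$tissue != "stroma")
  epc1 <- first_pc_score(x[, tum], co$truth$late_probes_direct,
                         name = "EPC1")
  tg <- timing_groups(co$clinical)
  times <- setNames(co$clinical$dmfs_years, co$clinical$sample_id)
  val <- validate_signature(epc1, tg, times = times)
  pw <- val$pairwise
  late_early <- pw[pw$comparison == "early vs late", ]
  expect_lt(late_early$p, 0.01)
  g <- tg[names(epc1$scores)]
  expect_gt(stats::median(epc1$scores[g == "late"], na.rm = TRUE),
            stats::median(epc1$scores[g == "early"], na.rm = TRUE))
  expect_lt(val$anova_p, 0.01)
})

test_that("validation p-values are calibrated and rank-invariant", {
  set.seed(43)
  groups <- factor(rep(c("none", "early", "late"), each = 20),
                   levels = c("none", "early", "late"))
  names(groups) <- sprintf("s%03d", 1:60)
  attr(groups, "params") <- c(boundary = 5, long_followup = 15)
  ps <- replicate(200, {
    s <- setNames(rnorm(60), names(groups))
    pw <- validate_signature(s, groups)$pairwise
    pw$p[pw$comparison == "early vs late"]
  })
  # exact rank-test p-values are discrete, hence tied; suppress the KS
  # ties warning
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  # strictly monotone transforms leave the rank-based p unchanged
  s <- setNames(rnorm(60), names(groups))
  p1 <- validate_signature(s, groups)$pairwise$p
  p2 <- validate_signature(exp(2 * s) + 1, groups)$pairwise$p
  expect_equal(p1, p2, tolerance = 1e-12)
  # singleton group errors
  g1 <- groups; g1[22:40] <- "none"   # leaves one early sample
  expect_error(validate_signature(s, g1), "fewer than 2")
})

test_that("concordance reflects shared latent structure", {
  set.seed(47)
  n <- 200
  f <- rnorm(n)
  m1 <- outer(rep(1, 10), 0.9 * f) + matrix(rnorm(10 * n, sd = sqrt(1 - 0.81)), 10, n)
  m2 <- outer(rep(1, 10), 0.9 * f) + matrix(rnorm(10 * n, sd = sqrt(1 - 0.81)), 10, n)
  x <- make_expr(rbind(m1, m2))
  conc <- concordance_scores(x, rownames(x$values)[1:10],
                             rownames(x$values)[11:20])
  expect_gt(conc$r, 0.8)
  # identical probe sets: r is exactly 1
  same <- concordance_scores(x, rownames(x$values)[1:10],
                             rownames(x$values)[1:10])
  expect_equal(same$r, 1, tolerance = 1e-12)
  # independent factors: near-zero correlation
  set.seed(49)
  a1 <- outer(rep(1, 10), rnorm(n)) + matrix(rnorm(10 * n, sd = 0.4), 10, n)
  a2 <- outer(rep(1, 10), rnorm(n)) + matrix(rnorm(10 * n, sd = 0.4), 10, n)
  x2 <- make_expr(rbind(a1, a2))
  conc2 <- concordance_scores(x2, rownames(x2$values)[1:10],
                              rownames(x2$values)[11:20])
  expect_lt(abs(conc2$r), 2 / sqrt(n))
})
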