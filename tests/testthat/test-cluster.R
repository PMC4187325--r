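test_that("duplicate profiles merge first at height zero", {
  set.seed(1)
  m <- matrix(rnorm(5 * 12), 5, 12)
  m[3, ] <- m[1, ]
  fit <- centroid_hclust(m)
  expect_equal(fit$height[1], 0, tolerance = 1e-12)
  expect_setequal(fit$merge[1, ], c(-1, -3))
})

test_that("two planted orthogonal blocks are recovered exactly", {
  set.seed(2)
  m <- matrix(0, 6, 6)
  m[1:3, 1:3] <- 5; m[4:6, 4:6] <- 5
  m <- m + matrix(rnorm(36, sd = 0.3), 6, 6)
  fit <- centroid_hclust(m)
  labels <- as.integer(cut_dendrogram(fit, 2))
  expect_true(same_partition(labels, rep(1:2, each = 3)))
  expect_true(all(table(labels, rep(1:2, each = 3)) %in% c(0, 3)))
})

test_that("centroid linkage agrees with a quadratic-time re-agglomeration", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(5:8, 1)
    m <- matrix(rnorm(n * 7), n, 7)
    for (dist_ in c("correlation", "euclidean")) {
      fit <- centroid_hclust(m, dist_)
      orc <- oracle_centroid(m, dist_)
      expect_equal(fit$height, orc$heights, tolerance = 1e-10)
      for (k in 2:(n - 1)) {
        expect_true(same_partition(as.integer(cut_dendrogram(fit, k)),
                                   oracle_cut(orc, n, k)))
      }
    }
  }
})

test_that("cutting at k = n makes every item its own group", {
  set.seed(3)
  m <- matrix(rnorm(6 * 8), 6, 8)
  x <- make_expr(m)
  gr <- cluster_two_way(x, k_samples = 8, k_probes = 6)
  expect_equal(length(unique(gr$sample_groups)), 8)
  expect_equal(length(unique(gr$probe_clusters)), 6)
  # constant rows are dropped with a warning under correlation distance
  m2 <- m; m2[2, ] <- 1
  expect_warning(cluster_two_way(make_expr(m2), 2, 2, center_probes = FALSE),
                 "constant probe")
})

test_that("printed enrichment tables are reproduced from their counts", {
  # group of 88 with 85 members vs 676 outside with 449 members
  g1 <- enrichment_2x2(85, 3, 449, 227)
  expect_equal(g1$odds_ratio, 14.3244, tolerance = 1e-4)
  expect_equal(g1$ci_high, 45.8043, tolerance = 1e-3)
  expect_equal(g1$fisher_p, 4.90e-11, tolerance = 0.02)
  g4 <- enrichment_2x2(15, 128, 113, 508)
  expect_equal(g4$odds_ratio, 0.5268, tolerance = 1e-3)
  u <- enrichment_2x2(1, 1, 1, 1)
  expect_equal(u$odds_ratio, 1)
  expect_equal(u$fisher_p, 1)
})

test_that("enrichment obeys its symmetry and containment properties", {
  set.seed(8)
  for (i in 1:25) {
    cells <- stats::rpois(4, 8) + 1
    e <- enrichment_2x2(cells[1], cells[2], cells[3], cells[4])
    # swapping both rows and both columns leaves OR and p unchanged
    sw <- enrichment_2x2(cells[4], cells[3], cells[2], cells[1])
    expect_equal(sw$odds_ratio, e$odds_ratio, tolerance = 1e-12)
    expect_equal(sw$fisher_p, e$fisher_p, tolerance = 1e-12)
    # swapping rows only inverts the OR
    rs <- enrichment_2x2(cells[3], cells[4], cells[1], cells[2])
    expect_equal(rs$odds_ratio, 1 / e$odds_ratio, tolerance = 1e-12)
    # the Woolf interval contains the point estimate
    expect_lte(e$ci_low, e$odds_ratio)
    expect_gte(e$ci_high, e$odds_ratio)
    # Fisher p against exhaustive hypergeometric enumeration
    expect_equal(e$fisher_p,
                 fisher_enum(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
})

test_that("zero cells flag the continuity correction and degenerate margins error", {
  e <- enrichment_2x2(0, 10, 5, 20)
  expect_equal(e$odds_ratio, 0)
  expect_true(e$continuity)
  expect_true(is.finite(e$ci_low) && is.finite(e$ci_high))
  e2 <- enrichment_2x2(5, 0, 3, 20)
  expect_equal(e2$odds_ratio, Inf)
  expect_error(enrichment_2x2(0, 0, 5, 5), "margin")
  expect_error(enrichment_2x2(2, -1, 5, 5), "nonnegative")
})

test_that("cluster-category enrichment matches direct arithmetic", {
  # planted construction: 25-probe cluster with 20 late-direct members,
  # 200 other probes with 10 late-direct
  n <- 225
  ids <- sprintf("p%03d", seq_len(n))
  clusters <- factor(rep(c("C1", "C2"), c(25, 200)))
  names(clusters) <- ids
  screen <- data.frame(
    probe_id = ids,
    coef_early = 0.1, p_early = 1,
    coef_late = 1, p_late = 1, stringsAsFactors = FALSE)
  screen$p_late[c(1:20, 26:35)] <- 1e-5
  screen$p_early[36:40] <- 1e-5          # early-direct exists only outside
  attr(screen, "threshold") <- 0.001
  res <- cluster_category_enrichment(clusters, screen)
  row <- res[res$cluster == "C1" & res$category == "late-direct", ]
  expect_equal(row$a, 20)
  expect_equal(row$odds_ratio, (20 * 190) / (5 * 10))
  # a category empty inside the cluster: zero-cell OR with continuity flag
  row0 <- res[res$cluster == "C1" & res$category == "early-direct", ]
  expect_equal(row0$odds_ratio, 0)
  expect_true(row0$continuity)
})

test_that("log-rank separates groups exactly when hazards differ", {
  sim <- sim_two_group(400, hr = 3, seed = 17)
  cl <- data.frame(sample_id = sprintf("s%03d", seq_len(400)),
                   rfs_years = sim$time, rfs_event = sim$event)
  groups <- factor(ifelse(sim$group == 1, "high", "low"))
  names(groups) <- cl$sample_id
  km <- km_logrank(cl, groups)
  expect_lt(km$p, 0.001)
  expect_equal(km$df, 1)
  # duplicated data in both groups: no difference, p = 1
  cl2 <- data.frame(sample_id = sprintf("d%03d", seq_len(400)),
                    rfs_years = rep(sim$time[1:200], 2),
                    rfs_event = rep(sim$event[1:200], 2))
  g2 <- factor(rep(c("a", "b"), each = 200))
  names(g2) <- cl2$sample_id
  km2 <- km_logrank(cl2, g2)
  expect_equal(km2$chisq, 0, tolerance = 1e-12)
  expect_equal(km2$p, 1, tolerance = 1e-12)
  expect_error(km_logrank(cl, factor(setNames(rep("a", 400),
                                              cl$sample_id))),
               "two non-empty groups")
})
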