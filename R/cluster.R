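# distance between centroid profiles
.cdist <- function(a, B, distance) {
  # a: vector, B: matrix with items in rows; returns vector of distances
  if (distance == "correlation") {
    if (stats::sd(a) == 0) return(rep(1, nrow(B)))
    r <- suppressWarnings(stats::cor(a, t(B)))
    r[is.na(r)] <- 0
    1 - as.vector(r)
  } else {
    sqrt(colSums((t(B) - a)^2))
  }
}

#' Agglomerative clustering with true centroid linkage
#'
#' Hierarchical agglomeration in which the distance between two clusters
#' is the distance between their (size-weighted mean) centroid profiles,
#' recomputed after every merge — the behaviour of the classic gene
#' expression clustering tools, which differs from the Lance-Williams
#' "centroid" update (valid only for squared Euclidean distances) when a
#' correlation metric is used. Centroid linkage can produce height
#' inversions; they are permitted and counted.
#'
#' @param mat numeric matrix, items to cluster in rows.
#' @param distance `"correlation"` (1 - centered Pearson, the default) or
#'   `"euclidean"`.
#' @return An `hclust`-compatible object (`merge`, `height`, `order`,
#'   `labels`, `method = "centroid"`) with attribute `inversions` (number
#'   of height decreases along the merge sequence).
#' @export
centroid_hclust <- function(mat, distance = c("correlation", "euclidean")) {
  distance <- match.arg(distance)
  n <- nrow(mat)
  if (n < 2) stop("need at least 2 items to cluster")
  cent <- mat
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  id <- -seq_len(n)                       # hclust convention
  D <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) {
    d <- .cdist(cent[i, ], cent[(i + 1):n, , drop = FALSE], distance)
    D[i, (i + 1):n] <- D[(i + 1):n, i] <- d
  }
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    w <- which.min(D)                     # first minimum in column order
    j <- (w - 1) %/% n + 1
    i <- w - (j - 1) * n
    pair <- sort(c(id[i], id[j]))
    merge[s, ] <- if (pair[1] < 0 && pair[2] > 0) c(pair[1], pair[2]) else pair
    height[s] <- D[i, j]
    cent[i, ] <- (size[i] * cent[i, ] + size[j] * cent[j, ]) /
      (size[i] + size[j])
    size[i] <- size[i] + size[j]
    id[i] <- s
    active[j] <- FALSE
    D[j, ] <- D[, j] <- Inf
    others <- which(active & seq_len(n) != i)
    if (length(others)) {
      d <- .cdist(cent[i, ], cent[others, , drop = FALSE], distance)
      D[i, others] <- D[others, i] <- d
    }
    D[i, i] <- Inf
  }
  ord <- integer(0)
  walk <- function(k) {
    if (k < 0) return(-k)
    c(walk(merge[k, 1]), walk(merge[k, 2]))
  }
  ord <- walk(n - 1)
  out <- structure(
    list(merge = merge, height = height, order = ord,
         labels = rownames(mat), method = "centroid",
         dist.method = distance, call = match.call()),
    class = "hclust")
  attr(out, "inversions") <- sum(diff(height) < -1e-12)
  out
}

#' Cut a merge sequence into k clusters, labeled in dendrogram order
#'
#' Membership is taken from the state of the agglomeration after `n - k`
#' merges (not from a height threshold, so centroid inversions are
#' harmless). Cluster labels `<prefix>1..<prefix>k` are assigned by the
#' position of each cluster's first leaf in the dendrogram order.
#'
#' @param tree a [centroid_hclust()] (or any `hclust`) result.
#' @param k number of clusters.
#' @param prefix label prefix (`"G"` for sample groups, `"C"` for probe
#'   clusters).
#' @return Factor of labels, named by item.
#' @export
cut_dendrogram <- function(tree, k, prefix = "G") {
  n <- length(tree$order)
  stopifnot(k >= 1, k <= n)
  memb <- -seq_len(n)                      # cluster id per item
  if (n - k >= 1) {
    for (s in seq_len(n - k)) {
      for (m in tree$merge[s, ]) {
        memb[if (m < 0) -m else which(memb == m)] <- s
      }
    }
  }
  first_leaf <- vapply(unique(memb[tree$order]), function(cl)
    min(which(memb[tree$order] == cl)), numeric(1))
  lab_of <- stats::setNames(
    paste0(prefix, seq_along(first_leaf))[rank(first_leaf)],
    unique(memb[tree$order]))
  out <- factor(lab_of[as.character(memb)],
                levels = paste0(prefix, seq_len(k)))
  names(out) <- tree$labels
  out
}

#' Two-way centroid-linkage clustering of probes and samples
#'
#' Clusters samples (columns) and probes (rows) of a selected-probe
#' expression matrix by agglomerative centroid linkage under the
#' 1 - Pearson correlation distance, and cuts both trees to the requested
#' number of groups, mirroring the standard two-way heatmap analysis of a
#' prognostic probe set. Constant rows/columns (undefined correlation) are
#' dropped with a warning.
#'
#' @param x an [expr_matrix] restricted to the selected probes.
#' @param k_samples,k_probes number of sample groups / probe clusters
#'   (default 4 and 4).
#' @param distance `"correlation"` or `"euclidean"`.
#' @param center_probes subtract each probe's mean before clustering
#'   (default `TRUE`, the usual gene-centering step of heatmap clustering
#'   tools; without it the probes' shared baseline dominates sample-sample
#'   similarity).
#' @return An object of class `grouping_result`: `sample_groups` (factor
#'   `G1..Gk` named by sample), `probe_clusters` (factor `C1..Cm` named by
#'   probe), the two linkage trees, and the per-dimension inversion
#'   counts.
#' @export
cluster_two_way <- function(x, k_samples = 4, k_probes = 4,
                            distance = "correlation",
                            center_probes = TRUE) {
  stopifnot(inherits(x, "expr_matrix"))
  m <- x$values
  if (center_probes) m <- m - rowMeans(m)
  if (distance == "correlation") {
    bad_r <- apply(m, 1, stats::sd) == 0
    bad_c <- apply(m, 2, stats::sd) == 0
    if (any(bad_r)) {
      warning(sum(bad_r), " constant probe(s) dropped")
      m <- m[!bad_r, , drop = FALSE]
    }
    if (any(bad_c)) {
      warning(sum(bad_c), " constant sample(s) dropped")
      m <- m[, !bad_c, drop = FALSE]
    }
  }
  if (nrow(m) < k_probes || ncol(m) < k_samples)
    stop("fewer rows/columns than requested clusters")
  probe_tree <- centroid_hclust(m, distance)
  sample_tree <- centroid_hclust(t(m), distance)
  structure(
    list(sample_groups = cut_dendrogram(sample_tree, k_samples, "G"),
         probe_clusters = cut_dendrogram(probe_tree, k_probes, "C"),
         sample_tree = sample_tree, probe_tree = probe_tree,
         inversions = c(samples = attr(sample_tree, "inversions"),
                        probes = attr(probe_tree, "inversions"))),
    class = "grouping_result")
}

#' @export
print.grouping_result <- function(x, ...) {
  cat("grouping_result:\n  sample groups: ")
  print(table(x$sample_groups))
  cat("  probe clusters: ")
  print(table(x$probe_clusters))
  invisible(x)
}

#' 2x2 enrichment statistics (cross-product OR, Woolf CI, Fisher p)
#'
#' For the table `[[a, b], [c, d]]` (members/nonmembers inside the group
#' over members/nonmembers outside) computes the cross-product odds ratio
#' `ad/bc`, its Woolf-logit 95% confidence interval
#' `exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`, and the two-sided
#' Fisher exact p-value. With a zero cell the OR is reported as 0 or
#' infinity and the CI uses the Haldane-Anscombe 0.5 correction, with
#' `continuity = TRUE`.
#'
#' @param members_in_group,nonmembers_in_group,members_outside,nonmembers_outside
#'   nonnegative integer cells `a`, `b`, `c`, `d`; every margin must be
#'   positive.
#' @return An object of class `contingency_result`: `table`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `fisher_p`, `continuity`.
#' @export
enrichment_2x2 <- function(members_in_group, nonmembers_in_group,
                           members_outside, nonmembers_outside) {
  a <- members_in_group; b <- nonmembers_in_group
  c <- members_outside; d <- nonmembers_outside
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be nonnegative integers")
  tab <- matrix(cells, nrow = 2, byrow = TRUE,
                dimnames = list(c("in_group", "outside"),
                                c("member", "nonmember")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("every margin must be positive")
  continuity <- any(cells == 0)
  or <- (a * d) / (b * c)          # 0/Inf/NaN propagate for zero cells
  cc <- if (continuity) cells + 0.5 else cells
  se <- sqrt(sum(1 / cc))
  or_ci <- (cc[1] * cc[4]) / (cc[2] * cc[3])
  ci <- exp(log(or_ci) + c(-1, 1) * 1.96 * se)   # Woolf's 1.96, not qnorm
  p <- stats::fisher.test(tab)$p.value
  structure(list(table = tab, odds_ratio = or,
                 ci_low = ci[1], ci_high = ci[2],
                 fisher_p = p, continuity = continuity),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("2x2 enrichment: OR %.4f (95%% CI %.4f - %.4f), Fisher p %.3g%s\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$fisher_p,
              if (x$continuity) " [continuity-corrected CI]" else ""))
  invisible(x)
}

#' Enrichment of screen categories within probe clusters
#'
#' For every probe cluster and each of the four screen categories
#' (early/late association crossed with direct/inverse coefficient sign),
#' tests the 2x2 table of category membership against cluster membership.
#'
#' @param probe_clusters factor of cluster labels named by probe ID.
#' @param screen a [screen_genome()] result covering the clustered probes.
#' @param threshold p-value threshold defining category membership;
#'   defaults to the screen's own discovery threshold.
#' @return data.frame with one row per (cluster, category): cell counts,
#'   `odds_ratio`, `ci_low`, `ci_high`, `fisher_p`, `continuity`.
#' @export
cluster_category_enrichment <- function(probe_clusters, screen,
                                        threshold = NULL) {
  if (is.null(threshold)) threshold <- attr(screen, "threshold")
  probe_clusters <- probe_clusters[!is.na(probe_clusters)]
  idx <- match(names(probe_clusters), screen$probe_id)
  if (anyNA(idx)) stop("clustered probes missing from screen result")
  s <- screen[idx, ]
  cats <- list(
    `early-direct` = !is.na(s$p_early) & s$p_early < threshold &
      s$coef_early > 0,
    `early-inverse` = !is.na(s$p_early) & s$p_early < threshold &
      s$coef_early < 0,
    `late-direct` = !is.na(s$p_late) & s$p_late < threshold &
      s$coef_late > 0,
    `late-inverse` = !is.na(s$p_late) & s$p_late < threshold &
      s$coef_late < 0)
  res <- list()
  for (cl in levels(factor(probe_clusters))) {
    inside <- probe_clusters == cl
    if (!any(inside)) stop("empty cluster: ", cl)
    for (cat in names(cats)) {
      mem <- cats[[cat]]
      a <- sum(inside & mem); b <- sum(inside & !mem)
      c_ <- sum(!inside & mem); d <- sum(!inside & !mem)
      row <- data.frame(cluster = cl, category = cat, a = a, b = b,
                        c = c_, d = d, odds_ratio = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        fisher_p = NA_real_, continuity = NA,
                        stringsAsFactors = FALSE)
      ok <- tryCatch({
        e <- enrichment_2x2(a, b, c_, d)
        row$odds_ratio <- e$odds_ratio
        row$ci_low <- e$ci_low; row$ci_high <- e$ci_high
        row$fisher_p <- e$fisher_p; row$continuity <- e$continuity
        TRUE
      }, error = function(e) FALSE)
      if (!ok) row$continuity <- TRUE   # degenerate margin, flagged
      res[[length(res) + 1]] <- row
    }
  }
  do.call(rbind, res)
}

#' Kaplan-Meier curves and k-group log-rank test per sample group
#'
#' Applies the requested censoring scheme first, then computes per-group
#' Kaplan-Meier estimates and the (Mantel-Cox) log-rank chi-square.
#'
#' @param clinical data.frame with `sample_id` and endpoint columns.
#' @param groups factor of group labels named by sample ID (at least two
#'   non-empty groups).
#' @param scheme `"overall"`, `"early"` or `"late"`.
#' @param endpoint `"rfs"` or `"dmfs"`.
#' @param boundary early/late boundary in years.
#' @return List with `fit` (a `survfit` object), `chisq`, `df`, `p`,
#'   `scheme`, `n` per group.
#' @export
km_logrank <- function(clinical, groups, scheme = "overall",
                       endpoint = "rfs", boundary = 5) {
  scheme <- match.arg(scheme, c("overall", "early", "late"))
  groups <- groups[!is.na(groups)]
  ids <- intersect(names(groups), clinical$sample_id)
  g <- factor(groups[ids])
  if (nlevels(g) < 2) stop("need at least two non-empty groups")
  if (any(table(g) == 0)) stop("group with zero samples")
  cl <- clinical[match(ids, clinical$sample_id), ]
  records <- data.frame(time = cl[[paste0(endpoint, "_years")]],
                        event = cl[[paste0(endpoint, "_event")]])
  records <- switch(scheme, overall = records,
                    early = censor_early(records, boundary),
                    late = censor_late(records, boundary))
  sv <- survival::Surv(records$time, records$event)
  fit <- survival::survfit(sv ~ g)
  sd_ <- survival::survdiff(sv ~ g)
  df <- length(sd_$n) - 1
  list(fit = fit, chisq = unname(sd_$chisq), df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE),
       scheme = scheme, n = table(g))
}

#' Write groupings in the tab-delimited dialect
#'
#' @param grouping a [cluster_two_way()] result.
#' @param samples_file,probes_file output paths.
#' @return Invisibly, the two paths.
#' @export
write_grouping <- function(grouping, samples_file, probes_file) {
  utils::write.table(
    data.frame(sample_id = names(grouping$sample_groups),
               group = as.character(grouping$sample_groups)),
    samples_file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(probe_id = names(grouping$probe_clusters),
               cluster = as.character(grouping$probe_clusters)),
    probes_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(samples = samples_file, probes = probes_file))
}
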