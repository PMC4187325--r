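#' First-principal-component metagene score
#'
#' Standardizes each probe of the set to zero mean and unit variance
#' across samples, then scores every sample on the first principal
#' component of the standardized probe-subset matrix. The sign of a
#' principal component is arbitrary, so the orientation is anchored: the
#' score is flipped if necessary so that it correlates nonnegatively with
#' the mean standardized expression of the set's upregulated probes (all
#' probes, if no directions are supplied). Scores have zero mean over the
#' defining cohort.
#'
#' @param x an [expr_matrix].
#' @param probe_set character vector of probe IDs, or a data.frame with
#'   columns `probe_id` and `direction` (`"up"`/`"down"`).
#' @param name metagene name recorded in the result (e.g. `"SPC1"`,
#'   `"EPC1"`).
#' @return An object of class `metagene_score`: `name`, `probe_ids` (those
#'   found and non-constant), `loadings`, `scores` (named per sample),
#'   `var_explained`, `sign_anchor`.
#' @export
first_pc_score <- function(x, probe_set, name = "PC1") {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.data.frame(probe_set)) {
    direction <- stats::setNames(probe_set$direction, probe_set$probe_id)
    probe_ids <- probe_set$probe_id
  } else {
    direction <- stats::setNames(rep("up", length(probe_set)), probe_set)
    probe_ids <- probe_set
  }
  missing_ids <- setdiff(probe_ids, x$probes$probe_id)
  found <- intersect(probe_ids, x$probes$probe_id)
  # a deliberate one-probe set degenerates to the standardized probe; an
  # incomplete set (probes absent from the matrix) is an error
  if (length(found) == 0 || (length(found) < 2 && length(missing_ids) > 0))
    stop("fewer than 2 probes of the set present; missing: ",
         paste(missing_ids, collapse = ", "))
  if (ncol(x$values) < 2) stop("need at least 2 samples")
  v <- x$values[found, , drop = FALSE]
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant probe(s) dropped from metagene")
    v <- v[sds > 0, , drop = FALSE]
    found <- rownames(v)
    if (nrow(v) < 2) stop("fewer than 2 non-constant probes")
  }
  z <- (v - rowMeans(v)) / apply(v, 1, stats::sd)
  if (length(found) == 1) {
    scores <- z[1, ]
    loadings <- stats::setNames(1, found)
    ve <- 1
  } else {
    pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
    scores <- pc$x[, 1]
    loadings <- pc$rotation[, 1]
    ve <- pc$sdev[1]^2 / sum(pc$sdev^2)
  }
  up <- found[direction[found] == "up"]
  if (!length(up)) up <- found
  anchor <- colMeans(z[up, , drop = FALSE])
  r <- suppressWarnings(stats::cor(scores, anchor))
  if (is.finite(r) && r < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  names(scores) <- x$samples$sample_id
  structure(list(
    name = name, probe_ids = found,
    loadings = stats::setNames(as.vector(loadings), found),
    scores = scores, var_explained = ve,
    sign_anchor = paste("score correlates nonnegatively with mean",
                        "standardized expression of the upregulated probes")),
    class = "metagene_score")
}

#' @export
print.metagene_score <- function(x, ...) {
  cat(sprintf("metagene_score %s: %d probes, %d samples, PC1 explains %.1f%%\n",
              x$name, length(x$probe_ids), length(x$scores),
              100 * x$var_explained))
  invisible(x)
}

#' Trend of a metagene score across outcome-ordered groups
#'
#' One-way ANOVA of the score across the ordered groups, Mann-Whitney
#' tests for each adjacent pair (exact when both groups have at most
#' `exact_max` samples and the data are tie-free, normal approximation
#' with continuity and tie correction otherwise; the method used is
#' recorded), and a monotone-trend summary (Spearman correlation of the
#' score with group rank).
#'
#' @param scores a [first_pc_score()] result or a named numeric vector.
#' @param groups factor (ordered by outcome class) named by sample ID;
#'   samples with `NA` group are dropped.
#' @param exact_max largest per-group size at which the exact Mann-Whitney
#'   distribution is used (default 25).
#' @return List with `anova_p`, `pairwise` (data.frame comparison /
#'   statistic / p / method), `trend_rho`, `trend_direction`, `n` per
#'   group.
#' @export
trend_across_groups <- function(scores, groups, exact_max = 25) {
  if (inherits(scores, "metagene_score")) scores <- scores$scores
  groups <- groups[!is.na(groups)]
  ids <- intersect(names(groups), names(scores))
  g <- factor(groups[ids])
  g <- droplevels(g)
  s <- scores[ids]
  if (nlevels(g) < 2) stop("need at least two groups")
  if (any(table(g) < 2)) stop("singleton group")
  anova_p <- stats::anova(stats::lm(s ~ g))[["Pr(>F)"]][1]
  lev <- levels(g)
  pw <- lapply(seq_len(nlevels(g) - 1), function(i) {
    s1 <- s[g == lev[i]]; s2 <- s[g == lev[i + 1]]
    exact <- max(length(s1), length(s2)) <= exact_max &&
      !anyDuplicated(c(s1, s2))
    wt <- suppressWarnings(
      stats::wilcox.test(s1, s2, exact = exact, correct = TRUE))
    data.frame(comparison = paste(lev[i], "vs", lev[i + 1]),
               statistic = unname(wt$statistic), p = wt$p.value,
               method = if (exact) "exact" else "normal approximation",
               stringsAsFactors = FALSE)
  })
  rho <- suppressWarnings(
    stats::cor(s, as.integer(g), method = "spearman"))
  list(anova_p = anova_p, pairwise = do.call(rbind, pw),
       trend_rho = rho,
       trend_direction = if (is.na(rho) || rho == 0) "flat"
                         else if (rho > 0) "increasing" else "decreasing",
       n = table(g))
}

#' Write a metagene signature / score in the tab-delimited dialect
#'
#' @param metagene a [first_pc_score()] result.
#' @param signature_file path for the (probe_id, loading) table.
#' @param score_file path for the (sample_id, score) table.
#' @return Invisibly, the two paths.
#' @export
write_metagene <- function(metagene, signature_file, score_file) {
  utils::write.table(
    data.frame(probe_id = metagene$probe_ids,
               loading = metagene$loadings[metagene$probe_ids]),
    signature_file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(metagene$scores),
               score = unname(metagene$scores)),
    score_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(signature = signature_file, scores = score_file))
}
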