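#' Thresholds of the three-filter epithelial signature cascade
#'
#' @param r_min minimum Pearson correlation between epithelial expression
#'   and the paired-stroma activation score (default 0.25; must lie in
#'   (0, 1)).
#' @param de_fdr FDR threshold for target-subgroup upregulation in the
#'   epithelium (default 0.05).
#' @param cox_p p-value threshold for direct recurrence association in
#'   the discovery cohort (default 0.01).
#' @return An object of class `cascade_criteria`.
#' @export
cascade_criteria <- function(r_min = 0.25, de_fdr = 0.05, cox_p = 0.01) {
  stopifnot(r_min > 0, r_min < 1, de_fdr > 0, de_fdr < 1,
            cox_p > 0, cox_p < 1)
  structure(list(r_min = r_min, de_fdr = de_fdr, cox_p = cox_p),
            class = "cascade_criteria")
}

#' Three-filter cascade for the epithelial stromal-activation signature
#'
#' Selects epithelial probes that are simultaneously (a) correlated with
#' the paired-stroma activation score (Pearson r > `r_min`), (b)
#' specifically upregulated in the target epithelium subgroup (two-sample
#' t-test, BH q < `de_fdr`, positive direction), and (c) directly (positive
#' coefficient) associated with recurrence in the discovery cohort
#' (univariable Cox, p < `cox_p`). The three filters are intersections, so
#' their order is irrelevant; probes are returned in descending order of
#' the correlation in (a).
#'
#' @param pairs a [paired_compartments()] result.
#' @param spc1 a [first_pc_score()] result on the stroma samples (the
#'   stromal-activation score).
#' @param groups factor of subgroup labels named by epithelium sample ID.
#' @param discovery_x an [expr_matrix] of the discovery cohort.
#' @param discovery_clinical its clinical table.
#' @param criteria a [cascade_criteria()].
#' @param target target subgroup (default `"G4"`).
#' @param scheme censoring scheme for filter (c): `"overall"` (default) or
#'   `"late"`.
#' @param endpoint `"rfs"` or `"dmfs"`.
#' @param boundary early/late boundary in years.
#' @param var_equal pooled-variance t-test for filter (b) (default) or
#'   Welch (`FALSE`).
#' @return data.frame of class `cascade_signature` with per selected
#'   probe `r`, `q_de`, `cox_coef`, `cox_p`, ordered by descending `r`.
#'   Empty (with a warning) when no probe passes.
#' @export
cascade_select <- function(pairs, spc1, groups, discovery_x,
                           discovery_clinical,
                           criteria = cascade_criteria(),
                           target = "G4", scheme = c("overall", "late"),
                           endpoint = "rfs", boundary = 5,
                           var_equal = TRUE) {
  stopifnot(inherits(pairs, "paired_compartments"),
            inherits(spc1, "metagene_score"),
            inherits(criteria, "cascade_criteria"))
  scheme <- match.arg(scheme)
  if (ncol(discovery_x$values) == 0 || nrow(discovery_clinical) == 0)
    stop("empty discovery cohort")
  epi <- pairs$epithelium
  keep <- !epi$probes$is_control
  m <- epi$values[keep, , drop = FALSE]

  ## (a) correlation of epithelial expression with paired-stroma score
  sc <- spc1$scores[pairs$stroma$samples$sample_id]
  if (anyNA(sc)) stop("spc1 does not score every stroma sample")
  r <- suppressWarnings(as.vector(stats::cor(t(m), sc)))
  pass_a <- !is.na(r) & r > criteria$r_min

  ## (b) upregulated in the target epithelium subgroup
  g <- groups[epi$samples$sample_id]
  if (anyNA(g)) stop("every epithelium sample needs a subgroup label")
  in_group <- g == target
  if (sum(in_group) < 2 || sum(!in_group) < 2)
    stop("target subgroup or its complement has fewer than 2 samples")
  de <- .row_ttest(m, in_group, var_equal)
  q <- stats::p.adjust(de$p, "BH")
  pass_b <- !is.na(q) & q < criteria$de_fdr & de$mean_diff > 0

  ## (c) direct recurrence association in the discovery cohort
  ids <- intersect(discovery_x$samples$sample_id,
                   discovery_clinical$sample_id)
  dx <- discovery_x[, ids]
  cl <- discovery_clinical[match(ids, discovery_clinical$sample_id), ]
  records <- data.frame(time = cl[[paste0(endpoint, "_years")]],
                        event = cl[[paste0(endpoint, "_event")]])
  if (scheme == "late") records <- censor_late(records, boundary)
  y <- survival::Surv(records$time, records$event)
  probe_ids <- rownames(m)
  idx <- match(probe_ids, dx$probes$probe_id)
  cox <- matrix(NA_real_, length(probe_ids), 3)
  todo <- which(!is.na(idx))
  cox[todo, ] <- t(apply(dx$values[idx[todo], , drop = FALSE], 1,
                         .cox1, y = y))
  pass_c <- !is.na(cox[, 3]) & cox[, 1] > 0 & cox[, 3] < criteria$cox_p

  sel <- which(pass_a & pass_b & pass_c)
  sel <- sel[order(r[sel], decreasing = TRUE)]
  out <- data.frame(probe_id = probe_ids[sel], r = r[sel], q_de = q[sel],
                    cox_coef = cox[sel, 1], cox_p = cox[sel, 3],
                    stringsAsFactors = FALSE)
  if (!nrow(out)) warning("no probe passes all three cascade filters")
  attr(out, "criteria") <- criteria
  attr(out, "target") <- target
  attr(out, "scheme") <- scheme
  class(out) <- c("cascade_signature", "data.frame")
  out
}

#' Metastasis-timing groups
#'
#' Labels each sample by the timing of its distant metastasis: `early`
#' (event before `boundary` years), `late` (event at or after it), or
#' `none` (event-free with at least `long_followup` years of follow-up).
#' Event-free samples with shorter follow-up are uninformative for the
#' contrast and get `NA`.
#'
#' @param clinical data.frame with `sample_id`, `dmfs_years`,
#'   `dmfs_event`.
#' @param boundary early/late boundary (default 5 years).
#' @param long_followup minimum event-free follow-up for the `none` group
#'   (default 15 years).
#' @return Factor with levels `none`, `early`, `late`, named by sample
#'   ID; attribute `params` records the rule parameters.
#' @export
timing_groups <- function(clinical, boundary = 5, long_followup = 15) {
  if (boundary <= 0 || long_followup <= 0)
    stop("timing parameters must be positive")
  if (!all(c("dmfs_years", "dmfs_event") %in% names(clinical)))
    stop("clinical table lacks DMFS fields")
  t <- clinical$dmfs_years; e <- clinical$dmfs_event
  lab <- rep(NA_character_, nrow(clinical))
  lab[e == 1 & t < boundary] <- "early"
  lab[e == 1 & t >= boundary] <- "late"
  lab[e == 0 & t >= long_followup] <- "none"
  out <- factor(lab, levels = c("none", "early", "late"))
  names(out) <- clinical$sample_id
  attr(out, "params") <- c(boundary = boundary,
                           long_followup = long_followup)
  out
}

#' Validate a signature score against metastasis timing
#'
#' Pairwise Mann-Whitney tests between the timing groups (exact below the
#' size threshold, normal approximation with tie correction above) and,
#' when event times are supplied, a one-way ANOVA of the score across
#' binned time-of-metastasis groups.
#'
#' @param scores a [first_pc_score()] result or named numeric vector.
#' @param groups a [timing_groups()] factor.
#' @param times optional named vector of distant-metastasis times (years)
#'   used to bin event samples for the ANOVA; typically
#'   `clinical$dmfs_years` named by sample.
#' @param breaks bin boundaries for the timing ANOVA.
#' @param exact_max largest per-group size using the exact Mann-Whitney
#'   distribution.
#' @return List with `pairwise` (all group pairs: statistic, p, method),
#'   `anova_p` (across timing bins if `times` given, across the groups
#'   otherwise), `n` per group.
#' @export
validate_signature <- function(scores, groups, times = NULL,
                               breaks = c(0, 2.5, 5, 7.5, 10, Inf),
                               exact_max = 25) {
  if (inherits(scores, "metagene_score")) scores <- scores$scores
  g <- groups[!is.na(groups)]
  ids <- intersect(names(g), names(scores))
  g <- droplevels(factor(g[ids]))
  s <- scores[ids]
  if (nlevels(g) < 2) stop("need at least two non-empty timing groups")
  if (any(table(g) < 2)) stop("timing group with fewer than 2 samples")
  lev <- levels(g)
  combs <- utils::combn(lev, 2)
  pw <- lapply(seq_len(ncol(combs)), function(i) {
    s1 <- s[g == combs[1, i]]; s2 <- s[g == combs[2, i]]
    exact <- max(length(s1), length(s2)) <= exact_max &&
      !anyDuplicated(c(s1, s2))
    wt <- suppressWarnings(
      stats::wilcox.test(s1, s2, exact = exact, correct = TRUE))
    data.frame(comparison = paste(combs[1, i], "vs", combs[2, i]),
               statistic = unname(wt$statistic), p = wt$p.value,
               method = if (exact) "exact" else "normal approximation",
               stringsAsFactors = FALSE)
  })
  if (!is.null(times)) {
    ev <- ids[g %in% c("early", "late")]
    b <- cut(times[ev], breaks, right = FALSE)
    ok <- !is.na(b)
    ev <- ev[ok]; b <- droplevels(b[ok])
    big <- table(b)
    keep <- b %in% names(big)[big >= 2]
    ev <- ev[keep]; b <- droplevels(b[keep])
    anova_p <- if (nlevels(b) >= 2)
      stats::anova(stats::lm(s[ev] ~ b))[["Pr(>F)"]][1]
    else NA_real_
  } else {
    anova_p <- stats::anova(stats::lm(s ~ g))[["Pr(>F)"]][1]
  }
  list(pairwise = do.call(rbind, pw), anova_p = anova_p, n = table(g))
}

#' Concordance of two metagene scores on one cohort
#'
#' Computes [first_pc_score()] for both probe sets on the same cohort
#' (orientation-anchored) and their Pearson correlation.
#'
#' @param x an [expr_matrix].
#' @param probes_1,probes_2 probe sets (IDs or data.frame with
#'   directions), each with at least 2 probes present in `x`.
#' @param names_ labels for the two scores.
#' @return List with `score_1`, `score_2` ([first_pc_score()] results) and
#'   `r` (Pearson correlation of the two score vectors).
#' @export
concordance_scores <- function(x, probes_1, probes_2,
                               names_ = c("C4PC1", "EPC1")) {
  s1 <- first_pc_score(x, probes_1, name = names_[1])
  s2 <- first_pc_score(x, probes_2, name = names_[2])
  list(score_1 = s1, score_2 = s2,
       r = stats::cor(s1$scores, s2$scores))
}
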