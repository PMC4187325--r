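#' Default two-Gaussian marker parameters
#'
#' Generating parameters of the bimodal (IHC-negative / IHC-positive) mRNA
#' distributions for the three clinical receptor markers, on the log2 scale
#' typical of normalized microarray data. `prevalence` is the marginal
#' positive fraction used as the prior weight when recording the planted
#' maximum-likelihood cutoff; `frac_ihc` is the fraction of samples whose
#' IHC label is observed (the rest must be called from mRNA).
#'
#' @return Named list with entries `ER`, `PR`, `HER2`, each a list with
#'   `mean_neg`, `sd_neg`, `mean_pos`, `sd_pos`, `prevalence`, `frac_ihc`.
#' @export
default_marker_params <- function() {
  list(
    ER   = list(mean_neg = 4.5, sd_neg = 0.7, mean_pos = 8.0, sd_pos = 1.0,
                prevalence = 0.67, frac_ihc = 0.5),
    PR   = list(mean_neg = 4.5, sd_neg = 0.7, mean_pos = 7.5, sd_pos = 1.1,
                prevalence = 0.60, frac_ihc = 0.5),
    HER2 = list(mean_neg = 5.0, sd_neg = 0.6, mean_pos = 7.5, sd_pos = 0.9,
                prevalence = 0.22, frac_ihc = 0.5)
  )
}

#' Specification of a synthetic multi-study cohort
#'
#' Collects every knob of the synthetic-data generator: cohort layout,
#' batch structure carried by invariant control probes, bimodal receptor
#' markers with partially observed IHC labels, prognostic genes acting
#' before or after the early/late boundary, and paired epithelium/stroma
#' samples sharing a latent stromal-activation factor.
#'
#' @param n_studies number of independent studies (batches).
#' @param samples_per_study bulk tumor samples per study.
#' @param n_probes total probes on the array.
#' @param n_control_probes invariant control probes (no biological signal).
#' @param n_batch_factors latent batch factors; their per-study scores are
#'   shared by control and biological probes. Keep below `n_studies` so the
#'   centered factor scores have full rank.
#' @param subtype_proportions 4-vector (LumA, LumB, HER2type, TNBC) summing
#'   to 1.
#' @param marker_params per-marker mixture parameters, see
#'   [default_marker_params()].
#' @param n_early_genes,n_late_genes counts of planted prognostic probes
#'   whose hazard effect acts only before / only at-or-after the boundary.
#' @param early_loghr,late_loghr log hazard-ratio magnitudes (per SD of the
#'   latent early/late risk factor).
#' @param boundary_years early/late boundary (years).
#' @param followup_max_years administrative censoring time (years).
#' @param stroma_pairs paired epithelium/stroma sample count.
#' @param stroma_coupling correlation in `[0,1]` between the latent stromal
#'   factor and the paired epithelium's latent late-risk factor.
#' @param n_stromal_probes probes responding to the stromal factor in the
#'   stroma compartment.
#' @param noise_sd residual SD of biological probes.
#' @param control_noise_sd residual SD of control probes.
#' @param seed integer seed; the generator is fully deterministic given it.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_studies = 4, samples_per_study = 200,
                        n_probes = 2000, n_control_probes = 69,
                        n_batch_factors = 3,
                        subtype_proportions = c(LumA = 0.55, LumB = 0.12,
                                                HER2type = 0.10, TNBC = 0.23),
                        marker_params = default_marker_params(),
                        n_early_genes = 40, n_late_genes = 40,
                        early_loghr = 0.8, late_loghr = 0.8,
                        boundary_years = 5, followup_max_years = 15,
                        stroma_pairs = 46, stroma_coupling = 0.8,
                        n_stromal_probes = 40,
                        noise_sd = 1, control_noise_sd = 0.1, seed = 1) {
  spec <- list(n_studies = as.integer(n_studies),
               samples_per_study = as.integer(samples_per_study),
               n_probes = as.integer(n_probes),
               n_control_probes = as.integer(n_control_probes),
               n_batch_factors = as.integer(n_batch_factors),
               subtype_proportions = subtype_proportions,
               marker_params = marker_params,
               n_early_genes = as.integer(n_early_genes),
               n_late_genes = as.integer(n_late_genes),
               early_loghr = early_loghr, late_loghr = late_loghr,
               boundary_years = boundary_years,
               followup_max_years = followup_max_years,
               stroma_pairs = as.integer(stroma_pairs),
               stroma_coupling = stroma_coupling,
               n_stromal_probes = as.integer(n_stromal_probes),
               noise_sd = noise_sd, control_noise_sd = control_noise_sd,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_studies < 1 || samples_per_study < 1 || n_probes < 1)
      stop("cohort dimensions must be positive")
    if (length(subtype_proportions) != 4 || any(subtype_proportions < 0))
      stop("subtype_proportions must be a nonnegative 4-vector")
    if (abs(sum(subtype_proportions) - 1) > 1e-12)
      stop("subtype_proportions must sum to 1")
    if (n_control_probes < 0 || n_control_probes >= n_probes)
      stop("need 0 <= n_control_probes < n_probes")
    if (min(n_batch_factors, n_early_genes, n_late_genes, stroma_pairs,
            n_stromal_probes) < 0)
      stop("counts must be nonnegative")
    if (boundary_years <= 0 || followup_max_years <= 0)
      stop("time parameters must be positive")
    if (stroma_coupling < 0 || stroma_coupling > 1)
      stop("stroma_coupling must lie in [0, 1]")
    needed <- n_control_probes + 3L + n_early_genes + n_late_genes +
      n_stromal_probes
    if (needed > n_probes)
      stop(sprintf("n_probes = %d too small for %d structured probes",
                   n_probes, needed))
  })
  invisible(spec)
}

# deterministic per-component sub-seed, kept below 2^31
sub_seed <- function(seed, k) (seed %% 1048576L) * 1024L + as.integer(k)

# baseline hazards (per year) of the piecewise-exponential recurrence model
.H_EARLY <- 0.045
.H_LATE <- 0.015

#' Generate a synthetic multi-study cohort
#'
#' Builds probe-level expression, clinical outcomes and a ground-truth
#' record with the structure the discovery pipeline assumes:
#' \itemize{
#'   \item per-study batch factors loaded by every probe, with control
#'     probes carrying batch structure and noise only;
#'   \item marker probes drawn from two-Gaussian mixtures conditional on
#'     true receptor status, with IHC labels observed for a fraction of
#'     samples;
#'   \item recurrence times from a piecewise-exponential hazard in which a
#'     latent early-risk factor (loaded by the planted early genes) acts
#'     only before `boundary_years` and a latent late-risk factor (loaded
#'     by the planted late genes) only at or after it, with administrative
#'     censoring at `followup_max_years`;
#'   \item `stroma_pairs` paired epithelium/stroma samples whose latent
#'     stromal-activation factor correlates (`stroma_coupling`) with the
#'     epithelium's late-risk factor and drives the planted stromal probes
#'     in the stroma compartment.
#' }
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `synthetic_cohort`: list with `expression`
#'   (an [expr_matrix]), `clinical` (data.frame, one row per sample) and
#'   `truth` (planted quantities).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  validate_cohort_spec(spec)

  n_bulk <- spec$n_studies * spec$samples_per_study
  n_pair <- spec$stroma_pairs
  n_tum <- n_bulk + n_pair              # samples with tumor biology
  n_all <- n_tum + n_pair               # + stroma compartment samples

  studies <- sprintf("study%02d", seq_len(spec$n_studies))
  bulk_ids <- sprintf("%s_s%03d", rep(studies, each = spec$samples_per_study),
                      rep(seq_len(spec$samples_per_study), spec$n_studies))
  epi_ids <- sprintf("pairs_e%03d", seq_len(n_pair))
  str_ids <- sprintf("pairs_t%03d", seq_len(n_pair))
  pair_ids <- sprintf("pair%03d", seq_len(n_pair))
  sample_ids <- c(bulk_ids, epi_ids, str_ids)
  study_of <- c(rep(studies, each = spec$samples_per_study),
                rep("study_pairs", 2L * n_pair))
  tissue <- c(rep("bulk", n_bulk), rep("epithelium", n_pair),
              rep("stroma", n_pair))
  pair_of <- c(rep(NA_character_, n_bulk), pair_ids, pair_ids)
  tum_idx <- seq_len(n_tum)
  str_idx <- n_tum + seq_len(n_pair)

  ## probe layout ------------------------------------------------------------
  p <- spec$n_probes
  ctrl_idx <- seq_len(spec$n_control_probes)
  nxt <- spec$n_control_probes
  marker_idx <- nxt + 1:3; nxt <- nxt + 3L
  early_idx <- nxt + seq_len(spec$n_early_genes); nxt <- nxt + spec$n_early_genes
  late_idx <- nxt + seq_len(spec$n_late_genes); nxt <- nxt + spec$n_late_genes
  stromal_idx <- nxt + seq_len(spec$n_stromal_probes)
  nxt <- nxt + spec$n_stromal_probes
  n_sub <- min(150L, max(0L, (p - nxt) %/% 2L))  # subtype-shifted probes
  sub_idx <- nxt + seq_len(n_sub)

  probe_id <- sprintf("p%05d", seq_len(p))
  probe_id[ctrl_idx] <- sprintf("ctrl%03d", seq_along(ctrl_idx))
  gene <- sprintf("GENE%05d", seq_len(p))
  gene[ctrl_idx] <- sprintf("AFFX%03d", seq_along(ctrl_idx))
  gene[marker_idx] <- c("ESR1", "PGR", "ERBB2")
  is_control <- seq_len(p) %in% ctrl_idx
  probes <- data.frame(probe_id = probe_id, gene_symbol = gene,
                       is_control = is_control, stringsAsFactors = FALSE)

  ## design: subtypes, receptor truth, clinical covariates -------------------
  set.seed(sub_seed(spec$seed, 1))
  subtype_lv <- c("LumA", "LumB", "HER2type", "TNBC")
  subtype <- sample(subtype_lv, n_tum, replace = TRUE,
                    prob = spec$subtype_proportions)
  luminal <- subtype %in% c("LumA", "LumB")
  her2 <- subtype %in% c("LumB", "HER2type")
  er <- luminal & stats::runif(n_tum) < 0.9
  pr <- luminal & stats::runif(n_tum) < 0.7
  er[luminal & !er & !pr] <- TRUE       # luminal requires ER+ and/or PR+

  grade_lat <- NULL; u_e <- u_l <- NULL # filled below (separate stream)

  node <- stats::rbinom(n_tum, 1, 0.15)
  treated <- stats::rbinom(n_tum, 1, 0.15)
  size <- round(exp(stats::rnorm(n_tum, log(2), 0.35)), 1)
  age <- pmin(90, pmax(25, round(stats::rnorm(n_tum, 57, 11))))

  ## latent risk factors ------------------------------------------------------
  ## A 4-component mixture over (early, late) risk gives the cohort real
  ## prognostic subgroups (good prognosis / early-recurrence / late-
  ## recurrence / intermediate) while keeping each factor standardized.
  set.seed(sub_seed(spec$seed, 2))
  ## independent binary high/low states on each risk axis give four
  ## prognostic classes (good / early / late / double-high) while keeping
  ## the early and late risk factors exactly independent
  p_e_hi <- 0.42; p_l_hi <- 0.36
  sep_e <- 2.3; sep_l <- 2.6
  within_sd <- 0.35
  z_e_hi <- stats::runif(n_tum) < p_e_hi
  z_l_hi <- stats::runif(n_tum) < p_l_hi
  mk_axis <- function(hi, p_hi, sep) {
    cen <- ifelse(hi, (1 - p_hi) * sep, -p_hi * sep)
    (cen + within_sd * stats::rnorm(length(hi))) /
      sqrt(p_hi * (1 - p_hi) * sep^2 + within_sd^2)
  }
  u_e <- mk_axis(z_e_hi, p_e_hi, sep_e)
  u_l <- mk_axis(z_l_hi, p_l_hi, sep_l)
  z_class <- 1L + z_e_hi + 2L * z_l_hi   # 1 good, 2 early, 3 late, 4 both
  rho <- spec$stroma_coupling
  v <- rho * u_l[n_bulk + seq_len(n_pair)] +
    sqrt(1 - rho^2) * stats::rnorm(n_pair)
  # grade tracks the early-risk factor (a real prognostic confounder)
  g_lat <- 0.8 * u_e + 0.6 * stats::rnorm(n_tum)
  grade <- cut(g_lat, c(-Inf, stats::qnorm(0.30), stats::qnorm(0.70), Inf),
               labels = FALSE)

  ## batch structure ----------------------------------------------------------
  set.seed(sub_seed(spec$seed, 3))
  B <- spec$n_batch_factors
  all_studies <- c(studies, "study_pairs")
  delta <- matrix(stats::rnorm(length(all_studies) * B),
                  nrow = length(all_studies),
                  dimnames = list(all_studies, NULL))
  if (B > 0 && length(all_studies) > 1) {
    # centered orthonormal factor directions, scaled to a 1.2 SD spread
    # across studies, so no planted factor is degenerate by chance
    delta <- scale(delta, center = TRUE, scale = FALSE)
    delta <- qr.Q(qr(delta))[, seq_len(B), drop = FALSE] *
      (1.2 * sqrt(length(all_studies)))
    rownames(delta) <- all_studies
  }
  lambda <- matrix(stats::rnorm(p * B), nrow = p)
  if (B > 0)   # decaying factor strengths: the first factor dominates
    lambda <- sweep(lambda, 2, 0.5 / seq_len(B), "*")
  scores <- delta[match(study_of, all_studies), , drop = FALSE]
  batch <- if (B > 0) lambda %*% t(scores) else matrix(0, p, n_all)

  ## expression ---------------------------------------------------------------
  set.seed(sub_seed(spec$seed, 4))
  baseline <- stats::runif(p, 5, 9)
  x <- matrix(stats::rnorm(p * n_all, sd = spec$noise_sd), p, n_all)
  x[ctrl_idx, ] <- stats::rnorm(length(ctrl_idx) * n_all,
                                sd = spec$control_noise_sd)
  x <- x + baseline + batch

  status_mat <- cbind(ER = er, PR = pr, HER2 = her2)
  for (m in 1:3) {
    mp <- spec$marker_params[[c("ER", "PR", "HER2")[m]]]
    st <- status_mat[, m]
    mu <- ifelse(st, mp$mean_pos, mp$mean_neg)
    sg <- ifelse(st, mp$sd_pos, mp$sd_neg)
    x[marker_idx[m], tum_idx] <- stats::rnorm(n_tum, mu, sg) +
      batch[marker_idx[m], tum_idx]
  }
  ## half of each planted set is directly associated (positive loading),
  ## half inversely, as in real prognostic probe sets
  half_signs <- function(n) ifelse(seq_len(n) <= ceiling(n / 2), 1, -1)
  sgn_e <- half_signs(spec$n_early_genes)
  sgn_l <- half_signs(spec$n_late_genes)
  sgn_s <- half_signs(spec$n_stromal_probes)
  a_e <- stats::runif(spec$n_early_genes, 1.3, 1.7) * sgn_e
  a_l <- stats::runif(spec$n_late_genes, 1.3, 1.7) * sgn_l
  a_s <- stats::runif(spec$n_stromal_probes, 2.0, 2.5) * sgn_s
  if (spec$n_early_genes > 0)
    x[early_idx, tum_idx] <- x[early_idx, tum_idx] + outer(a_e, u_e)
  if (spec$n_late_genes > 0)
    x[late_idx, tum_idx] <- x[late_idx, tum_idx] + outer(a_l, u_l)
  if (spec$n_stromal_probes > 0 && n_pair > 0)
    x[stromal_idx, str_idx] <- x[stromal_idx, str_idx] + outer(a_s, v)
  if (n_sub > 0) {
    off <- matrix(stats::rnorm(n_sub * 4, sd = 0.7), n_sub, 4,
                  dimnames = list(NULL, subtype_lv))
    x[sub_idx, tum_idx] <- x[sub_idx, tum_idx] +
      off[, match(subtype, subtype_lv), drop = FALSE]
  }
  dimnames(x) <- list(probe_id, sample_ids)

  ## survival ------------------------------------------------------------------
  set.seed(sub_seed(spec$seed, 5))
  b <- spec$boundary_years; fmax <- spec$followup_max_years
  h1 <- .H_EARLY * exp(spec$early_loghr * u_e)
  h2 <- .H_LATE * exp(spec$late_loghr * u_l)
  E <- stats::rexp(n_tum)
  t_rec <- ifelse(E < h1 * b, E / h1, b + (E - h1 * b) / h2)
  rfs_event <- as.integer(t_rec < fmax)
  rfs_years <- pmin(t_rec, fmax)
  distant <- rfs_event == 1L & stats::runif(n_tum) < 0.75
  recurrence_type <- ifelse(rfs_event == 0L, "none",
                            ifelse(distant, "distant", "local"))
  dmfs_event <- as.integer(distant)
  dmfs_years <- ifelse(distant, rfs_years, fmax)
  death_gap <- stats::rexp(n_tum, rate = 1 / 2.5)
  os_years <- ifelse(distant, pmin(rfs_years + death_gap, fmax), fmax)
  os_event <- as.integer(distant & (rfs_years + death_gap) < fmax &
                           stats::runif(n_tum) < 0.85)
  bg_death <- !distant & stats::runif(n_tum) < 0.05
  os_years[bg_death] <- stats::runif(sum(bg_death), 2, fmax)
  os_event[bg_death] <- 1L

  ## observed IHC labels --------------------------------------------------------
  set.seed(sub_seed(spec$seed, 6))
  obs <- vapply(c("ER", "PR", "HER2"), function(mk)
    stats::runif(n_tum) < spec$marker_params[[mk]]$frac_ihc, logical(n_tum))
  ihc <- ifelse(obs, status_mat + 0L, NA_integer_)

  clin_tum <- data.frame(
    sample_id = sample_ids[tum_idx], study_id = study_of[tum_idx],
    tissue = tissue[tum_idx], pair_id = pair_of[tum_idx],
    rfs_years = rfs_years, rfs_event = rfs_event,
    dmfs_years = dmfs_years, dmfs_event = dmfs_event,
    os_years = os_years, os_event = os_event,
    recurrence_type = recurrence_type,
    node_status = node, systemic_treated = treated,
    size_cm = size, grade = grade, age = age,
    ihc_er = ihc[, 1], ihc_pr = ihc[, 2], ihc_her2 = ihc[, 3],
    stringsAsFactors = FALSE)
  # stroma rows share the paired epithelium's clinical record
  clin_str <- clin_tum[n_bulk + seq_len(n_pair), , drop = FALSE]
  if (n_pair > 0) {
    clin_str$sample_id <- str_ids
    clin_str$tissue <- "stroma"
    clin_str[, c("ihc_er", "ihc_pr", "ihc_her2")] <- NA_integer_
  }
  clinical <- rbind(clin_tum, clin_str)
  rownames(clinical) <- NULL

  marker_probes <- stats::setNames(probe_id[marker_idx], c("ER", "PR", "HER2"))
  cutoffs <- vapply(c("ER", "PR", "HER2"), function(mk) {
    mp <- spec$marker_params[[mk]]
    prior <- mean(status_mat[, mk])
    if (!is.finite(prior) || prior <= 0 || prior >= 1) prior <- mp$prevalence
    mixture_cutoff(mp$mean_neg, mp$sd_neg, mp$mean_pos, mp$sd_pos, prior)
  }, numeric(1))

  truth <- list(
    marker_probes = marker_probes,
    marker_cutoffs = cutoffs,
    early_probes = probe_id[early_idx],
    early_probes_direct = probe_id[early_idx][sgn_e > 0],
    late_probes = probe_id[late_idx],
    late_probes_direct = probe_id[late_idx][sgn_l > 0],
    stromal_probes = probe_id[stromal_idx],
    stromal_probes_up = probe_id[stromal_idx][sgn_s > 0],
    subtype_probes = probe_id[sub_idx],
    subtype = stats::setNames(subtype, sample_ids[tum_idx]),
    er = stats::setNames(er, sample_ids[tum_idx]),
    pr = stats::setNames(pr, sample_ids[tum_idx]),
    her2 = stats::setNames(her2, sample_ids[tum_idx]),
    latent_class = stats::setNames(
      c("good", "early", "late", "double-high")[z_class],
      sample_ids[tum_idx]),
    u_early = stats::setNames(u_e, sample_ids[tum_idx]),
    u_late = stats::setNames(u_l, sample_ids[tum_idx]),
    stroma_factor = stats::setNames(v, str_ids),
    batch_scores = scores,
    batch_loadings = lambda)

  samples <- data.frame(sample_id = sample_ids, study_id = study_of,
                        tissue = tissue, pair_id = pair_of,
                        stringsAsFactors = FALSE)
  structure(list(expression = expr_matrix(x, probes, samples),
                 clinical = clinical, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic_cohort: %d samples (%d bulk, %d pairs), ",
                     "%d probes, seed %d\n"),
              ncol(x$expression$values),
              sum(x$expression$samples$tissue == "bulk"),
              sum(x$expression$samples$tissue == "stroma"),
              nrow(x$expression$values), x$spec$seed))
  invisible(x)
}

.fmt_clin <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      v <- sprintf("%.17g", df[[nm]])
      v[is.na(df[[nm]])] <- NA_character_
      df[[nm]] <- v
    }
  }
  df
}

#' Write a synthetic cohort to disk
#'
#' Writes three files: `expression.tsv` (probe annotation + full-precision
#' values, see [write_expr()]), `clinical.tsv` (per-sample annotation and
#' outcomes, `NA` for missing) and `truth.json` (the planted quantities).
#'
#' @param cohort a [generate_cohort()] result.
#' @param directory output directory, created if absent.
#' @return Named character vector of the three file paths (the manifest).
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  f_expr <- file.path(directory, "expression.tsv")
  f_clin <- file.path(directory, "clinical.tsv")
  f_truth <- file.path(directory, "truth.json")
  write_expr(cohort$expression, f_expr)
  utils::write.table(.fmt_clin(cohort$clinical), f_clin, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  truth <- cohort$truth
  truth$batch_scores <- unclass(as.data.frame(truth$batch_scores))
  truth$batch_loadings <- unclass(as.data.frame(truth$batch_loadings))
  jsonlite::write_json(truth, f_truth, auto_unbox = FALSE, digits = NA,
                       na = "null")
  c(expression = f_expr, clinical = f_clin, truth = f_truth)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory directory holding `expression.tsv`, `clinical.tsv` and
#'   `truth.json`.
#' @return A list with `expression` ([expr_matrix]), `clinical`
#'   (data.frame) and `truth` (list).
#' @export
read_cohort <- function(directory) {
  clinical <- utils::read.delim(file.path(directory, "clinical.tsv"),
                                stringsAsFactors = FALSE)
  expression <- read_expr(file.path(directory, "expression.tsv"), clinical)
  truth <- jsonlite::read_json(file.path(directory, "truth.json"),
                               simplifyVector = TRUE)
  list(expression = expression, clinical = clinical, truth = truth)
}
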