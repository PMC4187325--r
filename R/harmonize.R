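#' Estimate cross-study structure from invariant control probes
#'
#' Control probes carry no biology, so any reproducible structure in them is
#' technical (study/batch) variation. The model takes the first
#' `n_components` principal components of the control-probe submatrix
#' (probes centered across samples) as per-sample scores of that technical
#' structure, and regresses every probe on those scores by ordinary least
#' squares; [remove_structure()] subtracts the fitted contribution.
#'
#' @param x an [expr_matrix] containing at least one control probe.
#' @param n_components number of control-probe principal components to
#'   estimate (40 for a large bulk compendium, 15 for a smaller
#'   multi-tissue set are typical choices). Must not exceed
#'   `min(#control probes, #samples - 1)`.
#' @return An object of class `harmonization_model`: `n_components`,
#'   `component_scores` (samples x k, orthogonal columns with zero mean),
#'   `removal_coefficients` (probes x k), and the sample/probe IDs the
#'   model was fitted on.
#' @export
fit_control_structure <- function(x, n_components) {
  stopifnot(inherits(x, "expr_matrix"))
  ctrl <- x$values[x$probes$is_control, , drop = FALSE]
  if (nrow(ctrl) == 0) stop("no control probes present")
  n_components <- as.integer(n_components)
  k_max <- min(nrow(ctrl), ncol(ctrl) - 1L)
  if (n_components < 0 || n_components > k_max)
    stop(sprintf("n_components must lie in [0, %d]", k_max))
  if (n_components == 0) {
    scores <- matrix(numeric(0), nrow = ncol(x$values), ncol = 0,
                     dimnames = list(x$samples$sample_id, NULL))
    coefs <- matrix(numeric(0), nrow = nrow(x$values), ncol = 0,
                    dimnames = list(x$probes$probe_id, NULL))
  } else {
    pc <- stats::prcomp(t(ctrl), center = TRUE, scale. = FALSE,
                        rank. = n_components)
    scores <- pc$x[, seq_len(n_components), drop = FALSE]
    rownames(scores) <- x$samples$sample_id
    # OLS slope of every probe on the (column-centered) scores; the
    # intercept is absorbed because the scores have zero column means
    beta <- solve(crossprod(scores), crossprod(scores, t(x$values)))
    coefs <- t(beta)
    rownames(coefs) <- x$probes$probe_id
  }
  structure(list(n_components = n_components,
                 component_scores = scores,
                 removal_coefficients = coefs,
                 sample_ids = x$samples$sample_id,
                 probe_ids = x$probes$probe_id),
            class = "harmonization_model")
}

#' Remove estimated cross-study structure from an expression matrix
#'
#' Replaces every probe's values by the residual after subtracting the
#' fitted component contribution `removal_coefficients %*% t(scores)`.
#' Probe and sample metadata, and per-probe means, are unchanged; the
#' residuals of every probe are exactly uncorrelated with every component
#' score. Applying fit + remove a second time is a no-op up to numerical
#' round-off.
#'
#' @param x an [expr_matrix]; must contain exactly the samples the model
#'   was fitted on.
#' @param model a [fit_control_structure()] result.
#' @return The residual [expr_matrix].
#' @export
remove_structure <- function(x, model) {
  stopifnot(inherits(x, "expr_matrix"), inherits(model, "harmonization_model"))
  if (!setequal(x$samples$sample_id, model$sample_ids))
    stop("sample mismatch between x and model")
  if (!identical(as.character(x$probes$probe_id),
                 as.character(model$probe_ids)))
    stop("probe mismatch between x and model")
  if (model$n_components == 0) return(x)
  sc <- model$component_scores[match(x$samples$sample_id,
                                     rownames(model$component_scores)), ,
                               drop = FALSE]
  # project the input onto the orthogonal complement of the score space;
  # on the matrix the model was fitted to, the slopes equal the model's
  # removal_coefficients, and reapplying the projection is a no-op
  beta <- solve(crossprod(sc), crossprod(sc, t(x$values)))
  res <- x$values - t(sc %*% beta)
  dimnames(res) <- dimnames(x$values)
  expr_matrix(res, x$probes, x$samples)
}

#' Visual and numerical check of study mixing
#'
#' Projects samples onto the first two principal components of the
#' top-variance non-control probes and quantifies residual batch structure
#' as the fraction of PC1 variance explained by study label (one-way
#' between-study sum of squares over total). After a successful
#' [remove_structure()] on batch-confounded data the statistic drops
#' towards its permutation null.
#'
#' @param x an [expr_matrix] with samples from at least two studies.
#' @param n_top number of top-variance probes used for the embedding.
#' @return List with `embedding` (samples x 2, columns `PC1`, `PC2`),
#'   `variance_ratio` (PC1 variance explained by study), and `study`
#'   (factor of study labels).
#' @export
confirm_mixing <- function(x, n_top = 1000) {
  stopifnot(inherits(x, "expr_matrix"))
  study <- factor(x$samples$study_id)
  if (nlevels(study) < 2)
    stop("mixing statistic undefined for a single study")
  v <- x$values[!x$probes$is_control, , drop = FALSE]
  vars <- apply(v, 1, stats::var)
  keep <- order(vars, decreasing = TRUE)[seq_len(min(n_top, nrow(v)))]
  pc <- stats::prcomp(t(v[keep, , drop = FALSE]), center = TRUE,
                      scale. = FALSE, rank. = 2)
  emb <- pc$x[, 1:2, drop = FALSE]
  colnames(emb) <- c("PC1", "PC2")
  rownames(emb) <- x$samples$sample_id
  list(embedding = emb,
       variance_ratio = variance_ratio(emb[, 1], study),
       study = study)
}

#' Fraction of a score's variance explained by a grouping
#'
#' One-way between-group sum of squares over total sum of squares; the
#' mixing statistic of [confirm_mixing()], exposed so permutation nulls can
#' be computed on a fixed embedding.
#'
#' @param score numeric vector.
#' @param group factor of the same length.
#' @return A number in `[0, 1]`.
#' @export
variance_ratio <- function(score, group) {
  group <- factor(group)
  gm <- tapply(score, group, mean)
  ss_b <- sum(tabulate(group) * (gm - mean(score))^2)
  ss_t <- sum((score - mean(score))^2)
  if (ss_t == 0) return(0)
  ss_b / ss_t
}

#' Serialize / load a harmonization model as tab-delimited tables
#'
#' Writes `<prefix>_scores.tsv` (sample_id + one column per component) and
#' `<prefix>_coefficients.tsv` (probe_id + one column per component) with
#' full double precision.
#'
#' @param model a [fit_control_structure()] result.
#' @param prefix path prefix for the two files.
#' @return `write_harmonization_model` returns the two paths invisibly;
#'   `read_harmonization_model` returns a `harmonization_model`.
#' @export
write_harmonization_model <- function(model, prefix) {
  stopifnot(inherits(model, "harmonization_model"))
  fs <- paste0(prefix, "_scores.tsv")
  fc <- paste0(prefix, "_coefficients.tsv")
  sdf <- data.frame(sample_id = model$sample_ids,
                    .fmt_full(model$component_scores),
                    check.names = FALSE, stringsAsFactors = FALSE)
  cdf <- data.frame(probe_id = model$probe_ids,
                    .fmt_full(model$removal_coefficients),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(sdf, fs, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cdf, fc, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(scores = fs, coefficients = fc))
}

#' @rdname write_harmonization_model
#' @export
read_harmonization_model <- function(prefix) {
  sdf <- utils::read.delim(paste0(prefix, "_scores.tsv"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  cdf <- utils::read.delim(paste0(prefix, "_coefficients.tsv"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  scores <- as.matrix(sdf[, -1, drop = FALSE])
  rownames(scores) <- sdf$sample_id
  coefs <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(coefs) <- cdf$probe_id
  storage.mode(scores) <- storage.mode(coefs) <- "double"
  structure(list(n_components = ncol(scores), component_scores = scores,
                 removal_coefficients = coefs,
                 sample_ids = sdf$sample_id, probe_ids = cdf$probe_id),
            class = "harmonization_model")
}
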