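#' Posterior-0.5 cutoff between two Gaussian classes
#'
#' Solves for the expression value at which the prior-weighted densities of
#' the negative and positive class Gaussians are equal, i.e. the point
#' where the posterior probability of positivity crosses 0.5. Equating log
#' densities gives a quadratic in x; with unequal variances there can be
#' two real roots, in which case the root strictly between the class means
#' is taken, and if none lies between, the root nearest the prior-weighted
#' pooled mean.
#'
#' @param mean_neg,sd_neg,mean_pos,sd_pos class Gaussian parameters
#'   (`sd_* > 0`).
#' @param prior_pos prior probability of the positive class, in (0, 1).
#' @return The cutoff (a single numeric value).
#' @export
mixture_cutoff <- function(mean_neg, sd_neg, mean_pos, sd_pos,
                           prior_pos = 0.5) {
  stopifnot(sd_neg > 0, sd_pos > 0, prior_pos > 0, prior_pos < 1)
  # pi+ N(x; m+, s+) = pi- N(x; m-, s-)  <=>  A x^2 + B x + C = 0
  A <- 1 / (2 * sd_neg^2) - 1 / (2 * sd_pos^2)
  B <- mean_pos / sd_pos^2 - mean_neg / sd_neg^2
  C <- mean_neg^2 / (2 * sd_neg^2) - mean_pos^2 / (2 * sd_pos^2) +
    log(prior_pos * sd_neg / ((1 - prior_pos) * sd_pos))
  lo <- min(mean_neg, mean_pos); hi <- max(mean_neg, mean_pos)
  if (abs(A) < 1e-12) {
    if (abs(B) < 1e-12) stop("degenerate mixture: identical components")
    return(-C / B)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) stop("no real density crossing for these parameters")
  roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  inside <- roots > lo & roots < hi
  if (any(inside)) return(roots[inside][1])
  pooled <- prior_pos * mean_pos + (1 - prior_pos) * mean_neg
  roots[which.min(abs(roots - pooled))]
}

#' Fit a bimodal marker model from partially IHC-labeled expression
#'
#' Fits maximum-likelihood normals to the IHC-positive and IHC-negative
#' labeled samples of one marker and derives the mRNA cutoff at which the
#' prior-weighted class densities are equal ([mixture_cutoff()]). The class
#' prior defaults to the labeled positive fraction; equal priors are
#' available for sensitivity analyses.
#'
#' @param expression numeric vector of per-sample marker expression.
#' @param ihc_labels vector of the same length: 1 = IHC positive,
#'   0 = IHC negative, `NA` = unlabeled.
#' @param marker marker name carried in the result (`"ER"`, `"PR"`,
#'   `"HER2"`).
#' @param equal_priors if `TRUE`, use prior 0.5 instead of the labeled
#'   prevalence.
#' @return An object of class `marker_model` with the component Gaussians,
#'   `prior_pos` and `cutoff`.
#' @export
fit_marker_model <- function(expression, ihc_labels, marker = "marker",
                             equal_priors = FALSE) {
  stopifnot(length(expression) == length(ihc_labels))
  pos <- expression[!is.na(ihc_labels) & ihc_labels == 1]
  neg <- expression[!is.na(ihc_labels) & ihc_labels == 0]
  if (length(pos) < 2 || length(neg) < 2)
    stop("need at least 2 IHC-labeled samples per class")
  ml_sd <- function(v) sqrt(mean((v - mean(v))^2))
  sd_pos <- ml_sd(pos); sd_neg <- ml_sd(neg)
  if (sd_pos == 0 || sd_neg == 0)
    stop("a labeled class has zero within-class variance")
  prior <- if (equal_priors) 0.5 else length(pos) / (length(pos) + length(neg))
  cut <- mixture_cutoff(mean(neg), sd_neg, mean(pos), sd_pos, prior)
  structure(list(marker = marker,
                 mean_pos = mean(pos), sd_pos = sd_pos,
                 mean_neg = mean(neg), sd_neg = sd_neg,
                 prior_pos = prior, cutoff = cut,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "marker_model")
}

#' @export
print.marker_model <- function(x, ...) {
  cat(sprintf(
    "marker_model %s: neg N(%.3f, %.3f) pos N(%.3f, %.3f) prior+ %.3f cutoff %.4f\n",
    x$marker, x$mean_neg, x$sd_neg, x$mean_pos, x$sd_pos, x$prior_pos,
    x$cutoff))
  invisible(x)
}

#' Call ER/PR/HER2 status and molecular subtype
#'
#' Samples with an observed IHC label keep it as the final call (provenance
#' `"IHC"`); unlabeled samples are called positive iff marker expression
#' strictly exceeds the model cutoff (provenance `"mRNA"`; a value exactly
#' at the cutoff is called negative).
#'
#' @param x an [expr_matrix] containing the marker probes.
#' @param ihc data.frame with `sample_id` and columns `ihc_er`, `ihc_pr`,
#'   `ihc_her2` (1/0/`NA`), e.g. the cohort clinical table.
#' @param models named list of [fit_marker_model()] results for `ER`, `PR`,
#'   `HER2`.
#' @param marker_probes named character vector mapping `ER`, `PR`, `HER2`
#'   to probe IDs in `x`.
#' @return data.frame of class `receptor_calls`: `sample_id`, logical
#'   `er`/`pr`/`her2`, provenance `er_src`/`pr_src`/`her2_src`, `subtype`.
#' @export
call_receptors <- function(x, ihc, models, marker_probes) {
  stopifnot(inherits(x, "expr_matrix"),
            all(c("ER", "PR", "HER2") %in% names(marker_probes)),
            all(c("ER", "PR", "HER2") %in% names(models)))
  missing_p <- setdiff(marker_probes[c("ER", "PR", "HER2")],
                       x$probes$probe_id)
  if (length(missing_p))
    stop("marker probes absent from matrix: ",
         paste(missing_p, collapse = ", "))
  ids <- x$samples$sample_id
  ihc <- ihc[match(ids, ihc$sample_id), , drop = FALSE]
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  cols <- c(ER = "ihc_er", PR = "ihc_pr", HER2 = "ihc_her2")
  for (mk in c("ER", "PR", "HER2")) {
    model <- models[[mk]]
    if (!inherits(model, "marker_model"))
      stop("models$", mk, " is not a marker_model")
    expr <- x$values[marker_probes[[mk]], ]
    lab <- ihc[[cols[[mk]]]]
    if (is.null(lab)) lab <- rep(NA_integer_, length(ids))
    call <- ifelse(is.na(lab), expr > model$cutoff, lab == 1)
    src <- ifelse(is.na(lab), "mRNA", "IHC")
    out[[tolower(mk)]] <- as.logical(call)
    out[[paste0(tolower(mk), "_src")]] <- src
  }
  out$subtype <- assign_subtype(out$er, out$pr, out$her2)
  class(out) <- c("receptor_calls", "data.frame")
  out
}

#' Assign molecular subtype from receptor calls
#'
#' Luminal A: ER+ and/or PR+, HER2-; luminal B: ER+ and/or PR+, HER2+;
#' HER2 type: ER-, PR-, HER2+; TNBC: ER-, PR-, HER2-. The four classes
#' partition the 8 call combinations.
#'
#' @param er,pr,her2 logical vectors (TRUE = positive), no `NA`.
#' @return Character vector of subtypes.
#' @export
assign_subtype <- function(er, pr, her2) {
  if (anyNA(er) || anyNA(pr) || anyNA(her2))
    stop("subtype assignment requires complete ER/PR/HER2 calls")
  luminal <- er | pr
  ifelse(luminal & !her2, "LumA",
         ifelse(luminal & her2, "LumB",
                ifelse(her2, "HER2type", "TNBC")))
}

#' Write receptor calls as a tab-delimited table
#'
#' Columns: sample_id, er, pr, her2 (`positive`/`negative`), per-marker
#' provenance and subtype.
#'
#' @param calls a [call_receptors()] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_receptor_calls <- function(calls, file) {
  df <- data.frame(
    sample_id = calls$sample_id,
    er = ifelse(calls$er, "positive", "negative"),
    pr = ifelse(calls$pr, "positive", "negative"),
    her2 = ifelse(calls$her2, "positive", "negative"),
    er_src = calls$er_src, pr_src = calls$pr_src, her2_src = calls$her2_src,
    subtype = calls$subtype, stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
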