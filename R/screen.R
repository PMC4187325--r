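#' Time-window censoring transforms
#'
#' The early/late dichotomy is realized by re-censoring: for the *late*
#' analysis, events occurring before the boundary are converted to
#' censorings at their event time (`censor_late`, keeping only late
#' events); for the *early* analysis, events occurring at or after the
#' boundary are converted to censorings (`censor_early`, keeping only
#' early events). A recurrence at exactly the boundary counts as late.
#' Censored records are never altered, so for every event record exactly
#' one of the two transforms retains the event.
#'
#' @param records data.frame with numeric `time` (years, nonnegative) and
#'   binary `event`; extra columns are preserved.
#' @param boundary boundary in years (default 5).
#' @return The transformed data.frame.
#' @export
censor_late <- function(records, boundary = 5) {
  check_records(records, boundary)
  records$event[records$event == 1 & records$time < boundary] <- 0L
  records
}

#' @rdname censor_late
#' @export
censor_early <- function(records, boundary = 5) {
  check_records(records, boundary)
  records$event[records$event == 1 & records$time >= boundary] <- 0L
  records
}

check_records <- function(records, boundary = 1) {
  stopifnot(is.data.frame(records),
            all(c("time", "event") %in% names(records)))
  if (boundary <= 0) stop("boundary must be positive")
  if (any(records$time < 0, na.rm = TRUE)) stop("negative survival times")
  if (!all(records$event %in% c(0, 1, NA)))
    stop("event must be binary")
  invisible(records)
}

# fast single-covariate Cox fit; returns c(coef, se, p) or NAs
.cox1 <- function(x, y, method = "efron") {
  if (!is.finite(stats::var(x)) || stats::var(x) == 0)
    return(c(NA_real_, NA_real_, NA_real_))
  fit <- tryCatch(
    suppressWarnings(survival::coxph.fit(
      matrix(x, ncol = 1), y, strata = NULL, offset = NULL, init = 0,
      control = survival::coxph.control(), weights = NULL,
      method = method, rownames = NULL)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$coefficients[1]) ||
      !is.finite(fit$var[1, 1]) || fit$var[1, 1] <= 0)
    return(c(NA_real_, NA_real_, NA_real_))
  co <- fit$coefficients[1]
  se <- sqrt(fit$var[1, 1])
  c(co, se, 2 * stats::pnorm(-abs(co / se)))
}

#' Univariable Cox regression on a continuous covariate
#'
#' Partial-likelihood fit of a single continuous covariate (Efron tie
#' handling) with a Wald p-value.
#'
#' @param covariate per-sample numeric values (e.g. one probe's log
#'   expression).
#' @param records data.frame with `time` and `event`.
#' @param ties tie-handling method passed to the Cox engine.
#' @return List with `coef` (log hazard ratio per covariate unit), `se`,
#'   `p`.
#' @export
cox_univariable <- function(covariate, records, ties = "efron") {
  check_records(records)
  stopifnot(length(covariate) == nrow(records))
  if (sum(records$event) < 1) stop("no events in records")
  if (!all(is.finite(covariate))) stop("non-finite covariate")
  if (stats::var(covariate) == 0)
    stop("zero-variance covariate")
  r <- .cox1(covariate, survival::Surv(records$time, records$event),
             method = ties)
  if (is.na(r[1])) stop("Cox fit did not converge")
  list(coef = unname(r[1]), se = unname(r[2]), p = unname(r[3]))
}

#' Genome-scale Cox screen under overall / early / late censoring
#'
#' Runs a univariable Cox regression of the chosen endpoint on every
#' non-control probe (expression as a continuous covariate) under each of
#' the three censoring schemes, and classifies probes at the discovery
#' threshold: early-associated if the early-scheme p-value is below it,
#' late-associated if the late-scheme p-value is, `both` or `neither`
#' otherwise. No multiple-testing correction is applied to the discovery
#' call (the screen uses a raw p threshold); BH FDR values are reported
#' alongside for information. Probes whose fit fails (zero variance,
#' nonconvergence) are classified `neither` with the reason recorded.
#'
#' @param x an [expr_matrix].
#' @param clinical data.frame with `sample_id` and the endpoint columns
#'   (`rfs_years`/`rfs_event` or `dmfs_years`/`dmfs_event`).
#' @param endpoint `"rfs"` (default) or `"dmfs"`.
#' @param boundary early/late boundary in years.
#' @param threshold discovery p-value threshold (default 0.001).
#' @return data.frame of class `survival_screen`: per probe
#'   `coef_overall`, `p_overall`, `coef_early`, `p_early`, `coef_late`,
#'   `p_late`, BH FDRs, `direction` (`direct` if overall coefficient
#'   positive), `category`, `note`. Attributes record the scheme records
#'   and parameters.
#' @export
screen_genome <- function(x, clinical, endpoint = c("rfs", "dmfs"),
                          boundary = 5, threshold = 0.001) {
  stopifnot(inherits(x, "expr_matrix"))
  endpoint <- match.arg(endpoint)
  keep <- x$samples$sample_id %in% clinical$sample_id
  if (!any(keep)) stop("no overlapping samples between x and clinical")
  x <- x[, which(keep)]
  cl <- clinical[match(x$samples$sample_id, clinical$sample_id), ]
  records <- data.frame(time = cl[[paste0(endpoint, "_years")]],
                        event = cl[[paste0(endpoint, "_event")]])
  schemes <- list(overall = records,
                  early = censor_early(records, boundary),
                  late = censor_late(records, boundary))
  probes <- which(!x$probes$is_control)
  vals <- x$values[probes, , drop = FALSE]
  out <- data.frame(probe_id = x$probes$probe_id[probes],
                    stringsAsFactors = FALSE)
  for (s in names(schemes)) {
    y <- survival::Surv(schemes[[s]]$time, schemes[[s]]$event)
    if (sum(schemes[[s]]$event) < 1)
      stop("scheme '", s, "' has no events")
    stats_m <- t(apply(vals, 1, .cox1, y = y))
    out[[paste0("coef_", s)]] <- stats_m[, 1]
    out[[paste0("p_", s)]] <- stats_m[, 3]
  }
  out$fdr_early <- stats::p.adjust(out$p_early, "BH")
  out$fdr_late <- stats::p.adjust(out$p_late, "BH")
  early_hit <- !is.na(out$p_early) & out$p_early < threshold
  late_hit <- !is.na(out$p_late) & out$p_late < threshold
  out$direction <- ifelse(is.na(out$coef_overall), NA_character_,
                          ifelse(out$coef_overall > 0, "direct", "inverse"))
  out$category <- ifelse(early_hit & late_hit, "both",
                         ifelse(early_hit, "early-associated",
                                ifelse(late_hit, "late-associated",
                                       "neither")))
  failed <- is.na(out$p_overall) | is.na(out$p_early) | is.na(out$p_late)
  out$category[failed] <- "neither"
  out$note <- ifelse(failed, "fit failed (zero variance or nonconvergence)",
                     "")
  attr(out, "threshold") <- threshold
  attr(out, "boundary") <- boundary
  attr(out, "endpoint") <- endpoint
  class(out) <- c("survival_screen", "data.frame")
  out
}

#' Covariate-adjusted Cox fit for one expression covariate
#'
#' Multivariable Cox model of the expression covariate alongside clinical
#' covariates (size, grade, nodal status, age, receptor status, ...);
#' returns the expression term's adjusted statistics, used to confirm
#' screen hits. Constant covariates are dropped; collinear covariates are
#' dropped with a warning; the fit is flagged when complete-case rows fall
#' below 10 per covariate.
#'
#' @param covariate numeric expression values per sample.
#' @param records data.frame with `time` and `event`.
#' @param covariates data.frame of clinical covariates (numeric or
#'   convertible), one row per sample.
#' @param ties tie-handling method.
#' @return List with `coef`, `se`, `p` for the expression term, `n`
#'   (complete cases), `dropped` (covariates removed) and `flagged`.
#' @export
cox_adjusted <- function(covariate, records, covariates, ties = "efron") {
  check_records(records)
  if (!is.data.frame(covariates) || ncol(covariates) == 0)
    stop("empty covariate table")
  stopifnot(length(covariate) == nrow(records),
            nrow(covariates) == nrow(records))
  cv <- as.data.frame(lapply(covariates, function(v) as.numeric(v)))
  const <- vapply(cv, function(v) stats::var(v, na.rm = TRUE) == 0 ||
                    all(is.na(v)), logical(1))
  dropped <- names(cv)[const]
  cv <- cv[!const]
  df <- data.frame(.expr = covariate, cv,
                   .time = records$time, .event = records$event)
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  k <- ncol(df) - 2L
  flagged <- nrow(df) < 10 * k
  if (flagged)
    warning(sprintf("only %d complete cases for %d covariates", nrow(df), k))
  xmat <- as.matrix(df[, seq_len(k), drop = FALSE])
  fit <- survival::coxph(
    survival::Surv(df$.time, df$.event) ~ xmat, ties = ties)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    bad <- sub("^xmat", "", names(co)[is.na(co)])
    warning("collinear covariates dropped: ", paste(bad, collapse = ", "))
    dropped <- c(dropped, bad)
    xmat <- xmat[, !colnames(xmat) %in% bad, drop = FALSE]
    fit <- survival::coxph(
      survival::Surv(df$.time, df$.event) ~ xmat, ties = ties)
    co <- stats::coef(fit)
  }
  i <- if (length(co) == 1) 1L else which(names(co) == "xmat.expr")
  se <- sqrt(diag(stats::vcov(fit)))[i]
  list(coef = unname(co[i]), se = unname(se),
       p = unname(2 * stats::pnorm(-abs(co[i] / se))),
       n = nrow(df), dropped = dropped, flagged = flagged)
}

#' Cox regression of a dichotomized clinical parameter
#'
#' Fits a binary-covariate Cox model under the requested censoring scheme
#' with the conventional dichotomizations: tumor size >= 2 cm vs < 2 cm,
#' grade 3 vs others, age >= 50 vs < 50, receptor status positive vs
#' negative, TNBC vs others.
#'
#' @param clinical data.frame with endpoint columns and the clinical
#'   fields (`size_cm`, `grade`, `age`, `ihc_*`).
#' @param parameter one of `"her2"`, `"er"`, `"pr"`, `"tnbc"`, `"size"`,
#'   `"grade"`, `"age"`.
#' @param scheme `"overall"`, `"early"` or `"late"`.
#' @param calls optional [call_receptors()] result supplying final
#'   receptor calls and subtypes; if absent, receptor parameters fall back
#'   to the IHC columns of `clinical`.
#' @param endpoint `"rfs"` (default) or `"dmfs"`.
#' @param boundary early/late boundary in years.
#' @return List with `hr`, `ci` (95% Wald), `p`, `n`, `events`,
#'   `parameter`, `scheme`.
#' @export
clinical_param_cox <- function(clinical, parameter, scheme = "overall",
                               calls = NULL, endpoint = "rfs",
                               boundary = 5) {
  parameter <- match.arg(tolower(parameter),
                         c("her2", "er", "pr", "tnbc", "size", "grade",
                           "age"))
  scheme <- match.arg(scheme, c("overall", "early", "late"))
  get_call <- function(col, ihc_col) {
    if (!is.null(calls)) {
      v <- calls[[col]][match(clinical$sample_id, calls$sample_id)]
      as.logical(v)
    } else clinical[[ihc_col]] == 1
  }
  z <- switch(parameter,
    her2 = get_call("her2", "ihc_her2"),
    er = get_call("er", "ihc_er"),
    pr = get_call("pr", "ihc_pr"),
    tnbc = if (!is.null(calls))
      calls$subtype[match(clinical$sample_id, calls$sample_id)] == "TNBC"
      else stop("TNBC requires receptor calls"),
    size = clinical$size_cm >= 2,
    grade = clinical$grade == 3,
    age = clinical$age >= 50)
  records <- data.frame(time = clinical[[paste0(endpoint, "_years")]],
                        event = clinical[[paste0(endpoint, "_event")]])
  records <- switch(scheme, overall = records,
                    early = censor_early(records, boundary),
                    late = censor_late(records, boundary))
  ok <- !is.na(z) & !is.na(records$time) & !is.na(records$event)
  z <- as.numeric(z[ok]); records <- records[ok, , drop = FALSE]
  if (length(unique(z)) < 2) stop("one-level covariate: ", parameter)
  fit <- cox_univariable(z, records)
  list(hr = exp(fit$coef),
       ci = exp(fit$coef + c(-1, 1) * stats::qnorm(0.975) * fit$se),
       p = fit$p, n = nrow(records), events = sum(records$event),
       parameter = parameter, scheme = scheme)
}

#' Write screen results in the tab-delimited dialect
#'
#' @param screen a [screen_genome()] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_screen <- function(screen, file) {
  cols <- c("probe_id", "coef_overall", "p_overall", "coef_early",
            "p_early", "coef_late", "p_late", "direction", "category")
  utils::write.table(as.data.frame(screen)[, cols], file, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(file)
}
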