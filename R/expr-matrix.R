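#' Expression matrix container
#'
#' Lightweight container for probe-by-sample log-scale expression values
#' together with probe annotation (gene symbol, control flag) and sample
#' annotation (study, tissue compartment, pairing).
#'
#' @param values numeric matrix, probes in rows, samples in columns. Row and
#'   column names are taken as probe and sample identifiers.
#' @param probe_annotation data.frame with columns `probe_id`, `gene_symbol`,
#'   `is_control` (logical), one row per probe, in the row order of `values`.
#' @param sample_annotation data.frame with columns `sample_id`, `study_id`,
#'   `tissue` (one of `"bulk"`, `"epithelium"`, `"stroma"`) and `pair_id`
#'   (`NA` for unpaired samples), one row per sample, in the column order of
#'   `values`.
#'
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, probe_annotation, sample_annotation) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values))) rownames(values) <- probe_annotation$probe_id
  if (is.null(colnames(values))) colnames(values) <- sample_annotation$sample_id
  stopifnot(
    nrow(probe_annotation) == nrow(values),
    nrow(sample_annotation) == ncol(values),
    all(c("probe_id", "gene_symbol", "is_control") %in% names(probe_annotation)),
    all(c("sample_id", "study_id", "tissue") %in% names(sample_annotation))
  )
  if (anyDuplicated(probe_annotation$probe_id))
    stop("duplicate probe IDs")
  if (anyDuplicated(sample_annotation$sample_id))
    stop("duplicate sample IDs")
  norm_names <- function(x) if (is.null(x)) character(0) else as.character(x)
  if (!identical(norm_names(rownames(values)),
                 as.character(probe_annotation$probe_id)))
    stop("rownames(values) do not match probe_annotation$probe_id")
  if (!identical(norm_names(colnames(values)),
                 as.character(sample_annotation$sample_id)))
    stop("colnames(values) do not match sample_annotation$sample_id")
  if (!"pair_id" %in% names(sample_annotation)) sample_annotation$pair_id <- NA_character_
  structure(
    list(values = values,
         probes = probe_annotation,
         samples = sample_annotation),
    class = "expr_matrix"
  )
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples (%d control probes, %d studies)\n",
              nrow(x$values), ncol(x$values),
              sum(x$probes$is_control),
              length(unique(x$samples$study_id))))
  invisible(x)
}

#' Subset an expression matrix
#'
#' @param x an [expr_matrix].
#' @param i probe index (integer, logical or probe IDs).
#' @param j sample index (integer, logical or sample IDs).
#' @param ... ignored.
#' @return The subset `expr_matrix`.
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(i)) i <- match(i, x$probes$probe_id)
  if (is.character(j)) j <- match(j, x$samples$sample_id)
  if (anyNA(i)) stop("unknown probe ID in subset")
  if (anyNA(j)) stop("unknown sample ID in subset")
  expr_matrix(x$values[i, j, drop = FALSE],
              x$probes[i, , drop = FALSE],
              x$samples[j, , drop = FALSE])
}

#' Merge studies onto a common probe set
#'
#' Restricts a list of expression matrices to the probes present on every
#' platform and concatenates their samples, the standard first step when
#' combining multi-study microarray compendia measured on overlapping chip
#' designs. Probe order follows the first input.
#'
#' @param matrices list of [expr_matrix] objects.
#' @return A single [expr_matrix] on the common probe set.
#' @export
intersect_platforms <- function(matrices) {
  if (!length(matrices)) stop("need at least one matrix")
  lapply(matrices, function(m)
    if (!inherits(m, "expr_matrix")) stop("all inputs must be expr_matrix"))
  common <- Reduce(intersect, lapply(matrices, function(m) m$probes$probe_id))
  if (!length(common)) stop("empty probe intersection")
  # keep the probe order of the first input
  common <- matrices[[1]]$probes$probe_id[matrices[[1]]$probes$probe_id %in% common]
  ids <- unlist(lapply(matrices, function(m) m$samples$sample_id))
  if (anyDuplicated(ids)) stop("duplicate sample IDs across inputs")
  vals <- do.call(cbind, lapply(matrices, function(m)
    m$values[match(common, m$probes$probe_id), , drop = FALSE]))
  rownames(vals) <- common
  probes <- matrices[[1]]$probes[match(common, matrices[[1]]$probes$probe_id), , drop = FALSE]
  samples <- do.call(rbind, lapply(matrices, function(m) m$samples))
  rownames(probes) <- rownames(samples) <- NULL
  expr_matrix(vals, probes, samples)
}

# format a numeric matrix so that read.delim round-trips doubles exactly
.fmt_full <- function(m) {
  if (ncol(m) == 0L || nrow(m) == 0L)
    return(matrix(character(0), nrow = nrow(m), ncol = ncol(m),
                  dimnames = dimnames(m)))
  out <- vapply(seq_len(ncol(m)), function(j) sprintf("%.17g", m[, j]),
                character(nrow(m)))
  matrix(out, nrow = nrow(m), dimnames = dimnames(m))
}

#' Write / read an expression matrix in the package's tab-delimited dialect
#'
#' The table carries `probe_id`, `gene_symbol` and `is_control` in the first
#' three columns followed by one column per sample; values are written with
#' full double precision so a round trip is exact. Sample annotation travels
#' with the clinical table (see [write_cohort()]).
#'
#' @param x an [expr_matrix].
#' @param file path of the tab-delimited file.
#' @param sample_annotation for `read_expr`: data.frame with `sample_id`,
#'   `study_id`, `tissue`, `pair_id` rows covering every sample column
#'   (extra rows ignored).
#' @return `write_expr` returns `file` invisibly; `read_expr` returns an
#'   [expr_matrix].
#' @export
write_expr <- function(x, file) {
  df <- data.frame(probe_id = x$probes$probe_id,
                   gene_symbol = x$probes$gene_symbol,
                   is_control = x$probes$is_control,
                   .fmt_full(x$values),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(file)
}

#' @rdname write_expr
#' @export
read_expr <- function(file, sample_annotation) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("probe_id", "gene_symbol", "is_control")
  sample_cols <- setdiff(names(df), meta)
  vals <- as.matrix(df[, sample_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- df$probe_id
  probes <- df[, meta, drop = FALSE]
  probes$is_control <- as.logical(probes$is_control)
  ann <- sample_annotation[match(sample_cols, sample_annotation$sample_id), ,
                           drop = FALSE]
  if (anyNA(ann$sample_id) && length(sample_cols))
    stop("sample_annotation does not cover all expression columns")
  rownames(ann) <- NULL
  expr_matrix(vals, probes, ann)
}
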