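#' Extract paired epithelium/stroma compartments
#'
#' Splits an expression matrix into its epithelium and stroma samples and
#' matches them one-to-one through `pair_id`. Unpaired compartment samples
#' are an error: the downstream differential analysis assumes a bijection.
#'
#' @param x an [expr_matrix] whose sample annotation carries
#'   `tissue` in `{bulk, epithelium, stroma}` and `pair_id`.
#' @return An object of class `paired_compartments`: `epithelium` and
#'   `stroma` ([expr_matrix] objects, columns aligned by pair) and
#'   `pair_ids`.
#' @export
paired_compartments <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  epi <- x[, which(x$samples$tissue == "epithelium")]
  str <- x[, which(x$samples$tissue == "stroma")]
  pe <- epi$samples$pair_id
  ps <- str$samples$pair_id
  if (!length(pe)) stop("no epithelium samples")
  if (anyDuplicated(pe) || anyDuplicated(ps) || !setequal(pe, ps))
    stop("epithelium/stroma pairing is not one-to-one")
  str <- str[, match(pe, ps)]
  structure(list(epithelium = epi, stroma = str, pair_ids = pe),
            class = "paired_compartments")
}

#' @export
print.paired_compartments <- function(x, ...) {
  cat(sprintf("paired_compartments: %d pairs, %d probes\n",
              length(x$pair_ids), nrow(x$epithelium$values)))
  invisible(x)
}

# vectorized two-sample t-test over matrix rows (Welch by default)
.row_ttest <- function(m, in_group, var_equal = FALSE) {
  m1 <- m[, in_group, drop = FALSE]
  m2 <- m[, !in_group, drop = FALSE]
  n1 <- ncol(m1); n2 <- ncol(m2)
  mu1 <- rowMeans(m1); mu2 <- rowMeans(m2)
  v1 <- rowSums((m1 - mu1)^2) / (n1 - 1)
  v2 <- rowSums((m2 - mu2)^2) / (n2 - 1)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (mu1 - mu2) / se
  data.frame(mean_diff = mu1 - mu2, t = t, df = df,
             p = 2 * stats::pt(-abs(t), df))
}

#' Differential stromal expression of one epithelium subgroup
#'
#' Compares stroma expression between the pairs whose epithelium belongs
#' to the target subgroup and all other pairs, probe by probe (Welch
#' two-sample t-test by default), and selects probes at a
#' Benjamini-Hochberg FDR below `fdr`, with the direction of regulation in
#' the target group's stroma.
#'
#' @param pairs a [paired_compartments()] result.
#' @param epithelium_groups factor of subgroup labels named by epithelium
#'   sample ID (e.g. from [cluster_two_way()] on the joint cohort).
#' @param target subgroup whose stroma is contrasted against the rest
#'   (default `"G4"`).
#' @param fdr FDR threshold (default 0.05).
#' @param var_equal use the pooled-variance t-test (default; the classic
#'   two-sample t of the desktop statistics tools, and the better-powered
#'   choice at the ~10-sample subgroup sizes this design produces) or the
#'   Welch unequal-variance test (`FALSE`).
#' @return data.frame of class `stromal_de`: per non-control probe
#'   `mean_diff`, `t`, `df`, `p`, `q`, `direction` (`up`/`down` in the
#'   target stroma) and `selected`; attribute `target`.
#' @export
stromal_de <- function(pairs, epithelium_groups, target = "G4", fdr = 0.05,
                       var_equal = TRUE) {
  stopifnot(inherits(pairs, "paired_compartments"))
  if (fdr < 0 || fdr > 1) stop("fdr must lie in [0, 1]")
  g <- epithelium_groups[pairs$epithelium$samples$sample_id]
  if (anyNA(g)) stop("every pair's epithelium needs a subgroup label")
  in_group <- g == target
  if (sum(in_group) < 2)
    stop("subgroup '", target, "' has fewer than 2 stroma samples")
  if (sum(!in_group) < 2)
    stop("complement of subgroup '", target,
         "' has fewer than 2 stroma samples")
  keep <- !pairs$stroma$probes$is_control
  m <- pairs$stroma$values[keep, , drop = FALSE]
  res <- .row_ttest(m, in_group, var_equal)
  out <- data.frame(probe_id = rownames(m), res,
                    q = stats::p.adjust(res$p, "BH"),
                    stringsAsFactors = FALSE)
  out$direction <- ifelse(out$mean_diff > 0, "up", "down")
  out$selected <- !is.na(out$q) & out$q < fdr
  rownames(out) <- NULL
  attr(out, "target") <- target
  attr(out, "fdr") <- fdr
  class(out) <- c("stromal_de", "data.frame")
  out
}
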