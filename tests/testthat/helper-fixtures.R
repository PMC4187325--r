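# shared fixture builders (all data generated in code)

# bare expression matrix from a numeric matrix, with optional control rows
make_expr <- function(values, is_control = rep(FALSE, nrow(values)),
                      study = "s1", tissue = "bulk", pair_id = NA) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("p%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("smp%03d", seq_len(ncol(values)))
  expr_matrix(
    values,
    data.frame(probe_id = rownames(values),
               gene_symbol = paste0("G_", rownames(values)),
               is_control = is_control, stringsAsFactors = FALSE),
    data.frame(sample_id = colnames(values),
               study_id = rep_len(study, ncol(values)),
               tissue = rep_len(tissue, ncol(values)),
               pair_id = rep_len(pair_id, ncol(values)),
               stringsAsFactors = FALSE))
}

# small default-structured cohort for module tests (fast to generate)
small_spec <- function(seed = 1, ...) {
  args <- list(n_studies = 3, samples_per_study = 60, n_probes = 300,
               n_control_probes = 20, n_batch_factors = 2,
               n_early_genes = 15, n_late_genes = 15, n_stromal_probes = 15,
               stroma_pairs = 20, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(cohort_spec, args)
}

# exponential 2-group survival fixture with known hazard ratio
sim_two_group <- function(n, hr, seed, base = 0.1, cens = 15) {
  set.seed(seed)
  grp <- rep(0:1, each = n / 2)
  t <- stats::rexp(n, rate = base * hr^grp)
  data.frame(time = pmin(t, cens), event = as.integer(t < cens), group = grp)
}

# independent brute-force centroid agglomeration: recomputes *all* pairwise
# centroid distances from scratch at every step (quadratic-time oracle)
oracle_centroid <- function(mat, distance = "correlation") {
  d_fun <- function(a, b) {
    if (distance == "correlation") 1 - stats::cor(a, b) else
      sqrt(sum((a - b)^2))
  }
  clusters <- lapply(seq_len(nrow(mat)), function(i) i)
  heights <- numeric(0)
  partitions <- list(lapply(clusters, identity))
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      ci <- colMeans(mat[clusters[[i]], , drop = FALSE])
      cj <- colMeans(mat[clusters[[j]], , drop = FALSE])
      d <- d_fun(ci, cj)
      if (d < best[1]) best <- c(d, i, j)
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, best[1])
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
    partitions[[length(partitions) + 1]] <- clusters
  }
  list(heights = heights, partitions = partitions)
}

# partition labels (integers) from an oracle partition list at k clusters
oracle_cut <- function(oracle, n, k) {
  part <- oracle$partitions[[n - k + 1]]
  lab <- integer(n)
  for (ci in seq_along(part)) lab[part[[ci]]] <- ci
  lab
}

# agreement of two partitions up to label permutation
same_partition <- function(a, b) {
  ta <- table(a, b)
  sum(ta > 0) == length(unique(a)) && length(unique(a)) == length(unique(b))
}

# explicit Cox partial likelihood (no ties) for a single binary/continuous
# covariate; used as a grid-search oracle
partial_loglik <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- which(time >= time[i])
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}

# two-sided Fisher exact p by exhaustive hypergeometric enumeration
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n_ <- c + d; k <- a + c
  lo <- max(0, k - n_); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
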