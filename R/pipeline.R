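#' Configuration of an end-to-end pipeline run
#'
#' Exactly one input source must be given: either a [cohort_spec()] (the
#' cohort is synthesized) or `input_dir` (a directory written by
#' [write_cohort()]). All stage parameters default to the analysis's
#' standard values: 40 harmonization components, discovery screen at
#' p < 0.001, four sample groups and probe clusters, stromal FDR < 0.05,
#' cascade thresholds r > 0.25 / FDR < 0.05 / p < 0.01, 5-year early/late
#' boundary and 15-year long-follow-up rule.
#'
#' @param spec a [cohort_spec()], or `NULL` when reading from disk.
#' @param input_dir directory holding `expression.tsv` / `clinical.tsv`,
#'   or `NULL` when synthesizing.
#' @param out_dir output directory for stage outputs and the manifest.
#' @param n_components control-probe components removed in harmonization.
#' @param screen_threshold discovery screen p threshold.
#' @param boundary early/late boundary (years).
#' @param long_followup minimum event-free follow-up of the `none` timing
#'   group (years).
#' @param k_samples,k_probes cluster counts.
#' @param stromal_fdr FDR for the stromal signature.
#' @param r_min,de_fdr,cox_p cascade thresholds.
#' @param endpoint screen endpoint, `"rfs"` or `"dmfs"`.
#' @param discovery_filter restrict the discovery cohort to node-negative,
#'   systemically untreated bulk samples (the study design the screen
#'   assumes).
#' @param seed seed for any synthesis step.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = NULL, input_dir = NULL,
                            out_dir = tempfile("dormsig_run_"),
                            n_components = 40, screen_threshold = 0.001,
                            boundary = 5, long_followup = 15,
                            k_samples = 4, k_probes = 4,
                            stromal_fdr = 0.05, r_min = 0.25,
                            de_fdr = 0.05, cox_p = 0.01,
                            endpoint = "rfs", discovery_filter = TRUE,
                            seed = 1) {
  if (is.null(spec) == is.null(input_dir))
    stop("provide exactly one of `spec` (synthesize) or `input_dir` (load)")
  stopifnot(screen_threshold >= 0, screen_threshold <= 1,
            stromal_fdr > 0, stromal_fdr < 1,
            boundary > 0, long_followup > 0, k_samples >= 2, k_probes >= 1)
  cascade_criteria(r_min, de_fdr, cox_p)  # validates the three thresholds
  structure(list(spec = spec, input_dir = input_dir, out_dir = out_dir,
                 n_components = n_components,
                 screen_threshold = screen_threshold, boundary = boundary,
                 long_followup = long_followup, k_samples = k_samples,
                 k_probes = k_probes, stromal_fdr = stromal_fdr,
                 r_min = r_min, de_fdr = de_fdr, cox_p = cox_p,
                 endpoint = endpoint, discovery_filter = discovery_filter,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s (check the stage's inputs and %s)",
                 name, conditionMessage(e),
                 "parameters in the pipeline_config"), call. = FALSE))
}

#' Run the discovery-and-validation pipeline end to end
#'
#' Sequences synthesize/load, harmonize, receptor calling, the three-scheme
#' survival screen, two-way clustering with subtype enrichment, stromal
#' signature discovery (SPC1), the epithelial cascade (EPC1), timing-group
#' validation, and the probe-cluster concordance score. Stage outputs are
#' written to `config$out_dir` as tab-delimited tables plus a JSON manifest
#' recording parameters, seed and file hashes; a rerun with the same
#' configuration reproduces them bit for bit.
#'
#' The subgroup playing the late-recurrence role ("G4-like") is chosen as
#' the sample group whose members have the largest share of late events,
#' not by label, since dendrogram-order labels are arbitrary.
#'
#' @param config a [pipeline_config()].
#' @param stages character vector of stage names to run (default all, in
#'   order); upstream results must already exist in memory when a suffix
#'   is requested, so partial runs are mainly useful programmatically via
#'   the returned `state`.
#' @return Invisibly, a list of class `pipeline_run` with every stage
#'   result and `manifest`.
#' @export
run_pipeline <- function(config, stages = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  all_stages <- c("data", "harmonize", "receptors", "screen", "cluster",
                  "stroma", "cascade", "validate")
  if (is.null(stages)) stages <- all_stages
  run <- list(config = config)
  files <- character(0)

  ## data ---------------------------------------------------------------
  run$cohort <- .stage("data", {
    if (!is.null(config$spec)) {
      spec <- config$spec
      spec$seed <- config$seed
      generate_cohort(do.call(cohort_spec, unclass(spec)))
    } else {
      ch <- read_cohort(config$input_dir)
      structure(list(expression = ch$expression, clinical = ch$clinical,
                     truth = ch$truth, spec = NULL),
                class = "synthetic_cohort")
    }
  })
  x <- run$cohort$expression
  clinical <- run$cohort$clinical

  ## harmonize ----------------------------------------------------------
  if ("harmonize" %in% stages) {
    run$harmonization <- .stage("harmonize", {
      k <- min(config$n_components, sum(x$probes$is_control),
               ncol(x$values) - 1L)
      model <- fit_control_structure(x, k)
      list(model = model, x = remove_structure(x, model))
    })
    x <- run$harmonization$x
  }

  ## receptor calls -----------------------------------------------------
  if ("receptors" %in% stages) {
    run$calls <- .stage("receptors", {
      marker_probes <- c(
        ER = x$probes$probe_id[x$probes$gene_symbol == "ESR1"][1],
        PR = x$probes$probe_id[x$probes$gene_symbol == "PGR"][1],
        HER2 = x$probes$probe_id[x$probes$gene_symbol == "ERBB2"][1])
      if (anyNA(marker_probes))
        stop("marker probes (ESR1/PGR/ERBB2) not found in annotation")
      tum <- which(x$samples$tissue %in% c("bulk", "epithelium"))
      xt <- x[, tum]
      models <- lapply(stats::setNames(nm = c("ER", "PR", "HER2")),
                       function(mk) {
        col <- c(ER = "ihc_er", PR = "ihc_pr", HER2 = "ihc_her2")[[mk]]
        lab <- clinical[[col]][match(xt$samples$sample_id,
                                     clinical$sample_id)]
        fit_marker_model(xt$values[marker_probes[[mk]], ], lab, marker = mk)
      })
      calls <- call_receptors(xt, clinical, models, marker_probes)
      write_receptor_calls(calls, file.path(config$out_dir,
                                            "receptor_calls.tsv"))
      list(models = models, marker_probes = marker_probes, calls = calls)
    })
    files <- c(files, "receptor_calls.tsv")
  }

  ## discovery cohort ---------------------------------------------------
  disc <- clinical$tissue == "bulk"
  if (config$discovery_filter)
    disc <- disc & clinical$node_status == 0 & clinical$systemic_treated == 0
  discovery_ids <- clinical$sample_id[disc]

  ## screen -------------------------------------------------------------
  if ("screen" %in% stages) {
    run$screen <- .stage("screen", {
      sc <- screen_genome(x[, intersect(x$samples$sample_id, discovery_ids)],
                          clinical, endpoint = config$endpoint,
                          boundary = config$boundary,
                          threshold = config$screen_threshold)
      write_screen(sc, file.path(config$out_dir, "screen.tsv"))
      sc
    })
    files <- c(files, "screen.tsv")
  }

  ## cluster ------------------------------------------------------------
  if ("cluster" %in% stages) {
    run$grouping <- .stage("cluster", {
      selected <- run$screen$probe_id[run$screen$category != "neither"]
      if (length(selected) < config$k_probes)
        stop(sprintf("only %d probes selected at p < %g; cannot cut %d clusters",
                     length(selected), config$screen_threshold,
                     config$k_probes))
      joint_ids <- c(intersect(x$samples$sample_id, discovery_ids),
                     x$samples$sample_id[x$samples$tissue == "epithelium"])
      gr <- cluster_two_way(x[selected, joint_ids],
                            k_samples = config$k_samples,
                            k_probes = config$k_probes)
      write_grouping(gr, file.path(config$out_dir, "sample_groups.tsv"),
                     file.path(config$out_dir, "probe_clusters.tsv"))
      gr
    })
    files <- c(files, "sample_groups.tsv", "probe_clusters.tsv")

    run$group_stats <- .stage("cluster", {
      g <- run$grouping$sample_groups
      bulk_ids <- intersect(names(g), discovery_ids)
      cl <- clinical[match(bulk_ids, clinical$sample_id), ]
      time <- cl[[paste0(config$endpoint, "_years")]]
      event <- cl[[paste0(config$endpoint, "_event")]]
      late_share <- tapply(event == 1 & time >= config$boundary,
                           g[bulk_ids], mean)
      # the late-recurrence role can only go to a group that is more than
      # a stray branch and is represented among the paired samples
      epi_ids <- x$samples$sample_id[x$samples$tissue == "epithelium"]
      n_bulk <- table(g[bulk_ids])
      n_epi <- table(g[intersect(names(g), epi_ids)])
      eligible <- names(n_bulk)[n_bulk >= max(10, 0.05 * length(bulk_ids)) &
                                  n_epi >= 2]
      if (!length(eligible)) eligible <- names(n_bulk)[n_bulk > 0]
      late_share_eligible <- late_share[eligible]
      enr <- subtype_enrichment(g[bulk_ids], run$calls)
      utils::write.table(enr, file.path(config$out_dir,
                                        "subtype_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cat_enr <- cluster_category_enrichment(run$grouping$probe_clusters,
                                             run$screen)
      utils::write.table(cat_enr,
                         file.path(config$out_dir,
                                   "cluster_category_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      km <- km_logrank(clinical, g[bulk_ids], scheme = "late",
                       endpoint = config$endpoint,
                       boundary = config$boundary)
      list(late_share = late_share,
           g4_like = names(which.max(late_share_eligible)),
           subtype_enrichment = enr, category_enrichment = cat_enr,
           km_late = km[c("chisq", "df", "p")])
    })
    files <- c(files, "subtype_enrichment.tsv",
               "cluster_category_enrichment.tsv")
  }

  ## stroma -------------------------------------------------------------
  if ("stroma" %in% stages) {
    run$stroma <- .stage("stroma", {
      pairs <- paired_compartments(x)
      target <- run$group_stats$g4_like
      de <- stromal_de(pairs, run$grouping$sample_groups, target = target,
                       fdr = config$stromal_fdr)
      sel <- de[de$selected, c("probe_id", "direction")]
      if (nrow(sel) < 2)
        stop("fewer than 2 stromal probes at FDR < ", config$stromal_fdr)
      spc1 <- first_pc_score(pairs$stroma, sel, name = "SPC1")
      write_metagene(spc1, file.path(config$out_dir, "spc1_signature.tsv"),
                     file.path(config$out_dir, "spc1_scores.tsv"))
      # order subgroups by their late-event share for the trend test
      ord <- names(sort(run$group_stats$late_share))
      g_epi <- run$grouping$sample_groups[pairs$epithelium$samples$sample_id]
      g_pair <- stats::setNames(factor(as.character(g_epi), levels = ord),
                                pairs$stroma$samples$sample_id)
      trend <- tryCatch(trend_across_groups(spc1, g_pair),
                        error = function(e) NULL)
      list(pairs = pairs, target = target, de = de, signature = sel,
           spc1 = spc1, trend = trend)
    })
    files <- c(files, "spc1_signature.tsv", "spc1_scores.tsv")
  }

  ## cascade ------------------------------------------------------------
  if ("cascade" %in% stages) {
    run$cascade <- .stage("cascade", {
      sig <- cascade_select(
        run$stroma$pairs, run$stroma$spc1, run$grouping$sample_groups,
        x[, intersect(x$samples$sample_id, discovery_ids)], clinical,
        criteria = cascade_criteria(config$r_min, config$de_fdr,
                                    config$cox_p),
        target = run$stroma$target, endpoint = config$endpoint,
        boundary = config$boundary)
      utils::write.table(as.data.frame(sig),
                         file.path(config$out_dir, "cascade_signature.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      epc1 <- NULL
      if (nrow(sig) >= 2) {
        tum_ids <- x$samples$sample_id[x$samples$tissue %in%
                                         c("bulk", "epithelium")]
        epc1 <- first_pc_score(x[, tum_ids], sig$probe_id, name = "EPC1")
        write_metagene(epc1, file.path(config$out_dir,
                                       "epc1_signature.tsv"),
                       file.path(config$out_dir, "epc1_scores.tsv"))
      }
      list(signature = sig, epc1 = epc1)
    })
    files <- c(files, "cascade_signature.tsv")
    if (!is.null(run$cascade$epc1))
      files <- c(files, "epc1_signature.tsv", "epc1_scores.tsv")
  }

  ## validate -----------------------------------------------------------
  if ("validate" %in% stages) {
    run$validation <- .stage("validate", {
      if (is.null(run$cascade$epc1)) list(skipped = "empty signature")
      else {
      tg <- timing_groups(clinical, boundary = config$boundary,
                          long_followup = config$long_followup)
      times <- stats::setNames(clinical$dmfs_years, clinical$sample_id)
      val <- validate_signature(run$cascade$epc1, tg, times = times)
      # concordance of the late-enriched probe cluster's metagene with EPC1
      pc <- run$grouping$probe_clusters
      late_dir <- run$screen$probe_id[run$screen$category ==
                                        "late-associated" &
                                        run$screen$direction == "direct"]
      n_late_dir <- tapply(names(pc) %in% late_dir, pc, sum)
      c4_like <- names(which.max(n_late_dir))
      c4_probes <- names(pc)[pc == c4_like]
      conc <- if (length(c4_probes) >= 2) {
        tum_ids <- x$samples$sample_id[x$samples$tissue %in%
                                         c("bulk", "epithelium")]
        concordance_scores(x[, tum_ids], c4_probes,
                           run$cascade$signature$probe_id)
      } else NULL
      rep_df <- data.frame(
        comparison = val$pairwise$comparison,
        statistic = val$pairwise$statistic, p = val$pairwise$p)
      utils::write.table(rep_df,
                         file.path(config$out_dir, "validation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(timing = tg, validation = val, c4_like = c4_like,
           concordance = conc)
      }
    })
    files <- c(files, "validation.tsv")
  }

  ## manifest -----------------------------------------------------------
  paths <- file.path(config$out_dir, files)
  params <- unclass(config)
  params$spec <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("dormsig")),
    seed = config$seed,
    parameters = params,
    stages = stages,
    files = stats::setNames(as.list(unname(tools::md5sum(paths))), files))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  run$manifest <- manifest
  class(run) <- "pipeline_run"
  invisible(run)
}

#' Subtype enrichment of sample groups (contingency layout)
#'
#' For every (group, subtype) pair, counts members and computes the 2x2
#' enrichment of subtype membership within the group against all other
#' groups.
#'
#' @param groups factor of group labels named by sample ID.
#' @param calls a [call_receptors()] result (or its `list` wrapper from
#'   the pipeline) covering those samples.
#' @return Long-format data.frame with `group`, `subtype`, `n`, `pct`,
#'   `fisher_p`, `odds_ratio`, `ci_low`, `ci_high`.
#' @export
subtype_enrichment <- function(groups, calls) {
  if (!is.data.frame(calls) && !is.null(calls$calls)) calls <- calls$calls
  groups <- droplevels(factor(groups[!is.na(groups)]))
  sub <- calls$subtype[match(names(groups), calls$sample_id)]
  if (anyNA(sub)) stop("receptor calls missing for some grouped samples")
  res <- list()
  for (g in levels(groups)) {
    for (s in c("LumA", "LumB", "HER2type", "TNBC")) {
      a <- sum(groups == g & sub == s)
      b <- sum(groups == g & sub != s)
      c_ <- sum(groups != g & sub == s)
      d <- sum(groups != g & sub != s)
      e <- tryCatch(enrichment_2x2(a, b, c_, d), error = function(e) NULL)
      res[[length(res) + 1]] <- data.frame(
        group = g, subtype = s, n = a,
        pct = round(100 * a / (a + b), 1),
        fisher_p = if (is.null(e)) NA_real_ else e$fisher_p,
        odds_ratio = if (is.null(e)) NA_real_ else e$odds_ratio,
        ci_low = if (is.null(e)) NA_real_ else e$ci_low,
        ci_high = if (is.null(e)) NA_real_ else e$ci_high,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Summarize a completed pipeline run directory
#'
#' Builds a plain-markdown report from a run directory's tables and
#' manifest only (so regenerating it is a pure function of the run
#' directory): cohort and screen summaries, the subtype-enrichment and
#' cluster-category tables, and the validation statistics. A run whose
#' cascade selected no probe is reported as an empty signature.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param file output path (default `report.md` inside `run_dir`).
#' @return The report path, invisibly.
#' @export
make_report <- function(run_dir, file = file.path(run_dir, "report.md")) {
  mpath <- file.path(run_dir, "manifest.json")
  if (!file.exists(mpath)) stop("incomplete run: no manifest in ", run_dir)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  rd <- function(f) {
    p <- file.path(run_dir, f)
    if (file.exists(p)) utils::read.delim(p, stringsAsFactors = FALSE)
    else NULL
  }
  screen <- rd("screen.tsv")
  enr <- rd("subtype_enrichment.tsv")
  cat_enr <- rd("cluster_category_enrichment.tsv")
  sig <- rd("cascade_signature.tsv")
  val <- rd("validation.tsv")
  fmt_tab <- function(df) {
    if (is.null(df)) return("(not produced)")
    paste(c(paste(names(df), collapse = "\t"),
            apply(df, 1, paste, collapse = "\t")), collapse = "\n")
  }
  lines <- c(
    "# Pipeline run report", "",
    sprintf("Seed: %s", manifest$seed), "",
    "## Survival screen",
    if (is.null(screen)) "(not produced)" else sprintf(
      "%d probes screened; %d early-associated, %d late-associated, %d both.",
      nrow(screen), sum(screen$category == "early-associated"),
      sum(screen$category == "late-associated"),
      sum(screen$category == "both")),
    "", "## Subtype distribution across subgroups", fmt_tab(enr),
    "", "## Screen-category enrichment across probe clusters",
    fmt_tab(cat_enr),
    "", "## Epithelial signature",
    if (is.null(sig) || nrow(sig) == 0)
      "Empty signature: no probe passed all three cascade filters."
    else sprintf("%d probes selected by the cascade.", nrow(sig)),
    "", "## Timing-group validation", fmt_tab(val), "")
  writeLines(lines, file)
  invisible(file)
}
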