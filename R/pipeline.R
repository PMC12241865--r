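read_run_catalog <- function(run_dir, window_length = 100) {
  bed <- file.path(run_dir, "ref.bed")
  fasta <- file.path(run_dir, "ref.fasta")
  ids <- utils::read.table(bed, sep = "\t", stringsAsFactors = FALSE)[[4L]]
  load_catalog(bed, if (file.exists(fasta)) fasta else NULL,
               window_length = window_length,
               host_gene_ids = ids[!grepl("^HERV", ids)])
}

#' Simulate a synthetic cohort run directory
#'
#' Thin wrapper over [cohort_preset()] + [simulate_cohort()]: writes the
#' reference, per-sample SAMs and barcode tables, sample metadata and the
#' ground-truth manifest under `out_dir`.
#'
#' @param out_dir Run directory.
#' @param seed Integer seed.
#' @param ... Passed to [cohort_preset()].
#' @return Invisibly, the [simulate_cohort()] result.
#' @export
wha_simulate <- function(out_dir, seed = 1, ...) {
  sim <- simulate_cohort(cohort_preset(seed = seed, ...), out_dir)
  message("simulated cohort: ", nrow(sim$samples), " samples, ",
          nrow(sim$catalog$regions), " regions -> ", out_dir)
  invisible(sim)
}

#' Score every sample of a run directory
#'
#' Ingests each sample's SAM through the barcode and identity filters,
#' computes window profiles and writes one locus-call row per (sample,
#' region) to `calls.tsv`, with the thresholds recorded in
#' `thresholds.tsv`. Per-sample reads surviving each filter are logged.
#'
#' @param run_dir Run directory created by [wha_simulate()] (or laid out
#'   the same way: `ref.bed`, `ref.fasta`, `samples.tsv`,
#'   `<sample>.sam`, `<sample>.barcodes.tsv`).
#' @param thresholds A [wha_thresholds()].
#' @return Invisibly, the calls `data.frame`.
#' @export
wha_score <- function(run_dir, thresholds = wha_thresholds()) {
  catalog <- read_run_catalog(run_dir, thresholds$window_length)
  meta <- utils::read.delim(file.path(run_dir, "samples.tsv"),
                            stringsAsFactors = FALSE)
  calls <- do.call(rbind, lapply(meta$sample_id, function(sid) {
    prof <- ingest_sam(file.path(run_dir, paste0(sid, ".sam")), catalog,
                       file.path(run_dir, paste0(sid, ".barcodes.tsv")),
                       sample_id = sid,
                       min_identity = thresholds$min_identity)
    fc <- attr(prof, "filter_counts")
    message(sprintf(
      "%s: %d reads, %d after barcode filter (%d unknown), %d after identity filter",
      sid, fc["n_total"], fc["n_barcode_pass"], fc["n_unknown_barcode"],
      fc["n_identity_pass"]))
    score_sample(prof, catalog, thresholds, sample_id = sid)
  }))
  utils::write.table(calls, file.path(run_dir, "calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  thr <- data.frame(key = names(unclass(thresholds)),
                    value = unlist(lapply(unclass(thresholds), as.character)))
  utils::write.table(thr, file.path(run_dir, "thresholds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(calls)
}

read_run_calls <- function(run_dir) {
  calls <- utils::read.delim(file.path(run_dir, "calls.tsv"),
                             stringsAsFactors = FALSE)
  meta <- utils::read.delim(file.path(run_dir, "samples.tsv"),
                            stringsAsFactors = FALSE)
  presence_matrix(calls, meta)
}

#' Pangenome-filter the loci of a scored run
#'
#' Controls are the samples whose cohort label is `control_cohort`; all
#' other samples are patients. Writes the retained region ids to
#' `filtered_loci.tsv`.
#'
#' @param run_dir Scored run directory (after [wha_score()]).
#' @param control_cohort Cohort label of the healthy panel.
#' @return Invisibly, the retained region ids.
#' @export
wha_filter <- function(run_dir, control_cohort = "control") {
  pm <- read_run_calls(run_dir)
  ctrl <- pm$samples$sample_id[pm$samples$cohort == control_cohort]
  pat <- setdiff(pm$samples$sample_id, ctrl)
  keep <- pangenome_filter(pm, ctrl, pat)
  utils::write.table(data.frame(region_id = keep),
                     file.path(run_dir, "filtered_loci.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(length(keep), " loci retained by pangenome filter")
  invisible(keep)
}

#' Cohort comparisons for a scored run
#'
#' Welch t-tests per retained HERV locus (both window-count and depth
#' metrics) between two cohorts, plus ANOVA + Tukey HSD across all cohorts
#' for the host genes. Writes `comparisons.tsv`, `host_anova.tsv` and
#' `host_tukey.tsv`.
#'
#' @param run_dir Scored (and filtered) run directory.
#' @param group_a,group_b Cohort labels for the two-group locus contrasts.
#' @param alpha Significance level.
#' @return Invisibly, list with `comparisons`, `host_anova`, `host_tukey`.
#' @export
wha_compare <- function(run_dir, group_a = "PASC", group_b = "acute",
                        alpha = 0.05) {
  pm <- read_run_calls(run_dir)
  flt <- file.path(run_dir, "filtered_loci.tsv")
  loci <- if (file.exists(flt))
    utils::read.delim(flt, stringsAsFactors = FALSE)$region_id
  else colnames(pm$status)
  ids_a <- pm$samples$sample_id[pm$samples$cohort == group_a]
  ids_b <- pm$samples$sample_id[pm$samples$cohort == group_b]
  cmp <- rbind(
    compare_cohorts(pm, ids_a, ids_b, "n_usable_windows", regions = loci,
                    alpha = alpha),
    compare_cohorts(pm, ids_a, ids_b, "locus_depth", regions = loci,
                    alpha = alpha))
  utils::write.table(cmp, file.path(run_dir, "comparisons.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  host <- utils::read.table(file.path(run_dir, "ref.bed"), sep = "\t",
                            stringsAsFactors = FALSE)[[4L]]
  host <- host[!grepl("^HERV", host)]
  groups <- split(pm$samples$sample_id, pm$samples$cohort)
  groups <- groups[lengths(groups) >= 2L]
  res <- list(comparisons = cmp, host_anova = NULL, host_tukey = NULL)
  if (length(host) && length(groups) >= 2L) {
    aw <- host_gene_anova(pm, groups, host, "n_usable_windows", alpha)
    ad <- host_gene_anova(pm, groups, host, "locus_depth", alpha)
    res$host_anova <- rbind(aw$anova, ad$anova)
    res$host_tukey <- rbind(aw$tukey, ad$tukey)
    utils::write.table(res$host_anova, file.path(run_dir, "host_anova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$host_tukey, file.path(run_dir, "host_tukey.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(res)
}

#' Presence-matrix report for a scored run
#'
#' Writes the wide status matrix (`presence_matrix.tsv`), a long
#' heatmap-ready table (`heatmap_long.tsv`: sample, region, status, usable
#' windows, depth) restricted to the filtered loci when a filter output is
#' present, and optionally a PNG heatmap of usable-window counts.
#'
#' @param run_dir Scored run directory.
#' @param png Logical; also render `heatmap.png`.
#' @return Invisibly, the long-format `data.frame`.
#' @export
wha_report <- function(run_dir, png = FALSE) {
  pm <- read_run_calls(run_dir)
  flt <- file.path(run_dir, "filtered_loci.tsv")
  loci <- if (file.exists(flt))
    utils::read.delim(flt, stringsAsFactors = FALSE)$region_id
  else colnames(pm$status)
  if (!length(loci)) {
    warning("no loci retained; writing header-only report", call. = FALSE)
    long <- data.frame(sample_id = character(), region_id = character(),
                       status = character(), n_usable_windows = integer(),
                       locus_depth = numeric())
  } else {
    wide <- data.frame(sample_id = rownames(pm$status),
                       pm$status[, loci, drop = FALSE],
                       check.names = FALSE)
    utils::write.table(wide, file.path(run_dir, "presence_matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    long <- do.call(rbind, lapply(loci, function(r)
      data.frame(sample_id = rownames(pm$status), region_id = r,
                 status = pm$status[, r], n_usable_windows = pm$windows[, r],
                 locus_depth = pm$depth[, r], stringsAsFactors = FALSE)))
    rownames(long) <- NULL
  }
  utils::write.table(long, file.path(run_dir, "heatmap_long.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (png && length(loci)) {
    grDevices::png(file.path(run_dir, "heatmap.png"), width = 900,
                   height = 600)
    m <- pm$windows[, loci, drop = FALSE]
    graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                    col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                    xlab = "locus", ylab = "sample", axes = FALSE,
                    main = "usable windows per locus")
    graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = .6)
    graphics::axis(2, seq_len(nrow(m)), rownames(m), las = 2, cex.axis = .5)
    grDevices::dev.off()
  }
  invisible(long)
}

#' Significance power of the amplification contrast
#'
#' Stats-level replicate study of the two-group usable-window comparison:
#' per replicate, one amplified locus (group means differing by
#' `delta_windows`) and `n_null` null loci (equal means) are drawn with
#' Gaussian between-sample jitter and tested with [compare_windows_ttest()].
#' Reports, per replicate, whether the amplified locus was flagged and how
#' many null loci were false positives.
#'
#' @param n_rep Number of replicates.
#' @param n_a,n_b Group sizes (amplified contrast).
#' @param mean_b,delta_windows Baseline mean and amplification effect.
#' @param sd Between-sample standard deviation of window counts.
#' @param n_null Number of null loci per replicate.
#' @param null_n Per-group sample count for null loci.
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @return `data.frame` with one row per replicate: `significant`,
#'   `n_false_pos`.
#' @export
amplification_power <- function(n_rep = 200, n_a = 12, n_b = 11,
                                mean_b = 15, delta_windows = 10, sd = 2,
                                n_null = 10, null_n = 4, alpha = 0.05,
                                seed = 1) {
  set.seed(seed)
  out <- data.frame(significant = logical(n_rep),
                    n_false_pos = integer(n_rep))
  for (r in seq_len(n_rep)) {
    a <- round(stats::rnorm(n_a, mean_b + delta_windows, sd))
    b <- round(stats::rnorm(n_b, mean_b, sd))
    out$significant[r] <-
      compare_windows_ttest(a, b, alpha = alpha)$significant
    fp <- 0L
    for (k in seq_len(n_null)) {
      x <- round(stats::rnorm(null_n, mean_b, sd))
      y <- round(stats::rnorm(null_n, mean_b, sd))
      fp <- fp + compare_windows_ttest(x, y, alpha = alpha)$significant
    }
    out$n_false_pos[r] <- fp
  }
  out
}
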