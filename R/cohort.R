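#' Build a presence matrix from locus calls
#'
#' Stacks per-sample call tables into parallel samples-by-regions matrices
#' of status, usable-window counts and locus depth — the cohort-level
#' red/yellow grid the pangenome filter and set arithmetic operate on.
#'
#' @param calls `data.frame` of locus calls for all samples (rbind of
#'   [score_sample()] outputs).
#' @param sample_meta `data.frame` with columns `sample_id`, `cohort`
#'   (and optionally `timepoint`).
#' @return A `PresenceMatrix`: list with `samples` (metadata, row order),
#'   `regions`, and matrices `status`, `windows`, `depth`.
#' @export
presence_matrix <- function(calls, sample_meta) {
  stopifnot(all(c("sample_id", "region_id", "status", "n_usable_windows",
                  "locus_depth") %in% names(calls)))
  stopifnot(all(c("sample_id", "cohort") %in% names(sample_meta)))
  samples <- sample_meta$sample_id
  regions <- unique(calls$region_id)
  missing <- setdiff(unique(calls$sample_id), samples)
  if (length(missing))
    stop("calls contain sample(s) absent from metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  shape <- function(col, fill) {
    m <- matrix(fill, nrow = length(samples), ncol = length(regions),
                dimnames = list(samples, regions))
    m[cbind(match(calls$sample_id, samples),
            match(calls$region_id, regions))] <- calls[[col]]
    m
  }
  structure(list(samples = sample_meta, regions = regions,
                 status = shape("status", "negative"),
                 windows = shape("n_usable_windows", 0L),
                 depth = shape("locus_depth", 0)),
            class = "PresenceMatrix")
}

check_sample_ids <- function(pm, ids, what) {
  unknown <- setdiff(ids, rownames(pm$status))
  if (length(unknown))
    stop("unknown ", what, " sample id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
}

#' Pangenome-control filtering of loci
#'
#' Retains a locus iff it is negative in every control sample and positive
#' in at least one patient sample — the filter that removes loci with any
#' constitutive expression in the healthy panel.
#'
#' @param pm A `PresenceMatrix`.
#' @param control_ids,patient_ids Disjoint, non-empty sample-id vectors.
#' @return Character vector of retained region ids.
#' @export
pangenome_filter <- function(pm, control_ids, patient_ids) {
  stopifnot(inherits(pm, "PresenceMatrix"))
  if (!length(control_ids) || !length(patient_ids))
    stop("control and patient groups must be non-empty", call. = FALSE)
  if (length(intersect(control_ids, patient_ids)))
    stop("control and patient groups overlap: ",
         paste(intersect(control_ids, patient_ids), collapse = ", "),
         call. = FALSE)
  check_sample_ids(pm, control_ids, "control")
  check_sample_ids(pm, patient_ids, "patient")
  ctrl_neg <- colSums(pm$status[control_ids, , drop = FALSE] ==
                        "positive") == 0L
  pat_pos <- colSums(pm$status[patient_ids, , drop = FALSE] ==
                       "positive") >= 1L
  colnames(pm$status)[ctrl_neg & pat_pos]
}

#' Loci positive in every sample of a group
#'
#' @param pm A `PresenceMatrix`.
#' @param group_ids Non-empty sample ids.
#' @return Character vector of region ids positive in all group samples.
#' @export
shared_loci <- function(pm, group_ids) {
  stopifnot(inherits(pm, "PresenceMatrix"))
  if (!length(group_ids)) stop("group must be non-empty", call. = FALSE)
  check_sample_ids(pm, group_ids, "group")
  all_pos <- colSums(pm$status[group_ids, , drop = FALSE] == "positive") ==
    length(group_ids)
  colnames(pm$status)[all_pos]
}

#' Unique and shared positive loci between two groups
#'
#' A locus counts for a group when it is positive in at least one of its
#' samples; `unique_a`/`unique_b` are loci positive only in that group and
#' `shared` are loci positive in at least one sample of each.
#'
#' @param pm A `PresenceMatrix`.
#' @param group_a_ids,group_b_ids Disjoint sample-id vectors.
#' @return List with id vectors `unique_a`, `unique_b`, `shared` and the
#'   corresponding `counts`.
#' @export
set_summary <- function(pm, group_a_ids, group_b_ids) {
  stopifnot(inherits(pm, "PresenceMatrix"))
  if (length(intersect(group_a_ids, group_b_ids)))
    stop("groups overlap", call. = FALSE)
  check_sample_ids(pm, group_a_ids, "group A")
  check_sample_ids(pm, group_b_ids, "group B")
  pos_in <- function(ids)
    colnames(pm$status)[colSums(pm$status[ids, , drop = FALSE] ==
                                  "positive") >= 1L]
  a <- pos_in(group_a_ids); b <- pos_in(group_b_ids)
  out <- list(unique_a = setdiff(a, b), unique_b = setdiff(b, a),
              shared = intersect(a, b))
  out$counts <- c(unique_a = length(out$unique_a),
                  unique_b = length(out$unique_b),
                  shared = length(out$shared))
  out
}

#' Two-group comparison of a locus metric (Welch t-test)
#'
#' Welch's unequal-variance two-sample t-test, two-sided; the variant used
#' for window-count and depth contrasts between cohorts. Both groups
#' constant and equal is reported as statistic 0, p = 1.
#'
#' @param values_a,values_b Numeric vectors (length >= 2, finite).
#' @param region_id,metric Labels carried into the result row.
#' @param alpha Significance level (default 0.05).
#' @return One-row `data.frame`: `region_id`, `metric`, `test`,
#'   `statistic`, `df`, `p_value`, `mean_a`, `mean_b`, `n_a`, `n_b`,
#'   `significant`.
#' @export
compare_windows_ttest <- function(values_a, values_b,
                                  region_id = NA_character_,
                                  metric = "n_usable_windows",
                                  alpha = 0.05) {
  if (length(values_a) < 2L)
    stop("group A has fewer than 2 values", call. = FALSE)
  if (length(values_b) < 2L)
    stop("group B has fewer than 2 values", call. = FALSE)
  if (!all(is.finite(c(values_a, values_b))))
    stop("non-finite values in input", call. = FALSE)
  va <- stats::var(values_a); vb <- stats::var(values_b)
  if (va == 0 && vb == 0) {
    if (mean(values_a) == mean(values_b)) {
      stat <- 0; p <- 1; df <- NA_real_
    } else {
      stat <- sign(mean(values_a) - mean(values_b)) * Inf
      p <- 0; df <- NA_real_
    }
  } else {
    tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
    stat <- unname(tt$statistic); df <- unname(tt$parameter)
    p <- tt$p.value
  }
  data.frame(region_id = region_id, metric = metric, test = "welch_t",
             statistic = stat, df = df, p_value = p,
             mean_a = mean(values_a), mean_b = mean(values_b),
             n_a = length(values_a), n_b = length(values_b),
             significant = p < alpha, stringsAsFactors = FALSE)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Fits a one-way ANOVA across the groups and follows it with Tukey's
#' honestly-significant-difference test (studentized-range adjusted p per
#' group pair). When every value across all groups is an identical
#' constant, the F ratio is 0/0; this degenerate case is reported as p = 1
#' for the omnibus test and every pair.
#'
#' @param values_by_group Named list mapping group label to numeric vector
#'   (>= 2 groups, each of length >= 2).
#' @param gene_id Label carried into the result.
#' @param metric Metric label.
#' @param alpha Significance level.
#' @return List with `anova` (one-row data.frame: `gene_id`, `metric`,
#'   `statistic` = F, `df1`, `df2`, `p_value`, `significant`) and `tukey`
#'   (one row per group pair with adjusted p).
#' @export
anova_tukey <- function(values_by_group, gene_id = NA_character_,
                        metric = "n_usable_windows", alpha = 0.05) {
  if (length(values_by_group) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  small <- names(values_by_group)[lengths(values_by_group) < 2L]
  if (length(small))
    stop("group '", small[1L], "' has fewer than 2 values", call. = FALSE)
  dat <- data.frame(
    value = unlist(values_by_group, use.names = FALSE),
    group = factor(rep(names(values_by_group),
                       lengths(values_by_group))))
  if (!all(is.finite(dat$value)))
    stop("non-finite values in input", call. = FALSE)
  pairs_lab <- utils::combn(levels(dat$group), 2L)
  pair_names <- paste(pairs_lab[2L, ], pairs_lab[1L, ], sep = "-")
  if (stats::var(dat$value) == 0) {
    an <- data.frame(gene_id = gene_id, metric = metric, test = "anova",
                     statistic = 0, df1 = nlevels(dat$group) - 1L,
                     df2 = nrow(dat) - nlevels(dat$group),
                     p_value = 1, significant = FALSE,
                     stringsAsFactors = FALSE)
    tk <- data.frame(gene_id = gene_id, metric = metric, pair = pair_names,
                     diff = 0, p_adj = 1, significant = FALSE,
                     stringsAsFactors = FALSE)
    return(list(anova = an, tukey = tk))
  }
  fit <- stats::aov(value ~ group, data = dat)
  tab <- summary(fit)[[1L]]
  fstat <- tab["group", "F value"]
  p <- tab["group", "Pr(>F)"]
  if (!is.finite(p)) p <- 0   # zero residual variance, groups differ
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(gene_id = gene_id, metric = metric,
                      pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  list(anova = data.frame(gene_id = gene_id, metric = metric,
                          test = "anova", statistic = fstat,
                          df1 = tab["group", "Df"],
                          df2 = tab["Residuals", "Df"],
                          p_value = p, significant = p < alpha,
                          stringsAsFactors = FALSE),
       tukey = tukey)
}

#' Per-locus two-group comparisons over a presence matrix
#'
#' For each requested region, compares the metric between the two groups'
#' positive samples (negative samples are excluded by default, mirroring
#' comparisons restricted to samples where the locus is called). Regions
#' with fewer than `min_n` positive samples in either group are skipped.
#'
#' @param pm A `PresenceMatrix`.
#' @param group_a_ids,group_b_ids Disjoint sample-id vectors.
#' @param metric `"n_usable_windows"` or `"locus_depth"`.
#' @param regions Region ids to test (default: all).
#' @param include_negative Include negative samples (their zero/low values)
#'   instead of restricting to positive samples.
#' @param min_n Minimum per-group sample count (default 2).
#' @param alpha Significance level.
#' @param p_adjust Optional `"BH"` to append Benjamini-Hochberg adjusted
#'   p-values.
#' @return `data.frame`, one row per tested region.
#' @export
compare_cohorts <- function(pm, group_a_ids, group_b_ids,
                            metric = c("n_usable_windows", "locus_depth"),
                            regions = NULL, include_negative = FALSE,
                            min_n = 2L, alpha = 0.05, p_adjust = NULL) {
  stopifnot(inherits(pm, "PresenceMatrix"))
  metric <- match.arg(metric)
  vals <- if (metric == "n_usable_windows") pm$windows else pm$depth
  if (is.null(regions)) regions <- colnames(pm$status)
  check_sample_ids(pm, c(group_a_ids, group_b_ids), "comparison")
  rows <- list()
  for (rid in regions) {
    pick <- function(ids) {
      v <- vals[ids, rid]
      if (!include_negative) v <- v[pm$status[ids, rid] == "positive"]
      v
    }
    a <- pick(group_a_ids); b <- pick(group_b_ids)
    if (length(a) < min_n || length(b) < min_n) next
    rows[[rid]] <- compare_windows_ttest(a, b, region_id = rid,
                                         metric = metric, alpha = alpha)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else compare_windows_ttest(1:2, 1:2)[0, ]
  rownames(out) <- NULL
  if (!is.null(p_adjust) && nrow(out)) {
    out$p_adj <- stats::p.adjust(out$p_value, method = p_adjust)
    out$significant_adj <- out$p_adj < alpha
  }
  out
}

#' Host-gene group comparison (ANOVA + Tukey HSD) over a presence matrix
#'
#' @param pm A `PresenceMatrix`.
#' @param groups Named list mapping group label to sample ids.
#' @param gene_ids Regions to test (default: all).
#' @param metric `"n_usable_windows"` or `"locus_depth"`.
#' @param alpha Significance level.
#' @return List with stacked `anova` and `tukey` data.frames.
#' @export
host_gene_anova <- function(pm, groups, gene_ids = NULL,
                            metric = c("n_usable_windows", "locus_depth"),
                            alpha = 0.05) {
  stopifnot(inherits(pm, "PresenceMatrix"))
  metric <- match.arg(metric)
  vals <- if (metric == "n_usable_windows") pm$windows else pm$depth
  if (is.null(gene_ids)) gene_ids <- colnames(pm$status)
  for (ids in groups) check_sample_ids(pm, ids, "group")
  res <- lapply(gene_ids, function(g) {
    vbg <- lapply(groups, function(ids) vals[ids, g])
    anova_tukey(vbg, gene_id = g, metric = metric, alpha = alpha)
  })
  list(anova = do.call(rbind, lapply(res, `[[`, "anova")),
       tukey = do.call(rbind, lapply(res, `[[`, "tukey")))
}
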