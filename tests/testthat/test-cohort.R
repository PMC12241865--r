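fixed_pm <- function(status) {
  # build a PresenceMatrix from a character matrix of calls
  calls <- data.frame(
    sample_id = rep(rownames(status), times = ncol(status)),
    region_id = rep(colnames(status), each = nrow(status)),
    status = as.vector(status),
    n_usable_windows = ifelse(as.vector(status) == "positive", 12L, 0L),
    locus_depth = ifelse(as.vector(status) == "positive", 5, 0))
  presence_matrix(calls, data.frame(sample_id = rownames(status),
                                    cohort = "other"))
}

test_that("pangenome filter retains patient-only loci", {
  status <- matrix("negative", 4, 3,
                   dimnames = list(c("C1", "C2", "P1", "P2"),
                                   c("R1", "R2", "R3")))
  status["P1", "R1"] <- "positive"           # retained: 1 patient positive
  status["C1", "R2"] <- "positive"           # excluded: a control positive
  status["P2", "R2"] <- "positive"
  pm <- fixed_pm(status)
  expect_equal(pangenome_filter(pm, c("C1", "C2"), c("P1", "P2")), "R1")
  expect_error(pangenome_filter(pm, c("C1", "P1"), c("P1", "P2")),
               "overlap")
  expect_error(pangenome_filter(pm, "C9", "P1"), "unknown")
  expect_error(pangenome_filter(pm, character(), "P1"), "non-empty")
})

test_that("shared loci are the intersection of per-sample positive sets", {
  status <- matrix("negative", 3, 3,
                   dimnames = list(c("S1", "S2", "S3"), c("R1", "R2", "R3")))
  status["S1", c("R1", "R2")] <- "positive"
  status["S2", c("R2", "R3")] <- "positive"
  pm <- fixed_pm(status)
  expect_equal(shared_loci(pm, "S1"), c("R1", "R2"))  # single sample group
  expect_equal(shared_loci(pm, c("S1", "S2")), "R2")
  expect_equal(shared_loci(pm, c("S1", "S3")), character(0))  # disjoint
  expect_error(shared_loci(pm, "S9"), "unknown")
})

test_that("set summary partitions positives into unique and shared", {
  status <- matrix("negative", 4, 4,
                   dimnames = list(c("A1", "A2", "B1", "B2"),
                                   paste0("R", 1:4)))
  status["A1", c("R1", "R2")] <- "positive"
  status["B1", c("R2", "R3")] <- "positive"
  pm <- fixed_pm(status)
  s <- set_summary(pm, c("A1", "A2"), c("B1", "B2"))
  expect_equal(s$unique_a, "R1")
  expect_equal(s$unique_b, "R3")
  expect_equal(s$shared, "R2")
  # identical positive sets -> no uniques
  status2 <- status; status2["B1", ] <- status2["A1", ]
  s2 <- set_summary(fixed_pm(status2), c("A1", "A2"), c("B1", "B2"))
  expect_equal(unname(s2$counts), c(0L, 0L, 2L))
})

test_that("cohort set operations match brute-force oracles on fuzzed matrices", {
  set.seed(83)
  for (i in 1:100) {
    ns <- sample(4:12, 1); nr <- sample(3:20, 1)
    pm <- random_presence(ns, nr, p_pos = stats::runif(1, 0.1, 0.6))
    ids <- rownames(pm$status)
    ctrl <- sample(ids, sample(1:(ns - 2), 1))
    rest <- setdiff(ids, ctrl)
    pat <- sample(rest, sample(1:length(rest), 1))
    expect_equal(pangenome_filter(pm, ctrl, pat),
                 pangenome_oracle(pm$status, ctrl, pat))
    grp <- sample(ids, sample(1:ns, 1))
    expect_equal(shared_loci(pm, grp), shared_oracle(pm$status, grp))
    s <- set_summary(pm, ctrl, pat)
    o <- set_summary_oracle(pm$status, ctrl, pat)
    expect_equal(s[c("unique_a", "unique_b", "shared")], o)
    # conservation: uniques + shared do not exceed the group's positives
    pos_a <- sum(colSums(pm$status[ctrl, , drop = FALSE] ==
                           "positive") >= 1)
    expect_lte(length(s$unique_a) + length(s$shared), pos_a)
  }
})

test_that("Welch t-test matches the closed-form computation", {
  r <- compare_windows_ttest(c(10, 11, 12), c(1, 2, 3))
  o <- welch_oracle(c(10, 11, 12), c(1, 2, 3))
  expect_equal(r$statistic, o$t, tolerance = 1e-10)
  expect_equal(r$df, o$df, tolerance = 1e-10)
  expect_equal(r$p_value, o$p, tolerance = 1e-10)

  # identical constant samples -> statistic 0, p 1
  r0 <- compare_windows_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$p_value, welch_oracle(c(1, 2, 3), c(1, 2, 3))$p)
  rc <- compare_windows_ttest(c(5, 5), c(5, 5))
  expect_equal(rc$statistic, 0)
  expect_equal(rc$p_value, 1)

  expect_error(compare_windows_ttest(1, c(1, 2)), "group A")
  expect_error(compare_windows_ttest(c(1, 2), 3), "group B")

  set.seed(89)
  for (i in 1:100) {
    a <- stats::rnorm(sample(3:15, 1), sample(0:10, 1), stats::runif(1, .5, 3))
    b <- stats::rnorm(sample(3:15, 1), sample(0:10, 1), stats::runif(1, .5, 3))
    r <- compare_windows_ttest(a, b)
    o <- welch_oracle(a, b)
    expect_equal(r$statistic, o$t, tolerance = 1e-8)
    expect_equal(r$p_value, o$p, tolerance = 1e-8)
  }
})

test_that("ANOVA + Tukey HSD match closed forms and symmetries", {
  g <- list(ctrl = c(2, 3, 4, 3), acute = c(5, 6, 7, 6),
            pasc = c(9, 10, 11, 10))
  r <- anova_tukey(g)
  o <- anova_f_oracle(g)
  expect_equal(r$anova$statistic, o$f, tolerance = 1e-10)
  expect_equal(r$anova$p_value, o$p, tolerance = 1e-10)
  expect_equal(nrow(r$tukey), 3L)

  # Tukey pair p-values invariant to group relabeling
  g2 <- g[c("pasc", "ctrl", "acute")]
  r2 <- anova_tukey(g2)
  expect_equal(sort(r$tukey$p_adj), sort(r2$tukey$p_adj), tolerance = 1e-12)

  # identical constants across all groups -> p = 1 contract
  rconst <- anova_tukey(list(a = c(4, 4), b = c(4, 4), c = c(4, 4)))
  expect_equal(rconst$anova$p_value, 1)
  expect_true(all(rconst$tukey$p_adj == 1))

  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), "fewer than 2")
  expect_error(anova_tukey(list(a = c(1, 2))), "at least 2 groups")

  set.seed(97)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    g <- lapply(seq_len(k), function(j)
      stats::rnorm(sample(3:10, 1), sample(0:5, 1)))
    names(g) <- paste0("g", seq_len(k))
    r <- anova_tukey(g)
    o <- anova_f_oracle(g)
    expect_equal(r$anova$statistic, o$f, tolerance = 1e-8)
    expect_equal(r$anova$p_value, o$p, tolerance = 1e-8)
  }
})

test_that("per-locus cohort comparisons use positive samples only", {
  status <- matrix("negative", 6, 2,
                   dimnames = list(c("A1", "A2", "A3", "B1", "B2", "B3"),
                                   c("R1", "R2")))
  status[c("A1", "A2", "B1", "B2"), "R1"] <- "positive"
  calls <- data.frame(
    sample_id = rep(rownames(status), 2),
    region_id = rep(colnames(status), each = 6),
    status = as.vector(status),
    n_usable_windows = c(25L, 27L, 0L, 15L, 14L, 0L, rep(0L, 6)),
    locus_depth = ifelse(as.vector(status) == "positive", 5, 0))
  pm <- presence_matrix(calls, data.frame(sample_id = rownames(status),
                                          cohort = rep(c("a", "b"), each = 3)))
  cmp <- compare_cohorts(pm, c("A1", "A2", "A3"), c("B1", "B2", "B3"))
  # R2 skipped (no positive samples); R1 uses the 2+2 positive samples
  expect_equal(cmp$region_id, "R1")
  expect_equal(c(cmp$n_a, cmp$n_b), c(2L, 2L))
  expect_equal(cmp$mean_a, 26)
  expect_equal(cmp$mean_b, 14.5)
  # include_negative pulls in the zero rows
  cmp0 <- compare_cohorts(pm, c("A1", "A2", "A3"), c("B1", "B2", "B3"),
                          include_negative = TRUE)
  expect_equal(c(cmp0$n_a[1], cmp0$n_b[1]), c(3L, 3L))
})
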