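# independent brute-force oracles; deliberately naive implementations

pileup_oracle <- function(reads, scheme) {
  region_length <- scheme$win_end[nrow(scheme)]
  per_base <- integer(region_length)
  for (i in seq_len(nrow(reads))) {
    idx <- (reads$pos[i] + 1L):(reads$pos[i] + reads$aligned_length[i])
    per_base[idx] <- per_base[idx] + 1L
  }
  vapply(seq_len(nrow(scheme)), function(w)
    mean(per_base[(scheme$win_start[w] + 1L):scheme$win_end[w]]), 0)
}

pangenome_oracle <- function(status, control_ids, patient_ids) {
  keep <- character()
  for (r in colnames(status)) {
    ok_ctrl <- TRUE
    for (s in control_ids) if (status[s, r] == "positive") ok_ctrl <- FALSE
    any_pat <- FALSE
    for (s in patient_ids) if (status[s, r] == "positive") any_pat <- TRUE
    if (ok_ctrl && any_pat) keep <- c(keep, r)
  }
  keep
}

shared_oracle <- function(status, ids) {
  keep <- character()
  for (r in colnames(status)) {
    all_pos <- TRUE
    for (s in ids) if (status[s, r] != "positive") all_pos <- FALSE
    if (all_pos) keep <- c(keep, r)
  }
  keep
}

set_summary_oracle <- function(status, a_ids, b_ids) {
  pos_a <- pos_b <- character()
  for (r in colnames(status)) {
    for (s in a_ids) if (status[s, r] == "positive") pos_a <- union(pos_a, r)
    for (s in b_ids) if (status[s, r] == "positive") pos_b <- union(pos_b, r)
  }
  list(unique_a = setdiff(pos_a, pos_b), unique_b = setdiff(pos_b, pos_a),
       shared = intersect(pos_a, pos_b))
}

welch_oracle <- function(a, b) {
  # closed-form Welch statistic and Welch-Satterthwaite df
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1); vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

anova_f_oracle <- function(groups) {
  # closed-form one-way ANOVA F from sums of squares
  all_v <- unlist(groups)
  grand <- mean(all_v)
  k <- length(groups); n <- length(all_v)
  ss_between <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - grand)^2, 0))
  ss_within <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), 0))
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  list(f = f, p = p)
}
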