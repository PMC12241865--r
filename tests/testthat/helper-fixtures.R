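# constructors and tiny fixtures shared across the suite

make_profile <- function(depths, imperfect = rep(FALSE, length(depths)),
                         region_id = "HERVX", sample_id = "S1") {
  structure(list(region_id = region_id, sample_id = sample_id,
                 depths = as.numeric(depths),
                 mismatch_bases = as.integer(imperfect),
                 imperfect = imperfect),
            class = "WindowProfile")
}

make_reads <- function(pos, len, n_matches = len, barcode = "B1",
                       region_id = "HERVX", mismatch_pos = NULL) {
  n <- length(pos)
  df <- data.frame(read_id = sprintf("r%03d", seq_len(n)),
                   region_id = rep_len(region_id, n),
                   pos = as.integer(pos),
                   aligned_length = as.integer(rep_len(len, n)),
                   barcode = rep_len(barcode, n),
                   stringsAsFactors = FALSE)
  df$mismatch_pos <- if (is.null(mismatch_pos)) vector("list", n)
                     else mismatch_pos
  df$n_matches <- as.integer(rep_len(n_matches, n))
  df
}

write_tiny_reference <- function(dir, ids = c("HERV001", "HERV002", "JAKMIP2"),
                                 len = 300) {
  set.seed(99)
  seqs <- vapply(ids, function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), "")
  fasta <- file.path(dir, "tiny.fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), fasta)
  bed <- file.path(dir, "tiny.bed")
  writeLines(sprintf("chr1\t%d\t%d\t%s\t0\t+",
                     seq_along(ids) * 1000L, seq_along(ids) * 1000L + len,
                     ids), bed)
  list(fasta = fasta, bed = bed, ids = ids, len = len, seqs = seqs)
}

# a minimal status matrix for cohort-analysis fuzz tests
random_presence <- function(n_samples, n_regions, p_pos = 0.3) {
  status <- matrix(ifelse(stats::runif(n_samples * n_regions) < p_pos,
                          "positive", "negative"),
                   nrow = n_samples,
                   dimnames = list(sprintf("S%02d", seq_len(n_samples)),
                                   sprintf("R%02d", seq_len(n_regions))))
  calls <- data.frame(
    sample_id = rep(rownames(status), times = n_regions),
    region_id = rep(colnames(status), each = n_samples),
    status = as.vector(status),
    n_usable_windows = ifelse(as.vector(status) == "positive",
                              sample(9:30, n_samples * n_regions, TRUE), 0L),
    locus_depth = ifelse(as.vector(status) == "positive",
                         stats::runif(n_samples * n_regions, 3, 20), 0))
  meta <- data.frame(sample_id = rownames(status), cohort = "other")
  presence_matrix(calls, meta)
}
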