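bc_table <- data.frame(barcode = c("B1", "B2", "B3"),
                       cell_type = c("Mono", "Mono", "B"))

test_that("barcode filter keeps only the target cell type", {
  reads <- make_reads(pos = c(0, 10, 20), len = 50,
                      barcode = c("B1", "B2", "B1"))
  out <- filter_barcodes(reads, bc_table)
  expect_equal(nrow(out), 3L)          # all monocyte -> identity

  reads$barcode <- "B3"
  expect_equal(nrow(filter_barcodes(reads, bc_table)), 0L)

  reads$barcode <- c("B1", "ZZZZ", "B3")
  expect_warning(out <- filter_barcodes(reads, bc_table), "absent")
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "n_unknown_barcode"), 1L)
})

test_that("identity filter is strictly greater than the threshold", {
  reads <- make_reads(pos = c(0, 0, 0, 0), len = 100,
                      n_matches = c(100, 99, 100, 0))
  reads$aligned_length[3] <- 1000L; reads$n_matches[3] <- 995L
  reads$aligned_length[4] <- 0L;   reads$n_matches[4] <- 0L
  out <- identity_filter(reads)
  # 100% and 99.5% retained; exactly 99.0% and zero-length excluded
  expect_equal(out$read_id, c("r001", "r003"))
  expect_equal(attr(out, "n_zero_length"), 1L)
})

test_that("barcode and identity filters commute", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    reads <- make_reads(pos = sample(0:200, n, TRUE), len = 100,
                        barcode = sample(c("B1", "B2", "B3"), n, TRUE))
    reads$n_matches <- sample(97:100, n, TRUE)
    a <- identity_filter(filter_barcodes(reads, bc_table))
    b <- filter_barcodes(identity_filter(reads), bc_table)
    attributes(a) <- attributes(a)[c("names", "row.names", "class")]
    attributes(b) <- attributes(b)[c("names", "row.names", "class")]
    expect_identical(a, b)
  }
})

test_that("window depth equals total overlapping bases per window", {
  scheme <- partition_windows(500, 100)
  # no reads -> all-zero profile
  p0 <- window_depth_profile(make_reads(integer(), 50), "R", scheme)
  expect_equal(p0$depths, rep(0, 5))

  # 3 reads exactly tiling window 2 -> depth 3 there, 0 elsewhere
  p <- window_depth_profile(make_reads(c(100, 100, 100), 100), "R", scheme)
  expect_equal(p$depths, c(0, 3, 0, 0, 0))

  # a boundary-straddling read splits its bases between windows
  p <- window_depth_profile(make_reads(50, 100), "R", scheme)
  expect_equal(p$depths, c(0.5, 0.5, 0, 0, 0))
})

test_that("depth profile matches the per-base pileup oracle on fuzzed reads", {
  set.seed(53)
  for (i in 1:100) {
    len <- sample(200:1500, 1)
    L <- sample(c(50, 100, 130), 1)
    scheme <- partition_windows(len, L)
    n <- sample(0:60, 1)
    rl <- sample(20:80, 1)
    reads <- make_reads(pos = if (n) sample(0:(len - rl), n, TRUE)
                              else integer(), len = rl)
    p <- window_depth_profile(reads, "R", scheme)
    expect_equal(p$depths, pileup_oracle(reads, scheme), tolerance = 1e-12)
    # conservation: depth-weighted window lengths = total aligned bases
    expect_equal(sum(p$depths * (scheme$win_end - scheme$win_start)),
                 sum(reads$aligned_length))
  }
})

test_that("mismatch positions mark exactly the windows they fall in", {
  scheme <- partition_windows(300, 100)
  reads <- make_reads(c(0, 90, 210), 50,
                      mismatch_pos = list(NULL, 95L, NULL))
  reads$n_matches[2] <- 49L
  p <- window_depth_profile(reads, "R", scheme)
  expect_equal(p$imperfect, c(TRUE, FALSE, FALSE))
  # unknown mismatch positions poison every window the read overlaps
  reads2 <- make_reads(90, 50)
  reads2$n_matches <- 49L
  p2 <- window_depth_profile(reads2, "R", scheme)
  expect_equal(p2$imperfect, c(TRUE, TRUE, FALSE))
})

test_that("ingest_sam composes the filters over a synthetic sample", {
  d <- withr::local_tempdir()
  expressed <- data.frame(region_id = "HERV002", n_covered_windows = 15,
                          mean_depth = 8)
  spec <- cohort_spec(list(sample_spec("S1", "acute", expressed,
                                       fraction_monocyte_barcodes = 0.5)),
                      n_loci = 5, locus_length = 3000, seed = 61)
  sim <- simulate_cohort(spec, file.path(d, "run"))
  prof <- ingest_sam(sim$sam[["S1"]], sim$catalog, sim$barcodes[["S1"]],
                     sample_id = "S1")
  fc <- attr(prof, "filter_counts")

  # barcode filter retains exactly the generator's monocyte reads
  body <- grep("^@", readLines(sim$sam[["S1"]]), invert = TRUE, value = TRUE)
  expect_equal(unname(fc["n_barcode_pass"]),
               sum(grepl("XO:Z:expressed", body)))
  expect_equal(unname(fc["n_total"]), length(body))

  # noiseless: identity filter removes nothing further
  expect_equal(unname(fc["n_identity_pass"]), unname(fc["n_barcode_pass"]))

  # covered windows of the expressed region sit near the intended depth
  dpt <- prof[["HERV002"]]$depths
  expect_equal(sum(dpt > 0), 15L)
  expect_lt(abs(mean(dpt[dpt > 0]) - 8), 1.5)
  # decoy-only loci are all zero after filtering
  other <- setdiff(names(prof), c("HERV002", sim$host_gene_ids))
  expect_true(all(vapply(prof[other], function(p) all(p$depths == 0), TRUE)))
})

test_that("degenerate SAM inputs give all-zero profiles or clear errors", {
  d <- withr::local_tempdir()
  ref <- write_tiny_reference(d)
  catalog <- load_catalog(ref$bed, ref$fasta)
  empty_sam <- file.path(d, "empty.sam")
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", ref$ids, ref$len)), empty_sam)
  bt <- data.frame(barcode = "AAAACCCCGGGGTTTT", cell_type = "Mono")
  prof <- ingest_sam(empty_sam, catalog, bt)
  expect_true(all(vapply(prof, function(p) all(p$depths == 0), TRUE)))

  # only non-monocyte barcodes -> all-zero
  sam2 <- file.path(d, "nk.sam")
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", ref$ids, ref$len),
               sprintf("r1\t0\tHERV001\t1\t60\t50M\t*\t0\t0\t%s\t%s\tNM:i:0\tCB:Z:CCCCGGGGTTTTAAAA",
                       substring(ref$seqs[1], 1, 50), strrep("I", 50))),
             sam2)
  bt2 <- data.frame(barcode = "CCCCGGGGTTTTAAAA", cell_type = "NK")
  prof2 <- ingest_sam(sam2, catalog, bt2)
  expect_true(all(vapply(prof2, function(p) all(p$depths == 0), TRUE)))

  # unknown reference name -> validation error
  sam3 <- file.path(d, "bad.sam")
  writeLines(c("@HD\tVN:1.6\tSO:unknown", "@SQ\tSN:NOTREAL\tLN:100"), sam3)
  expect_error(ingest_sam(sam3, catalog, bt), "NOTREAL")
})
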