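#' Specify one synthetic sample
#'
#' @param sample_id Sample identifier (unique within the cohort).
#' @param cohort Cohort label, one of `"control"`, `"acute"`, `"ERS"`,
#'   `"LRS"`, `"PASC"`, `"vaccine"`, `"other"`.
#' @param expressed `data.frame` with columns `region_id`,
#'   `n_covered_windows`, `mean_depth` listing the regions this sample
#'   transcribes; empty frame (or NULL) for a silent sample.
#' @param fraction_monocyte_barcodes Fraction of the sample's cell barcodes
#'   annotated as monocytes.
#' @param n_barcodes Number of distinct cell barcodes in the sample.
#' @param timepoint Free-text timepoint label (e.g. `"d0"`, `"8m"`).
#' @return A `SampleSpec` list.
#' @export
sample_spec <- function(sample_id, cohort = "other", expressed = NULL,
                        fraction_monocyte_barcodes = 0.6, n_barcodes = 100,
                        timepoint = "t0") {
  cohorts <- c("control", "acute", "ERS", "LRS", "PASC", "vaccine", "other")
  if (!cohort %in% cohorts)
    stop("unknown cohort label '", cohort, "'", call. = FALSE)
  if (is.null(expressed))
    expressed <- data.frame(region_id = character(),
                            n_covered_windows = integer(),
                            mean_depth = numeric())
  stopifnot(all(c("region_id", "n_covered_windows", "mean_depth") %in%
                  names(expressed)))
  if (any(expressed$mean_depth < 0) || any(expressed$n_covered_windows < 0))
    stop("expressed windows/depth must be non-negative", call. = FALSE)
  if (fraction_monocyte_barcodes < 0 || fraction_monocyte_barcodes > 1)
    stop("fraction_monocyte_barcodes must lie in [0, 1]", call. = FALSE)
  structure(list(sample_id = sample_id, cohort = cohort,
                 expressed = expressed,
                 fraction_monocyte_barcodes = fraction_monocyte_barcodes,
                 n_barcodes = as.integer(n_barcodes),
                 timepoint = timepoint),
            class = "SampleSpec")
}

#' Specify a synthetic cohort
#'
#' Collects everything `simulate_cohort()` needs: the catalog geometry, the
#' per-sample expression structure, read chemistry and the seed. The cohort
#' spec is validated up front so no files are written for an invalid cohort.
#'
#' @param samples List of [sample_spec()] objects.
#' @param n_loci Number of HERV loci in the reference catalog.
#' @param locus_length Length of every locus/gene in nucleotides.
#' @param n_host_genes Number of host-gene regions.
#' @param window_length Window length L in nucleotides.
#' @param read_length Simulated read length in nucleotides.
#' @param substitution_rate Per-base substitution (sequencing error)
#'   probability in `[0, 1)`.
#' @param n_decoy_loci Number of loci per sample that receive non-monocyte
#'   decoy reads (removed by barcode filtering downstream).
#' @param decoy_depth,decoy_windows Depth and contiguous window count of the
#'   decoy signal.
#' @param seed Integer seed governing every random draw of the generator.
#' @return A `CohortSpec` list.
#' @export
cohort_spec <- function(samples, n_loci = 50, locus_length = 3000,
                        n_host_genes = 5, window_length = 100,
                        read_length = 50, substitution_rate = 0,
                        n_decoy_loci = 5, decoy_depth = 5,
                        decoy_windows = 12, seed = 1) {
  if (substitution_rate < 0 || substitution_rate >= 1)
    stop("substitution_rate must lie in [0, 1)", call. = FALSE)
  if (any(c(n_loci, n_host_genes) < 0) || locus_length < 1 ||
      window_length < 1 || read_length < 1)
    stop("counts and lengths must be positive", call. = FALSE)
  if (read_length > locus_length)
    stop("read_length exceeds region length", call. = FALSE)
  ids <- vapply(samples, `[[`, "", "sample_id")
  if (anyDuplicated(ids))
    stop("duplicate sample_id: ", ids[duplicated(ids)][1L], call. = FALSE)
  region_ids <- c(sprintf("HERV%03d", seq_len(n_loci)),
                  host_gene_names(n_host_genes))
  n_windows <- ceiling(locus_length / window_length)
  for (s in samples) {
    unknown <- setdiff(s$expressed$region_id, region_ids)
    if (length(unknown))
      stop("sample '", s$sample_id, "' expresses unknown region '",
           unknown[1L], "'", call. = FALSE)
    if (any(s$expressed$n_covered_windows > n_windows))
      stop("sample '", s$sample_id,
           "': n_covered_windows exceeds windows per region (", n_windows,
           ")", call. = FALSE)
  }
  structure(list(samples = samples, n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length),
                 n_host_genes = as.integer(n_host_genes),
                 window_length = as.integer(window_length),
                 read_length = as.integer(read_length),
                 substitution_rate = substitution_rate,
                 n_decoy_loci = as.integer(n_decoy_loci),
                 decoy_depth = decoy_depth,
                 decoy_windows = as.integer(decoy_windows),
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

host_gene_names <- function(n) {
  canonical <- c("JAKMIP2", "DPYSL3", "SPINK1", "STK32A", "SCGB3A2")
  if (n <= length(canonical)) canonical[seq_len(n)]
  else c(canonical, sprintf("GENE%02d", seq_len(n - length(canonical))))
}

#' Simulate reads over a contiguous block of windows
#'
#' Draws a Poisson number of reads per covered window with mean
#' `depth * window_length / read_length`, so each covered window's expected
#' mean per-base coverage equals `depth`. Read starts are uniform within
#' their window and reads are kept fully inside it, so windows outside the
#' block receive no coverage. Substitutions are i.i.d. per base; a
#' substituted base is always changed to a different nucleotide.
#'
#' @param region_id Region identifier.
#' @param sequence Reference sequence (character scalar).
#' @param scheme Window scheme from [partition_windows()].
#' @param block Integer vector of window indices (1-based into `scheme`)
#'   forming the covered block.
#' @param depth Target mean per-base depth per covered window.
#' @param read_length Read length (<= region length).
#' @param substitution_rate Per-base substitution probability.
#' @return `data.frame` with columns `region_id`, `start` (0-based),
#'   `length`, `seq`, `n_mismatch`.
#' @export
simulate_reads <- function(region_id, sequence, scheme, block, depth,
                           read_length, substitution_rate = 0) {
  region_length <- nchar(sequence)
  if (read_length > region_length)
    stop("read_length (", read_length, ") exceeds region length (",
         region_length, ")", call. = FALSE)
  if (depth < 0) stop("depth must be >= 0", call. = FALSE)
  empty <- data.frame(region_id = character(), start = integer(),
                      length = integer(), seq = character(),
                      n_mismatch = integer())
  if (depth == 0 || length(block) == 0L) return(empty)

  starts <- integer()
  for (w in block) {
    ws <- scheme$win_start[w]; we <- scheme$win_end[w]
    wl <- we - ws
    n <- stats::rpois(1L, depth * wl / read_length)
    if (n == 0L) next
    if (wl >= read_length) {
      # read fully contained in its window: no leakage outside the block
      starts <- c(starts, ws + sample.int(wl - read_length + 1L, n,
                                          replace = TRUE) - 1L)
    } else {
      # terminal partial window shorter than a read: anchor at region end
      starts <- c(starts, rep(max(we - read_length, 0L), n))
    }
  }
  if (length(starts) == 0L) return(empty)
  seqs <- substring(sequence, starts + 1L, starts + read_length)
  n_mismatch <- integer(length(starts))
  if (substitution_rate > 0) {
    n_sub <- stats::rbinom(length(starts), read_length, substitution_rate)
    for (i in which(n_sub > 0L)) {
      pos <- sample.int(read_length, n_sub[i])
      s <- strsplit(seqs[i], "")[[1L]]
      for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
      seqs[i] <- paste(s, collapse = "")
      n_mismatch[i] <- n_sub[i]
    }
  }
  data.frame(region_id = region_id, start = starts,
             length = read_length, seq = seqs, n_mismatch = n_mismatch)
}

random_barcodes <- function(n) {
  # 16-nt cell barcodes, 10x convention; regenerate on (vanishingly rare)
  # collision so barcodes are unique within a sample
  repeat {
    bc <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 16L, replace = TRUE),
            collapse = ""), "")
    if (!anyDuplicated(bc)) return(bc)
  }
}

#' Write a barcode -> cell-type table
#'
#' @param barcode_table `data.frame` with columns `barcode`, `cell_type`.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_barcode_table <- function(barcode_table, path) {
  stopifnot(all(c("barcode", "cell_type") %in% names(barcode_table)))
  if (anyDuplicated(barcode_table$barcode))
    stop("barcodes must be unique within a sample", call. = FALSE)
  utils::write.table(barcode_table[, c("barcode", "cell_type")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

make_barcode_table <- function(n_barcodes, fraction_mono) {
  bc <- random_barcodes(n_barcodes)
  n_mono <- stats::rbinom(1L, n_barcodes, fraction_mono)
  decoy_types <- c("CD4 T", "CD8 T", "B", "NK")
  cell_type <- c(rep("Mono", n_mono),
                 sample(decoy_types, n_barcodes - n_mono, replace = TRUE))
  data.frame(barcode = bc, cell_type = cell_type)
}

write_sam <- function(reads, catalog, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", catalog$regions$region_id,
                     catalog$regions$length), con)
  if (nrow(reads)) {
    writeLines(sprintf(
      "%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d\tCB:Z:%s\tXO:Z:%s",
      reads$read_id, reads$region_id, reads$start + 1L, reads$length,
      reads$seq, strrep("I", reads$length), reads$n_mismatch,
      reads$barcode, reads$origin), con)
  }
  invisible(path)
}

#' Generate a complete synthetic cohort on disk
#'
#' Emits, under `out_dir`: the reference catalog (`ref.fasta`, `ref.bed`),
#' one SAM and one barcode table per sample, a sample-metadata TSV and a
#' ground-truth manifest recording each (sample, region) pair's intended
#' expression state. Monocyte reads realize the intended coverage; decoy
#' reads carrying non-monocyte barcodes are laid over both expressed and
#' silent loci so that barcode filtering is consequential downstream.
#' Identical seeds produce byte-identical output files.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created; default a seed-named directory
#'   under `tempdir()`).
#' @param thresholds Thresholds used to derive `intended_status` in the
#'   manifest (see [wha_thresholds()]).
#' @return Invisibly, a list with the catalog, file paths, the ground-truth
#'   manifest and per-sample metadata.
#' @export
simulate_cohort <- function(spec, out_dir = NULL,
                            thresholds = wha_thresholds()) {
  stopifnot(inherits(spec, "CohortSpec"))
  if (is.null(out_dir))
    out_dir <- file.path(tempdir(), sprintf("wha_cohort_seed%d", spec$seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)

  region_ids <- c(sprintf("HERV%03d", seq_len(spec$n_loci)),
                  host_gene_names(spec$n_host_genes))
  kinds <- c(rep("herv", spec$n_loci), rep("host_gene", spec$n_host_genes))
  n_regions <- length(region_ids)
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(n_regions), function(i)
    paste(sample(c("A", "C", "G", "T"), spec$locus_length, replace = TRUE),
          collapse = ""), ""))
  names(seqs) <- region_ids
  regions <- data.frame(
    region_id = region_ids, kind = kinds,
    chrom = paste0("chr", rep_len(c(1:22, "X"), n_regions)),
    start = 100000L + (seq_len(n_regions) - 1L) * 10000L,
    end = 100000L + (seq_len(n_regions) - 1L) * 10000L + spec$locus_length,
    strand = "+", length = spec$locus_length,
    stringsAsFactors = FALSE)
  catalog <- new_region_catalog(regions, seqs, spec$window_length)

  bed_path <- file.path(out_dir, "ref.bed")
  fasta_path <- file.path(out_dir, "ref.fasta")
  write_catalog(catalog, bed_path, fasta_path)

  scheme <- catalog$schemes[[1L]]   # all regions share one geometry
  n_windows <- nrow(scheme)
  seq_chars <- as.character(seqs)

  manifest <- do.call(rbind, lapply(spec$samples, function(s) {
    m <- data.frame(sample_id = s$sample_id, region_id = region_ids,
                    intended_windows = 0L, intended_depth = 0,
                    stringsAsFactors = FALSE)
    if (nrow(s$expressed)) {
      i <- match(s$expressed$region_id, m$region_id)
      m$intended_windows[i] <- s$expressed$n_covered_windows
      m$intended_depth[i] <- s$expressed$mean_depth
    }
    m
  }))
  manifest$intended_status <- ifelse(
    manifest$intended_windows >= thresholds$windows_min &
      manifest$intended_depth >= thresholds$depth_min,
    "positive", "negative")

  sample_meta <- data.frame(
    sample_id = vapply(spec$samples, `[[`, "", "sample_id"),
    cohort = vapply(spec$samples, `[[`, "", "cohort"),
    timepoint = vapply(spec$samples, `[[`, "", "timepoint"),
    stringsAsFactors = FALSE)

  sam_paths <- character(0)
  barcode_paths <- character(0)
  for (s in spec$samples) {
    bt <- make_barcode_table(s$n_barcodes, s$fraction_monocyte_barcodes)
    mono_bc <- bt$barcode[bt$cell_type == "Mono"]
    other_bc <- bt$barcode[bt$cell_type != "Mono"]

    reads_list <- list()
    if (nrow(s$expressed) && length(mono_bc)) {
      for (j in seq_len(nrow(s$expressed))) {
        rid <- s$expressed$region_id[j]
        nw <- s$expressed$n_covered_windows[j]
        if (nw == 0L) next
        b0 <- sample.int(n_windows - nw + 1L, 1L)
        r <- simulate_reads(rid, seq_chars[[rid]], scheme,
                            block = b0:(b0 + nw - 1L),
                            depth = s$expressed$mean_depth[j],
                            read_length = spec$read_length,
                            substitution_rate = spec$substitution_rate)
        if (nrow(r)) {
          r$barcode <- sample(mono_bc, nrow(r), replace = TRUE)
          r$origin <- "expressed"
          reads_list[[length(reads_list) + 1L]] <- r
        }
      }
    }
    if (spec$n_decoy_loci > 0L && length(other_bc)) {
      decoy_ids <- sample(region_ids[kinds == "herv"],
                          min(spec$n_decoy_loci, spec$n_loci))
      for (rid in decoy_ids) {
        nw <- min(spec$decoy_windows, n_windows)
        b0 <- sample.int(n_windows - nw + 1L, 1L)
        r <- simulate_reads(rid, seq_chars[[rid]], scheme,
                            block = b0:(b0 + nw - 1L),
                            depth = spec$decoy_depth,
                            read_length = spec$read_length,
                            substitution_rate = spec$substitution_rate)
        if (nrow(r)) {
          r$barcode <- sample(other_bc, nrow(r), replace = TRUE)
          r$origin <- "decoy"
          reads_list[[length(reads_list) + 1L]] <- r
        }
      }
    }
    reads <- if (length(reads_list)) do.call(rbind, reads_list)
             else data.frame(region_id = character(), start = integer(),
                             length = integer(), seq = character(),
                             n_mismatch = integer(), barcode = character(),
                             origin = character())
    if (nrow(reads))
      reads$read_id <- sprintf("%s_r%06d", s$sample_id, seq_len(nrow(reads)))
    else reads$read_id <- character(0)

    sam <- file.path(out_dir, paste0(s$sample_id, ".sam"))
    write_sam(reads, catalog, sam)
    bcp <- file.path(out_dir, paste0(s$sample_id, ".barcodes.tsv"))
    write_barcode_table(bt, bcp)
    sam_paths <- c(sam_paths, sam)
    barcode_paths <- c(barcode_paths, bcp)
  }
  names(sam_paths) <- names(barcode_paths) <- sample_meta$sample_id

  utils::write.table(sample_meta, file.path(out_dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    manifest[, c("sample_id", "region_id", "intended_status",
                 "intended_windows", "intended_depth")],
    file.path(out_dir, "ground_truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(out_dir = out_dir, catalog = catalog,
                 bed = bed_path, fasta = fasta_path,
                 sam = sam_paths, barcodes = barcode_paths,
                 samples = sample_meta, manifest = manifest,
                 host_gene_ids = region_ids[kinds == "host_gene"]))
}

jitter_windows <- function(n, mean, sd = 2, lo = 10L, hi = 30L) {
  pmin(pmax(as.integer(round(stats::rnorm(n, mean, sd))), lo), hi)
}

#' Default synthetic cohort preset
#'
#' A desk-scale cohort mirroring the shape of a pangenome-control study:
#' 31 healthy controls with every HERV locus silent, 11 acute patients and
#' 12 PASC patients, over 50 HERV loci and 5 host genes. Three loci
#' (HERV001-003) are expressed in all 12 PASC samples and three more
#' (HERV004-006) in 11 of 12; these six are "PASC-amplified" (about 10 more
#' covered windows and 3 more units of depth than the same loci in acute
#' samples). Five loci are PASC-only, nine acute-only, ten shared with equal
#' expression in both patient groups (null loci), and the remainder silent
#' everywhere. Host genes carry a baseline signal in every sample, with
#' JAKMIP2/SPINK1 amplified (windows and depth) and DPYSL3 amplified in
#' windows only in the PASC group. Per-sample window counts are jittered
#' (sd 2 windows) around the group means.
#'
#' @param seed Integer seed.
#' @param n_controls,n_acute,n_pasc Group sizes.
#' @param n_loci Number of HERV loci.
#' @param substitution_rate Per-base sequencing error rate (default 0:
#'   noiseless, so the window-similarity gate is exact).
#' @return A `CohortSpec`.
#' @export
cohort_preset <- function(seed = 1, n_controls = 31, n_acute = 11,
                          n_pasc = 12, n_loci = 50, substitution_rate = 0) {
  stopifnot(n_loci >= 30)
  set.seed(seed + 7919L)   # preset-level draws, distinct from read-level RNG
  genes <- host_gene_names(5)
  host_base <- function() data.frame(
    region_id = genes,
    n_covered_windows = jitter_windows(5, 12),
    mean_depth = 8)
  host_pasc <- function() {
    e <- data.frame(region_id = genes,
                    n_covered_windows = jitter_windows(5, 12),
                    mean_depth = 8)
    amp <- e$region_id %in% c("JAKMIP2", "SPINK1", "DPYSL3")
    e$n_covered_windows[amp] <- jitter_windows(sum(amp), 22, lo = 18L)
    e$mean_depth[e$region_id %in% c("JAKMIP2", "SPINK1")] <- 11
    e
  }
  herv <- function(ids, mean_w, depth, lo = 10L)
    data.frame(region_id = ids,
               n_covered_windows = jitter_windows(length(ids), mean_w, lo = lo),
               mean_depth = depth)
  amplified <- sprintf("HERV%03d", 1:6)
  pasc_only <- sprintf("HERV%03d", 7:11)
  acute_only <- sprintf("HERV%03d", 12:20)
  null_shared <- sprintf("HERV%03d", 21:30)

  samples <- list()
  for (i in seq_len(n_controls))
    samples[[length(samples) + 1L]] <- sample_spec(
      sprintf("C%02d", i), "control", host_base())

  # each amplified/null locus is pre-assigned to a fixed subset of patients
  acute_has <- lapply(seq_along(amplified), function(j)
    sort(sample.int(n_acute, min(3L, n_acute))))
  null_acute <- lapply(seq_along(null_shared), function(j)
    sort(sample.int(n_acute, min(4L, n_acute))))
  null_pasc <- lapply(seq_along(null_shared), function(j)
    sort(sample.int(n_pasc, min(4L, n_pasc))))
  acute_extra <- lapply(seq_along(acute_only), function(j)
    sort(sample.int(n_acute, sample(seq_len(min(3L, n_acute)), 1))))
  pasc_extra <- lapply(seq_along(pasc_only), function(j)
    sort(sample.int(n_pasc, min(6L, n_pasc))))
  # one PASC sample misses each of loci 4-6
  pasc_miss_456 <- sample.int(n_pasc, min(3L, n_pasc))
  length(pasc_miss_456) <- 3L

  for (i in seq_len(n_acute)) {
    ids <- c(amplified[vapply(acute_has, function(x) i %in% x, TRUE)],
             acute_only[vapply(acute_extra, function(x) i %in% x, TRUE)],
             null_shared[vapply(null_acute, function(x) i %in% x, TRUE)])
    samples[[length(samples) + 1L]] <- sample_spec(
      sprintf("A%02d", i), "acute",
      rbind(host_base(), herv(ids, 15, 12)))
  }
  for (i in seq_len(n_pasc)) {
    amp_here <- c(amplified[1:3],
                  amplified[4:6][is.na(pasc_miss_456) | pasc_miss_456 != i])
    ids_base <- c(pasc_only[vapply(pasc_extra, function(x) i %in% x, TRUE)],
                  null_shared[vapply(null_pasc, function(x) i %in% x, TRUE)])
    samples[[length(samples) + 1L]] <- sample_spec(
      sprintf("P%02d", i), "PASC",
      rbind(host_pasc(),
            herv(amp_here, 25, 15, lo = 20L),
            herv(ids_base, 15, 12)),
      timepoint = "8m")
  }
  cohort_spec(samples, n_loci = n_loci, substitution_rate = substitution_rate,
              seed = seed)
}
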