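cigar_ref_match_length <- function(cigar) {
  # alignment columns on the reference contributed by M/=/X operations
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  vapply(regmatches(cigar, ops), function(parts) {
    lens <- as.integer(sub("[MIDNSHP=X]$", "", parts))
    op <- substring(parts, nchar(parts), nchar(parts))
    sum(lens[op %in% c("M", "=", "X")])
  }, 0L)
}

#' Read primary alignments from a SAM file
#'
#' Converts the SAM through [Rsamtools::asBam()] and extracts primary,
#' mapped records with their cell barcode (`CB`) and edit-distance (`NM`)
#' tags. When the catalog carries reference sequences, each read's mismatch
#' positions are recomputed by direct comparison against the reference, so
#' the identity filter and the window-similarity gate do not depend on
#' aligner-written tags. Secondary, supplementary and unmapped records are
#' skipped.
#'
#' @param sam_path Path to a SAM (or BAM) file whose header sequence names
#'   are a subset of the catalog's region ids.
#' @param catalog A `RegionCatalog`.
#' @return `data.frame` with columns `read_id`, `region_id`, `pos` (0-based
#'   start on the region), `aligned_length`, `n_matches`, `barcode`, plus a
#'   list-column `mismatch_pos` of 0-based region coordinates of mismatched
#'   bases (NULL-entries when positions are unknown).
#' @export
read_sam_alignments <- function(sam_path, catalog) {
  stopifnot(inherits(catalog, "RegionCatalog"))
  if (!file.exists(sam_path))
    stop("alignment file not found: ", sam_path, call. = FALSE)
  bam <- sam_path
  if (!grepl("\\.bam$", sam_path)) {
    dest <- tempfile(fileext = "")
    bam <- tryCatch(
      Rsamtools::asBam(sam_path, dest, overwrite = TRUE,
                       indexDestination = FALSE),
      error = function(e) stop("malformed SAM '", sam_path, "': ",
                               conditionMessage(e), call. = FALSE))
    on.exit(unlink(paste0(dest, c(".bam", ".bam.bai"))), add = TRUE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  unknown <- setdiff(names(hdr), catalog$regions$region_id)
  if (length(unknown))
    stop("SAM reference name(s) not in catalog: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "seq"),
    tag = c("NM", "CB"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  x <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(x$qname)
  barcode <- if (is.null(x$tag$CB)) rep(NA_character_, n) else x$tag$CB
  nm <- if (is.null(x$tag$NM)) rep(NA_integer_, n) else x$tag$NM
  aligned_length <- if (n) cigar_ref_match_length(x$cigar) else integer()

  reads <- data.frame(read_id = as.character(x$qname),
                      region_id = as.character(x$rname),
                      pos = x$pos - 1L,
                      aligned_length = aligned_length,
                      barcode = barcode,
                      stringsAsFactors = FALSE)
  reads$mismatch_pos <- vector("list", n)
  reads$n_matches <- reads$aligned_length - ifelse(is.na(nm), 0L, nm)

  if (!is.null(catalog$sequences) && n) {
    simple <- grepl("^\\d+M$", x$cigar)
    seq_chr <- as.character(x$seq)
    for (rid in unique(reads$region_id)) {
      ref <- as.character(catalog$sequences[[rid]])
      idx <- which(reads$region_id == rid & simple)
      if (!length(idx)) next
      refsub <- substring(ref, reads$pos[idx] + 1L,
                          reads$pos[idx] + reads$aligned_length[idx])
      mismatched <- which(refsub != seq_chr[idx])
      reads$n_matches[idx] <- reads$aligned_length[idx]
      for (k in mismatched) {
        i <- idx[k]
        a <- utf8ToInt(seq_chr[i]) != utf8ToInt(refsub[k])
        mmpos <- reads$pos[i] + which(a) - 1L
        reads$mismatch_pos[[i]] <- mmpos
        reads$n_matches[i] <- reads$aligned_length[i] - length(mmpos)
      }
    }
  }
  reads
}

#' Keep reads whose cell barcode belongs to the target cell type
#'
#' Mirrors the barcode-listing step of single-cell workflows in which the
#' alignment is subset to one annotated cell population (monocytes here)
#' before locus scoring. Reads with barcodes absent from the table are
#' dropped and tallied, not fatal.
#'
#' @param reads Alignment table from [read_sam_alignments()].
#' @param barcode_table `data.frame` with columns `barcode`, `cell_type`.
#' @param target_cell_type Cell-type label to retain (default `"Mono"`).
#' @return Filtered reads; attributes `n_input`, `n_retained`,
#'   `n_unknown_barcode` record the tallies.
#' @export
filter_barcodes <- function(reads, barcode_table, target_cell_type = "Mono") {
  stopifnot(all(c("barcode", "cell_type") %in% names(barcode_table)))
  type <- barcode_table$cell_type[match(reads$barcode, barcode_table$barcode)]
  unknown <- is.na(type) & !is.na(reads$barcode) |
    is.na(reads$barcode)
  keep <- !is.na(type) & type == target_cell_type
  out <- reads[keep, , drop = FALSE]
  if (any(unknown))
    warning(sum(unknown), " read(s) with barcode absent from table dropped",
            call. = FALSE)
  attr(out, "n_input") <- nrow(reads)
  attr(out, "n_retained") <- nrow(out)
  attr(out, "n_unknown_barcode") <- sum(unknown)
  out
}

#' Drop reads below the percent-identity threshold
#'
#' Retains a read iff `100 * n_matches / aligned_length` is strictly greater
#' than `min_identity` (default 99: a read at exactly 99.0% identity is
#' rejected). Reads with zero aligned length are dropped and tallied.
#'
#' @param reads Alignment table.
#' @param min_identity Exclusive lower bound on percent identity.
#' @return Filtered reads with tally attributes `n_input`, `n_retained`,
#'   `n_zero_length`.
#' @export
identity_filter <- function(reads, min_identity = 99.0) {
  zero <- reads$aligned_length == 0L
  ident <- ifelse(zero, -Inf, 100 * reads$n_matches / reads$aligned_length)
  keep <- ident > min_identity
  out <- reads[keep, , drop = FALSE]
  attr(out, "n_input") <- nrow(reads)
  attr(out, "n_retained") <- nrow(out)
  attr(out, "n_zero_length") <- sum(zero)
  out
}

#' Per-window mean depth profile of one region
#'
#' Depth of window w is the total number of aligned bases overlapping w
#' divided by the window length — i.e. the mean per-base coverage of the
#' window. A read overlapping several windows contributes its overlapping
#' bases to each. Mismatching bases are tallied per window for the
#' window-similarity gate; reads whose mismatch positions are unknown (no
#' reference sequence available) mark every window they overlap imperfect.
#'
#' @param reads Alignment table, already filtered, all on `region_id`.
#' @param region_id Region identifier.
#' @param scheme Window scheme from [partition_windows()].
#' @param sample_id Optional sample label carried into the profile.
#' @return A `WindowProfile`: list with `region_id`, `sample_id`, `depths`
#'   (one per window), `mismatch_bases` and `imperfect` (logical per
#'   window).
#' @export
window_depth_profile <- function(reads, region_id, scheme,
                                 sample_id = NA_character_) {
  nw <- nrow(scheme)
  region_length <- scheme$win_end[nw]
  win_len <- scheme$win_end - scheme$win_start
  depths <- numeric(nw)
  mism <- integer(nw)
  imperfect <- logical(nw)
  if (nrow(reads)) {
    if (any(reads$pos < 0L | reads$pos + reads$aligned_length > region_length))
      stop("read outside region bounds for '", region_id, "'", call. = FALSE)
    ir <- IRanges::IRanges(start = reads$pos + 1L,
                           width = reads$aligned_length)
    cov <- IRanges::coverage(ir, width = region_length)
    tot <- IRanges::viewSums(IRanges::Views(cov, scheme$win_start + 1L,
                                            scheme$win_end))
    depths <- as.numeric(tot) / win_len
    mm <- unlist(reads$mismatch_pos, use.names = FALSE)
    if (length(mm)) {
      w <- findInterval(mm, scheme$win_start)
      t <- tabulate(w, nbins = nw)
      mism <- mism + t
      imperfect <- imperfect | t > 0L
    }
    unk <- which(vapply(reads$mismatch_pos, is.null, TRUE) &
                   reads$n_matches < reads$aligned_length)
    for (i in unk) {
      w1 <- findInterval(reads$pos[i], scheme$win_start)
      w2 <- findInterval(reads$pos[i] + reads$aligned_length - 1L,
                         scheme$win_start)
      imperfect[w1:w2] <- TRUE
      mism[w1:w2] <- mism[w1:w2] +
        (reads$aligned_length[i] - reads$n_matches[i])
    }
  }
  structure(list(region_id = region_id, sample_id = sample_id,
                 depths = depths, mismatch_bases = mism,
                 imperfect = imperfect),
            class = "WindowProfile")
}

#' Ingest one sample's SAM into per-region window profiles
#'
#' Composition of [filter_barcodes()], [identity_filter()] and
#' [window_depth_profile()] over every catalog region. Regions without any
#' retained read get an all-zero profile.
#'
#' @param sam_path SAM/BAM path.
#' @param catalog A `RegionCatalog`.
#' @param barcode_table Barcode/cell-type table for the sample (data.frame
#'   or path to its TSV).
#' @param sample_id Sample label for the profiles.
#' @param target_cell_type Cell type to retain (default `"Mono"`).
#' @param min_identity Exclusive percent-identity cut (default 99).
#' @return Named list (one `WindowProfile` per region id) with attribute
#'   `filter_counts` recording reads surviving each filter.
#' @export
ingest_sam <- function(sam_path, catalog, barcode_table,
                       sample_id = NA_character_, target_cell_type = "Mono",
                       min_identity = 99.0) {
  if (is.character(barcode_table) && length(barcode_table) == 1L)
    barcode_table <- utils::read.delim(barcode_table,
                                       stringsAsFactors = FALSE)
  reads <- read_sam_alignments(sam_path, catalog)
  n_total <- nrow(reads)
  reads <- filter_barcodes(reads, barcode_table, target_cell_type)
  n_bc <- nrow(reads)
  n_unknown <- attr(reads, "n_unknown_barcode")
  reads <- identity_filter(reads, min_identity)
  n_id <- nrow(reads)

  by_region <- split(seq_len(nrow(reads)), reads$region_id)
  profiles <- lapply(catalog$regions$region_id, function(rid) {
    idx <- by_region[[rid]]
    window_depth_profile(
      if (is.null(idx)) reads[0, , drop = FALSE]
      else reads[idx, , drop = FALSE],
      rid, catalog$schemes[[rid]], sample_id)
  })
  names(profiles) <- catalog$regions$region_id
  attr(profiles, "filter_counts") <- c(n_total = n_total,
                                       n_barcode_pass = n_bc,
                                       n_unknown_barcode = n_unknown,
                                       n_identity_pass = n_id)
  profiles
}

#' Write window profiles as a long-format TSV
#'
#' @param profiles Named list of `WindowProfile`s (from [ingest_sam()]).
#' @param path Output TSV path (`region_id`, `window_index`, `depth`).
#' @return Invisibly, the path.
#' @export
write_profiles <- function(profiles, path) {
  long <- do.call(rbind, lapply(profiles, function(p)
    data.frame(region_id = p$region_id,
               window_index = seq_along(p$depths),
               depth = p$depths)))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
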