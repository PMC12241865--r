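#' Partition a region into sequential non-overlapping windows
#'
#' Tiles `[0, region_length)` with consecutive windows of `window_length`
#' nucleotides. The final window is retained even when shorter than
#' `window_length`, so the windows always reproduce the region exactly.
#' Coordinates are 0-based, half-open (BED convention).
#'
#' @param region_length Region length in nucleotides (>= 1).
#' @param window_length Window length in nucleotides (>= 1).
#' @return A `data.frame` with columns `win_start`, `win_end` (0-based,
#'   half-open, region-local) and attribute `window_length`.
#' @examples
#' partition_windows(950, 100)  # 10 windows, last of length 50
#' @export
partition_windows <- function(region_length, window_length) {
  if (!is.numeric(region_length) || length(region_length) != 1L ||
      is.na(region_length) || region_length < 1)
    stop("`region_length` must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(window_length) || length(window_length) != 1L ||
      is.na(window_length) || window_length < 1)
    stop("`window_length` must be a single integer >= 1", call. = FALSE)
  region_length <- as.integer(region_length)
  window_length <- as.integer(window_length)
  starts <- seq.int(0L, region_length - 1L, by = window_length)
  ends <- pmin(starts + window_length, region_length)
  scheme <- data.frame(win_start = starts, win_end = ends)
  attr(scheme, "window_length") <- window_length
  scheme
}

new_region_catalog <- function(regions, sequences, window_length) {
  schemes <- lapply(regions$length, partition_windows,
                    window_length = window_length)
  names(schemes) <- regions$region_id
  structure(
    list(regions = regions, sequences = sequences,
         window_length = window_length, schemes = schemes),
    class = "RegionCatalog")
}

#' Load a region catalog from BED (and optionally FASTA)
#'
#' The catalog describes the reference loci the pipeline scores: autonomous
#' HERV proviruses and, optionally, nearby host genes. Each BED record becomes
#' one region; the FASTA (keyed by region id) supplies the per-region
#' reference sequence needed for identity filtering of synthetic reads and for
#' the window-similarity gate. The BED is read directly so that validation
#' failures can name the offending record's line number.
#'
#' @param bed_path Path to a BED file (4+ columns: chrom, start, end, name
#'   and optionally score, strand). Coordinates 0-based half-open.
#' @param fasta_path Optional path to a FASTA whose sequence names are the
#'   BED `name` fields. When given, every region must have a sequence of the
#'   exact region length.
#' @param window_length Window length L in nucleotides used to tile every
#'   region (default 100).
#' @param host_gene_ids Character vector of region ids to label as host genes
#'   rather than HERV loci.
#' @return A `RegionCatalog`: regions table (`region_id`, `kind`, `chrom`,
#'   `start`, `end`, `strand`, `length`), sequences (`DNAStringSet` or NULL),
#'   the window length, and one window scheme per region.
#' @export
load_catalog <- function(bed_path, fasta_path = NULL, window_length = 100,
                         host_gene_ids = character()) {
  if (!file.exists(bed_path))
    stop("BED file not found: ", bed_path, call. = FALSE)
  lines <- readLines(bed_path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  if (length(lineno) == 0L)
    stop("BED file has no records: ", bed_path, call. = FALSE)
  fields <- strsplit(lines[keep], "\t| +")
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop("BED line ", lineno[which(nf < 4L)[1L]],
         ": fewer than 4 columns (name column required)", call. = FALSE)
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  name <- vapply(fields, `[`, "", 4L)
  strand <- vapply(fields, function(f) if (length(f) >= 6L) f[6L] else "+", "")
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("BED line ", lineno[bad[1L]], ": non-numeric start/end",
         call. = FALSE)
  bad <- which(end <= start)
  if (length(bad))
    stop("BED line ", lineno[bad[1L]], ": interval end <= start (region '",
         name[bad[1L]], "')", call. = FALSE)
  dup <- name[duplicated(name)]
  if (length(dup))
    stop("duplicate region_id in BED: '", dup[1L], "'", call. = FALSE)
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop("BED line ", lineno[bad[1L]], ": strand must be '+' or '-'",
         call. = FALSE)

  regions <- data.frame(
    region_id = name,
    kind = ifelse(name %in% host_gene_ids, "host_gene", "herv"),
    chrom = chrom, start = start, end = end, strand = strand,
    length = end - start,
    stringsAsFactors = FALSE)

  sequences <- NULL
  if (!is.null(fasta_path)) {
    sequences <- Biostrings::readDNAStringSet(fasta_path)
    names(sequences) <- sub("\\s.*$", "", names(sequences))
    missing <- setdiff(regions$region_id, names(sequences))
    if (length(missing))
      stop("region(s) in BED absent from FASTA: ",
           paste(missing, collapse = ", "), call. = FALSE)
    sequences <- sequences[regions$region_id]
    lens <- Biostrings::width(sequences)
    bad <- which(lens != regions$length)
    if (length(bad))
      stop("sequence length mismatch for region '",
           regions$region_id[bad[1L]], "': BED says ",
           regions$length[bad[1L]], " nt, FASTA has ", lens[bad[1L]], " nt",
           call. = FALSE)
  }
  new_region_catalog(regions, sequences, window_length)
}

#' Write a region catalog to BED + FASTA
#'
#' @param catalog A `RegionCatalog`.
#' @param bed_path,fasta_path Output paths; FASTA is skipped when the catalog
#'   carries no sequences or `fasta_path` is NULL.
#' @return Invisibly, the catalog.
#' @export
write_catalog <- function(catalog, bed_path, fasta_path = NULL) {
  stopifnot(inherits(catalog, "RegionCatalog"))
  r <- catalog$regions
  bed <- data.frame(r$chrom, r$start, r$end, r$region_id, 0L, r$strand)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(fasta_path) && !is.null(catalog$sequences))
    Biostrings::writeXStringSet(catalog$sequences, fasta_path)
  invisible(catalog)
}

#' Summarize a catalog as a table
#'
#' @param catalog A `RegionCatalog`.
#' @return A `data.frame` with one row per region including window counts.
#' @export
catalog_summary <- function(catalog) {
  stopifnot(inherits(catalog, "RegionCatalog"))
  r <- catalog$regions
  r$n_windows <- vapply(catalog$schemes[r$region_id], nrow, 0L)
  r$window_length <- catalog$window_length
  r
}

#' @export
print.RegionCatalog <- function(x, ...) {
  cat("RegionCatalog:", nrow(x$regions), "regions (",
      sum(x$regions$kind == "herv"), "HERV loci,",
      sum(x$regions$kind == "host_gene"), "host genes ), window length",
      x$window_length, "nt,",
      if (is.null(x$sequences)) "no sequences\n" else "with sequences\n")
  invisible(x)
}
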