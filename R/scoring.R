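#' WHA decision thresholds
#'
#' The classifier's operating point: a window is usable at mean depth >=
#' `depth_min` (3), a locus is positive with >= `windows_min` (9) usable
#' windows and locus depth >= `depth_min`, gated on the window-similarity
#' score. `wss_gate = "strict"` requires `wss >= wss_min` (100: every
#' covered window perfect); `"off"` disables the gate, appropriate when
#' simulated substitution noise is under study.
#'
#' @param depth_min Minimum per-window (and per-locus) mean depth.
#' @param windows_min Minimum usable windows for a positive call.
#' @param wss_min Minimum window-similarity score in percent.
#' @param wss_gate `"strict"` or `"off"`.
#' @param min_identity Exclusive percent-identity cut applied upstream.
#' @param window_length Window length L recorded in outputs.
#' @return A `wha_thresholds` list.
#' @export
wha_thresholds <- function(depth_min = 3, windows_min = 9, wss_min = 100,
                           wss_gate = c("strict", "off"),
                           min_identity = 99.0, window_length = 100) {
  wss_gate <- match.arg(wss_gate)
  if (depth_min < 0 || windows_min < 0 || wss_min < 0 || wss_min > 100)
    stop("invalid thresholds", call. = FALSE)
  structure(list(depth_min = depth_min, windows_min = windows_min,
                 wss_min = wss_min, wss_gate = wss_gate,
                 min_identity = min_identity,
                 window_length = window_length),
            class = "wha_thresholds")
}

#' Count usable windows in a depth profile
#'
#' A window is usable (synonymously, "good") when its mean per-base read
#' depth is `depth_min` or greater; the boundary counts (a window at exactly
#' depth 3 is usable).
#'
#' @param profile A `WindowProfile` or a numeric depth vector.
#' @param depth_min Usability threshold (default 3).
#' @return Integer count of usable windows.
#' @export
count_usable_windows <- function(profile, depth_min = 3) {
  depths <- if (inherits(profile, "WindowProfile")) profile$depths
            else as.numeric(profile)
  sum(depths >= depth_min)
}

#' Window-similarity score (WSS) of a profile
#'
#' Percentage of covered windows (depth > 0) in which every retained read's
#' aligned bases match the reference perfectly. 100 when all covered
#' windows are perfect, and 100 by convention when no window is covered, so
#' that the depth and window-count rules alone decide silent loci.
#'
#' @param profile A `WindowProfile` (carries per-window mismatch tallies).
#' @return Score in percent, in `[0, 100]`.
#' @export
wss_score <- function(profile) {
  stopifnot(inherits(profile, "WindowProfile"))
  covered <- profile$depths > 0
  if (!any(covered)) return(100)
  100 * sum(covered & !profile$imperfect) / sum(covered)
}

#' Locus-level depth
#'
#' Mean of window depths over the usable windows; 0 when no window is
#' usable.
#'
#' @param profile A `WindowProfile` or numeric depth vector.
#' @param depth_min Window-usability threshold.
#' @return Mean depth over usable windows.
#' @export
locus_depth <- function(profile, depth_min = 3) {
  depths <- if (inherits(profile, "WindowProfile")) profile$depths
            else as.numeric(profile)
  usable <- depths >= depth_min
  if (!any(usable)) return(0)
  mean(depths[usable])
}

#' Positive/negative locus call
#'
#' Positive iff the usable-window count is at least `windows_min` (9), the
#' locus depth is at least `depth_min` (3) and, under the strict gate, the
#' window-similarity score is at least `wss_min` (100). Otherwise negative:
#' 8 or fewer usable windows, or depth below 3, always yields negative.
#'
#' @param n_usable Usable-window count.
#' @param locus_depth Locus-level mean depth.
#' @param wss_percent Window-similarity score in percent.
#' @param thresholds A [wha_thresholds()].
#' @return `"positive"` or `"negative"`.
#' @export
classify_locus <- function(n_usable, locus_depth, wss_percent,
                           thresholds = wha_thresholds()) {
  stopifnot(is.finite(n_usable), is.finite(locus_depth),
            is.finite(wss_percent), n_usable >= 0, locus_depth >= 0)
  wss_ok <- thresholds$wss_gate == "off" ||
    wss_percent >= thresholds$wss_min
  if (wss_ok && n_usable >= thresholds$windows_min &&
      locus_depth >= thresholds$depth_min) "positive" else "negative"
}

#' Score every catalog region of one sample
#'
#' Applies [count_usable_windows()], [wss_score()], [locus_depth()] and
#' [classify_locus()] per region. A catalog region without a profile is
#' treated as all-zero (negative) and noted.
#'
#' @param profiles Named list of `WindowProfile`s (from [ingest_sam()]).
#' @param catalog A `RegionCatalog`.
#' @param thresholds A [wha_thresholds()].
#' @param sample_id Sample label (defaults to the profiles' label).
#' @return `data.frame` of locus calls: `sample_id`, `region_id`, `kind`,
#'   `wss_percent`, `n_usable_windows`, `locus_depth`, `status`, plus the
#'   thresholds as attributes.
#' @export
score_sample <- function(profiles, catalog, thresholds = wha_thresholds(),
                         sample_id = NULL) {
  stopifnot(inherits(catalog, "RegionCatalog"))
  if (is.null(sample_id)) {
    sid <- unique(stats::na.omit(vapply(profiles, `[[`, "", "sample_id")))
    sample_id <- if (length(sid) == 1L) sid else NA_character_
  }
  missing <- setdiff(catalog$regions$region_id, names(profiles))
  if (length(missing))
    message("no profile for ", length(missing),
            " region(s); treated as all-zero")
  calls <- do.call(rbind, lapply(seq_len(nrow(catalog$regions)), function(i) {
    rid <- catalog$regions$region_id[i]
    p <- profiles[[rid]]
    if (is.null(p)) {
      nw <- nrow(catalog$schemes[[rid]])
      p <- structure(list(region_id = rid, sample_id = sample_id,
                          depths = numeric(nw),
                          mismatch_bases = integer(nw),
                          imperfect = logical(nw)),
                     class = "WindowProfile")
    }
    nu <- count_usable_windows(p, thresholds$depth_min)
    ld <- locus_depth(p, thresholds$depth_min)
    wss <- wss_score(p)
    data.frame(sample_id = sample_id, region_id = rid,
               kind = catalog$regions$kind[i],
               wss_percent = wss, n_usable_windows = nu,
               locus_depth = ld,
               status = classify_locus(nu, ld, wss, thresholds),
               stringsAsFactors = FALSE)
  }))
  attr(calls, "thresholds") <- thresholds
  calls
}
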