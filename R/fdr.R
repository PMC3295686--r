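#' Empirical FDR table: expected versus observed window fractions
#'
#' For each read count value observed in the track, the raw empirical FDR is
#' the fraction of windows expected under the null distribution divided by
#' the fraction observed in the data. In the default tail form both fractions
#' are upper-tail fractions at the count:
#'
#'   FDR_raw(c) = P_null(C >= c) / (observed fraction of windows with count >= c)
#'
#' A per-count (density) form, using P(C = c) over the observed fraction
#' exactly at c, is available via `mode = "density"`. Raw values are clipped
#' to \[0, 1\] and then regularized to be monotone non-increasing in the
#' count by a running minimum over increasing count values
#' (`FDR(c) = min_{c' <= c} FDR_raw(c')`), which never increases any value
#' and preserves the ordering of calls across thresholds. Count values never
#' observed in the track are not tabulated.
#'
#' @param track A `window_track` from [count_windows()].
#' @param null A `null_model` fitted on the same track.
#' @param mode `"tail"` (default) or `"density"`.
#' @return An `fdr_table`: data frame with columns `count`, `fdr_raw`
#'   (clipped, pre-monotonization) and `fdr` (monotone), sorted by `count`.
#' @export
compute_fdr_table <- function(track, null, mode = c("tail", "density")) {
  mode <- match.arg(mode)
  stopifnot(inherits(track, "window_track"), inherits(null, "null_model"))
  counts <- track$count
  n <- length(counts)
  tab <- table(counts)
  cs <- as.integer(names(tab))
  freq <- as.integer(tab)
  if (mode == "tail") {
    obs <- rev(cumsum(rev(freq))) / n      # observed fraction with count >= c
    expected <- null_tail_prob(null, cs)
  } else {
    obs <- freq / n                         # observed fraction with count == c
    expected <- null_point_prob(null, cs)
  }
  fdr_raw <- pmin(pmax(expected / obs, 0), 1)
  structure(
    data.frame(count = cs, fdr_raw = fdr_raw, fdr = cummin(fdr_raw)),
    mode = mode,
    class = c("fdr_table", "data.frame")
  )
}

#' Scan windows for candidate peaks against the FDR table
#'
#' Returns every window whose (monotone) FDR at its read count is at or
#' below `max_fdr`. Windows with count 0 are never candidates.
#'
#' @param track A `window_track`.
#' @param fdr_table An `fdr_table` computed on the same track.
#' @param max_fdr Maximum acceptable FDR among called windows; default 0.01.
#' @return A `candidate_windows` data frame (`chrom`, `start`, `end`,
#'   `count`, `fdr`), carrying the track's `window_size` and `step`.
#' @export
scan_candidates <- function(track, fdr_table, max_fdr = 0.01) {
  stopifnot(inherits(track, "window_track"), inherits(fdr_table, "fdr_table"),
            max_fdr > 0, max_fdr <= 1)
  idx <- match(track$count, fdr_table$count)
  fdr <- fdr_table$fdr[idx]
  keep <- !is.na(fdr) & fdr <= max_fdr & track$count >= 1L
  out <- data.frame(chrom = track$chrom[keep], start = track$start[keep],
                    end = track$end[keep], count = track$count[keep],
                    fdr = fdr[keep], stringsAsFactors = FALSE)
  structure(out, window_size = attr(track, "window_size"),
            step = attr(track, "step"),
            chrom_sizes = attr(track, "chrom_sizes"),
            class = c("candidate_windows", "data.frame"))
}
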