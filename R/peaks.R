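#' Merge overlapping candidate windows into peaks
#'
#' Windows overlapping by at least 1 bp are merged into one peak spanning
#' their union; when the scan used non-overlapping tiling
#' (`step == window_size`), book-ended windows (adjacent, sharing a
#' boundary) are merged too. Each peak records the minimum window FDR over
#' its merged windows and, when reads are supplied, the number of reads
#' whose 5' coordinate lies in the merged span.
#'
#' @param windows A `candidate_windows` data frame from [scan_candidates()].
#' @param reads Optional read data frame used to count reads per merged span
#'   (5'-coordinate containment); without it `read_count` is `NA`.
#' @return Data frame of peaks: `chrom`, `start`, `end`, `read_count`,
#'   `min_window_fdr`.
#' @export
merge_candidates <- function(windows, reads = NULL) {
  stopifnot(inherits(windows, "candidate_windows"))
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      read_count = integer(0), min_window_fdr = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(windows) == 0L) return(empty)
  step <- attr(windows, "step")
  window_size <- attr(windows, "window_size")
  merge_bookended <- !is.null(step) && !is.null(window_size) && step == window_size
  gapwidth <- if (merge_bookended) 1L else 0L

  gr <- df_to_gr(windows)
  red <- GenomicRanges::reduce(gr, min.gapwidth = gapwidth, with.revmap = TRUE)
  peaks <- gr_to_df(red)
  peaks$min_window_fdr <- vapply(S4Vectors::mcols(red)$revmap,
                                 function(i) min(windows$fdr[i]), numeric(1))
  peaks$read_count <- if (is.null(reads)) NA_integer_ else
    count_reads_in_spans(peaks, reads)
  peaks <- peaks[order(peaks$chrom, peaks$start),
                 c("chrom", "start", "end", "read_count", "min_window_fdr")]
  rownames(peaks) <- NULL
  peaks
}

# reads whose 5'-most coordinate falls inside each span
count_reads_in_spans <- function(spans, reads) {
  if (nrow(spans) == 0L) return(integer(0))
  if (nrow(reads) == 0L) return(integer(nrow(spans)))
  p <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  pts <- GenomicRanges::GRanges(reads$chrom, IRanges::IRanges(p + 1L, width = 1L))
  GenomicRanges::countOverlaps(df_to_gr(spans), pts)
}

#' One-sided Wilcoxon rank-sum p-value for strand separation
#'
#' Tests the alternative that forward-read 5' positions lie to the left of
#' reverse-read 5' positions — the spatial signature of reads flanking a
#' true enrichment site. Ties are handled by midranks. When
#' `n + m <= exact_limit` the p-value is exact: the probability, over all
#' `choose(n + m, n)` assignments of the (mid)ranks to the forward group,
#' that the forward rank sum is at or below the observed one. For larger
#' samples a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param forward,reverse Numeric vectors of 5' positions.
#' @param exact_limit Largest `n + m` for which the exact distribution is
#'   enumerated (default 20).
#' @return A single p-value in (0, 1].
#' @export
wilcoxon_strand_p <- function(forward, reverse, exact_limit = 20L) {
  n <- length(forward); m <- length(reverse)
  if (n == 0L || m == 0L) return(1)
  r <- rank(c(forward, reverse))
  w_obs <- sum(r[seq_len(n)])
  N <- n + m
  if (N <= exact_limit) {
    # exact tail via subset-sum DP over doubled (integer) midranks
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    # f[j+1, s+1] = number of j-subsets of the ranks seen so far summing to s
    f <- matrix(0, nrow = n + 1L, ncol = total + 1L)
    f[1L, 1L] <- 1
    for (v in r2) {
      jmax <- n
      for (j in seq.int(jmax, 1L)) {
        cols <- seq_len(total + 1L - v)
        f[j + 1L, cols + v] <- f[j + 1L, cols + v] + f[j, cols]
      }
    }
    obs2 <- as.integer(round(2 * w_obs))
    n_le <- sum(f[n + 1L, seq_len(obs2 + 1L)])
    return(n_le / choose(N, n))
  }
  mu <- n * (N + 1) / 2
  ties <- table(r)
  sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  stats::pnorm((w_obs - mu + 0.5) / sqrt(sigma2))
}

#' Refine peaks by the spatial distribution of forward and reverse reads
#'
#' For each peak, the 5' coordinates of `+` and `-` reads within the span
#' are compared with the one-sided Wilcoxon rank-sum test
#' ([wilcoxon_strand_p()]): at a genuine enrichment site, forward reads
#' accumulate on the left flank and reverse reads on the right. The p-value
#' is recorded on every peak; peaks with fewer than 2 reads on either strand
#' get `wilcoxon_p = 1`. By default no peak is dropped (annotate-only);
#' with `require_orientation = TRUE`, peaks with `wilcoxon_p >
#' wilcoxon_alpha` (including the under-populated ones) are removed.
#'
#' @param peaks Peak data frame from [merge_candidates()].
#' @param reads Read data frame with strand.
#' @param wilcoxon_alpha Significance threshold used when filtering.
#' @param require_orientation Drop peaks failing the strand-orientation test.
#' @return The peak data frame with columns `wilcoxon_p` and `refined`
#'   (logical: passed the orientation test) added.
#' @export
refine_peaks <- function(peaks, reads, wilcoxon_alpha = 0.05,
                         require_orientation = FALSE) {
  if (nrow(peaks) == 0L) {
    peaks$wilcoxon_p <- numeric(0)
    peaks$refined <- logical(0)
    return(peaks)
  }
  p5 <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  pvals <- vapply(seq_len(nrow(peaks)), function(i) {
    sel <- reads$chrom == peaks$chrom[i] & p5 >= peaks$start[i] & p5 < peaks$end[i]
    fwd <- p5[sel & reads$strand == "+"]
    rev <- p5[sel & reads$strand == "-"]
    if (length(fwd) < 2L || length(rev) < 2L) return(1)
    wilcoxon_strand_p(fwd, rev)
  }, numeric(1))
  peaks$wilcoxon_p <- pvals
  peaks$refined <- pvals <= wilcoxon_alpha
  if (require_orientation) peaks <- peaks[peaks$refined, , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

#' Call methylation peaks from mapped reads
#'
#' The four-stage peak finder: (1) fit the negative-binomial null on
#' low-coverage windows ([fit_null()]); (2) scan windows for counts higher
#' than expected under the null at the empirical-FDR threshold
#' ([compute_fdr_table()], [scan_candidates()]); (3) merge overlapping
#' candidate windows ([merge_candidates()]); (4) refine peaks by the
#' forward/reverse read distribution ([refine_peaks()]).
#'
#' @param reads Read data frame (`chrom`, `start`, `end`, `strand`).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param window_size Scan window width in bp (default 300).
#' @param step Window step in bp (default `window_size / 3`).
#' @param max_fdr Maximum empirical FDR for candidate windows (default 0.01).
#' @param low_coverage_quantile Quantile defining low-coverage windows for
#'   the null fit (default 0.90).
#' @param fdr_mode `"tail"` or `"density"`; see [compute_fdr_table()].
#' @param require_orientation Drop peaks failing the strand test.
#' @param wilcoxon_alpha Threshold for the strand test when filtering.
#' @param verbose Log stage summaries via `message()`.
#' @return Data frame of peaks (`chrom`, `start`, `end`, `read_count`,
#'   `min_window_fdr`, `wilcoxon_p`, `refined`) with attribute `stats`
#'   (list: `n_reads`, `n_windows`, `low_coverage_cutoff`, `mu`, `k`,
#'   `family`, `n_candidates`, `n_peaks`) and attribute `null_model`.
#' @export
call_peaks <- function(reads, chrom_sizes, window_size = 300L, step = NULL,
                       max_fdr = 0.01, low_coverage_quantile = 0.9,
                       fdr_mode = c("tail", "density"),
                       require_orientation = FALSE, wilcoxon_alpha = 0.05,
                       verbose = FALSE) {
  fdr_mode <- match.arg(fdr_mode)
  track <- count_windows(reads, chrom_sizes, window_size, step)
  null <- fit_null(track, low_coverage_quantile)
  fdr_table <- compute_fdr_table(track, null, mode = fdr_mode)
  cand <- scan_candidates(track, fdr_table, max_fdr)
  peaks <- merge_candidates(cand, reads)
  peaks <- refine_peaks(peaks, reads, wilcoxon_alpha, require_orientation)
  stats <- list(n_reads = nrow(reads), n_windows = nrow(track),
                low_coverage_cutoff = null$low_coverage_cutoff,
                mu = null$mu, k = null$k, family = null$family,
                n_candidates = nrow(cand), n_peaks = nrow(peaks))
  if (verbose) {
    message(sprintf(
      "call_peaks: %d reads, %d windows; null %s(mu=%.3g%s), cutoff %g; %d candidate windows -> %d peaks",
      stats$n_reads, stats$n_windows, stats$family, stats$mu,
      if (stats$family == "nb") sprintf(", k=%.3g", stats$k) else "",
      stats$low_coverage_cutoff, stats$n_candidates, stats$n_peaks))
  }
  attr(peaks, "stats") <- stats
  attr(peaks, "null_model") <- null
  peaks
}
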