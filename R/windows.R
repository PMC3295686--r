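#' Count reads in tiled or sliding windows
#'
#' Tiles each chromosome with windows of `window_size` bp placed every `step`
#' bp starting at 0 (the last partial window is kept, clipped at the
#' chromosome end). Each read is counted in every window containing its
#' 5'-most coordinate: `start` for `+` reads, `end - 1` for `-` reads.
#' Assigning reads by their 5' point (rather than by overlap) makes the
#' counts of a non-overlapping tiling a partition of the reads, so window
#' counts are conserved.
#'
#' @param reads Read data frame (`chrom`, `start`, `end`, `strand`).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param window_size Window width in bp (default 300).
#' @param step Window placement step in bp, `1 <= step <= window_size`;
#'   default `window_size / 3` rounded down (sub-window scan resolution).
#' @return A `window_track`: data frame with columns `chrom`, `start`, `end`,
#'   `count`, windows sorted per chromosome, with attributes `window_size`,
#'   `step`, `chrom_sizes`.
#' @export
count_windows <- function(reads, chrom_sizes, window_size = 300L, step = NULL) {
  chrom_sizes <- check_chrom_sizes(chrom_sizes)
  window_size <- as.integer(window_size)
  if (is.null(step)) step <- max(1L, window_size %/% 3L)
  step <- as.integer(step)
  stopifnot(window_size >= 1L, step >= 1L, step <= window_size)

  unknown <- setdiff(unique(reads$chrom), names(chrom_sizes))
  if (length(unknown)) {
    stop(sprintf("read on unknown chromosome '%s' (not in chrom_sizes)", unknown[1]),
         call. = FALSE)
  }
  five_prime <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)

  pieces <- lapply(names(chrom_sizes), function(chrom) {
    L <- chrom_sizes[[chrom]]
    starts <- seq.int(0L, by = step, length.out = ceiling(L / step))
    starts <- starts[starts < L]
    n_win <- length(starts)
    counts <- integer(n_win)
    p <- five_prime[reads$chrom == chrom]
    if (length(p) > 0L) {
      kmax <- p %/% step
      n_shifts <- ceiling(window_size / step)
      for (j in seq_len(n_shifts) - 1L) {
        k <- kmax - j
        valid <- k >= 0L & (k * step + window_size) > p
        if (any(valid)) counts <- counts + tabulate(k[valid] + 1L, nbins = n_win)
      }
    }
    data.frame(chrom = chrom, start = as.integer(starts),
               end = as.integer(pmin(starts + window_size, L)),
               count = counts, stringsAsFactors = FALSE)
  })
  track <- do.call(rbind, pieces)
  rownames(track) <- NULL
  structure(track, window_size = window_size, step = step,
            chrom_sizes = chrom_sizes, class = c("window_track", "data.frame"))
}
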