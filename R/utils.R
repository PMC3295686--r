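# Internal helpers shared across modules.

#' Evaluate an expression with a locally seeded RNG
#'
#' Saves and restores the global RNG state so simulation calls are
#' reproducible without clobbering the caller's random stream.
#' @noRd
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("rng_seed must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' @noRd
check_chrom_sizes <- function(chrom_sizes) {
  if (length(chrom_sizes) == 0L) {
    stop("chrom_sizes is empty: at least one chromosome is required", call. = FALSE)
  }
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop("chrom_sizes must be a named vector of chromosome lengths", call. = FALSE)
  }
  if (anyDuplicated(names(chrom_sizes))) {
    stop("chrom_sizes has duplicated chromosome names", call. = FALSE)
  }
  sizes <- as.numeric(chrom_sizes)
  if (any(!is.finite(sizes)) || any(sizes < 1)) {
    stop("all chromosome lengths must be positive", call. = FALSE)
  }
  stats::setNames(sizes, names(chrom_sizes))
}

#' Convert an interval data frame (chrom/start/end, 0-based half-open) to GRanges
#' @noRd
df_to_gr <- function(df, strand = NULL) {
  if (nrow(df) == 0L) {
    return(GenomicRanges::GRanges())
  }
  s <- if (is.null(strand)) "*" else strand
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = s
  )
}

#' @noRd
gr_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Merge intervals of one condition (union of overlapping or book-ended spans)
#' @noRd
merge_intervals_df <- function(df) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  red <- GenomicRanges::reduce(df_to_gr(df))
  out <- gr_to_df(red)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
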