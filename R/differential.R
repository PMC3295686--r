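# Sample-specific methylation calls: a peak found only in the treated
# sample marks treatment-induced hypermethylation, a peak found only in the
# control marks hypomethylation (lost under treatment); peaks present in
# both are shared.

#' Classify peaks as hyper-, hypo-methylated or shared across samples
#'
#' A treated peak overlapping any control peak by at least `min_overlap_bp`
#' is `shared` (and vice versa); treated-only peaks are `hyper`,
#' control-only peaks `hypo`. Shared peaks record their largest-overlap
#' partner in the other sample.
#'
#' @param peaks_treated,peaks_control Peak data frames (annotated or not).
#' @param min_overlap_bp Minimum overlap in bp to count as shared
#'   (default 1).
#' @return Data frame with one row per peak from both samples: original peak
#'   columns plus `sample` ("treated"/"control"), `label`
#'   ("hyper"/"hypo"/"shared"), `partner` (row index of the largest-overlap
#'   partner in the other sample, `NA` for specific peaks) and `overlap_bp`.
#' @export
classify_differential <- function(peaks_treated, peaks_control, min_overlap_bp = 1L) {
  stopifnot(min_overlap_bp >= 1)
  lab <- function(peaks, other, specific_label) {
    n <- nrow(peaks)
    out <- peaks
    out$sample <- if (specific_label == "hyper") "treated" else "control"
    out$label <- rep(specific_label, n)
    out$partner <- rep(NA_integer_, n)
    out$overlap_bp <- rep(0L, n)
    if (n == 0L || nrow(other) == 0L) return(out)
    hits <- GenomicRanges::findOverlaps(df_to_gr(peaks), df_to_gr(other),
                                        minoverlap = as.integer(min_overlap_bp))
    if (length(hits) > 0L) {
      q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
      w <- GenomicRanges::width(IRanges::pintersect(df_to_gr(peaks)[q],
                                                    df_to_gr(other)[s]))
      for (i in unique(q)) {
        sel <- q == i
        j <- which.max(w[sel])
        out$label[i] <- "shared"
        out$partner[i] <- s[sel][j]
        out$overlap_bp[i] <- w[sel][j]
      }
    }
    out
  }
  res <- rbind(lab(peaks_treated, peaks_control, "hyper"),
               lab(peaks_control, peaks_treated, "hypo"))
  rownames(res) <- NULL
  res
}

#' Normalized difference of library-size-normalized peak counts
#'
#' With `a` = treated reads in the span per million treated reads and `b` =
#' the control analogue, returns `(a - b) / (a + b)`: 0 for equal normalized
#' coverage, +1 for treated-exclusive signal, -1 for control-exclusive
#' signal. When both counts are 0 the value is 0 and flagged degenerate.
#'
#' @param peaks Data frame of spans (`chrom`, `start`, `end`).
#' @param reads_treated,reads_control Read data frames; counts use
#'   5'-coordinate containment in the span.
#' @param lib_size_treated,lib_size_control Library sizes; default the
#'   number of rows of each read set.
#' @return Data frame with columns `normalized_difference` and `degenerate`.
#' @export
normalized_difference <- function(peaks, reads_treated, reads_control,
                                  lib_size_treated = nrow(reads_treated),
                                  lib_size_control = nrow(reads_control)) {
  if (lib_size_treated <= 0 || lib_size_control <= 0) {
    stop("library sizes must be positive for both samples", call. = FALSE)
  }
  ct <- count_reads_in_spans(peaks, reads_treated)
  cc <- count_reads_in_spans(peaks, reads_control)
  a <- ct / lib_size_treated * 1e6
  b <- cc / lib_size_control * 1e6
  denom <- a + b
  nd <- ifelse(denom == 0, 0, (a - b) / denom)
  data.frame(normalized_difference = nd, degenerate = denom == 0)
}

#' Summarize differential calls genome-wide
#'
#' @param calls Data frame from [classify_differential()].
#' @return List: `n_hyper`, `n_hypo`, `n_shared` (shared pairs counted once
#'   via the treated side; unpaired shared labels counted as entries),
#'   `per_chromosome` breakdown, and `global_hypomethylation` — `TRUE` when
#'   hypo calls outnumber hyper calls, the genome-wide loss-of-methylation
#'   signature.
#' @export
global_methylation_summary <- function(calls) {
  n_hyper <- sum(calls$label == "hyper")
  n_hypo <- sum(calls$label == "hypo")
  n_shared_pairs <- sum(calls$label == "shared" & calls$sample == "treated")
  chroms <- sort(unique(calls$chrom))
  per_chrom <- data.frame(
    chrom = chroms,
    n_hyper = vapply(chroms, function(c) sum(calls$chrom == c & calls$label == "hyper"), numeric(1)),
    n_hypo = vapply(chroms, function(c) sum(calls$chrom == c & calls$label == "hypo"), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(n_hyper = n_hyper, n_hypo = n_hypo, n_shared = n_shared_pairs,
       per_chromosome = per_chrom,
       global_hypomethylation = n_hypo > n_hyper)
}
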