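# Feature classes: promoter = 20 kbp upstream of the TSS, 3'-flank = 20 kbp
# downstream of the TTS (both strand-aware), gene body = the transcribed
# span (exons and introns); everything else is intergenic.

#' Build the strand-aware feature interval index
#'
#' Per gene, in genome coordinates (0-based half-open):
#' * gene body: `[min(tss, tts), max(tss, tts))`;
#' * promoter: `flank_size` bp upstream of the TSS — `[tss - flank, tss)` on
#'   `+`, `[tss, tss + flank)` on `-`;
#' * 3'-flank: `flank_size` bp downstream of the TTS in the direction of
#'   transcription — `[tts, tts + flank)` on `+`, `[tts - flank, tts)` on `-`.
#'
#' Intervals are clipped at 0 and, when `chrom_sizes` is given, at the
#' chromosome length.
#'
#' @param gene_models Gene-model data frame from [read_gene_models()].
#' @param flank_size Promoter / 3'-flank width in bp (default 20000).
#' @param chrom_sizes Optional named vector of chromosome lengths for
#'   clipping; genes on chromosomes absent from it raise an error.
#' @return A `feature_index`: list of data frames (`gene_body`, `promoter`,
#'   `three_prime_flank`), each with `chrom`, `start`, `end`, `gene_id`,
#'   plus the gene table itself.
#' @export
build_feature_index <- function(gene_models, flank_size = 20000L, chrom_sizes = NULL) {
  stopifnot(flank_size > 0)
  if (!is.null(chrom_sizes)) {
    chrom_sizes <- check_chrom_sizes(chrom_sizes)
    unknown <- setdiff(unique(gene_models$chrom), names(chrom_sizes))
    if (length(unknown)) {
      stop(sprintf("gene on unknown chromosome '%s'", unknown[1]), call. = FALSE)
    }
  }
  g <- gene_models
  minus <- g$strand == "-"
  body_start <- pmin(g$tss, g$tts)
  body_end <- pmax(g$tss, g$tts)
  prom_start <- ifelse(minus, g$tss, g$tss - flank_size)
  prom_end <- ifelse(minus, g$tss + flank_size, g$tss)
  flank_start <- ifelse(minus, g$tts - flank_size, g$tts)
  flank_end <- ifelse(minus, g$tts, g$tts + flank_size)

  clip <- function(start, end) {
    start <- pmax(start, 0)
    if (!is.null(chrom_sizes)) end <- pmin(end, as.numeric(chrom_sizes[g$chrom]))
    keep <- start < end
    data.frame(chrom = g$chrom[keep], start = as.integer(start[keep]),
               end = as.integer(end[keep]), gene_id = g$gene_id[keep],
               stringsAsFactors = FALSE)
  }
  structure(
    list(gene_body = clip(body_start, body_end),
         promoter = clip(prom_start, prom_end),
         three_prime_flank = clip(flank_start, flank_end),
         genes = g, flank_size = flank_size),
    class = "feature_index"
  )
}

feature_classes <- c("gene_body", "promoter", "three_prime_flank", "intergenic")

#' Annotate peaks with genomic feature classes and nearest genes
#'
#' Each peak is assigned the class whose interval union overlaps the peak
#' span most (in bp); ties are broken by the precedence gene body > promoter
#' > 3'-flank; a peak with no overlap is intergenic. The nearest gene is the
#' gene (on the same chromosome) whose TSS is closest to the peak midpoint;
#' `distance_to_tss` is signed in the gene's orientation (negative upstream
#' of the TSS).
#'
#' @param peaks Peak data frame (`chrom`, `start`, `end`, ...).
#' @param index A `feature_index` from [build_feature_index()].
#' @return The peak data frame with `feature_class`, `nearest_gene` and
#'   `distance_to_tss` columns added.
#' @export
annotate_peaks <- function(peaks, index) {
  stopifnot(inherits(index, "feature_index"))
  n <- nrow(peaks)
  peaks$feature_class <- character(n)
  peaks$nearest_gene <- rep(NA_character_, n)
  peaks$distance_to_tss <- rep(NA_real_, n)
  if (n == 0L) return(peaks)

  peak_gr <- df_to_gr(peaks)
  class_order <- c("gene_body", "promoter", "three_prime_flank")
  # bp of each peak covered by the union of each class's intervals
  overlap_bp <- sapply(class_order, function(cl) {
    feats <- index[[cl]]
    if (nrow(feats) == 0L) return(rep(0L, n))
    union_gr <- GenomicRanges::reduce(df_to_gr(feats))
    hits <- GenomicRanges::findOverlaps(peak_gr, union_gr)
    w <- GenomicRanges::width(IRanges::pintersect(
      peak_gr[S4Vectors::queryHits(hits)], union_gr[S4Vectors::subjectHits(hits)]))
    out <- rep(0L, n)
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(agg))] <- as.integer(agg)
    out
  })
  overlap_bp <- matrix(overlap_bp, nrow = n,
                       dimnames = list(NULL, class_order))
  best <- apply(overlap_bp, 1L, function(v) {
    if (all(v == 0)) return("intergenic")
    class_order[which.max(v)]  # which.max takes the first max: fixed precedence
  })
  peaks$feature_class <- best

  genes <- index$genes
  if (nrow(genes) > 0L) {
    mid <- (peaks$start + peaks$end) / 2
    for (i in seq_len(n)) {
      on_chrom <- which(genes$chrom == peaks$chrom[i])
      if (length(on_chrom) == 0L) next
      d_abs <- abs(genes$tss[on_chrom] - mid[i])
      j <- on_chrom[which.min(d_abs)]
      peaks$nearest_gene[i] <- genes$gene_id[j]
      # signed in gene orientation: negative upstream of the TSS
      d <- mid[i] - genes$tss[j]
      peaks$distance_to_tss[i] <- if (genes$strand[j] == "-") -d else d
    }
  }
  peaks
}

#' Class proportions over annotated peaks
#'
#' @param annotated_peaks Data frame with a `feature_class` column.
#' @return List with `n`, `fractions` (named over the four classes, summing
#'   to 1 for `n > 0`), and `grouped3` — the 3-way grouping used in summary
#'   pie charts: gene body, regulatory (promoter + 3'-flank), intergenic.
#' @export
feature_proportions <- function(annotated_peaks) {
  n <- nrow(annotated_peaks)
  counts <- vapply(feature_classes,
                   function(cl) sum(annotated_peaks$feature_class == cl), numeric(1))
  fractions <- if (n == 0L) stats::setNames(rep(0, 4), feature_classes) else counts / n
  grouped3 <- c(gene_body = unname(fractions["gene_body"]),
                regulatory = unname(fractions["promoter"] + fractions["three_prime_flank"]),
                intergenic = unname(fractions["intergenic"]))
  list(n = n, fractions = fractions, grouped3 = grouped3)
}

#' Per-chromosome peak counts for two samples
#'
#' @param peaks_treated,peaks_control Peak data frames.
#' @param chroms Optional character vector fixing the chromosome universe;
#'   defaults to all chromosomes seen in either sample.
#' @return Data frame with `chrom`, `n_treated`, `n_control`, `ratio`
#'   (treated / control; `NA` with `ratio_undefined = TRUE` when the control
#'   count is 0).
#' @export
chromosomal_distribution <- function(peaks_treated, peaks_control, chroms = NULL) {
  if (is.null(chroms)) {
    chroms <- sort(unique(c(peaks_treated$chrom, peaks_control$chrom)))
  }
  n_t <- vapply(chroms, function(c) sum(peaks_treated$chrom == c), numeric(1))
  n_c <- vapply(chroms, function(c) sum(peaks_control$chrom == c), numeric(1))
  ratio <- ifelse(n_c == 0, NA_real_, n_t / n_c)
  data.frame(chrom = chroms, n_treated = as.integer(n_t),
             n_control = as.integer(n_c), ratio = ratio,
             ratio_undefined = n_c == 0, row.names = NULL,
             stringsAsFactors = FALSE)
}
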