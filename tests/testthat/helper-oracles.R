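# Independent oracles and fixture builders shared by the test files.

# Fabricate a window_track directly from a count vector (tiled windows).
make_track <- function(counts, window_size = 300L, step = window_size,
                       chrom = "chr1") {
  n <- length(counts)
  starts <- seq.int(0L, by = step, length.out = n)
  L <- starts[n] + window_size
  structure(
    data.frame(chrom = chrom, start = starts,
               end = pmin(starts + window_size, L), count = as.integer(counts),
               stringsAsFactors = FALSE),
    window_size = as.integer(window_size), step = as.integer(step),
    chrom_sizes = stats::setNames(L, chrom),
    class = c("window_track", "data.frame")
  )
}

# Brute-force empirical FDR: explicit loop over observed count values,
# tail fractions computed by direct counting (no table/cumsum tricks).
bf_fdr_raw <- function(counts, null, mode = "tail") {
  cs <- sort(unique(counts))
  n <- length(counts)
  sapply(cs, function(c) {
    if (mode == "tail") {
      obs <- sum(counts >= c) / n
      expd <- null_tail_prob(null, c)
    } else {
      obs <- sum(counts == c) / n
      expd <- if (null$degenerate) as.numeric(c == 0)
              else if (null$family == "nb") dnbinom(c, size = null$k, mu = null$mu)
              else dpois(c, lambda = null$mu)
    }
    min(max(expd / obs, 0), 1)
  })
}

# Full-enumeration one-sided Wilcoxon rank-sum p: over all choose(N, n)
# assignments of the midranks to the forward group, the fraction whose
# forward rank sum is <= the observed one.
bf_wilcoxon_p <- function(forward, reverse) {
  n <- length(forward); m <- length(reverse)
  r <- rank(c(forward, reverse))
  obs <- sum(r[seq_len(n)])
  subs <- utils::combn(n + m, n)
  sums <- apply(subs, 2L, function(i) sum(r[i]))
  mean(sums <= obs + 1e-9)
}

# Hypergeometric right tail by direct binomial-coefficient summation.
bf_fisher_tail <- function(q, n_focus, n_set, N) {
  xs <- seq.int(q, min(n_focus, n_set))
  sum(choose(n_set, xs) * choose(N - n_set, n_focus - xs)) / choose(N, n_focus)
}

# Union-find merge of intervals (overlap >= 1 bp; book-ended optional).
bf_merge <- function(df, bookended = FALSE) {
  if (nrow(df) == 0L) return(df)
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || df$chrom[i] != df$chrom[j]) next
    ov <- min(df$end[i], df$end[j]) - max(df$start[i], df$start[j])
    if (ov > 0 || (bookended && ov == 0)) parent[find(i)] <- find(j)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(unique(comp), function(c) {
    sub <- df[comp == c, , drop = FALSE]
    data.frame(chrom = sub$chrom[1], start = min(sub$start), end = max(sub$end),
               stringsAsFactors = FALSE)
  }))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Two-gene annotation fixture as a GTF written to a temp file: geneA on +
# with two transcripts (exon union test), geneB on -.
write_mini_gtf <- function(path,
                           a_exons = list(c(100001, 101000), c(103001, 105000),
                                          c(104001, 106000)),
                           b_exons = list(c(200001, 202000))) {
  gtf_line <- function(chrom, start, end, strand, gene, tx) {
    sprintf(paste0("%s\ttest\texon\t%d\t%d\t.\t%s\t.\t",
                   "gene_id \"%s\"; transcript_id \"%s\";"),
            chrom, start, end, strand, gene, tx)
  }
  lines <- c(
    gtf_line("chr1", a_exons[[1]][1], a_exons[[1]][2], "+", "geneA", "geneA.t1"),
    gtf_line("chr1", a_exons[[2]][1], a_exons[[2]][2], "+", "geneA", "geneA.t1"),
    gtf_line("chr1", a_exons[[3]][1], a_exons[[3]][2], "+", "geneA", "geneA.t2"),
    gtf_line("chr1", b_exons[[1]][1], b_exons[[1]][2], "-", "geneB", "geneB.t1")
  )
  writeLines(lines, path)
  path
}

# Minimal gene-model data frame built in code (0-based half-open spans).
make_gene <- function(gene_id, chrom, strand, span_start, span_end) {
  minus <- strand == "-"
  df <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   tss = if (minus) span_end else span_start,
                   tts = if (minus) span_start else span_end,
                   stringsAsFactors = FALSE)
  df$exons <- list(cbind(start = span_start, end = span_end))
  df
}

make_peaks <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

# GRanges from a 0-based half-open interval data frame (test-side copy).
df_to_gr_test <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
}
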