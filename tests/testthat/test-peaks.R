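# Candidate merging and strand-spatial refinement.

make_candidates <- function(chrom, start, end, fdr = NULL, step = 300L,
                            window_size = 300L) {
  structure(
    data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
               count = 1L, fdr = fdr %||% rep(0.001, length(start)),
               stringsAsFactors = FALSE),
    window_size = as.integer(window_size), step = as.integer(step),
    class = c("candidate_windows", "data.frame"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("overlapping windows merge into union spans; disjoint stay apart", {
  cand <- make_candidates("chr1", c(0, 200), c(300, 500), fdr = c(0.004, 0.002),
                          step = 100)
  pk <- merge_candidates(cand)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$start, pk$end), c(0, 500))
  expect_equal(pk$min_window_fdr, 0.002)

  pk2 <- merge_candidates(make_candidates("chr1", c(0, 600), c(300, 900)))
  expect_equal(nrow(pk2), 2)
  # book-ended windows merge only under non-overlapping tiling
  tiled <- make_candidates("chr1", c(0, 300), c(300, 600), step = 300)
  expect_equal(nrow(merge_candidates(tiled)), 1)
  sliding <- make_candidates("chr1", c(0, 300), c(300, 600), step = 100)
  expect_equal(nrow(merge_candidates(sliding)), 2)
})

test_that("merged spans equal a union-find oracle and are pairwise disjoint", {
  set.seed(19)
  for (trial in 1:10) {
    n <- sample(5:25, 1)
    start <- sample(seq(0, 5000, by = 100), n, replace = TRUE)
    cand <- make_candidates(sample(c("chr1", "chr2"), n, TRUE),
                            start, start + 300, step = 100)
    pk <- merge_candidates(cand)
    oracle <- bf_merge(cand[, c("chrom", "start", "end")])
    expect_equal(pk[, c("chrom", "start", "end")], oracle, ignore_attr = TRUE)
    # pairwise disjointness per chromosome
    for (chr in unique(pk$chrom)) {
      sub <- pk[pk$chrom == chr, ]
      if (nrow(sub) > 1) expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
    }
  }
})

test_that("peak read counts use 5'-coordinate containment", {
  cand <- make_candidates("chr1", 0, 300)
  reads <- data.frame(
    chrom = "chr1",
    start = c(100L, 250L, 290L, 500L),
    end = c(200L, 400L, 301L, 600L),
    name = paste0("r", 1:4),
    # 5' coords: 100 (+), 250 (+), 300 (-, end-1 outside? no: 300) , 500 (+)
    strand = c("+", "+", "-", "+"), stringsAsFactors = FALSE)
  pk <- merge_candidates(cand, reads)
  # 5' positions are 100, 250, 300, 500; the span [0, 300) holds the first two
  expect_equal(pk$read_count, 2L)
})

test_that("exact Wilcoxon p-values match full permutation enumeration", {
  # separated strands: forward fully left of reverse, p = 1 / C(6,3)
  expect_equal(wilcoxon_strand_p(c(10, 20, 30), c(40, 50, 60)), 1 / 20)
  # reversed orientation is in the far right tail
  expect_equal(wilcoxon_strand_p(c(40, 50, 60), c(10, 20, 30)), 1)
  # identical multisets carry no directional signal: p >= 0.5
  expect_gte(wilcoxon_strand_p(c(5, 10, 15), c(5, 10, 15)), 0.5)
  # random cases incl. ties, all n + m <= 12: exact DP equals combn oracle
  set.seed(42)
  for (trial in 1:100) {
    n <- sample(1:8, 1); m <- sample(1:8, 1)
    if (n + m > 12) next
    fwd <- sample(1:15, n, replace = TRUE)
    rev <- sample(1:15, m, replace = TRUE)
    expect_equal(wilcoxon_strand_p(fwd, rev), bf_wilcoxon_p(fwd, rev))
  }
})

test_that("large-sample branch matches the corrected normal approximation", {
  set.seed(7)
  fwd <- sample(1:1000, 30); rev <- sample(1:1000, 35) + 100
  p <- wilcoxon_strand_p(fwd, rev)
  ref <- wilcox.test(fwd, rev, alternative = "less", exact = FALSE,
                     correct = TRUE)$p.value
  expect_equal(p, ref, tolerance = 1e-10)
  # with ties the tie-corrected variance is used
  fwd <- sample(1:40, 30, replace = TRUE); rev <- sample(1:40, 35, replace = TRUE)
  expect_equal(wilcoxon_strand_p(fwd, rev),
               suppressWarnings(wilcox.test(fwd, rev, alternative = "less",
                                            exact = FALSE)$p.value),
               tolerance = 1e-10)
})

test_that("refinement annotates all peaks and filters only under the flag", {
  peaks <- data.frame(chrom = "chr1", start = c(0L, 1000L), end = c(500L, 1500L),
                      read_count = NA_integer_, min_window_fdr = 0.001,
                      stringsAsFactors = FALSE)
  # peak 1: oriented (forward left, reverse right); peak 2: anti-oriented
  reads <- data.frame(
    chrom = "chr1",
    start = c(10L, 30L, 50L, 400L, 420L, 440L,
              1400L, 1420L, 1440L, 1010L, 1030L, 1050L),
    end = c(110L, 130L, 150L, 460L, 470L, 480L,
            1460L, 1470L, 1480L, 1110L, 1130L, 1150L),
    name = paste0("r", 1:12),
    strand = rep(c("+", "+", "+", "-", "-", "-"), 2),
    stringsAsFactors = FALSE)
  out <- refine_peaks(peaks, reads, wilcoxon_alpha = 0.05)
  expect_equal(nrow(out), 2)                    # annotate-only by default
  expect_equal(out$wilcoxon_p[1], 1 / 20)
  expect_equal(out$wilcoxon_p[2], 1)            # anti-oriented: far tail
  filtered <- refine_peaks(peaks, reads, wilcoxon_alpha = 0.05,
                           require_orientation = TRUE)
  expect_equal(nrow(filtered), 1)
  expect_equal(filtered$start, 0L)
  # fewer than 2 reads on a strand: p = 1, dropped only under the flag
  sparse <- refine_peaks(peaks[1, ], reads[c(1, 4), ], require_orientation = FALSE)
  expect_equal(sparse$wilcoxon_p, 1)
})

test_that("composed caller recovers a planted region and handles no reads", {
  sizes <- c(chr1 = 2e5)
  none <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                     name = character(0), strand = character(0))
  expect_equal(nrow(call_peaks(none, sizes)), 0)

  land <- structure(
    list(chrom_sizes = sizes,
         regions = list(
           treated = data.frame(chrom = "chr1", start = 100000L, end = 102000L,
                                stringsAsFactors = FALSE),
           control = data.frame(chrom = "chr1", start = 100000L, end = 102000L,
                                stringsAsFactors = FALSE)),
         condition_names = c("treated", "control")),
    class = "methylation_landscape")
  rd <- simulate_reads(land, "treated",
                       simulation_config(enrichment_factor = 10, n_reads = 8000,
                                         rng_seed = 4))
  pk <- call_peaks(rd, sizes)
  expect_gte(nrow(pk), 1)
  # the planted region is hit by a called peak
  hit <- pk$start < 102000 & pk$end > 100000
  expect_true(any(hit))
  expect_true(all(pk$read_count >= 1))
  st <- attr(pk, "stats")
  expect_equal(st$n_reads, 8000)
  expect_equal(st$n_peaks, nrow(pk))
})
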