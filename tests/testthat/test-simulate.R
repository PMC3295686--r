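# Synthetic methylation landscapes and capture-enriched read sets.

test_that("landscape construction: counts, subset structure, edge cases", {
  sizes <- c(chr1 = 1e6)
  land <- simulate_landscape(sizes, 200, 0.6, c(500, 1500), rng_seed = 7)
  expect_equal(nrow(land$regions$control), 200)
  expect_equal(nrow(land$regions$treated), 120)
  # treated intervals are a subset of control intervals
  key <- function(df) paste(df$chrom, df$start, df$end)
  expect_true(all(key(land$regions$treated) %in% key(land$regions$control)))
  # control intervals are non-overlapping and sorted
  ctl <- land$regions$control
  expect_true(all(diff(ctl$start) > 0))
  expect_true(all(ctl$start[-1] >= ctl$end[-nrow(ctl)]))
  expect_true(all(ctl$start >= 0 & ctl$end <= sizes[["chr1"]] & ctl$start < ctl$end))

  # identity and empty cases
  full <- simulate_landscape(sizes, 50, 1.0, c(500, 1500), rng_seed = 1)
  expect_identical(full$regions$treated, full$regions$control)
  none <- simulate_landscape(sizes, 0, 0.5, c(500, 1500), rng_seed = 1)
  expect_equal(nrow(none$regions$control), 0)
  expect_equal(nrow(none$regions$treated), 0)
})

test_that("landscape placement fails loudly when regions cannot fit", {
  expect_error(
    simulate_landscape(c(tiny = 3000), 10, 1, c(1000, 1000), rng_seed = 1),
    "chromosome|place"
  )
})

test_that("read simulation is deterministic and conserves the read target", {
  sizes <- c(chr1 = 5e5, chr2 = 3e5)
  land <- simulate_landscape(sizes, 20, 0.5, c(500, 1500), rng_seed = 11)
  cfg <- simulation_config(enrichment_factor = 4, n_reads = 5000, rng_seed = 42)
  r1 <- simulate_reads(land, "treated", cfg)
  r2 <- simulate_reads(land, "treated", cfg)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 5000)
  expect_true(all(r1$strand %in% c("+", "-")))
  expect_true(all(r1$start >= 0))
  expect_true(all(r1$end <= sizes[r1$chrom]))
  # fragment lengths: uniform on [50, 350], truncated only at chromosome ends
  len <- r1$end - r1$start
  expect_true(all(len <= 350))
  not_truncated <- r1$end < sizes[r1$chrom]
  expect_true(all(len[not_truncated] >= 50))
  # a different seed gives a different read set
  r3 <- simulate_reads(land, "treated",
                       simulation_config(4, 5000, rng_seed = 43))
  expect_false(identical(r1$start, r3$start))
  # zero target is an empty read list, not an error
  r0 <- simulate_reads(land, "treated", simulation_config(4, 0, rng_seed = 1))
  expect_equal(nrow(r0), 0)
  expect_error(simulate_reads(land, "mystery", cfg), "condition")
})

test_that("capture enrichment reproduces the configured density ratio", {
  # one 10 kb methylated region on a 1 Mb chromosome, enrichment 8
  sizes <- c(chr1 = 1e6)
  land <- structure(
    list(chrom_sizes = sizes,
         regions = list(
           treated = data.frame(chrom = "chr1", start = 500000L, end = 510000L,
                                stringsAsFactors = FALSE),
           control = data.frame(chrom = "chr1", start = 500000L, end = 510000L,
                                stringsAsFactors = FALSE)),
         condition_names = c("treated", "control")),
    class = "methylation_landscape")
  rd <- simulate_reads(land, "treated",
                       simulation_config(enrichment_factor = 8, n_reads = 1e5,
                                         rng_seed = 5))
  tr <- count_windows(rd, sizes, 300, 300)
  inside <- tr$start >= 500000 & tr$end <= 510000
  # windows near region edges mix the two densities; also exclude a margin
  margin <- tr$start >= 499000 & tr$start <= 511000 & !inside
  ratio <- mean(tr$count[inside]) / mean(tr$count[!inside & !margin])
  expect_gt(ratio, 8 * 0.9)
  expect_lt(ratio, 8 * 1.1)
})

test_that("no-enrichment null gives statistically uniform coverage", {
  sizes <- c(chr1 = 1e6)
  land <- simulate_landscape(sizes, 5, 1, c(5000, 10000), rng_seed = 2)
  rd <- simulate_reads(land, "treated",
                       simulation_config(enrichment_factor = 1, n_reads = 1e5,
                                         rng_seed = 9))
  tr <- count_windows(rd, sizes, 300, 300)
  reg <- land$regions$treated
  in_reg <- rep(FALSE, nrow(tr))
  for (i in seq_len(nrow(reg))) {
    in_reg <- in_reg | (tr$start >= reg$start[i] & tr$end <= reg$end[i])
  }
  m_in <- mean(tr$count[in_reg]); m_out <- mean(tr$count[!in_reg])
  se <- sqrt(var(tr$count[in_reg]) / sum(in_reg) +
               var(tr$count[!in_reg]) / sum(!in_reg))
  expect_lt(abs(m_in - m_out), 3 * se)
})

test_that("within-region density is monotone in the enrichment factor", {
  sizes <- c(chr1 = 5e5)
  land <- structure(
    list(chrom_sizes = sizes,
         regions = list(
           treated = data.frame(chrom = "chr1", start = 200000L, end = 210000L,
                                stringsAsFactors = FALSE),
           control = data.frame(chrom = "chr1", start = 200000L, end = 210000L,
                                stringsAsFactors = FALSE)),
         condition_names = c("treated", "control")),
    class = "methylation_landscape")
  means <- vapply(c(1, 4, 8), function(e) {
    rd <- simulate_reads(land, "treated",
                         simulation_config(e, n_reads = 2e4, rng_seed = 13))
    tr <- count_windows(rd, sizes, 300, 300)
    mean(tr$count[tr$start >= 200000 & tr$end <= 210000])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("truth BED round-trips the landscape exactly", {
  sizes <- c(chr1 = 1e6, chr2 = 5e5)
  land <- simulate_landscape(sizes, 100, 0.5, c(500, 1500), rng_seed = 3)
  prefix <- file.path(tempdir(), "truth_test")
  paths <- write_truth(land, prefix)
  for (cond in c("treated", "control")) {
    back <- read_bed_regions(paths[[cond]])
    expect_identical(back[, c("chrom", "start", "end")],
                     land$regions[[cond]][, c("chrom", "start", "end")])
    # sorted by chrom then start
    expect_false(is.unsorted(order(back$chrom, back$start)))
  }
  expect_equal(length(readLines(paths[["control"]])), 100)
  # empty landscape writes valid zero-length files
  none <- simulate_landscape(sizes, 0, 1, c(500, 1500), rng_seed = 1)
  p0 <- write_truth(none, file.path(tempdir(), "truth_empty"))
  expect_equal(nrow(read_bed_regions(p0[["control"]])), 0)
})
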