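#' Simulate a ground-truth methylation landscape
#'
#' Builds a two-condition methylation landscape over a small genome: a set of
#' non-overlapping methylated intervals for the control condition and, for the
#' treated condition, a uniformly sampled subset of those intervals. The
#' subset construction emulates global hypomethylation after a toxic insult:
#' the treated sample retains only a fraction of the control's methylated
#' regions, so control-specific regions (future "hypo" calls) outnumber
#' treated-specific ones.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param n_regions_control Number of methylated intervals in the control
#'   condition.
#' @param fraction_retained_in_treated Fraction (0..1) of control intervals
#'   retained in the treated condition; the retained subset is sampled
#'   uniformly without replacement and has exactly
#'   `round(fraction * n_regions_control)` members.
#' @param region_length_range Length-2 vector, min/max region length in bp.
#' @param rng_seed Integer seed; a fixed seed gives an identical landscape.
#'
#' @return An object of class `methylation_landscape`: a list with
#'   `chrom_sizes`, `regions` (a named list of data frames with columns
#'   `chrom`, `start`, `end`, 0-based half-open, sorted and non-overlapping
#'   within each condition) and `condition_names` (`c("treated", "control")`).
#'
#' @examples
#' land <- simulate_landscape(c(chr1 = 1e6), 20, 0.5, c(500, 2000), rng_seed = 1)
#' nrow(land$regions$control)  # 20
#' nrow(land$regions$treated)  # 10
#' @export
simulate_landscape <- function(chrom_sizes,
                               n_regions_control,
                               fraction_retained_in_treated,
                               region_length_range = c(500, 2000),
                               rng_seed = 1L) {
  chrom_sizes <- check_chrom_sizes(chrom_sizes)
  stopifnot(
    n_regions_control >= 0,
    fraction_retained_in_treated >= 0, fraction_retained_in_treated <= 1,
    length(region_length_range) == 2L,
    region_length_range[1] >= 1,
    region_length_range[1] <= region_length_range[2]
  )
  if (n_regions_control > 0 && region_length_range[1] > max(chrom_sizes)) {
    stop("minimum region length exceeds every chromosome length", call. = FALSE)
  }

  control <- with_local_seed(rng_seed, {
    place_nonoverlapping(chrom_sizes, n_regions_control, region_length_range)
  })
  n_treated <- as.integer(round(fraction_retained_in_treated * n_regions_control))
  treated <- with_local_seed(rng_seed + 1L, {
    if (n_treated == 0L || nrow(control) == 0L) {
      control[integer(0), , drop = FALSE]
    } else {
      keep <- sort(sample.int(nrow(control), n_treated))
      control[keep, , drop = FALSE]
    }
  })
  rownames(control) <- rownames(treated) <- NULL

  structure(
    list(
      chrom_sizes = chrom_sizes,
      regions = list(treated = treated, control = control),
      condition_names = c("treated", "control")
    ),
    class = "methylation_landscape"
  )
}

# Rejection placement of non-overlapping intervals; chromosomes drawn with
# probability proportional to the number of admissible start positions.
place_nonoverlapping <- function(chrom_sizes, n, len_range, max_tries_per_region = 1000L) {
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  occupied <- lapply(chrom_sizes, function(...) empty)
  chroms <- names(chrom_sizes)
  out_chrom <- character(n); out_start <- numeric(n); out_end <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    last_chrom <- chroms[1L]
    for (try in seq_len(max_tries_per_region)) {
      len <- if (len_range[1] == len_range[2]) len_range[1] else
        sample(seq(len_range[1], len_range[2]), 1L)
      fits <- chrom_sizes - len + 1
      ok <- fits >= 1
      if (!any(ok)) break
      chrom <- sample(chroms[ok], 1L, prob = fits[ok])
      last_chrom <- chrom
      start <- sample.int(as.integer(fits[[chrom]]), 1L) - 1L
      end <- start + len
      occ <- occupied[[chrom]]
      if (nrow(occ) == 0L || all(end <= occ$start | start >= occ$end)) {
        occupied[[chrom]] <- rbind(occ, data.frame(chrom = chrom, start = start,
                                                   end = end, stringsAsFactors = FALSE))
        out_chrom[i] <- chrom; out_start[i] <- start; out_end[i] <- end
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(
        "could not place region %d without overlap after %d tries (last chromosome tried: %s)",
        i, max_tries_per_region, last_chrom
      ), call. = FALSE)
    }
  }
  df <- data.frame(chrom = out_chrom, start = as.integer(out_start),
                   end = as.integer(out_end), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Simulation configuration for capture-enriched reads
#'
#' @param enrichment_factor Capture probability of a fragment overlapping a
#'   methylated interval relative to a background fragment; must be >= 1.
#'   1 means no enrichment (null capture).
#' @param n_reads Target number of emitted reads; met exactly.
#' @param fragment_length_min,fragment_length_max Fragment length bounds in bp
#'   (defaults 50 and 350); lengths are uniform on this range, truncated at
#'   the chromosome end.
#' @param rng_seed Integer seed for the simulation RNG stream.
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(enrichment_factor = 1,
                              n_reads = 1e5,
                              fragment_length_min = 50L,
                              fragment_length_max = 350L,
                              rng_seed = 1L) {
  stopifnot(
    enrichment_factor >= 1,
    n_reads >= 0,
    fragment_length_min >= 1,
    fragment_length_min <= fragment_length_max
  )
  structure(
    list(
      enrichment_factor = enrichment_factor,
      n_reads = as.integer(n_reads),
      fragment_length_min = as.integer(fragment_length_min),
      fragment_length_max = as.integer(fragment_length_max),
      rng_seed = as.integer(rng_seed)
    ),
    class = "simulation_config"
  )
}

#' Simulate MBP-capture reads for one condition
#'
#' Fragments are dropped uniformly on the genome (start uniform over
#' positions, chromosome weighted by length, length uniform on the configured
#' range and truncated at the chromosome end, strand uniform). Capture is
#' modelled as per-fragment acceptance: a fragment overlapping a methylated
#' interval of the condition by at least 1 bp is always retained, a
#' background fragment is retained with probability `1 / enrichment_factor`,
#' so the expected per-window read density inside methylated regions exceeds
#' the background density by exactly the enrichment factor. Fragments are
#' drawn until exactly `n_reads` are retained.
#'
#' @param landscape A `methylation_landscape` from [simulate_landscape()].
#' @param condition `"treated"` or `"control"`.
#' @param config A `simulation_config`.
#'
#' @return A data frame of read alignments with columns `chrom`, `start`,
#'   `end` (0-based half-open), `name`, `strand` (`+`/`-`), one row per read.
#' @export
simulate_reads <- function(landscape, condition, config) {
  stopifnot(inherits(landscape, "methylation_landscape"),
            inherits(config, "simulation_config"))
  if (!condition %in% landscape$condition_names) {
    stop(sprintf("unknown condition '%s' (expected one of: %s)", condition,
                 paste(landscape$condition_names, collapse = ", ")), call. = FALSE)
  }
  chrom_sizes <- check_chrom_sizes(landscape$chrom_sizes)
  n_target <- config$n_reads
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      name = character(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (n_target == 0L) return(empty)

  regions <- landscape$regions[[condition]]
  regions_gr <- df_to_gr(regions)
  chroms <- names(chrom_sizes)
  p_accept_bg <- 1 / config$enrichment_factor

  with_local_seed(config$rng_seed, {
    kept <- list()
    n_kept <- 0L
    while (n_kept < n_target) {
      batch <- max(2L * (n_target - n_kept), 1000L)
      # sub-draws in fixed order: position, length, strand, acceptance
      chrom <- sample(chroms, batch, replace = TRUE, prob = chrom_sizes)
      start <- floor(stats::runif(batch) * chrom_sizes[chrom])
      len <- sample(seq(config$fragment_length_min, config$fragment_length_max),
                    batch, replace = TRUE)
      end <- pmin(start + len, chrom_sizes[chrom])
      strand <- ifelse(stats::runif(batch) < 0.5, "+", "-")
      u <- stats::runif(batch)

      frag <- data.frame(chrom = chrom, start = as.integer(start),
                         end = as.integer(end), strand = strand,
                         stringsAsFactors = FALSE)
      in_region <- if (length(regions_gr) == 0L) rep(FALSE, batch) else
        IRanges::overlapsAny(df_to_gr(frag), regions_gr)
      accept <- in_region | u < p_accept_bg
      frag <- frag[accept, , drop = FALSE]
      if (nrow(frag) > 0L) {
        n_take <- min(nrow(frag), n_target - n_kept)
        kept[[length(kept) + 1L]] <- frag[seq_len(n_take), , drop = FALSE]
        n_kept <- n_kept + n_take
      }
    }
    reads <- do.call(rbind, kept)
    rownames(reads) <- NULL
    reads$name <- sprintf("read_%07d", seq_len(nrow(reads)))
    reads[, c("chrom", "start", "end", "name", "strand")]
  })
}

#' Write ground-truth methylated intervals as BED6
#'
#' One BED6 file per condition (`<prefix>.<condition>.bed`), unstranded
#' (strand "."), score 0, sorted by chromosome then start. Re-reading with
#' [read_bed_regions()] reproduces the interval sets exactly.
#'
#' @param landscape A `methylation_landscape`.
#' @param prefix Output path prefix (directories must exist).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_truth <- function(landscape, prefix) {
  stopifnot(inherits(landscape, "methylation_landscape"))
  paths <- character(0)
  for (cond in landscape$condition_names) {
    df <- landscape$regions[[cond]]
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    path <- paste0(prefix, ".", cond, ".bed")
    bed <- if (nrow(df) == 0L) {
      character(0)
    } else {
      sprintf("%s\t%d\t%d\t%s\t0\t.", df$chrom, df$start, df$end,
              sprintf("%s_region_%04d", cond, seq_len(nrow(df))))
    }
    ok <- tryCatch({
      writeLines(bed, path); TRUE
    }, error = function(e) FALSE)
    if (!ok) stop(sprintf("failed to write truth BED to '%s'", path), call. = FALSE)
    paths[cond] <- path
  }
  invisible(paths)
}
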