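# End-to-end orchestration: simulate (optional) -> call peaks per sample ->
# annotate -> differential calls -> gene-set enrichment, with a config file,
# per-stage logging and a machine-readable run report.

default_config <- function() {
  list(
    seed = 1L,
    # simulation (used when no read files are supplied)
    chrom_sizes = list(chr1 = 1200000L, chr2 = 800000L),
    n_regions = 100L,
    retained_fraction = 0.6,
    region_length_min = 500L,
    region_length_max = 2000L,
    enrichment = 8,
    n_reads = 100000L,
    fragment_length_min = 50L,
    fragment_length_max = 350L,
    # peak calling
    window = 300L,
    step = 100L,
    max_fdr = 0.01,
    low_coverage_quantile = 0.9,
    fdr_mode = "tail",
    require_orientation = FALSE,
    wilcoxon_alpha = 0.05,
    # annotation / differential
    flank = 20000L,
    min_overlap = 1L,
    # optional inputs (paths); NULL means simulate / skip
    treated_reads = NULL,
    control_reads = NULL,
    genes = NULL,
    genes_format = "gtf",
    gmt = NULL,
    enrich_classes = c("promoter", "gene_body", "three_prime_flank"),
    enrich_labels = c("hypo", "hyper")
  )
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML configuration, rejects unknown keys, type- and range-checks
#' every parameter, and fills defaults for missing ones (an empty file
#' yields the full default configuration). All violations are reported
#' together, each naming the offending key.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @param overrides Named list of values overriding the file (CLI flags).
#' @return A validated `run_config` list.
#' @export
validate_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: '%s'", path),
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
    cfg[names(user)] <- user
  }
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg[names(overrides)] <- overrides

  errors <- character(0)
  need <- function(ok, key, constraint) {
    if (!isTRUE(ok)) errors <<- c(errors, sprintf("%s: %s", key, constraint))
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  need(num1(cfg$window) && cfg$window >= 1, "window", "must be a single number >= 1")
  need(num1(cfg$step) && cfg$step >= 1 &&
         (!num1(cfg$window) || cfg$step <= cfg$window),
       "step", "must satisfy 1 <= step <= window")
  need(num1(cfg$max_fdr) && cfg$max_fdr > 0 && cfg$max_fdr <= 1,
       "max_fdr", "must be in (0, 1]")
  need(num1(cfg$low_coverage_quantile) && cfg$low_coverage_quantile > 0 &&
         cfg$low_coverage_quantile <= 1,
       "low_coverage_quantile", "must be in (0, 1]")
  need(num1(cfg$flank) && cfg$flank > 0, "flank", "must be > 0")
  need(num1(cfg$min_overlap) && cfg$min_overlap >= 1, "min_overlap", "must be >= 1")
  need(num1(cfg$retained_fraction) && cfg$retained_fraction >= 0 &&
         cfg$retained_fraction <= 1, "retained_fraction", "must be in [0, 1]")
  need(num1(cfg$enrichment) && cfg$enrichment >= 1, "enrichment", "must be >= 1")
  need(num1(cfg$n_reads) && cfg$n_reads >= 0, "n_reads", "must be >= 0")
  need(num1(cfg$n_regions) && cfg$n_regions >= 0, "n_regions", "must be >= 0")
  need(num1(cfg$fragment_length_min) && cfg$fragment_length_min >= 1,
       "fragment_length_min", "must be >= 1")
  need(num1(cfg$fragment_length_max) &&
         cfg$fragment_length_max >= cfg$fragment_length_min,
       "fragment_length_max", "must be >= fragment_length_min")
  need(num1(cfg$wilcoxon_alpha) && cfg$wilcoxon_alpha > 0 && cfg$wilcoxon_alpha <= 1,
       "wilcoxon_alpha", "must be in (0, 1]")
  need(num1(cfg$seed), "seed", "must be a single integer")
  need(is.character(cfg$fdr_mode) && cfg$fdr_mode %in% c("tail", "density"),
       "fdr_mode", "must be 'tail' or 'density'")
  need(is.logical(cfg$require_orientation) && length(cfg$require_orientation) == 1L,
       "require_orientation", "must be TRUE or FALSE")
  need(is.character(cfg$genes_format) && cfg$genes_format %in% c("gtf", "bed12"),
       "genes_format", "must be 'gtf' or 'bed12'")
  if (length(errors)) {
    stop(paste(c("invalid configuration:", paste0("  - ", errors)), collapse = "\n"),
         call. = FALSE)
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Run the full MBD-seq analysis pipeline
#'
#' Executes, in order: read simulation (unless read files are configured),
#' peak calling per sample, feature annotation, differential
#' (hypo/hyper/shared) classification with normalized difference, and
#' optional gene-set enrichment. All stage outputs are written under
#' `out_dir`; identical config and seed give byte-identical outputs. A
#' failing stage aborts with the stage named and leaves a `FAILED` marker
#' file next to any partial outputs.
#'
#' @param config A `run_config` from [validate_config()] (or `NULL` for
#'   defaults).
#' @param out_dir Output directory (created if needed).
#' @param verbose Log stage progress via `message()`.
#' @return A run report (list): per-stage counts, class fractions, top
#'   enriched sets, package version, config echo, wall time per stage.
#'   Written as `report.json` in `out_dir`.
#' @export
run_pipeline <- function(config = NULL, out_dir, verbose = FALSE) {
  if (is.null(config)) config <- validate_config(NULL)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package_version = as.character(utils::packageVersion("mbdscan")),
                 config = unclass(config), stages = list())
  current_stage <- "setup"
  log <- function(fmt, ...) if (verbose) message(sprintf(paste0("[", current_stage, "] ", fmt), ...))
  timed <- function(stage, expr) {
    current_stage <<- stage
    t0 <- proc.time()[["elapsed"]]
    value <- tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    report$stages[[stage]]$seconds <<- round(proc.time()[["elapsed"]] - t0, 3)
    value
  }

  chrom_sizes <- unlist(config$chrom_sizes)

  # --- reads: load or simulate ---------------------------------------------
  reads <- timed("reads", {
    if (!is.null(config$treated_reads) && !is.null(config$control_reads)) {
      log("loading mapped reads from BED")
      list(treated = read_bed_reads(config$treated_reads),
           control = read_bed_reads(config$control_reads),
           landscape = NULL)
    } else {
      log("simulating landscape and capture reads (seed %d)", config$seed)
      land <- simulate_landscape(
        chrom_sizes, config$n_regions, config$retained_fraction,
        c(config$region_length_min, config$region_length_max),
        rng_seed = config$seed)
      mk <- function(cond, seed_off) simulate_reads(
        land, cond,
        simulation_config(enrichment_factor = config$enrichment,
                          n_reads = config$n_reads,
                          fragment_length_min = config$fragment_length_min,
                          fragment_length_max = config$fragment_length_max,
                          rng_seed = config$seed + seed_off))
      rt <- mk("treated", 101L); rc <- mk("control", 202L)
      write_truth(land, file.path(out_dir, "truth"))
      write_bed_reads(rt, file.path(out_dir, "treated.reads.bed"))
      write_bed_reads(rc, file.path(out_dir, "control.reads.bed"))
      list(treated = rt, control = rc, landscape = land)
    }
  })
  report$stages$reads$n_treated <- nrow(reads$treated)
  report$stages$reads$n_control <- nrow(reads$control)

  # --- peak calling per sample ---------------------------------------------
  peaks <- list()
  for (cond in c("treated", "control")) {
    peaks[[cond]] <- timed(paste0("callpeaks_", cond), {
      log("calling peaks")
      call_peaks(reads[[cond]], chrom_sizes,
                 window_size = config$window, step = config$step,
                 max_fdr = config$max_fdr,
                 low_coverage_quantile = config$low_coverage_quantile,
                 fdr_mode = config$fdr_mode,
                 require_orientation = config$require_orientation,
                 wilcoxon_alpha = config$wilcoxon_alpha, verbose = verbose)
    })
    st <- attr(peaks[[cond]], "stats")
    report$stages[[paste0("callpeaks_", cond)]] <-
      c(report$stages[[paste0("callpeaks_", cond)]], st)
    null <- attr(peaks[[cond]], "null_model")
    jsonlite::write_json(unclass(null), file.path(out_dir, paste0(cond, ".null.json")),
                         auto_unbox = TRUE, digits = NA)
  }

  # --- annotation -----------------------------------------------------------
  ann <- timed("annotate", {
    genes <- if (!is.null(config$genes)) {
      read_gene_models(config$genes, config$genes_format)
    } else {
      gene_model_df(character(0), character(0), character(0),
                    numeric(0), numeric(0), list())
    }
    idx <- build_feature_index(genes, config$flank, chrom_sizes)
    list(treated = annotate_peaks(peaks$treated, idx),
         control = annotate_peaks(peaks$control, idx),
         genes = genes)
  })
  report$stages$annotate$class_fractions <- list(
    treated = as.list(feature_proportions(ann$treated)$fractions),
    control = as.list(feature_proportions(ann$control)$fractions))

  # --- differential calls ---------------------------------------------------
  calls <- timed("diff", {
    log("classifying hypo/hyper/shared")
    cl <- classify_differential(ann$treated, ann$control, config$min_overlap)
    nd <- normalized_difference(cl, reads$treated, reads$control)
    cl$normalized_difference <- nd$normalized_difference
    cl
  })
  summ <- global_methylation_summary(calls)
  report$stages$diff <- c(report$stages$diff,
                          summ[c("n_hyper", "n_hypo", "n_shared",
                                 "global_hypomethylation")])

  timed("write_tables", {
    for (cond in c("treated", "control")) {
      tab <- calls[calls$sample == cond, , drop = FALSE]
      tab$fdr <- tab$min_window_fdr
      tab$differential_label <- tab$label
      write_peak_table(tab, file.path(out_dir, paste0(cond, ".peaks")))
    }
    utils::write.table(calls, file.path(out_dir, "diff.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })

  # --- gene-set enrichment (optional) --------------------------------------
  if (!is.null(config$gmt) && nrow(ann$genes) > 0L) {
    enr <- timed("enrich", {
      sets <- read_gmt(config$gmt)
      fg <- focus_genes(calls, classes = config$enrich_classes,
                        labels = config$enrich_labels)
      enrich(fg, sets, universe = ann$genes$gene_id)
    })
    utils::write.table(enr, file.path(out_dir, "enrich.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$stages$enrich$n_sets <- nrow(enr)
    report$stages$enrich$top_sets <- utils::head(
      enr[, c("set_id", "p_value", "adjusted_p")], 5)
  }

  report$peaks <- list(n_treated = nrow(peaks$treated),
                       n_control = nrow(peaks$control))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
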