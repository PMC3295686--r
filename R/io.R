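# Format boundaries. Internal convention everywhere: 0-based half-open
# intervals (BED-native); GTF's 1-based closed coordinates are converted on
# read and write only.

#' Read mapped reads from a BED6 file
#'
#' Coordinates are kept 0-based half-open as in the file; record order is
#' preserved. Strand must be `+` or `-`: reads without strand cannot be used
#' by the strand-spatial peak refinement, so `.` is rejected.
#'
#' @param path Path to a BED file with at least 6 columns.
#' @return Data frame with columns `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_bed_reads <- function(path) {
  parse_bed6(path, strand_required = TRUE)
}

#' Read unstranded regions (truth intervals or peaks) from BED
#'
#' Like [read_bed_reads()] but permits strand `.`; used for methylated-region
#' truth files and peak BEDs, which are unstranded.
#'
#' @inheritParams read_bed_reads
#' @return Data frame with columns `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_bed_regions <- function(path) {
  parse_bed6(path, strand_required = FALSE)
}

parse_bed6 <- function(path, strand_required) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      name = character(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields < 6L)
  if (length(bad)) {
    stop(sprintf("malformed BED line %d in '%s': expected >= 6 tab-separated columns, got %d",
                 bad[1], path, n_fields[bad[1]]), call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("malformed BED line %d in '%s': non-numeric coordinates", bad[1], path),
         call. = FALSE)
  }
  bad <- which(!(start < end) | start < 0)
  if (length(bad)) {
    stop(sprintf("invalid interval on line %d in '%s': need 0 <= start < end (got %s, %s)",
                 bad[1], path, m[bad[1], 2], m[bad[1], 3]), call. = FALSE)
  }
  strand <- m[, 6]
  allowed <- if (strand_required) c("+", "-") else c("+", "-", ".")
  bad <- which(!strand %in% allowed)
  if (length(bad)) {
    stop(sprintf("invalid strand '%s' on line %d in '%s' (allowed: %s)",
                 strand[bad[1]], bad[1], path, paste(allowed, collapse = " ")),
         call. = FALSE)
  }
  data.frame(chrom = m[, 1], start = as.integer(start), end = as.integer(end),
             name = m[, 4], strand = strand, stringsAsFactors = FALSE)
}

#' Write reads to BED6
#'
#' @param reads Read data frame (`chrom`, `start`, `end`, `name`, `strand`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed_reads <- function(reads, path) {
  lines <- if (nrow(reads) == 0L) character(0) else
    sprintf("%s\t%d\t%d\t%s\t0\t%s", reads$chrom, reads$start, reads$end,
            reads$name, reads$strand)
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE)
  if (!ok) stop(sprintf("failed to write BED to '%s'", path), call. = FALSE)
  invisible(path)
}

#' Read gene models from GTF or BED12
#'
#' Produces one record per gene. For GTF, exon features are grouped by
#' `gene_id` and the union of exons defines the gene; the transcription start
#' site (TSS) and termination site (TTS) are the strand-appropriate extreme
#' coordinates of the union span. GTF's 1-based closed coordinates are
#' converted to 0-based half-open. For BED12, each line is one gene
#' (`name` = gene id, block fields define exons).
#'
#' TSS/TTS convention in genome coordinates (0-based half-open spans): on the
#' `+` strand `tss` = span start and `tts` = span end; on the `-` strand
#' `tss` = span end and `tts` = span start, so `tss` always marks the
#' transcription start and the gene body is `[min(tss, tts), max(tss, tts))`.
#'
#' @param path Path to the annotation file.
#' @param format `"gtf"` or `"bed12"`.
#' @return Data frame with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `tts`, and a list-column `exons` of two-column matrices (start, end).
#' @export
read_gene_models <- function(path, format = c("gtf", "bed12")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  switch(format, gtf = read_gene_models_gtf(path), bed12 = read_gene_models_bed12(path))
}

read_gene_models_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  empty <- gene_model_df(character(0), character(0), character(0),
                         numeric(0), numeric(0), list())
  if (length(gr) == 0L) return(empty)
  gid <- as.character(S4Vectors::mcols(gr)$gene_id)
  if (any(is.na(gid) | !nzchar(gid))) {
    stop("GTF exon record without a gene_id attribute", call. = FALSE)
  }
  # rtracklayer keeps 1-based closed; convert to 0-based half-open
  df <- data.frame(gene_id = gid,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  if (any(!df$strand %in% c("+", "-"))) {
    stop("gene model exon without a +/- strand", call. = FALSE)
  }
  build_gene_models(df)
}

read_gene_models_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(gene_model_df(character(0), character(0), character(0),
                         numeric(0), numeric(0), list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 12L)
  if (length(bad)) {
    stop(sprintf("malformed BED12 line %d: expected 12 columns", bad[1]), call. = FALSE)
  }
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    chrom_start <- as.integer(f[2])
    n_blocks <- as.integer(f[10])
    sizes <- as.integer(strsplit(f[11], ",", fixed = TRUE)[[1]])
    offsets <- as.integer(strsplit(f[12], ",", fixed = TRUE)[[1]])
    if (length(sizes) != n_blocks || length(offsets) != n_blocks) {
      stop(sprintf("malformed BED12 line %d: block count mismatch", i), call. = FALSE)
    }
    data.frame(gene_id = f[4], chrom = f[1], strand = f[6],
               start = chrom_start + offsets,
               end = chrom_start + offsets + sizes,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (any(!df$strand %in% c("+", "-"))) {
    stop("BED12 gene without a +/- strand", call. = FALSE)
  }
  build_gene_models(df)
}

# Collapse per-exon records into one gene model per gene_id: exon union,
# span extremes, strand-aware TSS/TTS.
build_gene_models <- function(exon_df) {
  ids <- unique(exon_df$gene_id)
  models <- lapply(ids, function(id) {
    sub <- exon_df[exon_df$gene_id == id, , drop = FALSE]
    if (length(unique(sub$chrom)) != 1L || length(unique(sub$strand)) != 1L) {
      stop(sprintf("gene '%s' has exons on multiple chromosomes or strands", id),
           call. = FALSE)
    }
    red <- IRanges::reduce(IRanges::IRanges(start = sub$start + 1L, end = sub$end))
    exons <- cbind(start = IRanges::start(red) - 1L, end = IRanges::end(red))
    span <- c(min(exons[, "start"]), max(exons[, "end"]))
    minus <- sub$strand[1] == "-"
    list(gene_id = id, chrom = sub$chrom[1], strand = sub$strand[1],
         tss = if (minus) span[2] else span[1],
         tts = if (minus) span[1] else span[2],
         exons = exons)
  })
  gene_model_df(
    vapply(models, `[[`, character(1), "gene_id"),
    vapply(models, `[[`, character(1), "chrom"),
    vapply(models, `[[`, character(1), "strand"),
    vapply(models, `[[`, numeric(1), "tss"),
    vapply(models, `[[`, numeric(1), "tts"),
    lapply(models, `[[`, "exons")
  )
}

gene_model_df <- function(gene_id, chrom, strand, tss, tts, exons) {
  df <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   tss = as.integer(tss), tts = as.integer(tts),
                   stringsAsFactors = FALSE)
  df$exons <- exons
  df
}

#' Read gene sets from a GMT file
#'
#' GMT dialect: tab-separated; column 1 is the set name, column 2 a free-text
#' description, remaining columns are member gene ids (duplicates dropped).
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors of gene ids; the `description`
#'   attribute on each element carries column 2.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) {
      stop(sprintf("malformed GMT line %d: expected at least set name and description", i),
           call. = FALSE)
    }
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    attr(members, "description") <- f[2]
    sets[[f[1]]] <- members
  }
  sets
}

peak_table_columns <- c("chrom", "start", "end", "read_count", "fdr",
                        "normalized_difference", "wilcoxon_p", "feature_class",
                        "nearest_gene", "differential_label")

#' Write an annotated peak table as TSV plus companion BED6
#'
#' The TSV has the fixed column order `chrom`, `start`, `end`, `read_count`,
#' `fdr`, `normalized_difference`, `wilcoxon_p`, `feature_class`,
#' `nearest_gene`, `differential_label`; floats are serialized with 6
#' significant digits. The BED6 score is `round(-10 * log10(fdr))` capped at
#' 1000 (0 when fdr = 1), mirroring the Phred-style peak scores used in
#' genome browsers.
#'
#' @param peaks Data frame carrying at least the columns above; missing
#'   statistic columns raise an error.
#' @param prefix Output prefix; writes `<prefix>.tsv` and `<prefix>.bed`.
#' @return Invisibly, a named vector with the two paths.
#' @export
write_peak_table <- function(peaks, prefix) {
  missing_cols <- setdiff(peak_table_columns, names(peaks))
  if (length(missing_cols)) {
    stop(sprintf("peak table is missing required columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  tsv_path <- paste0(prefix, ".tsv")
  bed_path <- paste0(prefix, ".bed")
  out <- peaks[, peak_table_columns, drop = FALSE]
  fmt_num <- function(x) {
    ifelse(is.na(x), "NA", vapply(x, function(v) format(signif(v, 6), scientific = FALSE,
                                                        trim = TRUE), character(1)))
  }
  lines <- paste(peak_table_columns, collapse = "\t")
  if (nrow(out) > 0L) {
    body <- paste(out$chrom, out$start, out$end, out$read_count,
                  fmt_num(out$fdr), fmt_num(out$normalized_difference),
                  fmt_num(out$wilcoxon_p), out$feature_class,
                  ifelse(is.na(out$nearest_gene), ".", out$nearest_gene),
                  out$differential_label, sep = "\t")
    lines <- c(lines, body)
  }
  score <- if (nrow(out) > 0L) {
    s <- round(-10 * log10(pmax(out$fdr, 1e-100)))
    pmin(pmax(s, 0), 1000)
  } else integer(0)
  bed <- if (nrow(out) == 0L) character(0) else
    sprintf("%s\t%d\t%d\t%s\t%d\t.", out$chrom, out$start, out$end,
            sprintf("peak_%04d", seq_len(nrow(out))), as.integer(score))
  ok <- tryCatch({
    writeLines(lines, tsv_path)
    writeLines(bed, bed_path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop(sprintf("failed to write peak table to '%s(.tsv/.bed)'", prefix),
                call. = FALSE)
  invisible(c(tsv = tsv_path, bed = bed_path))
}

#' Read a peak table written by [write_peak_table()]
#'
#' @param path Path to the TSV.
#' @return Data frame with the standard peak-table columns.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character",
                                         nearest_gene = "character",
                                         feature_class = "character",
                                         differential_label = "character"))
  if (!identical(names(df), peak_table_columns)) {
    stop(sprintf("'%s' does not have the expected peak-table columns", path),
         call. = FALSE)
  }
  df$nearest_gene[df$nearest_gene == "."] <- NA_character_
  df
}
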