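# Gene-set enrichment of peak-associated genes: right-tailed Fisher's exact
# test (hypergeometric upper tail) against user-supplied sets, with
# Benjamini-Hochberg adjustment across sets.

#' Select focus genes from annotated differential calls
#'
#' @param annotated_calls Data frame with `feature_class`, `label` and
#'   `nearest_gene` columns (e.g. annotated output of
#'   [classify_differential()]).
#' @param classes Feature classes to keep (subset of `gene_body`,
#'   `promoter`, `three_prime_flank`, `intergenic`); intergenic calls are
#'   only included when requested explicitly.
#' @param labels Differential labels to keep (subset of `hyper`, `hypo`,
#'   `shared`).
#' @return Character vector of unique gene ids (sorted).
#' @export
focus_genes <- function(annotated_calls,
                        classes = c("promoter", "gene_body", "three_prime_flank"),
                        labels = c("hyper", "hypo")) {
  stopifnot(all(classes %in% feature_classes),
            all(labels %in% c("hyper", "hypo", "shared")))
  keep <- annotated_calls$feature_class %in% classes &
    annotated_calls$label %in% labels &
    !is.na(annotated_calls$nearest_gene)
  sort(unique(annotated_calls$nearest_gene[keep]))
}

#' Right-tailed Fisher's exact test p-value
#'
#' Probability that at least `n_focus_in_set` of the `n_focus` focus genes
#' fall in a set of size `n_set` when drawn without replacement from a
#' universe of `n_universe` genes: the upper tail of
#' Hypergeom(N = n_universe, K = n_set, n = n_focus), accumulated from exact
#' hypergeometric point masses.
#'
#' @param n_focus_in_set Overlap between focus list and set.
#' @param n_focus Focus list size.
#' @param n_set Set size (within the universe).
#' @param n_universe Universe size.
#' @return p-value in (0, 1].
#' @export
fisher_right_tail <- function(n_focus_in_set, n_focus, n_set, n_universe) {
  if (n_universe < n_focus || n_universe < n_set ||
      n_focus_in_set > min(n_focus, n_set) ||
      n_focus_in_set < max(0, n_focus + n_set - n_universe) ||
      any(c(n_focus_in_set, n_focus, n_set, n_universe) < 0)) {
    stop("inconsistent contingency counts for Fisher's exact test", call. = FALSE)
  }
  if (n_focus_in_set == 0) return(1)
  xs <- seq.int(n_focus_in_set, min(n_focus, n_set))
  sum(stats::dhyper(xs, m = n_set, n = n_universe - n_set, k = n_focus))
}

#' Gene-set enrichment of a focus gene list
#'
#' One right-tailed Fisher's exact test per gene set (each set intersected
#' with the universe first), Benjamini-Hochberg adjustment across all tested
#' sets, results sorted by raw p ascending with ties broken by set id.
#'
#' @param focus Character vector of focus gene ids; must be a subset of
#'   `universe`.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector of all gene ids under consideration —
#'   conventionally every gene in the gene model, not just genes named in
#'   the sets.
#' @return Data frame: `set_id`, `description`, `n_focus_in_set`, `n_focus`,
#'   `n_set`, `n_universe`, `p_value`, `adjusted_p`.
#' @export
enrich <- function(focus, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe", call. = FALSE)
  focus <- unique(focus)
  outside <- setdiff(focus, universe)
  if (length(outside)) {
    stop(sprintf("focus genes not in the universe: %s%s",
                 paste(utils::head(outside, 3), collapse = ", "),
                 if (length(outside) > 3) ", ..." else ""), call. = FALSE)
  }
  if (length(gene_sets) == 0L) {
    return(data.frame(set_id = character(0), description = character(0),
                      n_focus_in_set = integer(0), n_focus = integer(0),
                      n_set = integer(0), n_universe = integer(0),
                      p_value = numeric(0), adjusted_p = numeric(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(names(gene_sets), function(id) {
    members <- intersect(unique(gene_sets[[id]]), universe)
    overlap <- length(intersect(focus, members))
    data.frame(set_id = id,
               description = attr(gene_sets[[id]], "description") %||% "",
               n_focus_in_set = overlap, n_focus = length(focus),
               n_set = length(members), n_universe = length(universe),
               p_value = fisher_right_tail(overlap, length(focus),
                                           length(members), length(universe)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$adjusted_p <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
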