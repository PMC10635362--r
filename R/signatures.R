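# Directional signature derivation: per-gene differential expression,
# threshold filtering, and the consensus-overlap rule.

#' Per-gene differential expression between two cell groups
#'
#' Tests every shared gene with the Wilcoxon rank-sum test on normalized
#' expression and reports the log2 fold change of group A over group B with
#' pseudocount 1 on the normalized (counts-per-10k) group means; the
#' rank-sum test is invariant to the usual log1p transform, so ranks are
#' taken on the same scale. P-values are Benjamini-Hochberg adjusted over
#' all tested genes (no prefilter). Genes with identical values in both
#' groups (including all-zero genes) get log2fc 0 and p 1 and are retained.
#'
#' @param counts_a,counts_b Genes x cells matrices sharing a gene universe.
#'   Each group needs at least 2 cells (3 or more recommended for any power).
#' @param normalize If `TRUE` (default) apply counts-per-10k scaling first;
#'   set `FALSE` when the inputs are already normalized expression values.
#' @return Tibble: gene, log2fc, pct_in (fraction of group-A cells with
#'   nonzero expression), p_raw, fdr.
#' @export
differential_expression <- function(counts_a, counts_b, normalize = TRUE) {
  if (ncol(counts_a) < 2L || ncol(counts_b) < 2L) {
    rlang::abort("Each group needs at least 2 cells.")
  }
  genes <- intersect(rownames(counts_a), rownames(counts_b))
  if (!length(genes)) rlang::abort("Groups share no genes.")
  a <- counts_a[genes, , drop = FALSE]
  b <- counts_b[genes, , drop = FALSE]
  if (normalize) {
    a <- normalize_cp10k(a)
    b <- normalize_cp10k(b)
  }
  a <- as.matrix(a); b <- as.matrix(b)
  m <- ncol(a); n <- ncol(b); N <- m + n

  p <- vapply(seq_along(genes), function(g) {
    x <- a[g, ]; y <- b[g, ]
    if (length(unique(c(x, y))) == 1L) return(1)
    rank_sum_compare(x, y)$p_value
  }, numeric(1))
  mean_a <- rowMeans(a)
  mean_b <- rowMeans(b)
  tibble(
    gene = genes,
    log2fc = unname(log2((mean_a + 1) / (mean_b + 1))),
    pct_in = unname(rowMeans(a > 0)),
    p_raw = p,
    fdr = stats::p.adjust(p, method = "BH")
  )
}

#' Filter a DEG table into a directional signature
#'
#' Retains genes with `fdr < fdr_max` and `log2fc > log2fc_min`, both strict.
#'
#' @param deg_table Tibble with gene, log2fc, fdr (from
#'   [differential_expression()]).
#' @param fdr_max,log2fc_min Strict thresholds (defaults: the stringent
#'   signature cutoffs FDR < 0.001, log2FC > 0.5).
#' @return Tibble of retained rows (gene, log2fc, fdr, ...).
#' @export
filter_signature <- function(deg_table, fdr_max = 0.001, log2fc_min = 0.5) {
  if (fdr_max <= 0 || log2fc_min < 0) rlang::abort("Thresholds must be positive.")
  dplyr::filter(deg_table, .data$fdr < fdr_max, .data$log2fc > log2fc_min)
}

#' Consensus signature across two comparisons
#'
#' Restricts each DEG table to its significant up-genes (via
#' [filter_signature()]), overlaps the two gene lists, and keeps genes whose
#' arithmetic mean of the two comparison-specific log2 fold changes strictly
#' exceeds `avg_log2fc_min` (default 0.9, the consensus rule).
#'
#' @param deg_a,deg_b DEG tables from two independent comparisons.
#' @param avg_log2fc_min Strict threshold on the average log2FC.
#' @param fdr_max,log2fc_min Per-table significance filters applied before
#'   the overlap.
#' @return Tibble: gene, log2fc_a, log2fc_b, avg_log2fc, sorted by
#'   decreasing average.
#' @export
consensus_signature <- function(deg_a, deg_b, avg_log2fc_min = 0.9,
                                fdr_max = 0.001, log2fc_min = 0.5) {
  sa <- filter_signature(deg_a, fdr_max, log2fc_min)
  sb <- filter_signature(deg_b, fdr_max, log2fc_min)
  dplyr::inner_join(
    dplyr::select(sa, "gene", log2fc_a = "log2fc"),
    dplyr::select(sb, "gene", log2fc_b = "log2fc"),
    by = "gene"
  ) |>
    dplyr::mutate(avg_log2fc = (.data$log2fc_a + .data$log2fc_b) / 2) |>
    dplyr::filter(.data$avg_log2fc > avg_log2fc_min) |>
    dplyr::arrange(dplyr::desc(.data$avg_log2fc))
}

#' Bundle directional gene lists into a signature set
#'
#' @param name Signature name.
#' @param positive,negative Disjoint character vectors of up-
#'   (e.g. BMP-like) and down- (e.g. T-specified) genes.
#' @return List of class `signature_set`.
#' @export
signature_set <- function(name, positive, negative = character()) {
  positive <- unique(positive); negative <- unique(negative)
  if (length(intersect(positive, negative))) {
    rlang::abort("Positive and negative gene lists must be disjoint.")
  }
  structure(list(name = name, positive = positive, negative = negative),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %s: %d positive, %d negative genes\n",
              x$name, length(x$positive), length(x$negative)))
  invisible(x)
}
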