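# Sample-level signature scoring: Z-difference, recovery-curve AUC, and
# cohort binarization.

#' Z-difference signature score per sample
#'
#' Z-scores each gene across samples (population standard deviation; genes
#' with zero variance contribute z = 0) and returns, per sample, the mean z
#' over positive-signature genes minus the mean z over negative-signature
#' genes. A score above 0 reads as positive-state (e.g. BMP-like) dominant.
#'
#' @param expr Samples x genes numeric matrix (rownames = sample ids).
#' @param signature A [signature_set()].
#' @return Tibble: sample_id, zdiff, n_pos_genes, n_neg_genes.
#' @export
zdiff_score <- function(expr, signature) {
  stopifnot(inherits(signature, "signature_set"))
  if (nrow(expr) < 2L) rlang::abort("Need at least 2 samples to z-score.")
  expr <- as.matrix(expr)
  for (side in c("positive", "negative")) {
    gs <- signature[[side]]
    if (length(gs) && !length(intersect(gs, colnames(expr)))) {
      rlang::abort(sprintf(
        "No %s-signature gene present in the matrix (missing: %s).",
        side, paste(utils::head(gs, 10), collapse = ", ")))
    }
  }
  z <- apply(expr, 2, function(x) {
    s <- sd_pop(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  })
  pos <- intersect(signature$positive, colnames(expr))
  neg <- intersect(signature$negative, colnames(expr))
  mean_side <- function(gs) {
    if (!length(gs)) return(rep(0, nrow(expr)))
    rowMeans(z[, gs, drop = FALSE])
  }
  tibble(
    sample_id = rownames(expr) %||% sprintf("S%03d", seq_len(nrow(expr))),
    zdiff = unname(mean_side(pos) - mean_side(neg)),
    n_pos_genes = length(pos), n_neg_genes = length(neg)
  )
}

#' Recovery-curve AUC of a signature in one expression profile
#'
#' Ranks all genes by decreasing expression (ties broken by a fixed-seed
#' shuffle followed by a stable sort, so the result is deterministic and
#' unbiased in expectation), truncates the ranking at
#' `T = ceiling(max_rank_fraction * N)` (default: top 25% of genes), and
#' accumulates the recovery curve `hits(k)` = number of signature genes among
#' the top `k`. The score is `sum_k hits(k)` over `k = 1..T`, normalized by
#' the maximal achievable area `sum_k min(k, n_signature_present)`.
#'
#' @param expr Named numeric vector of expression for one sample.
#' @param signature_genes Character vector of signature genes.
#' @param max_rank_fraction Fraction of genes eligible for recovery.
#' @param tie_seed Seed for the tie-breaking shuffle (recorded in the
#'   `tie_seed` attribute).
#' @return A single AUC in `[0, 1]`; 0 with a warning when no signature gene
#'   is in the gene universe.
#' @export
auc_score <- function(expr, signature_genes, max_rank_fraction = 0.25,
                      tie_seed = 1L) {
  if (!length(signature_genes)) rlang::abort("Signature must be non-empty.")
  N <- length(expr)
  if (N < 4L) rlang::abort("Gene universe must hold at least 4 genes.")
  genes <- names(expr)
  if (is.null(genes)) rlang::abort("`expr` must be named by gene.")
  n_sig <- length(intersect(signature_genes, genes))
  if (n_sig == 0L) {
    rlang::warn("No signature gene present in the expression vector; AUC = 0.")
    return(structure(0, tie_seed = tie_seed))
  }
  perm <- withr::with_seed(tie_seed, sample.int(N))
  ord <- perm[order(-expr[perm], method = "radix")]
  T_cut <- ceiling(max_rank_fraction * N)
  is_sig <- genes[ord[seq_len(T_cut)]] %in% signature_genes
  raw <- sum(cumsum(is_sig))
  maxraw <- sum(pmin(seq_len(T_cut), n_sig))
  structure(raw / maxraw, tie_seed = tie_seed)
}

#' Recovery-curve AUC scores for a cohort matrix
#'
#' Applies [auc_score()] to each sample (row) of an expression matrix for the
#' positive and (if present) negative gene lists of a signature.
#'
#' @param expr Samples x genes matrix with dimnames.
#' @param signature A [signature_set()].
#' @inheritParams auc_score
#' @return Tibble: sample_id, auc_positive, auc_negative (NA when the
#'   signature has no negative side).
#' @export
score_cohort_auc <- function(expr, signature, max_rank_fraction = 0.25,
                             tie_seed = 1L) {
  stopifnot(inherits(signature, "signature_set"))
  expr <- as.matrix(expr)
  one_side <- function(gs) {
    if (!length(gs)) return(rep(NA_real_, nrow(expr)))
    vapply(seq_len(nrow(expr)), function(i) {
      as.numeric(auc_score(expr[i, ], gs, max_rank_fraction, tie_seed))
    }, numeric(1))
  }
  tibble(
    sample_id = rownames(expr) %||% sprintf("S%03d", seq_len(nrow(expr))),
    auc_positive = one_side(signature$positive),
    auc_negative = one_side(signature$negative)
  )
}

#' Binarize a cohort by signature score
#'
#' `sign` mode calls a sample positive-state (`"BMP-like"`) iff its score is
#' strictly greater than 0, else `"T-specified"`. `median_split` mode labels
#' samples strictly above the cohort median `"top50"` and everything else
#' (including exact-median ties) `"bottom50"`; identical scores across the
#' cohort are an error since no split exists, and an unbalanced split caused
#' by median ties is flagged with a warning.
#'
#' @param scores Data frame with `sample_id` and a score column, or a bare
#'   numeric vector.
#' @param score_col Name of the score column (default `"zdiff"`; the first
#'   numeric column is used as fallback).
#' @param mode `"sign"` or `"median_split"`.
#' @return Input tibble with a `call` column appended (or a character vector
#'   for vector input).
#' @export
binarize_cohort <- function(scores, mode = c("sign", "median_split"),
                            score_col = "zdiff") {
  mode <- match.arg(mode)
  vec_in <- is.numeric(scores) && is.null(dim(scores))
  if (vec_in) {
    x <- scores
  } else {
    if (!score_col %in% names(scores)) {
      score_col <- names(scores)[vapply(scores, is.numeric, logical(1))][1]
      if (is.na(score_col)) rlang::abort("No numeric score column found.")
    }
    x <- scores[[score_col]]
  }
  if (mode == "sign") {
    call <- ifelse(x > 0, "BMP-like", "T-specified")
  } else {
    if (length(x) < 2L) rlang::abort("median_split needs at least 2 samples.")
    if (length(unique(x)) == 1L) {
      rlang::abort("All scores identical: no median split exists.")
    }
    med <- stats::median(x)
    call <- ifelse(x > med, "top50", "bottom50")
    n_top <- sum(call == "top50")
    if (abs(n_top - (length(x) - n_top)) > 1L) {
      rlang::warn(sprintf(
        "Median ties give an unbalanced split (%d top50 vs %d bottom50).",
        n_top, length(x) - n_top))
    }
  }
  if (vec_in) return(call)
  dplyr::mutate(as_tibble(scores), call = call)
}
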