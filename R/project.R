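# Reference mapping: shared principal-component latent space plus
# k-nearest-neighbour plurality label transfer.

# Fix component signs so the largest-magnitude loading of each PC is
# positive; makes the basis deterministic up to the data.
fix_pc_signs <- function(rotation, scores) {
  flip <- vapply(seq_len(ncol(rotation)), function(j) {
    v <- rotation[, j]
    sign(v[which.max(abs(v))]) < 0
  }, logical(1))
  scores[, flip] <- -scores[, flip, drop = FALSE]
  scores
}

#' Fit the shared latent space on reference counts
#'
#' Normalizes (counts-per-10k, log1p), selects the most variable genes,
#' centres, and extracts principal components with a fixed sign convention
#' (largest-magnitude loading positive), so the basis is deterministic for a
#' given input and invariant to cell order.
#'
#' @param counts Reference counts, genes x cells (sparse or dense).
#' @param n_dims Number of latent dimensions.
#' @param n_hvg Number of highly variable genes kept (default: all genes).
#' @return Object of class `latent_model`: gene list, per-gene centres,
#'   rotation (genes x dims), and per-component standard deviations.
#' @export
fit_latent <- function(counts, n_dims = 10L, n_hvg = NULL) {
  if (is.null(dim(counts)) || ncol(counts) == 0L) {
    rlang::abort("Reference counts must be a non-empty matrix.")
  }
  ln <- normalize_log_cp10k(counts)
  n_hvg <- min(n_hvg %||% nrow(ln), nrow(ln))
  if (n_hvg < n_dims) {
    rlang::abort(sprintf("Fewer genes (%d) than requested dimensions (%d).",
                         n_hvg, n_dims))
  }
  x <- as.matrix(Matrix::t(ln))           # cells x genes
  v <- apply(x, 2, stats::var)
  keep <- sort(order(v, decreasing = TRUE)[seq_len(n_hvg)])
  x <- x[, keep, drop = FALSE]
  pc <- stats::prcomp(x, rank. = min(n_dims, ncol(x), nrow(x) - 1L),
                      center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    sign(rot[which.max(abs(rot[, j])), j]) < 0
  }, logical(1))
  rot[, flip] <- -rot[, flip, drop = FALSE]
  structure(list(
    genes = colnames(x), center = pc$center, rotation = rot,
    sdev = pc$sdev[seq_len(ncol(rot))], normalization = "cp10k_log1p"
  ), class = "latent_model")
}

#' Project counts into a fitted latent space
#'
#' Applies the model's normalization, restricts to the model's gene list
#' (genes absent from the query contribute zero expression), centres with the
#' reference means, and rotates.
#'
#' @param model A [fit_latent()] result.
#' @param counts Query counts, genes x cells.
#' @return Cells x dims score matrix.
#' @export
project_cells <- function(model, counts) {
  stopifnot(inherits(model, "latent_model"))
  ln <- normalize_log_cp10k(counts)
  x <- matrix(0, ncol(counts), length(model$genes),
              dimnames = list(colnames(counts), model$genes))
  present <- intersect(model$genes, rownames(counts))
  x[, present] <- as.matrix(Matrix::t(ln[present, , drop = FALSE]))
  sweep(x, 2, model$center) %*% model$rotation
}

#' Transfer stage labels, confidence, and pseudotime onto query blasts
#'
#' For each query cell the k nearest reference cells in latent space vote:
#' the predicted label is the plurality stage (ties broken by smaller mean
#' neighbour distance, then lexicographic label order), confidence is the
#' fraction of neighbours carrying that label, and pseudotime is the mean raw
#' branch pseudotime of neighbours on the predicted label's branch, mapped to
#' the unified `[-1, 1]` axis (myeloid negative, T positive).
#'
#' @param query_counts Query counts, genes x cells.
#' @param reference A `reference_atlas` (or list with `counts` and `cells`
#'   carrying cell_id, stage, branch, raw_pseudotime).
#' @param latent A [fit_latent()] model; fitted on the reference counts if
#'   omitted.
#' @param k Number of neighbours.
#' @param sample_id Sample identifier stamped on the output (recycled).
#' @param min_gene_overlap Minimum fraction of the latent gene list that must
#'   be present in the query.
#' @return Tibble: cell_id, sample_id, predicted_label, confidence,
#'   branch, raw_pseudotime, unified_pseudotime.
#' @export
transfer_labels <- function(query_counts, reference, latent = NULL, k = 25L,
                            sample_id = "query", min_gene_overlap = 0.5) {
  cells <- reference$cells
  stopifnot(all(c("stage", "branch", "raw_pseudotime") %in% names(cells)))
  if (is.null(latent)) latent <- fit_latent(reference$counts)
  n_missing <- sum(!(latent$genes %in% rownames(query_counts)))
  overlap <- 1 - n_missing / length(latent$genes)
  if (overlap < min_gene_overlap) {
    rlang::abort(sprintf(
      "Query shares only %.0f%% of the %d latent genes (%d missing); need >= %.0f%%.",
      100 * overlap, length(latent$genes), n_missing, 100 * min_gene_overlap))
  }
  k <- min(as.integer(k), nrow(cells))
  ref_sc <- project_cells(latent, reference$counts)
  qry_sc <- project_cells(latent, query_counts)

  # squared Euclidean distances query x reference via the crossprod identity
  d2 <- outer(rowSums(qry_sc^2), rowSums(ref_sc^2), "+") -
    2 * qry_sc %*% t(ref_sc)
  d2[d2 < 0] <- 0

  branch_of_stage <- stats::setNames(cells$branch, cells$stage)

  res <- purrr::map_dfr(seq_len(nrow(qry_sc)), function(i) {
    ord <- order(d2[i, ], cells$cell_id)[seq_len(k)]
    labs <- cells$stage[ord]
    cnt <- table(labs)
    top <- names(cnt)[cnt == max(cnt)]
    if (length(top) > 1L) {
      md <- vapply(top, function(l) mean(d2[i, ord[labs == l]]), numeric(1))
      top <- top[md == min(md)]
      top <- sort(top)[1]
    }
    branch <- unname(branch_of_stage[top])
    on_branch <- ord[cells$branch[ord] == branch]
    if (!length(on_branch)) on_branch <- ord
    raw_pt <- mean(cells$raw_pseudotime[on_branch])
    tibble(
      cell_id = colnames(query_counts)[i] %||% sprintf("q%05d", i),
      predicted_label = top,
      confidence = unname(cnt[top]) / k,
      branch = branch,
      raw_pseudotime = raw_pt
    )
  })
  res$sample_id <- rep_len(sample_id, nrow(res))
  res$unified_pseudotime <- unify_pseudotime(res$branch, res$raw_pseudotime)
  dplyr::select(res, "cell_id", "sample_id", "predicted_label", "confidence",
                "branch", "raw_pseudotime", "unified_pseudotime")
}
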