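# Unified pseudotime arrest spectra, group comparisons, and BMP-like
# classification.

#' Map branch pseudotime onto the unified [-1, 1] axis
#'
#' T-branch pseudotime is kept as-is (0 to 1); myeloid pseudotime is negated
#' (0 to -1), so the shared HSPC root sits at 0 and the two branches extend
#' in opposite directions.
#'
#' @param branch Character vector, `"myeloid"` or `"T"`.
#' @param raw Raw branch pseudotime in `[0, 1]`.
#' @return Numeric vector in `[-1, 1]`.
#' @examples
#' unify_pseudotime(c("T", "myeloid"), c(0.7, 0.5))  # 0.7, -0.5
#' @export
unify_pseudotime <- function(branch, raw) {
  if (any(raw < 0 | raw > 1, na.rm = TRUE)) {
    rlang::abort("Raw pseudotime must lie in [0, 1].")
  }
  bad <- setdiff(unique(branch), c("myeloid", "T"))
  if (length(bad)) {
    rlang::abort(sprintf("Unknown branch: %s", paste(bad, collapse = ", ")))
  }
  ifelse(branch == "myeloid", -raw, raw)
}

#' Bin unified pseudotimes into a 20-bin arrest spectrum
#'
#' Bins are the 20 equal-width intervals partitioning `[-1, 1]`, left-closed
#' right-open except the final bin which also includes 1. Proportions are
#' normalized by the number of cells; an empty input yields all-zero
#' proportions with `n_cells = 0`.
#'
#' @param pseudotimes Unified pseudotimes in `[-1, 1]`.
#' @param group_id Label for the group (one spectrum per call).
#' @return Tibble of class `arrest_spectrum`, 20 rows: group_id, bin,
#'   bin_lo, bin_hi, n, proportion, n_cells.
#' @export
bin_spectrum <- function(pseudotimes, group_id = "all") {
  if (any(pseudotimes < -1 | pseudotimes > 1, na.rm = TRUE)) {
    rlang::abort("Unified pseudotimes must lie in [-1, 1].")
  }
  edges <- seq(-1, 1, by = 0.1)
  # left-closed bins; 1e-9 guard absorbs representation error at bin edges
  idx <- pmin(floor((pseudotimes + 1) / 0.1 + 1e-9), 19) + 1
  n <- tabulate(idx, nbins = 20L)
  n_cells <- length(pseudotimes)
  out <- tibble(
    group_id = group_id,
    bin = 1:20,
    bin_lo = edges[1:20],
    bin_hi = edges[2:21],
    n = n,
    proportion = if (n_cells > 0) n / n_cells else rep(0, 20),
    n_cells = n_cells
  )
  class(out) <- c("arrest_spectrum", class(out))
  out
}

# Asymptotic two-sided Kolmogorov distribution tail Q(lambda).
kolmogorov_tail <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov comparison of arrest distributions
#'
#' D is the exact supremum difference of the two empirical CDFs; the p-value
#' uses the asymptotic Kolmogorov distribution with effective sample size
#' `m n / (m + n)`.
#'
#' @param a,b Numeric vectors (e.g. unified pseudotimes of two groups).
#' @return Tibble: statistic (D), p_value, n_a, n_b.
#' @export
ks_compare <- function(a, b) {
  if (!length(a) || !length(b)) rlang::abort("Both groups must be non-empty.")
  pooled <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a)(pooled)
  fb <- stats::ecdf(b)(pooled)
  d <- max(abs(fa - fb))
  n_eff <- length(a) * length(b) / (length(a) + length(b))
  tibble(statistic = d, p_value = kolmogorov_tail(sqrt(n_eff) * d),
         n_a = length(a), n_b = length(b))
}

# U statistic for group a vs b (ties count 1/2).
u_stat <- function(ra, rb) {
  # via rank sum: U = W_a - m(m+1)/2 with midranks handling ties
  m <- length(ra)
  sum(ra) - m * (m + 1) / 2
}

#' Wilcoxon rank-sum comparison with exact small-sample p-values
#'
#' Computes the Mann-Whitney U statistic (ties contribute 1/2). For combined
#' sample sizes up to `exact_max_n` the two-sided p-value is exact, by full
#' enumeration of all group assignments of the pooled values
#' (`p = min(1, 2 min(P(U <= u), P(U >= u)))`), which remains valid under
#' ties. Larger samples use the normal approximation with tie correction
#' (no continuity correction). If every value is tied across both groups the
#' p-value is 1 by convention and the result is flagged.
#'
#' @param a,b Numeric vectors.
#' @param exact_max_n Largest combined size for which enumeration is used.
#' @return Tibble: statistic (U for group `a`), p_value, method, degenerate.
#' @export
rank_sum_compare <- function(a, b, exact_max_n = 12L) {
  if (!length(a) || !length(b)) rlang::abort("Both groups must be non-empty.")
  m <- length(a); n <- length(b); N <- m + n
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- u_stat(r[seq_len(m)], r[m + seq_len(n)])
  if (length(unique(pooled)) == 1L) {
    return(tibble(statistic = u_obs, p_value = 1,
                  method = "degenerate", degenerate = TRUE))
  }
  if (N <= exact_max_n) {
    subsets <- utils::combn(N, m)
    us <- apply(subsets, 2, function(ix) u_stat(r[ix], r[-ix]))
    p <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
    return(tibble(statistic = u_obs, p_value = p,
                  method = "exact_enumeration", degenerate = FALSE))
  }
  mu <- m * n / 2
  ties <- table(pooled)
  sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- (u_obs - mu) / sqrt(sigma2)
  tibble(statistic = u_obs, p_value = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal_tie_corrected", degenerate = FALSE)
}

#' Per-sample arrest-state proportions and BMP-like class
#'
#' Collapses projected blast labels into the standard state partition
#' (BMP-like = HSPC/LMPP/CLP/ETP; Pro-T; Pre-T; post-commitment = DP/AB;
#' myeloid = all myeloid-branch stages) and classifies each sample High or
#' Low by its BMP-like fraction.
#'
#' @param projected Tibble with `sample_id` and `predicted_label` (e.g. from
#'   [transfer_labels()], or `true_state` renamed for ground-truth use).
#' @param label_col Column holding the stage label.
#' @param bmp_states,prot_states,pret_states,postcommit_states Stage sets of
#'   the partition; anything else is counted as myeloid/other.
#' @param threshold BMP-like High/Low boundary (strict `>`).
#' @return Tibble: sample_id, n_cells, one fraction column per compartment,
#'   bmp_fraction, bmp_class.
#' @export
state_proportions <- function(projected, label_col = "predicted_label",
                              bmp_states = c("HSPC", "LMPP", "CLP", "ETP"),
                              prot_states = "ProT", pret_states = "PreT",
                              postcommit_states = c("DP", "AB"),
                              threshold = 0.30) {
  lab <- projected[[label_col]]
  compartment <- dplyr::case_when(
    lab %in% bmp_states ~ "bmp_like",
    lab %in% prot_states ~ "pro_t",
    lab %in% pret_states ~ "pre_t",
    lab %in% postcommit_states ~ "post_commit",
    TRUE ~ "myeloid_other"
  )
  out <- tibble(sample_id = projected$sample_id, compartment = compartment) |>
    dplyr::count(.data$sample_id, .data$compartment) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(n_cells = sum(.data$n), frac = .data$n / .data$n_cells) |>
    dplyr::ungroup() |>
    dplyr::select(-"n") |>
    tidyr::pivot_wider(names_from = "compartment", values_from = "frac",
                       values_fill = 0)
  for (col in c("bmp_like", "pro_t", "pre_t", "post_commit", "myeloid_other")) {
    if (!col %in% names(out)) out[[col]] <- 0
  }
  out$bmp_fraction <- out$bmp_like
  out$bmp_class <- classify_bmp(out$bmp_fraction, threshold)
  out
}

#' Classify samples as BMP-like High or Low
#'
#' High iff the BMP-like blast fraction strictly exceeds the threshold
#' (default 0.30); a fraction exactly at the threshold is Low (the strict
#' boundary convention is recorded in the result's attributes).
#'
#' @param bmp_fraction Numeric vector of BMP-like fractions in `[0, 1]`.
#' @param threshold Boundary (strict `>`).
#' @return Character vector, `"High"` or `"Low"`, with attribute
#'   `boundary_rule = "strict_gt_threshold_else_Low"`.
#' @export
classify_bmp <- function(bmp_fraction, threshold = 0.30) {
  if (any(bmp_fraction < 0 | bmp_fraction > 1, na.rm = TRUE)) {
    rlang::abort("BMP-like fractions must lie in [0, 1].")
  }
  structure(ifelse(bmp_fraction > threshold, "High", "Low"),
            boundary_rule = "strict_gt_threshold_else_Low")
}
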