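# Shared small-scale generator configs and fixtures built in code.

tiny_traj <- function(...) {
  trajectory_config(n_genes = 300L, n_cells_per_stage = 30L,
                    n_signature_genes = 20L, model_seed = 42L, ...)
}

# Mid-size config used by the projection / signature recovery checks.
study_traj <- function(effect_log2fc = 1, ...) {
  trajectory_config(n_genes = 800L, n_cells_per_stage = 100L,
                    n_signature_genes = 30L, effect_log2fc = effect_log2fc,
                    model_seed = 42L, ...)
}

# Single-stage degenerate trajectory (root only).
root_only_traj <- function() {
  trajectory_config(
    stage_names = list(myeloid = "HSPC", T = "HSPC"),
    stage_centers = list(myeloid = c(HSPC = 0), T = c(HSPC = 0)),
    n_genes = 100L, n_cells_per_stage = 20L, n_signature_genes = 5L,
    model_seed = 7L)
}

# Brute-force two-sample KS D: ECDFs evaluated at every pooled point.
brute_ks_d <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(t) {
    abs(mean(a <= t) - mean(b <= t))
  }, numeric(1)))
}

# Brute-force recovery-curve AUC: explicit hits(k) summation after the same
# deterministic tie-break ranking contract (shuffle seed, stable sort).
brute_auc <- function(expr, sig, frac = 0.25, tie_seed = 1L) {
  N <- length(expr)
  perm <- withr::with_seed(tie_seed, sample.int(N))
  ord <- perm[order(-expr[perm], method = "radix")]
  T_cut <- ceiling(frac * N)
  n_sig <- length(intersect(sig, names(expr)))
  raw <- 0
  for (k in seq_len(T_cut)) {
    raw <- raw + sum(names(expr)[ord[seq_len(k)]] %in% sig)
  }
  raw / sum(pmin(seq_len(T_cut), n_sig))
}

# Independent exact two-sided rank-sum p via the rank-sum (W) distribution.
brute_ranksum_p <- function(a, b) {
  m <- length(a)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(m)])
  ws <- apply(utils::combn(length(r), m), 2, function(ix) sum(r[ix]))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}
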