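#' Configure the synthetic two-branch hematopoietic trajectory
#'
#' Defines the reference trajectory the generator simulates: a myeloid branch
#' (HSPC -> GMP -> Mono) and a T branch (HSPC -> LMPP -> CLP -> ETP -> ProT ->
#' PreT -> DP -> AB) sharing the HSPC root at pseudotime 0, plus the
#' negative-binomial expression model with a planted progenitor
#' (BMP-like) versus T-committed signature contrast.
#'
#' Expression means are log-linear in stage: a per-gene baseline, a per-branch
#' smooth slope along pseudotime, an independent per-stage program effect, and
#' (for the planted signature genes) a symmetric +/- `effect_log2fc`/2 shift
#' between the progenitor block (HSPC/LMPP/CLP/ETP) and the T-committed block
#' (ProT/PreT/DP/AB), so the planted block-level contrast equals
#' `effect_log2fc` on the log2 scale.
#'
#' @param stage_names Named list with `myeloid` and `T` character vectors of
#'   ordered stage labels; both must start with the shared root stage.
#' @param stage_centers Named list of per-stage pseudotime centers on `[0, 1]`,
#'   strictly increasing within each branch, root at 0.
#' @param stage_spread Standard deviation of per-cell pseudotime around its
#'   stage center (truncated to `[0, 1]` by clipping).
#' @param n_genes Total number of genes simulated.
#' @param n_signature_genes Planted signature genes per direction (up = higher
#'   in the progenitor block, down = higher in the T-committed block).
#' @param effect_log2fc Planted log2 fold change between the progenitor and
#'   T-committed blocks for signature genes.
#' @param dispersion Negative-binomial dispersion (variance = mu + dispersion *
#'   mu^2).
#' @param library_size_mean Expected total counts per cell.
#' @param library_size_cv Coefficient of variation of per-cell library size
#'   (log-normal).
#' @param n_cells_per_stage Reference cells simulated per stage.
#' @param baseline_log2_sd Spread of per-gene baseline abundance (log2 scale).
#' @param slope_log2_sd Spread of the per-gene, per-branch smooth pseudotime
#'   slope (log2 units per unit pseudotime); signature genes get slope 0 so the
#'   planted contrast is exactly the block effect.
#' @param stage_effect_log2_sd Spread of the independent per-stage, per-gene
#'   program effect (log2); this is what makes adjacent stages separable.
#' @param model_seed Seed for the gene-level expression model. Part of the
#'   configuration so reference and blast simulations drawn from the same
#'   config share one expression model regardless of their sampling seeds.
#'
#' @return A list of class `trajectory_config`.
#' @examples
#' cfg <- trajectory_config(n_genes = 200, n_cells_per_stage = 20)
#' ref <- make_reference(cfg, seed = 1)
#' @export
trajectory_config <- function(stage_names = list(
                                myeloid = c("HSPC", "GMP", "Mono"),
                                T = c("HSPC", "LMPP", "CLP", "ETP",
                                      "ProT", "PreT", "DP", "AB")),
                              stage_centers = NULL,
                              stage_spread = 0.04,
                              n_genes = 2000L,
                              n_signature_genes = 50L,
                              effect_log2fc = 2,
                              dispersion = 0.4,
                              library_size_mean = 5000,
                              library_size_cv = 0.1,
                              n_cells_per_stage = 150L,
                              baseline_log2_sd = 1.5,
                              slope_log2_sd = 0.5,
                              stage_effect_log2_sd = 0.6,
                              model_seed = 20260101L) {
  if (!is.list(stage_names) || !all(c("myeloid", "T") %in% names(stage_names))) {
    rlang::abort("`stage_names` must be a list with elements `myeloid` and `T`.")
  }
  root <- stage_names$myeloid[1]
  if (stage_names$T[1] != root) {
    rlang::abort("Both branches must share the same root stage (first element).")
  }
  if (is.null(stage_centers)) {
    stage_centers <- lapply(stage_names, function(s) {
      stats::setNames(seq(0, 1, length.out = length(s)), s)
    })
  }
  for (br in c("myeloid", "T")) {
    ctr <- stage_centers[[br]]
    if (length(ctr) != length(stage_names[[br]])) {
      rlang::abort(sprintf("Centers for branch %s do not match its stages.", br))
    }
    if (ctr[[1]] != 0) rlang::abort("Root stage must sit at pseudotime 0.")
    if (any(diff(ctr) <= 0) || any(ctr < 0) || any(ctr > 1)) {
      rlang::abort(sprintf(
        "Stage centers must be strictly increasing within [0, 1] (branch %s).", br))
    }
  }
  if (n_genes < 1 || n_cells_per_stage < 0) {
    rlang::abort("Cell and gene counts must be positive.")
  }
  if (2L * n_signature_genes >= n_genes) {
    rlang::abort("`n_genes` must exceed twice `n_signature_genes`.")
  }
  if (dispersion <= 0 || library_size_mean <= 0) {
    rlang::abort("`dispersion` and `library_size_mean` must be positive.")
  }
  cfg <- list(
    stage_names = stage_names,
    stage_centers = stage_centers,
    stage_spread = stage_spread,
    n_genes = as.integer(n_genes),
    n_signature_genes = as.integer(n_signature_genes),
    effect_log2fc = effect_log2fc,
    dispersion = dispersion,
    library_size_mean = library_size_mean,
    library_size_cv = library_size_cv,
    n_cells_per_stage = as.integer(n_cells_per_stage),
    baseline_log2_sd = baseline_log2_sd,
    slope_log2_sd = slope_log2_sd,
    stage_effect_log2_sd = stage_effect_log2_sd,
    model_seed = assert_seed(model_seed),
    root = root,
    bmp_states = intersect(c("HSPC", "LMPP", "CLP", "ETP"),
                           unlist(stage_names)),
    t_committed_states = intersect(c("ProT", "PreT", "DP", "AB"),
                                   unlist(stage_names))
  )
  structure(cfg, class = "trajectory_config")
}

#' Configure a synthetic leukemia cohort
#'
#' Governs per-sample arrest-state mixtures, survival outcomes whose hazard
#' increases with the BMP-like blast fraction, and NOTCH1 mutation dosage that
#' shifts mixture mass toward T-committed states.
#'
#' @param n_samples Number of patients.
#' @param hazard_log_effect Coefficient linking the BMP-like fraction to the
#'   log hazard (the planted Cox coefficient). No default: it must be given
#'   explicitly.
#' @param mixture_prior Named Dirichlet concentration vector over arrest
#'   states (T-branch stages). Default is a flat, mildly sparse prior.
#' @param hazard_baseline Baseline event rate per unit time (years).
#' @param censor_time Administrative censoring horizon (years).
#' @param notch_shift Mixture mass moved from BMP-like to T-committed states
#'   per NOTCH1 mutation.
#' @param notch_bin_probs Probabilities of carrying 0, 1, or 2+ NOTCH1
#'   mutations. Defaults reflect an ETP-ALL-like cohort (69/110, 23/110,
#'   18/110).
#' @param efs_hazard_ratio Event-free-survival baseline hazard as a multiple
#'   of the overall-survival baseline.
#' @param seed Seed used by [make_cohort()] unless overridden there.
#'
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 100L,
                          hazard_log_effect,
                          mixture_prior = NULL,
                          hazard_baseline = 0.05,
                          censor_time = 6,
                          notch_shift = 0.15,
                          notch_bin_probs = c(69, 23, 18) / 110,
                          efs_hazard_ratio = 1.5,
                          seed = 1L) {
  if (missing(hazard_log_effect)) {
    rlang::abort(paste0("`hazard_log_effect` must be supplied explicitly ",
                        "(no silent default)."))
  }
  if (hazard_baseline <= 0) rlang::abort("`hazard_baseline` must be > 0.")
  if (censor_time <= 0) rlang::abort("`censor_time` must be > 0.")
  if (n_samples < 1) rlang::abort("`n_samples` must be positive.")
  if (length(notch_bin_probs) != 3L || any(notch_bin_probs < 0)) {
    rlang::abort("`notch_bin_probs` must be three non-negative probabilities.")
  }
  structure(list(
    n_samples = as.integer(n_samples),
    hazard_log_effect = hazard_log_effect,
    mixture_prior = mixture_prior,
    hazard_baseline = hazard_baseline,
    censor_time = censor_time,
    notch_shift = notch_shift,
    notch_bin_probs = notch_bin_probs / sum(notch_bin_probs),
    efs_hazard_ratio = efs_hazard_ratio,
    seed = assert_seed(seed)
  ), class = "cohort_config")
}
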