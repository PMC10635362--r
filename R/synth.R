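# Synthetic-data module: reference trajectory, blast populations, cohorts,
# and evidence/drug fixtures with known ground truth.

# Unique stage table (root listed once, carried on the T branch).
stage_table <- function(config) {
  my <- tibble(stage = config$stage_names$myeloid, branch = "myeloid",
               center = unname(config$stage_centers$myeloid))
  tt <- tibble(stage = config$stage_names$T, branch = "T",
               center = unname(config$stage_centers$T))
  dplyr::bind_rows(tt[1, ], my[-1, ], tt[-1, ])
}

#' Gene-level expression model implied by a trajectory configuration
#'
#' Deterministically derives (from `config$model_seed`) the per-gene,
#' per-stage relative expression used by [make_reference()] and
#' [make_blasts()], including the planted signature gene sets.
#'
#' @param config A [trajectory_config()].
#' @return A list with `stages` (tibble: stage, branch, center), `prop`
#'   (genes x stages matrix of expected expression proportions),
#'   `signature_up`, `signature_down` (planted gene sets: up = higher in the
#'   progenitor block), and `genes`.
#' @export
build_gene_model <- function(config) {
  stopifnot(inherits(config, "trajectory_config"))
  stages <- stage_table(config)
  n_g <- config$n_genes
  n_sig <- config$n_signature_genes
  genes <- sprintf("gene%05d", seq_len(n_g))

  withr::with_seed(config$model_seed, {
    sig_idx <- sample.int(n_g, 2L * n_sig)
    up <- sort(sig_idx[seq_len(n_sig)])
    down <- sort(sig_idx[n_sig + seq_len(n_sig)])
    base <- rnorm(n_g, 0, config$baseline_log2_sd)
    base[c(up, down)] <- base[c(up, down)] + 2  # keep planted genes well expressed
    slope_my <- rnorm(n_g, 0, config$slope_log2_sd)
    slope_t <- rnorm(n_g, 0, config$slope_log2_sd)
    slope_my[c(up, down)] <- 0
    slope_t[c(up, down)] <- 0
    jit <- matrix(rnorm(n_g * nrow(stages), 0, config$stage_effect_log2_sd),
                  nrow = n_g)
  })

  half <- config$effect_log2fc / 2
  log2rel <- matrix(0, n_g, nrow(stages), dimnames = list(genes, stages$stage))
  for (s in seq_len(nrow(stages))) {
    slope <- if (stages$branch[s] == "myeloid") slope_my else slope_t
    eff <- numeric(n_g)
    if (stages$stage[s] %in% config$bmp_states) {
      eff[up] <- half
      eff[down] <- -half
    } else if (stages$stage[s] %in% config$t_committed_states) {
      eff[up] <- -half
      eff[down] <- half
    }
    log2rel[, s] <- base + slope * stages$center[s] + jit[, s] + eff
  }
  w <- 2^log2rel
  prop <- sweep(w, 2, colSums(w), "/")
  list(stages = stages, prop = prop,
       signature_up = genes[up], signature_down = genes[down], genes = genes)
}

# Draw a counts matrix (genes x cells) for cells assigned to stages.
simulate_counts <- function(model, stage_of_cell, config, cell_ids) {
  n_c <- length(stage_of_cell)
  n_g <- length(model$genes)
  if (n_c == 0L) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n_g, 0L),
                                dimnames = list(model$genes, character())))
  }
  sdlog <- sqrt(log(1 + config$library_size_cv^2))
  lib <- rlnorm(n_c, log(config$library_size_mean) - sdlog^2 / 2, sdlog)
  size <- 1 / config$dispersion
  m <- matrix(0L, n_g, n_c, dimnames = list(model$genes, cell_ids))
  for (j in seq_len(n_c)) {
    mu <- lib[j] * model$prop[, stage_of_cell[j]]
    m[, j] <- rnbinom(n_g, mu = mu, size = size)
  }
  methods::as(m, "CsparseMatrix")
}

trunc_gauss <- function(n, center, spread) {
  pmin(pmax(rnorm(n, center, spread), 0), 1)
}

#' Simulate the healthy two-branch reference atlas
#'
#' Draws `n_cells_per_stage` cells per stage from the negative-binomial
#' expression model, assigns each a raw branch pseudotime (truncated Gaussian
#' around its stage center), and computes a 2-D embedding as the top two
#' principal directions of the log-normalized counts. Identical seed and
#' configuration reproduce identical output.
#'
#' @param config A [trajectory_config()].
#' @param seed Integer seed for cell sampling.
#' @return An object of class `reference_atlas`: list with `counts` (sparse
#'   genes x cells), `cells` (tibble: cell_id, stage, branch, raw_pseudotime,
#'   embed_1, embed_2), `model`, and `config`.
#' @export
make_reference <- function(config, seed) {
  stopifnot(inherits(config, "trajectory_config"))
  seed <- assert_seed(seed)
  model <- build_gene_model(config)
  stages <- model$stages
  n_per <- config$n_cells_per_stage
  if (n_per < 1) rlang::abort("Reference needs at least one cell per stage.")

  stage_of_cell <- rep(stages$stage, each = n_per)
  branch_of_cell <- rep(stages$branch, each = n_per)
  center_of_cell <- rep(stages$center, each = n_per)
  n_c <- length(stage_of_cell)
  cell_ids <- sprintf("ref_%05d", seq_len(n_c))

  withr::with_seed(seed, {
    pt <- trunc_gauss(n_c, center_of_cell, config$stage_spread)
    counts <- simulate_counts(model, stage_of_cell, config, cell_ids)
  })

  ln <- normalize_log_cp10k(counts)
  pc <- stats::prcomp(Matrix::t(ln), rank. = 2, center = TRUE, scale. = FALSE)
  emb <- fix_pc_signs(pc$rotation, pc$x)

  cells <- tibble(
    cell_id = cell_ids, stage = stage_of_cell, branch = branch_of_cell,
    raw_pseudotime = pt, embed_1 = emb[, 1], embed_2 = emb[, 2]
  )
  structure(list(counts = counts, cells = cells, model = model,
                 config = config, seed = seed),
            class = "reference_atlas")
}

#' @export
print.reference_atlas <- function(x, ...) {
  cat(sprintf("<reference_atlas> %d genes x %d cells, %d stages (%s root)\n",
              nrow(x$counts), ncol(x$counts), nrow(x$model$stages),
              x$config$root))
  invisible(x)
}

#' Simulate a blast population as a mixture over arrest states
#'
#' Each blast is drawn from one arrest state's expression model; the true
#' state is recorded so downstream label transfer can be tested against
#' ground truth.
#'
#' @param mixture Named non-negative weights over arrest states (stage
#'   names); must sum to 1 within 1e-9.
#' @param n_cells Number of blasts (0 allowed: returns an empty matrix).
#' @param config A [trajectory_config()].
#' @param seed Integer seed.
#' @param sample_id Identifier stamped on every cell.
#' @return List with `counts` (sparse genes x cells) and `cells` (tibble:
#'   cell_id, sample_id, true_state, branch, raw_pseudotime).
#' @export
make_blasts <- function(mixture, n_cells, config, seed, sample_id = "sample1") {
  stopifnot(inherits(config, "trajectory_config"))
  seed <- assert_seed(seed)
  if (is.null(names(mixture)) || any(!nzchar(names(mixture)))) {
    rlang::abort("`mixture` must be a named vector of arrest-state weights.")
  }
  if (any(mixture < 0)) rlang::abort("Mixture weights must be non-negative.")
  if (abs(sum(mixture) - 1) > 1e-9) {
    rlang::abort("Mixture weights must sum to 1 (tolerance 1e-9).")
  }
  model <- build_gene_model(config)
  stages <- model$stages
  bad <- setdiff(names(mixture), stages$stage)
  if (length(bad)) {
    rlang::abort(sprintf("Unknown arrest states: %s", paste(bad, collapse = ", ")))
  }
  if (n_cells == 0L) {
    return(list(
      counts = simulate_counts(model, character(), config, character()),
      cells = tibble(cell_id = character(), sample_id = character(),
                     true_state = character(), branch = character(),
                     raw_pseudotime = numeric())))
  }
  cell_ids <- sprintf("%s_c%05d", sample_id, seq_len(n_cells))
  withr::with_seed(seed, {
    st <- sample(names(mixture), n_cells, replace = TRUE, prob = mixture)
    centers <- stages$center[match(st, stages$stage)]
    pt <- trunc_gauss(n_cells, centers, config$stage_spread)
    counts <- simulate_counts(model, st, config, cell_ids)
  })
  cells <- tibble(cell_id = cell_ids, sample_id = sample_id, true_state = st,
                  branch = stages$branch[match(st, stages$stage)],
                  raw_pseudotime = pt)
  list(counts = counts, cells = cells)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Simulate a clinical cohort with arrest-state mixtures and outcomes
#'
#' Per sample: a Dirichlet mixture over T-branch arrest states; a NOTCH1
#' mutation count (0, 1, or 2+ with 2-5 mutations) whose dosage shifts
#' mixture mass from BMP-like to T-committed states; survival times drawn
#' with hazard `hazard_baseline * exp(hazard_log_effect * BMP fraction)`
#' under administrative censoring; plus end-of-induction MRD and CNS status.
#' Decoy mutated genes are planted alongside NOTCH1 so recurrence filters
#' have realistic input.
#'
#' @param config A [cohort_config()]; `hazard_log_effect` is the planted Cox
#'   coefficient.
#' @param traj A [trajectory_config()] naming the arrest states.
#' @param n_cells_per_sample If positive, per-sample blast count matrices are
#'   simulated with [make_blasts()].
#' @param seed Overrides `config$seed`.
#' @return List with `cohort` (one row per sample: outcomes, MRD/CNS, NOTCH1
#'   dosage, true BMP fraction), `mixtures` (samples x states matrix),
#'   `mutations` (sample_id, gene, vaf), and `blasts` (named list or NULL).
#' @export
make_cohort <- function(config, traj, n_cells_per_sample = 0L, seed = NULL) {
  stopifnot(inherits(config, "cohort_config"), inherits(traj, "trajectory_config"))
  seed <- assert_seed(seed %||% config$seed)
  states <- traj$stage_names$T
  prior <- config$mixture_prior %||% stats::setNames(rep(0.8, length(states)), states)
  if (!all(names(prior) %in% states) || length(prior) != length(states)) {
    rlang::abort("`mixture_prior` must cover exactly the T-branch arrest states.")
  }
  prior <- prior[states]
  bmp <- intersect(traj$bmp_states, states)
  tcom <- intersect(traj$t_committed_states, states)
  n <- config$n_samples
  gamma <- config$hazard_log_effect

  withr::with_seed(seed, {
    mix <- t(vapply(seq_len(n), function(i) rdirichlet1(prior), numeric(length(states))))
    colnames(mix) <- states
    bin <- sample(c(0L, 1L, 2L), n, replace = TRUE, prob = config$notch_bin_probs)
    n_mut <- ifelse(bin == 2L, sample(2:5, n, replace = TRUE), bin)
    vafs <- lapply(n_mut, function(k) if (k > 0) runif(k, 0.05, 0.5) else numeric())

    for (i in seq_len(n)) {
      if (n_mut[i] > 0 && config$notch_shift > 0) {
        bfrac <- sum(mix[i, bmp])
        delta <- min(config$notch_shift * n_mut[i], bfrac)
        if (bfrac > 0) {
          mix[i, bmp] <- mix[i, bmp] * (1 - delta / bfrac)
          tw <- mix[i, tcom]
          add <- if (sum(tw) > 0) tw / sum(tw) else rep(1 / length(tcom), length(tcom))
          mix[i, tcom] <- tw + delta * add
        }
      }
    }
    bmp_frac <- rowSums(mix[, bmp, drop = FALSE])

    rate_os <- config$hazard_baseline * exp(gamma * bmp_frac)
    t_os <- rexp(n, rate_os)
    rate_efs <- config$hazard_baseline * config$efs_hazard_ratio * exp(gamma * bmp_frac)
    t_efs <- rexp(n, rate_efs)
    mrd <- stats::rbinom(n, 1, stats::plogis(-1.5 + 4 * bmp_frac))
    cns <- sample(c("CNS1", "CNS2", "CNS3"), n, replace = TRUE,
                  prob = c(0.7, 0.2, 0.1))
    subtype <- sample(c("ETP", "Near-ETP", "Non-ETP"), n, replace = TRUE,
                      prob = c(0.5, 0.25, 0.25))

    decoy_genes <- c("JAK3", "NRAS", "WT1", "ETV6", "SATB1",
                     "IL7R", "RUNX1", "KRAS", "PTEN", "FBXW7")
    decoy <- purrr::map_dfr(decoy_genes, function(g) {
      carriers <- which(runif(n) < 0.08)
      if (!length(carriers)) return(NULL)
      tibble(sample_id = sprintf("P%03d", carriers), gene = g,
             vaf = runif(length(carriers), 0.02, 0.5))
    })
  })

  sample_ids <- sprintf("P%03d", seq_len(n))
  rownames(mix) <- sample_ids
  cohort <- tibble(
    sample_id = sample_ids,
    subtype = subtype,
    mrd_status = ifelse(mrd == 1, "positive", "negative"),
    cns_status = cns,
    os_time = pmin(t_os, config$censor_time),
    os_event = as.integer(t_os <= config$censor_time),
    efs_time = pmin(t_efs, config$censor_time),
    efs_event = as.integer(t_efs <= config$censor_time),
    notch1_mutation_count = n_mut,
    notch1_total_vaf = vapply(vafs, sum, numeric(1)),
    bmp_fraction_true = bmp_frac
  )
  notch <- purrr::map_dfr(seq_len(n), function(i) {
    if (n_mut[i] == 0) return(NULL)
    tibble(sample_id = sample_ids[i], gene = "NOTCH1", vaf = vafs[[i]])
  })
  mutations <- dplyr::arrange(dplyr::bind_rows(notch, decoy),
                              .data$sample_id, .data$gene)

  blasts <- NULL
  if (n_cells_per_sample > 0) {
    blasts <- lapply(seq_len(n), function(i) {
      make_blasts(mix[i, ], n_cells_per_sample, traj, seed = seed + i,
                  sample_id = sample_ids[i])
    })
    names(blasts) <- sample_ids
  }
  list(cohort = cohort, mixtures = mix, mutations = mutations, blasts = blasts)
}

#' Build an IC50 drug-screen fixture with planted BMP-differential compounds
#'
#' Emulates the five-model PDX screen layout: four ETP samples (three
#' BMP-high/MRD-positive, one BMP-low) plus one non-ETP BMP-low/MRD-negative
#' sample, and the three predefined group comparisons used to nominate
#' BMP-specific drugs. Planted compounds are roughly 10-fold more potent in
#' the BMP-high samples and active (IC50 < 1000 nM) in all four ETP samples;
#' neutral compounds have comparable IC50s everywhere; one always-included
#' inactive compound exceeds the activity threshold in every ETP sample.
#'
#' @param planted_compounds Character vector of differential compound names.
#' @param n_neutral Number of non-differential active compounds.
#' @param seed Integer seed.
#' @return List: `ic50` (compound, sample_id, ic50_nM, censored), `samples`
#'   (annotations), `comparisons` (three high/low id lists), `etp_samples`,
#'   `planted`.
#' @export
make_ic50_fixture <- function(planted_compounds, n_neutral = 5L, seed = 1L) {
  seed <- assert_seed(seed)
  samples <- tibble(
    sample_id = c("E1", "E2", "E3", "E4", "N1"),
    subtype = c("ETP", "ETP", "ETP", "ETP", "Non-ETP"),
    bmp_class = c("High", "High", "High", "Low", "Low"),
    mrd_class = c("high", "high", "positive", "negative", "negative")
  )
  etp <- c("E1", "E2", "E3", "E4")
  high3 <- c("E1", "E2", "E3")
  comparisons <- list(
    list(high = high3, low = c("E4", "N1")),
    list(high = c("E1", "E2"), low = "E4"),
    list(high = high3, low = "E4")
  )
  neutral <- if (n_neutral > 0) sprintf("NEUT%02d", seq_len(n_neutral)) else character()
  withr::with_seed(seed, {
    rows <- purrr::map_dfr(c(planted_compounds, neutral, "INACTIVE01"), function(cp) {
      ic <- if (cp %in% planted_compounds) {
        c(runif(3, 40, 90), runif(2, 500, 900))
      } else if (cp == "INACTIVE01") {
        runif(5, 2000, 5000)
      } else {
        rep(runif(1, 300, 700), 5)  # equipotent everywhere: never differential
      }
      tibble(compound = cp, sample_id = samples$sample_id,
             ic50_nM = ic, censored = FALSE)
    })
  })
  list(ic50 = rows, samples = samples, comparisons = comparisons,
       etp_samples = etp, planted = planted_compounds)
}

#' Build evidence-database fixtures with planted hits
#'
#' Creates the three drug-target database tables, the connectivity-screen
#' table, the dependency-screen table, and a matching differential-expression
#' table. Planted genes carry full evidence (all three databases, a
#' connectivity row passing every compound filter, a dependency row passing
#' every dependency filter, and top-tier DE metrics, so their aggregate
#' evidence is the maximal 8). Each decoy fails exactly one designated
#' database or screen filter, recorded in the manifest, capping its
#' aggregate strictly below the planted genes.
#'
#' @param planted_full_hit_genes Character vector of planted target genes.
#' @param n_decoys Number of decoy genes.
#' @param seed Integer seed (decoy failure assignment).
#' @return List of tibbles: `db_ttd`, `db_drugidb`, `db_opentargets`,
#'   `connectivity`, `dependency`, `degs`, and `manifest` (gene, role,
#'   failing_filter).
#' @export
make_evidence_fixtures <- function(planted_full_hit_genes, n_decoys, seed = 1L) {
  seed <- assert_seed(seed)
  planted <- toupper(planted_full_hit_genes)
  decoys <- sprintf("DECOY%03d", seq_len(n_decoys))
  if (length(intersect(planted, decoys))) {
    rlang::abort("Planted genes must be disjoint from decoy names.")
  }
  fail_modes <- c("db_ttd", "db_drugidb", "db_opentargets",
                  "lincs_specificity", "depmap_dependency")
  withr::with_seed(seed, {
    fails <- if (n_decoys > 0) sample(fail_modes, n_decoys, replace = TRUE)
             else character()
  })
  genes <- c(planted, decoys)
  role <- c(rep("planted", length(planted)), rep("decoy", n_decoys))
  fail_of <- stats::setNames(c(rep(NA_character_, length(planted)), fails), genes)

  in_db <- function(db) genes[is.na(fail_of) | fail_of != db]
  connectivity <- tibble(
    perturbation_id = sprintf("BRD-%04d", seq_along(genes)),
    perturbation_class = "compound",
    target_gene = genes,
    neg_log10_fdr = 1.5,
    normalized_connectivity = 0.9,
    raw_connectivity = ifelse(!is.na(fail_of) & fail_of == "lincs_specificity",
                              -0.2, 0.5),
    n_leukemia_lines_active = 3L
  )
  dependency <- tibble(
    gene = genes,
    mean_dep_leukemia = ifelse(!is.na(fail_of) & fail_of == "depmap_dependency",
                               -0.05, -0.3),
    mean_dep_other = -0.1,
    pct_expressed_bmp = 0.6
  )
  degs <- tibble(
    gene = genes,
    log2fc = ifelse(role == "planted", 1.2, 1.1),
    pct_in = 0.85,
    p_raw = 1e-121,
    fdr = 1e-120
  )
  list(
    db_ttd = tibble(gene = in_db("db_ttd")),
    db_drugidb = tibble(gene = in_db("db_drugidb")),
    db_opentargets = tibble(gene = in_db("db_opentargets")),
    connectivity = connectivity,
    dependency = dependency,
    degs = degs,
    manifest = tibble(gene = genes, role = role,
                      failing_filter = unname(fail_of))
  )
}
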