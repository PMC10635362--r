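test_that("identical seed and config reproduce identical output", {
  cfg <- tiny_traj()
  r1 <- make_reference(cfg, seed = 11)
  r2 <- make_reference(cfg, seed = 11)
  expect_identical(as.matrix(r1$counts), as.matrix(r2$counts))
  expect_identical(r1$cells, r2$cells)
  b1 <- make_blasts(c(ETP = 1), 40, cfg, seed = 5)
  b2 <- make_blasts(c(ETP = 1), 40, cfg, seed = 5)
  expect_identical(as.matrix(b1$counts), as.matrix(b2$counts))
})

test_that("a single-stage trajectory collapses to the root", {
  cfg <- root_only_traj()
  ref <- make_reference(cfg, seed = 3)
  expect_true(all(ref$cells$stage == "HSPC"))
  # clipped Gaussian around center 0 stays within a few spreads of it
  expect_true(all(abs(ref$cells$raw_pseudotime) <= 5 * cfg$stage_spread))
})

test_that("configuration errors are caught", {
  expect_error(trajectory_config(n_genes = 0), "positive")
  expect_error(trajectory_config(
    stage_names = list(myeloid = c("HSPC", "GMP"), T = c("CLP", "DP"))),
    "root")
  expect_error(trajectory_config(
    stage_centers = list(myeloid = c(HSPC = 0, GMP = 0.9, Mono = 0.5),
                         T = setNames(seq(0, 1, length.out = 8),
                                      c("HSPC", "LMPP", "CLP", "ETP",
                                        "ProT", "PreT", "DP", "AB")))),
    "increasing")
})

test_that("planted signature genes carry the configured block contrast", {
  cfg <- trajectory_config(n_genes = 600L, n_signature_genes = 30L,
                           effect_log2fc = 2, model_seed = 42L)
  model <- build_gene_model(cfg)
  expect_length(intersect(model$signature_up, model$signature_down), 0)
  prog <- make_blasts(c(HSPC = .25, LMPP = .25, CLP = .25, ETP = .25),
                      500, cfg, seed = 21)
  tcom <- make_blasts(c(ProT = .25, PreT = .25, DP = .25, AB = .25),
                      500, cfg, seed = 22)
  fc_up <- log2(Matrix::rowMeans(prog$counts[model$signature_up, ])) -
    log2(Matrix::rowMeans(tcom$counts[model$signature_up, ]))
  fc_dn <- log2(Matrix::rowMeans(prog$counts[model$signature_down, ])) -
    log2(Matrix::rowMeans(tcom$counts[model$signature_down, ]))
  expect_lt(abs(mean(fc_up) - 2), 0.3)
  expect_lt(abs(mean(fc_dn) + 2), 0.3)
})

test_that("blast mixtures honour their weights", {
  cfg <- tiny_traj()
  pm <- make_blasts(c(ETP = 1), 60, cfg, seed = 1)
  expect_true(all(pm$cells$true_state == "ETP"))

  mix <- make_blasts(c(HSPC = 0.5, DP = 0.5), 1000, cfg, seed = 2)
  n_hspc <- sum(mix$cells$true_state == "HSPC")
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.5)
  expect_gte(n_hspc, bounds[1])
  expect_lte(n_hspc, bounds[2])

  empty <- make_blasts(c(ETP = 1), 0, cfg, seed = 3)
  expect_equal(ncol(empty$counts), 0)
  expect_equal(nrow(empty$cells), 0)

  expect_error(make_blasts(c(ETP = 0.5, DP = 0.4), 10, cfg, seed = 1), "sum to 1")
  expect_error(make_blasts(c(ETP = 1.5, DP = -0.5), 10, cfg, seed = 1),
               "non-negative")
})

test_that("cohort generation enforces an explicit hazard effect", {
  expect_error(cohort_config(n_samples = 10), "hazard_log_effect")
})

test_that("cohort mixtures are conserved and NOTCH1 dosage shifts them", {
  traj <- tiny_traj()
  cc0 <- cohort_config(n_samples = 400, hazard_log_effect = 1,
                       notch_shift = 0, seed = 9)
  c0 <- make_cohort(cc0, traj)
  expect_true(all(abs(rowSums(c0$mixtures) - 1) < 1e-9))
  expect_true(all(c0$cohort$notch1_total_vaf[c0$cohort$notch1_mutation_count == 0] == 0))
  expect_true(all(c0$cohort$notch1_total_vaf[c0$cohort$notch1_mutation_count > 0] > 0))

  # no shift: BMP fraction unrelated to mutation bin
  d0 <- abs(mean(c0$cohort$bmp_fraction_true[c0$cohort$notch1_mutation_count == 0]) -
              mean(c0$cohort$bmp_fraction_true[c0$cohort$notch1_mutation_count >= 2]))
  expect_lt(d0, 0.06)

  cc1 <- cohort_config(n_samples = 400, hazard_log_effect = 1,
                       notch_shift = 0.15, seed = 9)
  c1 <- make_cohort(cc1, traj)
  d1 <- mean(c1$cohort$bmp_fraction_true[c1$cohort$notch1_mutation_count == 0]) -
    mean(c1$cohort$bmp_fraction_true[c1$cohort$notch1_mutation_count >= 2])
  expect_gt(d1, 0.1)

  # 2+ bin always holds 2-5 mutations with VAFs in (0.05, 0.5]
  expect_true(all(c1$cohort$notch1_mutation_count %in% c(0:1, 2:5)))
  expect_true(all(c1$mutations$vaf[c1$mutations$gene == "NOTCH1"] > 0.05 - 1e-12))
  expect_true(all(c1$mutations$vaf[c1$mutations$gene == "NOTCH1"] <= 0.5))
})

test_that("censoring and hazard behave at the limits", {
  traj <- tiny_traj()
  cc <- cohort_config(n_samples = 50, hazard_log_effect = 1,
                      censor_time = 1e-9, seed = 4)
  ch <- make_cohort(cc, traj)
  expect_true(all(ch$cohort$os_event == 0))
  expect_true(all(ch$cohort$efs_event == 0))

  # monotone hazard: mean survival time falls across BMP-fraction terciles
  cc2 <- cohort_config(n_samples = 1500, hazard_log_effect = 1.5,
                       hazard_baseline = 0.05, censor_time = 500, seed = 8)
  ch2 <- make_cohort(cc2, traj)
  ter <- cut(ch2$cohort$bmp_fraction_true,
             quantile(ch2$cohort$bmp_fraction_true, c(0, 1/3, 2/3, 1)),
             include.lowest = TRUE, labels = c("lo", "mid", "hi"))
  mt <- tapply(ch2$cohort$os_time, ter, mean)
  expect_true(mt[["lo"]] > mt[["mid"]] && mt[["mid"]] > mt[["hi"]])
})

test_that("evidence fixtures plant full hits and record decoy failures", {
  fx1 <- make_evidence_fixtures("TARGET1", n_decoys = 0, seed = 1)
  led1 <- evidence_ledger(fx1$degs, fx1$db_ttd, fx1$db_drugidb,
                          fx1$db_opentargets, fx1$connectivity, fx1$dependency)
  expect_equal(led1$db_total, 5)
  expect_equal(led1$aggregate, 8)

  fx <- make_evidence_fixtures(c("G1", "G2"), n_decoys = 30, seed = 2)
  expect_true(all(c("G1", "G2") %in% fx$db_ttd$gene))
  expect_true(all(is.na(fx$manifest$failing_filter[fx$manifest$role == "planted"])))
  expect_true(all(!is.na(fx$manifest$failing_filter[fx$manifest$role == "decoy"])))

  # a connectivity-specificity decoy fails only that filter
  spec_decoy <- fx$manifest$gene[!is.na(fx$manifest$failing_filter) &
                                   fx$manifest$failing_filter == "lincs_specificity"]
  expect_gt(length(spec_decoy), 0)
  g <- spec_decoy[1]
  expect_lt(fx$connectivity$raw_connectivity[fx$connectivity$target_gene == g], 0)
  expect_equal(lincs_filter(fx$connectivity, g)$lincs_hit, 0L)
  expect_equal(depmap_filter(fx$dependency, g)$depmap_hit, 1L)
  expect_true(g %in% fx$db_ttd$gene && g %in% fx$db_drugidb$gene &&
                g %in% fx$db_opentargets$gene)
})

test_that("counts round-trip through Matrix Market sidecar files", {
  cfg <- root_only_traj()
  ref <- make_reference(cfg, seed = 1)
  dir <- withr::local_tempdir()
  write_counts_mtx(ref$counts, dir)
  back <- read_counts_mtx(dir)
  expect_equal(as.matrix(back), as.matrix(ref$counts))
})
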