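test_that("candidate selection applies both strict thresholds", {
  tab <- tibble::tibble(
    gene = c("edge_fc", "weak_p", "pass"),
    log2fc = c(0.2, 0.5, 0.25),
    fdr = c(1e-5, 0.02, 1e-3))
  expect_equal(candidate_degs(tab), "PASS")
})

test_that("database hits are case-normalized memberships", {
  ttd <- tibble::tibble(gene = c("abc", "DEF"))
  dgi <- tibble::tibble(gene = "XYZ")
  ot <- tibble::tibble(gene = c("ABC", "XYZ"))
  h <- db_hits(c("ABC", "xyz", "nope"), ttd, dgi, ot)
  expect_equal(h$db_ttd, c(1L, 0L, 0L))
  expect_equal(h$db_drugidb, c(0L, 1L, 0L))
  expect_equal(h$db_opentargets, c(1L, 1L, 0L))
  expect_equal(rowSums(h[, -1]), c(2, 2, 0), ignore_attr = TRUE)
})

test_that("connectivity rows pass or fail by class-specific criteria", {
  rows <- tibble::tibble(
    perturbation_id = sprintf("p%d", 1:5),
    perturbation_class = c("compound", "compound", "overexpression",
                           "knockdown", "mystery"),
    target_gene = c("G1", "G2", "G3", "G4", "G5"),
    neg_log10_fdr = c(1.5, 1.5, 1.5, 1.5, 1.5),
    normalized_connectivity = c(0.9, 0.9, 0.9, 0.9, 0.9),
    raw_connectivity = c(0.5, -0.2, 0.5, 0.5, 0.5),
    n_leukemia_lines_active = c(3L, 3L, 3L, 3L, 3L))
  expect_warning(out <- lincs_filter(rows, c("G1", "G2", "G3", "G4", "G5")),
                 "unknown perturbation class")
  # compound passing all four criteria; compound failing specificity;
  # overexpression needs the negative sign; knockdown passes positive
  expect_equal(out$lincs_hit, c(1L, 0L, 0L, 1L, 0L))

  few_lines <- dplyr::mutate(rows[1, ], n_leukemia_lines_active = 1L)
  expect_equal(lincs_filter(few_lines, "G1")$lincs_hit, 0L)
  oe_neg <- dplyr::mutate(rows[3, ], raw_connectivity = -0.5)
  expect_equal(lincs_filter(oe_neg, "G3")$lincs_hit, 1L)
})

test_that("dependency filter uses magnitude fold-change with the Inf convention", {
  dep <- tibble::tibble(
    gene = c("HIT", "WEAK", "INFHIT", "LOWFC"),
    mean_dep_leukemia = c(-0.3, -0.05, -0.3, -0.3),
    mean_dep_other = c(-0.1, -0.5, 0.1, -0.2),
    pct_expressed_bmp = c(0.6, 0.9, 0.6, 0.6))
  out <- depmap_filter(dep, dep$gene)
  expect_equal(out$dep_fold_change[out$gene == "HIT"], 3)
  expect_equal(out$depmap_hit, c(1L, 0L, 1L, 0L))
  expect_equal(out$dep_fold_change[out$gene == "INFHIT"], Inf)

  dep$pct_expressed_bmp[1] <- NA
  expect_warning(out2 <- depmap_filter(dep, dep$gene), "missing expression")
  expect_equal(out2$depmap_hit[out2$gene == "HIT"], 0L)
})

test_that("DE evidence tiers score exactly as specified, boundaries included", {
  tab <- tibble::tibble(
    gene = c("top", "mid", "low", "b_fc1", "b_pct", "b_p100"),
    log2fc = c(1.2, 0.6, 0.3, 1.0, 0.9, 1.5),
    pct_in = c(0.85, 0.60, 0.30, 0.7, 0.80, 0.9),
    fdr = c(1e-120, 1e-60, 1e-10, 1e-60, 1e-60, 1e-100))
  ev <- de_evidence(tab)
  expect_equal(ev$de_total[ev$gene == "TOP"], 3)
  expect_equal(unlist(ev[ev$gene == "TOP", c("de_fc_score", "de_pct_score",
                                             "de_sig_score")]),
               c(de_fc_score = 1, de_pct_score = 1, de_sig_score = 1))
  expect_equal(ev$de_total[ev$gene == "MID"], 1.5)
  expect_equal(ev$de_total[ev$gene == "LOW"], 0)
  # boundary conventions: log2fc exactly 1, pct exactly 0.8, p exactly 1e-100
  expect_equal(ev$de_fc_score[ev$gene == "B_FC1"], 0.5)
  expect_equal(ev$de_pct_score[ev$gene == "B_PCT"], 0.5)
  expect_equal(ev$de_sig_score[ev$gene == "B_P100"], 0.5)
})

test_that("aggregate score decomposes exactly and tie-breaks as stated", {
  fx <- make_evidence_fixtures(c("T1", "T2", "T3"), n_decoys = 50, seed = 5)
  led <- evidence_ledger(fx$degs, fx$db_ttd, fx$db_drugidb, fx$db_opentargets,
                         fx$connectivity, fx$dependency)
  expect_true(all(led$aggregate == led$db_total + led$de_total))
  expect_true(all(led$db_total == led$db_ttd + led$db_drugidb +
                    led$db_opentargets + led$lincs_hit + led$depmap_hit))
  expect_setequal(led$gene[led$rank <= 3], c("T1", "T2", "T3"))
  expect_true(all(led$aggregate[led$rank <= 3] == 8))
  expect_true(max(led$aggregate[!led$gene %in% c("T1", "T2", "T3")]) < 8)

  # tie at aggregate 5 broken by higher database total:
  # DBRICH db 3 + de 2; DERICH db 2 + de 3
  tie <- tibble::tibble(
    gene = c("DBRICH", "DERICH"),
    log2fc = c(1.5, 1.2), pct_in = c(0.95, 0.85), fdr = c(1e-10, 1e-120))
  led2 <- evidence_ledger(
    tie,
    db_ttd = tibble::tibble(gene = c("DBRICH", "DERICH")),
    db_drugidb = tibble::tibble(gene = c("DBRICH", "DERICH")),
    db_opentargets = tibble::tibble(gene = "DBRICH"),
    connectivity = fx$connectivity[0, ],
    dependency = fx$dependency[0, ])
  expect_equal(led2$aggregate, c(5, 5))
  expect_equal(led2$gene, c("DBRICH", "DERICH"))

  # zero-evidence gene aggregates to 0
  zero <- evidence_ledger(
    tibble::tibble(gene = "nohit", log2fc = 0.3, pct_in = 0.1, fdr = 1e-3),
    tibble::tibble(gene = character()), tibble::tibble(gene = character()),
    tibble::tibble(gene = character()), fx$connectivity[0, ], fx$dependency[0, ])
  expect_equal(zero$aggregate, 0)
})

test_that("score ranges are bounded by construction over the full tier space", {
  grid <- tidyr::expand_grid(
    log2fc = c(-1, 0.3, 0.5, 0.75, 1, 1.5),
    pct_in = c(0.1, 0.5, 0.65, 0.8, 0.95),
    fdr = c(1e-10, 1e-50 / 2, 1e-100, 1e-150))
  grid$gene <- sprintf("g%03d", seq_len(nrow(grid)))
  ev <- de_evidence(grid)
  expect_equal(max(ev$de_total), 3)
  expect_true(all(ev$de_total >= 0))
})
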