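# Multi-evidence consensus target prioritization: three target databases,
# connectivity-screen and dependency-screen filters, and tiered differential
# expression evidence combined into a 0-8 aggregate per gene.

norm_gene <- function(x) toupper(trimws(x))

#' Candidate DEGs for target nomination
#'
#' Upregulated genes entering the evidence pipeline: `log2fc > log2fc_min`
#' and adjusted p strictly below `fdr_max` (defaults 0.2 and 0.01, the
#' candidate-selection thresholds).
#'
#' @param deg_table Tibble with gene, log2fc, fdr.
#' @param log2fc_min,fdr_max Strict thresholds.
#' @return Character vector of candidate gene symbols (case-normalized).
#' @export
candidate_degs <- function(deg_table, log2fc_min = 0.2, fdr_max = 0.01) {
  norm_gene(deg_table$gene[deg_table$log2fc > log2fc_min &
                             deg_table$fdr < fdr_max])
}

#' Database membership evidence
#'
#' Looks each candidate up in the three drug-target database tables
#' (case-normalized symbols); each membership contributes one evidence point.
#'
#' @param candidates Character vector of gene symbols.
#' @param db_ttd,db_drugidb,db_opentargets Tibbles with a `gene` column.
#' @return Tibble: gene, db_ttd, db_drugidb, db_opentargets (0/1 each).
#' @export
db_hits <- function(candidates, db_ttd, db_drugidb, db_opentargets) {
  g <- norm_gene(candidates)
  tibble(
    gene = g,
    db_ttd = as.integer(g %in% norm_gene(db_ttd$gene)),
    db_drugidb = as.integer(g %in% norm_gene(db_drugidb$gene)),
    db_opentargets = as.integer(g %in% norm_gene(db_opentargets$gene))
  )
}

# Row-level connectivity filter by perturbation class.
lincs_row_pass <- function(rows) {
  base <- rows$neg_log10_fdr > 1 & rows$normalized_connectivity > 0.8
  dplyr::case_when(
    rows$perturbation_class == "compound" ~
      base & rows$raw_connectivity > 0 & rows$n_leukemia_lines_active >= 2,
    rows$perturbation_class == "knockdown" ~ base & rows$raw_connectivity > 0,
    rows$perturbation_class == "overexpression" ~ base & rows$raw_connectivity < 0,
    TRUE ~ NA
  )
}

#' Connectivity-screen evidence
#'
#' A perturbation row passes when it is significant (-log10 FDR > 1), strong
#' (normalized connectivity > 0.8), and state-specific: compounds and gene
#' knockdowns need a positive raw connectivity (mimicking loss of the
#' BMP-like state), overexpression needs a negative one; compounds must
#' additionally be active in at least 2 leukemia cell lines. A candidate
#' gene scores `lincs_hit = 1` iff at least one passing row targets it. Rows
#' of unknown class are skipped with a warning.
#'
#' @param connectivity Tibble of connectivity rows (perturbation_id,
#'   perturbation_class, target_gene, neg_log10_fdr, normalized_connectivity,
#'   raw_connectivity, n_leukemia_lines_active).
#' @param candidates Character vector of gene symbols.
#' @return Tibble: gene, lincs_hit (0/1).
#' @export
lincs_filter <- function(connectivity, candidates) {
  pass <- lincs_row_pass(connectivity)
  if (anyNA(pass)) {
    bad <- unique(connectivity$perturbation_class[is.na(pass)])
    rlang::warn(sprintf("Skipping rows with unknown perturbation class: %s",
                        paste(bad, collapse = ", ")))
    pass[is.na(pass)] <- FALSE
  }
  hits <- norm_gene(connectivity$target_gene[pass])
  g <- norm_gene(candidates)
  tibble(gene = g, lincs_hit = as.integer(g %in% hits))
}

#' Dependency-screen evidence
#'
#' A gene is a dependency hit when leukemia lines depend on it (mean
#' dependency score < -0.1), the dependency is leukemia-enriched
#' (fold-change > 2, computed as the ratio of leukemia to non-leukemia mean
#' dependency magnitudes; treated as infinite when the comparator lines show
#' no dependency at all), and it is expressed in more than 25% of BMP-like
#' blasts. Genes missing the expression fraction are skipped with a warning.
#'
#' @param dependency Tibble: gene, mean_dep_leukemia, mean_dep_other,
#'   pct_expressed_bmp.
#' @param candidates Character vector of gene symbols.
#' @return Tibble: gene, depmap_hit (0/1), dep_fold_change.
#' @export
depmap_filter <- function(dependency, candidates) {
  dep <- dplyr::mutate(dependency, gene = norm_gene(.data$gene))
  if (anyNA(dep$pct_expressed_bmp)) {
    rlang::warn(sprintf(
      "Skipping %d dependency rows with missing expression fraction.",
      sum(is.na(dep$pct_expressed_bmp))))
    dep <- dplyr::filter(dep, !is.na(.data$pct_expressed_bmp))
  }
  dep <- dep |>
    dplyr::mutate(
      dep_fold_change = dplyr::case_when(
        .data$mean_dep_leukemia >= 0 ~ 0,
        .data$mean_dep_other >= 0 ~ Inf,
        TRUE ~ .data$mean_dep_leukemia / .data$mean_dep_other
      ),
      depmap_hit = as.integer(.data$mean_dep_leukemia < -0.1 &
                                .data$dep_fold_change > 2 &
                                .data$pct_expressed_bmp > 0.25)
    )
  g <- norm_gene(candidates)
  out <- dplyr::left_join(
    tibble(gene = g),
    dplyr::select(dep, "gene", "depmap_hit", "dep_fold_change"),
    by = "gene")
  out$depmap_hit[is.na(out$depmap_hit)] <- 0L
  out
}

#' Tiered differential-expression evidence
#'
#' Three components, each scored 1 / 0.5 / 0: fold change (log2FC > 1 scores
#' 1; 0.5 <= log2FC <= 1 scores 0.5), expression breadth (pct > 80% scores 1;
#' 50%-80% inclusive scores 0.5), and significance (adjusted p < 1e-100
#' scores 1; < 1e-50 scores 0.5). Boundary conventions: log2FC exactly 1,
#' pct exactly 0.5 or 0.8, and p exactly 1e-100 all score 0.5.
#'
#' @param deg_table Tibble with gene, log2fc, pct_in, fdr.
#' @return Tibble: gene, de_fc_score, de_pct_score, de_sig_score, de_total.
#' @export
de_evidence <- function(deg_table) {
  deg_table |>
    dplyr::transmute(
      gene = norm_gene(.data$gene),
      log2fc = .data$log2fc,
      de_fc_score = dplyr::case_when(
        .data$log2fc > 1 ~ 1,
        .data$log2fc >= 0.5 ~ 0.5,
        TRUE ~ 0),
      de_pct_score = dplyr::case_when(
        .data$pct_in > 0.8 ~ 1,
        .data$pct_in >= 0.5 ~ 0.5,
        TRUE ~ 0),
      de_sig_score = dplyr::case_when(
        .data$fdr < 1e-100 ~ 1,
        .data$fdr < 1e-50 ~ 0.5,
        TRUE ~ 0),
      de_total = .data$de_fc_score + .data$de_pct_score + .data$de_sig_score
    )
}

#' Assemble and rank the evidence ledger
#'
#' Runs candidate selection, database lookup, connectivity and dependency
#' filters, and DE tiering, then ranks genes by the aggregate score
#' (database evidence 0-5 plus DE evidence 0-3, maximum 8). Ties are broken
#' by higher database total, then higher log2 fold change, then gene symbol.
#'
#' @param deg_table Candidate DEG table (gene, log2fc, pct_in, fdr).
#' @param db_ttd,db_drugidb,db_opentargets Target-database tables.
#' @param connectivity Connectivity-screen rows.
#' @param dependency Dependency-screen rows.
#' @param log2fc_min,fdr_max Candidate thresholds (see [candidate_degs()]).
#' @return Tibble ledger: gene, the five binary database/screen components,
#'   three DE tiers, db_total, de_total, aggregate, rank.
#' @export
evidence_ledger <- function(deg_table, db_ttd, db_drugidb, db_opentargets,
                            connectivity, dependency,
                            log2fc_min = 0.2, fdr_max = 0.01) {
  cand <- candidate_degs(deg_table, log2fc_min, fdr_max)
  if (!length(cand)) return(tibble())
  ledger <- db_hits(cand, db_ttd, db_drugidb, db_opentargets) |>
    dplyr::left_join(lincs_filter(connectivity, cand), by = "gene") |>
    dplyr::left_join(dplyr::select(depmap_filter(dependency, cand),
                                   "gene", "depmap_hit"), by = "gene") |>
    dplyr::left_join(de_evidence(deg_table) |>
                       dplyr::filter(.data$gene %in% cand), by = "gene") |>
    dplyr::mutate(
      db_total = .data$db_ttd + .data$db_drugidb + .data$db_opentargets +
        .data$lincs_hit + .data$depmap_hit,
      aggregate = .data$db_total + .data$de_total
    ) |>
    dplyr::arrange(dplyr::desc(.data$aggregate), dplyr::desc(.data$db_total),
                   dplyr::desc(.data$log2fc), .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number())
  ledger
}
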