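# Survival machinery: Kaplan-Meier curves, Cox proportional-hazards fits with
# clinical covariates, NOTCH1 mutation-dosage analysis, and recurrence filters.

#' Kaplan-Meier product-limit estimate
#'
#' Thin tidy wrapper around [survival::survfit()]: censored subjects leave
#' the risk set after their time, and the survival curve steps down at event
#' times only.
#'
#' @param data Data frame with time and event columns.
#' @param time,event Column names (event coded 0 = censored, 1 = event).
#' @return Tibble: time, n_risk, n_event, n_censor, survival, std_err.
#' @export
km_estimate <- function(data, time = "os_time", event = "os_event") {
  tt <- data[[time]]; ev <- data[[event]]
  if (is.null(tt) || is.null(ev)) rlang::abort("Time/event columns not found.")
  if (any(tt < 0)) rlang::abort("Survival times must be non-negative.")
  if (!all(ev %in% c(0, 1))) rlang::abort("Events must be coded 0/1.")
  fit <- survival::survfit(survival::Surv(tt, ev) ~ 1)
  tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, survival = fit$surv, std_err = fit$std.err
  )
}

#' Survival probability at a horizon
#'
#' Reads `S(t)` off a [km_estimate()] curve (step function, right-continuous).
#'
#' @param km Tibble from [km_estimate()].
#' @param at Horizon (same time units as the input; e.g. 5 for 5-year OS).
#' @return Single survival probability.
#' @export
km_at <- function(km, at) {
  s <- km$survival[km$time <= at]
  if (!length(s)) 1 else s[length(s)]
}

#' Cox proportional-hazards fit with covariates
#'
#' Fits the partial likelihood with Breslow tie handling via
#' [survival::coxph()] and reports both the likelihood-ratio and Wald tests.
#' Degenerate designs fail loudly: zero events, covariates constant across
#' subjects, and rank-deficient model matrices are errors naming the
#' offending term; monotone-likelihood (complete separation) fits are
#' flagged with a warning and the runaway coefficient reported as capped.
#'
#' @param data Data frame of cohort records.
#' @param terms Character vector of covariate column names.
#' @param time,event Outcome column names.
#' @return Object of class `arrest_cox` (supports [generics::tidy()],
#'   [generics::glance()], and `autoplot()`).
#' @export
cox_fit <- function(data, terms, time = "os_time", event = "os_event") {
  if (!all(terms %in% names(data))) {
    rlang::abort(sprintf("Missing covariate columns: %s",
                         paste(setdiff(terms, names(data)), collapse = ", ")))
  }
  if (sum(data[[event]]) == 0) {
    rlang::abort("No events in the data: the partial likelihood is uninformative.")
  }
  for (tm in terms) {
    if (length(unique(data[[tm]])) == 1L) {
      rlang::abort(sprintf("Covariate `%s` is constant across all subjects.", tm))
    }
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(sprintf("`%s`", terms), collapse = " + ")))
  mm <- stats::model.matrix(
    stats::as.formula(paste("~", paste(sprintf("`%s`", terms), collapse = "+"))),
    data = data)[, -1, drop = FALSE]
  if (qr(mm)$rank < ncol(mm)) {
    rlang::abort("Model matrix is rank deficient (collinear covariates).")
  }
  fit <- survival::coxph(fml, data = data, ties = "breslow")
  sep <- any(abs(stats::coef(fit)) > 15 | sqrt(diag(fit$var)) > 100)
  if (sep) {
    rlang::warn(paste0("Possible monotone likelihood (complete separation): ",
                       "a coefficient is effectively unbounded."))
  }
  lrt_stat <- 2 * diff(fit$loglik)
  df <- sum(!is.na(stats::coef(fit)))
  structure(list(
    fit = fit, terms = terms, time = time, event = event,
    n = fit$n, n_events = fit$nevent,
    lrt_statistic = lrt_stat, lrt_df = df,
    lrt_p = stats::pchisq(lrt_stat, df, lower.tail = FALSE),
    wald_p = 1 - stats::pchisq(fit$wald.test, df),
    separation_flag = sep
  ), class = "arrest_cox")
}

#' @export
print.arrest_cox <- function(x, ...) {
  cat(sprintf("<arrest_cox> n = %d, events = %d; LRT p = %.3g (df %d)\n",
              x$n, x$n_events, x$lrt_p, x$lrt_df))
  print(tidy(x))
  invisible(x)
}

#' Tidy a Cox fit
#'
#' @param x An `arrest_cox` object.
#' @param ... Unused.
#' @return Tibble: term, estimate (log hazard ratio), std_error, statistic,
#'   p_value, conf_low, conf_high (95% Wald interval).
#' @export
tidy.arrest_cox <- function(x, ...) {
  co <- stats::coef(x$fit)
  se <- sqrt(diag(x$fit$var))
  z <- co / se
  tibble(
    term = names(co), estimate = unname(co), std_error = unname(se),
    statistic = unname(z), p_value = unname(2 * stats::pnorm(-abs(z))),
    conf_low = unname(co - 1.96 * se), conf_high = unname(co + 1.96 * se)
  )
}

#' One-row model summary of a Cox fit
#'
#' @param x An `arrest_cox` object.
#' @param ... Unused.
#' @return Tibble: n, n_events, lrt_statistic, lrt_df, lrt_p, wald_p,
#'   concordance, separation_flag.
#' @export
glance.arrest_cox <- function(x, ...) {
  tibble(
    n = x$n, n_events = x$n_events,
    lrt_statistic = x$lrt_statistic, lrt_df = x$lrt_df, lrt_p = x$lrt_p,
    wald_p = x$wald_p,
    concordance = unname(x$fit$concordance["concordance"]),
    separation_flag = x$separation_flag
  )
}

#' Per-sample NOTCH1 mutation dosage from a mutation call table
#'
#' Counts a gene's mutations per sample, sums their variant allele fractions,
#' and bins the count as 0 (WT), 1, or 2+.
#'
#' @param mutations Tibble: sample_id, gene, vaf.
#' @param gene Gene symbol to tally (default `"NOTCH1"`).
#' @param all_samples Optional sample ids to include as zero-count rows.
#' @return Tibble: sample_id, n_mutations, total_vaf, bin (factor 0/1/2+).
#' @export
notch_dosage_table <- function(mutations, gene = "NOTCH1", all_samples = NULL) {
  tab <- mutations |>
    dplyr::filter(.data$gene == !!gene) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_mutations = dplyr::n(), total_vaf = sum(.data$vaf),
                     .groups = "drop")
  if (!is.null(all_samples)) {
    tab <- dplyr::left_join(tibble(sample_id = all_samples), tab,
                            by = "sample_id") |>
      tidyr::replace_na(list(n_mutations = 0L, total_vaf = 0))
  }
  dplyr::mutate(tab, bin = factor(
    dplyr::case_when(.data$n_mutations == 0 ~ "0",
                     .data$n_mutations == 1 ~ "1",
                     TRUE ~ "2+"),
    levels = c("0", "1", "2+")))
}

#' NOTCH1 mutation-dosage association analysis
#'
#' Bins samples by NOTCH1 mutation count (0 = WT, 1, 2+), runs pairwise
#' rank-sum comparisons of signature scores and of total variant allele
#' fraction across bins (empty bins skip their comparisons with a notice),
#' and fits a Cox model of survival on the dosage bin with end-of-induction
#' MRD as covariate.
#'
#' @param records Cohort tibble carrying `notch1_mutation_count`,
#'   `notch1_total_vaf`, the score columns, MRD, and outcome columns.
#' @param score_cols Score columns to compare across bins.
#' @param mrd_col,time,event Column names for the Cox arm.
#' @return List: `binned` (records plus `notch_bin` factor), `score_tests`,
#'   `vaf_tests` (pairwise rank-sum tibbles), and `cox` (`arrest_cox` or NULL
#'   when a bin is empty or events are absent).
#' @export
notch_dosage_analysis <- function(records, score_cols = "zdiff",
                                  mrd_col = "mrd_status",
                                  time = "os_time", event = "os_event") {
  cnt <- records$notch1_mutation_count
  if (is.null(cnt)) rlang::abort("`notch1_mutation_count` column required.")
  bin <- factor(dplyr::case_when(cnt == 0 ~ "0", cnt == 1 ~ "1", TRUE ~ "2+"),
                levels = c("0", "1", "2+"))
  records <- dplyr::mutate(records, notch_bin = bin)
  pairs <- utils::combn(levels(bin), 2, simplify = FALSE)

  pairwise <- function(value_col) {
    purrr::map_dfr(pairs, function(pr) {
      xa <- records[[value_col]][bin == pr[1]]
      xb <- records[[value_col]][bin == pr[2]]
      if (!length(xa) || !length(xb)) {
        rlang::inform(sprintf("Bin %s vs %s skipped for %s: empty bin.",
                              pr[1], pr[2], value_col))
        return(NULL)
      }
      dplyr::mutate(rank_sum_compare(xa, xb),
                    value = value_col, bin_a = pr[1], bin_b = pr[2],
                    median_a = stats::median(xa), median_b = stats::median(xb),
                    .before = 1)
    })
  }
  score_tests <- purrr::map_dfr(score_cols, pairwise)
  vaf_tests <- pairwise("notch1_total_vaf")

  cox <- NULL
  if (all(table(bin) > 0) && sum(records[[event]]) > 0) {
    cox <- cox_fit(records, terms = c("notch_bin", mrd_col),
                   time = time, event = event)
  } else {
    rlang::inform("Dosage Cox fit skipped (empty bin or no events).")
  }
  list(binned = records, score_tests = score_tests,
       vaf_tests = vaf_tests, cox = cox)
}

#' Recurrence filters for mutation and fusion tables
#'
#' Keeps mutated genes observed in at least `min_samples` samples with mean
#' VAF strictly above `min_mean_vaf`, and fusions observed in at least
#' `fusion_min_samples` samples. When a per-sample score table is supplied,
#' each retained gene/fusion is annotated with the mean scores over its
#' carrier samples.
#'
#' @param mutations Tibble: sample_id, gene, vaf.
#' @param fusions Optional tibble: sample_id, fusion.
#' @param scores Optional tibble keyed by sample_id with numeric score
#'   columns (e.g. auc_positive / auc_negative).
#' @param min_samples,min_mean_vaf SNV thresholds (`>=` count, strict `>`
#'   VAF).
#' @param fusion_min_samples Fusion count threshold (`>=`).
#' @return List: `genes`, `fusions` tibbles with carrier counts, mean VAF,
#'   and mean carrier scores.
#' @export
recurrence_filter <- function(mutations, fusions = NULL, scores = NULL,
                              min_samples = 5L, min_mean_vaf = 0.05,
                              fusion_min_samples = 2L) {
  gene_tab <- mutations |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_samples = dplyr::n_distinct(.data$sample_id),
                     mean_vaf = mean(.data$vaf), .groups = "drop") |>
    dplyr::filter(.data$n_samples >= min_samples, .data$mean_vaf > min_mean_vaf)

  annotate <- function(keep_tab, raw_tab, key) {
    if (is.null(scores) || !nrow(keep_tab)) return(keep_tab)
    carrier <- raw_tab |>
      dplyr::filter(.data[[key]] %in% keep_tab[[key]]) |>
      dplyr::distinct(.data[[key]], .data$sample_id) |>
      dplyr::inner_join(scores, by = "sample_id") |>
      dplyr::group_by(.data[[key]]) |>
      dplyr::summarise(dplyr::across(dplyr::where(is.numeric),
                                     \(x) mean(x, na.rm = TRUE),
                                     .names = "mean_{.col}"),
                       .groups = "drop")
    dplyr::left_join(keep_tab, carrier, by = key)
  }
  gene_tab <- annotate(gene_tab, mutations, "gene")

  fusion_tab <- NULL
  if (!is.null(fusions)) {
    fusion_tab <- fusions |>
      dplyr::group_by(.data$fusion) |>
      dplyr::summarise(n_samples = dplyr::n_distinct(.data$sample_id),
                       .groups = "drop") |>
      dplyr::filter(.data$n_samples >= fusion_min_samples)
    fusion_tab <- annotate(fusion_tab, fusions, "fusion")
  }
  list(genes = gene_tab, fusions = fusion_tab)
}
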