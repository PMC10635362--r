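# In-vitro screening decision rules: per-compound activity categories across
# ETP models and the three-comparison nomination of BMP-specific drugs.

#' Categorize compound activity across ETP samples
#'
#' A compound is counted active in a sample when its IC50 is strictly below
#' `active_threshold_nM` (censored measurements — no response at the top
#' dose — count as inactive). Counts over the designated ETP sample set map
#' to categories: 0 active = `not_active`, 1-3 = `partially_active`, all 4 =
#' `active`.
#'
#' @param ic50 Tibble: compound, sample_id, ic50_nM, optional logical
#'   `censored`.
#' @param etp_samples Character vector of the designated ETP sample ids
#'   (default category boundaries assume 4).
#' @param active_threshold_nM Strict activity cutoff in nM.
#' @return Tibble: compound, n_active, n_etp, category.
#' @export
categorize_activity <- function(ic50, etp_samples, active_threshold_nM = 1000) {
  cens <- ic50[["censored"]] %||% rep(FALSE, nrow(ic50))
  ic50 <- dplyr::mutate(ic50,
                        .ic50_eff = ifelse(cens, Inf, .data$ic50_nM))
  etp <- dplyr::filter(ic50, .data$sample_id %in% etp_samples)
  missing <- etp |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(miss = list(setdiff(etp_samples, .data$sample_id)),
                     .groups = "drop") |>
    dplyr::filter(lengths(.data$miss) > 0)
  if (nrow(missing)) {
    rlang::abort(sprintf(
      "Missing IC50 measurement(s): compound %s lacks sample(s) %s.",
      missing$compound[1], paste(missing$miss[[1]], collapse = ", ")))
  }
  n_etp <- length(etp_samples)
  etp |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(n_active = sum(.data$.ic50_eff < active_threshold_nM),
                     .groups = "drop") |>
    dplyr::mutate(
      n_etp = n_etp,
      category = dplyr::case_when(
        .data$n_active == 0 ~ "not_active",
        .data$n_active == n_etp ~ "active",
        TRUE ~ "partially_active"
      ))
}

#' Nominate BMP-specific drugs by the three-comparison rule
#'
#' For each compound that is active or partially active, compares the median
#' IC50 of the BMP-high group against the comparator group in each of the
#' three predefined comparisons; censored IC50s enter the medians as
#' infinite. Differential activity means a strictly lower BMP-high median
#' (optionally by at least `fold_min`-fold); a compound is nominated iff the
#' criterion holds in all three comparisons.
#'
#' @param ic50 Tibble: compound, sample_id, ic50_nM, optional `censored`.
#' @param comparisons List of (usually three) lists with `high` and `low`
#'   character vectors of sample ids.
#' @param categories Output of [categorize_activity()]; compounds categorized
#'   `not_active` are excluded. If NULL, all compounds are eligible.
#' @param fold_min Minimum fold difference low/high medians (default 1 =
#'   any strict difference).
#' @return Tibble: compound, category, median_high_k / median_low_k /
#'   differential_k per comparison, nominated (logical).
#' @export
nominate_bmp_drugs <- function(ic50, comparisons, categories = NULL,
                               fold_min = 1) {
  if (!length(comparisons)) rlang::abort("At least one comparison required.")
  cens <- ic50[["censored"]] %||% rep(FALSE, nrow(ic50))
  ic50 <- dplyr::mutate(ic50, .ic50_eff = ifelse(cens, Inf, .data$ic50_nM))
  compounds <- unique(ic50$compound)
  if (!is.null(categories)) {
    eligible <- categories$compound[categories$category != "not_active"]
    compounds <- intersect(compounds, eligible)
  }
  out <- purrr::map_dfr(compounds, function(cp) {
    sub <- dplyr::filter(ic50, .data$compound == cp)
    row <- tibble(compound = cp)
    ok <- logical(length(comparisons))
    for (k in seq_along(comparisons)) {
      grp <- comparisons[[k]]
      hi <- sub$.ic50_eff[sub$sample_id %in% grp$high]
      lo <- sub$.ic50_eff[sub$sample_id %in% grp$low]
      if (length(hi) < length(grp$high) || length(lo) < length(grp$low) ||
          !length(hi) || !length(lo)) {
        rlang::abort(sprintf(
          "Comparison %d for compound %s has unmeasured group members.", k, cp))
      }
      mh <- stats::median(hi); ml <- stats::median(lo)
      ok[k] <- is.finite(mh) && mh * fold_min < ml
      row[[paste0("median_high_", k)]] <- mh
      row[[paste0("median_low_", k)]] <- ml
      row[[paste0("differential_", k)]] <- ok[k]
    }
    row$nominated <- all(ok)
    row
  })
  if (!is.null(categories)) {
    out <- dplyr::left_join(out, dplyr::select(categories, "compound", "category"),
                            by = "compound") |>
      dplyr::relocate("category", .after = "compound")
  }
  out
}
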