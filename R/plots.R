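# ggplot2 views of the main result types.

#' Plot arrest spectra as a binned heat-strip
#'
#' One row per group, 20 pseudotime bins on the unified axis (myeloid -1 to
#' 0, T 0 to 1), fill = proportion of blasts.
#'
#' @param spectra Tibble from [bin_spectrum()] (one or several groups bound
#'   together).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectra) {
  ggplot(spectra, aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                      y = .data$group_id, fill = .data$proportion)) +
    geom_tile(height = 0.9) +
    scale_fill_viridis_c(name = "Proportion") +
    geom_vline(xintercept = 0, linetype = "dashed", linewidth = 0.3) +
    labs(x = "Unified pseudotime (myeloid − | T +)", y = NULL,
         title = "Developmental arrest spectrum") +
    theme_minimal()
}

#' @rdname plot_spectrum
#' @param object An `arrest_spectrum` tibble.
#' @param ... Unused.
#' @export
autoplot.arrest_spectrum <- function(object, ...) plot_spectrum(object)

#' Kaplan-Meier step plot
#'
#' @param km Tibble from [km_estimate()], optionally with a `group` column
#'   (bind several curves with [dplyr::bind_rows()]).
#' @return A ggplot object.
#' @export
plot_km <- function(km) {
  if (!"group" %in% names(km)) km$group <- "all"
  start <- dplyr::distinct(km, .data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  ggplot(dplyr::bind_rows(start, km),
         aes(.data$time, .data$survival, colour = .data$group)) +
    geom_step() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "Time", y = "Survival probability", colour = NULL) +
    theme_minimal()
}

#' Forest plot of Cox coefficients
#'
#' @param object An `arrest_cox` fit.
#' @param ... Unused.
#' @return A ggplot object of log hazard ratios with 95% Wald intervals.
#' @export
autoplot.arrest_cox <- function(object, ...) {
  td <- tidy(object)
  ggplot(td, aes(.data$estimate, .data$term)) +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$conf_low, xmax = .data$conf_high),
                   height = 0.2) +
    geom_vline(xintercept = 0, linetype = "dashed", linewidth = 0.3) +
    labs(x = "log hazard ratio (95% CI)", y = NULL) +
    theme_minimal()
}

#' Bar chart of top-ranked evidence-ledger genes
#'
#' @param ledger Tibble from [evidence_ledger()].
#' @param top_n Number of genes shown.
#' @return A ggplot object stacking database and DE evidence per gene.
#' @export
plot_ledger <- function(ledger, top_n = 20L) {
  top <- utils::head(dplyr::arrange(ledger, .data$rank), top_n) |>
    dplyr::mutate(gene = factor(.data$gene, levels = rev(.data$gene))) |>
    tidyr::pivot_longer(c("db_total", "de_total"),
                        names_to = "component", values_to = "score")
  ggplot(top, aes(.data$score, .data$gene, fill = .data$component)) +
    geom_col() +
    scale_fill_manual(values = c(db_total = "#31688e", de_total = "#35b779"),
                      labels = c(db_total = "Database (0–5)",
                                 de_total = "DE (0–3)")) +
    labs(x = "Aggregate evidence (0–8)", y = NULL, fill = NULL) +
    theme_minimal()
}
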