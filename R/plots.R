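## ggplot2 figure helpers for the main result types.

#' @describeIn meth_pca Scree plot of variance fractions.
#' @param object A `meth_pca` object.
#' @param n_components Components shown (default: those kept).
#' @export
autoplot.meth_pca <- function(object, n_components = NULL, ...) {
  k <- n_components %||% object$n_components
  df <- tidy(object) |>
    head(k) |>
    mutate(component = factor(.data$component, levels = .data$component))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$var_frac)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "Variance fraction") +
    ggplot2::theme_minimal()
}

#' Heatmap of PC-covariate association p-values
#'
#' Displays `-log10(p)` for every component x covariate pair from
#' [associate_pcs()], the companion panel to the scree plot when deciding
#' which phenotypes drive methylation variance.
#'
#' @param assoc Association tibble from [associate_pcs()].
#' @return A ggplot object.
#' @export
plot_pc_associations <- function(assoc) {
  df <- assoc |>
    mutate(component = factor(.data$component,
                              levels = unique(.data$component)),
           neglog10p = -log10(pmax(.data$p_value, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$covariate,
                                   fill = .data$neglog10p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10](p))) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Methylation of one CpG against passage
#'
#' Beta values of a single probe by passage, coloured by donor with lines
#' connecting samples from the same donor, plus the fitted passage trend —
#' the standard way of displaying an individual drifting CpG.
#'
#' @param beta Beta matrix.
#' @param sheet Sample sheet.
#' @param probe_id Probe to plot.
#' @return A ggplot object.
#' @export
plot_cpg_trend <- function(beta, sheet, probe_id) {
  if (!probe_id %in% rownames(beta)) stop_ctx("probe '%s' not in beta matrix", probe_id)
  df <- tibble(
    sample_id = colnames(beta),
    beta = beta[probe_id, ]
  ) |>
    left_join(sheet, by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$passage, y = .data$beta)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$donor_id), colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$passage)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.6) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Passage", y = "Beta", title = probe_id) +
    ggplot2::theme_minimal()
}

#' @describeIn sampling_enrichment Fold-change bar plot with standard-error
#'   bars across samplings.
#' @param object A `drift_enrichment` tibble.
#' @param ... Unused.
#' @export
autoplot.drift_enrichment <- function(object, ...) {
  df <- as_tibble(object) |>
    filter(!is.na(.data$fold)) |>
    mutate(significant = .data$q_enrich < 0.05 | .data$q_deplete < 0.05)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature, y = .data$fold,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$fold - .data$se_fold,
                                        ymax = .data$fold + .data$se_fold),
                           width = 0.25) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
                               name = "FDR < 0.05") +
    ggplot2::labs(x = NULL, y = "Fold change vs sampled background") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
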