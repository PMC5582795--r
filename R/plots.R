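# ggplot2 views of the main result types.

#' Plot a site posterior profile
#'
#' Needle plot of the per-site posterior probability Q(k) along the
#' reference coordinate, with the calling cutoff drawn as a dashed line and
#' called sites highlighted — the site-specific profile view used to scan
#' for divergent residues.
#'
#' @param object A `site_posterior_profile`.
#' @param cutoff Calling cutoff to display (default 0.67).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot site_posterior_profile
#' @export
autoplot.site_posterior_profile <- function(object, cutoff = 0.67, ...) {
  model <- attr(object, "model") %||% "divergence"
  lab <- if (identical(model, "type2")) "Q[II](k)" else
    if (identical(model, "type1")) "Q[I](k)" else "Q(k)"
  df <- dplyr::mutate(tibble::as_tibble(object), called = .data$Q > cutoff)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ref_pos, y = .data$Q)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$ref_pos, yend = 0,
                                       colour = .data$called),
                          show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "reference position",
                  y = parse(text = lab)[[1]]) +
    ggplot2::theme_minimal()
}

#' Plot an enrichment result
#'
#' Observed vs expected counts of divergent residues inside and outside the
#' binding-site set.
#'
#' @param object An `enrichment_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- tidy(object)
  df <- dplyr::filter(df, .data$divergent == "yes")
  long <- tidyr::pivot_longer(df, c("n", "expected"),
                              names_to = "kind", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$binding, y = .data$count,
                                     fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "inside binding site", y = "divergent residues",
                  fill = NULL,
                  subtitle = sprintf("p = %.3g (%s)", object$p_value,
                                     object$method)) +
    ggplot2::theme_minimal()
}

#' Conservation bar plot for selected sites
#'
#' Modal-residue frequency per cluster at each site, annotated with the
#' modal residue — a compact logo substitute for checking the type-II
#' pattern (conserved within clusters, different between them).
#'
#' @param cons A tibble from [conservation_summary()].
#' @return A ggplot object.
#' @export
plot_conservation <- function(cons) {
  ggplot2::ggplot(cons, ggplot2::aes(x = factor(.data$site),
                                     y = .data$modal_fraction,
                                     fill = .data$cluster)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(ggplot2::aes(label = .data$modal_residue),
                       position = ggplot2::position_dodge(width = 0.9),
                       vjust = -0.3, size = 3) +
    ggplot2::ylim(0, 1.05) +
    ggplot2::labs(x = "site", y = "modal residue fraction", fill = NULL) +
    ggplot2::theme_minimal()
}
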