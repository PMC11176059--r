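# ggplot2 views of the result objects.

#' Forest plot of a decomposition report
#'
#' Standardized estimates with 95\% intervals by trait, faceted by effect
#' type — the usual way trio-model transmission and nurture estimates are
#' displayed.
#'
#' @param object A `decomposition_result` from [build_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decomposition_result <- function(object, ...) {
  d <- dplyr::filter(tibble::as_tibble(object),
                     .data$effect_type %in% c("transmission", "nurture", "direct"))
  d$label <- ifelse(d$effect_type == "nurture",
                    paste0(d$trait, " (", d$parent, ")"), d$trait)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high,
                                          colour = .data$significant)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$effect_type),
                        scales = "free_y", space = "free_y") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00", `FALSE` = "grey30"),
                                 na.value = "grey30") +
    ggplot2::labs(x = "standardized estimate (95% CI)", y = NULL,
                  colour = "q < 0.05") +
    ggplot2::theme_minimal()
}

#' Power curve of a Monte-Carlo power result
#'
#' Rejection proportion against the target effect size with the binomial
#' Monte-Carlo interval as a ribbon.
#'
#' @param object A `power_result` from [run_power()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_result <- function(object, ...) {
  d <- tibble::as_tibble(object)
  sc <- attr(object, "scenario")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$effect, y = .data$power)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mc_low, ymax = .data$mc_high),
                         alpha = 0.2, fill = "#0072B2") +
    ggplot2::geom_line(colour = "#0072B2") +
    ggplot2::geom_point(colour = "#0072B2") +
    ggplot2::geom_hline(yintercept = 0.8, linetype = 2, colour = "grey50") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = sprintf("true %s effect (standardized)",
                              sc$target %||% "target"),
                  y = "power", title = sprintf("n = %s trios, %s correction",
                                               format(sc$n_trios, big.mark = ","),
                                               toupper(sc$correction))) +
    ggplot2::theme_minimal()
}

#' Heatmap of a mixed correlation matrix
#'
#' @param object A `mixed_cor` from [mixed_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mixed_cor <- function(object, ...) {
  R <- object$R
  d <- tibble::as_tibble(as.data.frame(as.table(R)), .name_repair = "minimal")
  names(d) <- c("var1", "var2", "r")
  d$var2 <- factor(d$var2, levels = rev(colnames(R)))
  ggplot2::ggplot(d, ggplot2::aes(.data$var1, .data$var2, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC",
                                  mid = "white", high = "#B2182B") +
    ggplot2::labs(x = NULL, y = NULL, fill = "correlation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
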