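# ggplot2 layers for the result types.

#' @importFrom ggplot2 ggplot aes geom_tile geom_text geom_col geom_point
#'   geom_line geom_errorbar geom_abline facet_wrap labs scale_fill_gradient
#'   position_dodge theme_minimal ylim
NULL

#' Plot a model-recovery confusion matrix
#'
#' @param object A `coop_confusion` from [model_recovery()].
#' @param ... Unused.
#' @return A ggplot: generator model against best-fitting model, tile
#'   shade giving the proportion of datasets.
#' @export
autoplot.coop_confusion <- function(object, ...) {
  d <- tidy(object)
  d$generator <- factor(d$generator, levels = rev(rownames(object$matrix)))
  d$fitted <- factor(d$fitted, levels = colnames(object$matrix))
  ggplot(d, aes(x = .data$fitted, y = .data$generator, fill = .data$prop)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$prop)), size = 3) +
    scale_fill_gradient(low = "white", high = "steelblue4", limits = c(0, 1)) +
    labs(x = "best-fitting model", y = "generative model",
         fill = "proportion") +
    theme_minimal()
}

#' Plot group-level model-selection results
#'
#' @param object A `coop_bms` from [group_bms()].
#' @param ... Unused.
#' @return A ggplot of protected exceedance probability per model.
#' @export
autoplot.coop_bms <- function(object, ...) {
  d <- tidy(object)
  d$model <- factor(d$model, levels = d$model)
  ggplot(d, aes(x = .data$model, y = .data$pep)) +
    geom_col(fill = "steelblue4") +
    ylim(0, 1) +
    labs(x = NULL, y = "protected exceedance probability") +
    theme_minimal()
}

#' Plot parameter recovery
#'
#' @param object A `coop_recovery` from [parameter_recovery()].
#' @param ... Unused.
#' @return A ggplot of recovered against generating values, one facet per
#'   parameter, with the identity line and the Pearson r.
#' @export
autoplot.coop_recovery <- function(object, ...) {
  lab <- object$correlations |>
    mutate(label = sprintf("r = %.2f", .data$r))
  ggplot(filter(object$pairs, .data$converged),
         aes(x = .data$true, y = .data$recovered)) +
    geom_abline(linetype = 2, colour = "grey60") +
    geom_point(alpha = 0.6, size = 1) +
    facet_wrap(~param, scales = "free") +
    geom_text(data = lab, aes(label = .data$label),
              x = -Inf, y = Inf, hjust = -0.2, vjust = 1.5,
              inherit.aes = FALSE) +
    labs(x = "generating value", y = "recovered value") +
    theme_minimal()
}

#' Conditional-means group figure
#'
#' Group mean with across-participant standard error of the dependent
#' variable after runs of partner cooperation/defection, in the style of
#' the conditional-cooperation panels.
#'
#' @param cond_tbl Per-participant table from [conditional_means()] (a
#'   `group` column is used for colour when present).
#' @return A ggplot faceted by conditioning partner action.
#' @export
plot_conditional_means <- function(cond_tbl) {
  s <- conditional_summary(cond_tbl)
  has_group <- "group" %in% names(s)
  mapping <- if (has_group) {
    aes(x = factor(.data$k), y = .data$mean, colour = .data$group,
        group = .data$group)
  } else {
    aes(x = factor(.data$k), y = .data$mean, group = 1)
  }
  ggplot(s, mapping) +
    geom_line(position = position_dodge(0.2)) +
    geom_point(position = position_dodge(0.2)) +
    geom_errorbar(aes(ymin = .data$mean - .data$se,
                      ymax = .data$mean + .data$se),
                  width = 0.15, position = position_dodge(0.2)) +
    facet_wrap(~partner_action,
               labeller = ggplot2::labeller(
                 partner_action = c(C = "after partner cooperation",
                                    D = "after partner defection"))) +
    labs(x = "run length k of consistent partner action",
         y = unique(s$variable)) +
    theme_minimal()
}
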