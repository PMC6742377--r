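# ggplot2 visualisations: loading heatmaps, partial-correlation tiles,
# effect-decomposition bars, and a path diagram for fitted models.

#' @importFrom ggplot2 ggplot aes autoplot geom_tile geom_text geom_col
#'   geom_segment geom_label scale_fill_gradient2 facet_wrap labs
#'   position_dodge theme_minimal theme element_blank arrow unit
NULL

#' @export
ggplot2::autoplot

#' Heatmap of rotated factor loadings
#'
#' @param object A `factor_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.factor_model <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(dplyr::starts_with("factor"),
                        names_to = "factor", values_to = "loading")
  ggplot(d, aes(x = .data$factor, y = .data$snp_id, fill = .data$loading)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$loading)), size = 3) +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(title = sprintf("Block %s: varimax-rotated loadings", object$block_id),
         x = NULL, y = NULL) +
    theme_minimal()
}

#' Tile map of a partial-correlation matrix
#'
#' @param object A `partial_cor`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.partial_cor <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$var1, y = .data$var2, fill = .data$estimate)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.3f", .data$estimate)), size = 3) +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL,
         title = sprintf("Partial correlations given {%s}",
                         paste(object$covariates, collapse = ", "))) +
    theme_minimal()
}

#' Bar chart of the standardized effect decomposition
#'
#' Direct, indirect, and total standardized effects per source variable,
#' faceted by endogenous target.
#'
#' @param object An `effect_table` from [effect_decomposition()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.effect_table <- function(object, ...) {
  d <- object |>
    as_tibble() |>
    select("source", "target", "direct", "indirect", "total") |>
    tidyr::pivot_longer(c("direct", "indirect", "total"),
                        names_to = "component", values_to = "effect")
  ggplot(d, aes(x = .data$source, y = .data$effect, fill = .data$component)) +
    geom_col(position = position_dodge()) +
    facet_wrap(~ .data$target, scales = "free_x") +
    labs(x = NULL, y = "standardized effect") +
    theme_minimal() +
    theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Path diagram of a fitted structural model
#'
#' Variables are placed on columns by topological depth; edges are labelled
#' with standardized estimates, dashed when p >= 0.05.
#'
#' @param object A `sem_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sem_fit <- function(object, ...) {
  vars <- object$ram$variables
  edges <- filter(object$parameters, .data$type == "path")
  depth <- setNames(integer(length(vars)), vars)
  for (v in vars) {
    parents <- edges$from[edges$to == v]
    if (length(parents) > 0) depth[v] <- max(depth[parents]) + 1L
  }
  nodes <- tibble(name = vars, x = as.numeric(depth[vars])) |>
    group_by(.data$x) |>
    mutate(y = seq_len(dplyr::n()) - (dplyr::n() + 1) / 2) |>
    ungroup()
  ed <- edges |>
    left_join(nodes, by = c(from = "name")) |>
    rename(x0 = "x", y0 = "y") |>
    left_join(nodes, by = c(to = "name")) |>
    mutate(significant = !is.na(.data$p_value) & .data$p_value < 0.05)
  ggplot() +
    geom_segment(data = ed,
                 aes(x = .data$x0, y = .data$y0, xend = .data$x,
                     yend = .data$y, linetype = .data$significant),
                 arrow = arrow(length = unit(2, "mm")), alpha = 0.6) +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid", `FALSE` = "dashed"),
                                   guide = "none") +
    geom_label(data = ed,
               aes(x = (.data$x0 + .data$x) / 2, y = (.data$y0 + .data$y) / 2,
                   label = sprintf("%.3f", .data$std_estimate)), size = 2.7) +
    geom_label(data = nodes, aes(x = .data$x, y = .data$y, label = .data$name),
               fontface = "bold") +
    theme_minimal() +
    theme(axis.text = element_blank(), axis.title = element_blank(),
          panel.grid = element_blank())
}
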