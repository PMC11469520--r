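#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot reward-per-episode traces of a trained ensemble
#'
#' @param object A `q_ensemble`.
#' @param ... Unused.
#' @return A ggplot: final episode reward vs episode, one line per member,
#'   with the exploration schedule overlaid.
#' @export
autoplot.q_ensemble <- function(object, ...) {
  tr <- tidy(object)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$episode)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$final_reward,
                                    colour = factor(.data$member)),
                       alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$epsilon),
                       linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "episode", y = "terminal reward (F1)",
                  colour = "member",
                  title = "Q-learning progress",
                  subtitle = "dashed: exploration probability") +
    ggplot2::theme_minimal()
}

#' Plot per-molecule screening outcome
#'
#' @param object A `screen_result`.
#' @param ... Unused.
#' @return A ggplot bar chart of matched/unmatched by activity label.
#' @export
autoplot.screen_result <- function(object, ...) {
  pm <- object$per_molecule
  pm$label <- ifelse(pm$is_active, "active", "decoy")
  pm$outcome <- ifelse(pm$matched, "matched", "unmatched")
  ggplot2::ggplot(pm, ggplot2::aes(x = .data$label, fill = .data$outcome)) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::labs(x = NULL, y = "molecules",
                  title = sprintf("F1 = %.3f, EF = %.2f",
                                  object$metrics$f1,
                                  object$metrics$enrichment_factor)) +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a confidence grid
#'
#' @param grid A `confidence_grid` from [evaluate_grid()].
#' @param class Feature class to display.
#' @param k Slice index along z (default: middle).
#' @return A ggplot tile map of the confidence slice.
#' @export
plot_grid_slice <- function(grid, class = "HydrogenAcceptor", k = NULL) {
  assert_class(class)
  ci <- class_code(class) + 1L
  d <- dim(grid$values)
  if (is.null(k)) k <- ceiling(d[3] / 2)
  sl <- grid$values[, , k, ci]
  df <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
  df$x <- grid$origin[1] + (df$i - 1) * grid$spacing
  df$y <- grid$origin[2] + (df$j - 1) * grid$spacing
  df$confidence <- sl[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$confidence)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(title = paste0(class, " confidence (z-slice ", k, ")"),
                  x = "x (A)", y = "y (A)") +
    ggplot2::theme_minimal()
}
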