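#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an embedded affect landscape
#'
#' Scatter of the embedded image coordinates, coloured by emotion category
#' (parsed from the image identifier prefix unless a design is supplied).
#'
#' @param object A [embed_landscape()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot landscape_embedding
#' @export
autoplot.landscape_embedding <- function(object, ...) {
  df <- object$coordinates
  df$category <- sub("_[0-9]+$", "", df$image)
  ggplot2::ggplot(
    df,
    ggplot2::aes(.data$dim1, .data$dim2, colour = .data$category)
  ) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "dimension 1", y = "dimension 2", colour = NULL,
      title = "Affect landscape",
      subtitle = sprintf("stress-1 = %.3g", object$stress)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fitted structural model as a path diagram
#'
#' Nodes (latents and manifests) on a circle, structural paths as arrows
#' labelled with their standardized coefficients.
#'
#' @param object An `affectmap_sem` fit.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot affectmap_sem
#' @export
autoplot.affectmap_sem <- function(object, ...) {
  vars <- c(object$layout$manifest, object$layout$latents)
  n <- length(vars)
  ang <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  nodes <- tibble::tibble(
    var = vars, x = cos(ang), y = sin(ang),
    kind = ifelse(vars %in% object$layout$latents, "latent", "manifest")
  )
  paths <- object$estimates |>
    dplyr::filter(.data$type == "path") |>
    tidyr::separate_wider_delim(
      "term",
      delim = " -> ", names = c("from", "to"), cols_remove = FALSE
    ) |>
    dplyr::left_join(
      dplyr::select(nodes, "var", x0 = "x", y0 = "y"),
      by = c(from = "var")
    ) |>
    dplyr::left_join(
      dplyr::select(nodes, "var", x1 = "x", y1 = "y"),
      by = c(to = "var")
    ) |>
    dplyr::mutate(
      # pull arrow ends off the node markers
      xs = .data$x0 + 0.12 * (.data$x1 - .data$x0),
      ys = .data$y0 + 0.12 * (.data$y1 - .data$y0),
      xe = .data$x1 - 0.12 * (.data$x1 - .data$x0),
      ye = .data$y1 - 0.12 * (.data$y1 - .data$y0)
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = paths,
      ggplot2::aes(
        x = .data$xs, y = .data$ys, xend = .data$xe, yend = .data$ye
      ),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.18, "cm")),
      colour = "grey40"
    ) +
    ggplot2::geom_label(
      data = paths,
      ggplot2::aes(
        x = (.data$xs + .data$xe) / 2, y = (.data$ys + .data$ye) / 2,
        label = sprintf("%.2f", .data$std_beta)
      ),
      size = 3
    ) +
    ggplot2::geom_label(
      data = nodes,
      ggplot2::aes(.data$x, .data$y, label = .data$var, fill = .data$kind),
      colour = "black", show.legend = FALSE
    ) +
    ggplot2::scale_fill_manual(
      values = c(latent = "#cfe8ff", manifest = "#e8e8e8")
    ) +
    ggplot2::coord_equal(xlim = c(-1.4, 1.4), ylim = c(-1.3, 1.3)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Structural model (standardized paths)")
}

#' Histograms of participant-level scores
#'
#' @param scores Wide score table from [score_cohort()].
#' @param vars Columns to plot; defaults to the headline measures present.
#' @return A ggplot, faceted by measure.
#' @export
plot_score_distributions <- function(scores, vars = NULL) {
  if (is.null(vars)) {
    vars <- intersect(
      c(
        "emotional_consistency", "mean_rep_consistency",
        "matching_difficulty", "representation_matching",
        "accuracy", "mean_between", "mean_within"
      ),
      names(scores)
    )
  }
  long <- tidyr::pivot_longer(
    scores[, vars],
    dplyr::all_of(vars),
    names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 25, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~measure, scales = "free") +
    ggplot2::labs(x = NULL, y = "participants") +
    ggplot2::theme_minimal()
}
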