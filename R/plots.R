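#' Plot TI curves
#'
#' One line per curve, faceted by material. Useful for eyeballing raw
#' replicates, smoothed replicates or per-material average curves.
#'
#' @param curves Long curve table; a `material_id` column is required,
#'   `panelist_id`/`replicate` are used for line grouping when present.
#' @return A ggplot object.
#' @export
plot_ti_curves <- function(curves) {
  curves <- require_columns(curves, c("material_id", "time_s", "intensity"))
  grp <- interaction(
    curves$material_id,
    if ("panelist_id" %in% names(curves)) curves$panelist_id else "",
    if ("replicate" %in% names(curves)) curves$replicate else ""
  )
  ggplot2::ggplot(
    curves,
    ggplot2::aes(x = .data$time_s, y = .data$intensity, group = grp)
  ) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$material_id)) +
    ggplot2::labs(x = "time (s)", y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot masking scores in descending order
#'
#' @param masking Masking-score table from [masking_scores()].
#' @param materials Optional material metadata; when given, bars are
#'   colored by material type.
#' @return A ggplot object.
#' @export
plot_masking_scores <- function(masking, materials = NULL) {
  masking <- require_columns(masking, c("material_id", "masking_score"))
  df <- dplyr::arrange(masking, dplyr::desc(.data$masking_score))
  df$material_id <- factor(df$material_id, levels = df$material_id)
  p <- ggplot2::ggplot(
    df, ggplot2::aes(x = .data$material_id, y = .data$masking_score)
  )
  if (!is.null(materials)) {
    materials <- require_columns(materials, c("material_id", "mtype"))
    df <- dplyr::left_join(df, materials[c("material_id", "mtype")],
                           by = "material_id")
    p <- ggplot2::ggplot(
      df,
      ggplot2::aes(
        x = .data$material_id, y = .data$masking_score, fill = .data$mtype
      )
    )
  }
  p +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "masking score (10-point scale)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @describeIn classify_materials PCA1--PCA2 scatter of the materials,
#'   colored by cluster label.
#' @param object A `ti_cluster_model`.
#' @param ... Unused.
#' @export
autoplot.ti_cluster_model <- function(object, ...) {
  df <- dplyr::inner_join(object$scores, object$labels, by = "material_id")
  evr <- object$pca$explained_variance_ratio
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$PC1, y = .data$PC2, color = factor(.data$cluster)
    )
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PCA1 (%.1f%%)", 100 * evr[1]),
      y = sprintf("PCA2 (%.1f%%)", 100 * evr[2]),
      color = "cluster"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
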