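#' Tidy a fitted TI cluster model
#'
#' @param x A `ti_cluster_model` from [classify_materials()].
#' @param ... Unused.
#' @return One row per material: `material_id`, `PC1`, `PC2`, `cluster`
#'   and, when masking scores were supplied, `masking_score`.
#' @export
tidy.ti_cluster_model <- function(x, ...) {
  out <- dplyr::inner_join(
    x$scores[, c("material_id", "PC1", "PC2")], x$labels,
    by = "material_id"
  )
  if (!is.null(x$masking)) {
    out <- dplyr::left_join(
      out, x$masking[, c("material_id", "masking_score")],
      by = "material_id"
    )
  }
  out
}

#' @rdname tidy.ti_cluster_model
#' @return For `glance()`, a one-row model summary: `k`, `n`, `inertia`,
#'   the variance shares of the first two components and the seed.
#' @export
glance.ti_cluster_model <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n = nrow(x$labels),
    inertia = x$inertia,
    evr_pc1 = x$pca$explained_variance_ratio[1],
    evr_pc2 = x$pca$explained_variance_ratio[2],
    seed = x$seed
  )
}

#' Tidy PCA loadings into long format
#'
#' @param x A `ti_pca` object from [pca_fit()].
#' @param ... Unused.
#' @return Long tibble `parameter`, `component`, `loading`.
#' @export
tidy.ti_pca <- function(x, ...) {
  l <- x$loadings
  tibble::tibble(
    parameter = rep(rownames(l), ncol(l)),
    component = rep(colnames(l), each = nrow(l)),
    loading = as.vector(l)
  )
}
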