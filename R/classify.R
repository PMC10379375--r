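#' Principal component analysis of a standardized parameter matrix
#'
#' PCA via the singular value decomposition of the centered matrix.
#' Loadings (one unit-norm column per component) follow the sign
#' convention that the largest-magnitude loading within each component is
#' positive; scores are the data projected onto the loadings. Explained
#' variance ratios are reported over all components and sum to 1.
#'
#' Input is expected to come from [standardize_parameters()]; raw-scale
#' PCA must be requested explicitly with `allow_unstandardized = TRUE`
#' (useful to probe how variance-dominant parameters such as the large
#' phase areas behave without standardization).
#'
#' @param matrix Standardized parameter tibble; more rows than columns.
#' @param n_components Number of leading components reported as scores
#'   (default 2; loadings and variance ratios cover all components).
#' @param allow_unstandardized Set `TRUE` to permit raw-scale input.
#' @return Object of class `ti_pca`: list with `loadings` (parameters x
#'   components), `explained_variance_ratio`, `scores` (tibble
#'   `material_id`, `PC1`, ...), `center`, `n_components`.
#' @export
pca_fit <- function(matrix, n_components = 2, allow_unstandardized = FALSE) {
  if (!is_standardized(matrix) && !allow_unstandardized) {
    abort(paste(
      "pca_fit(): input is not standardized;",
      "run standardize_parameters() first or set allow_unstandardized = TRUE"
    ))
  }
  x <- parameter_values(matrix)
  if (nrow(x) <= ncol(x)) {
    abort("pca_fit(): need more materials (rows) than parameters (columns)")
  }
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  loadings <- fit$rotation
  scores <- fit$x
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  evr <- fit$sdev^2 / sum(fit$sdev^2)
  structure(
    list(
      loadings = loadings,
      explained_variance_ratio = evr,
      scores = tibble::tibble(
        material_id = rownames(x),
        !!!as.data.frame(scores)
      ),
      center = fit$center,
      n_components = n_components
    ),
    class = "ti_pca"
  )
}

#' Seeded k-means clustering with k-means++ initialization
#'
#' Runs `n_init` restarts of Lloyd's algorithm, each started from
#' k-means++ seeded centers, and keeps the solution with the lowest
#' within-cluster sum of squares (inertia). Fully reproducible for a
#' given seed.
#'
#' Raw k-means labels are permutation-arbitrary, so clusters are relabeled
#' deterministically 0..k-1: when masking scores are supplied, by
#' increasing mean masking score of the members (cluster k-1 is always the
#' highest-masking cluster); otherwise by increasing first-coordinate
#' centroid.
#'
#' @param scores Tibble with `material_id` plus numeric coordinate columns
#'   (e.g. the `PC1`/`PC2` scores of [pca_fit()]), or a numeric matrix.
#' @param k Number of clusters; `k <= n`.
#' @param seed Integer seed.
#' @param n_init Number of k-means++ restarts.
#' @param masking Optional masking-score table used for deterministic
#'   relabeling.
#' @return Object of class `ti_kmeans`: list with `labels` (tibble
#'   `material_id`, `cluster`), `centers`, `inertia`, `k`, `seed`.
#' @export
kmeans_fit <- function(scores, k = 3, seed = 1L, n_init = 10, masking = NULL) {
  if (is.data.frame(scores)) {
    x <- parameter_values(scores)
  } else {
    x <- as.matrix(scores)
    if (is.null(rownames(x))) {
      rownames(x) <- as.character(seq_len(nrow(x)))
    }
  }
  n <- nrow(x)
  if (k > n) {
    abort(sprintf("kmeans_fit(): k = %d exceeds the number of materials (%d)", k, n))
  }
  if (k < 1) {
    abort("kmeans_fit(): k must be >= 1")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(as.integer(seed))
  best <- NULL
  for (i in seq_len(n_init)) {
    centers <- kmeanspp_centers(x, k)
    fit <- tryCatch(
      suppressWarnings(
        kmeans(x, centers = centers, iter.max = 100, algorithm = "Lloyd")
      ),
      error = function(e) NULL  # a restart can die on an emptied cluster
    )
    if (!is.null(fit) &&
        (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    abort("kmeans_fit(): no restart converged to k non-empty clusters")
  }
  raw <- best$cluster

  # deterministic relabeling: 0 .. k-1 with k-1 the highest-ranked cluster
  key <- if (!is.null(masking)) {
    masking <- require_columns(masking, c("material_id", "masking_score"))
    ms <- masking$masking_score[match(rownames(x), masking$material_id)]
    vapply(seq_len(k), function(c) mean(ms[raw == c]), numeric(1))
  } else {
    best$centers[, 1]
  }
  new_label <- integer(k)
  new_label[order(key)] <- seq_len(k) - 1L
  labels <- new_label[raw]
  centers <- best$centers[order(key), , drop = FALSE]
  rownames(centers) <- as.character(seq_len(k) - 1L)

  structure(
    list(
      labels = tibble::tibble(material_id = rownames(x), cluster = labels),
      centers = centers,
      inertia = best$tot.withinss,
      k = k,
      seed = as.integer(seed)
    ),
    class = "ti_kmeans"
  )
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx[j] <- sample.int(n, 1, prob = prob)
      d2 <- pmin(d2, rowSums((x - matrix(x[idx[j], ], n, ncol(x), byrow = TRUE))^2))
    }
  }
  x[idx, , drop = FALSE] + 0  # force a plain matrix of k rows
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Classify materials by their TI profiles: PCA + seeded k-means
#'
#' Standardized PCA followed by k-means (default k = 3) on the PCA1--PCA2
#' score plane (`cluster_space = "full"` clusters in the full standardized
#' space instead). Clusters are relabeled so that the highest-masking
#' cluster always carries the largest label.
#'
#' @param params Parameter tibble (raw scale; retained parameters).
#' @param masking Masking-score table (used for relabeling and
#'   summaries).
#' @param k Number of clusters.
#' @param seed Integer seed for k-means.
#' @param n_init Number of k-means++ restarts.
#' @param cluster_space `"pca"` (default) or `"full"`.
#' @return Object of class `ti_cluster_model`: list with the `ti_pca` fit
#'   (`pca`), the `ti_kmeans` fit (`kmeans`), `labels`, `scores`, `k`,
#'   `seed`, `inertia` and the `masking` table.
#' @export
classify_materials <- function(params, masking, k = 3, seed = 1L, n_init = 10,
                               cluster_space = c("pca", "full")) {
  cluster_space <- match.arg(cluster_space)
  std <- standardize_parameters(params)
  pca <- pca_fit(std, n_components = 2)
  space <- if (cluster_space == "pca") {
    pca$scores[, c("material_id", "PC1", "PC2")]
  } else {
    std
  }
  km <- kmeans_fit(space, k = k, seed = seed, n_init = n_init, masking = masking)
  structure(
    list(
      pca = pca,
      kmeans = km,
      labels = km$labels,
      scores = pca$scores,
      k = k,
      seed = as.integer(seed),
      inertia = km$inertia,
      masking = masking,
      cluster_space = cluster_space
    ),
    class = "ti_cluster_model"
  )
}

#' Per-cluster masking summary with a top-cluster significance test
#'
#' Reports each cluster's size, mean masking score (full precision; round
#' for display) and members, and tests the highest-masking cluster
#' against all remaining materials with the two-tailed Mann-Whitney U
#' test. With a single cluster the test is skipped with a notice.
#'
#' @param model A `ti_cluster_model`, or a labels tibble
#'   (`material_id`, `cluster`).
#' @param masking Masking-score table; defaults to the table stored in
#'   the model.
#' @return List with `clusters` (tibble `cluster`, `n`,
#'   `mean_masking_score`, `members`), `test` (one-row tibble from
#'   [mann_whitney_u()] plus `cluster`, or `NULL`) and `note`.
#' @export
summarize_clusters <- function(model, masking = NULL) {
  if (inherits(model, "ti_cluster_model")) {
    labels <- model$labels
    masking <- masking %||% model$masking
  } else {
    labels <- require_columns(model, c("material_id", "cluster"))
  }
  masking <- require_columns(masking, c("material_id", "masking_score"))
  joined <- dplyr::inner_join(labels, masking, by = "material_id")
  if (nrow(joined) != nrow(labels)) {
    abort("summarize_clusters(): labels and masking scores are not aligned")
  }
  clusters <- joined |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_masking_score = mean(.data$masking_score),
      members = list(sort(.data$material_id)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cluster)
  if (nrow(clusters) < 2) {
    return(list(
      clusters = clusters, test = NULL,
      note = "single cluster: top-vs-rest test skipped"
    ))
  }
  top_cluster <- clusters$cluster[which.max(clusters$mean_masking_score)]
  in_top <- joined$cluster == top_cluster
  test <- mann_whitney_u(
    joined$masking_score[in_top], joined$masking_score[!in_top]
  )
  test$cluster <- top_cluster
  list(clusters = clusters, test = test, note = NULL)
}

#' Ranked first-component loading report
#'
#' Ranks the parameters by the magnitude of their first-component loading
#' and reports the ratio of the two largest magnitudes -- a quick reading
#' of how dominant the leading parameter is. Magnitudes are unaffected by
#' the arbitrary sign of a component.
#'
#' @param model A `ti_cluster_model` or `ti_pca` object.
#' @return Tibble `parameter`, `loading_pc1`, `abs_loading`, `rank`,
#'   sorted by decreasing magnitude, with attribute `ratio_top2`.
#' @export
loading_report <- function(model) {
  pca <- if (inherits(model, "ti_cluster_model")) model$pca else model
  if (!inherits(pca, "ti_pca")) {
    abort("loading_report(): expected a ti_cluster_model or ti_pca object")
  }
  l1 <- pca$loadings[, 1]
  out <- tibble::tibble(
    parameter = names(l1),
    loading_pc1 = unname(l1),
    abs_loading = abs(unname(l1))
  ) |>
    dplyr::arrange(dplyr::desc(.data$abs_loading), .data$parameter) |>
    dplyr::mutate(rank = dplyr::row_number())
  ratio <- if (nrow(out) >= 2 && out$abs_loading[2] > 0) {
    out$abs_loading[1] / out$abs_loading[2]
  } else {
    NA_real_
  }
  attr(out, "ratio_top2") <- ratio
  out
}
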