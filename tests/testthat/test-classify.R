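random_std_matrix <- function(n = 30, p = 5, seed = 61) {
  withr::with_seed(seed, {
    m <- tibble::tibble(material_id = sprintf("m%02d", 1:n))
    cols <- ti_parameter_names()[seq_len(p)]
    for (cl in cols) {
      m[[cl]] <- stats::rnorm(n)
    }
    standardize_parameters(m)
  })
}

test_that("PCA handles the rank-1 case and refuses raw-scale input silently", {
  m <- tibble::tibble(
    material_id = sprintf("m%d", 1:6),
    Imax = c(1, 2, 3, 4, 5, 6)
  )
  m$AreaDec <- m$Imax  # data on the line y = x
  fit <- pca_fit(standardize_parameters(m))
  expect_equal(fit$explained_variance_ratio, c(1, 0), tolerance = 1e-12)
  expect_equal(abs(unname(fit$loadings[, 1])), rep(1 / sqrt(2), 2),
               tolerance = 1e-12)
  # sign convention: the dominant loading is positive
  expect_gt(max(fit$loadings[, 1]), 0)

  expect_error(pca_fit(m), "not standardized")
  expect_s3_class(pca_fit(m, allow_unstandardized = TRUE), "ti_pca")
})

test_that("PCA scores are uncorrelated and reconstruct the data", {
  std <- random_std_matrix()
  fit <- pca_fit(std)
  sc <- as.matrix(fit$scores[, -1])
  expect_equal(abs(cov(sc[, 1], sc[, 2])), 0, tolerance = 1e-9)
  # variance ratios: non-negative, non-increasing, summing to 1
  evr <- fit$explained_variance_ratio
  expect_true(all(evr >= 0))
  expect_true(all(diff(evr) <= 1e-12))
  expect_equal(sum(evr), 1, tolerance = 1e-12)
  # unit-norm loading columns; full reconstruction
  expect_equal(colSums(fit$loadings^2), rep(1, ncol(fit$loadings)),
               tolerance = 1e-12, ignore_attr = TRUE)
  recon <- sc %*% t(fit$loadings) + rep(fit$center, each = nrow(sc))
  expect_equal(unname(recon), unname(as.matrix(std[, -1])), tolerance = 1e-9)
})

test_that("k-means recovers well-separated triplets at the brute-force optimum", {
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  withr::with_seed(71, {
    x <- do.call(rbind, lapply(1:3, function(i) {
      sweep(matrix(stats::rnorm(6, sd = 0.3), 3, 2), 2, centers[i, ], `+`)
    }))
  })
  rownames(x) <- sprintf("m%d", 1:9)
  fit <- kmeans_fit(x, k = 3, seed = 5)
  oracle <- enumerate_kmeans(x, 3)
  expect_equal(fit$inertia, oracle$wss, tolerance = 1e-9)
  # same partition (co-membership agrees pairwise, labels up to permutation)
  co <- function(lab) outer(lab, lab, `==`)
  expect_equal(co(fit$labels$cluster), co(oracle$labels))
  truth <- rep(1:3, each = 3)
  expect_equal(co(fit$labels$cluster), co(truth))
})

test_that("k-means is deterministic, monotone in k, and validates k", {
  std <- random_std_matrix(n = 25, p = 4, seed = 63)
  f1 <- kmeans_fit(std, k = 3, seed = 42)
  f2 <- kmeans_fit(std, k = 3, seed = 42)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$inertia, f2$inertia)

  inertias <- vapply(
    1:5, function(k) kmeans_fit(std, k = k, seed = 42)$inertia, numeric(1)
  )
  expect_true(all(diff(inertias) <= 1e-9))

  fn <- kmeans_fit(std, k = nrow(std), seed = 1)
  expect_equal(fn$inertia, 0, tolerance = 1e-12)
  expect_error(kmeans_fit(std, k = 26, seed = 1), "exceeds")
})

test_that("clusters are relabeled by mean masking score, highest last", {
  x <- rbind(matrix(0, 4, 2), matrix(5, 4, 2) + 0.01 * 1:8,
             matrix(20, 4, 2))
  rownames(x) <- sprintf("m%d", 1:12)
  masking <- tibble::tibble(
    material_id = rownames(x),
    masking_score = c(rep(9, 4), rep(2, 4), rep(5, 4))
  )
  fit <- kmeans_fit(x, k = 3, seed = 3, masking = masking)
  lab <- fit$labels$cluster
  # cluster k-1 = highest-masking members (m1-m4)
  expect_equal(unique(lab[1:4]), 2L)
  expect_equal(unique(lab[5:8]), 0L)
  expect_equal(unique(lab[9:12]), 1L)

  # without masking: relabeled by first-coordinate centroid
  fit2 <- kmeans_fit(x, k = 3, seed = 3)
  lab2 <- fit2$labels$cluster
  expect_equal(unique(lab2[1:4]), 0L)
  expect_equal(unique(lab2[9:12]), 2L)
})

test_that("cluster summaries report means and an exact top-vs-rest test", {
  labels <- tibble::tibble(
    material_id = sprintf("m%02d", 1:20),
    cluster = rep(c(1L, 0L), c(8, 12))
  )
  masking <- tibble::tibble(
    material_id = labels$material_id,
    masking_score = c(seq(8, 9.4, length.out = 8), seq(2, 6, length.out = 12))
  )
  s <- summarize_clusters(labels, masking)
  expect_equal(s$clusters$n, c(12L, 8L))
  expect_equal(s$test$cluster, 1L)
  expect_equal(s$test$U, 0)
  expect_equal(s$test$p_two_tailed, 2 / choose(20, 8))
  expect_lt(s$test$p_two_tailed, 0.05)

  one <- summarize_clusters(
    dplyr::mutate(labels, cluster = 0L), masking
  )
  expect_null(one$test)
  expect_match(one$note, "single cluster")
  expect_equal(one$clusters$mean_masking_score, mean(masking$masking_score))
})

test_that("loading report ranks magnitudes and reports the top-two ratio", {
  fake <- structure(
    list(loadings = matrix(
      c(0.167, 0.985, 0.167, -0.985), 2, 2,
      dimnames = list(c("AreaInc", "AreaDec"), c("PC1", "PC2"))
    )),
    class = "ti_pca"
  )
  rep1 <- loading_report(fake)
  expect_equal(rep1$parameter, c("AreaDec", "AreaInc"))
  expect_equal(round(attr(rep1, "ratio_top2"), 1), 5.9)

  # magnitudes are sign-invariant
  fake$loadings[, 1] <- -fake$loadings[, 1]
  rep2 <- loading_report(fake)
  expect_equal(rep2$abs_loading, rep1$abs_loading)

  eq <- structure(
    list(loadings = matrix(0.5, 4, 1,
                           dimnames = list(letters[1:4], "PC1"))),
    class = "ti_pca"
  )
  expect_equal(attr(loading_report(eq), "ratio_top2"), 1)
})

test_that("raw-scale PCA is dominated by the decreasing-phase area", {
  # on a study-structured matrix the variance of AreaDec (~1e6 a.u.^2 s^2)
  # dwarfs every other parameter, so unstandardized PCA concentrates on it:
  # near-total first-component variance and a near-unit AreaDec loading,
  # with AreaInc the only other visible contributor. Standardization
  # removes this dominance entirely.
  pruned <- prune_correlated(standin_parameter_matrix())
  raw <- pca_fit(pruned$matrix, allow_unstandardized = TRUE)
  expect_gt(raw$explained_variance_ratio[1], 0.96)
  expect_gt(abs(raw$loadings["AreaDec", 1]), 0.95)
  lr <- loading_report(raw)
  expect_equal(lr$parameter[1:2], c("AreaDec", "AreaInc"))

  std <- pca_fit(standardize_parameters(pruned$matrix))
  expect_lt(std$explained_variance_ratio[1], 0.8)
  expect_lt(abs(std$loadings["AreaDec", 1]), 0.6)
})

test_that("tidy and glance expose the fitted model as tibbles", {
  std <- random_std_matrix(n = 20, p = 4, seed = 65)
  masking <- tibble::tibble(
    material_id = std$material_id, masking_score = stats::runif(20, 0, 10)
  )
  model <- classify_materials(std[, ], masking, k = 3, seed = 9)
  td <- tidy(model)
  expect_equal(nrow(td), 20)
  expect_true(all(c("PC1", "PC2", "cluster", "masking_score") %in% names(td)))
  gl <- glance(model)
  expect_equal(gl$k, 3)
  expect_equal(gl$n, 20)
  expect_equal(gl$evr_pc1, model$pca$explained_variance_ratio[1])
  expect_equal(sort(unique(td$cluster)), 0:2)
})
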