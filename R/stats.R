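#' Pearson correlation matrix of a parameter matrix
#'
#' @param matrix Parameter tibble (`material_id` plus numeric parameter
#'   columns); at least 3 rows, no constant column.
#' @return Symmetric correlation matrix with unit diagonal, parameters as
#'   dimnames.
#' @export
pearson_corr_matrix <- function(matrix) {
  x <- parameter_values(matrix)
  if (nrow(x) < 3) {
    abort("pearson_corr_matrix(): at least 3 materials are required")
  }
  const <- apply(x, 2, function(col) max(col) - min(col) == 0)
  if (any(const)) {
    abort(sprintf(
      "pearson_corr_matrix(): constant column '%s' has no defined correlation",
      colnames(x)[which(const)[1]]
    ))
  }
  cor(x, method = "pearson")
}

#' Drop near-duplicate TI parameters by correlation grouping
#'
#' Two pruning rules are applied. First, when no material shows a plateau
#' (every `DurPl` is zero) the plateau descriptors `DurPl` and `AreaPl`
#' carry no information and are dropped. Second, the remaining parameters
#' are grouped by pairwise `|r| >= r_threshold` (transitively), and one
#' representative is kept per group:
#'
#' * `mode = "conventional"`: the field's conventional representatives --
#'   `DurInc` for the increasing-phase block (`TsPl`, `TePl`, `DurInc`),
#'   `DurDec` for (`DurDec`, `Tend`) and `AreaDec` for (`AreaDec`,
#'   `AreaTse`); groups without a conventional representative fall back to
#'   the highest-variance member.
#' * `mode = "auto"`: the highest-variance member of each group, ties
#'   broken by canonical parameter order.
#'
#' @param matrix Parameter tibble with the 14 TI columns.
#' @param r_threshold Absolute correlation at or above which two
#'   parameters are considered duplicates (default 0.98).
#' @param mode `"conventional"` or `"auto"`.
#' @return List with `matrix` (pruned tibble), `retained` (character
#'   vector in canonical order) and `exclusions` (tibble `parameter`,
#'   `reason`, `r`, `kept_as`).
#' @export
prune_correlated <- function(matrix, r_threshold = 0.98,
                             mode = c("conventional", "auto")) {
  mode <- match.arg(mode)
  matrix <- validate_parameter_matrix(matrix)
  pcols <- setdiff(names(matrix), "material_id")
  missing <- setdiff(ti_parameter_names(), pcols)
  if (length(missing) > 0) {
    abort(sprintf(
      "prune_correlated(): matrix must contain all 14 TI parameters; missing %s",
      paste(sprintf("'%s'", missing), collapse = ", ")
    ))
  }
  exclusions <- tibble::tibble(
    parameter = character(), reason = character(),
    r = numeric(), kept_as = character()
  )
  cols <- ti_parameter_names()
  if (all(matrix$DurPl == 0)) {
    exclusions <- dplyr::bind_rows(exclusions, tibble::tibble(
      parameter = c("DurPl", "AreaPl"),
      reason = "no material reached a plateau phase",
      r = NA_real_, kept_as = NA_character_
    ))
    cols <- setdiff(cols, c("DurPl", "AreaPl"))
  }
  rmat <- pearson_corr_matrix(matrix[, c("material_id", cols)])

  # transitive grouping: connected components of the |r| >= threshold graph
  adj <- abs(rmat) >= r_threshold
  comp <- rep(NA_integer_, length(cols))
  names(comp) <- cols
  cid <- 0L
  for (p in cols) {
    if (!is.na(comp[p])) next
    cid <- cid + 1L
    frontier <- p
    while (length(frontier) > 0) {
      comp[frontier] <- cid
      nxt <- cols[is.na(comp) & colSums(adj[frontier, cols, drop = FALSE]) > 0]
      frontier <- nxt
    }
  }

  vars <- apply(parameter_values(matrix[, c("material_id", cols)]), 2, var)
  preferred <- c("DurInc", "DurDec", "AreaDec")
  retained <- character()
  for (g in split(cols, comp[cols])) {
    if (length(g) == 1) {
      retained <- c(retained, g)
      next
    }
    rep_col <- if (mode == "conventional" && any(preferred %in% g)) {
      preferred[preferred %in% g][1]
    } else {
      ord <- order(-vars[g], match(g, ti_parameter_names()))
      g[ord[1]]
    }
    retained <- c(retained, rep_col)
    dropped <- setdiff(g, rep_col)
    exclusions <- dplyr::bind_rows(exclusions, tibble::tibble(
      parameter = dropped,
      reason = sprintf("|r| >= %s with retained parameter", format(r_threshold)),
      r = rmat[dropped, rep_col],
      kept_as = rep_col
    ))
  }
  retained <- intersect(ti_parameter_names(), retained)
  list(
    matrix = matrix[, c("material_id", retained)],
    retained = retained,
    exclusions = exclusions
  )
}

#' Mann-Whitney U test with exact small-sample p-values
#'
#' Computes the rank-sum U statistic with midranks on ties, reported in
#' the `min(U_a, U_b)` form. The two-tailed p-value is exact (from the
#' null distribution of U over all group assignments) whenever
#' `n + m <= 24` and the pooled data are tie-free; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return One-row tibble with `U`, `p_two_tailed` and `method`
#'   (`"exact"` or `"normal"`).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
mann_whitney_u <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    abort("mann_whitney_u(): each group needs at least 2 values")
  }
  if (any(!is.finite(c(a, b)))) {
    abort("mann_whitney_u(): values must be finite")
  }
  n <- length(a)
  m <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled, ties.method = "average")
  ua <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  ub <- n * m - ua
  u <- min(ua, ub)
  has_ties <- anyDuplicated(pooled) > 0
  if (!has_ties && n + m <= 24) {
    p <- min(1, 2 * pwilcox(u, n, m))
    method <- "exact"
  } else {
    mu <- n * m / 2
    nn <- n + m
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- n * m / 12 * ((nn + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu + 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(z))
    }
    method <- "normal"
  }
  tibble::tibble(U = u, p_two_tailed = p, method = method)
}

#' Compare retained TI parameters between top and bottom masking groups
#'
#' Splits the materials into top-k and bottom-k masking groups (boundary
#' ties included, see [rank_materials()]) and tests each parameter with
#' the two-tailed Mann-Whitney U test at `alpha`. No multiplicity
#' correction is applied: each parameter is reported at its own
#' per-comparison level.
#'
#' @param params Parameter tibble (raw scale; `material_id` plus numeric
#'   columns, typically the retained set after [prune_correlated()]).
#' @param masking Masking-score table from [masking_scores()].
#' @param k Group size (default 10).
#' @param alpha Significance level for the `significant` flag.
#' @return Tibble with one row per parameter: `parameter`, `U`,
#'   `p_two_tailed`, `method`, `median_top`, `median_bottom`,
#'   `significant`.
#' @export
compare_top_bottom <- function(params, masking, k = 10, alpha = 0.05) {
  params <- require_columns(params, "material_id")
  masking <- require_columns(masking, c("material_id", "masking_score"))
  shared <- intersect(params$material_id, masking$material_id)
  if (length(shared) < nrow(params) || length(shared) < nrow(masking)) {
    abort("compare_top_bottom(): params and masking must share the same material_ids")
  }
  groups <- rank_materials(masking, k)
  pcols <- setdiff(names(params), "material_id")
  top_ids <- groups$material_id[groups$group == "top"]
  bot_ids <- groups$material_id[groups$group == "bottom"]
  purrr::map_dfr(pcols, function(p) {
    top_vals <- params[[p]][match(top_ids, params$material_id)]
    bot_vals <- params[[p]][match(bot_ids, params$material_id)]
    test <- mann_whitney_u(top_vals, bot_vals)
    tibble::tibble(
      parameter = p,
      U = test$U,
      p_two_tailed = test$p_two_tailed,
      method = test$method,
      median_top = median(top_vals),
      median_bottom = median(bot_vals),
      significant = test$p_two_tailed < alpha
    )
  })
}

#' Standardize a parameter matrix to zero mean and unit variance
#'
#' Columns are centered and scaled with the population standard deviation
#' (divisor n), so each standardized column has mean 0 and variance 1 in
#' the divisor-n sense. The result carries a `standardized` attribute
#' checked by [pca_fit()].
#'
#' @param matrix Parameter tibble; no constant columns.
#' @param divisor `"n"` (population, default) or `"n-1"` (sample).
#' @return The standardized tibble with attribute `standardized = TRUE`.
#' @export
standardize_parameters <- function(matrix, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  matrix <- require_columns(matrix, "material_id")
  pcols <- setdiff(names(matrix), "material_id")
  n <- nrow(matrix)
  for (p in pcols) {
    x <- matrix[[p]]
    if (max(x) - min(x) == 0) {
      abort(sprintf("standardize_parameters(): constant column '%s' cannot be standardized", p))
    }
    s <- if (divisor == "n") sqrt(sum((x - mean(x))^2) / n) else sd(x)
    matrix[[p]] <- (x - mean(x)) / s
  }
  attr(matrix, "standardized") <- TRUE
  matrix
}

is_standardized <- function(matrix) {
  isTRUE(attr(matrix, "standardized"))
}

parameter_values <- function(matrix) {
  matrix <- require_columns(matrix, "material_id")
  x <- as.matrix(matrix[setdiff(names(matrix), "material_id")])
  rownames(x) <- matrix$material_id
  x
}
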