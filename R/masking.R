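#' Convert a median beany intensity to a masking score
#'
#' The masking score of a flavoring material is `10 - median beany
#' intensity` on the 10-point VAS-derived scale: a material whose residual
#' beany median is 4.0 scores 6.0; complete masking scores 10, no masking
#' scores 0.
#'
#' @param median_intensity Numeric vector of median beany intensities in
#'   \[0, 10\].
#' @return Masking scores on the same scale.
#' @export
#' @examples
#' masking_score(4.0)
masking_score <- function(median_intensity) {
  if (any(!is.finite(median_intensity) | median_intensity < 0 | median_intensity > 10)) {
    abort("`median_intensity` must lie in [0, 10]")
  }
  10 - median_intensity
}

#' Score materials from VAS beany-intensity ratings
#'
#' Pools all ratings of each material (panelists together), takes the
#' sample median (midpoint of the two central values on even counts) and
#' converts it to a masking score. Rounding, if any, is for display only;
#' full precision is kept here.
#'
#' @param vas VAS table (see [read_vas()]).
#' @return Tibble with `material_id`, `median_intensity`, `masking_score`,
#'   `n_ratings`, one row per material.
#' @export
masking_scores <- function(vas) {
  vas <- validate_vas(vas)
  if (nrow(vas) == 0) {
    abort("masking_scores(): no VAS records supplied")
  }
  vas |>
    dplyr::group_by(.data$material_id) |>
    dplyr::summarise(
      median_intensity = median(.data$beany_intensity),
      n_ratings = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(masking_score = masking_score(.data$median_intensity)) |>
    dplyr::select("material_id", "median_intensity", "masking_score", "n_ratings")
}

#' Top-k and bottom-k materials by masking score
#'
#' Materials are sorted by descending masking score (ties broken by
#' `material_id`); the `k` best form the top group and the `k` worst the
#' bottom group. When a tie in score straddles the k-boundary, every tied
#' material is included, so a group may hold more than `k` members.
#'
#' @param masking Masking-score table from [masking_scores()] (only
#'   `material_id` and `masking_score` are required).
#' @param k Nominal group size; must satisfy `2 * k <=` number of
#'   materials.
#' @return Tibble with columns `group` (`"top"` / `"bottom"`), `rank`
#'   (within group, 1 = most extreme) and the masking columns. A material
#'   tied across both boundaries can appear in both groups.
#' @export
rank_materials <- function(masking, k) {
  masking <- require_columns(masking, c("material_id", "masking_score"))
  if (length(k) != 1 || !is.finite(k) || k <= 0 || k != round(k)) {
    abort("`k` must be a positive integer")
  }
  n <- nrow(masking)
  if (2 * k > n) {
    abort(sprintf("`k` = %d too large for %d materials (need 2k <= n)", k, n))
  }
  desc_ord <- order(-masking$masking_score, masking$material_id)
  top_cut <- masking$masking_score[desc_ord[k]]
  top <- masking[masking$masking_score >= top_cut, ]
  top <- top[order(-top$masking_score, top$material_id), ]
  top$group <- "top"
  top$rank <- seq_len(nrow(top))

  asc_ord <- order(masking$masking_score, masking$material_id)
  bot_cut <- masking$masking_score[asc_ord[k]]
  bottom <- masking[masking$masking_score <= bot_cut, ]
  bottom <- bottom[order(bottom$masking_score, bottom$material_id), ]
  bottom$group <- "bottom"
  bottom$rank <- seq_len(nrow(bottom))

  dplyr::bind_rows(top, bottom) |>
    dplyr::select("group", "rank", dplyr::everything())
}
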