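#' Smooth TI curves with a centered moving average
#'
#' Each replicate curve is smoothed independently. At the boundaries the
#' window shrinks symmetrically (the first and last samples keep smaller,
#' centered windows), so the output has the same length and time grid as
#' the input. Smoothed intensities are clipped to \[0, 100\].
#'
#' @param curves Long curve table (see [read_ti_curves()]).
#' @param window_s Odd integer window width in seconds; `1` is the
#'   identity.
#' @return The curve table with smoothed intensities.
#' @export
#' @examples
#' curves <- tibble::tibble(
#'   material_id = "m1", panelist_id = "p1", replicate = 1L,
#'   time_s = 0:4, intensity = c(0, 0, 9, 0, 0)
#' )
#' smooth_curves(curves, window_s = 3)$intensity
smooth_curves <- function(curves, window_s = 5) {
  check_window(window_s)
  curves <- validate_ti_curves(curves)
  if (window_s == 1 || nrow(curves) == 0) {
    return(curves)
  }
  curves |>
    dplyr::group_by(.data$material_id, .data$panelist_id, .data$replicate) |>
    dplyr::mutate(intensity = moving_average(.data$intensity, window_s)) |>
    dplyr::ungroup()
}

check_window <- function(window_s) {
  if (length(window_s) != 1 || !is.finite(window_s) || window_s < 1 ||
      window_s != round(window_s) || window_s %% 2 == 0) {
    abort("`window_s` must be an odd integer >= 1")
  }
  invisible(window_s)
}

# centered moving average with symmetric window shrink at the boundaries;
# vectorised via cumulative sums
moving_average <- function(x, window) {
  n <- length(x)
  half <- (window - 1) / 2
  i <- seq_len(n)
  h <- pmin(half, i - 1, n - i)
  cs <- c(0, cumsum(x))
  out <- (cs[i + h + 1] - cs[i - h]) / (2 * h + 1)
  pmin(pmax(out, 0), 100)
}

#' Select the representative replicates of each curve group
#'
#' Replicates are kept whose three key parameters -- peak intensity
#' (`Imax`), plateau start (`TsPl`) and end time (`Tend`) -- sit closest to
#' the middle of the replicate set: for each parameter the replicates are
#' ranked (midranks on ties) and a replicate's score is the summed absolute
#' distance of its ranks from the median rank. The `n_keep` replicates with
#' the smallest score are retained (ties broken by lower replicate index)
#' and returned in their original order. This drops outlying evaluations
#' while staying scale-free in the parameters.
#'
#' Curves are expected to be smoothed already (see [smooth_curves()]); the
#' three parameters are measured on the curves as given.
#'
#' @param curves Long curve table; grouping is by
#'   (`material_id`, `panelist_id`).
#' @param n_keep Number of replicates to keep per group (default 3).
#' @param eps_i,min_dur_s,eps_pl,min_plateau_s Detection settings passed to
#'   the parameter extractor; see [extract_ti_parameters()].
#' @return The subset of `curves` belonging to the selected replicates.
#' @export
select_representatives <- function(curves, n_keep = 3,
                                   eps_i = 1, min_dur_s = 2,
                                   eps_pl = 0.05, min_plateau_s = 2) {
  curves <- validate_ti_curves(curves)
  if (n_keep < 1 || n_keep != round(n_keep)) {
    abort("`n_keep` must be a positive integer")
  }
  groups <- split(
    curves,
    interaction(curves$material_id, curves$panelist_id, drop = TRUE)
  )
  kept <- lapply(groups, function(g) {
    reps <- sort(unique(g$replicate))
    if (length(reps) < n_keep) {
      abort(sprintf(
        "material '%s', panelist '%s': %d replicate(s) available but n_keep = %d",
        g$material_id[1], g$panelist_id[1], length(reps), n_keep
      ))
    }
    stats3 <- vapply(reps, function(r) {
      d <- g[g$replicate == r, ]
      p <- extract_one_curve(
        d$time_s, d$intensity,
        eps_i = eps_i, min_dur_s = min_dur_s,
        eps_pl = eps_pl, min_plateau_s = min_plateau_s
      )
      c(p[["Imax"]], p[["TsPl"]], p[["Tend"]])
    }, numeric(3))
    dist <- rep(0, length(reps))
    for (j in 1:3) {
      rk <- rank(stats3[j, ], ties.method = "average")
      dist <- dist + abs(rk - median(rk))
    }
    ord <- order(dist, reps)
    keep <- sort(reps[ord[seq_len(n_keep)]])
    g[g$replicate %in% keep, ]
  })
  dplyr::bind_rows(kept) |>
    dplyr::arrange(.data$material_id, .data$panelist_id, .data$replicate, .data$time_s)
}

#' Average curves within groups, zero-extending shorter curves
#'
#' Within each group all curves must share the 1 Hz grid origin and step;
#' shorter curves are extended with zeros to the longest end time
#' (intensity after the flavor sensation has disappeared is by definition
#' zero) and the pointwise arithmetic mean is taken.
#'
#' @param curves Long curve table.
#' @param by Grouping columns defining one averaged curve (default
#'   `"material_id"`).
#' @return A tibble with the grouping columns plus `time_s`, `intensity`
#'   and `n_replicates_used`.
#' @export
average_curves <- function(curves, by = "material_id") {
  curves <- require_columns(curves, c(by, "time_s", "intensity"))
  if (nrow(curves) == 0) {
    abort("average_curves(): no curves supplied")
  }
  has_rep <- all(c("panelist_id", "replicate") %in% names(curves))
  key <- interaction(curves[by], drop = TRUE)
  out <- lapply(split(curves, key), function(g) {
    if (has_rep) {
      sub <- interaction(g$panelist_id, g$replicate, drop = TRUE)
    } else {
      sub <- factor(rep(1, nrow(g)))
    }
    pieces <- split(g, sub)
    origins <- vapply(pieces, function(d) min(d$time_s), numeric(1))
    steps <- vapply(pieces, function(d) diff(d$time_s[1:2]), numeric(1))
    if (max(origins) - min(origins) > 1e-9 || max(steps) - min(steps) > 1e-9) {
      abort(sprintf(
        "average_curves(): curves in group '%s' do not share a common time grid",
        as.character(g[[by[1]]][1])
      ))
    }
    t0 <- origins[1]
    dt <- steps[1]
    n_max <- max(vapply(pieces, nrow, integer(1)))
    acc <- rep(0, n_max)
    for (d in pieces) {
      y <- d$intensity[order(d$time_s)]
      acc <- acc + c(y, rep(0, n_max - length(y)))
    }
    res <- g[rep(1, n_max), by, drop = FALSE]
    res$time_s <- t0 + dt * (seq_len(n_max) - 1)
    res$intensity <- acc / length(pieces)
    res$n_replicates_used <- length(pieces)
    res
  })
  dplyr::bind_rows(out) |> tibble::as_tibble()
}

#' Build per-material average TI curves from raw replicates
#'
#' Runs the full curve-processing chain: smoothing, representative-replicate
#' selection within each (material, panelist), averaging within panelist,
#' then averaging across panelists (set
#' `config$curves$average_within_panelist = FALSE` to pool all selected
#' replicates directly).
#'
#' @param curves Raw long curve table.
#' @param config Run configuration (see [default_run_config()]).
#' @return Per-material average curves as returned by [average_curves()],
#'   with `n_replicates_used` the total number of replicate curves behind
#'   each average.
#' @export
process_curves <- function(curves, config = default_run_config()) {
  ccfg <- config$curves
  pcfg <- config$parameters
  smoothed <- smooth_curves(curves, window_s = ccfg$smooth_window_s)
  selected <- select_representatives(
    smoothed, n_keep = ccfg$n_representatives,
    eps_i = pcfg$eps_i, min_dur_s = pcfg$min_dur_s,
    eps_pl = pcfg$eps_pl, min_plateau_s = pcfg$min_plateau_s
  )
  n_sel <- selected |>
    dplyr::distinct(.data$material_id, .data$panelist_id, .data$replicate) |>
    dplyr::count(.data$material_id, name = "n_replicates_used")
  if (isTRUE(ccfg$average_within_panelist)) {
    per_panelist <- average_curves(selected, by = c("material_id", "panelist_id"))
    per_panelist$replicate <- 1L
    avg <- average_curves(per_panelist, by = "material_id")
  } else {
    avg <- average_curves(selected, by = "material_id")
  }
  avg$n_replicates_used <- NULL
  dplyr::left_join(avg, n_sel, by = "material_id")
}
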