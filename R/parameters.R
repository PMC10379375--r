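#' Detect curve onset and offset by a sustained intensity threshold
#'
#' The onset `Tstart` is the first sampled time whose intensity exceeds
#' `eps_i` and stays above it for at least `min_dur_s`; the offset `Tend`
#' is the last time above `eps_i` sustained backwards for `min_dur_s`.
#' Brief threshold crossings (noise blips shorter than `min_dur_s`) are
#' ignored.
#'
#' @param curve Data frame with `time_s` and `intensity` for one curve.
#' @param eps_i Intensity threshold in a.u.; must be > 0.
#' @param min_dur_s Minimum sustained duration above threshold, seconds.
#' @return Named numeric vector `c(Tstart = ..., Tend = ...)`.
#' @export
detect_onset_offset <- function(curve, eps_i = 1, min_dur_s = 2) {
  curve <- require_columns(curve, c("time_s", "intensity"))
  onset_offset(curve$time_s, curve$intensity, eps_i, min_dur_s)
}

onset_offset <- function(t, y, eps_i, min_dur_s) {
  if (length(eps_i) != 1 || !is.finite(eps_i) || eps_i <= 0) {
    abort("`eps_i` must be a single value > 0")
  }
  above <- y > eps_i
  if (!any(above)) {
    abort("flat curve: no sample exceeds the onset threshold")
  }
  dt <- t[2] - t[1]
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  qual <- r$values & (r$lengths - 1) * dt >= min_dur_s
  if (!any(qual)) {
    abort(sprintf(
      "flat curve: no run above the onset threshold lasts >= %s s", format(min_dur_s)
    ))
  }
  c(Tstart = t[starts[which(qual)[1]]],
    Tend = t[ends[max(which(qual))]])
}

#' Detect the plateau phase around the curve peak
#'
#' The candidate plateau is the maximal contiguous interval containing the
#' global maximum (earliest sample on ties) on which the intensity stays
#' within a fraction `eps_pl` of the peak. If that interval is shorter than
#' `min_plateau_s` the plateau collapses to the peak time itself, giving
#' `DurPl = AreaPl = 0` -- the typical outcome for sharply peaked flavor
#' release.
#'
#' @inheritParams detect_onset_offset
#' @param tstart,tend Onset and offset times from [detect_onset_offset()].
#' @param eps_pl Plateau tolerance as a fraction of `Imax`, in (0, 1).
#' @param min_plateau_s Minimum plateau duration in seconds.
#' @return Named numeric vector `c(TsPl = ..., TePl = ...)`.
#' @export
detect_plateau <- function(curve, tstart, tend, eps_pl = 0.05, min_plateau_s = 2) {
  curve <- require_columns(curve, c("time_s", "intensity"))
  if (missing(tstart) || missing(tend) || is.null(tstart) || is.null(tend)) {
    abort("detect_plateau() requires onset/offset times; run detect_onset_offset() first")
  }
  plateau(curve$time_s, curve$intensity, tstart, tend, eps_pl, min_plateau_s)
}

plateau <- function(t, y, tstart, tend, eps_pl, min_plateau_s) {
  if (length(eps_pl) != 1 || !is.finite(eps_pl) || eps_pl <= 0 || eps_pl >= 1) {
    abort("`eps_pl` must be a single fraction in (0, 1)")
  }
  win <- which(t >= tstart - 1e-9 & t <= tend + 1e-9)
  yw <- y[win]
  imax <- max(yw)
  peak <- win[which.max(yw)]  # earliest argmax on ties
  thr <- (1 - eps_pl) * imax
  lo <- peak
  while (lo > win[1] && y[lo - 1] >= thr) lo <- lo - 1
  hi <- peak
  while (hi < win[length(win)] && y[hi + 1] >= thr) hi <- hi + 1
  if (t[hi] - t[lo] < min_plateau_s) {
    return(c(TsPl = t[peak], TePl = t[peak]))
  }
  c(TsPl = t[lo], TePl = t[hi])
}

#' Extract the 14 TI parameters from average curves
#'
#' Segments each curve into increasing, plateau and decreasing phases and
#' computes the standard TI descriptors: onset/offset times, peak
#' intensity, plateau bounds and duration, phase durations, maximum phase
#' slopes from consecutive 1 s differences (`SIMDec` reported as a positive
#' magnitude), and trapezoidal phase areas, with
#' `AreaTse = AreaInc + AreaPl + AreaDec`.
#'
#' @param curves Data frame of one or more curves with columns
#'   `material_id`, `time_s`, `intensity` (one curve per material, e.g. the
#'   output of [process_curves()]).
#' @param config Run configuration supplying the detection settings
#'   (`config$parameters`); see [default_run_config()].
#' @param tstart,tend Optional fixed onset/offset times (applied to every
#'   curve), bypassing threshold detection -- useful for analytic checks on
#'   noiseless geometric curves. Must lie on the sampling grid.
#' @return A tibble with `material_id` and the 14 parameter columns in the
#'   order of [ti_parameter_names()].
#' @export
#' @examples
#' tri <- tibble::tibble(
#'   material_id = "tri", time_s = 0:20,
#'   intensity = c(rep(0, 5), 8 * (1:5), 40 - 4 * (1:10))
#' )
#' extract_ti_parameters(tri)
extract_ti_parameters <- function(curves, config = default_run_config(),
                                  tstart = NULL, tend = NULL) {
  curves <- require_columns(curves, c("material_id", "time_s", "intensity"))
  pcfg <- config$parameters
  groups <- split(curves, factor(curves$material_id, unique(curves$material_id)))
  rows <- lapply(groups, function(g) {
    g <- g[order(g$time_s), ]
    p <- extract_one_curve(
      g$time_s, g$intensity,
      eps_i = pcfg$eps_i, min_dur_s = pcfg$min_dur_s,
      eps_pl = pcfg$eps_pl, min_plateau_s = pcfg$min_plateau_s,
      tstart = tstart, tend = tend
    )
    tibble::tibble(material_id = g$material_id[1], !!!as.list(p))
  })
  dplyr::bind_rows(rows)
}

extract_one_curve <- function(t, y, eps_i = 1, min_dur_s = 2,
                              eps_pl = 0.05, min_plateau_s = 2,
                              tstart = NULL, tend = NULL) {
  if (is.null(tstart) || is.null(tend)) {
    oo <- onset_offset(t, y, eps_i, min_dur_s)
    tstart <- tstart %||% oo[["Tstart"]]
    tend <- tend %||% oo[["Tend"]]
  }
  pl <- plateau(t, y, tstart, tend, eps_pl, min_plateau_s)
  tspl <- pl[["TsPl"]]
  tepl <- pl[["TePl"]]
  win <- which(t >= tstart - 1e-9 & t <= tend + 1e-9)
  imax <- max(y[win])
  dt <- t[2] - t[1]

  max_slope <- function(a, b, sign) {
    idx <- which(t >= a - 1e-9 & t <= b + 1e-9)
    if (length(idx) < 2) {
      return(0)
    }
    d <- sign * diff(y[idx]) / dt
    m <- max(d)
    max(m, 0)
  }
  trapz_between <- function(a, b) {
    idx <- which(t >= a - 1e-9 & t <= b + 1e-9)
    if (length(idx) < 2) {
      return(0)
    }
    ts <- t[idx]
    ys <- y[idx]
    sum(diff(ts) * (ys[-length(ys)] + ys[-1]) / 2)
  }

  area_inc <- trapz_between(tstart, tspl)
  area_pl <- trapz_between(tspl, tepl)
  area_dec <- trapz_between(tepl, tend)
  c(
    Tstart = tstart, Tend = tend, Imax = imax,
    TsPl = tspl, TePl = tepl,
    DurPl = tepl - tspl, DurInc = tspl - tstart, DurDec = tend - tepl,
    SIMInc = max_slope(tstart, tspl, +1),
    SIMDec = max_slope(tepl, tend, -1),
    AreaTse = area_inc + area_pl + area_dec,
    AreaInc = area_inc, AreaDec = area_dec, AreaPl = area_pl
  )
}

#' Phase annotation of extracted parameters
#'
#' @param params Parameter tibble from [extract_ti_parameters()].
#' @return Tibble `material_id`, `Tstart`, `TsPl`, `TePl`, `Tend` -- the
#'   phase boundaries of each material's average curve.
#' @export
phase_annotation <- function(params) {
  params <- require_columns(params, c("material_id", "Tstart", "TsPl", "TePl", "Tend"))
  params[, c("material_id", "Tstart", "TsPl", "TePl", "Tend")]
}
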