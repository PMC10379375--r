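#' Draw a flavor-release archetype for a material type
#'
#' An archetype is a parametric ramp-plus-exponential-decay TI-curve
#' model: intensity rises linearly from `t_start` to `i_peak` over
#' `dur_inc`, then decays exponentially with time constant `tau` until it
#' falls below `cutoff`. Type-specific uniform ranges encode the release
#' kinetics seen across material classes: oils ramp slowly and persist
#' (large `dur_inc`, large `tau`), essences release and vanish fast, and
#' flavor-type materials sit in between.
#'
#' Draws use R's global RNG; seed with `set.seed()` for reproducibility.
#'
#' @param mtype One of `"essence"`, `"oil"`, `"flavor"`.
#' @param n Number of archetypes to draw.
#' @param ranges Optional override of the per-type ranges; a list like
#'   `archetype_ranges()`.
#' @return Tibble with `mtype`, `t_start`, `dur_inc`, `i_peak`, `tau`,
#'   `cutoff`.
#' @export
sample_archetype <- function(mtype, n = 1, ranges = archetype_ranges()) {
  if (length(mtype) != 1 || !mtype %in% material_types()) {
    abort(sprintf(
      "unknown mtype '%s'; allowed values are %s",
      as.character(mtype), paste(material_types(), collapse = ", ")
    ))
  }
  r <- ranges[[mtype]]
  tibble::tibble(
    mtype = mtype,
    t_start = stats::runif(n, ranges$t_start[1], ranges$t_start[2]),
    dur_inc = stats::runif(n, r$dur_inc[1], r$dur_inc[2]),
    i_peak = stats::runif(n, ranges$i_peak[1], ranges$i_peak[2]),
    tau = stats::runif(n, r$tau[1], r$tau[2]),
    cutoff = ranges$cutoff
  )
}

#' @rdname sample_archetype
#' @export
archetype_ranges <- function() {
  list(
    oil = list(dur_inc = c(12, 22), tau = c(30, 60)),
    essence = list(dur_inc = c(4, 8), tau = c(8, 15)),
    flavor = list(dur_inc = c(8, 14), tau = c(15, 30)),
    t_start = c(4, 8),
    i_peak = c(30, 90),
    cutoff = 1
  )
}

#' Closed-form TI parameters of an archetype
#'
#' Noiseless continuous-time values of the 14 TI parameters for the
#' ramp-plus-exponential-decay model -- the analytic oracle against which
#' sampled-curve extraction is checked. In particular
#' `AreaInc = i_peak * dur_inc / 2`,
#' `DurDec = tau * log(i_peak / cutoff)` and
#' `AreaDec = i_peak * tau * (1 - cutoff / i_peak)`; the model has no
#' plateau, so `DurPl = AreaPl = 0` and `TsPl = TePl`.
#'
#' @param archetypes Tibble of archetypes (see [sample_archetype()]);
#'   extra columns such as `material_id` are carried through.
#' @return Tibble with the carried id columns plus the 14 TI parameters.
#' @export
closed_form_params <- function(archetypes) {
  a <- require_columns(archetypes, c("t_start", "dur_inc", "i_peak", "tau", "cutoff"))
  keep <- intersect(c("material_id", "mtype"), names(a))
  tspl <- a$t_start + a$dur_inc
  durdec <- a$tau * log(a$i_peak / a$cutoff)
  areainc <- a$i_peak * a$dur_inc / 2
  areadec <- a$i_peak * a$tau * (1 - a$cutoff / a$i_peak)
  tibble::tibble(
    !!!a[keep],
    Tstart = a$t_start,
    Tend = tspl + durdec,
    Imax = a$i_peak,
    TsPl = tspl,
    TePl = tspl,
    DurPl = 0,
    DurInc = a$dur_inc,
    DurDec = durdec,
    SIMInc = a$i_peak / a$dur_inc,
    SIMDec = a$i_peak / a$tau,
    AreaTse = areainc + areadec,
    AreaInc = areainc,
    AreaDec = areadec,
    AreaPl = 0
  )
}

#' Render an archetype as a sampled 1 Hz TI curve
#'
#' Evaluates the continuous ramp/decay model (zero before onset, zero
#' again once the decay falls below `cutoff`), optionally rescaled by a
#' panelist intensity factor and shifted by replicate time jitter, samples
#' it at 1 Hz from t = 0, adds Gaussian intensity noise and clips to
#' \[0, 100\]. Uses the global RNG for the noise.
#'
#' @param archetype One-row archetype tibble.
#' @param panelist_scale Multiplicative intensity factor (1 = none).
#' @param time_jitter Onset shift in seconds (curve is clamped to start at
#'   or after t = 0).
#' @param noise_sd Standard deviation of the additive sample noise, a.u.
#' @param tail_s Seconds of baseline appended after the release ends.
#' @return Tibble with `time_s`, `intensity`.
#' @export
render_curve <- function(archetype, panelist_scale = 1, time_jitter = 0,
                         noise_sd = 0, tail_s = 3) {
  a <- require_columns(archetype, c("t_start", "dur_inc", "i_peak", "tau", "cutoff"))
  if (nrow(a) != 1) {
    abort("render_curve(): exactly one archetype row expected")
  }
  t0 <- max(0, a$t_start + time_jitter)
  peak <- a$i_peak * panelist_scale
  t_peak <- t0 + a$dur_inc
  t_end <- t_peak + a$tau * log(max(peak, a$cutoff * 1.001) / a$cutoff)
  times <- seq(0, ceiling(t_end) + tail_s)
  y <- numeric(length(times))
  inc <- times >= t0 & times <= t_peak
  y[inc] <- peak * (times[inc] - t0) / a$dur_inc
  dec <- times > t_peak
  y[dec] <- peak * exp(-(times[dec] - t_peak) / a$tau)
  y[y < a$cutoff & times > t_peak] <- 0
  if (noise_sd > 0) {
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  tibble::tibble(time_s = as.numeric(times), intensity = pmin(pmax(y, 0), 100))
}

#' Simulate VAS beany-intensity ratings linked to flavor persistence
#'
#' The true masking ability of a material is a linear function of its
#' closed-form `AreaDec` (flavor release in the decreasing phase),
#' clipped to the 10-point scale:
#' `s* = clip(beta0 + beta1 * AreaDec, 0, 10)`. Each panelist reports a
#' residual beany intensity `clip(10 - s* + N(0, sd), 0, 10)`.
#'
#' @param archetypes Archetype tibble with a `material_id` column.
#' @param n_panelists Number of panelists (one rating each per material).
#' @param beta0,beta1 Link intercept and slope (score points, points per
#'   a.u.-s of AreaDec).
#' @param rating_sd Rating noise standard deviation in score points.
#' @return Tibble of VAS records (`material_id`, `panelist_id`,
#'   `beany_intensity`) plus the underlying `true_score` per material as
#'   attribute `"true_scores"`.
#' @export
generate_vas <- function(archetypes, n_panelists = 10,
                         beta0 = 2, beta1 = 0.003, rating_sd = 1) {
  a <- require_columns(archetypes, "material_id")
  cf <- closed_form_params(a)
  s_true <- pmin(pmax(beta0 + beta1 * cf$AreaDec, 0), 10)
  panelists <- sprintf("p%02d", seq_len(n_panelists))
  vas <- tidyr::expand_grid(
    material_id = a$material_id,
    panelist_id = panelists
  )
  base <- rep(10 - s_true, each = n_panelists)
  noise <- if (rating_sd > 0) stats::rnorm(nrow(vas), 0, rating_sd) else 0
  vas$beany_intensity <- pmin(pmax(base + noise, 0), 10)
  attr(vas, "true_scores") <- tibble::tibble(
    material_id = a$material_id, true_score = s_true
  )
  vas
}

#' Generate a complete synthetic TI study
#'
#' Draws one archetype per material (33 essence / 33 oil / 34 flavor by
#' default), renders every (panelist x replicate) curve with panelist
#' intensity scaling, replicate time jitter and sample noise, and
#' simulates one VAS rating per (material, panelist). The closed-form
#' parameters and true masking scores are returned as a truth table for
#' recovery tests. Fully reproducible from `config$seed`.
#'
#' @param config Run configuration; the `synthetic` block holds all
#'   generator settings (see [default_run_config()]).
#' @return List of tibbles: `materials`, `curves`, `vas`, `truth`.
#' @seealso [write_study()] to store the four tables as CSV.
#' @export
generate_study <- function(config = default_run_config()) {
  scfg <- config$synthetic
  counts <- c(
    essence = scfg$n_essence, oil = scfg$n_oil, flavor = scfg$n_flavor
  )
  if (any(counts < 1) || scfg$n_panelists < 1 || scfg$n_replicates < 1) {
    abort("generate_study(): all counts must be >= 1")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(stage_seed(config$seed, "synthetic"))

  materials <- purrr::map_dfr(material_types(), function(ty) {
    idx <- seq_len(counts[[ty]])
    tibble::tibble(
      material_id = sprintf("%s%02d", substr(ty, 1, 1), idx),
      name = sprintf("synthetic %s %d", ty, idx),
      mtype = ty,
      category = "synthetic"
    )
  })
  archetypes <- purrr::map_dfr(material_types(), function(ty) {
    sample_archetype(ty, n = counts[[ty]])
  })
  archetypes$material_id <- materials$material_id

  panelists <- sprintf("p%02d", seq_len(scfg$n_panelists))
  scale_p <- pmax(stats::rnorm(scfg$n_panelists, 1, scfg$panelist_scale_sd), 0.5)
  names(scale_p) <- panelists

  curves <- purrr::map_dfr(seq_len(nrow(archetypes)), function(i) {
    arch <- archetypes[i, ]
    purrr::map_dfr(panelists, function(p) {
      purrr::map_dfr(seq_len(scfg$n_replicates), function(r) {
        jitter <- if (scfg$time_jitter_sd > 0) {
          stats::rnorm(1, 0, scfg$time_jitter_sd)
        } else {
          0
        }
        curve <- render_curve(
          arch,
          panelist_scale = scale_p[[p]],
          time_jitter = jitter,
          noise_sd = scfg$noise_sd
        )
        curve$material_id <- arch$material_id
        curve$panelist_id <- p
        curve$replicate <- as.integer(r)
        curve
      })
    })
  })
  curves <- curves[, c("material_id", "panelist_id", "replicate", "time_s", "intensity")]

  vas <- generate_vas(
    archetypes,
    n_panelists = scfg$n_panelists,
    beta0 = scfg$link_beta0, beta1 = scfg$link_beta1,
    rating_sd = scfg$rating_sd
  )
  truth <- closed_form_params(archetypes) |>
    dplyr::left_join(attr(vas, "true_scores"), by = "material_id")
  attr(vas, "true_scores") <- NULL

  list(
    materials = materials,
    curves = validate_ti_curves(curves),
    vas = validate_vas(vas),
    truth = truth
  )
}

#' Write the four tables of a synthetic study to a directory
#'
#' @param study List from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  write_materials(study$materials, file.path(dir, "materials.csv"))
  write_ti_curves(study$curves, file.path(dir, "curves.csv"))
  write_vas(study$vas, file.path(dir, "vas.csv"))
  readr::write_csv(study$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}
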