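test_that("archetype draws respect type-specific kinetic ranges", {
  expect_error(sample_archetype("gel"), "unknown mtype")

  withr::with_seed(3, {
    oil <- sample_archetype("oil", n = 500)
    ess <- sample_archetype("essence", n = 500)
    flv <- sample_archetype("flavor", n = 500)
  })
  # disjoint ramp durations: every oil ramps longer than any essence
  expect_gte(min(oil$dur_inc), 12)
  expect_lte(max(ess$dur_inc), 8)
  expect_gt(mean(oil$dur_inc), mean(flv$dur_inc))
  expect_gt(mean(flv$dur_inc), mean(ess$dur_inc))
  expect_gt(mean(oil$tau), mean(flv$tau))
  expect_gt(mean(flv$tau), mean(ess$tau))
  expect_true(all(oil$i_peak <= 100 & oil$cutoff < oil$i_peak))

  a1 <- withr::with_seed(5, sample_archetype("oil"))
  a2 <- withr::with_seed(5, sample_archetype("oil"))
  expect_identical(a1, a2)
})

test_that("closed-form parameters match the analytic model", {
  a <- tibble::tibble(
    mtype = "flavor", t_start = 5, dur_inc = 10, i_peak = 50,
    tau = 20, cutoff = 1
  )
  p <- closed_form_params(a)
  expect_equal(p$AreaInc, 250)
  expect_equal(p$DurDec, 20 * log(50), tolerance = 1e-12)
  expect_equal(round(p$DurDec, 2), 78.24)
  expect_equal(p$AreaDec, 980)
  expect_equal(p$SIMInc, 5)
  expect_equal(p$SIMDec, 2.5)
  expect_equal(p$AreaTse, p$AreaInc + p$AreaDec)
  expect_equal(p$DurPl, 0)

  # cutoff -> i_peak limit: decay phase vanishes
  lim <- closed_form_params(dplyr::mutate(a, cutoff = i_peak * (1 - 1e-12)))
  expect_equal(lim$DurDec, 0, tolerance = 1e-9)
  expect_equal(lim$AreaDec, 0, tolerance = 1e-6)

  # doubling the peak doubles amplitudes, shifts DurDec by tau * log(2)
  dbl <- closed_form_params(dplyr::mutate(a, i_peak = 100))
  expect_equal(dbl$AreaInc, 2 * p$AreaInc)
  expect_equal(dbl$SIMInc, 2 * p$SIMInc)
  expect_equal(dbl$DurInc, p$DurInc)
  expect_equal(dbl$DurDec, p$DurDec + 20 * log(2), tolerance = 1e-12)
})

test_that("rendered curves stay in range and are reproducible", {
  a <- oracle_archetypes()[5, ]
  c1 <- withr::with_seed(9, render_curve(a, noise_sd = 5))
  c2 <- withr::with_seed(9, render_curve(a, noise_sd = 5))
  expect_identical(c1, c2)
  expect_true(all(c1$intensity >= 0 & c1$intensity <= 100))
  expect_equal(c1$time_s, seq(0, max(c1$time_s)))
})

test_that("extraction on noiseless renders recovers the closed forms", {
  arch <- oracle_archetypes()
  cfg <- default_run_config()
  # the ramp/decay model has no plateau phase; a 5 s minimum keeps the
  # detector from labelling the slow-decay dwell near the peak as one
  cfg$parameters$min_plateau_s <- 5
  truth <- closed_form_params(arch)
  for (i in seq_len(nrow(arch))) {
    crv <- render_curve(arch[i, ])
    crv$material_id <- arch$material_id[i]
    # detected onset sits within a sample of the true (on-grid) ramp start
    detected <- extract_ti_parameters(crv, cfg)
    expect_lte(abs(detected$Tstart - truth$Tstart[i]), 1)
    # areas are compared from the geometric onset, as a threshold-detected
    # onset by construction discards the sub-threshold first second
    p <- extract_ti_parameters(crv, cfg, tstart = truth$Tstart[i])
    expect_lte(abs(p$Tend - truth$Tend[i]), 1.5)
    expect_lte(abs(p$Imax - truth$Imax[i]), 1)
    expect_lt(abs(p$AreaInc - truth$AreaInc[i]) / truth$AreaInc[i], 0.02)
    expect_lt(abs(p$AreaDec - truth$AreaDec[i]) / truth$AreaDec[i], 0.02)
    expect_lt(abs(p$AreaTse - truth$AreaTse[i]) / truth$AreaTse[i], 0.02)
    expect_lte(abs(p$SIMInc - truth$SIMInc[i]) / truth$SIMInc[i], 0.05)
  }
})

test_that("the VAS link maps flavor persistence to masking scores", {
  # tau * (i_peak - cutoff) = 2000 => AreaDec = 2000 exactly
  a <- tibble::tibble(
    material_id = "m1", mtype = "oil", t_start = 5, dur_inc = 15,
    i_peak = 51, tau = 40, cutoff = 1
  )
  vas <- generate_vas(a, n_panelists = 6, rating_sd = 0)
  expect_equal(vas$beany_intensity, rep(2, 6))
  expect_equal(masking_scores(vas)$masking_score, 8)

  # a null link makes scores independent of the curve shape
  b <- dplyr::mutate(a, material_id = "m2", tau = 4)
  vas0 <- generate_vas(dplyr::bind_rows(a, b), n_panelists = 5,
                       beta1 = 0, rating_sd = 0)
  expect_equal(unique(vas0$beany_intensity), 8)  # 10 - beta0
})

test_that("study generation is seeded, complete and self-consistent", {
  cfg <- small_config(seed = 19)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1, s2)

  n_mat <- with(cfg$synthetic, n_essence + n_oil + n_flavor)
  expect_equal(nrow(s1$materials), n_mat)
  expect_equal(
    nrow(dplyr::distinct(s1$curves, material_id, panelist_id, replicate)),
    n_mat * cfg$synthetic$n_panelists * cfg$synthetic$n_replicates
  )
  expect_equal(nrow(s1$vas), n_mat * cfg$synthetic$n_panelists)
  expect_equal(nrow(s1$truth), n_mat)

  # generator outputs pass every reader validation after a disk round trip
  dir <- withr::local_tempdir()
  write_study(s1, dir)
  expect_silent(read_ti_curves(file.path(dir, "curves.csv")))
  expect_silent(read_materials(file.path(dir, "materials.csv")))
  expect_silent(read_vas(file.path(dir, "vas.csv")))

  bad <- cfg
  bad$synthetic$n_panelists <- 0L
  expect_error(generate_study(bad), ">= 1")
})

test_that("the pipeline recovers generator truth on a study", {
  cfg <- small_config(seed = 29)
  study <- generate_study(cfg)
  avg <- process_curves(study$curves, cfg)
  params <- extract_ti_parameters(avg, cfg)
  joined <- dplyr::inner_join(
    params, study$truth, by = "material_id", suffix = c("", "_true")
  )
  for (p in c("AreaDec", "AreaInc", "DurInc", "DurDec")) {
    expect_gt(cor(joined[[p]], joined[[paste0(p, "_true")]]), 0.95)
  }
  # type separation mirrors the kinetic ranges
  typed <- dplyr::inner_join(params, study$materials, by = "material_id")
  mean_by <- function(col) tapply(typed[[col]], typed$mtype, mean)
  di <- mean_by("DurInc")
  expect_gt(di[["oil"]], di[["flavor"]])
  expect_gt(di[["flavor"]], di[["essence"]])
  dd <- mean_by("DurDec")
  expect_equal(names(which.min(dd)), "essence")
})
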