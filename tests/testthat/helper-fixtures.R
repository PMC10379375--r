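# fixtures built in code; all curves use the 1 Hz grid from t = 0

# triangle: zero to t = 5, rises to 40 at t = 10 (slope 8), back to 0 at
# t = 20 (slope -4)
triangle_curve <- function(material_id = "tri") {
  tibble::tibble(
    material_id = material_id,
    time_s = as.numeric(0:20),
    intensity = c(rep(0, 5), 8 * (0:5), 40 - 4 * (1:10))
  )
}

# flat top at 40 over t in [10, 14]
trapezoid_curve <- function(material_id = "trap") {
  t <- 0:24
  y <- pmin(pmax(0, 8 * (t - 5)), 40)
  y[t > 14] <- pmax(0, 40 - 4 * (t[t > 14] - 14))
  tibble::tibble(material_id = material_id, time_s = as.numeric(t), intensity = y)
}

# rectangle of height h over [a, b] on a 0..tmax grid
rectangle_curve <- function(h = 50, a = 10, b = 20, tmax = 25,
                            material_id = "rect") {
  t <- 0:tmax
  tibble::tibble(
    material_id = material_id,
    time_s = as.numeric(t),
    intensity = ifelse(t >= a & t <= b, h, 0)
  )
}

as_replicate <- function(curve, panelist_id = "p1", replicate = 1L) {
  curve$panelist_id <- panelist_id
  curve$replicate <- as.integer(replicate)
  curve
}

# a small but complete synthetic study config (fast enough for unit tests)
small_config <- function(seed = 11) {
  cfg <- default_run_config(seed = seed)
  cfg$synthetic$n_essence <- 6L
  cfg$synthetic$n_oil <- 6L
  cfg$synthetic$n_flavor <- 6L
  cfg$synthetic$n_panelists <- 4L
  cfg$synthetic$n_replicates <- 4L
  cfg$stats$top_bottom_k <- 4L
  cfg
}

# archetypes with on-grid onset and peak times so that 1 Hz sampling hits
# the peak exactly; used for closed-form recovery checks
oracle_archetypes <- function() {
  grid <- expand.grid(
    t_start = c(4, 6, 8),
    dur_inc = c(4, 10, 18),
    i_peak = c(30, 60, 90),
    tau = c(8, 20, 45)
  )
  tibble::tibble(
    material_id = sprintf("a%02d", seq_len(nrow(grid))),
    mtype = "flavor",
    t_start = grid$t_start,
    dur_inc = grid$dur_inc,
    i_peak = grid$i_peak,
    tau = grid$tau,
    cutoff = 1
  )
}

# closed-form (noise-free) parameter matrix with the field's typical
# correlation structure: onset nearly constant, type-dependent ramp and
# decay kinetics; serves as a synthetic stand-in for a real multi-material
# parameter table
standin_parameter_matrix <- function(n_per_type = c(essence = 33, oil = 33, flavor = 34),
                                     seed = 402) {
  withr::with_seed(seed, {
    ranges <- archetype_ranges()
    ranges$t_start <- c(5.5, 6.5)
    arch <- purrr::map_dfr(names(n_per_type), function(ty) {
      sample_archetype(ty, n = n_per_type[[ty]], ranges = ranges)
    })
    arch$material_id <- sprintf("m%03d", seq_len(nrow(arch)))
    closed_form_params(arch)[, c("material_id", ti_parameter_names())]
  })
}

# brute-force two-tailed Mann-Whitney p: enumerate all C(n+m, n) group
# assignments and count those whose min-form U is at least as extreme
enumerate_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  nm <- length(pooled)
  u_of <- function(idx) {
    rk <- rank(pooled)
    ua <- sum(rk[idx]) - n * (n + 1) / 2
    min(ua, n * (nm - n) - ua)
  }
  u_obs <- u_of(seq_len(n))
  assignments <- combn(nm, n)
  us <- apply(assignments, 2, u_of)
  mean(us <= u_obs)
}

# brute-force k-means oracle: best partition of x (n x d) into k clusters
# by total within-cluster sum of squares, over all label assignments
enumerate_kmeans <- function(x, k) {
  n <- nrow(x)
  best <- list(wss = Inf, labels = NULL)
  labels <- rep(1L, n)
  repeat {
    if (length(unique(labels)) == k) {
      wss <- 0
      for (c in unique(labels)) {
        pts <- x[labels == c, , drop = FALSE]
        ctr <- colMeans(pts)
        wss <- wss + sum(sweep(pts, 2, ctr)^2)
      }
      if (wss < best$wss) {
        best <- list(wss = wss, labels = labels)
      }
    }
    i <- 1L
    while (i <= n && labels[i] == k) {
      labels[i] <- 1L
      i <- i + 1L
    }
    if (i > n) break
    labels[i] <- labels[i] + 1L
  }
  best
}
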