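# Analytic surfaces and shared small fixtures. Everything is generated in
# code; the expensive fixtures are built once per session and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# plane z = a x + b y + c over an n x n grid
plane_grid <- function(n = 33, a = 0, b = 0, c = 0, cs = 1) {
  xs <- (seq_len(n) - 0.5) * cs
  ys <- rev(xs)  # row 1 is the northern edge
  z <- outer(ys, xs, function(y, x) a * x + b * y + c)
  lg_grid(z, x_origin = 0, y_origin = n * cs, cell_size = cs)
}

# cone z = slope * r (pit for slope > 0, peak for slope < 0), centred
cone_grid <- function(n = 33, slope = 1, cs = 1) {
  cc <- (n + 1) / 2
  r <- sqrt(outer((seq_len(n) - cc)^2, (seq_len(n) - cc)^2, "+")) * cs
  lg_grid(slope * r, x_origin = 0, y_origin = n * cs, cell_size = cs)
}

# triangular ridge running west-east: crest along the middle row
ridge_grid <- function(n = 33, slope = 0.5, cs = 1) {
  cc <- (n + 1) / 2
  z <- outer(-abs(seq_len(n) - cc) * cs * slope, rep(1, n))
  lg_grid(z, x_origin = 0, y_origin = n * cs, cell_size = cs)
}

# independent profile-walk oracle for openness/SVF/horizon: walks the same
# per-azimuth profiles (grid-aligned steps on the 8 principal azimuths,
# bilinear cs-steps otherwise) in plain R
oracle_max_tan <- function(g, row, col, az, radius, sgn = 1) {
  v <- g$values
  nr <- nrow(v); nc <- ncol(v); cs <- g$cell_size
  dc <- sin(az); dr <- -cos(az)
  card <- abs(dc) < 1e-9 || abs(dr) < 1e-9
  diag <- abs(dc^2 - 0.5) < 1e-9 && abs(dr^2 - 0.5) < 1e-9
  if (card || diag) {
    ir <- round(dr); ic <- round(dc)
    step <- if (diag) cs * sqrt(2) else cs
    nstep <- floor(radius / step)
    best <- -Inf
    for (t in seq_len(nstep)) {
      rr <- row + t * ir; cc <- col + t * ic
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) break
      best <- max(best, (sgn * v[rr, cc] - sgn * v[row, col]) / (t * step))
    }
  } else {
    nstep <- floor(radius / cs)
    best <- -Inf
    bil <- function(r, c) {
      r0 <- min(max(floor(r), 1), nr - 1)
      c0 <- min(max(floor(c), 1), nc - 1)
      fr <- r - r0; fc <- c - c0
      (1 - fr) * ((1 - fc) * v[r0, c0] + fc * v[r0, c0 + 1]) +
        fr * ((1 - fc) * v[r0 + 1, c0] + fc * v[r0 + 1, c0 + 1])
    }
    for (t in seq_len(nstep)) {
      rr <- row + t * dr; cc <- col + t * dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) break
      best <- max(best, (sgn * bil(rr, cc) - sgn * v[row, col]) / (t * cs))
    }
  }
  if (!is.finite(best)) best <- 0
  best
}

oracle_openness <- function(g, row, col, radius, n_az = 8, negative = FALSE) {
  sgn <- if (negative) -1 else 1
  mean(sapply(2 * pi * (0:(n_az - 1)) / n_az, function(az)
    pi / 2 - atan(oracle_max_tan(g, row, col, az, radius, sgn))))
}

oracle_svf <- function(g, row, col, radius, n_az = 16) {
  mean(sapply(2 * pi * (0:(n_az - 1)) / n_az, function(az) {
    h <- max(0, atan(oracle_max_tan(g, row, col, az, radius)))
    cos(h)^2
  }))
}

# shared small synthetic scenario (fast: ~240 x 60 cells at 1 m)
small_cfg <- function(seed = 3) {
  scenario_config(
    seed = seed, ridge_length = 240, ridge_width = 64, base_res = 1,
    elev_range = c(1900, 1990), crest_sigma = 12, crest_amp = 80,
    undulation_amp = 6, undulation_wavelength = 80, noise_sd = 2,
    n_individuals = 80, n_loci = 50, n_adaptive = 2,
    cline_center = 120, cline_width = 30, plot_occupancy = 0.7,
    adaptive_links = data.frame(variable = c("WEX", "Nor"), res = c(1, 2),
                                beta0 = 0, beta1 = c(2, -2),
                                stringsAsFactors = FALSE))
}

small_scenario <- function() {
  memo("small_scenario", {
    cfg <- small_cfg()
    tc <- terrain_config(wex_radius = 60, solar_horizon_radius = 30)
    simulate_scenario(cfg, extra_vars = "TOP", terrain_cfg = tc)
  })
}

# two clearly separated binary pools (no spatial component)
two_pool_matrix <- function(n_per = 40, L = 60, gap = 0.6, seed = 42) {
  set.seed(seed)
  pa <- runif(L, 0.5 + gap / 2, 0.95)
  pb <- pa - gap
  x <- rbind(matrix(rbinom(n_per * L, 1, rep(pa, each = n_per)), n_per, L),
             matrix(rbinom(n_per * L, 1, rep(pb, each = n_per)), n_per, L))
  rownames(x) <- sprintf("i%02d", seq_len(2 * n_per))
  colnames(x) <- sprintf("L%02d", seq_len(L))
  x
}
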