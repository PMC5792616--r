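#' @name terrain
#' @title Terrain variables derived from an elevation grid
#'
#' @description Geomorphometric habitat proxies computed on any pyramid
#' level: slope and aspect (Horn's method), northness/eastness, vector
#' ruggedness, positive/negative topographic openness, sky-view factor,
#' topographic wetness index, flow-path length, wind exposure, and monthly
#' clear-sky solar radiation. All operators return grids with the footprint
#' of their input.
NULL

# replicate-pad by one cell and return the 8 shifted neighbour matrices
shift8 <- function(v) {
  nr <- nrow(v); nc <- ncol(v)
  ri <- c(1, seq_len(nr), nr)
  ci <- c(1, seq_len(nc), nc)
  p <- v[ri, ci, drop = FALSE]
  i <- 1 + seq_len(nr); j <- 1 + seq_len(nc)
  list(nw = p[i - 1, j - 1, drop = FALSE], n = p[i - 1, j, drop = FALSE],
       ne = p[i - 1, j + 1, drop = FALSE], w = p[i, j - 1, drop = FALSE],
       e = p[i, j + 1, drop = FALSE],      sw = p[i + 1, j - 1, drop = FALSE],
       s = p[i + 1, j, drop = FALSE],      se = p[i + 1, j + 1, drop = FALSE])
}

#' Slope and aspect by Horn's weighted finite differences
#'
#' @param g an [lg_grid] (at least 3x3 for meaningful interior values; edge
#'   cells use replicated neighbours and are approximate).
#' @param flat_tol slope (degrees) below which a cell is flagged flat and
#'   its aspect left undefined.
#' @return list with \code{slope} (degrees, in `[0, 90)`), \code{aspect}
#'   (degrees clockwise from north, `[0, 360)`, \code{NA} on flat cells)
#'   and \code{flat} (logical matrix), the grids as [lg_grid]s.
#' @export
slope_aspect <- function(g, flat_tol = 0.01) {
  stopifnot(inherits(g, "lg_grid"))
  v <- g$values
  s8 <- shift8(v)
  cs <- g$cell_size
  dzdx <- ((s8$ne + 2 * s8$e + s8$se) - (s8$nw + 2 * s8$w + s8$sw)) / (8 * cs)
  dzdy <- ((s8$nw + 2 * s8$n + s8$ne) - (s8$sw + 2 * s8$s + s8$se)) / (8 * cs)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  flat <- !is.na(slope) & slope < flat_tol
  aspect <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  aspect[flat] <- NA_real_
  mk <- function(m) lg_grid(m, g$x_origin, g$y_origin, cs, g$nodata, g$crs)
  list(slope = mk(slope), aspect = mk(aspect), flat = flat)
}

#' Northness and eastness from aspect
#'
#' \code{Nor = cos(aspect)}, \code{Eas = sin(aspect)}; flat cells map to the
#' neutral value 0.
#'
#' @param sa output of [slope_aspect] (or a compatible list).
#' @return list of two [lg_grid]s, \code{nor} and \code{eas}.
#' @export
northness_eastness <- function(sa) {
  a <- sa$aspect$values * pi / 180
  nor <- cos(a); eas <- sin(a)
  nor[sa$flat] <- 0; eas[sa$flat] <- 0
  g <- sa$aspect
  mk <- function(m) lg_grid(m, g$x_origin, g$y_origin, g$cell_size, g$nodata, g$crs)
  list(nor = mk(nor), eas = mk(eas))
}

focal_sum <- function(v, window) {
  h <- (window - 1L) / 2L
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(0, nr, nc)
  for (dr in -h:h) for (dc in -h:h) {
    ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    out <- out + v[ri, ci, drop = FALSE]
  }
  out
}

#' Vector ruggedness measure
#'
#' Sappington-style dispersion of unit surface normals in a square moving
#' window: \code{1 - |sum of normals| / n}, in `[0, 1]`; exactly 0 on any
#' plane.
#'
#' @param g an [lg_grid].
#' @param window odd window edge length in cells (default 3).
#' @param sa optional precomputed [slope_aspect] result.
#' @return an [lg_grid].
#' @export
vrm <- function(g, window = 3L, sa = NULL) {
  stopifnot(window >= 3L, window %% 2L == 1L)
  if (is.null(sa)) sa <- slope_aspect(g)
  s <- sa$slope$values * pi / 180
  a <- sa$aspect$values * pi / 180
  sinS <- sin(s)
  nx <- sinS * sin(a); ny <- sinS * cos(a); nz <- cos(s)
  nx[sa$flat] <- 0; ny[sa$flat] <- 0; nz[sa$flat] <- 1
  rx <- focal_sum(nx, window); ry <- focal_sum(ny, window)
  rz <- focal_sum(nz, window)
  out <- 1 - sqrt(rx^2 + ry^2 + rz^2) / window^2
  out[out < 0] <- 0
  lg_grid(out, g$x_origin, g$y_origin, g$cell_size, g$nodata, g$crs)
}

check_radius <- function(g, radius) {
  if (radius < g$cell_size)
    stop("search radius (", radius, " m) smaller than the cell size (",
         g$cell_size, " m)")
}

#' Topographic openness
#'
#' Mean over azimuths of the zenith angle to the line of maximum elevation
#' within \code{radius} (positive openness, TOP), or the same on the
#' sign-inverted surface (negative openness, TON). Radians in (0, pi); a
#' plane gives pi/2.
#'
#' @param g an [lg_grid].
#' @param radius profile length in metres (>= cell size).
#' @param n_azimuths number of equally spaced azimuths.
#' @param sign \code{"positive"} (TOP) or \code{"negative"} (TON).
#' @return an [lg_grid].
#' @export
openness <- function(g, radius = 50, n_azimuths = 8L,
                     sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  check_radius(g, radius)
  out <- openness_cpp(g$values, g$cell_size, radius, as.integer(n_azimuths),
                      sign == "negative")
  lg_grid(out, g$x_origin, g$y_origin, g$cell_size, g$nodata, g$crs)
}

#' Sky-view factor
#'
#' Fraction of the hemisphere visible from each cell:
#' \code{mean(cos^2(h_d))} over azimuths, with \code{h_d} the horizon
#' elevation angle within \code{radius}. In (0, 1]; 1 on a plane.
#'
#' @inheritParams openness
#' @return an [lg_grid].
#' @export
sky_view_factor <- function(g, radius = 50, n_azimuths = 16L) {
  check_radius(g, radius)
  out <- svf_cpp(g$values, g$cell_size, radius, as.integer(n_azimuths))
  lg_grid(out, g$x_origin, g$y_origin, g$cell_size, g$nodata, g$crs)
}

#' Fill closed depressions (priority-flood)
#'
#' Minimal raising so that every cell has a non-ascending path to the grid
#' edge (nodata regions act as outlets). With \code{eps > 0} a strictly
#' descending drainage is enforced, which resolves flats for flow routing.
#'
#' @param g an [lg_grid].
#' @param eps optional per-step elevation increment (m); 0 gives the
#'   minimal fill and leaves sinkless grids unchanged.
#' @return an [lg_grid] with \code{values >= g$values} everywhere.
#' @export
fill_sinks <- function(g, eps = 0) {
  out <- fill_sinks_cpp(g$values, eps)
  lg_grid(out, g$x_origin, g$y_origin, g$cell_size, g$nodata, g$crs)
}

#' Topographic wetness index
#'
#' \code{ln(a / tan(beta))} with \code{a} the specific catchment area from
#' Freeman multiple-flow-direction accumulation (exponent
#' \code{mfd_exponent}) times the cell size, and the slope tangent floored
#' at \code{tan_floor}. The grid is sink-filled first.
#'
#' @param g an [lg_grid].
#' @param mfd_exponent Freeman flow-partition exponent (default 1.1).
#' @param tan_floor lower bound for tan(slope) (default 0.001).
#' @return an [lg_grid], finite everywhere.
#' @export
wetness_index <- function(g, mfd_exponent = 1.1, tan_floor = 0.001) {
  zf <- fill_sinks(g)
  acc <- mfd_accum_cpp(zf$values, g$cell_size, mfd_exponent)
  sca <- acc * g$cell_size
  tanb <- tan(slope_aspect(zf)$slope$values * pi / 180)
  out <- log(sca / pmax(tanb, tan_floor))
  lg_grid(out, g$x_origin, g$y_origin, g$cell_size, g$nodata, g$crs)
}

#' Downstream flow-path length
#'
#' Distance (m) along the D8 steepest-descent path from each cell to the
#' grid edge (or to an unresolvable pit); cells on the boundary are 0;
#' diagonal steps count \code{cell_size * sqrt(2)}. The grid is sink-filled
#' (with a small drainage epsilon) first.
#'
#' @param g an [lg_grid].
#' @param eps drainage-enforcement increment passed to [fill_sinks].
#' @return an [lg_grid] of non-negative distances.
#' @export
flow_path_length <- function(g, eps = 1e-6) {
  zf <- fill_sinks(g, eps = eps)
  out <- d8_fpl_cpp(zf$values, g$cell_size)
  lg_grid(out, g$x_origin, g$y_origin, g$cell_size, g$nodata, g$crs)
}

#' Wind exposure index
#'
#' Isotropic horizon-based exposure: for each azimuth the distance-weighted
#' mean of the slope angles from the focal cell to the terrain along the
#' profile is computed; rising terrain (shelter) contributes negatively,
#' overlooked terrain positively. The index is
#' \code{1 + mean_d(-(2/pi) * atan(weighted mean angle))}: about 1 on a
#' plane, > 1 on crests, < 1 in hollows. No prevailing wind direction is
#' assumed.
#'
#' @param g an [lg_grid].
#' @param radius profile length in metres (default 300).
#' @param n_azimuths number of azimuths (default 8).
#' @param decay per-metre distance weight (weight at distance d is
#'   \code{decay^d}; default 0.99).
#' @return an [lg_grid].
#' @export
wind_exposure <- function(g, radius = 300, n_azimuths = 8L, decay = 0.99) {
  check_radius(g, radius)
  out <- wex_cpp(g$values, g$cell_size, radius, as.integer(n_azimuths), decay)
  lg_grid(out, g$x_origin, g$y_origin, g$cell_size, g$nodata, g$crs)
}

# solar position table for one month: one row per time step with the sun
# above the astronomical horizon
sun_table <- function(month = c("june", "december"), latitude = 46.433,
                      transmittance = 0.7, step_minutes = 60,
                      n_azimuths = 16L) {
  month <- match.arg(month)
  days <- if (month == "june") 152:181 else 335:365
  phi <- latitude * pi / 180
  hours <- seq(step_minutes / 60 / 2, 24 - step_minutes / 60 / 2,
               by = step_minutes / 60)
  out <- NULL
  for (d in days) {
    decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + d) / 365)
    H <- (hours - 12) * 15 * pi / 180
    sinh_ <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(H)
    keep <- sinh_ > 1e-3
    if (!any(keep)) next
    sinh_ <- sinh_[keep]
    Hk <- H[keep]
    cosh_ <- sqrt(pmax(1 - sinh_^2, 0))
    cosA <- (sin(decl) - sinh_ * sin(phi)) / pmax(cosh_ * cos(phi), 1e-9)
    A <- acos(pmin(pmax(cosA, -1), 1))
    A <- ifelse(Hk > 0, 2 * pi - A, A)
    tb <- transmittance^(1 / sinh_)
    out <- rbind(out, cbind(sinh_ = sinh_, A = A, tb = tb))
  }
  h <- asin(pmin(pmax(out[, "sinh_"], -1), 1))
  sector <- as.integer(round(out[, "A"] / (2 * pi / n_azimuths)) %% n_azimuths)
  list(h = h, sinh = out[, "sinh_"], cosh = cos(h),
       sinaz = sin(out[, "A"]), cosaz = cos(out[, "A"]),
       tb = out[, "tb"], sector = sector,
       step_hours = step_minutes / 60)
}

#' Monthly clear-sky solar radiation
#'
#' Total June or December irradiation (kWh/m^2) on the sloping surface:
#' direct beam \code{1.367 * transmittance^(1/sin h) * cos(incidence)},
#' zeroed whenever the sun is below the DEM horizon in its azimuth, plus
#' isotropic diffuse irradiance
#' \code{1.367 * diffuse_fraction * (1 - transmittance^(1/sin h))} weighted
#' by the sky-view factor. Solar positions follow the standard
#' declination/hour-angle formulas at the given latitude.
#'
#' @param g an [lg_grid].
#' @param month \code{"june"} or \code{"december"}.
#' @param latitude degrees north (default 46.433).
#' @param transmittance lumped clear-sky atmospheric transmittance.
#' @param step_minutes integration time step.
#' @param horizon_radius profile length (m) for cast-shadow horizon angles.
#' @param n_azimuths horizon sectors.
#' @param diffuse_fraction isotropic diffuse share of the extinguished beam.
#' @param sa,svf optional precomputed [slope_aspect] / [sky_view_factor]
#'   results (recomputed when \code{NULL}).
#' @param horizon optional precomputed horizon-angle matrix (cells x
#'   azimuth sectors, from the internal horizon scan) so the two monthly
#'   totals can share one horizon computation.
#' @return an [lg_grid] of monthly totals, kWh/m^2.
#' @export
solar_radiation <- function(g, month = c("june", "december"),
                            latitude = 46.433, transmittance = 0.7,
                            step_minutes = 60, horizon_radius = 100,
                            n_azimuths = 16L, diffuse_fraction = 0.3,
                            sa = NULL, svf = NULL, horizon = NULL) {
  month <- match.arg(month)
  check_radius(g, horizon_radius)
  if (is.null(sa)) sa <- slope_aspect(g)
  if (is.null(svf)) svf <- sky_view_factor(g)
  sun <- sun_table(month, latitude, transmittance, step_minutes, n_azimuths)
  hor <- if (is.null(horizon))
    horizon_cpp(g$values, g$cell_size, horizon_radius, as.integer(n_azimuths))
  else horizon
  s <- sa$slope$values * pi / 180
  a <- sa$aspect$values * pi / 180
  sinA <- sin(a); cosA <- cos(a)
  sinA[sa$flat] <- 0; cosA[sa$flat] <- 0
  S0 <- 1.367
  e <- solar_accumulate_cpp(as.vector(sin(s)), as.vector(cos(s)),
                            as.vector(sinA), as.vector(cosA),
                            as.vector(svf$values), hor, sun$sector,
                            sun$h, sun$sinh, sun$cosh, sun$sinaz, sun$cosaz,
                            beam = S0 * sun$tb,
                            diffuse = S0 * diffuse_fraction * (1 - sun$tb),
                            step_hours = sun$step_hours)
  lg_grid(matrix(e, nrow(g$values), ncol(g$values)),
          g$x_origin, g$y_origin, g$cell_size, g$nodata, g$crs)
}

#' Default terrain-stack configuration
#'
#' Search radii and operator settings used by [compute_stack]; all recorded
#' in the stack's metadata.
#' @param ... overrides for individual entries.
#' @return named list of parameters.
#' @export
terrain_config <- function(...) {
  cfg <- list(vrm_window = 3L,
              openness_radius = 50, openness_azimuths = 8L,
              svf_radius = 50, svf_azimuths = 16L,
              wex_radius = 300, wex_azimuths = 8L, wex_decay = 0.99,
              solar_latitude = 46.433, solar_transmittance = 0.7,
              solar_step_minutes = 60, solar_horizon_radius = 100,
              solar_azimuths = 16L, diffuse_fraction = 0.3,
              mfd_exponent = 1.1, tan_floor = 0.001, flat_tol = 0.01)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' All terrain variable names computed by [compute_stack]
#' @export
terrain_variables <- function() {
  c("Nor", "Eas", "Slo", "VRM", "TOP", "TON", "SVF", "SWI", "FPL", "WEX",
    "Ti6", "Ti12")
}

#' Compute the multiscale terrain-variable stack
#'
#' Derives the 12 terrain variables on every level of a grid pyramid
#' (altitude is taken from the sample table, not from the stack).
#'
#' @param pyr named list of [lg_grid]s from [build_pyramid].
#' @param vars subset of [terrain_variables] (default: all).
#' @param config a [terrain_config].
#' @return a \code{terrain_stack}: list \code{stack[[var]][[res]]} of
#'   [lg_grid]s with the configuration stored as an attribute.
#' @export
compute_stack <- function(pyr, vars = terrain_variables(),
                          config = terrain_config()) {
  stopifnot(all(vars %in% terrain_variables()))
  out <- lapply(vars, function(v) list())
  names(out) <- vars
  for (res in names(pyr)) {
    g <- pyr[[res]]
    sa <- slope_aspect(g, flat_tol = config$flat_tol)
    need_svf <- any(c("SVF", "Ti6", "Ti12") %in% vars)
    svf <- if (need_svf)
      sky_view_factor(g, config$svf_radius, config$svf_azimuths)
    if ("Slo" %in% vars) out$Slo[[res]] <- sa$slope
    if (any(c("Nor", "Eas") %in% vars)) {
      ne <- northness_eastness(sa)
      if ("Nor" %in% vars) out$Nor[[res]] <- ne$nor
      if ("Eas" %in% vars) out$Eas[[res]] <- ne$eas
    }
    if ("VRM" %in% vars) out$VRM[[res]] <- vrm(g, config$vrm_window, sa = sa)
    if ("TOP" %in% vars)
      out$TOP[[res]] <- openness(g, config$openness_radius,
                                 config$openness_azimuths, "positive")
    if ("TON" %in% vars)
      out$TON[[res]] <- openness(g, config$openness_radius,
                                 config$openness_azimuths, "negative")
    if ("SVF" %in% vars) out$SVF[[res]] <- svf
    if ("SWI" %in% vars)
      out$SWI[[res]] <- wetness_index(g, config$mfd_exponent, config$tan_floor)
    if ("FPL" %in% vars) out$FPL[[res]] <- flow_path_length(g)
    if ("WEX" %in% vars)
      out$WEX[[res]] <- wind_exposure(g, config$wex_radius,
                                      config$wex_azimuths, config$wex_decay)
    if (any(c("Ti6", "Ti12") %in% vars)) {
      hor <- horizon_cpp(g$values, g$cell_size, config$solar_horizon_radius,
                         as.integer(config$solar_azimuths))
      for (m in c("june", "december")) {
        v <- if (m == "june") "Ti6" else "Ti12"
        if (v %in% vars)
          out[[v]][[res]] <- solar_radiation(
            g, m, config$solar_latitude, config$solar_transmittance,
            config$solar_step_minutes, config$solar_horizon_radius,
            config$solar_azimuths, config$diffuse_fraction,
            sa = sa, svf = svf, horizon = hor)
      }
    }
  }
  structure(out, class = "terrain_stack", config = config,
            resolutions = names(pyr))
}

#' Extract stack values at sample locations
#'
#' @param stack a \code{terrain_stack} from [compute_stack].
#' @param samples a sample table (see [read_samples]).
#' @return long data frame with columns \code{id}, \code{var}, \code{res}
#'   (cell size in metres), \code{value}.
#' @export
extract_stack <- function(stack, samples) {
  out <- list()
  k <- 1L
  for (v in names(stack)) {
    for (res in names(stack[[v]])) {
      vals <- suppressWarnings(extract_at(stack[[v]][[res]], samples))
      out[[k]] <- data.frame(id = samples$id, var = v,
                             res = as.numeric(res),
                             value = as.numeric(vals),
                             stringsAsFactors = FALSE)
      k <- k + 1L
    }
  }
  do.call(rbind, out)
}

#' Write every grid of a terrain stack to a directory
#'
#' Files are named \code{<var>_<res>m.asc}.
#' @param stack a \code{terrain_stack}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in names(stack))
    for (res in names(stack[[v]]))
      write_grid(stack[[v]][[res]],
                 file.path(dir, sprintf("%s_%sm.asc", v, res)))
  invisible(dir)
}
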