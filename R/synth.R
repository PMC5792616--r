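#' Synthetic ridge-landscape scenario configuration
#'
#' Defines the generative conditions for the synthetic study system: an
#' alpine ridge population of a polyploid, outcrossing plant sampled in a
#' cluster design and genotyped with dominant (band presence/absence)
#' markers drawn from two gene pools joined by an admixture cline, with a
#' small minority of loci whose band probability follows a logistic
#' function of a terrain variable.
#'
#' Defaults encode the study conditions the package emulates: a 1.2 km
#' ridge spanning 1,864-2,043 m elevation modelled at 0.5 m resolution; 361
#' individuals in 4 x 4 m areas (random 0-25 m spacings) subdivided into
#' 2 x 2 m plots of at least five plants; 233 polymorphic dominant loci
#' with a 2.93% genotyping error rate and a 0.05 minor-variant frequency
#' filter; per-locus pool frequency gaps of 0.05-0.20 and a 125 m-wide
#' admixture cline (which yields roughly 29% admixed individuals); and five
#' adaptive loci tied to terrain variables at specific resolutions with
#' logistic effect sizes of 1.5 per standard deviation.
#'
#' @param seed integer seed; every generator function derives its stream
#'   from it.
#' @param ... overrides for any configuration entry.
#' @return a \code{scenario_config} list.
#' @export
scenario_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    # landscape
    ridge_length = 1200, ridge_width = 120, base_res = 0.5,
    elev_range = c(1864, 2043),
    crest_sigma = 22, crest_amp = 160,
    undulation_amp = 15, undulation_wavelength = 300,
    noise_sd = 4, noise_exponent = 3,
    # sampling design
    n_individuals = 361, area_size = 4, plot_size = 2,
    gap_range = c(0, 25), plot_occupancy = 0.25,
    plot_min = 5, plot_max = 8, cross_jitter_sd = 18,
    gps_alt_sd = 0.04,
    # genotypes
    n_loci = 233, n_adaptive = 5,
    cline_center = 600, cline_width = 125, q_noise_sd = 0.5,
    pool_divergence = 0.2,  # max per-locus band-frequency gap; min is 1/4 of it
    adaptive_links = data.frame(
      variable = c("WEX", "TON", "Nor", "Ti12", "SWI"),
      res = c(0.5, 0.5, 1, 1, 2),
      beta0 = c(0, 0, 0, 0, 0),
      beta1 = c(1.5, -1.5, 1.5, -1.5, 1.5),
      stringsAsFactors = FALSE),
    error_rate = 0.0293, maf_min = 0.05, missing_rate = 0)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown scenario fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$n_adaptive <= cfg$n_loci,
            nrow(cfg$adaptive_links) == cfg$n_adaptive,
            cfg$cline_width > 0, cfg$pool_divergence >= 0,
            cfg$pool_divergence <= 1, cfg$error_rate >= 0,
            cfg$error_rate < 0.5)
  structure(cfg, class = "scenario_config")
}

# power-law ("fractal") noise field by spectral synthesis
spectral_noise <- function(nr, nc, exponent, sd_target) {
  fr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  f <- sqrt(outer(fr^2, fc^2, "+"))
  amp <- ifelse(f > 0, f^(-exponent / 2), 0)
  wh <- matrix(stats::rnorm(nr * nc), nr, nc)
  z <- Re(stats::fft(stats::fft(wh) * amp, inverse = TRUE)) / (nr * nc)
  z <- z - mean(z)
  if (stats::sd(z) > 0) z <- z * sd_target / stats::sd(z)
  z
}

#' Generate the synthetic ridge elevation model
#'
#' An elongated ridge with a Gaussian cross-profile, a sinusoidal
#' along-axis undulation of the crest, and a seedable correlated
#' (power-law spectrum) noise field, min-max scaled into the configured
#' elevation range. Deterministic given the seed.
#'
#' @param cfg a [scenario_config].
#' @param seed RNG seed (defaults to \code{cfg$seed}).
#' @return an [lg_grid].
#' @export
make_ridge_dem <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(seed)
  nc <- round(cfg$ridge_length / cfg$base_res)
  nr <- round(cfg$ridge_width / cfg$base_res)
  xs <- (seq_len(nc) - 0.5) * cfg$base_res
  ys <- (seq_len(nr) - 0.5) * cfg$base_res
  yc <- cfg$ridge_width / 2
  profile <- exp(-(ys - yc)^2 / (2 * cfg$crest_sigma^2))
  undul <- cfg$undulation_amp * sin(2 * pi * xs / cfg$undulation_wavelength)
  z <- cfg$crest_amp * outer(profile, rep(1, nc)) +
    outer(rep(1, nr), undul) +
    spectral_noise(nr, nc, cfg$noise_exponent, cfg$noise_sd)
  z <- cfg$elev_range[1] +
    (z - min(z)) / (max(z) - min(z)) * diff(cfg$elev_range)
  lg_grid(z, x_origin = 0, y_origin = cfg$ridge_width,
          cell_size = cfg$base_res, crs = "synthetic-meters")
}

#' Generate the cluster sampling design
#'
#' Walks 4 x 4 m areas along the ridge crest at random 0-25 m spacings;
#' each area is subdivided into four 2 x 2 m plots, a random subset of
#' which is occupied (emulating the rule that plots are only sampled when
#' at least five plants are present). Retained plots hold 5-8 individuals,
#' jittered uniformly inside the plot, for an exact total of
#' \code{cfg$n_individuals}.
#'
#' @param cfg a [scenario_config].
#' @param dem the ridge [lg_grid] from [make_ridge_dem].
#' @param seed RNG seed (defaults to \code{cfg$seed + 1}).
#' @return a sample table (data frame \code{id,x,y,alt,plot_id}) with an
#'   \code{"areas"} attribute recording area anchors and the sampled gaps.
#' @export
make_sampling <- function(cfg, dem, seed = cfg$seed + 1) {
  stopifnot(inherits(cfg, "scenario_config"), inherits(dem, "lg_grid"))
  set.seed(seed)
  n <- cfg$n_individuals
  a <- cfg$area_size
  ps <- cfg$plot_size
  yc <- cfg$ridge_width / 2
  ymax <- cfg$ridge_width - a - 2
  plots <- list()
  areas <- list()
  x <- 2 + stats::runif(1, cfg$gap_range[1], cfg$gap_range[2])
  ai <- 0L
  while (x + a < cfg$ridge_length - 2) {
    ai <- ai + 1L
    ay <- yc - a / 2 + stats::rnorm(1, 0, cfg$cross_jitter_sd)
    ay <- min(max(ay, 2), ymax)
    gap <- stats::runif(1, cfg$gap_range[1], cfg$gap_range[2])
    areas[[ai]] <- data.frame(area = ai, x0 = x, y0 = ay, gap_after = gap)
    occ <- stats::runif(4) < cfg$plot_occupancy
    for (p in which(occ)) {
      dx <- ((p - 1) %% 2) * ps
      dy <- ((p - 1) %/% 2) * ps
      plots[[length(plots) + 1L]] <-
        list(id = sprintf("a%03dp%d", ai, p), x0 = x + dx, y0 = ay + dy)
    }
    x <- x + a + gap
  }
  n_plots <- length(plots)
  if (n_plots < ceiling(n / cfg$plot_max))
    stop("ridge too short for the target number of individuals")
  p_use <- min(n_plots, max(ceiling(n / cfg$plot_max), round(n / 5.5)))
  keep <- sort(sample.int(n_plots, p_use))
  plots <- plots[keep]
  sizes <- rep(cfg$plot_min, p_use)
  rem <- n - sum(sizes)
  if (rem < 0) stop("cannot allocate individuals: too many plots retained")
  while (rem > 0) {
    open <- which(sizes < cfg$plot_max)
    take <- open[sample.int(length(open), 1)]
    sizes[take] <- sizes[take] + 1L
    rem <- rem - 1L
  }
  rows <- list()
  k <- 0L
  for (i in seq_len(p_use)) {
    for (j in seq_len(sizes[i])) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        id = sprintf("ind%03d", k),
        x = plots[[i]]$x0 + stats::runif(1, 0.05, ps - 0.05),
        y = plots[[i]]$y0 + stats::runif(1, 0.05, ps - 0.05),
        plot_id = plots[[i]]$id, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df$alt <- extract_at(dem, df) + stats::rnorm(nrow(df), 0, cfg$gps_alt_sd)
  df <- validate_samples(df[c("id", "x", "y", "alt", "plot_id")])
  attr(df, "areas") <- do.call(rbind, areas)
  df
}

#' Simulate dominant-marker genotypes over the landscape
#'
#' Each individual carries a latent admixture proportion \code{q*}: a
#' logistic cline along the ridge axis plus individual logit-normal noise.
#' A neutral locus l has band probability
#' \code{q* p_Al + (1 - q*) p_Bl} with pool frequencies differing by a
#' per-locus gap; an adaptive locus has band probability
#' \code{plogis(beta0 + beta1 * z)} with \code{z} the standardised linked
#' terrain variable at its linked resolution. Symmetric Bernoulli scoring
#' errors are applied at the configured rate, and loci failing the
#' minor-variant frequency filter are redrawn so the matrix keeps exactly
#' \code{n_loci} polymorphic loci.
#'
#' @param cfg a [scenario_config].
#' @param samples the sample table from [make_sampling].
#' @param stack a \code{terrain_stack} covering every adaptive link (may be
#'   \code{NULL} when \code{n_adaptive = 0}).
#' @param seed RNG seed (defaults to \code{cfg$seed + 2}).
#' @return list with \code{genotypes} (individuals x loci 0/1 matrix with
#'   dimnames) and \code{truth} (the generative record: \code{q_star},
#'   per-locus \code{class}, the \code{links} table with locus names, and
#'   the pool frequencies). The truth record is never consumed by the
#'   analysis modules.
#' @export
simulate_genotypes <- function(cfg, samples, stack = NULL,
                               seed = cfg$seed + 2) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (cfg$n_adaptive > 0 && is.null(stack))
    stop("a terrain stack is required when adaptive loci are configured")
  set.seed(seed)
  n <- nrow(samples)
  L <- cfg$n_loci
  q <- stats::plogis((samples$x - cfg$cline_center) / cfg$cline_width +
                       stats::rnorm(n, 0, cfg$q_noise_sd))
  links <- cfg$adaptive_links
  nA <- cfg$n_adaptive
  loci_names <- sprintf("L%03d", seq_len(L))
  adaptive_idx <- if (nA > 0) sort(sample.int(L, nA)) else integer(0)
  # standardized linked environmental values
  zlink <- matrix(0, n, nA)
  if (nA > 0) {
    for (k in seq_len(nA)) {
      v <- links$variable[k]
      res <- format(links$res[k])
      if (is.null(stack[[v]][[res]]))
        stop("terrain stack does not cover adaptive link ", v, "@", res, " m")
      val <- extract_at(stack[[v]][[res]], samples)
      if (stats::sd(val, na.rm = TRUE) == 0)
        stop("linked variable ", v, " is constant; cannot standardise")
      zlink[, k] <- as.numeric(scale(val))
    }
  }
  draw_neutral_probs <- function(nl) {
    pA <- stats::runif(nl, 0.1, 0.9)
    gap <- stats::runif(nl, cfg$pool_divergence / 4, cfg$pool_divergence) *
      sample(c(-1, 1), nl, replace = TRUE)
    pB <- pmin(pmax(pA + gap, 0.02), 0.98)
    cbind(pA, pB)
  }
  pool <- draw_neutral_probs(L)
  prob <- q %o% pool[, 1] + (1 - q) %o% pool[, 2]
  if (nA > 0)
    for (k in seq_len(nA))
      prob[, adaptive_idx[k]] <-
        stats::plogis(links$beta0[k] + links$beta1[k] * zlink[, k])
  draw <- function(pr) {
    y <- matrix(stats::rbinom(length(pr), 1, pr), nrow(pr), ncol(pr))
    if (cfg$error_rate > 0) {
      flip <- matrix(stats::rbinom(length(pr), 1, cfg$error_rate),
                     nrow(pr), ncol(pr))
      y <- abs(y - flip)
    }
    y
  }
  y <- draw(prob)
  # enforce the minor-variant frequency filter by redrawing failing loci
  for (round in seq_len(100)) {
    f <- colMeans(y)
    bad <- which(pmin(f, 1 - f) <= cfg$maf_min)
    if (!length(bad)) break
    if (round == 100)
      stop("minor-variant frequency filter unattainable under the ",
           "configured pool frequencies")
    redraw_neutral <- setdiff(bad, adaptive_idx)
    if (length(redraw_neutral)) {
      pool[redraw_neutral, ] <- draw_neutral_probs(length(redraw_neutral))
      prob[, redraw_neutral] <-
        q %o% pool[redraw_neutral, 1] + (1 - q) %o% pool[redraw_neutral, 2]
    }
    y[, bad] <- draw(prob[, bad, drop = FALSE])
  }
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(length(y)) < cfg$missing_rate,
                   nrow(y), ncol(y))
    y[miss] <- NA_integer_
  }
  dimnames(y) <- list(samples$id, loci_names)
  cls <- rep("neutral", L)
  cls[adaptive_idx] <- "adaptive"
  links_out <- if (nA > 0)
    cbind(data.frame(locus = loci_names[adaptive_idx],
                     stringsAsFactors = FALSE), links)
  else NULL
  list(genotypes = y,
       truth = list(q_star = stats::setNames(q, samples$id),
                    class = stats::setNames(cls, loci_names),
                    links = links_out,
                    pool_freq = data.frame(locus = loci_names,
                                           p_A = pool[, 1], p_B = pool[, 2])))
}

#' Run the full synthetic generator
#'
#' Convenience wrapper: elevation model, pyramid, terrain stack, sampling
#' design and genotypes in one call.
#'
#' @param cfg a [scenario_config].
#' @param vars terrain variables to compute (default: those needed by the
#'   adaptive links plus any in \code{extra_vars}).
#' @param extra_vars additional stack variables to compute.
#' @param terrain_cfg a [terrain_config].
#' @return list with \code{dem}, \code{pyramid}, \code{stack},
#'   \code{samples}, \code{genotypes}, \code{truth}.
#' @export
simulate_scenario <- function(cfg = scenario_config(),
                              vars = NULL, extra_vars = character(0),
                              terrain_cfg = terrain_config()) {
  dem <- make_ridge_dem(cfg)
  pyr <- build_pyramid(dem, resolution_ladder(cfg$base_res))
  if (is.null(vars))
    vars <- union(unique(cfg$adaptive_links$variable), extra_vars)
  stack <- compute_stack(pyr, vars = vars, config = terrain_cfg)
  samples <- make_sampling(cfg, dem)
  sim <- simulate_genotypes(cfg, samples, stack)
  list(dem = dem, pyramid = pyr, stack = stack, samples = samples,
       genotypes = sim$genotypes, truth = sim$truth)
}
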