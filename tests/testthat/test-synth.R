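test_that("the ridge elevation model is deterministic, bounded and crest-shaped", {
  cfg <- small_cfg()
  d1 <- make_ridge_dem(cfg)
  d2 <- make_ridge_dem(cfg)
  expect_identical(d1$values, d2$values)
  expect_equal(range(d1$values), cfg$elev_range)
  expect_equal(dim(d1$values),
               c(cfg$ridge_width / cfg$base_res,
                 cfg$ridge_length / cfg$base_res))
  # crest: per-column maximum lies near the central row
  crest_row <- nrow(d1$values) / 2
  mx <- apply(d1$values, 2, which.max)
  expect_true(all(abs(mx - crest_row) <= cfg$crest_sigma / cfg$base_res))
  # a different seed gives different terrain
  expect_false(identical(make_ridge_dem(cfg, seed = 99)$values, d1$values))
})

test_that("the cluster sampling design respects plot sizes, bounds and spacing", {
  sc <- small_scenario()
  cfg <- small_cfg()
  s <- sc$samples
  expect_equal(nrow(s), cfg$n_individuals)
  expect_false(anyDuplicated(s$id) > 0)
  # all inside the grid
  expect_true(all(s$x > 0 & s$x < cfg$ridge_length &
                    s$y > 0 & s$y < cfg$ridge_width))
  # every retained plot holds at least five individuals
  expect_true(all(table(s$plot_id) >= cfg$plot_min))
  expect_true(all(table(s$plot_id) <= cfg$plot_max))
  # consecutive areas are separated by at least the drawn gap
  ar <- attr(s, "areas")
  gaps <- diff(ar$x0) - cfg$area_size
  expect_true(all(gaps >= ar$gap_after[-nrow(ar)] - 1e-9))
  expect_true(all(gaps >= cfg$gap_range[1]))
  # measured altitude tracks the DEM within GPS noise
  expect_lt(max(abs(s$alt - extract_at(sc$dem, s))), 6 * cfg$gps_alt_sd)
})

test_that("genotypes are deterministic, complete and respect the frequency filter", {
  sc <- small_scenario()
  cfg <- small_cfg()
  g1 <- simulate_genotypes(cfg, sc$samples, sc$stack)
  g2 <- simulate_genotypes(cfg, sc$samples, sc$stack)
  expect_identical(g1$genotypes, g2$genotypes)
  gm <- g1$genotypes
  expect_equal(dim(gm), c(cfg$n_individuals, cfg$n_loci))
  expect_true(all(gm %in% c(0, 1)))
  f <- colMeans(gm)
  expect_true(all(pmin(f, 1 - f) > cfg$maf_min))
  # truth record is aligned and never empty
  expect_equal(names(g1$truth$q_star), sc$samples$id)
  expect_equal(sum(g1$truth$class == "adaptive"), cfg$n_adaptive)
  expect_equal(nrow(g1$truth$links), cfg$n_adaptive)
})

test_that("per-locus band frequencies track their generating means within binomial error", {
  sc <- small_scenario()
  cfg <- small_cfg(seed = 21)
  sim <- simulate_genotypes(cfg, sc$samples, sc$stack, seed = 77)
  q <- sim$truth$q_star
  pf <- sim$truth$pool_freq
  neutral <- names(sim$truth$class)[sim$truth$class == "neutral"]
  err <- cfg$error_rate
  n <- length(q)
  dev <- vapply(neutral, function(l) {
    pr <- q * pf$p_A[pf$locus == l] + (1 - q) * pf$p_B[pf$locus == l]
    pr <- pr * (1 - err) + (1 - pr) * err  # error flips shift the mean
    mu <- mean(pr)
    (mean(sim$genotypes[, l]) - mu) / sqrt(mu * (1 - mu) / n)
  }, numeric(1))
  # z-scores: none wildly out, and centred near 0 (the MAF redraw trims a
  # small amount of mass at the extremes)
  expect_lt(max(abs(dev)), 4)
  expect_lt(abs(mean(dev)), 0.5)
})

test_that("null configurations produce the degenerate structures they should", {
  sc <- small_scenario()
  # beta1 = 0 everywhere: adaptive loci are exchangeable with neutral ones
  cfg0 <- small_cfg()
  cfg0$adaptive_links$beta1 <- 0
  sim0 <- simulate_genotypes(cfg0, sc$samples, sc$stack, seed = 5)
  ad <- sim0$truth$links$locus
  fr <- colMeans(sim0$genotypes)
  expect_true(all(pmin(fr[ad], 1 - fr[ad]) > cfg0$maf_min))
  # plogis(0) = 0.5 band probability for every adaptive locus
  expect_true(all(abs(fr[ad] - 0.5) < 4 * sqrt(0.25 / nrow(sim0$genotypes))))
  # pool_divergence = 0 and a flat cline: homogeneous frequencies along the
  # ridge (first vs second half of the axis)
  cfgn <- small_cfg()
  cfgn$pool_divergence <- 0
  cfgn$n_adaptive <- 0
  cfgn$adaptive_links <- cfgn$adaptive_links[0, ]
  simn <- simulate_genotypes(cfgn, sc$samples, NULL, seed = 6)
  west <- sc$samples$x < median(sc$samples$x)
  fw <- colMeans(simn$genotypes[west, ])
  fe <- colMeans(simn$genotypes[!west, ])
  z <- (fw - fe) / sqrt(fw * (1 - fw) / sum(west) + fe * (1 - fe) / sum(!west))
  expect_lt(mean(abs(z) > 2), 0.12)  # ~5% expected under homogeneity
})

test_that("unattainable frequency filters are reported as configuration errors", {
  sc <- small_scenario()
  cfg <- small_cfg()
  cfg$maf_min <- 0.49  # band frequencies can essentially never satisfy this
  expect_error(simulate_genotypes(cfg, sc$samples, sc$stack),
               "filter unattainable")
})
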