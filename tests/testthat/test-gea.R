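test_that("the Laplace fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  set.seed(12)
  n <- 300; G <- 60
  gidx <- sort(sample(seq_len(G), n, replace = TRUE))
  x <- rnorm(n)
  u <- rnorm(G, 0, 0.9)
  y <- rbinom(n, 1, plogis(-0.3 + 0.8 * x + u[gidx]))
  fit <- fit_binomial_glmm(y, x, gidx)
  ref <- suppressMessages(lme4::glmer(y ~ x + (1 | gidx), family = binomial))
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 0.01)
  expect_equal(fit$beta1, unname(lme4::fixef(ref)[2]), tolerance = 0.01)
  expect_equal(fit$sigma_u, sqrt(unname(unlist(lme4::VarCorr(ref)))),
               tolerance = 0.02)
  expect_equal(fit$se_beta1,
               unname(summary(ref)$coefficients[2, 2]), tolerance = 0.02)
  expect_equal(fit$aic, 2 * 3 - 2 * fit$loglik)
})

test_that("with sigma_u estimated at zero the fit is exactly fixed-effects logistic regression", {
  set.seed(3)
  n <- 250
  gidx <- rep(1:50, each = 5)
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.4 + 0.6 * x))  # no group effect
  fit <- fit_binomial_glmm(y, x, gidx)
  ref <- glm(y ~ x, family = binomial)
  if (fit$sigma_u == 0) {
    expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
    expect_equal(unname(fit$beta1), unname(coef(ref)[2]), tolerance = 1e-6)
  } else {
    # a positive variance estimate must improve on the logistic likelihood
    expect_gte(fit$loglik, as.numeric(logLik(ref)))
  }
  # null model reduction too
  fit0 <- fit_binomial_glmm(y, groups = gidx)
  ref0 <- glm(y ~ 1, family = binomial)
  if (fit0$sigma_u == 0)
    expect_equal(fit0$loglik, as.numeric(logLik(ref0)), tolerance = 1e-6)
})

test_that("adaptive Gauss-Hermite quadrature corroborates the Laplace likelihood", {
  set.seed(21)
  n <- 200; G <- 40
  gidx <- rep(seq_len(G), each = 5)
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.2 + 0.7 * x + rnorm(G, 0, 0.8)[gidx]))
  fit <- fit_binomial_glmm(y, x, gidx)
  for (nodes in c(5, 9, 15)) {
    ll_agq <- glmm_loglik_agq(y, x, gidx, beta0 = fit$beta0,
                              beta1 = fit$beta1, sigma_u = fit$sigma_u,
                              n_nodes = nodes)
    expect_equal(ll_agq, fit$loglik, tolerance = 0.02)
  }
  # quadrature converges as nodes grow
  l9 <- glmm_loglik_agq(y, x, gidx, fit$beta0, fit$beta1, fit$sigma_u, 9)
  l25 <- glmm_loglik_agq(y, x, gidx, fit$beta0, fit$beta1, fit$sigma_u, 25)
  expect_equal(l9, l25, tolerance = 1e-4)
})

test_that("simulation-recovery: estimates fall within three standard errors of truth", {
  set.seed(31)
  n_grp <- 200; per <- 5
  gidx <- rep(seq_len(n_grp), each = per)
  x <- rnorm(n_grp * per)
  u <- rnorm(n_grp, 0, 0.8)
  y <- rbinom(n_grp * per, 1, plogis(0.5 + 1.0 * x + u[gidx]))
  fit <- fit_binomial_glmm(y, x, gidx)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta0 - 0.5) / fit$se_beta0, 3)
  expect_lt(abs(fit$beta1 - 1.0) / fit$se_beta1, 3)
  expect_gt(fit$sigma_u, 0.4)
  expect_lt(fit$sigma_u, 1.2)
})

test_that("degenerate designs are rejected or flagged, never silently wrong", {
  y <- rbinom(100, 1, 0.5)
  expect_error(fit_binomial_glmm(y, x = rep(1, 100), groups = rep(1:20, 5)),
               "constant")
  expect_warning(fit_binomial_glmm(y, groups = seq_len(100)), "singleton")
  expect_error(fit_binomial_glmm(c(y[1:99], 2), groups = rep(1:20, 5)), "0/1")
})

test_that("likelihood-ratio identities hold, including the AIC recovery form", {
  expect_equal(lrt_pvalue(-100, -100)$p, 1)
  expect_equal(lrt_pvalue(-95, -100)$stat, 10)
  # numerical jitter below the convergence tolerance is clipped at zero
  expect_equal(lrt_pvalue(-100 - 1e-9, -100)$stat, 0)
  out <- lrt_from_aic(250, 245)
  expect_equal(out$stat, 7)
  expect_equal(out$p, pchisq(7, 1, lower.tail = FALSE))
  expect_equal(bonferroni_threshold(0.05, 20), 0.0025)
})

test_that("the multiscale scan yields the right record grid with valid internal identities", {
  sc <- small_scenario()
  gmq <- qc_filter(sc$genotypes)
  env <- extract_stack(sc$stack, sc$samples)
  memb <- setNames(plogis(rnorm(nrow(sc$samples))), sc$samples$id)
  lab <- assign_populations(setNames(
    plogis((sc$samples$x - 120) / 10), sc$samples$id))
  rec <- scan_gea(gmq, env, sc$samples, sc$pyramid, membership = memb,
                  assignment = lab)
  n_vars <- length(unique(env$var))
  n_res <- length(unique(env$res))
  expect_equal(nrow(rec), ncol(gmq) * (n_vars * n_res + 4))
  expect_equal(attr(rec, "alpha_adj"), 0.05 / nrow(rec))
  # AIC <-> LRT identity on every converged record
  ok <- rec$converged
  expect_true(all(abs(rec$lrt_stat[ok] -
                        pmax(0, rec$aic_null[ok] - rec$aic_full[ok] + 2))
                  < 1e-9))
  expect_true(all(rec$p[ok] > 0 & rec$p[ok] <= 1))
  expect_true(all(rec$lrt_stat[ok] >= 0))
  expect_true(all(rec$sigma_u[ok] >= 0))
  # frequencies attached and bounded
  expect_true(all(rec$freq_A >= 0 & rec$freq_A <= 1))
  # extra covariates use the plot grouping: as many groups as plots
  alt_rec <- rec[rec$variable == "Alt", ]
  expect_true(all(alt_rec$n_groups == length(unique(sc$samples$plot_id))))
})

test_that("a planted locus is recovered with its strongest signal at or adjacent to the generating resolution", {
  sc <- small_scenario()
  gmq <- qc_filter(sc$genotypes)
  env <- extract_stack(sc$stack, sc$samples)
  rec <- scan_gea(gmq, env, sc$samples, sc$pyramid, extra_vars = FALSE)
  links <- sc$truth$links
  res_grid <- sort(unique(env$res))
  for (k in seq_len(nrow(links))) {
    sub <- rec[rec$locus == links$locus[k] &
                 rec$variable == links$variable[k], ]
    expect_true(any(sub$significant))
    best <- sub$resolution[which.min(sub$p)]
    gen_i <- match(links$res[k], res_grid)
    expect_lte(abs(match(best, res_grid) - gen_i), 1)
  }
})

test_that("resolution profiles are ordered, complete and flat for constant covariates", {
  sc <- small_scenario()
  gmq <- qc_filter(sc$genotypes)
  env <- extract_stack(sc$stack, sc$samples)
  rec <- scan_gea(gmq, env, sc$samples, sc$pyramid, extra_vars = FALSE)
  l <- sc$truth$links$locus[1]
  v <- sc$truth$links$variable[1]
  prof <- resolution_profile(rec, l, v)
  expect_equal(nrow(prof), length(unique(env$res)))
  expect_true(!is.unsorted(prof$resolution))
  expect_equal(prof$neglog10_p, -log10(prof$p))
  expect_equal(attr(prof, "alpha_adj"), attr(rec, "alpha_adj"))
  # constant env across resolutions -> identical covariate -> flat profile
  env2 <- env[env$var == "TOP", ]
  envc <- do.call(rbind, lapply(unique(env$res), function(r) {
    sub <- env2[env2$res == min(env2$res), ]
    sub$res <- r
    sub
  }))
  rec2 <- scan_gea(gmq, envc, sc$samples, sc$pyramid, extra_vars = FALSE)
  # grouping still differs per resolution, but the covariate is identical;
  # profiles vary only through the pixel grouping, so betas coincide
  pr <- rec2[rec2$locus == l, ]
  expect_lt(diff(range(pr$beta1)), 0.35)
})
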