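test_that("the minor-variant filter drops exactly the loci a hand count drops", {
  set.seed(1)
  gm <- cbind(
    mono0 = rep(0, 20), mono1 = rep(1, 20),
    rare = c(1, rep(0, 19)),            # f = 0.05: dropped (strict >)
    ok10 = c(rep(1, 2), rep(0, 18)),    # f = 0.10: kept
    half = rep(c(0, 1), 10),            # f = 0.5: kept
    hi95 = c(0, rep(1, 19)),            # f = 0.95: dropped
    hi90 = c(0, 0, rep(1, 18)))         # f = 0.90: kept
  rownames(gm) <- sprintf("i%02d", 1:20)
  out <- qc_filter(gm, 0.05)
  expect_equal(colnames(out), c("ok10", "half", "hi90"))
  expect_equal(attr(out, "qc")$dropped_loci,
               c("mono0", "mono1", "rare", "hi95"))
  gm2 <- gm
  gm2[1, ] <- NA
  gm2[1, 1] <- NA
  gmna <- rbind(gm, allna = rep(NA, 7))
  expect_equal(attr(qc_filter(gmna, 0.05), "qc")$dropped_individuals, "allna")
  expect_error(qc_filter(matrix(0, 5, 3)), "no locus")
  expect_error(qc_filter(matrix(2, 5, 3)), "0/1")
})

test_that("the Calinski criterion equals a brute-force sum-of-squares computation", {
  x <- matrix(c(0, 0, 0.2, 0, 0, 0.2,
                5, 5, 5.2, 5, 5, 5.2), ncol = 2, byrow = TRUE)
  cl <- c(1, 1, 1, 2, 2, 2)
  # brute force: B and W from explicit centroids
  gmean <- colMeans(x)
  W <- sum((x[1:3, ] - rep(colMeans(x[1:3, ]), each = 3))^2) +
    sum((x[4:6, ] - rep(colMeans(x[4:6, ]), each = 3))^2)
  B <- 3 * sum((colMeans(x[1:3, ]) - gmean)^2) +
    3 * sum((colMeans(x[4:6, ]) - gmean)^2)
  want <- (B / 1) / (W / 4)
  expect_equal(calinski_harabasz(x, cl), want, tolerance = 1e-12)
})

test_that("K-means with the Calinski criterion finds two planted pools", {
  gm <- two_pool_matrix()
  ck <- choose_k(gm, 2:8, n_init = 5, seed = 3)
  expect_equal(ck$K, 2L)
  expect_true(all(diff(ck$calinski) < 0))  # monotone decline beyond K = 2
  skip_if_not_installed("vegan")
  # independent implementation of the same criterion
  vk <- vegan::cascadeKM(gm, 2, 4, iter = 20, criterion = "calinski")
  expect_equal(unname(which.max(vk$results["calinski", ])), 1L)
  km <- kmeans(gm, 2, nstart = 5)
  expect_equal(calinski_harabasz(gm, km$cluster),
               (km$betweenss / 1) / (km$tot.withinss / (nrow(gm) - 2)),
               tolerance = 1e-10)
})

test_that("a homogeneous pool yields a flat/declining criterion with no early peak", {
  set.seed(8)
  gm <- matrix(rbinom(80 * 60, 1, 0.5), 80, 60)
  ck <- choose_k(gm, 2:8, n_init = 5, seed = 2)
  # no pronounced maximum: spread of the criterion is small
  expect_lt(diff(range(ck$calinski)) / mean(ck$calinski), 0.5)
})

test_that("fuzzy c-means separates distant clouds and degrades to uniform memberships as m grows", {
  gm <- two_pool_matrix()
  u <- cmeans_run(gm, K = 2, m = 1.02, seed = 1)
  expect_equal(unname(rowSums(u)), rep(1, nrow(u)), tolerance = 1e-12)
  hard <- pmax(u[, 1], u[, 2])
  expect_gt(mean(hard > 0.95), 0.9)  # near-hard at m = 1.02
  # the two true pools end in different clusters
  lab <- max.col(u)
  expect_true(abs(mean(lab[1:40] == lab[1]) - 1) < 0.06)
  expect_true(mean(lab[41:80] == lab[1]) < 0.06)
  # fuzzification limit: memberships approach 1/K
  u2 <- cmeans_run(gm, K = 2, m = 25, max_iter = 200, seed = 1)
  expect_lt(max(abs(u2 - 0.5)), 0.1)
  # objective is monotonically non-increasing across iterations
  obj <- attr(u, "objective")
  expect_true(all(diff(obj) <= 1e-8 * obj[-length(obj)]))
})

test_that("fuzzy c-means agrees with an independent implementation on separable data", {
  skip_if_not_installed("e1071")
  gm <- two_pool_matrix()
  u <- cmeans_run(gm, K = 2, m = 1.05, seed = 2)
  ref <- e1071::cmeans(gm, centers = 2, m = 1.05, iter.max = 500)
  ours <- max.col(u)
  theirs <- ref$cluster
  agree <- max(mean(ours == theirs), mean(ours == 3 - theirs))
  expect_gt(agree, 0.97)
})

test_that("greedy alignment undoes label switching exactly", {
  set.seed(5)
  base <- matrix(runif(30), 15, 2)
  base <- base / rowSums(base)
  runs <- list(base, base[, 2:1], base, base[, 2:1], base)
  al <- align_runs(runs, n_repeats = 20, seed = 1)
  expect_equal(al$similarity, 1, tolerance = 1e-12)
  expect_equal(max(al$sd), 0, tolerance = 1e-12)
  expect_true(all(abs(al$mean - base) < 1e-12) ||
                all(abs(al$mean - base[, 2:1]) < 1e-12))
})

test_that("greedy alignment at K = 2 matches the exhaustive-search oracle", {
  set.seed(6)
  mk <- function() {
    m <- matrix(runif(20), 10, 2)
    m / rowSums(m)
  }
  runs <- lapply(1:5, function(i) mk())
  al <- align_runs(runs, n_repeats = 50, seed = 2)
  # exhaustive: flip or not each run (first fixed), maximise mean pairwise G
  best <- -Inf
  for (mask in 0:(2^4 - 1)) {
    flips <- c(FALSE, as.logical(bitwAnd(mask, 2^(0:3))))
    aligned <- lapply(1:5, function(i)
      if (flips[i]) runs[[i]][, 2:1] else runs[[i]])
    g <- 0; np <- 0
    for (i in 1:4) for (j in (i + 1):5) {
      g <- g + similarity_G(aligned[[i]], aligned[[j]]); np <- np + 1
    }
    best <- max(best, g / np)
  }
  expect_equal(al$similarity, best, tolerance = 1e-10)
})

test_that("alignment is invariant to pre-permuting any subset of runs", {
  set.seed(7)
  runs <- lapply(1:4, function(i) {
    m <- matrix(runif(24), 12, 2)
    m / rowSums(m)
  })
  a1 <- align_runs(runs, n_repeats = 40, seed = 3)
  runs2 <- runs
  runs2[[2]] <- runs2[[2]][, 2:1]
  runs2[[4]] <- runs2[[4]][, 2:1]
  a2 <- align_runs(runs2, n_repeats = 40, seed = 3)
  expect_equal(a1$similarity, a2$similarity, tolerance = 1e-12)
  same <- max(abs(a1$mean - a2$mean)) < 1e-12 ||
    max(abs(a1$mean - a2$mean[, 2:1])) < 1e-12
  expect_true(same)
})

test_that("population labels follow the strict 0.2/0.8 thresholds", {
  m <- c(a = 0.85, b = 0.5, c = 0.15, d = 0.2, e = 0.8, f = 0.80001)
  lab <- assign_populations(m)
  expect_equal(unname(lab), c("A", "admixed", "B", "admixed", "admixed", "A"))
  expect_named(lab, names(m))
})

test_that("the full structure chain recovers planted pools on separable data", {
  gm <- two_pool_matrix(gap = 0.5, seed = 9)
  st <- infer_structure(gm, K = 2, n_runs = 10, n_repeats = 50, seed = 4)
  truth <- rep(c("A", "B"), each = 40)
  got <- ifelse(st$membership > 0.5, "A", "B")
  agree <- max(mean(got == truth), mean(got != truth))
  expect_gt(agree, 0.95)
  expect_gt(st$similarity, 0.95)
  expect_true(all(st$membership >= 0 & st$membership <= 1))
})
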