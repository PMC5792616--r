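#' Minor-variant frequency filter for dominant markers
#'
#' Removes loci whose minor-variant (band presence or absence) frequency is
#' at or below \code{maf_min}, and individuals with no scored locus.
#'
#' @param gm individuals x loci matrix in \{0, 1, NA\}.
#' @param maf_min threshold; loci are kept when
#'   \code{min(f, 1 - f) > maf_min}.
#' @return the filtered matrix, with a \code{"qc"} attribute listing
#'   dropped loci and individuals.
#' @export
qc_filter <- function(gm, maf_min = 0.05) {
  gm <- as.matrix(gm)
  if (!all(gm %in% c(0, 1, NA))) stop("genotypes must be 0/1/NA")
  all_missing <- rowSums(!is.na(gm)) == 0
  gm2 <- gm[!all_missing, , drop = FALSE]
  f <- colMeans(gm2, na.rm = TRUE)
  # rounding guard: 1 - 19/20 is a hair above 0.05 in doubles
  keep <- round(pmin(f, 1 - f), 12) > maf_min
  if (!any(keep)) stop("no locus passes the minor-variant frequency filter")
  out <- gm2[, keep, drop = FALSE]
  attr(out, "qc") <- list(
    dropped_loci = colnames(gm)[!keep],
    dropped_individuals = rownames(gm)[all_missing],
    maf_min = maf_min)
  out
}

# per-locus mean imputation, used for clustering only (never for the
# association scan)
impute_mean <- function(gm) {
  f <- colMeans(gm, na.rm = TRUE)
  idx <- which(is.na(gm), arr.ind = TRUE)
  if (nrow(idx)) gm[idx] <- f[idx[, 2]]
  gm
}

#' Calinski-Harabasz criterion
#'
#' \code{[B/(k-1)] / [W/(n-k)]} with B/W the between/within-cluster sums of
#' squares.
#'
#' @param x numeric matrix (observations x variables).
#' @param cluster integer cluster assignment.
#' @return the criterion value.
#' @export
calinski_harabasz <- function(x, cluster) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- length(unique(cluster))
  if (k < 2 || k >= n) stop("need 2 <= k < n clusters")
  gmean <- colMeans(x)
  B <- 0; W <- 0
  for (cl in unique(cluster)) {
    xi <- x[cluster == cl, , drop = FALSE]
    cm <- colMeans(xi)
    B <- B + nrow(xi) * sum((cm - gmean)^2)
    W <- W + sum(sweep(xi, 2, cm)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Select the number of gene pools by K-means and the Calinski criterion
#'
#' K-means (Euclidean, on the 0/1 matrix with per-locus mean imputation of
#' missing values) is run for each candidate k with multiple restarts; the
#' Calinski-Harabasz criterion is maximised.
#'
#' @param gm individuals x loci matrix in \{0, 1, NA\} (after [qc_filter]).
#' @param k_range candidate cluster counts.
#' @param n_init random restarts per k.
#' @param seed optional RNG seed.
#' @param iter_max K-means iteration cap.
#' @return list with \code{K} (argmax) and \code{calinski} (named vector of
#'   criterion values). When the criterion is flat or declining there is no
#'   strong optimum; the full profile is always returned for inspection.
#' @export
choose_k <- function(gm, k_range = 2:20, n_init = 10, seed = NULL,
                     iter_max = 100) {
  if (!is.null(seed)) set.seed(seed)
  x <- impute_mean(as.matrix(gm))
  stopifnot(nrow(x) > max(k_range))
  ch <- vapply(k_range, function(k) {
    km <- suppressWarnings(stats::kmeans(x, centers = k, nstart = n_init,
                                         iter.max = iter_max))
    (km$betweenss / (k - 1)) / (km$tot.withinss / (nrow(x) - k))
  }, numeric(1))
  names(ch) <- k_range
  list(K = k_range[which.max(ch)], calinski = ch)
}

#' One fuzzy c-means run
#'
#' Standard fuzzy c-means: memberships proportional to
#' \code{distance^(-2/(m-1))} (computed in log space, so small
#' fuzzification exponents such as 1.02 are numerically safe), centroids
#' the membership^m-weighted means, iterated until the maximum centroid
#' movement drops below \code{tol} or \code{max_iter} is reached.
#'
#' @param gm individuals x loci matrix in \{0, 1, NA\}.
#' @param K number of clusters.
#' @param m fuzzification exponent (> 1; default 1.02).
#' @param max_iter iteration cap (default 1e6).
#' @param tol centroid-movement convergence threshold.
#' @param seed optional RNG seed (controls the random centroid init).
#' @return n x K membership matrix (rows sum to 1) with attributes
#'   \code{"objective"} (the per-iteration objective trace, non-increasing)
#'   and \code{"iterations"}.
#' @export
cmeans_run <- function(gm, K = 2, m = 1.02, max_iter = 1e6, tol = 1e-8,
                       seed = NULL) {
  stopifnot(K >= 2, m > 1)
  if (!is.null(seed)) set.seed(seed)
  x <- impute_mean(as.matrix(gm))
  n <- nrow(x)
  cent <- x[sample.int(n, K), , drop = FALSE]
  expo <- 2 / (m - 1)
  obj <- numeric(0)
  d2 <- matrix(0, n, K)
  for (it in seq_len(max_iter)) {
    for (k in seq_len(K))
      d2[, k] <- rowSums(sweep(x, 2, cent[k, ])^2)
    d2p <- pmax(d2, 1e-12)
    lw <- -(expo / 2) * log(d2p)
    lw <- lw - apply(lw, 1, max)
    u <- exp(lw)
    u <- u / rowSums(u)
    # exact-hit rows: all membership on the coincident centroid
    hit <- d2 < 1e-12
    if (any(hit)) {
      rows <- which(rowSums(hit) > 0)
      u[rows, ] <- 0
      u[cbind(rows, max.col(-d2[rows, , drop = FALSE]))] <- 1
    }
    um <- u^m
    obj <- c(obj, sum(um * d2))
    newc <- t(um) %*% x / colSums(um)
    move <- max(abs(newc - cent))
    cent <- newc
    if (move < tol) break
  }
  dimnames(u) <- list(rownames(gm), paste0("pop", seq_len(K)))
  structure(u, objective = obj, iterations = length(obj))
}

#' Pairwise similarity between two membership matrices
#'
#' The normalised-Frobenius similarity
#' \code{G = 1 - ||A - B||_F / sqrt(2 n)}, the statistic used to align
#' label-switched clustering runs.
#'
#' @param a,b n x K membership matrices.
#' @return similarity in `[0, 1]` (1 for identical matrices).
#' @export
similarity_G <- function(a, b) {
  1 - sqrt(sum((a - b)^2)) / sqrt(2 * nrow(a))
}

permutations_of <- function(K) {
  if (K == 1) return(list(1L))
  out <- list()
  for (i in seq_len(K)) {
    rest <- permutations_of(K - 1L)
    for (p in rest) out[[length(out) + 1L]] <- c(i, setdiff(seq_len(K), i)[p])
  }
  out
}

#' Align label-switched clustering runs (greedy search)
#'
#' Runs are added one at a time in random order; each new run's column
#' permutation is chosen to maximise the similarity \code{G} to the running
#' average of the runs already aligned. The procedure is repeated over
#' \code{n_repeats} random input orders and the ordering with the best
#' total similarity is kept.
#'
#' @param runs list of n x K membership matrices (same shape).
#' @param n_repeats random input orders to try.
#' @param seed optional RNG seed.
#' @return list with \code{mean} (n x K mean aligned membership),
#'   \code{sd} (per-individual standard deviation of the first-column
#'   coefficient across runs), \code{similarity} (mean pairwise \code{G}
#'   among the aligned runs), and \code{permutations}.
#' @export
align_runs <- function(runs, n_repeats = 10000, seed = NULL) {
  stopifnot(length(runs) >= 2)
  K <- ncol(runs[[1]])
  n <- nrow(runs[[1]])
  if (!all(vapply(runs, function(r) all(dim(r) == c(n, K)), logical(1))))
    stop("all runs must share the same dimensions (same K)")
  if (!is.null(seed)) set.seed(seed)
  perms <- permutations_of(K)
  R <- length(runs)
  best_total <- -Inf
  best_perm <- NULL
  for (rep in seq_len(n_repeats)) {
    ord <- sample.int(R)
    sel <- vector("list", R)
    sel[[ord[1]]] <- seq_len(K)
    acc <- runs[[ord[1]]]
    total <- 0
    for (j in 2:R) {
      r <- ord[j]
      mbar <- acc / (j - 1)
      gbest <- -Inf
      pbest <- NULL
      for (p in perms) {
        gv <- similarity_G(runs[[r]][, p, drop = FALSE], mbar)
        if (gv > gbest) { gbest <- gv; pbest <- p }
      }
      sel[[r]] <- pbest
      acc <- acc + runs[[r]][, pbest, drop = FALSE]
      total <- total + gbest
    }
    if (total > best_total) {
      best_total <- total
      best_perm <- sel
    }
  }
  aligned <- lapply(seq_len(R), function(r) runs[[r]][, best_perm[[r]],
                                                     drop = FALSE])
  arr <- array(unlist(aligned), dim = c(n, K, R))
  mean_m <- apply(arr, c(1, 2), mean)
  sd1 <- apply(arr[, 1, , drop = FALSE], 1, stats::sd)
  gsum <- 0; npair <- 0
  for (i in 1:(R - 1)) for (j in (i + 1):R) {
    gsum <- gsum + similarity_G(aligned[[i]], aligned[[j]])
    npair <- npair + 1
  }
  dimnames(mean_m) <- dimnames(runs[[1]])
  list(mean = mean_m, sd = stats::setNames(sd1, rownames(runs[[1]])),
       similarity = gsum / npair, permutations = best_perm)
}

#' Threshold membership coefficients into population labels
#'
#' @param membership per-individual coefficient of membership to population
#'   A, in `[0, 1]`.
#' @param lower,upper strict thresholds: \code{A} when
#'   \code{membership > upper}, \code{B} when \code{membership < lower},
#'   \code{admixed} otherwise (boundary values are admixed).
#' @return character vector of labels with the input names.
#' @export
assign_populations <- function(membership, lower = 0.2, upper = 0.8) {
  lab <- ifelse(membership > upper, "A",
                ifelse(membership < lower, "B", "admixed"))
  stats::setNames(lab, names(membership))
}

#' Full population-structure inference
#'
#' Chains [cmeans_run] over independent random initialisations,
#' [align_runs], and [assign_populations]. The run counts default to
#' desk-scale values; the study-scale settings (1,000 runs, 10,000 greedy
#' repeats) are configuration choices.
#'
#' @param gm individuals x loci matrix (after [qc_filter]).
#' @param K number of gene pools.
#' @param n_runs independent c-means runs.
#' @param m fuzzification exponent.
#' @param n_repeats greedy-alignment repeats.
#' @param max_iter c-means iteration cap.
#' @param seed RNG seed (fans out to per-run seeds).
#' @return list (class \code{structure_result}) with \code{K},
#'   \code{membership} (mean coefficient to population A), \code{sd},
#'   \code{similarity}, \code{assignment}, \code{counts}.
#' @export
infer_structure <- function(gm, K = 2, n_runs = 50, m = 1.02,
                            n_repeats = 200, max_iter = 1e6, seed = 7) {
  runs <- lapply(seq_len(n_runs),
                 function(r) cmeans_run(gm, K = K, m = m,
                                        max_iter = max_iter,
                                        seed = seed + 13 * r))
  al <- align_runs(runs, n_repeats = n_repeats, seed = seed)
  memb <- stats::setNames(al$mean[, 1], rownames(gm))
  assign <- assign_populations(memb)
  structure(list(K = K, membership = memb, sd = al$sd,
                 similarity = al$similarity, assignment = assign,
                 counts = table(factor(assign, c("A", "B", "admixed")))),
            class = "structure_result")
}

#' @export
print.structure_result <- function(x, ...) {
  cat(sprintf("<structure_result> K = %d, mean pairwise similarity G = %.3f\n",
              x$K, x$similarity))
  print(x$counts)
  invisible(x)
}
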