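#' Pairwise relationship coefficients for dominant markers
#'
#' Frequency-centred cross-product estimator:
#' \deqn{r_{ij} = \sum_l (x_{il} - p_l)(x_{jl} - p_l) / \sum_l p_l (1 - p_l)}
#' summed over loci scored in both individuals, with \code{p_l} the sample
#' band frequency. Two identical genotype vectors at \code{p = 0.5}
#' everywhere give r = 1; complementary ones give r = -1.
#'
#' @param gm individuals x loci matrix in \{0, 1, NA\} (after [qc_filter]).
#' @return symmetric n x n matrix of pairwise coefficients (diagonal not
#'   meaningful). Pairs with no shared scored locus are \code{NA} (with a
#'   warning).
#' @export
pairwise_r <- function(gm) {
  gm <- as.matrix(gm)
  p <- colMeans(gm, na.rm = TRUE)
  pq <- p * (1 - p)
  xc <- sweep(gm, 2, p)
  xc[is.na(xc)] <- 0
  m <- (!is.na(gm)) * 1
  num <- xc %*% t(xc)
  den <- m %*% t(m * rep(pq, each = nrow(m)))
  r <- num / den
  if (any(!is.finite(r[upper.tri(r)]))) {
    warning("pair(s) with no shared scored locus excluded")
    r[!is.finite(r)] <- NA_real_
  }
  dimnames(r) <- list(rownames(gm), rownames(gm))
  r
}

#' Balanced distance classes over all sample pairs
#'
#' Class bounds at the pair-count quantiles of the Euclidean distance
#' distribution: pairs are ranked by distance and split into
#' \code{n_classes} contiguous blocks of equal size (+/- 1 pair); pairs
#' whose distance equals a class boundary are moved to the lower class, so
#' heavy ties can unbalance the counts.
#'
#' @param samples sample table with \code{x}, \code{y}.
#' @param n_classes number of classes (default 20).
#' @return data frame (\code{class}, \code{d_upper}, \code{n_pairs}) with
#'   attributes \code{"cls"} (per-pair class, in [dist] order) and
#'   \code{"pairs"} (the i,j index matrix).
#' @export
balanced_classes <- function(samples, n_classes = 20) {
  n <- nrow(samples)
  d <- as.vector(stats::dist(cbind(samples$x, samples$y)))
  np <- length(d)
  if (np < n_classes) stop("fewer pairs than distance classes")
  if (length(unique(d)) < n_classes)
    stop("fewer distinct pair distances than classes")
  ord <- order(d)
  base <- np %/% n_classes
  sizes <- base + (seq_len(n_classes) <= np %% n_classes)
  cls <- integer(np)
  cls[ord] <- rep(seq_len(n_classes), times = sizes)
  # ties on a boundary go to the lower class
  for (k in 2:n_classes) {
    b <- max(d[cls == k - 1])
    cls[cls == k & d == b] <- k - 1L
  }
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  # dist() runs column-wise over the lower triangle: (2,1),(3,1),...;
  # rebuild matching pair indices
  ii <- unlist(lapply(seq_len(n - 1), function(j) (j + 1):n))
  jj <- rep(seq_len(n - 1), times = (n - 1):1)
  out <- data.frame(class = seq_len(n_classes),
                    d_upper = as.numeric(tapply(d, cls, max)),
                    n_pairs = as.integer(table(factor(cls, seq_len(n_classes)))))
  attr(out, "cls") <- cls
  attr(out, "pairs") <- cbind(i = ii, j = jj)
  out
}

#' Spatial-genetic correlogram with permutation significance
#'
#' Observed mean relationship coefficient per balanced distance class; the
#' null distribution is built by permuting individual spatial locations
#' (genotypes fixed) and the two-tailed p-value uses the add-one
#' correction \code{p = (1 + #\{|null| >= |obs|\}) / (n_perm + 1)}. Classes
#' are flagged significant at the Bonferroni-adjusted level
#' \code{alpha / n_classes}.
#'
#' @param gm individuals x loci matrix (after [qc_filter]); rows are
#'   matched to \code{samples} by name when rownames are present.
#' @param samples sample table.
#' @param n_classes number of balanced distance classes.
#' @param n_perm number of permutations (study scale: 9,999).
#' @param seed optional RNG seed.
#' @param alpha familywise level before the class correction.
#' @return data frame (\code{class}, \code{d_upper}, \code{n_pairs},
#'   \code{mean_r}, \code{p}, \code{significant}) with attributes
#'   \code{"global_mean_r"}, \code{"alpha_adj"}, \code{"n_perm"}.
#' @export
correlogram <- function(gm, samples, n_classes = 20, n_perm = 9999,
                        seed = NULL, alpha = 0.05) {
  gm <- as.matrix(gm)
  if (!is.null(rownames(gm))) {
    if (!all(samples$id %in% rownames(gm)))
      stop("genotype matrix does not cover all sample ids")
    gm <- gm[samples$id, , drop = FALSE]
  } else stopifnot(nrow(gm) == nrow(samples))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(samples)
  r <- pairwise_r(gm)
  bc <- balanced_classes(samples, n_classes)
  cls <- attr(bc, "cls")
  pr <- attr(bc, "pairs")
  rvec <- r[pr]
  fcls <- factor(cls, seq_len(n_classes))
  obs <- as.numeric(tapply(rvec, fcls, mean, na.rm = TRUE))
  exceed <- integer(n_classes)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    pv <- r[cbind(idx[pr[, 1]], idx[pr[, 2]])]
    nm <- as.numeric(tapply(pv, fcls, mean, na.rm = TRUE))
    exceed <- exceed + (abs(nm) >= abs(obs))
  }
  p <- (1 + exceed) / (n_perm + 1)
  alpha_adj <- alpha / n_classes
  out <- data.frame(class = bc$class, d_upper = bc$d_upper,
                    n_pairs = bc$n_pairs, mean_r = obs, p = p,
                    significant = p < alpha_adj)
  attr(out, "global_mean_r") <- mean(rvec, na.rm = TRUE)
  attr(out, "alpha_adj") <- alpha_adj
  attr(out, "n_perm") <- n_perm
  out
}
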