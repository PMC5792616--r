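#' Compare terrain variables among inferred populations
#'
#' For every (variable, resolution): group means and standard deviations
#' for populations A, B and the admixed class, and a tie-corrected
#' Kruskal-Wallis test between A and B (the admixed group is shown
#' descriptively; a three-group variant is optional). Two Bonferroni
#' schemes are reported: a single family over all (variable, resolution)
#' tests, and a per-variable family over resolutions.
#'
#' @param env long environment table (\code{id,var,res,value}).
#' @param assignment population labels (\code{A}/\code{B}/\code{admixed}),
#'   named by sample id.
#' @param alpha familywise level.
#' @param three_group also test A vs B vs admixed.
#' @return data frame with one record per (variable, resolution) and
#'   attributes \code{"alpha_adj_global"} / \code{"n_tests"}.
#' @export
habitat_table <- function(env, assignment, alpha = 0.05,
                          three_group = FALSE) {
  lab <- assignment[env$id]
  if (anyNA(lab)) stop("assignment does not cover all sample ids")
  env$group <- factor(lab, c("A", "B", "admixed"))
  if (length(unique(stats::na.omit(lab[lab %in% c("A", "B")]))) < 2)
    stop("need both populations A and B present")
  keys <- unique(env[c("var", "res")])
  keys <- keys[order(keys$var, keys$res), ]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- env[env$var == keys$var[i] & env$res == keys$res[i], ]
    st <- function(g, f) f(sub$value[sub$group == g], na.rm = TRUE)
    ab <- sub[sub$group %in% c("A", "B"), ]
    kw <- stats::kruskal.test(value ~ droplevels(group), data = ab)
    rec <- data.frame(
      variable = keys$var[i], resolution = keys$res[i],
      mean_A = st("A", mean), sd_A = st("A", stats::sd),
      mean_B = st("B", mean), sd_B = st("B", stats::sd),
      mean_admixed = st("admixed", mean), sd_admixed = st("admixed", stats::sd),
      h = unname(kw$statistic), p = kw$p.value,
      stringsAsFactors = FALSE)
    if (three_group) {
      kw3 <- stats::kruskal.test(value ~ group, data = sub)
      rec$h3 <- unname(kw3$statistic)
      rec$p3 <- kw3$p.value
    }
    rec
  })
  out <- do.call(rbind, rows)
  n_tests <- nrow(out)
  out$significant <- out$p < alpha / n_tests
  # alternative family: per variable over its resolutions
  out$significant_by_var <- FALSE
  for (v in unique(out$variable)) {
    sel <- out$variable == v
    out$significant_by_var[sel] <- out$p[sel] < alpha / sum(sel)
  }
  attr(out, "alpha_adj_global") <- alpha / n_tests
  attr(out, "n_tests") <- n_tests
  out
}

#' One-line-per-variable habitat summary
#'
#' Collapses a [habitat_table] to the layout used for reporting: the group
#' means at the most significant resolution, its p-value, and the list of
#' resolutions where the A-vs-B difference stays significant after the
#' global Bonferroni correction.
#'
#' @param tab output of [habitat_table].
#' @return data frame with one row per variable.
#' @export
habitat_summary <- function(tab) {
  rows <- lapply(split(tab, tab$variable), function(sub) {
    best <- sub[which.min(sub$p), ]
    data.frame(
      variable = best$variable,
      mean_A = best$mean_A, sd_A = best$sd_A,
      mean_B = best$mean_B, sd_B = best$sd_B,
      mean_admixed = best$mean_admixed, sd_admixed = best$sd_admixed,
      best_p = best$p, best_resolution = best$resolution,
      significant_resolutions =
        paste(sub$resolution[sub$significant], collapse = ", "),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$variable), ]
}
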