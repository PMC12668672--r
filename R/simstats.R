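#' Thresholded Pearson correlation between two path distributions
#'
#' Values below `threshold` (default 0.5% of valid streamlines) are set to
#' zero in each normalised map; the Pearson correlation is then computed
#' over the voxels that are non-zero in at least one of the two maps. The
#' correlation is undefined (`NA`) when fewer than 3 such voxels exist or
#' either map is constant on the support.
#'
#' @param pd_a,pd_b normalised [path_distribution()] objects on one grid.
#' @param threshold absolute threshold on normalised values.
#' @return Pearson r in `[-1, 1]`, or `NA`.
#' @export
tract_pearson <- function(pd_a, pd_b, threshold = 0.005) {
  stopifnot(inherits(pd_a, "path_distribution"),
            inherits(pd_b, "path_distribution"))
  if (!pd_a$normalised || !pd_b$normalised)
    stop("path distributions must be normalised")
  if (!grids_equal(pd_a$grid, pd_b$grid)) stop("grid mismatch")
  a <- as.vector(pd_a$values)
  b <- as.vector(pd_b$values)
  a[a < threshold] <- 0
  b[b < threshold] <- 0
  sup <- a > 0 | b > 0
  if (sum(sup) < 3L) return(NA_real_)
  a <- a[sup]; b <- b[sup]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Pairwise tract similarity across a cohort
#'
#' For every listed subject pair and every tract, computes the thresholded
#' Pearson correlation of the two normalised path distributions, then the
#' mean and standard deviation across tracts per pair. Tracts whose
#' correlation is undefined are excluded from the per-pair mean and their
#' count reported.
#'
#' @param cohort named list: subject id -> named list of tract ->
#'   normalised [path_distribution()].
#' @param pairs data frame with columns `id_a`, `id_b` and optionally
#'   `group`.
#' @param threshold threshold for [tract_pearson()].
#' @return data frame of class `similarity_table`: one row per pair with
#'   columns `id_a`, `id_b`, `group`, `mean_r`, `sd_r`, `n_tracts`,
#'   `n_missing`, plus one `r_<tract>` column per tract.
#' @export
pairwise_similarity <- function(cohort, pairs, threshold = 0.005) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!nrow(pairs)) stop("empty pair list")
  tracts <- names(cohort[[1]])
  for (s in cohort) {
    if (!identical(names(s), tracts))
      stop("all subjects must share the same tract list")
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    sa <- cohort[[pairs$id_a[i]]]
    sb <- cohort[[pairs$id_b[i]]]
    if (is.null(sa) || is.null(sb)) stop("unknown subject in pair ", i)
    rs <- vapply(tracts, function(tr)
      tract_pearson(sa[[tr]], sb[[tr]], threshold), numeric(1))
    ok <- !is.na(rs)
    out <- data.frame(id_a = pairs$id_a[i], id_b = pairs$id_b[i],
                      group = if ("group" %in% names(pairs)) pairs$group[i] else NA,
                      mean_r = mean(rs[ok]),
                      sd_r = if (sum(ok) > 1L) stats::sd(rs[ok]) else 0,
                      n_tracts = sum(ok), n_missing = sum(!ok),
                      stringsAsFactors = FALSE)
    for (tr in tracts) out[[paste0("r_", tr)]] <- rs[[tr]]
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("similarity_table", "data.frame")
  out
}

## exact null distribution of U by explicit enumeration over group
## assignments (handles ties); feasible for n + m <= 14
u_enumerate <- function(x, y) {
  n <- length(x); m <- length(y)
  vals <- c(x, y)
  combs <- utils::combn(n + m, n)
  apply(combs, 2L, function(ix) {
    xx <- vals[ix]; yy <- vals[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  })
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test for a difference between two independent
#' samples. `exact` mode uses the exact null distribution of U: for untied
#' data via the closed-form count of rank assignments
#' (`stats::dwilcox`), for tied data by explicit enumeration over all group
#' assignments (feasible for `n + m <= 14`). `normal-approx` uses the
#' tie-corrected large-sample normal approximation with continuity
#' correction.
#'
#' @param x,y non-empty numeric samples.
#' @param mode `"exact"` or `"normal-approx"`.
#' @return list with `U` (the Mann-Whitney statistic of `x`, i.e. the
#'   number of pairs with `x > y`, counting ties as 1/2) and `p`
#'   (two-sided).
#' @export
mann_whitney_u <- function(x, y, mode = c("exact", "normal-approx")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("empty sample")
  n <- length(x); m <- length(y)
  u <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  ties <- anyDuplicated(c(x, y)) > 0L
  if (mode == "exact") {
    if (!ties) {
      lo <- min(u, n * m - u)
      hi <- max(u, n * m - u)
      p <- stats::pwilcox(lo, n, m) + 1 - stats::pwilcox(hi - 1, n, m)
    } else {
      if (n + m > 14L)
        stop("exact mode with ties limited to n + m <= 14; use normal-approx")
      null_u <- u_enumerate(x, y)
      dev <- abs(null_u - n * m / 2)
      p <- mean(dev >= abs(u - n * m / 2) - 1e-12)
    }
  } else {
    mu <- n * m / 2
    nn <- n + m
    tt <- table(c(x, y))
    tiecor <- sum(tt^3 - tt) / (nn * (nn - 1))
    sig2 <- n * m / 12 * (nn + 1 - tiecor)
    if (sig2 <= 0) return(list(U = u, p = 1))
    z <- (abs(u - mu) - 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-max(z, 0))
  }
  list(U = u, p = min(1, p))
}

#' Bonferroni correction
#'
#' Flags the p-values significant at family-wise level `alpha`:
#' `p_i < alpha / n`. Computed through `stats::p.adjust`.
#'
#' @param pvals p-values in `[0, 1]`.
#' @param alpha family-wise error level.
#' @return list with `significant` (logical flags), `adjusted_alpha`
#'   (`alpha / n`) and `adjusted_p` (Bonferroni-adjusted p-values).
#' @export
bonferroni <- function(pvals, alpha = 0.05) {
  if (!length(pvals)) stop("empty p-value list")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvals, method = "bonferroni")
  list(significant = adj < alpha,
       adjusted_alpha = alpha / length(pvals),
       adjusted_p = adj)
}

#' Representative subjects by similarity percentile
#'
#' Ranks subjects by their mean-over-tracts correlation to a group-average
#' map set and returns the subject at each requested percentile under the
#' nearest-rank rule (rank `ceiling(p/100 * n)` of the ascending order).
#' Among subjects tied at the selected value the lowest id is returned.
#'
#' @param cohort named list: subject -> tract -> normalised
#'   [path_distribution()].
#' @param group_average named list: tract -> normalised `path_distribution`.
#' @param percentiles percentiles to report (default 10, 50, 90).
#' @param threshold threshold for [tract_pearson()].
#' @return named character vector: percentile -> subject id; attribute
#'   `mean_r` holds every subject's mean correlation.
#' @export
rank_to_group_average <- function(cohort, group_average,
                                  percentiles = c(10, 50, 90),
                                  threshold = 0.005) {
  if (length(cohort) < 3L) stop("need at least three subjects")
  tracts <- names(group_average)
  mean_r <- vapply(cohort, function(s) {
    rs <- vapply(tracts, function(tr)
      tract_pearson(s[[tr]], group_average[[tr]], threshold), numeric(1))
    mean(rs, na.rm = TRUE)
  }, numeric(1))
  ord <- order(mean_r, names(mean_r))
  n <- length(mean_r)
  out <- vapply(percentiles, function(p) {
    k <- min(n, max(1L, ceiling(p / 100 * n)))
    val <- mean_r[ord[k]]
    tied <- names(mean_r)[abs(mean_r - val) < 1e-12]
    sort(tied)[1]
  }, character(1))
  names(out) <- paste0("p", percentiles)
  attr(out, "mean_r") <- mean_r
  out
}
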