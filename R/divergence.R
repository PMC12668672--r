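#' Symmetric Kullback-Leibler divergence between connectivity patterns
#'
#' The dissimilarity between two tract connection patterns `m` and `h`
#' (rows of two connectivity blueprints):
#' `D = sum_k m_k log2(m_k / h_k) + sum_k h_k log2(h_k / m_k)`,
#' in bits. To avoid degeneracies induced by zeros, both rows are first
#' shifted elementwise by `delta` (no renormalisation after the shift).
#' Symmetric in its arguments, non-negative, and zero iff the shifted rows
#' are equal.
#'
#' @param m_row,h_row non-negative numeric vectors of equal length.
#' @param delta shift added to every entry (default `1e-6`).
#' @return the divergence in bits.
#' @export
symmetric_kl <- function(m_row, h_row, delta = 1e-6) {
  if (length(m_row) != length(h_row)) stop("length mismatch")
  if (any(m_row < 0) || any(h_row < 0)) stop("negative entries")
  m <- m_row + delta
  h <- h_row + delta
  lg <- log2(m / h)
  sum(m * lg) - sum(h * lg)
}

#' Reference connectivity pattern of a region
#'
#' The mean of the selected blueprint rows, re-normalised to sum to 1: the
#' average connectivity pattern used as the reference side of a divergence
#' map.
#'
#' @param blueprint a [connectivity_blueprint()].
#' @param roi_rows row names (or indices) of the region of interest.
#' @return a probability vector over tracts.
#' @export
reference_pattern <- function(blueprint, roi_rows) {
  stopifnot(inherits(blueprint, "connectivity_blueprint"))
  if (!length(roi_rows)) stop("empty ROI")
  m <- unclass(blueprint)[roi_rows, , drop = FALSE]
  avg <- colMeans(m)
  s <- sum(avg)
  if (s <= 0) stop("ROI has zero total mass")
  avg / s
}

#' Divergence map of a blueprint against a reference pattern
#'
#' Compares every blueprint row to a reference probability vector with
#' [symmetric_kl()], optionally restricted to a tract subset
#' (cortico-cortical `"cc"`, cortico-subcortical `"cs"`, or `"all"`); both
#' the rows and the reference are re-normalised after restriction so the
#' divergence operates on comparable masses. Rows with zero mass on the
#' subset get `NA`.
#'
#' @param reference probability vector named by tract (e.g. from
#'   [reference_pattern()]).
#' @param blueprint a row-normalised [connectivity_blueprint()].
#' @param tract_subset `"all"`, `"cc"`, `"cs"` or tract names.
#' @param delta zero-shift passed to [symmetric_kl()].
#' @param reference_label free-text label stored in the result.
#' @return object of class `divergence_result`: `values` (named per-location
#'   divergences, bits), `reference_label`, `delta`, `subset`.
#' @export
divergence_map <- function(reference, blueprint, tract_subset = "all",
                           delta = 1e-6, reference_label = "reference") {
  bp <- restrict_blueprint(blueprint, tract_subset)
  keep <- colnames(bp)
  missing <- setdiff(keep, names(reference))
  if (length(missing)) stop("reference lacks tracts: ", paste(missing, collapse = ", "))
  ref <- reference[keep]
  if (sum(ref) <= 0) stop("tract subset yields a zero-mass reference")
  ref <- ref / sum(ref)
  m <- unclass(bp)
  vals <- apply(m, 1L, function(r) {
    if (sum(r) <= 0) return(NA_real_)
    symmetric_kl(ref, r, delta)
  })
  structure(list(values = vals, reference_label = reference_label,
                 delta = delta, subset = tract_subset),
            class = "divergence_result")
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf("divergence_result vs '%s' (%s tracts): %d locations, min %.4g bits at %s\n",
              x$reference_label, paste(x$subset, collapse = ","),
              length(x$values), min(x$values, na.rm = TRUE),
              names(x$values)[which.min(x$values)]))
  invisible(x)
}

#' Best-matching locations of a divergence map
#'
#' The locations whose divergence falls below the stated percentile of the
#' map (order-statistic rule: the `floor(p/100 * n)` smallest values, at
#' least one). A constant map is degenerate: an empty set is returned with
#' a warning.
#'
#' @param result a [divergence_map()] result.
#' @param percentile percentile in (0, 100); default 7.
#' @return character vector of location ids.
#' @export
best_match_region <- function(result, percentile = 7) {
  stopifnot(inherits(result, "divergence_result"))
  if (percentile <= 0 || percentile >= 100) stop("percentile must lie in (0, 100)")
  v <- result$values[!is.na(result$values)]
  if (length(unique(v)) <= 1L) {
    warning("degenerate (constant) divergence map; returning empty set")
    return(character(0))
  }
  k <- max(1L, floor(percentile / 100 * length(v)))
  names(sort(v))[seq_len(k)]
}

#' Cross-blueprint structure matching
#'
#' Computes the symmetric KL divergence between the reference patterns of
#' every ROI pair across two blueprints and assigns to each ROI of side A
#' the side-B ROI of minimal divergence — the homologue identification
#' logic.
#'
#' @param blueprint_a,blueprint_b row-normalised
#'   [connectivity_blueprint()] objects sharing tract columns.
#' @param roi_sets_a,roi_sets_b named lists of row-id vectors (>= 2 ROIs
#'   per side).
#' @param tract_subset `"all"`, `"cc"`, `"cs"` or tract names.
#' @param delta zero-shift for [symmetric_kl()].
#' @return list with `table` (divergence matrix, A ROIs x B ROIs, bits) and
#'   `assignment` (named character: per-A-ROI argmin over B ROIs).
#' @export
match_structures <- function(blueprint_a, blueprint_b, roi_sets_a, roi_sets_b,
                             tract_subset = "all", delta = 1e-6) {
  if (length(roi_sets_a) < 2L || length(roi_sets_b) < 2L)
    stop("need at least two ROIs per side")
  bpa <- restrict_blueprint(blueprint_a, tract_subset)
  bpb <- restrict_blueprint(blueprint_b, tract_subset)
  if (!identical(colnames(bpa), colnames(bpb)))
    stop("blueprints do not share tract columns")
  refs_a <- lapply(roi_sets_a, function(r) reference_pattern(bpa, r))
  refs_b <- lapply(roi_sets_b, function(r) reference_pattern(bpb, r))
  tab <- matrix(NA_real_, length(refs_a), length(refs_b),
                dimnames = list(names(roi_sets_a), names(roi_sets_b)))
  for (i in seq_along(refs_a))
    for (j in seq_along(refs_b))
      tab[i, j] <- symmetric_kl(refs_a[[i]], refs_b[[j]], delta)
  assignment <- colnames(tab)[apply(tab, 1L, which.min)]
  names(assignment) <- rownames(tab)
  list(table = tab, assignment = assignment)
}
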