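#' Tracer termination table
#'
#' Records of anterograde-tracer termination sites: world coordinates, the
#' cortical injection-ROI label of the originating injection, and a case
#' id. Labels must come from the declared label set, whose order also
#' defines the tie-break order of [dominant_label()].
#'
#' @param coords data frame (or matrix) with columns `x`, `y`, `z` in mm;
#'   may already contain `label` and `case` columns.
#' @param label injection-ROI labels (recycled); ignored when `coords`
#'   carries a `label` column.
#' @param case case ids (recycled).
#' @param label_set declared label set; defaults to the labels present, in
#'   order of first appearance.
#' @return data frame of class `termination_table` with attribute
#'   `label_set`.
#' @export
termination_table <- function(coords, label = NULL, case = "case1",
                              label_set = NULL) {
  df <- as.data.frame(coords, stringsAsFactors = FALSE)
  if (!is.null(label)) df$label <- label
  if (!"case" %in% names(df)) df$case <- case
  stopifnot(all(c("x", "y", "z", "label") %in% names(df)))
  if (any(!is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop("termination coordinates must be finite")
  if (is.null(label_set)) label_set <- unique(df$label)
  bad <- setdiff(df$label, label_set)
  if (length(bad)) stop("labels outside the declared set: ",
                        paste(bad, collapse = ", "))
  structure(df, label_set = label_set,
            class = c("termination_table", "data.frame"))
}

#' Termination-probability maps
#'
#' Per injection-ROI label: termination sites are binned to target-mask
#' voxels (nearest voxel under the voxel-centre convention) and counts are
#' divided by that label's total number of in-mask terminations, giving a
#' probability map over the target structure. Out-of-mask terminations are
#' dropped and counted in the `dropped` report; a label with no in-mask
#' termination yields an all-zero map with a warning.
#'
#' @param table a [termination_table()].
#' @param target_mask non-empty `binary_mask` (e.g. a putamen mask).
#' @return object of class `termination_map`: `grid`, `maps` (named list of
#'   per-label probability arrays), `labels`, `smoothed = FALSE`, `dropped`
#'   (out-of-mask count per label).
#' @export
termination_probability <- function(table, target_mask) {
  stopifnot(inherits(table, "termination_table"),
            inherits(target_mask, "binary_mask"))
  if (mask_is_empty(target_mask)) stop("empty target mask")
  grid <- target_mask$grid
  labels <- attr(table, "label_set")
  inmask <- as.vector(target_mask$values)
  lin <- world_to_linear(grid, as.matrix(table[, c("x", "y", "z")]))
  keep <- !is.na(lin) & inmask[pmax(lin, 1L)]
  keep[is.na(lin)] <- FALSE
  maps <- list()
  dropped <- stats::setNames(integer(length(labels)), labels)
  for (lb in labels) {
    sel <- table$label == lb
    dropped[lb] <- sum(sel & !keep)
    v <- numeric(n_voxels(grid))
    hits <- lin[sel & keep]
    if (!length(hits)) {
      warning("label '", lb, "' has no in-mask terminations; all-zero map")
    } else {
      tb <- base::table(hits)
      v[as.integer(names(tb))] <- as.numeric(tb) / sum(tb)
    }
    maps[[lb]] <- array(v, dim = grid$shape)
  }
  structure(list(grid = grid, maps = maps, labels = labels,
                 mask = target_mask, smoothed = FALSE, dropped = dropped),
            class = "termination_map")
}

## cubic B-spline kernel value at (scaled) offset t
bspline3 <- function(t) {
  t <- abs(t)
  ifelse(t < 1, (4 - 6 * t^2 + 3 * t^3) / 6,
         ifelse(t < 2, (2 - t)^3 / 6, 0))
}

## separable 1-D convolution of a 3-D array along one axis with kernel w
## centred at offset 0 (length 2*r+1), edge-clipped
conv_axis <- function(a, w, axis) {
  r <- (length(w) - 1L) %/% 2L
  out <- array(0, dim = dim(a))
  d <- dim(a)
  for (j in seq_along(w)) {
    off <- j - r - 1L
    src <- seq_len(d[axis]) + off
    ok <- src >= 1L & src <= d[axis]
    if (!any(ok)) next
    idx_dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx_src <- idx_dst
    idx_dst[[axis]] <- which(ok)
    idx_src[[axis]] <- src[ok]
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] +
      w[j] * a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  }
  out
}

#' Smooth termination maps
#'
#' Smooths each per-label probability volume with a separable cubic
#' B-spline kernel of the stated scale (mm), restricts the result to the
#' target mask, and re-normalises each label to total mass 1. In the limit
#' of vanishing scale the kernel degenerates to the identity.
#'
#' @param map an unsmoothed [termination_probability()] result.
#' @param smoothing_scale kernel scale in mm (> 0); default one voxel.
#' @return the smoothed `termination_map`.
#' @export
smooth_map <- function(map, smoothing_scale = NULL) {
  stopifnot(inherits(map, "termination_map"))
  if (map$smoothed) stop("map already smoothed")
  if (is.null(smoothing_scale)) smoothing_scale <- max(map$grid$voxel_size)
  if (smoothing_scale <= 0) stop("smoothing scale must be > 0")
  inmask <- map$mask$values
  for (lb in map$labels) {
    a <- map$maps[[lb]]
    total <- sum(a)
    if (total <= 0) next
    for (ax in 1:3) {
      s <- smoothing_scale / map$grid$voxel_size[ax]
      r <- max(1L, ceiling(2 * s))
      w <- bspline3((-r:r) / s)
      w <- w / sum(w)
      a <- conv_axis(a, w, ax)
    }
    a[!inmask] <- 0
    if (sum(a) > 0) a <- a * (total / sum(a))
    map$maps[[lb]] <- a
  }
  map$smoothed <- TRUE
  map
}

#' Dominant-label synthesis
#'
#' Per target-mask voxel, the label whose probability map is maximal; exact
#' ties are broken by the declared label order. Accepts either a
#' `termination_map` or any named list of equally shaped arrays together
#' with a mask (so tract path distributions can be labelled the same way).
#'
#' @param maps a [termination_probability()] result, or a named list of
#'   numeric arrays.
#' @param mask required when `maps` is a plain list: the `binary_mask` to
#'   label within.
#' @return list with `labels` (the declared order) and `index` (integer
#'   array: label index per voxel, 0 outside the mask or where all maps are
#'   zero).
#' @export
dominant_label <- function(maps, mask = NULL) {
  if (inherits(maps, "termination_map")) {
    mask <- maps$mask
    labels <- maps$labels
    vols <- maps$maps
  } else {
    if (!length(maps)) stop("empty map set")
    if (is.null(mask)) stop("mask required for a plain map list")
    labels <- names(maps)
    vols <- maps
  }
  d <- dim(vols[[1]])
  for (v in vols) stopifnot(all(dim(v) == d))
  n <- prod(d)
  best <- numeric(n)
  idx <- integer(n)
  for (k in seq_along(labels)) {
    v <- as.vector(vols[[k]])
    upd <- v > best  # strict: earlier labels win exact ties
    idx[upd] <- k
    best[upd] <- v[upd]
  }
  idx[!as.vector(mask$values)] <- 0L
  list(labels = labels, index = array(idx, dim = d))
}
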