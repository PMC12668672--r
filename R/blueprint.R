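#' Connectivity blueprint
#'
#' A GM-locations x tracts matrix: each row is the pattern of how one
#' grey-matter location (a cortical boundary location or a subcortical
#' voxel) connects to a fixed set of white-matter tracts. Rows are
#' sum-normalised by [assemble_blueprint()] (or at construction), after
#' which every row with non-zero mass sums to 1.
#'
#' @param mat non-negative numeric matrix with row names (location ids) and
#'   column names (tract names).
#' @param row_type character vector, `"cortical"` or `"subcortical"` per row.
#' @param row_normalised logical.
#' @return object of class `connectivity_blueprint` (a matrix with
#'   attributes `row_type` and `row_normalised`).
#' @export
connectivity_blueprint <- function(mat, row_type = rep("cortical", nrow(mat)),
                                   row_normalised = FALSE) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("blueprint entries must be >= 0")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("blueprint needs row (location) and column (tract) names")
  row_type <- rep_len(row_type, nrow(mat))
  if (row_normalised) {
    rs <- rowSums(mat)
    bad <- rs > 0 & abs(rs - 1) > 1e-9
    if (any(bad)) stop("row_normalised set but rows do not sum to 1")
  }
  structure(mat, row_type = row_type, row_normalised = isTRUE(row_normalised),
            class = c("connectivity_blueprint", "matrix", "array"))
}

#' @export
print.connectivity_blueprint <- function(x, ...) {
  cat(sprintf("connectivity_blueprint: %d locations (%d cortical, %d subcortical) x %d tracts%s\n",
              nrow(x), sum(attr(x, "row_type") == "cortical"),
              sum(attr(x, "row_type") == "subcortical"), ncol(x),
              if (attr(x, "row_normalised")) ", row-normalised" else ""))
  invisible(x)
}

#' GM x WM connectivity matrix
#'
#' Row `i` holds the visitation counts over white-matter voxels of
#' streamlines seeded at grey-matter boundary location `i`, with no waypoint
#' constraints (the intermediary matrix of the cortical blueprint
#' construction, which sidesteps the gyral bias of reading tract maps
#' directly at the cortex). Each location uses its own RNG substream derived
#' from the root seed and the location's coordinates, so identical
#' locations give identical rows.
#'
#' @param field a [fibre_field()].
#' @param gm_locations data frame with columns `label`, `x`, `y`, `z` (world
#'   mm), e.g. `scene$gm_locations` from [make_scene()].
#' @param wm_mask non-empty `binary_mask` selecting the white-matter voxels
#'   that form the columns.
#' @param params a [tracking_params()]; `streamlines_per_seed_voxel`
#'   streamlines are launched per location, jittered within its voxel.
#' @return object of class `gm_wm_matrix`: counts matrix (locations x WM
#'   voxels) with attribute `wm_voxels` (linear indices).
#' @export
build_gm_wm <- function(field, gm_locations, wm_mask,
                        params = tracking_params()) {
  stopifnot(inherits(field, "fibre_field"), inherits(wm_mask, "binary_mask"))
  if (mask_is_empty(wm_mask)) stop("empty WM mask")
  grid <- field$grid
  wm_lin <- mask_which(wm_mask)
  col_of <- rep(NA_integer_, n_voxels(grid))
  col_of[wm_lin] <- seq_along(wm_lin)
  nloc <- nrow(gm_locations)
  out <- matrix(0, nloc, length(wm_lin),
                dimnames = list(gm_locations$label, NULL))
  nper <- params$streamlines_per_seed_voxel
  for (i in seq_len(nloc)) {
    pt <- c(gm_locations$x[i], gm_locations$y[i], gm_locations$z[i])
    v0 <- world_to_linear(grid, pt)
    if (is.na(v0)) stop("GM location outside grid: ", gm_locations$label[i])
    set.seed(derive_seed(params$rng_seed, round(pt * 8)))
    ijk <- linear_to_ijk(grid, rep(v0, nper))
    jit <- matrix(stats::runif(3L * nper, -0.5, 0.5), nper, 3)
    seeds <- voxel_to_world(grid, ijk + jit)
    d0 <- sample_dirs(field, rep(v0, nper), NULL, params)$dir
    fwd <- track_half(field, seeds, d0, params, NULL, NULL)
    bwd <- track_half(field, seeds, -d0, params, NULL, NULL)
    fvox <- half_voxels(grid, fwd, nper)
    bvox <- half_voxels(grid, bwd, nper)
    for (s in seq_len(nper)) {
      vs <- c(v0,
              if (fwd$nsteps[s] > 0L) fvox[seq_len(fwd$nsteps[s]), s],
              if (bwd$nsteps[s] > 0L) bvox[seq_len(bwd$nsteps[s]), s])
      cols <- col_of[unique(vs[!is.na(vs)])]
      cols <- cols[!is.na(cols)]
      out[i, cols] <- out[i, cols] + 1
    }
  }
  structure(out, wm_voxels = wm_lin, class = c("gm_wm_matrix", "matrix", "array"))
}

#' WM x tracts matrix
#'
#' Collates normalised path distributions: column `k` is tract `k`'s
#' normalised visitation values restricted to the white-matter mask voxels.
#'
#' @param path_distributions named list of normalised [path_distribution()]
#'   objects on one grid.
#' @param wm_mask `binary_mask` on the same grid.
#' @return object of class `wm_tracts_matrix` (WM voxels x tracts) with
#'   attribute `wm_voxels`.
#' @export
build_wm_tracts <- function(path_distributions, wm_mask) {
  stopifnot(length(path_distributions) > 0, inherits(wm_mask, "binary_mask"))
  if (is.null(names(path_distributions)))
    stop("path distributions must be named by tract")
  wm_lin <- mask_which(wm_mask)
  cols <- lapply(path_distributions, function(pd) {
    stopifnot(inherits(pd, "path_distribution"))
    if (!pd$normalised) stop("path distributions must be normalised")
    if (!grids_equal(pd$grid, wm_mask$grid))
      stop("path distribution grid differs from WM mask grid")
    as.vector(pd$values)[wm_lin]
  })
  out <- do.call(cbind, cols)
  colnames(out) <- names(path_distributions)
  structure(out, wm_voxels = wm_lin,
            class = c("wm_tracts_matrix", "matrix", "array"))
}

#' Cortical blueprint via the intermediary matrix product
#'
#' Multiplies the GM x WM visitation matrix by the WM x tracts matrix,
#' producing unnormalised cortical blueprint rows. The product is taken on
#' raw counts; row normalisation is deferred to [assemble_blueprint()].
#'
#' @param gmwm a [build_gm_wm()] result.
#' @param wmt a [build_wm_tracts()] result on the same WM voxel set.
#' @return an unnormalised [connectivity_blueprint()] with cortical rows.
#' @export
cortical_blueprint <- function(gmwm, wmt) {
  stopifnot(inherits(gmwm, "gm_wm_matrix"), inherits(wmt, "wm_tracts_matrix"))
  if (!identical(attr(gmwm, "wm_voxels"), attr(wmt, "wm_voxels")))
    stop("WM voxel ids of the two matrices do not match")
  prod <- unclass(gmwm) %*% unclass(wmt)
  connectivity_blueprint(prod, row_type = rep("cortical", nrow(prod)),
                         row_normalised = FALSE)
}

#' Subcortical blueprint by direct intersection
#'
#' For each tract, the normalised path distribution is (optionally)
#' downsampled by block mean to `target_voxel_mm`, values below `threshold`
#' (default 0.1% of valid streamlines, an absolute cut on the normalised
#' map) are zeroed, and the map is multiplied by each binary nucleus mask.
#' Nucleus-mask voxels become rows, tracts columns. The order is downsample
#' then threshold. Masks may be supplied on the tract grid (they are then
#' carried to the target grid by block majority) or on the target grid.
#'
#' @param path_distributions named list of normalised [path_distribution()].
#' @param subcortical_masks named list of `binary_mask` nuclei.
#' @param threshold absolute threshold on the normalised values.
#' @param target_voxel_mm optional coarser voxel size for the intersection.
#' @return an unnormalised [connectivity_blueprint()] with subcortical rows
#'   named `nucleus:voxel`.
#' @export
subcortical_blueprint <- function(path_distributions, subcortical_masks,
                                  threshold = 0.001, target_voxel_mm = NULL) {
  stopifnot(length(path_distributions) > 0)
  if (!length(subcortical_masks)) stop("empty subcortical mask set")
  if (is.null(names(subcortical_masks)))
    stop("subcortical masks must be named")
  maps <- lapply(path_distributions, function(pd) {
    stopifnot(inherits(pd, "path_distribution"))
    if (!pd$normalised) stop("path distributions must be normalised")
    vol <- scalar_volume(pd$grid, pd$values)
    if (!is.null(target_voxel_mm) &&
        any(target_voxel_mm / pd$grid$voxel_size > 1 + 1e-9))
      vol <- downsample(vol, target_voxel_mm, method = "block-mean")
    vol$values[vol$values < threshold] <- 0
    vol
  })
  tgrid <- maps[[1]]$grid
  rows <- list()
  types <- character(0)
  for (nm in names(subcortical_masks)) {
    m <- subcortical_masks[[nm]]
    stopifnot(inherits(m, "binary_mask"))
    if (!grids_equal(m$grid, tgrid)) {
      if (all(abs(m$grid$voxel_size - path_distributions[[1]]$grid$voxel_size) < 1e-9) &&
          !is.null(target_voxel_mm)) {
        m <- downsample_mask(m, target_voxel_mm)
      }
      if (!grids_equal(m$grid, tgrid))
        stop("nucleus mask '", nm, "' is not on the tract grid")
    }
    lin <- mask_which(m)
    if (!length(lin)) next
    block <- vapply(maps, function(v) as.vector(v$values)[lin],
                    numeric(length(lin)))
    block <- matrix(block, nrow = length(lin),
                    dimnames = list(paste0(nm, ":", lin),
                                    names(path_distributions)))
    rows[[nm]] <- block
  }
  if (!length(rows)) stop("no nucleus voxels on the tract grid")
  out <- do.call(rbind, rows)
  connectivity_blueprint(out, row_type = rep("subcortical", nrow(out)),
                         row_normalised = FALSE)
}

#' Row-sum normalisation
#'
#' Divides each row by its sum; zero-mass rows are left zero and their ids
#' recorded in the `zero_rows` attribute. Idempotent.
#'
#' @param bp a [connectivity_blueprint()].
#' @return the row-normalised blueprint.
#' @export
normalise_rows <- function(bp) {
  stopifnot(inherits(bp, "connectivity_blueprint"))
  m <- unclass(bp)
  rs <- rowSums(m)
  zero <- rs == 0
  m[!zero, ] <- m[!zero, , drop = FALSE] / rs[!zero]
  out <- connectivity_blueprint(m, row_type = attr(bp, "row_type"),
                                row_normalised = TRUE)
  attr(out, "zero_rows") <- rownames(m)[zero]
  attr(out, "tract_class") <- attr(bp, "tract_class")
  out
}

#' Assemble the full blueprint
#'
#' Stacks cortical rows on top of subcortical rows (both over the same
#' tract columns) and row-sum-normalises. Zero-mass rows stay zero and are
#' reported in the `zero_rows` attribute.
#'
#' @param cortical,subcortical [connectivity_blueprint()] objects with
#'   identical tract columns.
#' @return a row-normalised `connectivity_blueprint`.
#' @export
assemble_blueprint <- function(cortical, subcortical) {
  stopifnot(inherits(cortical, "connectivity_blueprint"),
            inherits(subcortical, "connectivity_blueprint"))
  if (!identical(colnames(cortical), colnames(subcortical)))
    stop("tract columns differ between cortical and subcortical blueprints")
  m <- rbind(unclass(cortical), unclass(subcortical))
  bp <- connectivity_blueprint(m,
                               row_type = c(attr(cortical, "row_type"),
                                            attr(subcortical, "row_type")),
                               row_normalised = FALSE)
  normalise_rows(bp)
}

#' Restrict a blueprint to a tract subset
#'
#' Keeps the named tract columns (or a class from the `tract_class`
#' attribute: `"cc"` cortico-cortical, `"cs"` cortico-subcortical, `"all"`)
#' and re-normalises rows so divergence comparisons operate on comparable
#' masses.
#'
#' @param bp a row-normalised [connectivity_blueprint()].
#' @param subset `"all"`, `"cc"`, `"cs"`, or a character vector of tract
#'   names.
#' @return the restricted, re-normalised blueprint.
#' @export
restrict_blueprint <- function(bp, subset = "all") {
  stopifnot(inherits(bp, "connectivity_blueprint"))
  if (identical(subset, "all")) return(normalise_rows(bp))
  if (length(subset) == 1L && subset %in% c("cc", "cs")) {
    cls <- attr(bp, "tract_class")
    if (is.null(cls)) stop("blueprint carries no tract_class attribute")
    keep <- names(cls)[cls == subset]
  } else {
    keep <- subset
  }
  missing <- setdiff(keep, colnames(bp))
  if (length(missing)) stop("unknown tracts: ", paste(missing, collapse = ", "))
  m <- unclass(bp)[, keep, drop = FALSE]
  out <- connectivity_blueprint(m, row_type = attr(bp, "row_type"))
  attr(out, "tract_class") <- attr(bp, "tract_class")[keep]
  normalise_rows(out)
}
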