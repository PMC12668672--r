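#' Voxel grid
#'
#' Spatial reference shared by all volumes in a scene: voxel counts, voxel
#' sizes in mm, and a 4x4 affine mapping 0-based voxel indices to world
#' coordinates in mm. The convention throughout the package is voxel-centre
#' world coordinates: the affine maps index `(i,j,k)` (0-based) to the world
#' position of that voxel's centre. The default affine places voxel
#' `(0,0,0)` at the world origin with axes aligned to the voxel axes.
#'
#' @param shape integer vector of length 3, voxel counts per axis (all >= 1).
#' @param voxel_size voxel edge length in mm; scalar (isotropic) or length 3.
#' @param affine optional 4x4 voxel-index-to-world matrix; must be invertible.
#'   When omitted, built from `voxel_size` with the origin at voxel (0,0,0).
#' @return An object of class `voxel_grid` with fields `shape`, `voxel_size`
#'   and `affine`.
#' @export
voxel_grid <- function(shape, voxel_size = 1, affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("shape must be three integers >= 1")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size entries must be > 0")
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- voxel_size
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < 1e-12) stop("affine is not invertible")
  structure(
    list(shape = shape, voxel_size = voxel_size, affine = affine,
         inv_affine = solve(affine)),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d voxels, voxel size %s mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(signif(x$voxel_size, 4), collapse = " x ")))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) && all(abs(a$affine - b$affine) < tol)
}

n_voxels <- function(grid) prod(grid$shape)

#' Coordinate conversions
#'
#' Conversions between world coordinates (mm), 0-based voxel indices and
#' 1-based linear array indices under the voxel-centre convention.
#' `world_to_voxel` returns continuous 0-based voxel coordinates;
#' `voxel_to_world` maps 0-based indices to voxel-centre world positions;
#' `world_to_linear` returns the 1-based linear index of the nearest voxel
#' (`NA` outside the grid); `linear_to_ijk` inverts it to 0-based indices.
#'
#' @param grid a [voxel_grid()].
#' @param pts N x 3 matrix (or length-3 vector) of world points.
#' @param ijk N x 3 matrix (or length-3 vector) of 0-based voxel indices.
#' @param lin 1-based linear indices.
#' @name coordinates
NULL

#' @rdname coordinates
#' @export
world_to_voxel <- function(grid, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  h <- cbind(pts, 1) %*% t(grid$inv_affine)
  h[, 1:3, drop = FALSE]
}

#' @rdname coordinates
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  h <- cbind(ijk, 1) %*% t(grid$affine)
  h[, 1:3, drop = FALSE]
}

#' @rdname coordinates
#' @export
world_to_linear <- function(grid, pts) {
  v <- round(world_to_voxel(grid, pts))
  inside <- v[, 1] >= 0 & v[, 1] < grid$shape[1] &
    v[, 2] >= 0 & v[, 2] < grid$shape[2] &
    v[, 3] >= 0 & v[, 3] < grid$shape[3]
  inside[is.na(inside)] <- FALSE
  out <- rep(NA_integer_, nrow(v))
  out[inside] <- as.integer(
    v[inside, 1] + grid$shape[1] * (v[inside, 2] + grid$shape[2] * v[inside, 3]) + 1)
  out
}

#' @rdname coordinates
#' @export
linear_to_ijk <- function(grid, lin) {
  lin0 <- as.integer(lin) - 1L
  nx <- grid$shape[1]; ny <- grid$shape[2]
  cbind(lin0 %% nx, (lin0 %/% nx) %% ny, lin0 %/% (nx * ny))
}

#' @rdname coordinates
#' @export
all_voxel_centres <- function(grid) {
  ijk <- linear_to_ijk(grid, seq_len(n_voxels(grid)))
  voxel_to_world(grid, ijk)
}

#' Scalar volume
#'
#' A real-valued value per voxel on a [voxel_grid()].
#'
#' @param grid a `voxel_grid`.
#' @param values numeric array with dimensions equal to `grid$shape`; a scalar
#'   is recycled.
#' @return Object of class `scalar_volume` with fields `grid` and `values`.
#' @export
scalar_volume <- function(grid, values = 0) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (length(values) == 1L) values <- array(as.numeric(values), dim = grid$shape)
  values <- as.array(values)
  if (!all(dim(values) == grid$shape))
    stop("values array shape must equal grid shape")
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values), class = "scalar_volume")
}

#' Binary mask
#'
#' A boolean membership flag per voxel; an all-`FALSE` mask is a valid
#' (empty) mask. Masks define seed/target/stop/exclusion regions of
#' tractography protocols and nucleus regions for blueprints.
#'
#' @param grid a `voxel_grid`.
#' @param membership logical array matching `grid$shape`; numeric input is
#'   coerced via `> 0`. Default: empty mask.
#' @return Object of class `binary_mask` with fields `grid` and `values`.
#' @export
binary_mask <- function(grid, membership = FALSE) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (length(membership) == 1L)
    membership <- array(membership, dim = grid$shape)
  membership <- as.array(membership)
  if (!all(dim(membership) == grid$shape))
    stop("membership array shape must equal grid shape")
  if (!is.logical(membership)) membership <- membership > 0
  structure(list(grid = grid, values = membership), class = "binary_mask")
}

#' Linear indices of mask member voxels
#' @param mask a `binary_mask`.
#' @return integer vector of 1-based linear indices.
#' @export
mask_which <- function(mask) which(as.vector(mask$values))

mask_is_empty <- function(mask) !any(mask$values)

#' Make a binary mask from linear voxel indices
#' @param grid a `voxel_grid`.
#' @param lin 1-based linear voxel indices.
#' @return a `binary_mask`.
#' @export
mask_from_linear <- function(grid, lin) {
  v <- array(FALSE, dim = grid$shape)
  v[lin] <- TRUE
  binary_mask(grid, v)
}

#' Dilate a mask by one voxel
#'
#' Face-neighbour (6-connected) morphological dilation by a single voxel.
#' @param mask a `binary_mask`.
#' @return the dilated `binary_mask`.
#' @export
mask_dilate1 <- function(mask) {
  v <- mask$values
  d <- dim(v)
  out <- v
  shift <- function(a, ax, by) {
    idx <- lapply(d, seq_len)
    src <- idx
    src[[ax]] <- pmin(pmax(idx[[ax]] - by, 1L), d[ax])
    a[src[[1]], src[[2]], src[[3]]]
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) out <- out | shift(v, ax, by)
  binary_mask(mask$grid, out)
}

#' Read a 3D NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file into a [scalar_volume()], honouring the
#' stored affine (sform/qform as resolved by RNifti) and voxel sizes.
#' Values are promoted to double.
#'
#' @param path path to an existing NIfTI file holding a 3D image.
#' @return a `scalar_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  if (length(d) != 3L) stop("non-3D image: ", path)
  arr <- array(as.numeric(img)[seq_len(prod(d))], dim = d)
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  vs <- sqrt(colSums(aff[1:3, 1:3]^2))
  grid <- voxel_grid(d, voxel_size = vs, affine = aff)
  scalar_volume(grid, arr)
}

#' Write a volume or mask as NIfTI
#'
#' @param vol a `scalar_volume` or `binary_mask` (masks are written as 0/1).
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "scalar_volume") || inherits(vol, "binary_mask"))
  vals <- vol$values
  if (is.logical(vals)) {
    vals <- array(as.numeric(vals), dim = dim(vals))
  }
  img <- RNifti::asNifti(vals)
  img <- RNifti::`sform<-`(img, structure(vol$grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Change volume resolution
#'
#' Downsamples a volume by an integer factor per axis, either by block
#' averaging (`block-mean`, the default: the output voxel is the mean of the
#' constituent block, so total mass times voxel volume is conserved up to
#' partial edge blocks) or by `subsample` (the voxel nearest each block
#' centre is taken). Non-integer ratios between the target and source voxel
#' size are rejected rather than interpolated, which keeps mass accounting
#' exact.
#'
#' @param vol a `scalar_volume`.
#' @param target_voxel_mm desired isotropic-in-ratio voxel size: must be an
#'   integer multiple of each source voxel size, and at least as large.
#' @param method `"block-mean"` or `"subsample"`.
#' @return a `scalar_volume` on the coarser grid.
#' @export
downsample <- function(vol, target_voxel_mm, method = c("block-mean", "subsample")) {
  method <- match.arg(method)
  stopifnot(inherits(vol, "scalar_volume"))
  vs <- vol$grid$voxel_size
  ratio <- target_voxel_mm / vs
  if (any(ratio < 1 - 1e-9))
    stop("target voxel size smaller than source voxel size")
  f <- round(ratio)
  if (any(abs(ratio - f) > 1e-6))
    stop("non-integer downsampling ratio: ", paste(signif(ratio, 6), collapse = ", "))
  f <- as.integer(f)
  d <- vol$grid$shape
  nd <- as.integer(ceiling(d / f))
  vals <- vol$values
  if (method == "block-mean") {
    bi <- (seq_len(d[1]) - 1L) %/% f[1]
    bj <- (seq_len(d[2]) - 1L) %/% f[2]
    bk <- (seq_len(d[3]) - 1L) %/% f[3]
    blk <- outer(outer(bi, bj * nd[1], "+"), bk * nd[1] * nd[2], "+") + 1L
    sums <- as.vector(rowsum(as.vector(vals), as.vector(blk)))
    cnts <- as.vector(rowsum(rep(1, length(vals)), as.vector(blk)))
    newv <- array(sums / cnts, dim = nd)
  } else {
    off <- (f - 1L) %/% 2L
    newv <- vals[seq(1L + off[1], d[1], by = f[1]),
                 seq(1L + off[2], d[2], by = f[2]),
                 seq(1L + off[3], d[3], by = f[3]), drop = FALSE]
  }
  ## new affine: index scales by f; origin shifts to the centre of block 0
  aff <- vol$grid$affine
  scale <- diag(c(f, 1))
  new_aff <- aff %*% scale
  new_aff[1:3, 4] <- (aff %*% c((f - 1) / 2, 1))[1:3]
  scalar_volume(voxel_grid(nd, voxel_size = vs * f, affine = new_aff), newv)
}

#' Downsample a binary mask
#'
#' Block-majority rule: an output voxel is a member when at least half of its
#' source block is. Companion to [downsample()] for carrying protocol or
#' nucleus masks onto a coarser grid.
#'
#' @param mask a `binary_mask`.
#' @param target_voxel_mm target voxel size (integer multiple of the source).
#' @return a `binary_mask` on the coarser grid.
#' @export
downsample_mask <- function(mask, target_voxel_mm) {
  frac <- downsample(scalar_volume(mask$grid, array(as.numeric(mask$values),
                                                    dim = mask$grid$shape)),
                     target_voxel_mm, method = "block-mean")
  binary_mask(frac$grid, frac$values >= 0.5)
}
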