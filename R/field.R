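#' Multi-fibre orientation field
#'
#' The medium streamlines propagate through: a voxel grid where each voxel
#' carries up to three fibre populations, each with a mean orientation (unit
#' 3-vector, axial, i.e. sign-free), a volume fraction in `[0,1]` and an
#' angular dispersion in degrees. Populations are stored as flat per-voxel
#' arrays for fast vectorised lookup during tracking.
#'
#' @param grid a [voxel_grid()].
#' @return an empty `fibre_field` (no populations anywhere).
#' @export
fibre_field <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  nv <- n_voxels(grid)
  pop <- lapply(1:3, function(i) list(
    orient = matrix(0, nv, 3),
    f = numeric(nv),
    disp = numeric(nv)))
  structure(list(grid = grid, n_pop = integer(nv), pop = pop),
            class = "fibre_field")
}

#' Add a fibre population to a set of voxels
#'
#' @param field a `fibre_field`.
#' @param lin 1-based linear voxel indices receiving the population.
#' @param orient unit orientation(s): length-3 vector (shared) or
#'   `length(lin)` x 3 matrix.
#' @param f volume fraction in (0, 1], scalar or per-voxel.
#' @param dispersion angular dispersion in degrees (>= 0), scalar or per-voxel.
#' @return the updated `fibre_field`. Errors if any voxel would exceed three
#'   populations.
#' @export
field_add_population <- function(field, lin, orient, f, dispersion = 0) {
  stopifnot(inherits(field, "fibre_field"))
  lin <- as.integer(lin)
  if (is.null(dim(orient))) orient <- matrix(orient, length(lin), 3, byrow = TRUE)
  nrm <- sqrt(rowSums(orient^2))
  if (any(abs(nrm - 1) > 1e-6)) orient <- orient / nrm
  f <- rep_len(f, length(lin))
  dispersion <- rep_len(dispersion, length(lin))
  if (any(f <= 0) || any(f > 1)) stop("volume fractions must lie in (0, 1]")
  slot <- field$n_pop[lin] + 1L
  if (any(slot > 3L))
    stop("more than three fibre populations in a voxel")
  for (p in sort(unique(slot))) {
    sel <- slot == p
    field$pop[[p]]$orient[lin[sel], ] <- orient[sel, , drop = FALSE]
    field$pop[[p]]$f[lin[sel]] <- f[sel]
    field$pop[[p]]$disp[lin[sel]] <- dispersion[sel]
  }
  field$n_pop[lin] <- slot
  field
}

#' @export
print.fibre_field <- function(x, ...) {
  cat(sprintf("fibre_field: %s grid, %d voxels with fibre (max %d populations)\n",
              paste(x$grid$shape, collapse = "x"),
              sum(x$n_pop > 0L), max(x$n_pop)))
  invisible(x)
}
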