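#' Tracking parameters
#'
#' Parameters of probabilistic streamline propagation. Defaults follow the
#' standard protocol settings: 0.5 mm steps (human-scale; 0.2 mm is the
#' macaque-scale choice), an 80 degree curvature threshold, at most 2000
#' steps per half-streamline, and a 1% volume-fraction threshold below which
#' subsidiary fibre populations are ignored. The number of streamlines
#' launched per seed voxel defaults to 1000.
#'
#' @param step_size step length in mm (> 0).
#' @param curvature_threshold maximum turning angle per step, degrees in
#'   (0, 180].
#' @param max_steps maximum steps per half-streamline (>= 1).
#' @param volume_fraction_threshold populations with volume fraction below
#'   this are ignored; in `[0, 1)`.
#' @param streamlines_per_seed_voxel streamlines launched per seed voxel.
#' @param rng_seed integer seed controlling all stochastic choices.
#' @return object of class `tracking_params`.
#' @export
tracking_params <- function(step_size = 0.5, curvature_threshold = 80,
                            max_steps = 2000L,
                            volume_fraction_threshold = 0.01,
                            streamlines_per_seed_voxel = 1000L,
                            rng_seed = 1L) {
  if (step_size <= 0) stop("step_size must be > 0")
  if (curvature_threshold <= 0 || curvature_threshold > 180)
    stop("curvature_threshold must lie in (0, 180]")
  if (max_steps < 1) stop("max_steps must be >= 1")
  if (volume_fraction_threshold < 0 || volume_fraction_threshold >= 1)
    stop("volume_fraction_threshold must lie in [0, 1)")
  structure(list(step_size = step_size,
                 curvature_threshold = curvature_threshold,
                 max_steps = as.integer(max_steps),
                 volume_fraction_threshold = volume_fraction_threshold,
                 streamlines_per_seed_voxel = as.integer(streamlines_per_seed_voxel),
                 rng_seed = as.integer(rng_seed)),
            class = "tracking_params")
}

## rotate unit vectors by angles ~ N(0, sd_deg) about random axes
## perpendicular to each vector (the dispersion model: a zero-mean wrapped
## perturbation of the mean orientation)
perturb_dirs <- function(mean_dir, sd_deg) {
  n <- nrow(mean_dir)
  theta <- stats::rnorm(n, 0, sd_deg * pi / 180)
  r <- matrix(stats::rnorm(3L * n), n, 3)
  a <- r - mean_dir * rowSums(r * mean_dir)
  an <- sqrt(rowSums(a * a))
  deg <- an < 1e-9
  if (any(deg)) {
    ## random draw happened to be parallel: use a fixed fallback axis
    fb <- cbind(-mean_dir[deg, 2], mean_dir[deg, 1], 0)
    fn <- sqrt(rowSums(fb * fb))
    flat <- fn < 1e-9
    fb[flat, ] <- matrix(c(0, 0, 1), sum(flat), 3, byrow = TRUE)
    a[deg, ] <- fb / sqrt(rowSums(fb * fb))
    an[deg] <- 1
  }
  a <- a / an
  out <- mean_dir * cos(theta) + a * sin(theta)
  out / sqrt(rowSums(out * out))
}

## vectorised direction sampler at linear voxel indices `vox` (no NAs).
## prev is NULL (random population choice) or an n x 3 matrix of previous
## directions. Returns dir (n x 3, NA rows for no-fibre) and nofib flags.
sample_dirs <- function(field, vox, prev, params) {
  n <- length(vox)
  bestdot <- rep(-Inf, n)
  besti <- integer(n)
  npop <- field$n_pop[vox]
  for (p in 1:3) {
    okp <- npop >= p &
      field$pop[[p]]$f[vox] >= params$volume_fraction_threshold
    if (!any(okp)) next
    if (is.null(prev)) {
      d <- stats::runif(n)
    } else {
      o <- field$pop[[p]]$orient[vox, , drop = FALSE]
      d <- abs(o[, 1] * prev[, 1] + o[, 2] * prev[, 2] + o[, 3] * prev[, 3])
    }
    upd <- okp & d > bestdot
    bestdot[upd] <- d[upd]
    besti[upd] <- p
  }
  dir <- matrix(NA_real_, n, 3)
  nofib <- besti == 0L
  if (any(!nofib)) {
    disp <- numeric(n)
    for (p in unique(besti[!nofib])) {
      sel <- which(besti == p)
      dir[sel, ] <- field$pop[[p]]$orient[vox[sel], , drop = FALSE]
      disp[sel] <- field$pop[[p]]$disp[vox[sel]]
    }
    dsel <- which(!nofib & disp > 0)
    if (length(dsel))
      dir[dsel, ] <- perturb_dirs(dir[dsel, , drop = FALSE], disp[dsel])
    if (!is.null(prev)) {
      dots <- rowSums(dir * prev)
      flip <- which(!nofib & dots < 0)
      if (length(flip)) dir[flip, ] <- -dir[flip, , drop = FALSE]
    }
  }
  list(dir = dir, nofib = nofib)
}

#' Sample a propagation direction in one voxel
#'
#' The per-step direction rule: populations with volume fraction below the
#' threshold are ignored; among the survivors the population whose (axial)
#' mean orientation has maximal `|dot|` with the previous direction is
#' chosen (a uniformly random survivor when there is no previous direction);
#' a dispersed sample around its mean is drawn; and the sign is flipped if
#' needed so the result does not point backwards. Returns `NULL` as the
#' no-fibre signal when no population survives. Uses R's global RNG; seed it
#' for reproducibility.
#'
#' @param field a [fibre_field()].
#' @param voxel a 1-based linear voxel index, or a length-3 0-based ijk
#'   index.
#' @param prev_dir previous unit direction, or `NULL`.
#' @param params a [tracking_params()].
#' @return unit 3-vector, or `NULL` (no-fibre).
#' @export
sample_direction <- function(field, voxel, prev_dir = NULL,
                             params = tracking_params()) {
  if (length(voxel) == 3L)
    voxel <- world_to_linear(field$grid, voxel_to_world(field$grid, voxel))
  stopifnot(length(voxel) == 1L, !is.na(voxel))
  prev <- if (!is.null(prev_dir)) matrix(prev_dir / sqrt(sum(prev_dir^2)), 1, 3)
  res <- sample_dirs(field, as.integer(voxel), prev, params)
  if (res$nofib[1]) NULL else as.numeric(res$dir[1, ])
}

## propagate one half-streamline for a batch of seeds in lockstep.
## Returns recorded positions per step (list of n x 3 matrices), per-stream
## step counts, termination reasons, and invalid flags (exclusion entered).
track_half <- function(field, start, dir0, params, stopv, exclv) {
  grid <- field$grid
  n <- nrow(start)
  pos <- start
  dirp <- dir0
  reason <- rep(NA_character_, n)
  invalid <- rep(FALSE, n)
  nsteps <- integer(n)
  rec <- vector("list", 0L)
  active <- which(!is.na(dir0[, 1]))
  reason[is.na(dir0[, 1])] <- "no-fibre"
  costhr <- cos(params$curvature_threshold * pi / 180)
  step <- params$step_size
  for (s in seq_len(params$max_steps)) {
    if (!length(active)) break
    vox <- world_to_linear(grid, pos[active, , drop = FALSE])
    off <- is.na(vox)
    if (any(off)) {
      reason[active[off]] <- "left-field"
      active <- active[!off]
      vox <- vox[!off]
      if (!length(active)) break
    }
    sd_ <- sample_dirs(field, vox, dirp[active, , drop = FALSE], params)
    nf <- sd_$nofib
    if (any(nf)) {
      reason[active[nf]] <- "no-fibre"
      active <- active[!nf]
      if (!length(active)) break
      sd_$dir <- sd_$dir[!nf, , drop = FALSE]
    }
    dots <- rowSums(sd_$dir * dirp[active, , drop = FALSE])
    curv <- dots < costhr
    if (any(curv)) {
      reason[active[curv]] <- "curvature"
      active <- active[!curv]
      if (!length(active)) break
      sd_$dir <- sd_$dir[!curv, , drop = FALSE]
    }
    newpos <- pos[active, , drop = FALSE] + step * sd_$dir
    recmat <- matrix(NA_real_, n, 3)
    recmat[active, ] <- newpos
    rec[[s]] <- recmat
    nsteps[active] <- s
    pos[active, ] <- newpos
    dirp[active, ] <- sd_$dir
    nvox <- world_to_linear(grid, newpos)
    drop_ <- logical(length(active))
    outg <- is.na(nvox)
    if (any(outg)) {
      reason[active[outg]] <- "left-field"
      drop_ <- drop_ | outg
    }
    if (!is.null(exclv)) {
      hit <- !is.na(nvox) & exclv[pmax(nvox, 1L)]
      hit[is.na(nvox)] <- FALSE
      if (any(hit)) {
        reason[active[hit]] <- "exclusion"
        invalid[active[hit]] <- TRUE
        drop_ <- drop_ | hit
      }
    }
    if (!is.null(stopv)) {
      hit <- !is.na(nvox) & stopv[pmax(nvox, 1L)] & !drop_
      hit[is.na(nvox)] <- FALSE
      if (any(hit)) {
        reason[active[hit]] <- "stop-mask"
        drop_ <- drop_ | hit
      }
    }
    active <- active[!drop_]
  }
  reason[is.na(reason)] <- "max-steps"
  list(rec = rec, nsteps = nsteps, reason = reason, invalid = invalid)
}

## voxel indices of recorded points, per step (steps x n matrix)
half_voxels <- function(grid, half, n) {
  if (!length(half$rec)) return(matrix(NA_integer_, 0, n))
  do.call(rbind, lapply(half$rec, function(m) world_to_linear(grid, m)))
}

#' Propagate a single streamline
#'
#' Two half-streamlines are launched from the seed with opposite initial
#' signs of the locally sampled direction and concatenated. Each step moves
#' `step_size` mm along the sampled direction; a streamline half terminates
#' on leaving the grid (`left-field`), in a voxel without supra-threshold
#' fibre (`no-fibre`), when the turn would exceed the curvature threshold
#' (`curvature`), upon entering a stop or exclusion mask, or at `max_steps`.
#' Uses R's global RNG; seed it for reproducibility.
#'
#' @param field a [fibre_field()].
#' @param seed_point world seed coordinate (inside the grid).
#' @param params a [tracking_params()].
#' @param masks optional list with elements `stop` and/or `exclusion`
#'   (`binary_mask` objects).
#' @return object of class `streamline`: `points` (ordered world points,
#'   consecutive points `step_size` apart), `seed_index` (row of the seed
#'   point in `points`), `termination_reason` (forward half), `reasons`
#'   (both halves) and `invalid` (entered an exclusion). The curvature
#'   threshold constrains every step within each half; the single direction
#'   pair across the seed joins two independently initiated halves and is
#'   not curvature-constrained.
#' @export
propagate <- function(field, seed_point, params = tracking_params(),
                      masks = list()) {
  grid <- field$grid
  seed <- matrix(as.numeric(seed_point), 1, 3)
  v0 <- world_to_linear(grid, seed)
  if (is.na(v0)) stop("seed outside grid")
  stopv <- if (!is.null(masks$stop)) as.vector(masks$stop$values)
  exclv <- if (!is.null(masks$exclusion)) as.vector(masks$exclusion$values)
  d0 <- sample_dirs(field, v0, NULL, params)$dir
  fwd <- track_half(field, seed, d0, params, stopv, exclv)
  bwd <- track_half(field, seed, -d0, params, stopv, exclv)
  take <- function(h) {
    if (h$nsteps[1] == 0L) return(NULL)
    do.call(rbind, lapply(h$rec[seq_len(h$nsteps[1])], function(m) m[1, ]))
  }
  fp <- take(fwd); bp <- take(bwd)
  pts <- rbind(if (!is.null(bp)) bp[rev(seq_len(nrow(bp))), , drop = FALSE],
               seed, fp)
  structure(list(points = pts,
                 seed_index = if (is.null(bp)) 1L else nrow(bp) + 1L,
                 termination_reason = fwd$reason[1],
                 reasons = c(forward = fwd$reason[1], backward = bwd$reason[1]),
                 invalid = fwd$invalid[1] || bwd$invalid[1]),
            class = "streamline")
}

#' Path distribution
#'
#' Per-voxel visitation map for one tract: the number of distinct valid
#' streamlines entering each voxel, plus the valid-streamline count and a
#' normalisation flag. Created by [track_protocol()]; normalised values
#' (each count divided by `n_valid`) are interpretable as visitation
#' probabilities in `[0, 1]`.
#'
#' @param grid a `voxel_grid`.
#' @param values numeric array of per-voxel visitation.
#' @param n_valid number of valid streamlines.
#' @param n_total total number of launched streamlines.
#' @param normalised logical.
#' @param reasons termination-reason table (metadata).
#' @return object of class `path_distribution`.
#' @export
path_distribution <- function(grid, values, n_valid, n_total = NA_integer_,
                              normalised = FALSE, reasons = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  values <- as.array(values)
  stopifnot(all(dim(values) == grid$shape))
  structure(list(grid = grid, values = values, n_valid = as.integer(n_valid),
                 n_total = as.integer(n_total),
                 normalised = isTRUE(normalised), reasons = reasons),
            class = "path_distribution")
}

#' @export
print.path_distribution <- function(x, ...) {
  cat(sprintf("path_distribution: %s grid, n_valid = %d%s, %s\n",
              paste(x$grid$shape, collapse = "x"), x$n_valid,
              if (!is.na(x$n_total)) sprintf(" of %d", x$n_total) else "",
              if (x$normalised) "normalised" else "raw counts"))
  invisible(x)
}

#' Run a protocol through a fibre field
#'
#' Launches `streamlines_per_seed_voxel` streamlines per seed voxel, with
#' the start jittered uniformly within the voxel. A streamline is valid iff
#' it visits every target mask (unordered conjunction) and never enters an
#' exclusion mask; entering a stop mask truncates propagation, but the
#' truncated path still counts if the targets were visited. The visitation
#' map counts, per voxel, the number of distinct valid streamlines entering
#' it. Deterministic given `params$rng_seed`.
#'
#' @param field a [fibre_field()].
#' @param protocol a [protocol()] whose masks share the field's grid.
#' @param params a [tracking_params()].
#' @return an unnormalised [path_distribution()].
#' @export
track_protocol <- function(field, protocol, params = tracking_params()) {
  stopifnot(inherits(field, "fibre_field"), inherits(protocol, "protocol"))
  grid <- field$grid
  if (!grids_equal(grid, protocol$seed$grid))
    stop("protocol masks do not share the field's grid")
  seed_lin <- mask_which(protocol$seed)
  if (!length(seed_lin)) stop("empty seed")
  set.seed(params$rng_seed)
  nper <- params$streamlines_per_seed_voxel
  n <- length(seed_lin) * nper
  ijk <- linear_to_ijk(grid, rep(seed_lin, each = nper))
  jit <- matrix(stats::runif(3L * n, -0.5, 0.5), n, 3)
  seeds <- voxel_to_world(grid, ijk + jit)
  stopv <- if (!is.null(protocol$stop)) as.vector(protocol$stop$values)
  exclv <- NULL
  if (length(protocol$exclusions)) {
    exclv <- Reduce(`|`, lapply(protocol$exclusions,
                                function(m) as.vector(m$values)))
  }
  seedvox <- world_to_linear(grid, seeds)
  d0 <- sample_dirs(field, seedvox, NULL, params)$dir
  fwd <- track_half(field, seeds, d0, params, stopv, exclv)
  bwd <- track_half(field, seeds, -d0, params, stopv, exclv)
  fvox <- half_voxels(grid, fwd, n)
  bvox <- half_voxels(grid, bwd, n)
  tvs <- lapply(protocol$targets, function(m) as.vector(m$values))
  counts <- numeric(n_voxels(grid))
  n_valid <- 0L
  for (i in seq_len(n)) {
    vs <- c(seedvox[i],
            if (fwd$nsteps[i] > 0L) fvox[seq_len(fwd$nsteps[i]), i],
            if (bwd$nsteps[i] > 0L) bvox[seq_len(bwd$nsteps[i]), i])
    vs <- unique(vs[!is.na(vs)])
    if (fwd$invalid[i] || bwd$invalid[i]) next
    ok <- TRUE
    for (tv in tvs) if (!any(tv[vs])) { ok <- FALSE; break }
    if (!ok) next
    n_valid <- n_valid + 1L
    counts[vs] <- counts[vs] + 1
  }
  reasons <- table(factor(c(fwd$reason, bwd$reason),
                          levels = c("left-field", "no-fibre", "curvature",
                                     "max-steps", "stop-mask", "exclusion")))
  path_distribution(grid, array(counts, dim = grid$shape),
                    n_valid = n_valid, n_total = n, normalised = FALSE,
                    reasons = reasons)
}

#' Normalise a path distribution
#'
#' Divides every visitation count by the number of valid streamlines. When
#' no streamline was valid an all-zero map is returned with a warning.
#'
#' @param pd an unnormalised [path_distribution()].
#' @return the normalised `path_distribution`.
#' @export
normalise <- function(pd) {
  stopifnot(inherits(pd, "path_distribution"))
  if (pd$normalised) stop("path distribution already normalised")
  if (pd$n_valid == 0L) {
    warning("no valid streamlines; returning all-zero map")
    vals <- array(0, dim = pd$grid$shape)
  } else {
    vals <- pd$values / pd$n_valid
  }
  path_distribution(pd$grid, vals, pd$n_valid, pd$n_total,
                    normalised = TRUE, reasons = pd$reasons)
}

#' Symmetric two-run tracking
#'
#' For protocols with the reverse-run flag (e.g. commissural tracts run from
#' both sides): runs [track_protocol()] once as given and once with the seed
#' and the final target swapped, normalises each run, and returns the
#' voxelwise mean of the two normalised maps.
#'
#' @param field a [fibre_field()].
#' @param protocol a symmetric [protocol()] with at least one target.
#' @param params a [tracking_params()].
#' @return a normalised [path_distribution()]; `n_valid` is the sum over the
#'   two runs.
#' @export
run_symmetric <- function(field, protocol, params = tracking_params()) {
  stopifnot(inherits(protocol, "protocol"))
  if (!protocol$symmetric) stop("protocol does not set the symmetric flag")
  if (!length(protocol$targets)) stop("symmetric run requires a target")
  k <- length(protocol$targets)
  swapped <- protocol
  swapped$seed <- protocol$targets[[k]]
  swapped$targets[[k]] <- protocol$seed
  a <- suppressWarnings(normalise(track_protocol(field, protocol, params)))
  b <- suppressWarnings(normalise(track_protocol(field, swapped, params)))
  path_distribution(field$grid, (a$values + b$values) / 2,
                    n_valid = a$n_valid + b$n_valid,
                    n_total = a$n_total + b$n_total,
                    normalised = TRUE)
}
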