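## Synthetic fibre phantoms: bundles with known geometry, matched two-species
## blueprints, and family-structured cohorts. These generators define the
## study conditions every other module is tested under.

## Substream derivation: all generators take one root seed; per-object
## substreams are derived by hashing small integer keys with fixed primes,
## kept below 2^31, so any single object is reproducible in isolation.
derive_seed <- function(root, ...) {
  keys <- as.numeric(c(...))
  h <- (as.numeric(root) + sum(keys * c(73856093, 19349663, 83492791,
                                        15485863, 49979687)[seq_along(keys)])) %%
    2147483629
  as.integer(h)
}

#' Straight centreline
#' @param from,to world endpoints (mm), length-3 vectors.
#' @param step spacing of sampled points along the line (mm).
#' @return matrix of world points tracing the segment.
#' @export
centreline_line <- function(from, to, step = 0.5) {
  len <- sqrt(sum((to - from)^2))
  if (len <= 0) stop("degenerate line")
  t <- seq(0, 1, length.out = max(2L, ceiling(len / step) + 1L))
  cbind(from[1] + t * (to[1] - from[1]),
        from[2] + t * (to[2] - from[2]),
        from[3] + t * (to[3] - from[3]))
}

#' Circular-arc centreline in an axis plane
#' @param centre world centre of the circle (length 3).
#' @param radius arc radius (mm).
#' @param theta_from,theta_to start and end angle in degrees.
#' @param plane `"xy"`, `"xz"` or `"yz"`: the axis plane containing the arc.
#' @param step approximate spacing of sampled points (mm).
#' @return matrix of world points tracing the arc.
#' @export
centreline_arc <- function(centre, radius, theta_from, theta_to,
                           plane = c("xy", "xz", "yz"), step = 0.5) {
  plane <- match.arg(plane)
  if (radius <= 0) stop("radius must be > 0")
  arc_len <- abs(theta_to - theta_from) * pi / 180 * radius
  th <- seq(theta_from, theta_to,
            length.out = max(2L, ceiling(arc_len / step) + 1L)) * pi / 180
  u <- radius * cos(th); v <- radius * sin(th)
  out <- matrix(rep(centre, each = length(th)), ncol = 3)
  ax <- switch(plane, xy = c(1, 2), xz = c(1, 3), yz = c(2, 3))
  out[, ax[1]] <- out[, ax[1]] + u
  out[, ax[2]] <- out[, ax[2]] + v
  out
}

#' Bundle specification
#'
#' Geometry and microstructure of one synthetic fibre bundle: a tube of given
#' radius around a parametric centreline, filled with a single fibre
#' population following the local tangent.
#'
#' @param name bundle identifier.
#' @param centreline matrix of world points (polyline), e.g. from
#'   [centreline_line()] or [centreline_arc()].
#' @param radius tube radius in mm (> 0).
#' @param f fibre volume fraction in (0, 1].
#' @param dispersion angular dispersion of the population, degrees (>= 0).
#' @return object of class `bundle_spec`.
#' @export
bundle_spec <- function(name, centreline, radius, f = 0.6, dispersion = 0) {
  centreline <- as.matrix(centreline)
  if (ncol(centreline) != 3L || nrow(centreline) < 2L)
    stop("centreline must be an N x 3 matrix with N >= 2")
  if (radius <= 0) stop("radius must be > 0")
  if (f <= 0 || f > 1) stop("volume fraction must lie in (0, 1]")
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(list(name = name, centreline = centreline, radius = radius,
                 f = f, dispersion = dispersion),
            class = "bundle_spec")
}

## distance of every voxel centre to a polyline + tangent and arclength at
## the nearest point; vectorised over voxels, looped over segments
polyline_project <- function(grid, pts) {
  ctr <- all_voxel_centres(grid)
  nseg <- nrow(pts) - 1L
  seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  cum <- c(0, cumsum(seglen))
  best_d2 <- rep(Inf, nrow(ctr))
  best_tan <- matrix(0, nrow(ctr), 3)
  best_arc <- numeric(nrow(ctr))
  for (s in seq_len(nseg)) {
    a <- pts[s, ]; b <- pts[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 <= 0) next
    t <- ((ctr[, 1] - a[1]) * ab[1] + (ctr[, 2] - a[2]) * ab[2] +
            (ctr[, 3] - a[3]) * ab[3]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- ctr[, 1] - (a[1] + t * ab[1])
    dy <- ctr[, 2] - (a[2] + t * ab[2])
    dz <- ctr[, 3] - (a[3] + t * ab[3])
    d2 <- dx * dx + dy * dy + dz * dz
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      tan_s <- ab / sqrt(len2)
      best_tan[upd, 1] <- tan_s[1]
      best_tan[upd, 2] <- tan_s[2]
      best_tan[upd, 3] <- tan_s[3]
      best_arc[upd] <- cum[s] + t[upd] * seglen[s]
    }
  }
  list(dist = sqrt(best_d2), tangent = best_tan, arclen = best_arc,
       total_len = cum[nseg + 1L])
}

#' Build a phantom scene
#'
#' Rasterises bundle specifications onto a grid: every voxel whose centre
#' lies within `radius` of a bundle centreline carries that bundle's local
#' tangent as a fibre population (voxels inside two bundles carry two
#' populations, i.e. a crossing). Ground-truth masks, labelled grey-matter
#' boundary locations (the cap-face centres of each bundle) and optional
#' labelled nucleus masks are attached. Construction is deterministic given
#' the seed, which is stored for downstream substream derivation.
#'
#' @param specs list of [bundle_spec()] objects.
#' @param grid a [voxel_grid()].
#' @param rng_seed integer root seed for the scene.
#' @param nuclei optional named list of `binary_mask` objects (subcortical
#'   structures), or of `list(centre=, radius=)` sphere specs.
#' @return object of class `phantom_scene` with fields `grid`, `bundles`,
#'   `field`, `ground_truth_masks`, `gm_locations` (data frame with label and
#'   world coordinates), `subcortical_masks`, `geometry` (per-bundle
#'   projection data) and `rng_seed`.
#' @export
make_scene <- function(specs, grid, rng_seed = 1L, nuclei = list()) {
  if (inherits(specs, "bundle_spec")) specs <- list(specs)
  stopifnot(inherits(grid, "voxel_grid"))
  field <- fibre_field(grid)
  gt <- list()
  geom <- list()
  gm <- list()
  for (b in specs) {
    if (anyNA(world_to_linear(grid, b$centreline)))
      stop("bundle '", b$name, "' centreline leaves the grid")
    pr <- polyline_project(grid, b$centreline)
    lin <- which(pr$dist <= b$radius)
    if (!length(lin)) stop("bundle '", b$name, "' covers no voxels")
    field <- field_add_population(field, lin, pr$tangent[lin, , drop = FALSE],
                                  b$f, b$dispersion)
    gt[[b$name]] <- mask_from_linear(grid, lin)
    geom[[b$name]] <- list(arclen = pr$arclen, dist = pr$dist,
                           total_len = pr$total_len)
    gm[[length(gm) + 1L]] <- data.frame(
      label = paste0(b$name, c("_end1", "_end2")),
      bundle = b$name,
      x = c(b$centreline[1, 1], b$centreline[nrow(b$centreline), 1]),
      y = c(b$centreline[1, 2], b$centreline[nrow(b$centreline), 2]),
      z = c(b$centreline[1, 3], b$centreline[nrow(b$centreline), 3]),
      stringsAsFactors = FALSE)
  }
  sub <- list()
  for (nm in names(nuclei)) {
    nu <- nuclei[[nm]]
    if (inherits(nu, "binary_mask")) {
      sub[[nm]] <- nu
    } else {
      ctr <- all_voxel_centres(grid)
      d2 <- (ctr[, 1] - nu$centre[1])^2 + (ctr[, 2] - nu$centre[2])^2 +
        (ctr[, 3] - nu$centre[3])^2
      sub[[nm]] <- mask_from_linear(grid, which(d2 <= nu$radius^2))
    }
  }
  names(specs) <- vapply(specs, `[[`, "", "name")
  structure(list(grid = grid, bundles = specs, field = field,
                 ground_truth_masks = gt,
                 gm_locations = do.call(rbind, gm),
                 subcortical_masks = sub,
                 geometry = geom, rng_seed = as.integer(rng_seed)),
            class = "phantom_scene")
}

#' Derive a tracking protocol from a phantom bundle
#'
#' Builds an endpoint protocol for a bundle: the seed is the cap of
#' ground-truth voxels at the start of the centreline (projected arclength
#' within one voxel size), the target the cap at the far end. Style
#' `"symmetric"` additionally sets the reverse-run flag; `"with-exclusion"`
#' adds a full grid plane that the bundle does not intersect.
#'
#' @param scene a `phantom_scene`.
#' @param bundle_id bundle name present in the scene.
#' @param style `"endpoint"`, `"symmetric"` or `"with-exclusion"`.
#' @return a [protocol()].
#' @export
make_protocol_for_bundle <- function(scene, bundle_id,
                                     style = c("endpoint", "symmetric",
                                               "with-exclusion")) {
  style <- match.arg(style)
  stopifnot(inherits(scene, "phantom_scene"))
  if (!bundle_id %in% names(scene$bundles)) stop("unknown bundle: ", bundle_id)
  g <- scene$geometry[[bundle_id]]
  gt_lin <- mask_which(scene$ground_truth_masks[[bundle_id]])
  cap <- max(scene$grid$voxel_size)
  if (g$total_len < 2 * cap)
    stop("degenerate bundle: shorter than two cap depths")
  seed_lin <- gt_lin[g$arclen[gt_lin] <= cap]
  targ_lin <- gt_lin[g$arclen[gt_lin] >= g$total_len - cap]
  exclusions <- list()
  if (style == "with-exclusion") {
    ijk <- linear_to_ijk(scene$grid, gt_lin)
    plane <- NULL
    for (ax in 1:3) {
      free <- setdiff(seq_len(scene$grid$shape[ax]) - 1L, unique(ijk[, ax]))
      if (length(free)) { plane <- c(ax, free[length(free)]); break }
    }
    if (is.null(plane)) stop("no bundle-free plane available for exclusion")
    v <- array(FALSE, dim = scene$grid$shape)
    idx <- list(quote(expr = ), quote(expr = ), quote(expr = ))
    idx[[plane[1]]] <- plane[2] + 1L
    v <- do.call(`[<-`, c(list(v), idx, list(value = TRUE)))
    exclusions <- list(binary_mask(scene$grid, v))
  }
  protocol(name = bundle_id,
           seed = mask_from_linear(scene$grid, seed_lin),
           targets = list(mask_from_linear(scene$grid, targ_lin)),
           exclusions = exclusions,
           symmetric = style == "symmetric")
}

## Dirichlet draw via normalised gamma variates
rdirichlet1 <- function(k, concentration) {
  g <- stats::rgamma(k, shape = concentration, rate = 1)
  if (all(g == 0)) g <- rep(1, k)
  g / sum(g)
}

#' Matched two-species synthetic blueprints
#'
#' Emulates the cross-species setting used for homologue matching: each of
#' `n_regions` regions owns a tract connection profile drawn once from a
#' Dirichlet-type simplex distribution, and both "species" draw their
#' blueprint rows around that shared profile with independent multiplicative
#' log-normal noise before row normalisation. Tracts are split into a
#' cortico-cortical set (`cc*`), whose regional profiles share a common
#' background component (so cc tracts discriminate regions only weakly), and
#' a cortico-subcortical set (`cs*`) with fully region-specific profiles.
#' This makes the subcortical tracts the informative ones, mirroring the
#' motivation for including them in cross-species comparisons.
#'
#' @param n_regions number of homologous regions (>= 2).
#' @param n_tracts total number of tracts (>= 2); `n_cc` of them are
#'   cortico-cortical.
#' @param locations_per_region rows per region per species.
#' @param concentration Dirichlet concentration (> 0); smaller values give
#'   spikier, more distinctive profiles.
#' @param noise standard deviation of the multiplicative log-normal row noise.
#' @param rng_seed integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @param n_cc number of cortico-cortical tracts (default: half, rounded up).
#' @return list with `species_a` and `species_b` (row-normalised
#'   [connectivity_blueprint] objects carrying a `tract_class` attribute),
#'   `regions` (region label per row) and `tract_class`.
#' @export
make_matched_blueprints <- function(n_regions, n_tracts = 12L,
                                    locations_per_region = 20L,
                                    concentration = 0.5, noise = 0.25,
                                    rng_seed = 1L,
                                    n_cc = ceiling(n_tracts / 2)) {
  if (n_regions < 2L || n_tracts < 2L) stop("need >= 2 regions and >= 2 tracts")
  if (concentration <= 0) stop("concentration must be > 0")
  set.seed(derive_seed(rng_seed, 101L))
  n_cs <- n_tracts - n_cc
  tract_names <- c(if (n_cc > 0) paste0("cc", seq_len(n_cc)),
                   if (n_cs > 0) paste0("cs", seq_len(n_cs)))
  tract_class <- stats::setNames(rep(c("cc", "cs"), c(n_cc, n_cs)), tract_names)
  common_cc <- if (n_cc > 0) rdirichlet1(n_cc, concentration) else numeric(0)
  profiles <- matrix(0, n_regions, n_tracts,
                     dimnames = list(paste0("region", seq_len(n_regions)),
                                     tract_names))
  for (r in seq_len(n_regions)) {
    pcc <- if (n_cc > 0) 0.7 * common_cc + 0.3 * rdirichlet1(n_cc, concentration)
    else numeric(0)
    pcs <- if (n_cs > 0) rdirichlet1(n_cs, concentration) else numeric(0)
    prof <- c(0.5 * pcc, 0.5 * pcs)
    profiles[r, ] <- prof / sum(prof)
  }
  draw_species <- function(sub_seed) {
    set.seed(derive_seed(rng_seed, sub_seed))
    rows <- matrix(0, n_regions * locations_per_region, n_tracts)
    labels <- character(nrow(rows))
    for (r in seq_len(n_regions)) {
      for (l in seq_len(locations_per_region)) {
        i <- (r - 1L) * locations_per_region + l
        row <- profiles[r, ] * exp(stats::rnorm(n_tracts, 0, noise))
        rows[i, ] <- row / sum(row)
        labels[i] <- rownames(profiles)[r]
      }
    }
    dimnames(rows) <- list(paste0(labels, "_loc", rep(seq_len(locations_per_region),
                                                      n_regions)), tract_names)
    bp <- connectivity_blueprint(rows, row_type = rep("subcortical", nrow(rows)),
                                 row_normalised = TRUE)
    attr(bp, "tract_class") <- tract_class
    list(bp = bp, labels = labels)
  }
  a <- draw_species(202L)
  b <- draw_species(303L)
  list(species_a = a$bp, species_b = b$bp, regions = a$labels,
       tract_class = tract_class, profiles = profiles)
}

## deterministic scene builder used by the family cohort: latent z (length 2)
## controls the bow amplitude and axial offset of a single curved bundle
family_scene <- function(z, rng_seed, grid = NULL, dispersion = 3) {
  if (is.null(grid)) grid <- voxel_grid(c(16L, 16L, 16L), 1)
  a <- 1.5 + 0.6 * tanh(z[1])
  zoff <- 1.2 * tanh(z[2])
  t <- seq(0, 1, length.out = 24)
  pts <- cbind(2.5 + 11 * t,
               7.5 + a * sin(pi * t),
               7.5 + zoff)
  make_scene(list(bundle_spec("fam", pts, radius = 1.5, f = 0.6,
                              dispersion = dispersion)),
             grid, rng_seed = rng_seed)
}

#' Family-structured phantom cohort
#'
#' Emulates a twin-design cohort: each pair shares a latent bundle-geometry
#' parameter vector; the two members perturb it by the group's within-pair
#' standard deviation. Monozygotic (MZ) pairs get the smallest perturbation,
#' dizygotic (DZ) and non-twin sibling (sib) pairs an intermediate and equal
#' one, and unrelated pairs draw fully independent parameters. The latent
#' vector controls the bow amplitude and axial offset of a single curved
#' bundle in a small grid.
#'
#' @param n_pairs_per_group pairs per group.
#' @param groups subset of `c("MZ","DZ","sib","unrelated")`.
#' @param heritable_param_sd SD of the shared latent parameters.
#' @param within_pair_sd named numeric vector of within-pair SDs per group;
#'   `Inf` (the default for unrelated) means independent draws. Must be
#'   ordered MZ <= DZ == sib <= unrelated.
#' @param rng_seed integer root seed.
#' @param dispersion angular dispersion (degrees) of the bundle populations.
#' @return list of pair records: `group`, `id_a`, `id_b`, `scene_a`,
#'   `scene_b`.
#' @export
make_family_cohort <- function(n_pairs_per_group = 10L,
                               groups = c("MZ", "DZ", "sib", "unrelated"),
                               heritable_param_sd = 1,
                               within_pair_sd = c(MZ = 0.1, DZ = 0.5,
                                                  sib = 0.5, unrelated = Inf),
                               rng_seed = 1L, dispersion = 3) {
  if (!length(groups)) stop("empty group list")
  groups <- match.arg(groups, several.ok = TRUE)
  sds <- within_pair_sd[groups]
  if (anyNA(sds)) stop("within_pair_sd must name every requested group")
  full <- within_pair_sd[c("MZ", "DZ", "sib", "unrelated")]
  full <- full[!is.na(full)]
  if (is.unsorted(full)) stop("within-pair sd must be ordered MZ <= DZ ~ sib <= unrelated")
  out <- list()
  gi <- 0L
  for (g in groups) {
    gi <- gi + 1L
    for (p in seq_len(n_pairs_per_group)) {
      set.seed(derive_seed(rng_seed, 7L, gi, p))
      z <- stats::rnorm(2, 0, heritable_param_sd)
      if (is.finite(sds[[g]])) {
        za <- z + stats::rnorm(2, 0, sds[[g]])
        zb <- z + stats::rnorm(2, 0, sds[[g]])
      } else {
        za <- stats::rnorm(2, 0, heritable_param_sd)
        zb <- stats::rnorm(2, 0, heritable_param_sd)
      }
      out[[length(out) + 1L]] <- list(
        group = g,
        id_a = sprintf("%s%02d_a", g, p),
        id_b = sprintf("%s%02d_b", g, p),
        scene_a = family_scene(za, derive_seed(rng_seed, 11L, gi, p, 1L),
                               dispersion = dispersion),
        scene_b = family_scene(zb, derive_seed(rng_seed, 11L, gi, p, 2L),
                               dispersion = dispersion))
    }
  }
  out
}
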