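#' Tractography protocol
#'
#' A named recipe of protocol masks: where streamlines start (`seed`), which
#' regions they must all visit to be counted valid (`targets`, an unordered
#' conjunction of waypoint masks), where propagation truncates (`stop`) and
#' which regions invalidate a streamline (`exclusions`). `symmetric = TRUE`
#' marks protocols that are run a second time with seed and target swapped,
#' averaging the two normalised path distributions.
#'
#' @param name protocol name.
#' @param seed a non-empty [binary_mask()].
#' @param targets list of `binary_mask` waypoints (may be empty unless
#'   `symmetric`).
#' @param stop optional `binary_mask`.
#' @param exclusions list of `binary_mask` objects; the seed mask must not
#'   overlap any of them.
#' @param symmetric logical reverse-run flag; requires at least one target.
#' @param laterality `"bilateral"`, `"commissural"` or `"unilateral"`
#'   (metadata used by manifest expansion).
#' @return object of class `protocol`.
#' @export
protocol <- function(name, seed, targets = list(), stop = NULL,
                     exclusions = list(), symmetric = FALSE,
                     laterality = c("unilateral", "bilateral", "commissural")) {
  laterality <- match.arg(laterality)
  stopifnot(inherits(seed, "binary_mask"))
  if (inherits(targets, "binary_mask")) targets <- list(targets)
  if (inherits(exclusions, "binary_mask")) exclusions <- list(exclusions)
  if (mask_is_empty(seed)) base::stop("empty seed")
  for (m in c(targets, exclusions, if (!is.null(stop)) list(stop))) {
    stopifnot(inherits(m, "binary_mask"))
    if (!grids_equal(m$grid, seed$grid))
      base::stop("protocol masks do not share a grid")
  }
  for (ex in exclusions) {
    if (any(seed$values & ex$values))
      base::stop("seed mask overlaps an exclusion mask")
  }
  if (symmetric && !length(targets))
    base::stop("symmetric protocols require at least one target")
  structure(list(name = name, laterality = laterality, seed = seed,
                 targets = targets, stop = stop, exclusions = exclusions,
                 symmetric = isTRUE(symmetric)),
            class = "protocol")
}

#' @export
print.protocol <- function(x, ...) {
  cat(sprintf("protocol '%s' (%s%s): %d seed voxel(s), %d target(s), %s stop, %d exclusion(s)\n",
              x$name, x$laterality, if (x$symmetric) ", symmetric" else "",
              length(mask_which(x$seed)), length(x$targets),
              if (is.null(x$stop)) "no" else "a", length(x$exclusions)))
  invisible(x)
}

protocol_keys <- c("name", "laterality", "seed", "targets", "stop",
                   "exclusions", "symmetric")

#' Load a protocol from a YAML or JSON file
#'
#' The file holds keys `name`, `laterality`, `seed`, `targets`, optional
#' `stop`, `exclusions` and `symmetric`; mask values are NIfTI paths
#' interpreted relative to the protocol file's directory (mirroring a
#' protocol-directory layout). All masks must share one grid; an all-zero
#' seed or a seed listed as an exclusion is rejected.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` protocol file.
#' @return a validated [protocol()].
#' @export
load_protocol <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(spec), protocol_keys)
  if (length(unknown)) stop("unknown protocol keys: ", paste(unknown, collapse = ", "))
  if (is.null(spec$name) || is.null(spec$seed)) stop("protocol needs name and seed")
  dir <- dirname(path)
  load_mask <- function(p) {
    vol <- read_volume(if (file.exists(p)) p else file.path(dir, p))
    binary_mask(vol$grid, vol$values > 0)
  }
  protocol(name = spec$name,
           seed = load_mask(spec$seed),
           targets = lapply(spec$targets, load_mask),
           stop = if (!is.null(spec$stop)) load_mask(spec$stop),
           exclusions = lapply(spec$exclusions, load_mask),
           symmetric = isTRUE(spec$symmetric),
           laterality = if (is.null(spec$laterality)) "unilateral" else spec$laterality)
}

#' Protocol manifest
#'
#' A roster of protocol names with lateralities, plus a free-text space
#' label. Names must be unique.
#'
#' @param entries data frame with columns `name` and `laterality`
#'   (`"bilateral"`, `"commissural"` or `"unilateral"`).
#' @param space free-text space label (e.g. `"phantom"`, `"MNI152"`).
#' @return object of class `protocol_manifest`.
#' @export
protocol_manifest <- function(entries, space = "phantom") {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (nrow(entries)) {
    stopifnot(all(c("name", "laterality") %in% names(entries)))
    if (anyDuplicated(entries$name)) stop("duplicate protocol names in manifest")
    bad <- setdiff(entries$laterality, c("bilateral", "commissural", "unilateral"))
    if (length(bad)) stop("unknown laterality: ", paste(bad, collapse = ", "))
  }
  structure(list(entries = entries, space = space), class = "protocol_manifest")
}

#' Load a manifest from YAML
#'
#' @param path YAML file with keys `space` and `protocols` (list of
#'   `{name, laterality}` records). The packaged subcortical roster lives at
#'   `system.file("extdata", "subcortical_manifest.yaml", package = "subtract")`.
#' @return a [protocol_manifest()].
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  entries <- do.call(rbind, lapply(y$protocols, function(e)
    data.frame(name = e$name, laterality = e$laterality,
               stringsAsFactors = FALSE)))
  protocol_manifest(entries, space = if (is.null(y$space)) "phantom" else y$space)
}

#' Expand a manifest into tract instances
#'
#' Bilateral entries yield one left and one right instance (suffixes `_L`
#' and `_R`); commissural and unilateral entries yield one instance each.
#' Expansion is deterministic and order-preserving, so the returned count is
#' `2 * n_bilateral + n_commissural + n_unilateral`.
#'
#' @param manifest a [protocol_manifest()].
#' @return data frame of tract instances with columns `instance`, `name`,
#'   `laterality` and `hemisphere` (`"L"`, `"R"` or `NA`).
#' @export
expand_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "protocol_manifest"))
  e <- manifest$entries
  if (!nrow(e))
    return(data.frame(instance = character(), name = character(),
                      laterality = character(), hemisphere = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(e)), function(i) {
    if (e$laterality[i] == "bilateral") {
      data.frame(instance = paste0(e$name[i], c("_L", "_R")),
                 name = e$name[i], laterality = e$laterality[i],
                 hemisphere = c("L", "R"), stringsAsFactors = FALSE)
    } else {
      data.frame(instance = e$name[i], name = e$name[i],
                 laterality = e$laterality[i], hemisphere = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$instance)) stop("duplicate names after expansion")
  rownames(out) <- NULL
  out
}
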