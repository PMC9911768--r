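#' Biventricular surface mesh for one subject at one cardiac phase
#'
#' A `bv_surface` is a labelled, triangulated point set with vertex-level
#' point correspondence across a cohort. It carries the LV endocardium, RV
#' endocardium and epicardium as labelled sub-surfaces, the four valve
#' annulus rings as ordered open boundary cycles, a vertex-level LV/RV wall
#' assignment used to partition myocardial mass, and (for meshes produced by
#' [generate_template()]) the structured ring-by-meridian grid indexing that
#' the arc-length strain measures rely on.
#'
#' @param subject_id character scalar.
#' @param phase `"ED"` or `"ES"`.
#' @param vertices numeric N x 3 matrix of coordinates in mm.
#' @param triangles integer T x 3 matrix of 1-based vertex indices,
#'   consistently oriented with outward-facing normals.
#' @param surface_label character vector of length N with values
#'   `"LV_ENDO"`, `"RV_ENDO"` or `"EPI"`.
#' @param wall_assignment integer vector of length N; `1` for vertices of
#'   the LV wall (septum included), `2` for the RV free wall.
#' @param annuli named list with elements `mitral`, `tricuspid`, `aortic`,
#'   `pulmonary`, each an ordered integer vector of vertex indices forming
#'   an open boundary ring (first vertex not repeated).
#' @param component optional character vector of length N refining
#'   `surface_label` into connected components (`"LV_ENDO"`, `"RV_ENDO"`,
#'   `"EPI_LV"`, `"EPI_RV"`).
#' @param grid optional named list of structured-grid metadata per
#'   component (see [generate_template()]).
#' @param validate logical; run [validate_bv_surface()] on construction.
#'
#' @return An object of class `bv_surface`.
#' @seealso [generate_template()], [read_vtk_surface()], [compute_imaging_indices()]
#' @export
bv_surface <- function(subject_id, phase, vertices, triangles, surface_label,
                       wall_assignment, annuli, component = NULL, grid = NULL,
                       validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (is.null(component)) component <- surface_label
  obj <- structure(list(
    subject_id = as.character(subject_id),
    phase = match.arg(phase, c("ED", "ES")),
    vertices = vertices,
    triangles = triangles,
    surface_label = as.character(surface_label),
    wall_assignment = as.integer(wall_assignment),
    annuli = annuli,
    component = as.character(component),
    grid = grid
  ), class = "bv_surface")
  if (validate) validate_bv_surface(obj)
  obj
}

VALVE_NAMES <- c("mitral", "tricuspid", "aortic", "pulmonary")
SURFACE_LABELS <- c("LV_ENDO", "RV_ENDO", "EPI")

#' Validate the structural invariants of a biventricular surface
#'
#' Checks vertex/label/triangle consistency, that surface labels partition
#' the vertex set, that coordinates are finite, and that each valve annulus
#' ring is a closed cycle of boundary edges (edges used by exactly one
#' triangle).
#'
#' @param x a [bv_surface()].
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_bv_surface <- function(x) {
  n <- nrow(x$vertices)
  if (ncol(x$vertices) != 3L) stop_bv("vertices must be an N x 3 matrix")
  if (!all(is.finite(x$vertices))) stop_bv("vertex coordinates must be finite")
  if (length(x$surface_label) != n || length(x$wall_assignment) != n)
    stop_bv("surface_label and wall_assignment must have one entry per vertex")
  if (!all(x$surface_label %in% SURFACE_LABELS))
    stop_bv("surface_label values must be one of ",
            paste(SURFACE_LABELS, collapse = ", "))
  if (!all(x$wall_assignment %in% c(1L, 2L)))
    stop_bv("wall_assignment must be 1 (LV) or 2 (RV)")
  tr <- x$triangles
  if (ncol(tr) != 3L) stop_bv("triangles must be a T x 3 matrix")
  if (any(tr < 1L) || any(tr > n)) stop_bv("triangle indexes a missing vertex")
  if (!is.list(x$annuli) || !all(VALVE_NAMES %in% names(x$annuli)))
    stop_bv("annuli must name all four valves: ",
            paste(VALVE_NAMES, collapse = ", "))
  bnd <- boundary_edge_set(tr)
  for (v in VALVE_NAMES) {
    ring <- x$annuli[[v]]
    if (length(ring) < 3L) stop_bv("annulus ring '", v, "' has fewer than 3 vertices")
    e <- cbind(ring, c(ring[-1L], ring[1L]))
    keys <- edge_key(e[, 1L], e[, 2L])
    if (!all(keys %in% bnd))
      stop_bv("annulus ring '", v, "' contains a non-boundary edge")
  }
  invisible(x)
}

# Canonical undirected numeric edge key (vertex indices fit well below 2^26)
edge_key <- function(a, b) pmin(a, b) * 67108864 + pmax(a, b)

# counts of each value in `keys` aligned with `keys` (fast numeric table)
key_counts <- function(keys) {
  ord <- order(keys)
  r <- rle(keys[ord])
  cnt <- integer(length(keys))
  cnt[ord] <- rep.int(r$lengths, r$lengths)
  cnt
}

# Keys of edges used by exactly one triangle
boundary_edge_set <- function(triangles) {
  e <- rbind(triangles[, c(1L, 2L)], triangles[, c(2L, 3L)], triangles[, c(3L, 1L)])
  keys <- edge_key(e[, 1L], e[, 2L])
  keys[key_counts(keys) == 1L]
}

#' Extract a labelled sub-surface with reindexed triangles
#'
#' @param x a [bv_surface()].
#' @param label either a surface label (`"LV_ENDO"`, `"RV_ENDO"`, `"EPI"`)
#'   or a component name (`"EPI_LV"`, `"EPI_RV"`).
#' @return list with `vertices`, `triangles` (reindexed), and `map`, the
#'   original vertex index of each retained vertex.
#' @export
sub_surface <- function(x, label) {
  keep <- if (label %in% SURFACE_LABELS) x$surface_label == label
          else x$component == label
  if (!any(keep)) stop_bv("no vertices carry label '", label, "'")
  idx <- which(keep)
  tri_keep <- matrix(x$triangles %in% idx, ncol = 3L)
  tri <- x$triangles[rowSums(tri_keep) == 3L, , drop = FALSE]
  remap <- integer(nrow(x$vertices))
  remap[idx] <- seq_along(idx)
  list(vertices = x$vertices[idx, , drop = FALSE],
       triangles = matrix(remap[tri], ncol = 3L),
       map = idx)
}

#' @export
print.bv_surface <- function(x, ...) {
  cat("Biventricular surface mesh\n")
  cat("  subject:", x$subject_id, " phase:", x$phase, "\n")
  cat("  vertices:", nrow(x$vertices), " triangles:", nrow(x$triangles), "\n")
  tab <- table(x$surface_label)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  annuli:", paste(sprintf("%s(%d)", names(x$annuli),
                                 lengths(x$annuli)), collapse = ", "), "\n")
  invisible(x)
}

#' Apply a rigid transform to a surface
#'
#' @param x a [bv_surface()].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation (mm).
#' @return the transformed surface.
#' @export
transform_surface <- function(x, rotation = diag(3), translation = c(0, 0, 0)) {
  x$vertices <- apply_rigid(x$vertices, rotation, translation)
  x
}
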