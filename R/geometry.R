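#' Close a labelled sub-surface by capping its boundary rings
#'
#' Extracts the requested sub-surface and caps every closed boundary cycle
#' with a triangle fan to the cycle centroid, producing a closed,
#' consistently oriented 2-manifold on which [enclosed_volume()] is
#' well-defined. For the surfaces produced by [generate_template()] the
#' boundary cycles are the valve annulus rings (endocardium) and the basal
#' truncation rings (epicardium); the caps over the planar basal openings
#' are flat, so capped cavity volumes agree with the generator's
#' closed-form truncated-ellipsoid volumes up to lateral-surface
#' discretization.
#'
#' @param x a [bv_surface()], or a list with `vertices` and `triangles`.
#' @param label surface label or component name passed to [sub_surface()];
#'   ignored when `x` is a plain mesh list.
#' @return list with `vertices` and `triangles` of the closed surface and
#'   `n_caps`, the number of boundary cycles that were capped (0 when the
#'   input was already closed, which returns the mesh unchanged).
#' @export
close_surface <- function(x, label = NULL) {
  mesh <- if (inherits(x, "bv_surface")) {
    if (is.null(label)) stop_bv("a surface label is required for a bv_surface")
    sub_surface(x, label)
  } else {
    list(vertices = as.matrix(x$vertices), triangles = as.matrix(x$triangles))
  }
  cycles <- boundary_cycles(mesh$triangles)
  if (length(cycles) == 0L)
    return(list(vertices = mesh$vertices, triangles = mesh$triangles, n_caps = 0L))
  v <- mesh$vertices
  tri <- mesh$triangles
  for (cyc in cycles) {
    centroid <- colMeans(v[cyc, , drop = FALSE])
    cidx <- nrow(v) + 1L
    v <- rbind(v, centroid)
    # boundary directed edges run a -> b; caps traverse b -> a for a
    # consistent orientation with the open surface
    a <- cyc
    b <- c(cyc[-1L], cyc[1L])
    tri <- rbind(tri, cbind(b, a, cidx))
  }
  dimnames(tri) <- NULL
  list(vertices = v, triangles = tri, n_caps = length(cycles))
}

# Directed boundary edges chained into closed cycles; topology errors name
# the offending edges.
boundary_cycles <- function(triangles) {
  dir_e <- rbind(triangles[, c(1L, 2L)], triangles[, c(2L, 3L)],
                 triangles[, c(3L, 1L)])
  keys <- edge_key(dir_e[, 1L], dir_e[, 2L])
  cnt <- key_counts(keys)
  if (any(cnt > 2L)) {
    bad <- dir_e[cnt > 2L, , drop = FALSE]
    stop_bv("non-manifold edges (used by >2 triangles): ",
            paste(unique(paste(pmin(bad[, 1L], bad[, 2L]),
                               pmax(bad[, 1L], bad[, 2L]), sep = "-")),
                  collapse = "; "))
  }
  bd <- dir_e[cnt == 1L, , drop = FALSE]
  if (nrow(bd) == 0L) return(list())
  # orientation-consistency: a directed boundary edge must be unique
  dk <- bd[, 1L] * 67108864 + bd[, 2L]
  if (anyDuplicated(dk))
    stop_bv("inconsistently oriented boundary edges: ",
            paste(paste(bd[duplicated(dk), 1L], bd[duplicated(dk), 2L],
                        sep = "->"), collapse = "; "))
  nxt <- bd[, 2L]
  names(nxt) <- as.character(bd[, 1L])
  outdeg <- table(bd[, 1L])
  indeg <- table(bd[, 2L])
  if (any(outdeg > 1L) || any(indeg > 1L) ||
      !setequal(names(outdeg), names(indeg))) {
    dangling <- union(names(outdeg)[!(names(outdeg) %in% names(indeg))],
                      names(indeg)[!(names(indeg) %in% names(outdeg))])
    stop_bv("boundary is not a union of rings (open seam near vertices ",
            paste(c(dangling, names(outdeg)[outdeg > 1L]), collapse = ", "), ")")
  }
  cycles <- list()
  remaining <- bd[, 1L]
  visited <- logical(0)
  seen <- rep(FALSE, length(nxt))
  names(seen) <- names(nxt)
  for (start in as.character(remaining)) {
    if (seen[[start]]) next
    cyc <- integer(0)
    cur <- start
    repeat {
      seen[[cur]] <- TRUE
      cyc <- c(cyc, as.integer(cur))
      cur <- as.character(nxt[[cur]])
      if (cur == start) break
      if (seen[[cur]])
        stop_bv("boundary walk failed to close (open seam near vertex ", cur, ")")
    }
    cycles[[length(cycles) + 1L]] <- cyc
  }
  cycles
}

#' Enclosed volume of a closed triangulated surface
#'
#' Numerical integration of the mesh volume: the sum of signed tetrahedron
#' volumes of each triangle against the origin (divergence theorem), taken
#' in absolute value. Translation- and rotation-invariant; coordinates are
#' in mm and the result in mL.
#'
#' @param x closed mesh: a list with `vertices` (N x 3, mm) and
#'   `triangles`, e.g. the result of [close_surface()].
#' @param check logical; verify the surface is closed and consistently
#'   oriented (every directed edge used exactly once) before integrating.
#' @return volume in mL.
#' @export
enclosed_volume <- function(x, check = TRUE) {
  v <- as.matrix(x$vertices)
  tri <- as.matrix(x$triangles)
  if (check) {
    dir_e <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
    keys <- edge_key(dir_e[, 1L], dir_e[, 2L])
    cnt <- key_counts(keys)
    if (any(cnt != 2L))
      stop_bv("surface is not closed: ", sum(cnt != 2L) %/% 2L + sum(cnt != 2L) %% 2L,
              " edge(s) not shared by exactly 2 triangles")
    dk <- dir_e[, 1L] * 67108864 + dir_e[, 2L]
    if (anyDuplicated(dk))
      stop_bv("surface is not consistently oriented")
  }
  a <- v[tri[, 1L], , drop = FALSE]
  b <- v[tri[, 2L], , drop = FALSE]
  cc <- v[tri[, 3L], , drop = FALSE]
  signed <- a[, 1L] * (b[, 2L] * cc[, 3L] - b[, 3L] * cc[, 2L]) -
    a[, 2L] * (b[, 1L] * cc[, 3L] - b[, 3L] * cc[, 1L]) +
    a[, 3L] * (b[, 1L] * cc[, 2L] - b[, 2L] * cc[, 1L])
  abs(sum(signed) / 6) / 1000
}

#' Cavity and epicardial volumes of a biventricular surface
#'
#' Each labelled sub-surface is closed with [close_surface()] and measured
#' with [enclosed_volume()]. The epicardial volume is the sum over the two
#' epicardial shells (LV wall including septum, RV free wall).
#'
#' @param x a [bv_surface()].
#' @return list with `lv`, `rv` (cavity volumes, mL) and `epi` (total
#'   volume enclosed by the epicardium, mL).
#' @export
compute_cavity_volumes <- function(x) {
  list(lv = enclosed_volume(close_surface(x, "LV_ENDO")),
       rv = enclosed_volume(close_surface(x, "RV_ENDO")),
       epi = enclosed_volume(close_surface(x, "EPI_LV")) +
         enclosed_volume(close_surface(x, "EPI_RV")))
}

#' Ventricular wall masses from a biventricular surface
#'
#' The wall volume of each ventricle is the volume between its epicardial
#' shell and its cavity, partitioned by the vertex-level `wall_assignment`
#' (the septum belongs to the LV wall). Mass is wall volume times the
#' myocardial density.
#'
#' @param x a [bv_surface()] (conventionally the ED surface).
#' @param density myocardial density in g/mL; 1.05 is the standard value
#'   in the CMR literature.
#' @param on_zero_thickness `"error"` to reject walls of non-positive
#'   volume, `"zero"` to clamp them to 0 g (degenerate meshes).
#' @return list with `lv_mass`, `rv_mass` (g) and `lv_wall_volume`,
#'   `rv_wall_volume` (mL).
#' @export
compute_masses <- function(x, density = 1.05,
                           on_zero_thickness = c("error", "zero")) {
  on_zero_thickness <- match.arg(on_zero_thickness)
  lv_wall <- enclosed_volume(close_surface(x, "EPI_LV")) -
    enclosed_volume(close_surface(x, "LV_ENDO"))
  rv_wall <- enclosed_volume(close_surface(x, "EPI_RV")) -
    enclosed_volume(close_surface(x, "RV_ENDO"))
  tol <- 1e-9
  for (w in c(lv = lv_wall, rv = rv_wall)) {
    if (w < -tol && on_zero_thickness == "error")
      stop_bv("negative wall volume (", format(w), " mL): malformed mesh")
  }
  if (on_zero_thickness == "error" && (lv_wall <= tol || rv_wall <= tol))
    stop_bv("zero-thickness wall: epicardium coincides with endocardium")
  lv_wall <- max(lv_wall, 0)
  rv_wall <- max(rv_wall, 0)
  list(lv_mass = lv_wall * density, rv_mass = rv_wall * density,
       lv_wall_volume = lv_wall, rv_wall_volume = rv_wall)
}

#' Ejection fraction
#'
#' @param edv end-diastolic volume (mL), must be positive.
#' @param esv end-systolic volume (mL). A value above `edv` yields a
#'   negative EF with a warning rather than an error.
#' @return EF in percent: `100 * (edv - esv) / edv`.
#' @export
ejection_fraction <- function(edv, esv) {
  if (!is_number(edv) || edv <= 0) stop_bv("edv must be a positive number")
  if (!is_number(esv)) stop_bv("esv must be a number")
  if (esv > edv) warning("esv exceeds edv: negative ejection fraction")
  100 * (edv - esv) / edv
}

#' Index a measurement to body surface area
#'
#' @param value measurement (mL or g).
#' @param bsa body surface area in m^2, must be positive.
#' @return `value / bsa`.
#' @export
index_to_bsa <- function(value, bsa) {
  if (!is_number(bsa) || bsa <= 0) stop_bv("bsa must be a positive number")
  value / bsa
}

#' The ten standard imaging indices for one subject
#'
#' Computes BSA-indexed end-diastolic and end-systolic cavity volumes,
#' ejection fractions and ED mass indices for both ventricles by numerical
#' integration of mesh volumes, and carries over the pulmonary
#' regurgitation measures (PRVi, PRF) from the subject record. The ten
#' fields deliberately match the size of the shape-mode feature set.
#'
#' @param ed,es [bv_surface()] pair for the same subject at ED and ES.
#' @param record one row of a subject table (list or data.frame row) with
#'   at least `subject_id`, `bsa`, `prvi`, `prf`.
#' @param density myocardial density (g/mL) for the mass indices.
#' @return named list of class `imaging_indices` with fields `lv_edvi`,
#'   `lv_esvi`, `rv_edvi`, `rv_esvi` (mL/m^2), `lv_ef`, `rv_ef` (%),
#'   `lv_mi`, `rv_mi` (g/m^2), `prvi` (mL/m^2), `prf` (%).
#' @export
compute_imaging_indices <- function(ed, es, record, density = 1.05) {
  record <- as.list(record)
  if (!identical(ed$subject_id, es$subject_id) ||
      !identical(ed$subject_id, as.character(record$subject_id)))
    stop_bv("subject_id mismatch between ED surface (", ed$subject_id,
            "), ES surface (", es$subject_id, ") and record (",
            record$subject_id, ")")
  if (ed$phase != "ED" || es$phase != "ES")
    stop_bv("surfaces must be an (ED, ES) pair")
  bsa <- record$bsa
  ved <- compute_cavity_volumes(ed)
  ves <- compute_cavity_volumes(es)
  m <- compute_masses(ed, density = density)
  out <- list(
    lv_edvi = index_to_bsa(ved$lv, bsa),
    lv_esvi = index_to_bsa(ves$lv, bsa),
    rv_edvi = index_to_bsa(ved$rv, bsa),
    rv_esvi = index_to_bsa(ves$rv, bsa),
    lv_ef = ejection_fraction(ved$lv, ves$lv),
    rv_ef = ejection_fraction(ved$rv, ves$rv),
    lv_mi = index_to_bsa(m$lv_mass, bsa),
    rv_mi = index_to_bsa(m$rv_mass, bsa),
    prvi = as.numeric(record$prvi),
    prf = as.numeric(record$prf)
  )
  structure(out, class = "imaging_indices", subject_id = ed$subject_id)
}

#' @export
print.imaging_indices <- function(x, digits = 1, ...) {
  cat("Imaging indices for subject", attr(x, "subject_id"), "\n")
  print(round(unlist(x), digits))
  invisible(x)
}
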