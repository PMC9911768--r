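# Geometric systolic strain from paired ED/ES surfaces.
#
# Longitudinal and circumferential strains are Cauchy strains of the
# arc lengths of structured parameter lines on the endocardium; radial
# strain uses a centerline method on short-axis slice intersections: wall
# thickness is measured along chords normal to the mid-curve between the
# endocardial and epicardial slice contours.

#' Cauchy strain from a length change
#'
#' `100 * (length_es - length_ed) / length_ed` (%); negative for
#' shortening, positive for lengthening/thickening. Vectorized.
#'
#' @param length_ed reference (ED) lengths, must be positive.
#' @param length_es deformed (ES) lengths.
#' @return strain in percent.
#' @export
cauchy_strain <- function(length_ed, length_es) {
  if (any(!is.finite(length_ed)) || any(length_ed <= 0))
    stop_bv("ED lengths must be positive and finite")
  100 * (length_es - length_ed) / length_ed
}

#' Structured parameter lines of a ventricle
#'
#' Longitudinal lines run from the apex to the basal ring along each
#' meridian of the generator's structured grid; circumferential lines are
#' the closed vertex rings at each longitudinal level. LV lines cover the
#' whole LV endocardium (the septal wall is included in LV strain).
#'
#' @param surface a [bv_surface()] carrying grid metadata (see
#'   [generate_template()]).
#' @param direction `"LONGITUDINAL"` or `"CIRCUMFERENTIAL"`.
#' @param ventricle `"LV"` or `"RV"`.
#' @return list of integer vertex-index polylines; circumferential lines
#'   are closed (first index repeated at the end).
#' @export
sample_parameter_lines <- function(surface,
                                   direction = c("LONGITUDINAL",
                                                 "CIRCUMFERENTIAL"),
                                   ventricle = c("LV", "RV")) {
  direction <- match.arg(direction)
  ventricle <- match.arg(ventricle)
  comp <- paste0(ventricle, "_ENDO")
  g <- surface$grid[[comp]]
  if (is.null(g))
    stop_bv("surface carries no structured grid for ", comp,
            "; only slice-based radial strain is available for ",
            "unstructured meshes")
  rings <- g$rings
  if (direction == "LONGITUDINAL") {
    lapply(seq_len(ncol(rings)), function(gg) c(g$apex, rings[, gg]))
  } else {
    lapply(seq_len(nrow(rings)), function(j) c(rings[j, ], rings[j, 1L]))
  }
}

#' Directional (longitudinal/circumferential) systolic strain
#'
#' Arc length of every parameter line at ED and ES, Cauchy strain per
#' line, unweighted mean across lines.
#'
#' @param ed,es corresponded [bv_surface()] pair.
#' @inheritParams sample_parameter_lines
#' @return mean strain (%) with attribute `per_line` holding the
#'   individual line strains.
#' @export
directional_strain <- function(ed, es, direction, ventricle) {
  lines <- sample_parameter_lines(ed, direction, ventricle)
  per_line <- vapply(lines, function(idx) {
    cauchy_strain(polyline_length(ed$vertices[idx, , drop = FALSE]),
                  polyline_length(es$vertices[idx, , drop = FALSE]))
  }, numeric(1L))
  structure(mean(per_line), per_line = per_line)
}

# ---- slice geometry ------------------------------------------------------

# LV long axis (apex -> basal-opening centroid) plus an in-plane reference
# direction derived from the LV-to-RV offset; both rotate with the mesh,
# so strains are invariant to a common rigid transform of ED and ES.
lv_axis_frame <- function(surface) {
  v <- surface$vertices
  apex <- v[surface$grid$LV_ENDO$apex, ]
  base_ctr <- colMeans(v[c(surface$annuli$mitral, surface$annuli$aortic), ,
                         drop = FALSE])
  dir <- base_ctr - apex
  dir <- dir / sqrt(sum(dir^2))
  rv_apex <- v[surface$grid$RV_ENDO$apex, ]
  ref <- rv_apex - apex
  ref <- ref - sum(ref * dir) * dir
  nr <- sqrt(sum(ref^2))
  if (nr < 1e-9) {                      # degenerate: fall back to any normal
    ref <- c(dir[2L] - dir[3L], dir[3L] - dir[1L], dir[1L] - dir[2L])
    ref <- ref - sum(ref * dir) * dir
    nr <- sqrt(sum(ref^2))
  }
  e1 <- ref / nr
  e2 <- c(dir[2L] * e1[3L] - dir[3L] * e1[2L],
          dir[3L] * e1[1L] - dir[1L] * e1[3L],
          dir[1L] * e1[2L] - dir[2L] * e1[1L])
  list(apex = apex, dir = dir, e1 = e1, e2 = e2)
}

# Closed intersection contour of a sub-surface with a plane, chained from
# triangle-edge crossings; NULL when the plane misses the surface or the
# section is not a single closed loop.
plane_section <- function(vertices, triangles, origin, normal) {
  d <- as.numeric((vertices - matrix(origin, nrow(vertices), 3L,
                                     byrow = TRUE)) %*% normal)
  d[abs(d) < 1e-9] <- 1e-9
  s1 <- d[triangles[, 1L]]; s2 <- d[triangles[, 2L]]; s3 <- d[triangles[, 3L]]
  crossing <- which(pmin(s1, s2, s3) < 0 & pmax(s1, s2, s3) > 0)
  if (length(crossing) < 3L) return(NULL)
  edge_pts <- new.env(hash = TRUE)
  tri_edges <- vector("list", length(crossing))
  for (ii in seq_along(crossing)) {
    tri <- triangles[crossing[ii], ]
    keys <- character(0)
    for (e in list(c(1L, 2L), c(2L, 3L), c(3L, 1L))) {
      a <- tri[e[1L]]; b <- tri[e[2L]]
      if (sign(d[a]) == sign(d[b])) next
      key <- if (a < b) paste0(a, ":", b) else paste0(b, ":", a)
      keys <- c(keys, key)
      if (is.null(edge_pts[[key]])) {
        t0 <- d[a] / (d[a] - d[b])
        edge_pts[[key]] <- vertices[a, ] + t0 * (vertices[b, ] - vertices[a, ])
      }
    }
    if (length(keys) != 2L) return(NULL)
    tri_edges[[ii]] <- keys
  }
  # adjacency: edge key -> indices of crossing triangles using it
  adj <- new.env(hash = TRUE)
  for (ii in seq_along(tri_edges)) {
    for (key in tri_edges[[ii]]) adj[[key]] <- c(adj[[key]], ii)
  }
  start_tri <- 1L
  start_key <- tri_edges[[1L]][1L]
  path <- character(length(crossing) + 1L)
  path[1L] <- start_key
  cur_tri <- start_tri
  cur_key <- start_key
  np <- 1L
  repeat {
    nxt_key <- setdiff(tri_edges[[cur_tri]], cur_key)
    if (length(nxt_key) != 1L) return(NULL)
    if (nxt_key == start_key) break
    np <- np + 1L
    if (np > length(crossing)) return(NULL)
    path[np] <- nxt_key
    nbr <- setdiff(adj[[nxt_key]], cur_tri)
    if (length(nbr) != 1L) return(NULL)   # open section or non-manifold
    cur_tri <- nbr
    cur_key <- nxt_key
  }
  if (np < 3L) return(NULL)
  t(vapply(path[seq_len(np)], function(k) edge_pts[[k]], numeric(3L)))
}

# Crossing offsets of the ray p0 + s * dir with a closed 2D polygon
polygon_ray_crossings <- function(px, py, p0, dir) {
  n <- length(px)
  jn <- c(seq_len(n)[-1L], 1L)
  ax <- px - p0[1L]; ay <- py - p0[2L]
  bx <- px[jn] - p0[1L]; by <- py[jn] - p0[2L]
  # solve p0 + s*dir = a + t*(b - a), 0 <= t < 1
  ex <- bx - ax; ey <- by - ay
  den <- dir[1L] * (-ey) - dir[2L] * (-ex)
  ok <- abs(den) > 1e-12
  t_num <- dir[1L] * ay - dir[2L] * ax
  s_num <- ax * (-ey) - ay * (-ex)
  tt <- ifelse(ok, t_num / den, NA_real_)
  ss <- ifelse(ok, s_num / den, NA_real_)
  ss[!ok | tt < 0 | tt >= 1] <- NA_real_
  ss[!is.na(ss)]
}

# Project a 3D contour into the in-plane (e1, e2) frame
contour_2d <- function(pts, frame, origin) {
  rel <- pts - matrix(origin, nrow(pts), 3L, byrow = TRUE)
  cbind(as.numeric(rel %*% frame$e1), as.numeric(rel %*% frame$e2))
}

# Wall-thickness profile of one ventricle in one slice plane. Stations are
# paired by angle about the shared contour centroid; the centerline is the
# mid-curve of the endo/epi radial crossings along each station ray, and
# thickness is measured along chords normal to that centerline. Chord
# crossings far outside the local wall (which arise when a noisy normal
# grazes the contour) are rejected as invalid stations. Returns NULL when
# the plane misses either surface.
slice_thickness <- function(surface, ventricle, frame, origin, n_stations) {
  endo <- sub_surface(surface, paste0(ventricle, "_ENDO"))
  epi <- sub_surface(surface, paste0("EPI_", ventricle))
  c_endo <- plane_section(endo$vertices, endo$triangles, origin, frame$dir)
  c_epi <- plane_section(epi$vertices, epi$triangles, origin, frame$dir)
  if (is.null(c_endo) || is.null(c_epi)) return(NULL)
  p_en <- contour_2d(c_endo, frame, origin)
  p_ep <- contour_2d(c_epi, frame, origin)
  ctr <- (colMeans(p_en) + colMeans(p_ep)) / 2
  # half-step offset keeps rays off mesh symmetry planes, where they
  # would pass exactly through contour vertices
  theta <- 2 * pi * (seq_len(n_stations) - 0.5) / n_stations
  r_en <- rep(NA_real_, n_stations); r_ep <- rep(NA_real_, n_stations)
  for (k in seq_len(n_stations)) {
    dirk <- c(cos(theta[k]), sin(theta[k]))
    s1 <- polygon_ray_crossings(p_en[, 1L], p_en[, 2L], ctr, dirk)
    s2 <- polygon_ray_crossings(p_ep[, 1L], p_ep[, 2L], ctr, dirk)
    s1 <- s1[s1 > 0]; s2 <- s2[s2 > 0]
    if (length(s1) > 0L) r_en[k] <- min(s1)
    if (length(s2) > 0L) r_ep[k] <- max(min(s2), r_en[k])
  }
  if (sum(!is.na(r_en) & !is.na(r_ep)) < 3L) return(NULL)
  mx <- ctr[1L] + (r_en + r_ep) / 2 * cos(theta)
  my <- ctr[2L] + (r_en + r_ep) / 2 * sin(theta)
  n <- n_stations
  jp <- c(2:n, 1L); jm <- c(n, 1:(n - 1L))
  tx <- mx[jp] - mx[jm]; ty <- my[jp] - my[jm]
  tl <- sqrt(tx^2 + ty^2)
  nx <- -ty / tl; ny <- tx / tl
  thick <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    if (is.na(mx[k]) || is.na(nx[k])) next
    t_rad <- r_ep[k] - r_en[k]
    cap <- 3 * t_rad + 2          # admissible chord half-range (mm)
    p0 <- c(mx[k], my[k]); dirk <- c(nx[k], ny[k])
    s_en <- polygon_ray_crossings(p_en[, 1L], p_en[, 2L], p0, dirk)
    s_ep <- polygon_ray_crossings(p_ep[, 1L], p_ep[, 2L], p0, dirk)
    if (length(s_en) == 0L || length(s_ep) == 0L) next
    se <- s_en[which.min(abs(s_en))]
    sp <- s_ep[which.min(abs(s_ep))]
    # a chord far outside the local radial wall means the normal grazed
    # the contour; reject the station rather than record a bogus chord
    if (abs(se) > cap || abs(sp) > cap) next
    thick[k] <- abs(sp - se)
  }
  thick
}

#' Radial systolic strain by the centerline method
#'
#' Intersects the endocardial and epicardial surfaces of a ventricle with
#' a stack of short-axis planes (normal to the LV long axis, at fixed
#' fractions of the ventricle's apex-base extent in each phase), builds
#' the mid-curve between the two contours, measures wall thickness along
#' chords normal to that centerline at equally spaced stations, and
#' averages the per-station Cauchy strains of thickness over stations and
#' slices.
#'
#' @param ed,es corresponded [bv_surface()] pair.
#' @param ventricle `"LV"` or `"RV"`.
#' @param n_slices number of short-axis planes.
#' @param frac_range apex-base fractions spanned by the stack.
#' @param n_stations centerline stations per slice.
#' @param min_slices minimum number of valid slices required.
#' @param frame_ed,frame_es optional explicit slice-stack frames (lists
#'   with `apex`, `dir`, `e1`, `e2`), overriding the LV-long-axis frame
#'   derived from the mesh; used for phantom geometries.
#' @return mean radial strain (%) with attribute `per_slice`; slices the
#'   planes miss are skipped and recorded in attribute `skipped`.
#' @export
radial_strain_centerline <- function(ed, es, ventricle = c("LV", "RV"),
                                     n_slices = 8L,
                                     frac_range = c(0.1, 0.9),
                                     n_stations = 100L, min_slices = 4L,
                                     frame_ed = NULL, frame_es = NULL) {
  ventricle <- match.arg(ventricle)
  fr_ed <- frame_ed %||% lv_axis_frame(ed)
  fr_es <- frame_es %||% lv_axis_frame(es)
  extent <- function(surface, fr) {
    vv <- sub_surface(surface, paste0(ventricle, "_ENDO"))$vertices
    tt <- as.numeric((vv - matrix(fr$apex, nrow(vv), 3L, byrow = TRUE)) %*% fr$dir)
    range(tt)
  }
  rng_ed <- extent(ed, fr_ed)
  rng_es <- extent(es, fr_es)
  fracs <- seq(frac_range[1L], frac_range[2L], length.out = n_slices)
  per_slice <- rep(NA_real_, n_slices)
  skipped <- integer(0)
  for (si in seq_len(n_slices)) {
    o_ed <- fr_ed$apex + (rng_ed[1L] + fracs[si] * diff(rng_ed)) * fr_ed$dir
    o_es <- fr_es$apex + (rng_es[1L] + fracs[si] * diff(rng_es)) * fr_es$dir
    th_ed <- slice_thickness(ed, ventricle, fr_ed, o_ed, n_stations)
    th_es <- slice_thickness(es, ventricle, fr_es, o_es, n_stations)
    if (is.null(th_ed) || is.null(th_es)) { skipped <- c(skipped, si); next }
    ok <- !is.na(th_ed) & !is.na(th_es) & th_ed > 0
    if (sum(ok) < n_stations / 2) { skipped <- c(skipped, si); next }
    per_slice[si] <- mean(cauchy_strain(th_ed[ok], th_es[ok]))
  }
  valid <- which(!is.na(per_slice))
  if (length(valid) < min_slices)
    stop_bv("only ", length(valid), " valid short-axis slices (need ",
            min_slices, ")")
  structure(mean(per_slice[valid]), per_slice = per_slice, skipped = skipped)
}

#' The six geometric systolic strains of an ED/ES surface pair
#'
#' Longitudinal and circumferential strains from arc-length changes of the
#' structured parameter lines, radial strain by the centerline method, for
#' both ventricles. The identity deformation gives six exact zeros;
#' contracting ventricles give negative LS/CS and positive RS.
#'
#' @inheritParams radial_strain_centerline
#' @param ... passed to [radial_strain_centerline()].
#' @return object of class `strain_result` with fields `lv_ls`, `rv_ls`,
#'   `lv_cs`, `rv_cs`, `lv_rs`, `rv_rs` (%), each carrying its per-line or
#'   per-slice diagnostics as attributes.
#' @export
compute_strains <- function(ed, es, ...) {
  if (!identical(ed$subject_id, es$subject_id))
    stop_bv("subject_id mismatch between ED and ES surfaces")
  out <- list(
    lv_ls = directional_strain(ed, es, "LONGITUDINAL", "LV"),
    rv_ls = directional_strain(ed, es, "LONGITUDINAL", "RV"),
    lv_cs = directional_strain(ed, es, "CIRCUMFERENTIAL", "LV"),
    rv_cs = directional_strain(ed, es, "CIRCUMFERENTIAL", "RV"),
    lv_rs = radial_strain_centerline(ed, es, "LV", ...),
    rv_rs = radial_strain_centerline(ed, es, "RV", ...)
  )
  structure(out, class = "strain_result", subject_id = ed$subject_id)
}

#' @export
print.strain_result <- function(x, ...) {
  cat("Systolic strains (%) for subject", attr(x, "subject_id"), "\n")
  v <- vapply(x, as.numeric, numeric(1L))
  print(round(v, 2))
  invisible(x)
}
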