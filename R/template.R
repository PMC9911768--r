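# Parametric biventricular template mesh.
#
# Each ventricle is a truncated prolate ellipsoid (endocardium) with an
# offset epicardial shell truncated at the same base plane; the RV pair is
# placed beside the LV pair. The basal opening of each endocardium is split
# into two disjoint valve annulus rings (mitral + aortic for the LV,
# tricuspid + pulmonary for the RV) by a flat two-row bridge strip lying in
# the base plane, so that capping the rings with centroid fans (see
# close_surface) reproduces the flat-base truncated ellipsoid exactly and
# cavity volumes have closed forms.

#' Volume of an ellipsoid truncated by the plane z = h
#'
#' Closed-form volume of the region of the ellipsoid
#' `x^2/a^2 + y^2/b^2 + z^2/c^2 <= 1` with `-c <= z <= h`.
#'
#' @param a,b,c semi-axes (mm).
#' @param h truncation height, `-c < h <= c`.
#' @return volume in the cube of the input unit (mm^3 for mm).
#' @export
truncated_ellipsoid_volume <- function(a, b, c, h) {
  stopifnot(h > -c, h <= c)
  pi * a * b * ((h + c) - (h^3 + c^3) / (3 * c^2))
}

# One truncated-ellipsoid grid component. Returns local vertices/triangles,
# the structured grid (apex index + rings matrix, ring 1 nearest the apex,
# ring n_rings on the base plane), and when split_base = TRUE the two hole
# rings of the basal opening ("pos" on the y > 0 side, "neg" on y < 0).
build_component <- function(center, a, b, c, h, n_rings, n_merid,
                            split_base = FALSE, n_bridge = 7L) {
  stopifnot(n_merid %% 2L == 0L, n_rings >= 2L)
  theta_b <- acos(-h / c)
  theta <- theta_b * seq_len(n_rings) / n_rings
  phi <- 2 * pi * (seq_len(n_merid) - 1L) / n_merid
  apex <- center + c(0, 0, -c)
  st <- sin(theta); ct <- cos(theta)
  v <- matrix(0, nrow = 1L + n_rings * n_merid, ncol = 3L)
  v[1L, ] <- apex
  rings <- matrix(0L, n_rings, n_merid)
  k <- 1L
  for (j in seq_len(n_rings)) {
    idx <- k + seq_len(n_merid)
    v[idx, ] <- cbind(center[1L] + a * st[j] * cos(phi),
                      center[2L] + b * st[j] * sin(phi),
                      center[3L] - c * ct[j])
    rings[j, ] <- idx
    k <- k + n_merid
  }
  nxt <- c(seq_len(n_merid)[-1L], 1L)
  tri <- matrix(0L, 0L, 3L)
  # apex fan; winding consistent with the quad strips below
  tri <- rbind(tri, cbind(1L, rings[1L, ], rings[1L, nxt]))
  # quad strips
  for (j in seq_len(n_rings - 1L)) {
    A <- rings[j, ]; B <- rings[j, nxt]
    C <- rings[j + 1L, nxt]; D <- rings[j + 1L, ]
    tri <- rbind(tri, cbind(A, C, B), cbind(A, D, C))
  }
  out <- list(vertices = v, triangles = tri,
              grid = list(apex = 1L, rings = rings, center = center,
                          axes = c(a = a, b = b, c = c), h = h,
                          base_z = center[3L] + h,
                          apex_z = center[3L] - c))
  if (!split_base) return(out)

  stopifnot(n_bridge >= 3L)
  bnd <- rings[n_rings, ]            # basal ring, phi = 0, d, 2d, ...
  m <- n_merid %/% 2L
  # bridge rows: row_pos from bnd[2] to bnd[m] (y > 0 side endpoints),
  # row_neg from bnd[n_merid] to bnd[m + 2]
  p1 <- v[bnd[2L], ]; p2 <- v[bnd[m], ]
  q1 <- v[bnd[n_merid], ]; q2 <- v[bnd[m + 2L], ]
  tseq <- seq(0, 1, length.out = n_bridge)
  row_pos_pts <- outer(1 - tseq, p1) + outer(tseq, p2)
  row_neg_pts <- outer(1 - tseq, q1) + outer(tseq, q2)
  nin <- n_bridge - 2L
  base_n <- nrow(v)
  v <- rbind(v, row_pos_pts[2:(n_bridge - 1L), , drop = FALSE],
             row_neg_pts[2:(n_bridge - 1L), , drop = FALSE])
  row_pos <- c(bnd[2L], base_n + seq_len(nin), bnd[m])
  row_neg <- c(bnd[n_merid], base_n + nin + seq_len(nin), bnd[m + 2L])
  # strip quads + end triangles; winding chosen to oppose the lateral
  # surface's use of the basal boundary edges it absorbs
  for (i in seq_len(n_bridge - 1L)) {
    P1 <- row_pos[i]; P2 <- row_pos[i + 1L]
    N1 <- row_neg[i]; N2 <- row_neg[i + 1L]
    tri <- rbind(tri, cbind(P1, N1, N2), cbind(P1, N2, P2))
  }
  tri <- rbind(tri, cbind(row_pos[1L], bnd[1L], row_neg[1L]),
               cbind(bnd[m + 1L], row_pos[n_bridge], row_neg[n_bridge]))
  # hole rings (ordered cycles, disjoint from each other)
  ring_pos <- c(bnd[2:m], rev(row_pos[2:(n_bridge - 1L)]))
  ring_neg <- c(bnd[(m + 2L):n_merid], row_neg[2:(n_bridge - 1L)])
  out$vertices <- v
  out$triangles <- tri
  out$hole_rings <- list(pos = ring_pos, neg = ring_neg)
  out$bridge <- list(row_pos = row_pos, row_neg = row_neg)
  out
}

# Solve the epicardial offset t so the wall volume (epi shell minus cavity)
# hits a target, with both surfaces truncated at the same base plane.
solve_wall_offset <- function(a, b, c, h, target_wall) {
  f <- function(t) {
    truncated_ellipsoid_volume(a + t, b + t, c + t, h) -
      truncated_ellipsoid_volume(a, b, c, h) - target_wall
  }
  stats::uniroot(f, c(1e-3, 40), tol = 1e-10)$root
}

#' Generate the synthetic biventricular template mesh
#'
#' Builds a corresponded, labelled biventricular surface: LV and RV
#' endocardia as truncated ellipsoids with their basal openings split into
#' two disjoint valve annulus rings each, plus one epicardial shell per
#' ventricle truncated at the same base plane (the septum is carried by the
#' LV shell, matching the wall-assignment convention). Cavity and wall
#' volumes have exact closed forms, which are returned in `meta` and used
#' as ground truth by the cohort generator. Dimensions are solved so that,
#' at the reference BSA, the template reproduces typical rTOF imaging-index
#' scales (RV EDVi well above LV EDVi, LV Mi near 75 g/m^2).
#'
#' @param resolution integer vector `c(rings, meridians)` per component;
#'   at least `c(8, 16)`, meridians even.
#' @param n_bridge number of points across each basal bridge strip (>= 3).
#' @param ref_bsa reference body surface area (m^2) at which the template's
#'   absolute volumes correspond to the target indexed volumes.
#' @param lv_edvi,rv_edvi target cavity volume indices (mL/m^2) at `ref_bsa`.
#' @param lv_mi,rv_mi target mass indices (g/m^2) at `ref_bsa`.
#' @param density myocardial density (g/mL) used to convert mass targets to
#'   wall-volume targets.
#' @return a [bv_surface()] (phase ED, subject `"template"`) whose `grid`
#'   holds the structured ring/meridian indexing and whose `meta` attribute
#'   holds the analytic volumes (mm^3) and construction parameters.
#' @export
generate_template <- function(resolution = c(14L, 28L), n_bridge = 7L,
                              ref_bsa = 1.55,
                              lv_edvi = 79, rv_edvi = 140,
                              lv_mi = 75, rv_mi = 42,
                              density = 1.05) {
  n_rings <- as.integer(resolution[1L])
  n_merid <- as.integer(resolution[2L])
  if (n_rings < 8L || n_merid < 16L)
    stop_bv("resolution too coarse: need at least 8 rings x 16 meridians")
  if (n_merid %% 2L != 0L) stop_bv("meridian count must be even")

  v_lv <- lv_edvi * ref_bsa * 1000          # mm^3
  v_rv <- rv_edvi * ref_bsa * 1000
  w_lv <- lv_mi / density * ref_bsa * 1000
  w_rv <- rv_mi / density * ref_bsa * 1000

  # LV: prolate, a = b, c = 2a, truncated at h = 0.42 c
  unit_lv <- truncated_ellipsoid_volume(1, 1, 2, 0.84)
  a_lv <- (v_lv / unit_lv)^(1 / 3)
  c_lv <- 2 * a_lv; h_lv <- 0.84 * a_lv
  t_lv <- solve_wall_offset(a_lv, a_lv, c_lv, h_lv, w_lv)

  # RV: wider, slightly flattened in y
  unit_rv <- truncated_ellipsoid_volume(1.5, 0.95, 2.05, 0.82)
  u <- (v_rv / unit_rv)^(1 / 3)
  a_rv <- 1.5 * u; b_rv <- 0.95 * u; c_rv <- 2.05 * u; h_rv <- 0.82 * u
  t_rv <- solve_wall_offset(a_rv, b_rv, c_rv, h_rv, w_rv)

  dx <- (a_lv + t_lv) + (a_rv + t_rv) + 3   # 3 mm shell gap
  ctr_lv <- c(0, 0, 0); ctr_rv <- c(dx, 0, 0)

  comps <- list(
    lv_endo = build_component(ctr_lv, a_lv, a_lv, c_lv, h_lv, n_rings,
                              n_merid, split_base = TRUE, n_bridge = n_bridge),
    rv_endo = build_component(ctr_rv, a_rv, b_rv, c_rv, h_rv, n_rings,
                              n_merid, split_base = TRUE, n_bridge = n_bridge),
    lv_epi = build_component(ctr_lv, a_lv + t_lv, a_lv + t_lv, c_lv + t_lv,
                             h_lv, n_rings, n_merid),
    rv_epi = build_component(ctr_rv, a_rv + t_rv, b_rv + t_rv, c_rv + t_rv,
                             h_rv, n_rings, n_merid)
  )
  labels <- c(lv_endo = "LV_ENDO", rv_endo = "RV_ENDO",
              lv_epi = "EPI", rv_epi = "EPI")
  comp_names <- c(lv_endo = "LV_ENDO", rv_endo = "RV_ENDO",
                  lv_epi = "EPI_LV", rv_epi = "EPI_RV")
  walls <- c(lv_endo = 1L, rv_endo = 2L, lv_epi = 1L, rv_epi = 2L)

  vertices <- NULL; triangles <- NULL
  surface_label <- character(0); component <- character(0)
  wall_assignment <- integer(0)
  grid <- list(); offsets <- integer(0)
  for (nm in names(comps)) {
    off <- if (is.null(vertices)) 0L else nrow(vertices)
    offsets[nm] <- off
    cc <- comps[[nm]]
    vertices <- rbind(vertices, cc$vertices)
    triangles <- rbind(triangles, cc$triangles + off)
    nv <- nrow(cc$vertices)
    surface_label <- c(surface_label, rep(labels[[nm]], nv))
    component <- c(component, rep(comp_names[[nm]], nv))
    wall_assignment <- c(wall_assignment, rep(walls[[nm]], nv))
    g <- cc$grid
    g$apex <- g$apex + off
    g$rings <- g$rings + off
    grid[[comp_names[[nm]]]] <- g
  }
  annuli <- list(
    mitral = comps$lv_endo$hole_rings$pos + offsets["lv_endo"],
    tricuspid = comps$rv_endo$hole_rings$pos + offsets["rv_endo"],
    aortic = comps$lv_endo$hole_rings$neg + offsets["lv_endo"],
    pulmonary = comps$rv_endo$hole_rings$neg + offsets["rv_endo"]
  )
  annuli <- lapply(annuli, as.integer)
  dimnames(vertices) <- NULL
  dimnames(triangles) <- NULL

  surf <- bv_surface("template", "ED", vertices, triangles, surface_label,
                     wall_assignment, annuli, component = component,
                     grid = grid)
  surf$meta <- list(
    ref_bsa = ref_bsa, density = density,
    volumes = list(lv_endo = truncated_ellipsoid_volume(a_lv, a_lv, c_lv, h_lv),
                   rv_endo = truncated_ellipsoid_volume(a_rv, b_rv, c_rv, h_rv),
                   lv_epi = truncated_ellipsoid_volume(a_lv + t_lv, a_lv + t_lv,
                                                      c_lv + t_lv, h_lv),
                   rv_epi = truncated_ellipsoid_volume(a_rv + t_rv, b_rv + t_rv,
                                                      c_rv + t_rv, h_rv),
                   lv_wall = w_lv, rv_wall = w_rv),
    params = list(lv = c(a = a_lv, b = a_lv, c = c_lv, h = h_lv, t = t_lv),
                  rv = c(a = a_rv, b = b_rv, c = c_rv, h = h_rv, t = t_rv),
                  centers = list(lv = ctr_lv, rv = ctr_rv)),
    resolution = c(rings = n_rings, meridians = n_merid),
    n_bridge = as.integer(n_bridge)
  )
  surf
}
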