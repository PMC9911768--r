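# Shared fixtures: analytic phantom meshes and cached synthetic cohorts.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

get_template <- function() cached("template", generate_template())

# low-resolution cohort configs for loops
lowres_config <- function(seed, ...) {
  cohort_config(seed = seed, resolution = c(8L, 16L), ...)
}

get_cohort <- function() cached("cohort", generate_cohort(cohort_config(seed = 7)))

# Unit cube (12 triangles, consistently outward-oriented), volume 1 mm^3
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  colnames(v) <- NULL
  tri <- matrix(c(
    1, 3, 2, 2, 3, 4,    # z = 0 face (normal -z)
    5, 6, 7, 6, 8, 7,    # z = 1 face (+z)
    1, 2, 5, 2, 6, 5,    # y = 0
    3, 7, 4, 4, 7, 8,    # y = 1
    1, 5, 3, 3, 5, 7,    # x = 0
    2, 4, 6, 4, 8, 6     # x = 1
  ), ncol = 3L, byrow = TRUE)
  list(vertices = v, triangles = tri)
}

# Icosphere by subdividing an icosahedron; radius r, 20 * 4^level faces
icosphere <- function(level = 2L, r = 10) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  tri <- matrix(c(
    1, 12, 6, 1, 6, 2, 1, 2, 8, 1, 8, 11, 1, 11, 12,
    2, 6, 10, 6, 12, 5, 12, 11, 3, 11, 8, 7, 8, 2, 9,
    4, 10, 5, 4, 5, 3, 4, 3, 7, 4, 7, 9, 4, 9, 10,
    5, 10, 6, 3, 5, 12, 7, 3, 11, 9, 7, 8, 10, 9, 2
  ), ncol = 3L, byrow = TRUE)
  for (l in seq_len(level)) {
    mid <- new.env(hash = TRUE)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (is.null(mid[[key]])) {
        v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
        mid[[key]] <- nrow(v)
      }
      mid[[key]]
    }
    newtri <- matrix(0L, 0L, 3L)
    for (i in seq_len(nrow(tri))) {
      a <- tri[i, 1L]; b <- tri[i, 2L]; cc <- tri[i, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newtri <- rbind(newtri, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                      c(ab, bc, ca))
    }
    tri <- newtri
  }
  v <- v / sqrt(rowSums(v^2)) * r
  list(vertices = v, triangles = tri)
}

# Open hemisphere (z >= 0) of radius r with one equatorial boundary ring
open_hemisphere <- function(n_rings = 6L, n_merid = 16L, r = 10) {
  theta <- (pi / 2) * seq_len(n_rings) / n_rings
  phi <- 2 * pi * (seq_len(n_merid) - 1L) / n_merid
  v <- matrix(c(0, 0, r), 1L, 3L)
  rings <- matrix(0L, n_rings, n_merid)
  for (j in seq_len(n_rings)) {
    v <- rbind(v, cbind(r * sin(theta[j]) * cos(phi),
                        r * sin(theta[j]) * sin(phi),
                        r * cos(theta[j])))
    rings[j, ] <- (1L + (j - 1L) * n_merid) + seq_len(n_merid)
  }
  nxt <- c(seq_len(n_merid)[-1L], 1L)
  tri <- cbind(1L, rings[1L, ], rings[1L, nxt])
  for (j in seq_len(n_rings - 1L)) {
    A <- rings[j, ]; B <- rings[j, nxt]
    C <- rings[j + 1L, nxt]; D <- rings[j + 1L, ]
    tri <- rbind(tri, cbind(A, C, B), cbind(A, D, C))
  }
  list(vertices = v, triangles = tri, equator = rings[n_rings, ])
}

# Concentric open cylinders (one ventricle's endo + epi wall phantom) as a
# bv_surface-like object for the centerline radial strain; the slice-stack
# frame must be passed explicitly.
annulus_phantom <- function(r_endo, r_epi, height = 80, n_z = 24L,
                            n_merid = 48L, subject_id = "phantom",
                            phase = "ED", ventricle = "LV") {
  cyl <- function(r) {
    z <- seq(0, height, length.out = n_z)
    phi <- 2 * pi * (seq_len(n_merid) - 1L) / n_merid
    v <- NULL
    rings <- matrix(0L, n_z, n_merid)
    for (j in seq_len(n_z)) {
      v <- rbind(v, cbind(r * cos(phi), r * sin(phi), z[j]))
      rings[j, ] <- (j - 1L) * n_merid + seq_len(n_merid)
    }
    nxt <- c(seq_len(n_merid)[-1L], 1L)
    tri <- NULL
    for (j in seq_len(n_z - 1L)) {
      A <- rings[j, ]; B <- rings[j, nxt]
      C <- rings[j + 1L, nxt]; D <- rings[j + 1L, ]
      tri <- rbind(tri, cbind(A, C, B), cbind(A, D, C))
    }
    list(vertices = v, triangles = tri)
  }
  endo <- cyl(r_endo); epi <- cyl(r_epi)
  n1 <- nrow(endo$vertices)
  structure(list(
    subject_id = subject_id, phase = phase,
    vertices = rbind(endo$vertices, epi$vertices),
    triangles = rbind(endo$triangles, epi$triangles + n1),
    surface_label = rep(c(paste0(ventricle, "_ENDO"), "EPI"),
                        c(n1, nrow(epi$vertices))),
    component = rep(c(paste0(ventricle, "_ENDO"), paste0("EPI_", ventricle)),
                    c(n1, nrow(epi$vertices))),
    wall_assignment = rep(if (ventricle == "LV") 1L else 2L,
                          n1 + nrow(epi$vertices)),
    annuli = list(), grid = NULL
  ), class = "bv_surface")
}

phantom_frame <- function() {
  list(apex = c(0, 0, 0), dir = c(0, 0, 1),
       e1 = c(1, 0, 0), e2 = c(0, 1, 0))
}

rotate_mesh <- function(mesh, axis = c(1, 2, 2), angle = 0.7,
                        shift = c(5, -3, 11)) {
  R <- bivatlas:::rotation_about_axis(axis, angle)
  mesh$vertices <- mesh$vertices %*% t(R) +
    matrix(shift, nrow(mesh$vertices), 3L, byrow = TRUE)
  mesh
}

# contraction wrapper used by strain tests: per-ventricle scales with
# wall-conserving epicardial factor, mirroring the generator
contract_template <- function(tpl, lv_l = 0.86, lv_c = 0.79,
                              rv_l = 0.90, rv_c = 0.84) {
  vol <- bivatlas:::make_component_volumer(tpl)
  v_le <- vol(tpl$vertices, "LV_ENDO"); v_lp <- vol(tpl$vertices, "EPI_LV")
  v_re <- vol(tpl$vertices, "RV_ENDO"); v_rp <- vol(tpl$vertices, "EPI_RV")
  lam <- list(
    lv_lambda_l = lv_l, lv_lambda_c = lv_c,
    rv_lambda_l = rv_l, rv_lambda_c = rv_c,
    lv_lambda_c_epi = sqrt(((v_lp - v_le) + lv_c^2 * lv_l * v_le) /
                             (lv_l * v_lp)),
    rv_lambda_c_epi = sqrt(((v_rp - v_re) + rv_c^2 * rv_l * v_re) /
                             (rv_l * v_rp))
  )
  es <- tpl
  es$phase <- "ES"
  es$vertices <- bivatlas:::contract_vertices(tpl$vertices, tpl$component,
                                              tpl$grid, lam)
  es
}
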