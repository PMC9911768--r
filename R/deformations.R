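# Named, localized deformation fields planted by the cohort generator.
#
# Each field is an N x 3 displacement pattern on the template with unit
# peak vertex displacement (mm per unit magnitude). Fields are built to be
# mutually near-orthogonal as 3N vectors; LV conicity is explicitly
# orthogonalized against LV dilation, with which it shares support.

DEFORMATION_NAMES <- c("RV_APICAL_DILATION", "RV_BASAL_BULGE", "LV_DILATION",
                       "LV_CONICITY", "PV_ANNULUS_DILATION")

# weight envelope along the long axis, 1 at z0 decaying with scale sigma
gauss_window <- function(z, z0, sigma) exp(-((z - z0) / sigma)^2)

# unit radial directions about a vertical axis through (cx, cy); vertices
# on the axis get a zero direction
radial_dirs <- function(v, cx, cy) {
  d <- cbind(v[, 1L] - cx, v[, 2L] - cy, 0)
  r <- sqrt(d[, 1L]^2 + d[, 2L]^2)
  ok <- r > 1e-9
  d[ok, ] <- d[ok, ] / r[ok]
  d[!ok, ] <- 0
  d
}

# raw (un-normalized) field builders; each returns an N x 3 matrix
build_field <- function(template, name) {
  v <- template$vertices
  comp <- template$component
  g <- template$grid
  n <- nrow(v)
  f <- matrix(0, n, 3L)
  lv <- comp %in% c("LV_ENDO", "EPI_LV")
  rv <- comp %in% c("RV_ENDO", "EPI_RV")
  switch(name,
    RV_APICAL_DILATION = {
      ge <- g$RV_ENDO
      ctr <- ge$center
      span <- ge$base_z - ge$apex_z
      # outward from the RV centre, strongest near the apex
      d <- v[rv, , drop = FALSE] - matrix(ctr, sum(rv), 3L, byrow = TRUE)
      d <- d / pmax(sqrt(rowSums(d^2)), 1e-9)
      w <- gauss_window(v[rv, 3L], ge$apex_z, 0.45 * span)
      f[rv, ] <- d * w
    },
    RV_BASAL_BULGE = {
      ge <- g$RV_ENDO
      span <- ge$base_z - ge$apex_z
      dirs <- radial_dirs(v, ge$center[1L], ge$center[2L])
      # free wall only: the side facing away from the LV (+x of the RV axis)
      aw <- pmax(dirs[, 1L], 0)
      w <- gauss_window(v[, 3L], ge$base_z - 0.18 * span, 0.28 * span)
      sel <- rv
      f[sel, ] <- dirs[sel, , drop = FALSE] * (aw * w)[sel]
    },
    LV_DILATION = {
      ge <- g$LV_ENDO
      dirs <- radial_dirs(v, ge$center[1L], ge$center[2L])
      # uniform relative radial expansion (scaled by local radius)
      r <- sqrt((v[, 1L] - ge$center[1L])^2 + (v[, 2L] - ge$center[2L])^2)
      rmax <- max(r[lv])
      f[lv, ] <- dirs[lv, , drop = FALSE] * (r / rmax)[lv]
    },
    LV_CONICITY = {
      ge <- g$LV_ENDO
      span <- ge$base_z - ge$apex_z
      dirs <- radial_dirs(v, ge$center[1L], ge$center[2L])
      r <- sqrt((v[, 1L] - ge$center[1L])^2 + (v[, 2L] - ge$center[2L])^2)
      rmax <- max(r[lv])
      zmid <- (ge$base_z + ge$apex_z) / 2
      # widen the base, narrow the apex: a linear longitudinal profile
      w <- (v[, 3L] - zmid) / (0.5 * span) * (r / rmax)
      f[lv, ] <- dirs[lv, , drop = FALSE] * w[lv]
    },
    PV_ANNULUS_DILATION = {
      ring <- template$annuli$pulmonary
      ctr <- colMeans(v[ring, , drop = FALSE])
      # in-plane radial push away from the ring centroid, decaying with
      # distance from the ring into the rest of the RV endocardium
      sel <- comp == "RV_ENDO"
      d <- cbind(v[, 1L] - ctr[1L], v[, 2L] - ctr[2L], 0)
      r <- pmax(sqrt(rowSums(d^2)), 1e-9)
      d <- d / r
      ring_d <- apply_min_dist(v, v[ring, , drop = FALSE])
      tau <- 0.28 * mean(r[ring])
      w <- exp(-(ring_d / tau)^2)
      f[sel, ] <- d[sel, , drop = FALSE] * w[sel]
      f[ring, ] <- d[ring, , drop = FALSE]    # exactly unit radial on the ring
    },
    stop_bv("unknown deformation name '", name, "'; known: ",
            paste(DEFORMATION_NAMES, collapse = ", "))
  )
  f
}

# distance from every vertex to the nearest of a small set of points
apply_min_dist <- function(v, pts) {
  d2 <- matrix(Inf, nrow(v), 1L)
  for (i in seq_len(nrow(pts))) {
    di <- (v[, 1L] - pts[i, 1L])^2 + (v[, 2L] - pts[i, 2L])^2 +
      (v[, 3L] - pts[i, 3L])^2
    d2 <- pmin(d2, di)
  }
  sqrt(as.numeric(d2))
}

#' Displacement fields of the named template deformations
#'
#' Returns the five planted deformation patterns, unit-peak normalized and
#' with the LV conicity field orthogonalized against LV dilation. These are
#' the shape factors the synthetic cohort plants with group-linked
#' coefficients; they mimic the remodeling patterns reported for rTOF
#' (RV apical dilation, RV basal bulging, LV dilation, LV conicity,
#' pulmonary annulus dilation).
#'
#' @param template a surface from [generate_template()].
#' @param names which fields to build (default all five).
#' @return named list of N x 3 displacement matrices with unit peak vertex
#'   displacement; attribute `norms` gives each field's 3N euclidean norm.
#' @export
deformation_fields <- function(template, names = DEFORMATION_NAMES) {
  bad <- setdiff(names, DEFORMATION_NAMES)
  if (length(bad) > 0L)
    stop_bv("unknown deformation name '", bad[1L], "'; known: ",
            paste(DEFORMATION_NAMES, collapse = ", "))
  fields <- lapply(names, function(nm) build_field(template, nm))
  names(fields) <- names
  if ("LV_CONICITY" %in% names) {
    dil <- if ("LV_DILATION" %in% names) fields$LV_DILATION
           else build_field(template, "LV_DILATION")
    a <- stack_vertices(dil)
    b <- stack_vertices(fields$LV_CONICITY)
    b <- b - sum(a * b) / sum(a * a) * a
    fields$LV_CONICITY <- unstack_vertices(b)
  }
  # PV dilation keeps its exact unit ring displacement; the others are
  # normalized to unit peak
  for (nm in names) {
    if (nm == "PV_ANNULUS_DILATION") next
    pk <- sqrt(max(rowSums(fields[[nm]]^2)))
    fields[[nm]] <- fields[[nm]] / pk
  }
  norms <- vapply(fields, function(f) sqrt(sum(f^2)), numeric(1L))
  attr(fields, "norms") <- norms
  fields
}

#' Apply a named deformation to a template surface
#'
#' @param template a surface from [generate_template()].
#' @param name one of `r paste0('"', DEFORMATION_NAMES, '"', collapse = ", ")`.
#' @param magnitude peak displacement in mm (for `PV_ANNULUS_DILATION`, the
#'   increase of the pulmonary annulus mean radius in mm).
#' @return the deformed [bv_surface()].
#' @export
apply_named_deformation <- function(template, name, magnitude) {
  f <- deformation_fields(template, names = name)[[1L]]
  template$vertices <- template$vertices + magnitude * f
  template
}
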