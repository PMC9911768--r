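# Synthetic biventricular cohort generator.
#
# Emulates the statistical structure of an 84-subject rTOF cohort
# (48 PVR / 36 No-PVR): low-dimensional planted shape variation with
# group-linked mode coefficients, confounder distributions patterned on the
# study-population summaries, allometric size scaling with BSA, random
# rigid misalignment, iid vertex noise, and an ES frame produced by an
# analytic per-ventricle contraction so that strains and ejection
# fractions have known ground truth.

#' Configuration for a synthetic biventricular cohort
#'
#' All distributional choices are collected here so a cohort is
#' reproducible bit-for-bit from `config + seed`. Defaults emulate the
#' target study population: group sizes 48/36, sex and repair-type
#' frequencies, log-normal times since repair, group-distinct BSA, and ES
#' contraction scales tuned so mean RV EF lands near 37% (PVR) vs 42%
#' (No-PVR) and LV EF near 46% vs 48%.
#'
#' @param seed integer seed (mandatory); all five generator streams
#'   (shape, noise, confounders, misalignment, contraction) derive their
#'   own substream seeds from it.
#' @param n_pvr,n_no_pvr group sizes.
#' @param resolution template resolution `c(rings, meridians)`.
#' @param n_bridge basal bridge resolution (see [generate_template()]).
#' @param planted data frame with columns `name` (a deformation from
#'   [deformation_fields()]), `sd` (population SD of the mode coefficient,
#'   mm), `offset_pvr`, `offset_no_pvr` (group mean offsets in SD units).
#' @param background smooth anatomical background variation: a list with
#'   `n_fields` orthonormal random polynomial deformation fields (degree
#'   <= 3, drawn deterministically from the seed), `sd` (mm, the 3N-norm
#'   SD of the leading background mode) and `decay` (geometric SD decay
#'   per mode). This long spectral tail makes the atlas scree realistic:
#'   without it a handful of planted modes would explain nearly all
#'   variance, which real anatomies never do. Set `n_fields = 0` to
#'   disable (e.g. when planting a known eigen-spectrum).
#' @param noise_sd iid vertex noise SD (mm) added to each coordinate.
#' @param misalign_rot_deg,misalign_trans_mm ranges of the random rigid
#'   misalignment (uniform angle about a random axis; uniform per-axis
#'   translation), the same transform for a subject's ED and ES frames.
#' @param es end-systolic contraction parameters: per group and ventricle,
#'   mean longitudinal (`lambda_l`) and circumferential (`lambda_c`)
#'   endocardial scale factors, plus their between-subject SDs. The
#'   epicardial circumferential scale is solved per subject so wall volume
#'   is conserved between ED and ES.
#' @param confounders distributions for the subject table; see the source
#'   for the parameterization (normal, truncated normal, log-normal).
#' @param ref_bsa BSA (m^2) at which the template has its nominal size;
#'   each subject's geometry is scaled by `(bsa / ref_bsa)^(1/3)`.
#' @param scale_with_bsa logical; disable to remove the allometric size
#'   factor (used when planting a known eigen-spectrum).
#' @param volume_neutral logical (default TRUE): project the planted
#'   fields onto the subspace that leaves all four component volumes
#'   unchanged to first order. The group-linked variation is then a
#'   difference in regional shape style that global volume and mass
#'   indices cannot see - the mechanism the shape-mode analysis is
#'   designed to detect - while index differences between groups arise
#'   only from the contraction (EF) parameters and cohort size structure.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(seed,
                          n_pvr = 48L, n_no_pvr = 36L,
                          resolution = c(14L, 28L), n_bridge = 7L,
                          planted = default_planted_modes(),
                          background = list(n_fields = 40L, sd = 50,
                                            decay = 0.96),
                          noise_sd = 0.5,
                          misalign_rot_deg = 10, misalign_trans_mm = 10,
                          es = default_es_params(),
                          confounders = default_confounders(),
                          ref_bsa = 1.55,
                          scale_with_bsa = TRUE,
                          volume_neutral = TRUE) {
  if (missing(seed) || !is_number(seed)) stop_bv("an integer seed is mandatory")
  if (n_pvr <= 0L || n_no_pvr <= 0L) stop_bv("group sizes must be positive")
  if (noise_sd < 0) stop_bv("noise_sd must be >= 0")
  if (!is.data.frame(planted) ||
      !all(c("name", "sd", "offset_pvr", "offset_no_pvr") %in% names(planted)))
    stop_bv("planted must have columns name, sd, offset_pvr, offset_no_pvr")
  if (any(planted$sd < 0)) stop_bv("planted SDs must be >= 0")
  structure(list(seed = as.integer(seed), n_pvr = as.integer(n_pvr),
                 n_no_pvr = as.integer(n_no_pvr),
                 resolution = as.integer(resolution),
                 n_bridge = as.integer(n_bridge),
                 planted = planted, background = background,
                 noise_sd = noise_sd,
                 misalign_rot_deg = misalign_rot_deg,
                 misalign_trans_mm = misalign_trans_mm,
                 es = es, confounders = confounders, ref_bsa = ref_bsa,
                 scale_with_bsa = isTRUE(scale_with_bsa),
                 volume_neutral = isTRUE(volume_neutral)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_planted_modes <- function() {
  data.frame(
    name = c("RV_APICAL_DILATION", "RV_BASAL_BULGE", "LV_DILATION",
             "LV_CONICITY", "PV_ANNULUS_DILATION"),
    sd = c(4.6, 8.5, 4.1, 3.9, 5.7),
    offset_pvr = c(-0.60, 0.60, 0.60, 0.40, 0.60),
    offset_no_pvr = c(0.60, -0.60, -0.60, -0.40, -0.60)
  )
}

#' @rdname cohort_config
#' @export
default_es_params <- function() {
  list(pvr = list(lv = c(lambda_l = 0.86, lambda_c = 0.793),
                  rv = c(lambda_l = 0.90, lambda_c = 0.840)),
       no_pvr = list(lv = c(lambda_l = 0.85, lambda_c = 0.782),
                     rv = c(lambda_l = 0.87, lambda_c = 0.817)),
       sd = c(lambda_l = 0.035, lambda_c = 0.05))
}

#' @rdname cohort_config
#' @export
default_confounders <- function() {
  list(
    sex_p_male = c(pvr = 35 / 48, no_pvr = 17 / 36),
    repair_probs = rbind(pvr = c(35, 2, 11) / 48, no_pvr = c(30, 6, 0) / 36),
    time_lnorm = rbind(pvr = c(meanlog = log(12), sdlog = 0.43),
                       no_pvr = c(meanlog = log(19), sdlog = 0.41)),
    age_repair_lnorm = rbind(pvr = c(meanlog = log(0.4), sdlog = 0.6),
                             no_pvr = c(meanlog = log(1.6), sdlog = 0.9)),
    height = rbind(pvr = c(mean = 152, sd = 18, min = 100, max = 200),
                   no_pvr = c(mean = 162, sd = 8, min = 120, max = 200)),
    weight = rbind(pvr = c(mean = 49, sd = 23, min = 15, max = 110),
                   no_pvr = c(mean = 62, sd = 18, min = 25, max = 120)),
    prvi = rbind(pvr = c(mean = 27, sd = 12, min = 5, max = 80),
                 no_pvr = c(mean = 30, sd = 17, min = 5, max = 90)),
    prf = rbind(pvr = c(mean = 41, sd = 10, min = 20, max = 79),
                no_pvr = c(mean = 40, sd = 11, min = 20, max = 79)),
    symptomatic_p = c(pvr = 26 / 48, no_pvr = 0.2)
  )
}

REPAIR_TYPES <- c("TRANSANNULAR_PATCH", "VALVE_SPARING", "CONDUIT")

# truncated normal draws via inverse-CDF
rtnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# Closing topology of the four labelled components (open triangles + cap
# fans to ring centroids), shared by the fast volume integrator and the
# volume-gradient projection below.
component_closing_info <- function(template) {
  comps <- c("LV_ENDO", "RV_ENDO", "EPI_LV", "EPI_RV")
  info <- lapply(comps, function(cn) {
    sub <- sub_surface(template, cn)
    cycles <- boundary_cycles(sub$triangles)
    tri <- sub$triangles
    nv <- nrow(sub$vertices)
    cyc_tris <- list()
    for (ci in seq_along(cycles)) {
      cyc <- cycles[[ci]]
      cidx <- nv + ci
      a <- cyc; b <- c(cyc[-1L], cyc[1L])
      cyc_tris[[ci]] <- cbind(b, a, cidx)
    }
    list(map = sub$map, tri = do.call(rbind, c(list(tri), cyc_tris)),
         cycles = cycles, nv = nv)
  })
  names(info) <- comps
  info
}

# Precompute per-component closing topology so cavity volumes of many
# deformed copies of the template can be integrated quickly.
make_component_volumer <- function(template) {
  info <- component_closing_info(template)
  function(vertices, comp) {
    ci <- info[[comp]]
    v <- vertices[ci$map, , drop = FALSE]
    caps <- t(vapply(ci$cycles,
                     function(cyc) colMeans(v[cyc, , drop = FALSE]),
                     numeric(3L)))
    enclosed_volume(list(vertices = rbind(v, caps), triangles = ci$tri),
                    check = FALSE)
  }
}

# Gradient of each component's enclosed volume with respect to the global
# vertex coordinates, as stacked 3N vectors (one per component). Used to
# make the planted group-linked fields volume-neutral to first order, so
# group differences in shape style do not trivially show up in the global
# volume indices.
component_volume_gradients <- function(template) {
  info <- component_closing_info(template)
  n <- nrow(template$vertices)
  out <- matrix(0, 3L * n, length(info),
                dimnames = list(NULL, names(info)))
  for (cn in names(info)) {
    ci <- info[[cn]]
    v <- template$vertices[ci$map, , drop = FALSE]
    caps <- t(vapply(ci$cycles,
                     function(cyc) colMeans(v[cyc, , drop = FALSE]),
                     numeric(3L)))
    vall <- rbind(v, caps)
    tri <- ci$tri
    a <- vall[tri[, 1L], , drop = FALSE]
    b <- vall[tri[, 2L], , drop = FALSE]
    cc <- vall[tri[, 3L], , drop = FALSE]
    cross <- function(p, q) cbind(p[, 2L] * q[, 3L] - p[, 3L] * q[, 2L],
                                  p[, 3L] * q[, 1L] - p[, 1L] * q[, 3L],
                                  p[, 1L] * q[, 2L] - p[, 2L] * q[, 1L])
    signed <- sum(a[, 1L] * (b[, 2L] * cc[, 3L] - b[, 3L] * cc[, 2L]) -
                    a[, 2L] * (b[, 1L] * cc[, 3L] - b[, 3L] * cc[, 1L]) +
                    a[, 3L] * (b[, 1L] * cc[, 2L] - b[, 2L] * cc[, 1L])) / 6
    g <- matrix(0, nrow(vall), 3L)
    ga <- cross(b, cc) / 6; gb <- cross(cc, a) / 6; gc <- cross(a, b) / 6
    gsum <- rowsum(rbind(ga, gb, gc), c(tri[, 1L], tri[, 2L], tri[, 3L]))
    g[as.integer(rownames(gsum)), ] <- gsum
    # cap centroids are means of their ring vertices: redistribute
    for (cyi in seq_along(ci$cycles)) {
      cyc <- ci$cycles[[cyi]]
      g[cyc, ] <- g[cyc, ] + matrix(g[ci$nv + cyi, ] / length(cyc),
                                    length(cyc), 3L, byrow = TRUE)
    }
    g <- g[seq_len(ci$nv), , drop = FALSE] * sign(signed)
    gfull <- matrix(0, n, 3L)
    gfull[ci$map, ] <- g
    out[, cn] <- stack_vertices(gfull)
  }
  out
}

# Orthonormal random smooth deformation fields spanning a subspace of
# polynomial (degree <= 3) coordinate displacements; uses the current RNG
# stream for the random rotation within the polynomial subspace.
background_basis <- function(template, n_fields) {
  v <- template$vertices
  vc <- sweep(v, 2L, colMeans(v))
  vc <- vc / sqrt(mean(vc^2))
  x <- vc[, 1L]; y <- vc[, 2L]; z <- vc[, 3L]
  mono <- cbind(x, y, z, x^2, y^2, z^2, x * y, x * z, y * z,
                x^3, y^3, z^3, x^2 * y, x^2 * z, x * y^2, y^2 * z,
                x * z^2, y * z^2, x * y * z)
  nm <- ncol(mono)
  n <- nrow(v)
  B <- matrix(0, 3L * n, 3L * nm)
  for (j in seq_len(nm)) {
    for (a in 1:3) {
      col <- matrix(0, n, 3L)
      col[, a] <- mono[, j]
      B[, (j - 1L) * 3L + a] <- stack_vertices(col)
    }
  }
  Q <- qr.Q(qr(B))
  if (n_fields > ncol(Q))
    stop_bv("background n_fields cannot exceed ", ncol(Q))
  W <- qr.Q(qr(matrix(stats::rnorm(ncol(Q)^2), ncol(Q))))
  Q %*% W[, seq_len(n_fields), drop = FALSE]
}

# Analytic per-ventricle systolic contraction about the ventricle's own
# long axis and base plane. `lam` holds lambda_l and the endo/epi
# circumferential scales; applied to LV and RV components independently.
contract_vertices <- function(v, component, grid, lam) {
  out <- v
  specs <- list(
    list(comp = "LV_ENDO", g = "LV_ENDO", lc = lam$lv_lambda_c, ll = lam$lv_lambda_l),
    list(comp = "EPI_LV",  g = "LV_ENDO", lc = lam$lv_lambda_c_epi, ll = lam$lv_lambda_l),
    list(comp = "RV_ENDO", g = "RV_ENDO", lc = lam$rv_lambda_c, ll = lam$rv_lambda_l),
    list(comp = "EPI_RV",  g = "RV_ENDO", lc = lam$rv_lambda_c_epi, ll = lam$rv_lambda_l)
  )
  for (sp in specs) {
    sel <- component == sp$comp
    gg <- grid[[sp$g]]
    cx <- gg$center[1L]; cy <- gg$center[2L]; zb <- gg$base_z
    out[sel, 1L] <- cx + sp$lc * (v[sel, 1L] - cx)
    out[sel, 2L] <- cy + sp$lc * (v[sel, 2L] - cy)
    out[sel, 3L] <- zb + sp$ll * (v[sel, 3L] - zb)
  }
  out
}

#' Generate a synthetic biventricular cohort with ground truth
#'
#' Draws a cohort from a [cohort_config()]: per subject, planted mode
#' coefficients (group-shifted normals) deform the template, the geometry
#' is scaled allometrically with the subject's BSA, an analytic systolic
#' contraction (with wall-volume conservation) produces the ES frame, iid
#' vertex noise and a random rigid misalignment are applied, and the
#' subject table is drawn from the configured confounder distributions.
#'
#' @param config a [cohort_config()].
#' @return an object of class `bv_cohort`: list with `config`, `template`,
#'   `surfaces_ed`, `surfaces_es` (lists of [bv_surface()]), `records`
#'   (subject table data frame) and `ground_truth` (planted coefficients,
#'   deformation fields and their norms, contraction scales, true EFs,
#'   per-subject cavity volumes of the noise-free meshes, misalignment
#'   transforms, and the template's analytic volumes).
#' @seealso [compute_true_strains()], [cohort_config()]
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop_bv("config must be a cohort_config")
  set.seed(config$seed)
  stage_seed <- sample.int(2147483646L, 5L)

  template <- generate_template(resolution = config$resolution,
                                n_bridge = config$n_bridge,
                                ref_bsa = config$ref_bsa)
  fields <- deformation_fields(template, names = config$planted$name)
  volumer <- make_component_volumer(template)
  n <- config$n_pvr + config$n_no_pvr
  group <- c(rep("PVR", config$n_pvr), rep("NO_PVR", config$n_no_pvr))
  ids <- sprintf("S%03d", seq_len(n))
  nv <- nrow(template$vertices)
  K <- nrow(config$planted)

  # --- confounders -------------------------------------------------------
  set.seed(stage_seed[3L])
  cf <- config$confounders
  gi <- ifelse(group == "PVR", "pvr", "no_pvr")
  sex <- ifelse(stats::runif(n) < cf$sex_p_male[gi], "M", "F")
  repair <- vapply(gi, function(g)
    sample(REPAIR_TYPES, 1L, prob = cf$repair_probs[g, ]), character(1L))
  time_rep <- stats::rlnorm(n, cf$time_lnorm[gi, "meanlog"],
                            cf$time_lnorm[gi, "sdlog"])
  age_rep <- stats::rlnorm(n, cf$age_repair_lnorm[gi, "meanlog"],
                           cf$age_repair_lnorm[gi, "sdlog"])
  height <- rtnorm(n, cf$height[gi, "mean"], cf$height[gi, "sd"],
                   cf$height[gi, "min"], cf$height[gi, "max"])
  weight <- rtnorm(n, cf$weight[gi, "mean"], cf$weight[gi, "sd"],
                   cf$weight[gi, "min"], cf$weight[gi, "max"])
  bsa <- sqrt(height * weight / 3600)      # Mosteller
  prvi <- rtnorm(n, cf$prvi[gi, "mean"], cf$prvi[gi, "sd"],
                 cf$prvi[gi, "min"], cf$prvi[gi, "max"])
  prf <- rtnorm(n, cf$prf[gi, "mean"], cf$prf[gi, "sd"],
                cf$prf[gi, "min"], cf$prf[gi, "max"])
  symptomatic <- stats::runif(n) < cf$symptomatic_p[gi]
  records <- data.frame(
    subject_id = ids, group = group, sex = sex, repair_type = repair,
    age_at_repair = age_rep, age_at_cmr = age_rep + time_rep,
    time_after_repair = time_rep, height = height, weight = weight,
    bsa = bsa, symptomatic = symptomatic, prvi = prvi, prf = prf,
    stringsAsFactors = FALSE
  )

  # --- planted shape coefficients + background variation ----------------
  set.seed(stage_seed[1L])
  n_bg <- config$background$n_fields %||% 0L
  if (n_bg > 0L) {
    bg_basis <- background_basis(template, n_bg)
    bg_sd <- config$background$sd * config$background$decay^(seq_len(n_bg) - 1L)
    bg_coef <- matrix(stats::rnorm(n * n_bg, sd = rep(bg_sd, each = n)), n, n_bg)
  } else {
    bg_basis <- NULL; bg_sd <- numeric(0)
    bg_coef <- matrix(0, n, 0L)
  }
  offs <- ifelse(group == "PVR", 1L, 2L)
  coef_mean <- cbind(config$planted$offset_pvr,
                     config$planted$offset_no_pvr) * config$planted$sd  # K x 2
  mu <- t(coef_mean)[offs, , drop = FALSE]                              # n x K
  coefficients <- mu + matrix(stats::rnorm(n * K,
                                           sd = rep(config$planted$sd, each = n)),
                              n, K)
  colnames(coefficients) <- config$planted$name

  # --- contraction scales ------------------------------------------------
  set.seed(stage_seed[5L])
  esp <- config$es
  lam_mean <- function(vent, par)
    vapply(gi, function(g) esp[[g]][[vent]][[par]], numeric(1L))
  clamp <- function(x) pmin(pmax(x, 0.5), 1.05)
  lambdas <- data.frame(
    subject_id = ids,
    lv_lambda_l = clamp(stats::rnorm(n, lam_mean("lv", "lambda_l"), esp$sd["lambda_l"])),
    lv_lambda_c = clamp(stats::rnorm(n, lam_mean("lv", "lambda_c"), esp$sd["lambda_c"])),
    rv_lambda_l = clamp(stats::rnorm(n, lam_mean("rv", "lambda_l"), esp$sd["lambda_l"])),
    rv_lambda_c = clamp(stats::rnorm(n, lam_mean("rv", "lambda_c"), esp$sd["lambda_c"]))
  )

  # --- misalignment -------------------------------------------------------
  set.seed(stage_seed[4L])
  misalign <- lapply(seq_len(n), function(i) {
    list(rotation = random_rotation(config$misalign_rot_deg),
         translation = stats::runif(3L, -config$misalign_trans_mm,
                                    config$misalign_trans_mm))
  })

  # --- noise --------------------------------------------------------------
  set.seed(stage_seed[2L])
  noise_ed <- lapply(seq_len(n), function(i)
    matrix(stats::rnorm(nv * 3L, sd = config$noise_sd), nv, 3L))
  noise_es <- lapply(seq_len(n), function(i)
    matrix(stats::rnorm(nv * 3L, sd = config$noise_sd), nv, 3L))

  # --- assembly -----------------------------------------------------------
  F3 <- vapply(seq_len(K), function(k) stack_vertices(fields[[k]]),
               numeric(3L * nv))
  if (isTRUE(config$volume_neutral)) {
    vg <- component_volume_gradients(template)
    for (cn in colnames(vg)) {
      g <- vg[, cn]
      F3 <- F3 - g %*% (crossprod(g, F3) / sum(g^2))
    }
  }
  field_norms <- sqrt(colSums(F3^2))
  names(field_norms) <- config$planted$name
  scale_s <- if (config$scale_with_bsa) (bsa / config$ref_bsa)^(1 / 3)
             else rep(1, n)
  surfaces_ed <- vector("list", n)
  surfaces_es <- vector("list", n)
  vol_ed <- matrix(0, n, 4L,
                   dimnames = list(ids, c("lv", "rv", "epi_lv", "epi_rv")))
  lam_epi <- matrix(0, n, 2L, dimnames = list(ids, c("lv", "rv")))
  for (i in seq_len(n)) {
    disp <- as.numeric(F3 %*% coefficients[i, ])
    if (n_bg > 0L) disp <- disp + as.numeric(bg_basis %*% bg_coef[i, ])
    base_v <- template$vertices + unstack_vertices(disp)
    # noise-free volumes (template frame; scale applied analytically below)
    v_le <- volumer(base_v, "LV_ENDO"); v_re <- volumer(base_v, "RV_ENDO")
    v_lp <- volumer(base_v, "EPI_LV"); v_rp <- volumer(base_v, "EPI_RV")
    vol_ed[i, ] <- c(v_le, v_re, v_lp, v_rp) * scale_s[i]^3
    # wall-conserving epicardial circumferential scale
    lam <- as.list(lambdas[i, -1L])
    lam$lv_lambda_c_epi <- sqrt(((v_lp - v_le) +
                                   lam$lv_lambda_c^2 * lam$lv_lambda_l * v_le) /
                                  (lam$lv_lambda_l * v_lp))
    lam$rv_lambda_c_epi <- sqrt(((v_rp - v_re) +
                                   lam$rv_lambda_c^2 * lam$rv_lambda_l * v_re) /
                                  (lam$rv_lambda_l * v_rp))
    lam_epi[i, ] <- c(lam$lv_lambda_c_epi, lam$rv_lambda_c_epi)
    es_v <- contract_vertices(base_v, template$component, template$grid, lam)
    ed_v <- scale_s[i] * base_v + noise_ed[[i]]
    es_v <- scale_s[i] * es_v + noise_es[[i]]
    ed_v <- apply_rigid(ed_v, misalign[[i]]$rotation, misalign[[i]]$translation)
    es_v <- apply_rigid(es_v, misalign[[i]]$rotation, misalign[[i]]$translation)
    surfaces_ed[[i]] <- bv_surface(ids[i], "ED", ed_v, template$triangles,
                                   template$surface_label,
                                   template$wall_assignment, template$annuli,
                                   component = template$component,
                                   grid = template$grid, validate = FALSE)
    surfaces_es[[i]] <- bv_surface(ids[i], "ES", es_v, template$triangles,
                                   template$surface_label,
                                   template$wall_assignment, template$annuli,
                                   component = template$component,
                                   grid = template$grid, validate = FALSE)
  }
  names(surfaces_ed) <- ids
  names(surfaces_es) <- ids

  lambdas$lv_lambda_c_epi <- lam_epi[, "lv"]
  lambdas$rv_lambda_c_epi <- lam_epi[, "rv"]
  true_ef <- data.frame(
    subject_id = ids,
    lv_ef = 100 * (1 - lambdas$lv_lambda_c^2 * lambdas$lv_lambda_l),
    rv_ef = 100 * (1 - lambdas$rv_lambda_c^2 * lambdas$rv_lambda_l)
  )
  structure(list(
    config = config, template = template,
    surfaces_ed = surfaces_ed, surfaces_es = surfaces_es,
    records = records,
    ground_truth = list(
      coefficients = coefficients,
      fields = F3, field_norms = field_norms,
      background_basis = bg_basis, background_coefficients = bg_coef,
      background_sd = bg_sd,
      lambdas = lambdas, true_ef = true_ef,
      volumes_ed = vol_ed, scale = scale_s,
      misalignments = misalign,
      wall_assignment = template$wall_assignment,
      template_volumes = template$meta$volumes
    )
  ), class = "bv_cohort")
}

#' @export
print.bv_cohort <- function(x, ...) {
  cat("Synthetic biventricular cohort\n")
  cat("  subjects:", length(x$surfaces_ed),
      sprintf("(PVR %d / No-PVR %d)", x$config$n_pvr, x$config$n_no_pvr), "\n")
  cat("  vertices per surface:", nrow(x$template$vertices),
      " seed:", x$config$seed, "\n")
  invisible(x)
}

#' Noise-free reference strains for a synthetic cohort
#'
#' Rebuilds each subject's noise-free, unmisaligned ED/ES surface pair from
#' the stored ground truth (planted coefficients + analytic contraction)
#' and evaluates the geometric strain measures on them. These are the
#' reference values against which strains measured on the noisy, misaligned
#' meshes are compared; the circumferential ground truth additionally has
#' the exact closed form `100 * (lambda_c - 1)`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param subjects indices or subject ids (default: all).
#' @param ... passed to [compute_strains()].
#' @return matrix with one row per subject and columns
#'   `lv_ls, rv_ls, lv_cs, rv_cs, lv_rs, rv_rs` (%).
#' @export
compute_true_strains <- function(cohort, subjects = NULL, ...) {
  tpl <- cohort$template
  gt <- cohort$ground_truth
  ids <- cohort$records$subject_id
  if (is.null(subjects)) subjects <- seq_along(ids)
  if (is.character(subjects)) subjects <- match(subjects, ids)
  out <- matrix(NA_real_, length(subjects), 6L,
                dimnames = list(ids[subjects],
                                c("lv_ls", "rv_ls", "lv_cs", "rv_cs",
                                  "lv_rs", "rv_rs")))
  for (j in seq_along(subjects)) {
    i <- subjects[j]
    disp <- as.numeric(gt$fields %*% gt$coefficients[i, ])
    if (!is.null(gt$background_basis))
      disp <- disp + as.numeric(gt$background_basis %*%
                                  gt$background_coefficients[i, ])
    base_v <- tpl$vertices + unstack_vertices(disp)
    lam <- as.list(gt$lambdas[i, -1L])
    es_v <- contract_vertices(base_v, tpl$component, tpl$grid, lam)
    ed <- bv_surface(ids[i], "ED", base_v, tpl$triangles, tpl$surface_label,
                     tpl$wall_assignment, tpl$annuli,
                     component = tpl$component, grid = tpl$grid,
                     validate = FALSE)
    es <- bv_surface(ids[i], "ES", es_v, tpl$triangles, tpl$surface_label,
                     tpl$wall_assignment, tpl$annuli,
                     component = tpl$component, grid = tpl$grid,
                     validate = FALSE)
    s <- compute_strains(ed, es, ...)
    out[j, ] <- c(s$lv_ls, s$rv_ls, s$lv_cs, s$rv_cs, s$lv_rs, s$rv_rs)
  }
  out
}
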