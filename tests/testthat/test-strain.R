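# Cauchy strain, parameter lines, directional strains against analytic
# deformations, centerline radial strain on phantoms, and invariances.

test_that("Cauchy strain computes relative length change", {
  expect_equal(cauchy_strain(10, 8), -20)
  expect_equal(cauchy_strain(10, 10), 0)
  expect_equal(cauchy_strain(10, 11.5), 15)
  expect_equal(cauchy_strain(c(10, 5), c(9, 6)), c(-10, 20))
  expect_error(cauchy_strain(0, 5), "positive")
})

test_that("parameter lines follow the structured grid", {
  tpl <- get_template()
  G <- tpl$meta$resolution[["meridians"]]
  lv_long <- sample_parameter_lines(tpl, "LONGITUDINAL", "LV")
  expect_length(lv_long, G)
  expect_true(all(vapply(lv_long, function(l)
    l[1L] == tpl$grid$LV_ENDO$apex, logical(1L))))

  rings <- sample_parameter_lines(tpl, "CIRCUMFERENTIAL", "RV")
  expect_true(all(vapply(rings, function(l) l[1L] == l[length(l)],
                         logical(1L))))
  for (l in c(lv_long, list())) {
    expect_true(all(tpl$surface_label[l] == "LV_ENDO"))
  }
  for (l in rings) expect_true(all(tpl$surface_label[l] == "RV_ENDO"))

  nogrid <- tpl
  nogrid$grid <- NULL
  expect_error(sample_parameter_lines(nogrid, "LONGITUDINAL", "LV"),
               "radial strain")
})

test_that("directional strains equal analytic values for affine deformations", {
  tpl <- get_template()
  # uniform scaling: every arc length scales exactly
  uni <- tpl; uni$phase <- "ES"; uni$vertices <- 0.85 * uni$vertices
  expect_equal(as.numeric(directional_strain(tpl, uni, "LONGITUDINAL", "LV")),
               -15, tolerance = 1e-9)
  expect_equal(as.numeric(directional_strain(tpl, uni, "CIRCUMFERENTIAL", "RV")),
               -15, tolerance = 1e-9)

  # in-plane scaling: rings are horizontal curves, scaled exactly
  xy <- tpl; xy$phase <- "ES"
  xy$vertices[, 1:2] <- 0.9 * xy$vertices[, 1:2]
  expect_equal(as.numeric(directional_strain(tpl, xy, "CIRCUMFERENTIAL", "LV")),
               -10, tolerance = 1e-9)
  expect_equal(as.numeric(directional_strain(tpl, xy, "CIRCUMFERENTIAL", "RV")),
               -10, tolerance = 1e-9)

  # long-axis scaling: meridians are curved, so the analytic value comes
  # from dense numerical integration of the continuous meridian
  zs <- tpl; zs$phase <- "ES"
  zb <- tpl$grid$LV_ENDO$base_z
  zs$vertices[, 3L] <- zb + 0.85 * (zs$vertices[, 3L] - zb)
  got <- as.numeric(directional_strain(tpl, zs, "LONGITUDINAL", "LV"))
  p <- tpl$meta$params$lv
  theta_b <- acos(-p[["h"]] / p[["c"]])
  th <- seq(0, theta_b, length.out = 20001L)
  merid <- cbind(p[["a"]] * sin(th), -p[["c"]] * cos(th))
  arc <- function(m) sum(sqrt(rowSums(diff(m)^2)))
  merid_es <- merid
  merid_es[, 2L] <- p[["h"]] + 0.85 * (merid_es[, 2L] - p[["h"]])
  analytic <- 100 * (arc(merid_es) - arc(merid)) / arc(merid)
  expect_equal(got, analytic, tolerance = 0.5 / abs(analytic))

  # identity deformation
  expect_equal(as.numeric(directional_strain(tpl, tpl, "LONGITUDINAL", "RV")),
               0)
})

test_that("centerline radial strain matches the annulus closed form", {
  ed <- annulus_phantom(22, 30)                 # thickness 8 mm
  es <- annulus_phantom(21, 31, phase = "ES")   # thickness 10 mm
  fr <- phantom_frame()
  rs <- radial_strain_centerline(ed, es, "LV", frame_ed = fr, frame_es = fr)
  expect_equal(as.numeric(rs), 25, tolerance = 0.04)

  # identical phases give zero
  es0 <- ed; es0$phase <- "ES"
  expect_equal(as.numeric(radial_strain_centerline(ed, es0, "LV",
                                                   frame_ed = fr,
                                                   frame_es = fr)), 0,
               tolerance = 1e-9)

  # thickness halved
  half <- annulus_phantom(24, 28, phase = "ES")  # 8 mm -> 4 mm
  expect_equal(as.numeric(radial_strain_centerline(ed, half, "LV",
                                                   frame_ed = fr,
                                                   frame_es = fr)), -50,
               tolerance = 0.02)

  # the same phantom pair rotated rigidly, with a co-rotated frame
  R <- bivatlas:::rotation_about_axis(c(1, 1, 0), 0.8)
  shift <- c(12, -4, 7)
  rot <- function(s) { s$vertices <- s$vertices %*% t(R) +
    matrix(shift, nrow(s$vertices), 3L, byrow = TRUE); s }
  frr <- list(apex = as.numeric(R %*% c(0, 0, 0)) + shift,
              dir = as.numeric(R %*% c(0, 0, 1)),
              e1 = as.numeric(R %*% c(1, 0, 0)),
              e2 = as.numeric(R %*% c(0, 1, 0)))
  rs_rot <- radial_strain_centerline(rot(ed), rot(es), "LV",
                                     frame_ed = frr, frame_es = frr)
  expect_equal(as.numeric(rs_rot), as.numeric(rs), tolerance = 1e-6)
})

test_that("all six strains recover the wall-conserving template contraction", {
  tpl <- get_template()
  es <- contract_template(tpl)
  s <- compute_strains(tpl, es)
  expect_equal(as.numeric(s$lv_cs), -21, tolerance = 1e-9)   # lambda_c - 1
  expect_equal(as.numeric(s$rv_cs), -16, tolerance = 1e-9)
  expect_lt(s$lv_ls, 0); expect_lt(s$rv_ls, 0)
  expect_gt(s$lv_rs, 0); expect_gt(s$rv_rs, 0)    # thickening wall

  # identity deformation: six exact zeros
  es0 <- tpl; es0$phase <- "ES"
  s0 <- compute_strains(tpl, es0)
  expect_equal(unname(vapply(s0, as.numeric, numeric(1L))), rep(0, 6L))

  # LV-only deformation leaves RV strains at zero
  lvonly <- tpl; lvonly$phase <- "ES"
  lv <- tpl$component %in% c("LV_ENDO", "EPI_LV")
  lvonly$vertices[lv, ] <- 0.9 * lvonly$vertices[lv, ]
  slv <- compute_strains(tpl, lvonly)
  expect_equal(as.numeric(slv$rv_ls), 0)
  expect_equal(as.numeric(slv$rv_cs), 0)
  expect_equal(as.numeric(slv$rv_rs), 0, tolerance = 1e-9)
  expect_lt(slv$lv_cs, -5)
})

test_that("strains are invariant to a common rigid transform", {
  tpl <- get_template()
  es <- contract_template(tpl)
  s0 <- compute_strains(tpl, es)
  R <- bivatlas:::rotation_about_axis(c(0.3, -1, 0.7), 1.1)
  shift <- c(-15, 9, 22)
  s1 <- compute_strains(transform_surface(tpl, R, shift),
                        transform_surface(es, R, shift))
  for (nm in names(s0))
    expect_equal(as.numeric(s1[[nm]]), as.numeric(s0[[nm]]),
                 tolerance = 1e-6)
})

test_that("measured strains track the generator's noise-free references", {
  coh <- get_cohort()
  truth <- compute_true_strains(coh, subjects = 1:4)
  for (i in 1:4) {
    s <- compute_strains(coh$surfaces_ed[[i]], coh$surfaces_es[[i]])
    got <- vapply(s, as.numeric, numeric(1L))
    # arc-length strains: modest noise tolerance; radial strain on a thin
    # noisy wall is intrinsically less stable
    expect_equal(unname(got[c("lv_ls", "rv_ls", "lv_cs", "rv_cs")]),
                 unname(truth[i, c("lv_ls", "rv_ls", "lv_cs", "rv_cs")]),
                 tolerance = 0.25)
    expect_equal(unname(got["lv_rs"]), unname(truth[i, "lv_rs"]),
                 tolerance = 0.5)
    expect_equal(unname(got["rv_rs"]), unname(truth[i, "rv_rs"]),
                 tolerance = 0.8)
  }
})

test_that("strain signs match contracting-ventricle physiology cohort-wide", {
  coh <- get_cohort()
  for (i in c(3L, 30L, 70L)) {
    s <- compute_strains(coh$surfaces_ed[[i]], coh$surfaces_es[[i]])
    expect_lt(s$lv_ls, 0); expect_lt(s$rv_ls, 0)
    expect_lt(s$lv_cs, 0); expect_lt(s$rv_cs, 0)
    expect_gt(s$lv_rs, 0); expect_gt(s$rv_rs, 0)
  }
})
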