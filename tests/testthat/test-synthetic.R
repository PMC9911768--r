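# Template construction, named deformations, and the cohort generator.

test_that("template surfaces are valid, closable, and analytically sized", {
  tpl <- get_template()
  expect_silent(validate_bv_surface(tpl))
  for (comp in c("LV_ENDO", "RV_ENDO", "EPI_LV", "EPI_RV")) {
    cs <- close_surface(tpl, comp)
    e <- unique(t(apply(rbind(cs$triangles[, 1:2], cs$triangles[, 2:3],
                              cs$triangles[, c(3, 1)]), 1L, sort)))
    expect_equal(nrow(cs$vertices) - nrow(e) + nrow(cs$triangles), 2L)
  }
  # all four annulus rings present and pairwise disjoint
  expect_setequal(names(tpl$annuli),
                  c("mitral", "tricuspid", "aortic", "pulmonary"))
  all_ring <- unlist(tpl$annuli)
  expect_equal(anyDuplicated(all_ring), 0L)

  expect_error(generate_template(resolution = c(6L, 12L)), "coarse")
})

test_that("named deformations are local, unit-calibrated, near-orthogonal", {
  tpl <- get_template()
  expect_identical(apply_named_deformation(tpl, "LV_DILATION", 0)$vertices,
                   tpl$vertices)
  expect_error(apply_named_deformation(tpl, "SEPTAL_TWIST", 1), "unknown")

  # pulmonary ring mean radius grows by the magnitude
  ring <- tpl$annuli$pulmonary
  ring_radius <- function(s) {
    ctr <- colMeans(s$vertices[ring, ])
    mean(sqrt(rowSums(sweep(s$vertices[ring, ], 2L, ctr)^2)))
  }
  m <- 2.5
  def <- apply_named_deformation(tpl, "PV_ANNULUS_DILATION", m)
  expect_equal(ring_radius(def) - ring_radius(tpl), m, tolerance = 0.01)

  # LV fields leave RV-only vertices fixed and vice versa
  fl <- deformation_fields(tpl)
  rv_idx <- tpl$component %in% c("RV_ENDO", "EPI_RV")
  lv_idx <- tpl$component %in% c("LV_ENDO", "EPI_LV")
  expect_equal(max(abs(fl$LV_DILATION[rv_idx, ])), 0)
  expect_equal(max(abs(fl$LV_CONICITY[rv_idx, ])), 0)
  expect_equal(max(abs(fl$RV_BASAL_BULGE[lv_idx, ])), 0)

  # pairwise near-orthogonality as 3N vectors
  F3 <- vapply(fl, function(f) bivatlas:::stack_vertices(f),
               numeric(3L * nrow(tpl$vertices)))
  G <- crossprod(F3)
  cosines <- G / sqrt(outer(diag(G), diag(G)))
  expect_lt(max(abs(cosines[upper.tri(cosines)])), 0.2)
})

test_that("cohorts are bit-reproducible from config + seed", {
  cfg <- lowres_config(seed = 31, n_pvr = 5L, n_no_pvr = 4L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$surfaces_ed[[3L]]$vertices,
                   c2$surfaces_ed[[3L]]$vertices)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$ground_truth$coefficients,
                   c2$ground_truth$coefficients)
  c3 <- generate_cohort(lowres_config(seed = 32, n_pvr = 5L, n_no_pvr = 4L))
  expect_false(identical(c1$surfaces_ed[[3L]]$vertices,
                         c3$surfaces_ed[[3L]]$vertices))
})

test_that("config validation rejects malformed inputs", {
  expect_error(cohort_config(), "seed")
  expect_error(cohort_config(seed = 1, n_pvr = 0L), "positive")
  expect_error(cohort_config(seed = 1, noise_sd = -1), "noise_sd")
  bad <- default_planted_modes()
  bad$sd[2L] <- -3
  expect_error(cohort_config(seed = 1, planted = bad), "SD")
})

test_that("a zero-noise single-mode cohort concentrates variance on one mode", {
  planted <- default_planted_modes()[3L, ]
  cfg <- lowres_config(seed = 33, noise_sd = 0, planted = planted,
                       background = list(n_fields = 0L, sd = 0, decay = 1),
                       scale_with_bsa = FALSE)
  coh <- generate_cohort(cfg)
  atlas <- bv_atlas(coh$surfaces_ed)
  expect_gt(atlas$variance_explained[1L], 99.9)
})

test_that("group EF targets surface in the computed indices", {
  coh <- get_cohort()
  ef <- coh$ground_truth$true_ef
  g <- coh$records$group
  expect_lt(mean(ef$rv_ef[g == "PVR"]), mean(ef$rv_ef[g == "NO_PVR"]))
  expect_equal(mean(ef$rv_ef[g == "PVR"]), 37, tolerance = 0.06)
  expect_equal(mean(ef$rv_ef[g == "NO_PVR"]), 42, tolerance = 0.06)
})

test_that("confounder summaries sit inside the published IQR envelopes", {
  coh <- get_cohort()
  rec <- coh$records
  pvr <- rec$group == "PVR"
  # medians within the printed interquartile ranges
  expect_gt(median(rec$time_after_repair[pvr]), 9)
  expect_lt(median(rec$time_after_repair[pvr]), 16)
  expect_gt(median(rec$time_after_repair[!pvr]), 15)
  expect_lt(median(rec$time_after_repair[!pvr]), 26)
  expect_gt(median(rec$height[pvr]), 135)
  expect_lt(median(rec$height[pvr]), 165)
  # means near the printed mean +/- sd summaries
  expect_equal(mean(rec$bsa[pvr]), 1.4, tolerance = 0.1)
  expect_equal(mean(rec$bsa[!pvr]), 1.7, tolerance = 0.1)
  expect_equal(mean(rec$weight[pvr]), 49, tolerance = 0.15)
  expect_true(all(rec$prf >= 20 & rec$prf <= 100))
  expect_true(all(rec$age_at_cmr > rec$age_at_repair))
  # group sizes and symptomatic structure
  expect_equal(sum(pvr), 48L)
  expect_equal(sum(!pvr), 36L)
})

test_that("planted group effects are invisible to first-order cavity volumes", {
  # volume-neutral fields: deforming the template along any planted field
  # changes cavity volumes only at second order
  coh <- get_cohort()
  tpl <- coh$template
  F3 <- coh$ground_truth$fields
  vol <- bivatlas:::make_component_volumer(tpl)
  for (k in seq_len(ncol(F3))) {
    eps <- 0.5
    vplus <- tpl$vertices + eps * bivatlas:::unstack_vertices(F3[, k])
    dv <- abs(vol(vplus, "LV_ENDO") - vol(tpl$vertices, "LV_ENDO")) +
      abs(vol(vplus, "RV_ENDO") - vol(tpl$vertices, "RV_ENDO"))
    expect_lt(dv, 0.25)     # mL; first-order term cancelled
  }
})
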