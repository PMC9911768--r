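# Mesh closing, volume integration, masses, EF and imaging indices.

test_that("close_surface caps rings, passes closed meshes through, rejects seams", {
  hemi <- open_hemisphere()
  closed <- close_surface(hemi)
  expect_equal(closed$n_caps, 1L)
  # Euler characteristic of a sphere
  e <- unique(t(apply(rbind(closed$triangles[, 1:2], closed$triangles[, 2:3],
                            closed$triangles[, c(3, 1)]), 1L, sort)))
  expect_equal(nrow(closed$vertices) - nrow(e) + nrow(closed$triangles), 2L)
  expect_silent(enclosed_volume(closed))

  ico <- icosphere(1L)
  same <- close_surface(ico)
  expect_equal(same$n_caps, 0L)
  expect_identical(same$vertices, ico$vertices)
  expect_identical(same$triangles, ico$triangles)

  # duplicate a boundary triangle with flipped winding: the directed
  # boundary edge appears twice -> no longer a clean union of rings
  bad <- hemi
  extra <- bad$triangles[nrow(bad$triangles), c(1L, 3L, 2L)]
  bad$triangles <- rbind(bad$triangles, extra)
  expect_error(close_surface(bad), "seam|oriented|ring|manifold")
})

test_that("enclosed_volume matches analytic solids and is rigid-invariant", {
  expect_equal(enclosed_volume(unit_cube_mesh()), 0.001, tolerance = 1e-12)

  # icosphere volume converges to 4/3 pi r^3, error monotone in refinement
  errs <- vapply(0:3, function(l) {
    abs(enclosed_volume(icosphere(l)) - 4 / 3 * pi) / (4 / 3 * pi)
  }, numeric(1L))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[4L], 0.01)    # level 3 has 1280 faces

  ico <- icosphere(2L)
  v0 <- enclosed_volume(ico)
  expect_equal(enclosed_volume(rotate_mesh(ico)), v0, tolerance = 1e-9)
  scaled <- ico
  scaled$vertices <- 2 * scaled$vertices
  expect_equal(enclosed_volume(scaled), 8 * v0, tolerance = 1e-12)

  expect_error(enclosed_volume(open_hemisphere()), "not closed")
})

test_that("cavity volumes match the generator's closed forms within 2%", {
  tpl <- get_template()
  vols <- compute_cavity_volumes(tpl)
  ana <- tpl$meta$volumes
  expect_equal(vols$lv, ana$lv_endo / 1000, tolerance = 0.02)
  expect_equal(vols$rv, ana$rv_endo / 1000, tolerance = 0.02)
  expect_equal(vols$epi, (ana$lv_epi + ana$rv_epi) / 1000, tolerance = 0.02)

  scaled <- tpl
  scaled$vertices <- 2 * scaled$vertices
  vols2 <- compute_cavity_volumes(scaled)
  expect_equal(vols2$lv / vols$lv, 8, tolerance = 1e-9)
})

test_that("wall volume is conserved between ED and ES in synthetic pairs", {
  # the planted contraction is wall-conserving; assessed on a noise-free
  # cohort (vertex noise perturbs each closed volume independently)
  coh <- cached("cohort_nonoise",
                generate_cohort(lowres_config(seed = 11, noise_sd = 0)))
  for (i in c(1L, 40L, 84L)) {
    wed <- compute_masses(coh$surfaces_ed[[i]])
    wes <- compute_masses(coh$surfaces_es[[i]])
    total_ed <- wed$lv_wall_volume + wed$rv_wall_volume
    total_es <- wes$lv_wall_volume + wes$rv_wall_volume
    expect_equal(total_es, total_ed, tolerance = 0.02)
  }
})

test_that("masses use myocardial density and reject degenerate walls", {
  tpl <- get_template()
  m <- compute_masses(tpl)
  expect_equal(m$lv_mass, m$lv_wall_volume * 1.05, tolerance = 1e-12)
  expect_equal(m$lv_mass / 1.05, tpl$meta$volumes$lv_wall / 1000,
               tolerance = 0.03)

  # epi collapsed onto endo: zero-thickness wall
  flat <- tpl
  lv_epi <- flat$component == "EPI_LV"
  lv_endo_v <- flat$vertices[flat$component == "LV_ENDO", ]
  # shrink the epi shell to (nearly) the endo surface footprint
  ctr <- colMeans(lv_endo_v)
  flat$vertices[lv_epi, ] <- ctr +
    0.1 * (flat$vertices[lv_epi, ] - matrix(ctr, sum(lv_epi), 3L, byrow = TRUE))
  expect_error(compute_masses(flat), "wall")
  expect_equal(compute_masses(flat, on_zero_thickness = "zero")$lv_mass, 0)
})

test_that("cohort mean LV mass index recovers the generator target within 5%", {
  coh <- get_cohort()
  mi <- vapply(seq_len(84L), function(i) {
    m <- compute_masses(coh$surfaces_ed[[i]])
    m$lv_mass / coh$records$bsa[i]
  }, numeric(1L))
  expect_equal(mean(mi), 75, tolerance = 0.05)
})

test_that("ejection fraction handles standard, derived and degenerate inputs", {
  expect_equal(ejection_fraction(100, 50), 50)
  expect_equal(ejection_fraction(140, 87), 100 * (140 - 87) / 140)
  expect_equal(ejection_fraction(100, 100), 0)
  expect_warning(ef <- ejection_fraction(100, 110), "negative")
  expect_equal(ef, -10)
  expect_error(ejection_fraction(0, 10), "positive")
  expect_error(ejection_fraction(-5, 1), "positive")
})

test_that("BSA indexing divides and validates", {
  expect_equal(index_to_bsa(160, 2), 80)
  expect_equal(index_to_bsa(0, 1.3), 0)
  expect_equal(index_to_bsa(196, 1.4), 140)
  expect_error(index_to_bsa(100, 0), "positive")
})

test_that("imaging indices recover generator EF prescriptions within 2%", {
  coh <- get_cohort()
  for (i in c(2L, 50L)) {
    idx <- compute_imaging_indices(coh$surfaces_ed[[i]], coh$surfaces_es[[i]],
                                   coh$records[i, ])
    expect_length(unlist(idx), 10L)
    expect_equal(idx$lv_ef, coh$ground_truth$true_ef$lv_ef[i], tolerance = 0.04)
    expect_equal(idx$rv_ef, coh$ground_truth$true_ef$rv_ef[i], tolerance = 0.04)
    expect_equal(idx$prvi, coh$records$prvi[i])
  }
})

test_that("identical ED and ES surfaces give zero EF", {
  coh <- get_cohort()
  ed <- coh$surfaces_ed[[1L]]
  es2 <- ed
  es2$phase <- "ES"
  idx <- compute_imaging_indices(ed, es2, coh$records[1L, ])
  expect_equal(idx$lv_ef, 0)
  expect_equal(idx$rv_ef, 0)
})

test_that("imaging indices reject mismatched subjects", {
  coh <- get_cohort()
  expect_error(compute_imaging_indices(coh$surfaces_ed[[1L]],
                                       coh$surfaces_es[[2L]],
                                       coh$records[1L, ]),
               "mismatch")
})

test_that("cohort index means fall inside the published ranges", {
  coh <- get_cohort()
  idx <- t(vapply(seq_len(30L), function(i)
    unlist(compute_imaging_indices(coh$surfaces_ed[[i]], coh$surfaces_es[[i]],
                                   coh$records[i, ])), numeric(10L)))
  expect_gt(mean(idx[, "rv_edvi"]), 100)
  expect_lt(mean(idx[, "rv_edvi"]), 180)
  expect_gt(mean(idx[, "lv_edvi"]), 60)
  expect_lt(mean(idx[, "lv_edvi"]), 100)
  expect_gt(mean(idx[, "rv_ef"]), 25)
  expect_lt(mean(idx[, "rv_ef"]), 55)
})
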