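# Rigid alignment, the shape atlas fit, projection/reconstruction, and the
# cumulative-variance cut.

test_that("rigid_align recovers a known transform exactly", {
  set.seed(3)
  pts <- matrix(rnorm(60, sd = 20), 20L, 3L)
  R <- bivatlas:::rotation_about_axis(c(1, -2, 0.5), 0.9)
  tr <- c(4, -7, 2)
  moved <- pts %*% t(R) + matrix(tr, 20L, 3L, byrow = TRUE)
  al <- rigid_align(moved, pts)
  expect_equal(al$rotation %*% R, diag(3), tolerance = 1e-8)
  expect_lt(sqrt(mean((al$aligned - pts)^2)), 1e-10)

  id <- rigid_align(pts, pts)
  expect_equal(id$rotation, diag(3), tolerance = 1e-10)
  expect_equal(id$translation, c(0, 0, 0), tolerance = 1e-10)

  expect_error(rigid_align(matrix(1, 5L, 3L), matrix(1, 5L, 3L)),
               "degenerate")
})

test_that("noisy rigid alignment matches direct numerical optimization", {
  set.seed(4)
  pts <- matrix(rnorm(45, sd = 15), 15L, 3L)
  R <- bivatlas:::rotation_about_axis(c(0, 1, 1), -0.4)
  noisy <- pts %*% t(R) + matrix(c(2, 1, -3), 15L, 3L, byrow = TRUE) +
    matrix(rnorm(45, sd = 0.8), 15L, 3L)
  al <- rigid_align(noisy, pts)
  rss_kabsch <- sum((al$aligned - pts)^2)
  # independent oracle: numeric minimization over axis-angle + translation
  obj <- function(par) {
    ang <- sqrt(sum(par[1:3]^2))
    Rp <- if (ang < 1e-12) diag(3)
          else bivatlas:::rotation_about_axis(par[1:3] / ang, ang)
    sum((noisy %*% t(Rp) +
           matrix(par[4:6], 15L, 3L, byrow = TRUE) - pts)^2)
  }
  opt <- optim(c(0.01, 0.01, 0.01, 0, 0, 0), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(rss_kabsch, opt$value + 1e-6)
  expect_equal(rss_kabsch, opt$value, tolerance = 1e-5)
})

test_that("atlas on 84 subjects in general position yields 83 modes", {
  coh <- get_cohort()
  atlas <- cached("atlas", bv_atlas(coh$surfaces_ed))
  expect_equal(length(atlas$variances), 83L)
  expect_true(all(diff(atlas$variances) <= 0))
  expect_equal(sum(atlas$variance_explained), 100, tolerance = 1e-9)
  expect_equal(unname(apply(atlas$zscores, 2L, sd)), rep(1, 83L),
               tolerance = 1e-6)
  # orthonormal modes
  gram <- crossprod(atlas$modes[, 1:10])
  expect_equal(gram, diag(10L), tolerance = 1e-8)
})

test_that("a noiseless cohort built from planted orthogonal modes is low-rank", {
  cfg <- lowres_config(seed = 5, noise_sd = 0,
                       background = list(n_fields = 0L, sd = 0, decay = 1),
                       misalign_rot_deg = 5, misalign_trans_mm = 5,
                       scale_with_bsa = FALSE)
  coh <- generate_cohort(cfg)
  atlas <- bv_atlas(coh$surfaces_ed)
  ve <- cumsum(atlas$variance_explained)
  expect_gt(ve[5L], 99.9)
})

test_that("planted eigen-spectrum is recovered within tolerance", {
  # plant five orthonormal modes orthogonal to the rigid-motion tangent
  # space of the template, with decreasing variances, plus small noise
  tpl <- cached("tpl_low", generate_template(resolution = c(8L, 16L)))
  m0 <- bivatlas:::stack_vertices(tpl$vertices)
  n3 <- length(m0); nv <- n3 / 3L
  ctr <- sweep(tpl$vertices, 2L, colMeans(tpl$vertices))
  gens <- list(cbind(0, -ctr[, 3L], ctr[, 2L]),
               cbind(ctr[, 3L], 0, -ctr[, 1L]),
               cbind(-ctr[, 2L], ctr[, 1L], 0))
  rigid <- cbind(
    rep(c(1, 0, 0), nv), rep(c(0, 1, 0), nv), rep(c(0, 0, 1), nv),
    vapply(gens, bivatlas:::stack_vertices, numeric(n3))
  )
  set.seed(21)
  Q <- qr.Q(qr(cbind(rigid, matrix(rnorm(n3 * 5L), n3, 5L))))[, 7:11]
  sds <- c(20, 15, 10, 7, 5)
  S <- 84L
  coefs <- matrix(rnorm(S * 5L, sd = rep(sds, each = S)), S, 5L)
  X <- matrix(m0, S, n3, byrow = TRUE) + tcrossprod(coefs, Q) +
    matrix(rnorm(S * n3, sd = 0.05), S, n3)
  atlas <- bv_atlas(X)
  sample_var <- sort(eigen(cov(coefs), symmetric = TRUE,
                            only.values = TRUE)$values, decreasing = TRUE)
  expect_equal(unname(atlas$variances[1:5]), sample_var, tolerance = 0.1)
  sv <- svd(crossprod(atlas$modes[, 1:5], Q))$d
  angles <- acos(pmin(sv, 1)) * 180 / pi
  expect_lt(max(angles), 5)
})

test_that("projection is consistent with training scores and the mean", {
  coh <- get_cohort()
  atlas <- cached("atlas", bv_atlas(coh$surfaces_ed))
  z <- predict(atlas, coh$surfaces_ed[[13L]])
  expect_equal(as.numeric(z), unname(atlas$zscores[13L, ]), tolerance = 1e-8)

  z0 <- predict(atlas, matrix(atlas$center, 1L))
  expect_lt(max(abs(z0)), 1e-6)

  # rigid transform of the input leaves Z-scores unchanged
  moved <- transform_surface(coh$surfaces_ed[[13L]],
                             bivatlas:::rotation_about_axis(c(2, 1, 1), 0.6),
                             c(-20, 14, 8))
  zm <- predict(atlas, moved)
  expect_equal(as.numeric(zm), as.numeric(z), tolerance = 1e-6)

  small <- coh$surfaces_ed[[1L]]
  small$vertices <- small$vertices[1:10, ]
  small$surface_label <- small$surface_label[1:10]
  small$wall_assignment <- small$wall_assignment[1:10]
  expect_error(predict(atlas, list(small)), "mismatch")
})

test_that("reconstruction inverts projection and is linear in the scores", {
  coh <- get_cohort()
  atlas <- cached("atlas", bv_atlas(coh$surfaces_ed))
  expect_equal(reconstruct_shape(atlas, numeric(83L)), atlas$center)

  # mean + 2 SD along mode 4 projects back to z4 = 2
  z <- numeric(83L); z[4L] <- 2
  shape <- reconstruct_shape(atlas, z)
  zz <- predict(atlas, matrix(shape, 1L))
  expect_equal(as.numeric(zz), z, tolerance = 1e-6)

  # full-rank project-then-reconstruct returns the aligned training shape
  al <- rigid_align(unstacked <- matrix(coh$surfaces_ed[[5L]]$vertices,
                                        ncol = 3L),
                    matrix(atlas$mean_shape, ncol = 3L, byrow = TRUE))
  rec <- reconstruct_shape(atlas, unname(atlas$zscores[5L, ]))
  expect_equal(max(abs(rec - bivatlas:::stack_vertices(al$aligned))), 0,
               tolerance = 1e-6)

  # plus/minus excursions average to the mean
  zp <- numeric(83L); zp[7L] <- 2
  zm <- numeric(83L); zm[7L] <- -2
  avg <- (reconstruct_shape(atlas, zp) + reconstruct_shape(atlas, zm)) / 2
  expect_equal(avg, atlas$center, tolerance = 1e-9)

  expect_error(reconstruct_shape(atlas, numeric(90L), 90L), "between")
})

test_that("atlas is invariant to rigid transforms of every input", {
  cfg <- lowres_config(seed = 12, n_pvr = 8L, n_no_pvr = 6L)
  coh <- generate_cohort(cfg)
  a1 <- bv_atlas(coh$surfaces_ed)
  set.seed(99)
  moved <- lapply(coh$surfaces_ed, function(s)
    transform_surface(s, bivatlas:::random_rotation(30),
                      runif(3L, -30, 30)))
  a2 <- bv_atlas(moved)
  expect_equal(abs(a2$zscores), abs(a1$zscores), tolerance = 1e-5)
  expect_equal(a2$variances, a1$variances, tolerance = 1e-6)
})

test_that("atlas requires at least three subjects", {
  coh <- get_cohort()
  expect_error(bv_atlas(coh$surfaces_ed[1:2]), "at least 3")
})

test_that("cumulative variance cut returns the smallest exceeding prefix", {
  fake <- structure(list(variance_explained = c(60, 30, 6, 4)),
                    class = "bv_atlas")
  expect_equal(cumulative_variance_cut(fake, 95), 1:3)
  expect_equal(cumulative_variance_cut(fake, 100), 1:4)

  coh <- get_cohort()
  atlas <- cached("atlas", bv_atlas(coh$surfaces_ed))
  got <- cumulative_variance_cut(atlas, 95)
  # brute-force prefix scan oracle
  cum <- 0; k <- 0
  for (v in atlas$variance_explained) {
    k <- k + 1; cum <- cum + v
    if (cum > 95) break
  }
  expect_equal(got, seq_len(k))
})

test_that("simulate and residuals behave like a generative PCA model", {
  coh <- get_cohort()
  atlas <- cached("atlas", bv_atlas(coh$surfaces_ed))
  sims <- simulate(atlas, nsim = 3L, seed = 2)
  expect_equal(dim(sims), c(3L, length(atlas$center)))
  res_full <- residuals(atlas)
  expect_lt(max(res_full), 1e-8)
  res_10 <- residuals(atlas, n_modes = 10L)
  expect_true(all(res_10 >= 0))
  expect_gt(mean(res_10), mean(res_full))
})
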