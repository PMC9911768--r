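#' Least-squares rigid alignment of corresponded point sets
#'
#' Finds the rotation (determinant +1, no scaling or reflection) and
#' translation minimizing the mean squared distance between corresponded
#' points (Kabsch solution via SVD of the cross-covariance).
#'
#' @param points,reference N x 3 matrices with row correspondence.
#' @return list with `aligned` (N x 3), `rotation` (3 x 3) and
#'   `translation` (length 3), such that
#'   `aligned = points %*% t(rotation) + translation`.
#' @export
rigid_align <- function(points, reference) {
  points <- as.matrix(points); reference <- as.matrix(reference)
  if (!identical(dim(points), dim(reference)))
    stop_bv("points and reference must have identical dimensions")
  cp <- colMeans(points); cr <- colMeans(reference)
  P <- sweep(points, 2L, cp); Q <- sweep(reference, 2L, cr)
  H <- crossprod(P, Q)
  sv <- svd(H)
  if (sv$d[2L] < 1e-12 * max(sv$d[1L], 1e-300))
    stop_bv("degenerate point set: all points coincident or collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cr - as.numeric(R %*% cp)
  list(aligned = apply_rigid(points, R, tr), rotation = R, translation = tr)
}

# Coerce atlas inputs (list of bv_surface or an S x 3N matrix) to a matrix
# of stacked coordinate rows plus subject ids.
as_shape_matrix <- function(surfaces) {
  if (is.matrix(surfaces))
    return(list(x = surfaces,
                ids = rownames(surfaces) %||% sprintf("S%03d", seq_len(nrow(surfaces)))))
  if (!is.list(surfaces) || !all(vapply(surfaces, inherits, logical(1L), "bv_surface")))
    stop_bv("surfaces must be a list of bv_surface objects or an S x 3N matrix")
  nv <- vapply(surfaces, function(s) nrow(s$vertices), integer(1L))
  if (length(unique(nv)) != 1L)
    stop_bv("all surfaces must have the same vertex count (point correspondence)")
  x <- t(vapply(surfaces, function(s) stack_vertices(s$vertices),
                numeric(3L * nv[1L])))
  ids <- vapply(surfaces, function(s) s$subject_id, character(1L))
  list(x = x, ids = ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a statistical shape atlas by generalized alignment and PCA
#'
#' Iteratively aligns every subject's corresponded ED surface points to
#' the evolving population mean by rigid registration (no scaling; heart
#' size stays in the model and BSA is handled downstream as a regression
#' covariate), then performs principal component analysis on the stacked,
#' mean-centered coordinate vectors. Each retained mode is an orthonormal
#' 3N-vector; a subject's Z-score on a mode is its projection divided by
#' the mode's population SD, so Z-score columns have unit sample SD over
#' the training cohort.
#'
#' @param surfaces list of [bv_surface()] objects in point correspondence
#'   (at least 3), or an S x 3N matrix of stacked coordinates.
#' @param max_iter maximum generalized-alignment iterations.
#' @param tol convergence tolerance on the mean vertex displacement of the
#'   mean shape between iterations (mm).
#' @param degenerate_tol relative eigenvalue threshold below which a mode
#'   is dropped as degenerate (fraction of the leading eigenvalue).
#' @return an object of class `bv_atlas` with elements `mean_shape`
#'   (3N vector, the alignment target), `center` (3N vector, the PCA
#'   mean of the aligned data), `modes` (3N x M orthonormal matrix),
#'   `variances` (M eigenvalues, mm^2, non-increasing),
#'   `variance_explained` (percentages summing to 100), `zscores`
#'   (S x M), `subject_ids`, `n_vertices` and `convergence`.
#' @seealso [predict.bv_atlas()], [reconstruct_shape()],
#'   [cumulative_variance_cut()], [rank_modes_chi2()]
#' @export
bv_atlas <- function(surfaces, max_iter = 20L, tol = 1e-6,
                     degenerate_tol = 1e-10) {
  sm <- as_shape_matrix(surfaces)
  x <- sm$x
  S <- nrow(x)
  if (S < 3L) stop_bv("an atlas needs at least 3 subjects")
  nv <- ncol(x) / 3L

  ref <- x[1L, ]
  converged <- FALSE; change <- NA_real_; it <- 0L
  aligned <- x
  for (it in seq_len(max_iter)) {
    for (i in seq_len(S))
      aligned[i, ] <- stack_vertices(
        rigid_align(unstack_vertices(x[i, ]), unstack_vertices(ref))$aligned)
    new_ref <- colMeans(aligned)
    change <- mean(sqrt(rowSums(unstack_vertices(new_ref - ref)^2)))
    ref <- new_ref
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("generalized alignment did not converge after ", max_iter,
            " iterations (last mean change ", format(change, digits = 3),
            " mm); using last iterate")
  # final consistent pass: every training row aligned to the final mean,
  # so projecting a training surface reproduces its stored Z-scores
  for (i in seq_len(S))
    aligned[i, ] <- stack_vertices(
      rigid_align(unstack_vertices(x[i, ]), unstack_vertices(ref))$aligned)
  center <- colMeans(aligned)
  xc <- sweep(aligned, 2L, center)

  sv <- svd(xc, nu = S, nv = min(S, ncol(xc)))
  ev <- sv$d^2 / (S - 1)
  keep <- which(ev > degenerate_tol * ev[1L])
  modes <- sv$v[, keep, drop = FALSE]
  u <- sv$u[, keep, drop = FALSE]
  # deterministic sign: largest-magnitude coordinate of each mode positive
  for (m in seq_along(keep)) {
    j <- which.max(abs(modes[, m]))
    if (modes[j, m] < 0) { modes[, m] <- -modes[, m]; u[, m] <- -u[, m] }
  }
  zsc <- u * sqrt(S - 1)
  rownames(zsc) <- sm$ids
  colnames(zsc) <- paste0("ED", seq_along(keep))
  variances <- ev[keep]
  structure(list(
    mean_shape = ref, center = center, modes = modes,
    variances = variances,
    variance_explained = 100 * variances / sum(variances),
    zscores = zsc, subject_ids = sm$ids, n_vertices = as.integer(nv),
    convergence = list(iterations = it, converged = converged,
                       last_change = change),
    call = match.call()
  ), class = "bv_atlas")
}

#' @export
print.bv_atlas <- function(x, ...) {
  cat("Biventricular shape atlas (PCA after generalized rigid alignment)\n")
  cat("  subjects:", length(x$subject_ids), "  vertices:", x$n_vertices,
      "  modes:", length(x$variances), "\n")
  ve <- cumsum(x$variance_explained)
  cat(sprintf("  variance explained: mode 1 %.1f%%; %d modes to exceed 95%%\n",
              x$variance_explained[1L], which(ve > 95)[1L]))
  cat("  alignment:",
      if (x$convergence$converged) sprintf("converged in %d iterations",
                                           x$convergence$iterations)
      else "NOT converged", "\n")
  invisible(x)
}

#' @export
summary.bv_atlas <- function(object, n_modes = 10L, ...) {
  n_modes <- min(n_modes, length(object$variances))
  tab <- data.frame(
    mode = colnames(object$zscores)[seq_len(n_modes)],
    variance = object$variances[seq_len(n_modes)],
    pct_explained = object$variance_explained[seq_len(n_modes)],
    cumulative_pct = cumsum(object$variance_explained)[seq_len(n_modes)]
  )
  structure(list(table = tab, n_subjects = length(object$subject_ids),
                 n_modes = length(object$variances),
                 convergence = object$convergence),
            class = "summary.bv_atlas")
}

#' @export
print.summary.bv_atlas <- function(x, ...) {
  cat("Shape atlas:", x$n_subjects, "subjects,", x$n_modes,
      "non-degenerate modes\n\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Project surfaces onto atlas modes as Z-scores
#'
#' Rigidly aligns each surface to the atlas mean, subtracts the mean,
#' projects onto the orthonormal modes and divides by each mode's
#' population SD. Z-scores are invariant to any rigid transform of the
#' input surface.
#'
#' @param object a [bv_atlas()].
#' @param newdata a [bv_surface()], a list of them, or an S x 3N matrix.
#' @param ... unused.
#' @return an S x M matrix of Z-scores (one row for a single surface).
#' @export
predict.bv_atlas <- function(object, newdata, ...) {
  if (inherits(newdata, "bv_surface")) newdata <- list(newdata)
  sm <- as_shape_matrix(newdata)
  if (ncol(sm$x) != length(object$mean_shape))
    stop_bv("vertex count mismatch: atlas has ", object$n_vertices,
            " vertices, input has ", ncol(sm$x) / 3L)
  ref <- unstack_vertices(object$mean_shape)
  out <- matrix(0, nrow(sm$x), length(object$variances),
                dimnames = list(sm$ids, colnames(object$zscores)))
  for (i in seq_len(nrow(sm$x))) {
    al <- stack_vertices(rigid_align(unstack_vertices(sm$x[i, ]), ref)$aligned)
    out[i, ] <- as.numeric(crossprod(object$modes, al - object$center)) /
      sqrt(object$variances)
  }
  out
}

#' @describeIn predict.bv_atlas alias taking the atlas first:
#'   `project_zscores(atlas, surface)`.
#' @param atlas a [bv_atlas()].
#' @param surface a [bv_surface()], list of surfaces, or coordinate matrix.
#' @export
project_zscores <- function(atlas, surface) predict(atlas, surface)

#' Reconstruct a shape from atlas Z-scores
#'
#' `mean + sum(z_m * sd_m * mode_m)` over the first `n_modes` modes; all
#' Z-scores zero returns the mean shape.
#'
#' @param atlas a [bv_atlas()].
#' @param zscores numeric vector of Z-scores (recycled/truncated to
#'   `n_modes` entries must not be needed: length must equal `n_modes`).
#' @param n_modes number of leading modes to use.
#' @return a 3N coordinate vector.
#' @export
reconstruct_shape <- function(atlas, zscores, n_modes = length(zscores)) {
  M <- length(atlas$variances)
  if (n_modes < 0L || n_modes > M)
    stop_bv("n_modes must be between 0 and ", M)
  if (length(zscores) != n_modes)
    stop_bv("need exactly n_modes = ", n_modes, " zscores")
  if (n_modes == 0L) return(atlas$center)
  atlas$center + as.numeric(
    atlas$modes[, seq_len(n_modes), drop = FALSE] %*%
      (zscores * sqrt(atlas$variances[seq_len(n_modes)])))
}

#' @export
residuals.bv_atlas <- function(object, n_modes = length(object$variances), ...) {
  recon <- tcrossprod(object$zscores[, seq_len(n_modes), drop = FALSE] %*%
                        diag(sqrt(object$variances[seq_len(n_modes)]),
                             n_modes, n_modes),
                      object$modes[, seq_len(n_modes), drop = FALSE])
  full <- tcrossprod(object$zscores %*%
                       diag(sqrt(object$variances),
                            length(object$variances), length(object$variances)),
                     object$modes)
  res <- full - recon
  rms <- sqrt(rowSums(res^2) / object$n_vertices)
  names(rms) <- object$subject_ids
  rms
}

#' @export
coef.bv_atlas <- function(object, ...) object$zscores

#' Sample new shapes from the atlas model
#'
#' Draws independent standard-normal Z-scores for every mode and
#' reconstructs the corresponding surfaces, i.e. samples from the
#' multivariate normal shape distribution the PCA model defines.
#'
#' @param object a [bv_atlas()].
#' @param nsim number of shapes.
#' @param seed optional seed.
#' @param ... unused.
#' @return `nsim` x 3N matrix of stacked coordinates.
#' @export
simulate.bv_atlas <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  M <- length(object$variances)
  z <- matrix(stats::rnorm(nsim * M), nsim, M)
  out <- t(apply(z, 1L, function(zi) reconstruct_shape(object, zi, M)))
  rownames(out) <- sprintf("sim%03d", seq_len(nsim))
  out
}

#' Scree plot of a shape atlas
#'
#' Bars show the percent variance explained per mode, the line its
#' cumulative sum, with the 95% threshold marked.
#'
#' @param x a [bv_atlas()].
#' @param n_modes number of leading modes to display.
#' @param threshold cumulative-variance reference line (%).
#' @param ... passed to [graphics::barplot()].
#' @export
plot.bv_atlas <- function(x, n_modes = min(35L, length(x$variances)),
                          threshold = 95, ...) {
  ve <- x$variance_explained[seq_len(n_modes)]
  cum <- cumsum(x$variance_explained)[seq_len(n_modes)]
  bp <- graphics::barplot(ve, names.arg = seq_len(n_modes),
                          xlab = "Shape mode", ylab = "Variance explained (%)",
                          ylim = c(0, 100), ...)
  graphics::lines(bp, cum, type = "b", pch = 16, cex = 0.6)
  graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

#' Modes cumulatively explaining more than a variance threshold
#'
#' Returns the smallest prefix of modes whose cumulative variance
#' explained exceeds `threshold` percent — the candidate set for
#' chi-square mode ranking.
#'
#' @param atlas a [bv_atlas()].
#' @param threshold percent of total shape variance (default 95).
#' @return integer vector of mode indices `1:k`.
#' @export
cumulative_variance_cut <- function(atlas, threshold = 95) {
  cum <- cumsum(atlas$variance_explained)
  k <- which(cum > threshold)[1L]
  if (is.na(k)) k <- length(cum)
  seq_len(k)
}
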