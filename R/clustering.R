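# Cosine k-means discrimination of PVR status, matching-matrix scoring,
# and the threshold-criteria comparator.

#' K-means clustering with the cosine distance
#'
#' Lloyd iterations under distance `1 - cos(x, c)`: subjects are assigned
#' to the centroid of highest cosine similarity and centroids are the
#' renormalized means of their members (spherical k-means). The cosine
#' metric ignores the absolute sizes of the feature vectors and considers
#' only their relative sizes. The best of `n_restarts` random
#' initializations by within-cluster cosine inertia is returned;
#' deterministic given `seed`.
#'
#' @param features S x F numeric matrix, F >= 2, typically z-normalized
#'   columns; no row may have zero norm.
#' @param k number of clusters (default 2).
#' @param n_restarts random restarts (default 50).
#' @param seed integer seed (mandatory for reproducibility).
#' @param max_iter Lloyd iteration cap per restart.
#' @return object of class `cosine_kmeans`: list with `cluster` (length-S
#'   integer labels), `centroids` (k x F, unit rows), `inertia` (sum of
#'   `1 - cos` to own centroid), `iterations`.
#' @export
kmeans_cosine <- function(features, k = 2L, n_restarts = 50L, seed,
                          max_iter = 100L) {
  features <- as.matrix(features)
  if (missing(seed) || !is_number(seed)) stop_bv("an integer seed is mandatory")
  S <- nrow(features)
  if (ncol(features) < 2L)
    stop_bv("at least two feature variables are required")
  if (S < k) stop_bv("fewer subjects than clusters")
  nrm <- sqrt(rowSums(features^2))
  if (any(nrm < 1e-12))
    stop_bv("zero-norm feature row(s): ",
            paste(which(nrm < 1e-12), collapse = ", "))
  xu <- features / nrm
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    cen <- xu[sample.int(S, k), , drop = FALSE]
    assign_old <- integer(S)
    for (it in seq_len(max_iter)) {
      sim <- xu %*% t(cen)
      assignment <- max.col(sim, ties.method = "first")
      # re-seed an emptied centroid at the point farthest from its centroid
      for (j in seq_len(k)) {
        if (!any(assignment == j)) {
          far <- which.min(sim[cbind(seq_len(S), assignment)])
          assignment[far] <- j
        }
      }
      if (identical(assignment, assign_old)) break
      assign_old <- assignment
      for (j in seq_len(k)) {
        mj <- colMeans(xu[assignment == j, , drop = FALSE])
        nj <- sqrt(sum(mj^2))
        if (nj < 1e-12) mj <- xu[sample.int(S, 1L), ] else mj <- mj / nj
        cen[j, ] <- mj
      }
    }
    inertia <- sum(1 - (xu %*% t(cen))[cbind(seq_len(S), assignment)])
    if (is.null(best) || inertia < best$inertia - 1e-12)
      best <- list(cluster = assignment, centroids = cen, inertia = inertia,
                   iterations = it)
  }
  structure(best, class = "cosine_kmeans")
}

#' @export
print.cosine_kmeans <- function(x, ...) {
  cat("Cosine k-means:", length(unique(x$cluster)), "clusters, sizes",
      paste(tabulate(x$cluster), collapse = "/"),
      sprintf("(inertia %.4f)\n", x$inertia))
  invisible(x)
}

#' Matching matrix between two clusters and the true cohorts
#'
#' The predicted class of each cluster is its dominant cohort; a tied
#' cluster takes the assignment that maximizes the MCC (then PVR). Counts
#' are tabulated with PVR as the positive class. If both clusters share a
#' majority class the prediction is degenerate (single-class) and flagged.
#'
#' @param cluster_labels integer labels from a 2-cluster solution.
#' @param true_groups vector with values `"PVR"` / `"NO_PVR"`.
#' @return object of class `matching_matrix`: list with counts `tp`, `fn`,
#'   `fp`, `tn`, the per-cluster predicted class, and `degenerate`.
#' @export
match_clusters <- function(cluster_labels, true_groups) {
  cl <- as.integer(factor(cluster_labels))
  ks <- sort(unique(cl))
  if (length(ks) != 2L) stop_bv("exactly two non-empty clusters are required")
  grp <- as.character(true_groups)
  if (!all(grp %in% c("PVR", "NO_PVR")))
    stop_bv("true_groups must be 'PVR' or 'NO_PVR'")
  counts <- lapply(ks, function(j) table(factor(grp[cl == j],
                                                levels = c("PVR", "NO_PVR"))))
  choices <- lapply(counts, function(tt) {
    if (tt["PVR"] > tt["NO_PVR"]) "PVR"
    else if (tt["PVR"] < tt["NO_PVR"]) "NO_PVR"
    else c("PVR", "NO_PVR")        # tie: resolved below by MCC, then PVR
  })
  combos <- expand.grid(c1 = choices[[1L]], c2 = choices[[2L]],
                        stringsAsFactors = FALSE)
  tabulate_mm <- function(pred_class) {
    pred <- pred_class[cl]
    list(tp = sum(pred == "PVR" & grp == "PVR"),
         fn = sum(pred == "NO_PVR" & grp == "PVR"),
         fp = sum(pred == "PVR" & grp == "NO_PVR"),
         tn = sum(pred == "NO_PVR" & grp == "NO_PVR"))
  }
  best <- NULL
  for (i in seq_len(nrow(combos))) {
    cls <- c(combos$c1[i], combos$c2[i])
    m <- tabulate_mm(cls)
    m$cluster_class <- cls
    score <- mcc(m)
    pvr_pref <- sum(cls == "PVR")
    key <- c(score, pvr_pref)
    if (is.null(best) || key[1L] > best_key[1L] + 1e-12 ||
        (abs(key[1L] - best_key[1L]) <= 1e-12 && key[2L] > best_key[2L])) {
      best <- m; best_key <- key
    }
  }
  best$degenerate <- length(unique(best$cluster_class)) == 1L
  structure(best, class = "matching_matrix")
}

#' @export
print.matching_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2L, 2L, byrow = TRUE,
              dimnames = list(actual = c("PVR", "NO_PVR"),
                              predicted = c("PVR", "NO_PVR")))
  print(m)
  cat(sprintf("MCC %.3f", mcc(x)))
  if (x$degenerate) cat("  [degenerate: single-class prediction]")
  cat("\n")
  invisible(x)
}

#' Matthews correlation coefficient of a matching matrix
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, defined as 0
#' when any marginal factor vanishes.
#'
#' @param m a [match_clusters()] result, or any list with `tp`, `fn`,
#'   `fp`, `tn`.
#' @return value in `[-1, 1]`.
#' @export
mcc <- function(m) {
  tp <- m$tp; tn <- m$tn; fp <- m$fp; fn <- m$fn
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Sensitivity and specificity of a matching matrix
#'
#' @param m as for [mcc()].
#' @return list with `sensitivity` (`tp/(tp+fn)`) and `specificity`
#'   (`tn/(tn+fp)`); `NA` with attribute `undefined` when a denominator
#'   is zero.
#' @export
sensitivity_specificity <- function(m) {
  sens <- if (m$tp + m$fn == 0) NA_real_ else m$tp / (m$tp + m$fn)
  spec <- if (m$tn + m$fp == 0) NA_real_ else m$tn / (m$tn + m$fp)
  out <- list(sensitivity = sens, specificity = spec)
  if (anyNA(c(sens, spec))) attr(out, "undefined") <- TRUE
  out
}

#' Threshold-criteria PVR classifier
#'
#' Deterministic comparator patterned on published volumetric referral
#' criteria: counts how many of four thresholds are met (RV EDVi and RV
#' ESVi above, RV EF and LV EF below their cutoffs) and predicts PVR when
#' the count reaches the requirement, which is lower for symptomatic
#' subjects. The EF cutoffs and count rules are configuration values, not
#' quantities estimated by this package.
#'
#' @param indices an [compute_imaging_indices()] result or named list with
#'   `rv_edvi`, `rv_esvi`, `rv_ef`, `lv_ef`.
#' @param symptomatic logical.
#' @param thresholds list with `rv_edvi` (mL/m^2, default 160), `rv_esvi`
#'   (default 80), `rv_ef` (%, default 47), `lv_ef` (default 55),
#'   `n_asymptomatic` (default 2), `n_symptomatic` (default 1).
#' @return `"PVR"` or `"NO_PVR"`.
#' @export
criteria_classify <- function(indices, symptomatic,
                              thresholds = list(rv_edvi = 160, rv_esvi = 80,
                                                rv_ef = 47, lv_ef = 55,
                                                n_asymptomatic = 2L,
                                                n_symptomatic = 1L)) {
  need <- c("rv_edvi", "rv_esvi", "rv_ef", "lv_ef")
  have <- unlist(indices[need])
  if (length(have) != 4L || anyNA(have))
    stop_bv("indices must provide ", paste(need, collapse = ", "))
  n_met <- sum(have["rv_edvi"] > thresholds$rv_edvi,
               have["rv_esvi"] > thresholds$rv_esvi,
               have["rv_ef"] < thresholds$rv_ef,
               have["lv_ef"] < thresholds$lv_ef)
  required <- if (isTRUE(symptomatic)) thresholds$n_symptomatic
              else thresholds$n_asymptomatic
  if (n_met >= required) "PVR" else "NO_PVR"
}
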