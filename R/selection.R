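# Chi-square ranking of candidate shape modes for predicting PVR status.

#' Rank shape modes by chi-square association with a binary label
#'
#' Univariate feature ranking for classification: each candidate mode's
#' Z-scores are discretized into quantile bins, a Pearson chi-square test
#' of the bin-by-label contingency table is computed (bins with zero
#' marginal count are merged away), and modes are ranked by the importance
#' score `-log10(p)`. Ties are broken deterministically in favour of the
#' lower mode index.
#'
#' @param zscores S x M matrix of per-subject mode Z-scores
#'   (see [bv_atlas()]).
#' @param labels binary group labels, length S (factor, character or
#'   logical; exactly two observed levels).
#' @param candidates integer vector of candidate mode indices (default:
#'   all columns).
#' @param n_bins number of quantile bins for discretization.
#' @return object of class `mode_ranking`: list with `candidates`,
#'   `importance` (named by mode index, `-log10(p)`), `p_values`, and
#'   `rank` (candidate indices sorted by decreasing importance).
#' @export
rank_modes_chi2 <- function(zscores, labels, candidates = NULL, n_bins = 10L) {
  zscores <- as.matrix(zscores)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop_bv("labels must have exactly two observed levels")
  if (length(labels) != nrow(zscores))
    stop_bv("labels length must match the number of subjects")
  if (is.null(candidates)) candidates <- seq_len(ncol(zscores))
  if (length(candidates) == 0L) stop_bv("candidates must be non-empty")
  p_values <- vapply(candidates, function(m) {
    x <- zscores[, m]
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                                 type = 7, names = FALSE))
    if (length(br) < 2L) {
      warning("mode ", m, " has constant scores; importance set to 0")
      return(1)
    }
    bins <- cut(x, breaks = br, include.lowest = TRUE)
    tab <- table(bins, labels)
    tab <- tab[rowSums(tab) > 0L, , drop = FALSE]
    if (nrow(tab) < 2L) {
      warning("mode ", m, " collapses to a single bin; importance set to 0")
      return(1)
    }
    chi2_contingency_test(tab)$p
  }, numeric(1L))
  importance <- -log10(pmax(p_values, .Machine$double.xmin))
  ord <- order(-importance, candidates)
  structure(list(candidates = candidates,
                 importance = stats::setNames(importance, candidates),
                 p_values = stats::setNames(p_values, candidates),
                 rank = candidates[ord]),
            class = "mode_ranking")
}

#' @export
print.mode_ranking <- function(x, n = 10L, ...) {
  cat("Chi-square mode ranking (", length(x$candidates), " candidates)\n",
      sep = "")
  n <- min(n, length(x$rank))
  top <- x$rank[seq_len(n)]
  tab <- data.frame(rank = seq_len(n), mode = top,
                    importance = round(x$importance[as.character(top)], 3),
                    p = signif(x$p_values[as.character(top)], 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Select the top-k modes from a chi-square ranking
#'
#' @param ranking a [rank_modes_chi2()] result.
#' @param k number of modes to retain (default 10, matching the number of
#'   standard imaging indices).
#' @return integer vector of the k highest-importance mode indices.
#' @export
select_top_modes <- function(ranking, k = 10L) {
  if (!inherits(ranking, "mode_ranking")) stop_bv("ranking must be a mode_ranking")
  if (k > length(ranking$candidates))
    stop_bv("k = ", k, " exceeds the ", length(ranking$candidates),
            " candidate modes")
  if (k < 1L) stop_bv("k must be at least 1")
  ranking$rank[seq_len(k)]
}
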