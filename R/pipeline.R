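# End-to-end study replica: imaging indices -> shape atlas -> chi-square
# mode subset -> confounder-adjusted associations -> feature retention ->
# cosine k-means discrimination (full cohort, asymptomatic subset,
# threshold-criteria comparator) -> geometric strain summary/regressions.

# matching matrix from per-subject predictions (for the criteria
# comparator, where no clustering is involved)
mm_from_predictions <- function(pred, actual) {
  structure(list(
    tp = sum(pred == "PVR" & actual == "PVR"),
    fn = sum(pred == "NO_PVR" & actual == "PVR"),
    fp = sum(pred == "PVR" & actual == "NO_PVR"),
    tn = sum(pred == "NO_PVR" & actual == "NO_PVR"),
    cluster_class = NULL, degenerate = FALSE
  ), class = "matching_matrix")
}

cluster_and_score <- function(features, groups, seed, n_restarts) {
  km <- kmeans_cosine(scale(features), k = 2L, n_restarts = n_restarts,
                      seed = seed)
  m <- match_clusters(km$cluster, groups)
  ss <- sensitivity_specificity(m)
  list(kmeans = km, matrix = m, mcc = mcc(m),
       sensitivity = ss$sensitivity, specificity = ss$specificity)
}

#' Run the full biventricular shape-atlas analysis
#'
#' Executes the study stages in order: the ten standard imaging indices
#' per subject; the ED shape atlas with the 95% cumulative-variance cut,
#' chi-square mode ranking and top-10 retention; confounder-adjusted
#' associations of both feature sets with PVR status; retention of
#' features significant at `alpha` for clustering (padded with the
#' next-lowest-p feature so each set keeps the minimum two variables);
#' cosine k-means discrimination scored by matching matrix and MCC, on the
#' full cohort and on the asymptomatic subset, plus the threshold-criteria
#' comparator; and the geometric strain summary with univariate
#' strain-feature regressions.
#'
#' @param cohort a [generate_cohort()] result, a [cohort_config()] (the
#'   cohort is generated first), or a list with `surfaces_ed`,
#'   `surfaces_es`, `records`.
#' @param seed seed for the clustering restarts (defaults to the cohort
#'   config seed, else 1).
#' @param stages subset of
#'   `c("indices", "atlas", "associations", "clustering", "strain")`;
#'   later stages require the earlier ones they consume.
#' @param k_modes shape-mode feature-set size (default 10, the number of
#'   imaging indices).
#' @param alpha significance level for feature retention.
#' @param cluster_restarts k-means restarts.
#' @param variance_threshold cumulative-variance cut (%) for candidate
#'   modes.
#' @param ... passed to [compute_strains()] (slice/station resolution).
#' @return an object of class `pvr_report`; see [print.pvr_report()].
#' @export
run_pipeline <- function(cohort, seed = NULL,
                         stages = c("indices", "atlas", "associations",
                                    "clustering", "strain"),
                         k_modes = 10L, alpha = 0.05,
                         cluster_restarts = 50L,
                         variance_threshold = 95, ...) {
  t_start <- Sys.time()
  if (inherits(cohort, "cohort_config")) cohort <- generate_cohort(cohort)
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(seed)) seed <- cohort$config$seed %||% 1L
  records <- cohort$records
  groups <- records$group
  n <- nrow(records)
  notes <- character(0)
  timings <- c()
  report <- list(seed = seed, stages = stages, n_subjects = n,
                 config = cohort$config,
                 versions = list(r = R.version.string,
                                 bivatlas = tryCatch(
                                   as.character(utils::packageVersion("bivatlas")),
                                   error = function(e) "dev")))
  tick <- function(stage) {
    timings[[stage]] <<- as.numeric(Sys.time()) - as.numeric(t_last)
    t_last <<- Sys.time()
  }
  t_last <- Sys.time()

  # ---- cohort summary (always) ------------------------------------------
  cont_vars <- c("age_at_repair", "age_at_cmr", "time_after_repair",
                 "height", "weight", "bsa", "prvi", "prf")
  cohort_summary <- do.call(rbind, lapply(cont_vars, function(v) {
    cg <- compare_groups(records[[v]], groups)
    data.frame(variable = v,
               pvr_mean = mean(records[[v]][groups == "PVR"]),
               pvr_sd = stats::sd(records[[v]][groups == "PVR"]),
               no_pvr_mean = mean(records[[v]][groups == "NO_PVR"]),
               no_pvr_sd = stats::sd(records[[v]][groups == "NO_PVR"]),
               test = cg$test_name, p = cg$p)
  }))
  sex_tab <- table(records$sex, groups)
  repair_tab <- table(factor(records$repair_type, levels = REPAIR_TYPES),
                      groups)
  repair_tab <- repair_tab[rowSums(repair_tab) > 0L, , drop = FALSE]
  categorical <- list(
    sex = list(table = sex_tab, p = chi2_contingency_test(sex_tab)$p),
    repair_type = list(table = repair_tab,
                       p = chi2_contingency_test(repair_tab)$p)
  )
  report$cohort_summary <- cohort_summary
  report$categorical <- categorical
  tick("summary")

  # ---- imaging indices ---------------------------------------------------
  if ("indices" %in% stages) {
    idx <- t(vapply(seq_len(n), function(i)
      unlist(compute_imaging_indices(cohort$surfaces_ed[[i]],
                                     cohort$surfaces_es[[i]],
                                     records[i, ])),
      numeric(10L)))
    rownames(idx) <- records$subject_id
    report$indices <- idx
    report$index_summary <- do.call(rbind, lapply(colnames(idx), function(v) {
      cg <- compare_groups(idx[, v], groups)
      data.frame(index = v,
                 pvr_mean = mean(idx[groups == "PVR", v]),
                 pvr_sd = stats::sd(idx[groups == "PVR", v]),
                 no_pvr_mean = mean(idx[groups == "NO_PVR", v]),
                 no_pvr_sd = stats::sd(idx[groups == "NO_PVR", v]),
                 test = cg$test_name, p = cg$p)
    }))
    tick("indices")
  }

  # ---- atlas + mode subset ----------------------------------------------
  if ("atlas" %in% stages) {
    atlas <- bv_atlas(cohort$surfaces_ed)
    candidates <- cumulative_variance_cut(atlas, variance_threshold)
    ranking <- rank_modes_chi2(atlas$zscores, groups, candidates)
    k_use <- min(k_modes, length(candidates))
    if (k_use < k_modes)
      notes <- c(notes, sprintf(
        "only %d candidate modes under the %g%% cut; retaining all",
        length(candidates), variance_threshold))
    selected <- select_top_modes(ranking, k_use)
    report$atlas <- atlas
    report$candidates <- candidates
    report$ranking <- ranking
    report$selected_modes <- selected
    tick("atlas")
  }

  # ---- multivariate associations ----------------------------------------
  if ("associations" %in% stages) {
    if (is.null(report$indices) || is.null(report$atlas))
      stop_bv("associations stage requires the indices and atlas stages")
    assoc_table <- function(features, kind) {
      tab <- do.call(rbind, lapply(colnames(features), function(v) {
        a <- pvr_association(features[, v], records, kind, response_name = v)
        data.frame(feature = v, pvr_coefficient = a$pvr_coefficient,
                   p = a$pvr_p_value)
      }))
      tab[order(tab$p), ]
    }
    zsel <- report$atlas$zscores[, report$selected_modes, drop = FALSE]
    report$associations <- list(
      imaging_indices = assoc_table(report$indices, "IMAGING_INDEX"),
      shape_modes = assoc_table(zsel, "SHAPE_MODE")
    )
    retain <- function(tab) {
      sig <- tab$feature[tab$p < alpha]
      if (length(sig) < 2L) {
        pad <- setdiff(tab$feature, sig)[seq_len(2L - length(sig))]
        notes <<- c(notes, sprintf(
          "%s retained to meet the minimum two variables (p = %s)",
          paste(pad, collapse = ", "),
          paste(signif(tab$p[match(pad, tab$feature)], 3), collapse = ", ")))
        sig <- tab$feature[tab$feature %in% c(sig, pad)]
      }
      sig
    }
    report$retained <- list(
      imaging_indices = retain(report$associations$imaging_indices),
      shape_modes = retain(report$associations$shape_modes)
    )
    tick("associations")
  }

  # ---- clustering --------------------------------------------------------
  if ("clustering" %in% stages) {
    if (is.null(report$retained))
      stop_bv("clustering stage requires the associations stage")
    feat_idx <- report$indices[, report$retained$imaging_indices, drop = FALSE]
    feat_mod <- report$atlas$zscores[, report$retained$shape_modes,
                                     drop = FALSE]
    report$clustering <- list(
      imaging_indices = cluster_and_score(feat_idx, groups, seed,
                                          cluster_restarts),
      shape_modes = cluster_and_score(feat_mod, groups, seed,
                                      cluster_restarts)
    )
    asym <- !records$symptomatic
    if (sum(asym) >= 4L && length(unique(groups[asym])) == 2L) {
      report$clustering_asymptomatic <- list(
        imaging_indices = cluster_and_score(feat_idx[asym, , drop = FALSE],
                                            groups[asym], seed,
                                            cluster_restarts),
        shape_modes = cluster_and_score(feat_mod[asym, , drop = FALSE],
                                        groups[asym], seed,
                                        cluster_restarts)
      )
    } else {
      notes <- c(notes, "asymptomatic subset too small for clustering")
    }
    pred <- vapply(seq_len(n), function(i)
      criteria_classify(as.list(report$indices[i, ]),
                        records$symptomatic[i]), character(1L))
    m_crit <- mm_from_predictions(pred, groups)
    ss <- sensitivity_specificity(m_crit)
    report$criteria <- list(matrix = m_crit, mcc = mcc(m_crit),
                            sensitivity = ss$sensitivity,
                            specificity = ss$specificity)
    tick("clustering")
  }

  # ---- strain ------------------------------------------------------------
  if ("strain" %in% stages) {
    strains <- t(vapply(seq_len(n), function(i) {
      s <- compute_strains(cohort$surfaces_ed[[i]], cohort$surfaces_es[[i]],
                           ...)
      vapply(s, as.numeric, numeric(1L))
    }, numeric(6L)))
    rownames(strains) <- records$subject_id
    report$strains <- strains
    report$strain_summary <- do.call(rbind, lapply(colnames(strains),
                                                   function(v) {
      a <- pvr_association(strains[, v], records, "IMAGING_INDEX",
                           response_name = v, include_bsa = TRUE)
      data.frame(strain = v,
                 pvr_mean = mean(strains[groups == "PVR", v]),
                 pvr_se = stats::sd(strains[groups == "PVR", v]) /
                   sqrt(sum(groups == "PVR")),
                 no_pvr_mean = mean(strains[groups == "NO_PVR", v]),
                 no_pvr_se = stats::sd(strains[groups == "NO_PVR", v]) /
                   sqrt(sum(groups == "NO_PVR")),
                 adjusted_p = a$pvr_p_value)
    }))
    if (!is.null(report$retained)) {
      feats <- cbind(report$indices[, report$retained$imaging_indices,
                                    drop = FALSE],
                     report$atlas$zscores[, report$retained$shape_modes,
                                          drop = FALSE])
      reg <- expand.grid(strain = colnames(strains),
                         feature = colnames(feats),
                         stringsAsFactors = FALSE)
      reg$slope <- NA_real_; reg$r <- NA_real_; reg$p <- NA_real_
      for (i in seq_len(nrow(reg))) {
        fr <- strain_feature_regression(strains[, reg$strain[i]],
                                        feats[, reg$feature[i]])
        reg$slope[i] <- fr$slope; reg$r[i] <- fr$r; reg$p[i] <- fr$p
      }
      report$strain_regressions <- reg[order(reg$p), ]
    }
    tick("strain")
  }

  report$notes <- notes
  report$timings <- unlist(timings)
  structure(report, class = "pvr_report")
}

#' @describeIn run_pipeline Printed summary of the analysis report:
#'   Table-1-style cohort summary, Table-2-style imaging indices,
#'   mode-selection scree/ranking, association tables, matching matrices
#'   with MCC, and the strain summary.
#' @param x a `pvr_report`.
#' @export
print.pvr_report <- function(x, ...) {
  fmt_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
  cat("== Biventricular shape-atlas analysis report ==\n")
  cat(sprintf("subjects: %d   seed: %d   stages: %s\n\n", x$n_subjects,
              x$seed, paste(x$stages, collapse = ", ")))
  cat("-- Cohort characteristics (mean +/- SD; p from t / rank-sum) --\n")
  cs <- x$cohort_summary
  for (i in seq_len(nrow(cs)))
    cat(sprintf("  %-18s %7.1f +/- %5.1f | %7.1f +/- %5.1f  p=%s (%s)\n",
                cs$variable[i], cs$pvr_mean[i], cs$pvr_sd[i],
                cs$no_pvr_mean[i], cs$no_pvr_sd[i], fmt_p(cs$p[i]),
                cs$test[i]))
  cat(sprintf("  sex: p=%s   repair type: p=%s\n",
              fmt_p(x$categorical$sex$p), fmt_p(x$categorical$repair_type$p)))
  if (!is.null(x$index_summary)) {
    cat("\n-- Imaging indices (PVR | No-PVR) --\n")
    is_ <- x$index_summary
    for (i in seq_len(nrow(is_)))
      cat(sprintf("  %-8s %6.1f +/- %4.1f | %6.1f +/- %4.1f  p=%s\n",
                  is_$index[i], is_$pvr_mean[i], is_$pvr_sd[i],
                  is_$no_pvr_mean[i], is_$no_pvr_sd[i], fmt_p(is_$p[i])))
  }
  if (!is.null(x$atlas)) {
    cat(sprintf("\n-- Shape atlas: %d modes; %d candidates under the cut; top %d retained --\n",
                length(x$atlas$variances), length(x$candidates),
                length(x$selected_modes)))
    cat("  selected modes:",
        paste0("ED", x$selected_modes, collapse = ", "), "\n")
  }
  if (!is.null(x$associations)) {
    cat("\n-- PVR associations (confounder-adjusted p) --\n")
    a <- x$associations
    kmax <- max(nrow(a$imaging_indices), nrow(a$shape_modes))
    for (i in seq_len(kmax)) {
      lhs <- if (i <= nrow(a$imaging_indices))
        sprintf("%-8s %s", a$imaging_indices$feature[i],
                fmt_p(a$imaging_indices$p[i])) else ""
      rhs <- if (i <= nrow(a$shape_modes))
        sprintf("%-6s %s", a$shape_modes$feature[i],
                fmt_p(a$shape_modes$p[i])) else ""
      cat(sprintf("  %-22s | %s\n", lhs, rhs))
    }
    cat("  retained:", paste(x$retained$imaging_indices, collapse = ", "),
        "|", paste(x$retained$shape_modes, collapse = ", "), "\n")
  }
  if (!is.null(x$clustering)) {
    cat("\n-- Clustering discrimination (cosine k-means) --\n")
    for (set in names(x$clustering)) {
      cl <- x$clustering[[set]]
      m <- cl$matrix
      cat(sprintf("  %-16s MCC %.2f  sens %.2f  spec %.2f  [tp %d fn %d fp %d tn %d]\n",
                  set, cl$mcc, cl$sensitivity, cl$specificity,
                  m$tp, m$fn, m$fp, m$tn))
    }
    if (!is.null(x$clustering_asymptomatic)) {
      for (set in names(x$clustering_asymptomatic)) {
        cl <- x$clustering_asymptomatic[[set]]
        cat(sprintf("  asymptomatic %-12s MCC %.2f\n", set, cl$mcc))
      }
    }
    if (!is.null(x$criteria))
      cat(sprintf("  threshold criteria   MCC %.2f  sens %.2f  spec %.2f\n",
                  x$criteria$mcc, x$criteria$sensitivity,
                  x$criteria$specificity))
  }
  if (!is.null(x$strain_summary)) {
    cat("\n-- Systolic strains (%; mean +/- SE; adjusted p) --\n")
    ss <- x$strain_summary
    for (i in seq_len(nrow(ss)))
      cat(sprintf("  %-6s %6.1f +/- %4.1f | %6.1f +/- %4.1f  p=%s\n",
                  ss$strain[i], ss$pvr_mean[i], ss$pvr_se[i],
                  ss$no_pvr_mean[i], ss$no_pvr_se[i],
                  fmt_p(ss$adjusted_p[i])))
  }
  if (length(x$notes) > 0L) {
    cat("\nnotes:\n")
    for (nt in x$notes) cat("  -", nt, "\n")
  }
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Writes the report's tables and scores (cohort and index summaries,
#' variance/ranking tables, associations, retained features, matching
#' matrices with MCC/sensitivity/specificity, strain summary and
#' regressions, seeds, versions and notes) as JSON. The fitted atlas and
#' raw feature matrices are omitted; they are reproducible from
#' `config + seed`.
#'
#' @param report a [run_pipeline()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  mm_list <- function(cl) {
    if (is.null(cl)) return(NULL)
    m <- cl$matrix
    list(tp = m$tp, fn = m$fn, fp = m$fp, tn = m$tn, mcc = cl$mcc,
         sensitivity = cl$sensitivity, specificity = cl$specificity,
         degenerate = isTRUE(m$degenerate))
  }
  out <- list(
    seed = report$seed, stages = report$stages,
    n_subjects = report$n_subjects, versions = report$versions,
    cohort_summary = report$cohort_summary,
    categorical_p = lapply(report$categorical, `[[`, "p"),
    index_summary = report$index_summary,
    variance_explained = report$atlas$variance_explained,
    candidates = report$candidates,
    ranking = if (!is.null(report$ranking))
      list(rank = report$ranking$rank,
           importance = report$ranking$importance,
           p_values = report$ranking$p_values),
    selected_modes = report$selected_modes,
    associations = report$associations,
    retained = report$retained,
    clustering = lapply(report$clustering, mm_list),
    clustering_asymptomatic = lapply(report$clustering_asymptomatic, mm_list),
    criteria = if (!is.null(report$criteria))
      list(tp = report$criteria$matrix$tp, fn = report$criteria$matrix$fn,
           fp = report$criteria$matrix$fp, tn = report$criteria$matrix$tn,
           mcc = report$criteria$mcc,
           sensitivity = report$criteria$sensitivity,
           specificity = report$criteria$specificity),
    strain_summary = report$strain_summary,
    strain_regressions = report$strain_regressions,
    notes = report$notes, timings = as.list(report$timings)
  )
  out <- out[!vapply(out, is.null, logical(1L))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  invisible(path)
}

#' Write the mean shape plus/minus a mode excursion as mesh files
#'
#' Reconstructs the atlas mean shape at `+sd` and `-sd` standard
#' deviations along one mode and writes both as VTK polydata with the
#' template's topology and labels, for visual inspection of what the mode
#' encodes.
#'
#' @param atlas a [bv_atlas()].
#' @param mode mode index.
#' @param sd excursion in mode standard deviations (default 2).
#' @param template a [bv_surface()] supplying topology and labels
#'   (vertex count must match the atlas).
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the two file paths (`plus`, `minus`).
#' @export
render_mode_extremes <- function(atlas, mode, sd = 2, template, dir = ".",
                                 prefix = sprintf("mode%02d", mode)) {
  M <- length(atlas$variances)
  if (!is_number(mode) || mode < 1L || mode > M)
    stop_bv("mode must be between 1 and ", M)
  if (3L * nrow(template$vertices) != length(atlas$center))
    stop_bv("template vertex count does not match the atlas")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  z <- numeric(M)
  out <- c(plus = file.path(dir, paste0(prefix, "_plus.vtk")),
           minus = file.path(dir, paste0(prefix, "_minus.vtk")))
  for (s in c(1, -1)) {
    z[mode] <- s * sd
    shape <- template
    shape$vertices <- unstack_vertices(reconstruct_shape(atlas, z, M))
    shape$subject_id <- sprintf("%s_%s", prefix, if (s > 0) "plus" else "minus")
    write_vtk_surface(shape, out[[if (s > 0) "plus" else "minus"]])
  }
  invisible(out)
}
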