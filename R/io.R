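# File formats: legacy-ASCII VTK polydata and ASCII PLY for surfaces (with
# integer point-data arrays for labels and field data for annulus rings and
# the structured grid), CSV for the subject table.

SURFACE_LABEL_CODES <- c(LV_ENDO = 1L, RV_ENDO = 2L, EPI = 3L)
COMPONENT_CODES <- c(LV_ENDO = 1L, RV_ENDO = 2L, EPI_LV = 3L, EPI_RV = 4L)

#' Write a biventricular surface as legacy-ASCII VTK polydata
#'
#' Vertices, triangles, per-vertex integer arrays (`surface_label`,
#' `wall_assignment`, `component`) and field-data arrays for the four
#' annulus rings and the structured ring/meridian grid are stored, so a
#' round trip through [read_vtk_surface()] preserves everything the
#' analysis needs.
#'
#' @param x a [bv_surface()].
#' @param path output file path (`.vtk`).
#' @return `path`, invisibly.
#' @export
write_vtk_surface <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(..., con = con)
  n <- nrow(x$vertices); tt <- nrow(x$triangles)
  wl("# vtk DataFile Version 3.0")
  wl(sprintf("bivatlas subject=%s phase=%s", x$subject_id, x$phase))
  wl("ASCII")
  wl("DATASET POLYDATA")
  wl(sprintf("POINTS %d double", n))
  wl(apply(format(x$vertices, digits = 17, trim = TRUE, scientific = FALSE),
           1L, paste, collapse = " "))
  wl(sprintf("POLYGONS %d %d", tt, 4L * tt))
  wl(paste(3L, x$triangles[, 1L] - 1L, x$triangles[, 2L] - 1L,
           x$triangles[, 3L] - 1L))
  wl(sprintf("POINT_DATA %d", n))
  scalar <- function(name, values) {
    wl(sprintf("SCALARS %s int 1", name))
    wl("LOOKUP_TABLE default")
    wl(paste(values, collapse = " "))
  }
  scalar("surface_label", SURFACE_LABEL_CODES[x$surface_label])
  scalar("wall_assignment", x$wall_assignment)
  scalar("component", COMPONENT_CODES[x$component])
  grids <- x$grid[!vapply(x$grid, is.null, logical(1L))]
  n_arr <- length(x$annuli) + 2L * length(grids)
  wl(sprintf("FIELD bivatlas %d", n_arr))
  for (vn in names(x$annuli)) {
    ring <- x$annuli[[vn]]
    wl(sprintf("annulus_%s 1 %d int", vn, length(ring)))
    wl(paste(ring - 1L, collapse = " "))
  }
  for (cn in names(grids)) {
    g <- grids[[cn]]
    wl(sprintf("grid_%s_apex 1 1 int", cn))
    wl(as.character(g$apex - 1L))
    wl(sprintf("grid_%s_rings %d %d int", cn, ncol(g$rings), nrow(g$rings)))
    wl(apply(g$rings - 1L, 1L, paste, collapse = " "))
  }
  invisible(path)
}

#' Read a biventricular surface from legacy-ASCII VTK polydata
#'
#' Reads files written by [write_vtk_surface()] and validates the surface
#' invariants on load.
#'
#' @param path input file path.
#' @param validate run [validate_bv_surface()] (default TRUE).
#' @return a [bv_surface()].
#' @export
read_vtk_surface <- function(path, validate = TRUE) {
  lines <- readLines(path)
  if (!grepl("^# vtk DataFile", lines[1L])) stop_bv("not a VTK file: ", path)
  title <- lines[2L]
  subject_id <- sub(".*subject=(\\S+).*", "\\1", title)
  phase <- sub(".*phase=(\\S+).*", "\\1", title)
  if (!phase %in% c("ED", "ES")) phase <- "ED"
  i <- grep("^POINTS ", lines)[1L]
  n <- as.integer(strsplit(lines[i], "\\s+")[[1L]][2L])
  vertices <- matrix(as.numeric(unlist(strsplit(lines[(i + 1L):(i + n)],
                                                "\\s+"))), n, 3L, byrow = TRUE)
  i <- grep("^POLYGONS ", lines)[1L]
  tt <- as.integer(strsplit(lines[i], "\\s+")[[1L]][2L])
  poly <- matrix(as.integer(unlist(strsplit(lines[(i + 1L):(i + tt)],
                                            "\\s+"))), tt, 4L, byrow = TRUE)
  if (any(poly[, 1L] != 3L)) stop_bv("non-triangular polygon in ", path)
  triangles <- poly[, 2:4, drop = FALSE] + 1L
  read_scalar <- function(name) {
    j <- grep(paste0("^SCALARS ", name, " "), lines)[1L]
    if (is.na(j)) stop_bv("missing point-data array '", name, "' in ", path)
    as.integer(strsplit(lines[j + 2L], "\\s+")[[1L]])
  }
  lab <- read_scalar("surface_label")
  wall <- read_scalar("wall_assignment")
  comp <- read_scalar("component")
  annuli <- list()
  for (vn in VALVE_NAMES) {
    j <- grep(paste0("^annulus_", vn, " "), lines)[1L]
    if (is.na(j)) stop_bv("missing annulus ring '", vn, "' in ", path)
    annuli[[vn]] <- as.integer(strsplit(lines[j + 1L], "\\s+")[[1L]]) + 1L
  }
  grid <- list()
  for (cn in names(COMPONENT_CODES)) {
    j <- grep(paste0("^grid_", cn, "_apex "), lines)[1L]
    if (is.na(j)) next
    apex <- as.integer(lines[j + 1L]) + 1L
    j <- grep(paste0("^grid_", cn, "_rings "), lines)[1L]
    hd <- strsplit(lines[j], "\\s+")[[1L]]
    n_merid <- as.integer(hd[2L]); n_rings <- as.integer(hd[3L])
    rings <- matrix(as.integer(unlist(strsplit(lines[(j + 1L):(j + n_rings)],
                                               "\\s+"))),
                    n_rings, n_merid, byrow = TRUE) + 1L
    grid[[cn]] <- list(apex = apex, rings = rings)
  }
  bv_surface(subject_id, phase, vertices, triangles,
             names(SURFACE_LABEL_CODES)[lab], wall,
             annuli, component = names(COMPONENT_CODES)[comp],
             grid = if (length(grid)) grid else NULL,
             validate = validate)
}

#' Write a biventricular surface as ASCII PLY
#'
#' Labels travel as integer vertex properties and the annulus rings as
#' header comments. The structured ring/meridian grid is not representable
#' in PLY; meshes re-read from PLY support volume indices and slice-based
#' radial strain but not the arc-length (longitudinal/circumferential)
#' strain lines.
#'
#' @param x a [bv_surface()].
#' @param path output file path (`.ply`).
#' @return `path`, invisibly.
#' @export
write_ply_surface <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(..., con = con)
  n <- nrow(x$vertices); tt <- nrow(x$triangles)
  wl("ply")
  wl("format ascii 1.0")
  wl(sprintf("comment bivatlas subject=%s phase=%s", x$subject_id, x$phase))
  for (vn in names(x$annuli))
    wl(sprintf("comment annulus %s %s", vn,
               paste(x$annuli[[vn]] - 1L, collapse = " ")))
  wl(sprintf("element vertex %d", n))
  wl(c("property double x", "property double y", "property double z",
       "property int surface_label", "property int wall_assignment",
       "property int component"))
  wl(sprintf("element face %d", tt))
  wl("property list uchar int vertex_indices")
  wl("end_header")
  wl(paste(format(x$vertices[, 1L], digits = 17, trim = TRUE),
           format(x$vertices[, 2L], digits = 17, trim = TRUE),
           format(x$vertices[, 3L], digits = 17, trim = TRUE),
           SURFACE_LABEL_CODES[x$surface_label], x$wall_assignment,
           COMPONENT_CODES[x$component]))
  wl(paste(3L, x$triangles[, 1L] - 1L, x$triangles[, 2L] - 1L,
           x$triangles[, 3L] - 1L))
  invisible(path)
}

#' Read a biventricular surface from ASCII PLY
#'
#' @param path input file path.
#' @param validate run [validate_bv_surface()].
#' @return a [bv_surface()] (without structured-grid metadata; see
#'   [write_ply_surface()]).
#' @export
read_ply_surface <- function(path, validate = TRUE) {
  lines <- readLines(path)
  if (lines[1L] != "ply") stop_bv("not a PLY file: ", path)
  hdr_end <- which(lines == "end_header")[1L]
  hdr <- lines[seq_len(hdr_end)]
  n <- as.integer(sub("element vertex ", "", grep("^element vertex ", hdr,
                                                  value = TRUE)))
  tt <- as.integer(sub("element face ", "", grep("^element face ", hdr,
                                                 value = TRUE)))
  meta <- grep("^comment bivatlas ", hdr, value = TRUE)
  subject_id <- sub(".*subject=(\\S+).*", "\\1", meta)
  phase <- sub(".*phase=(\\S+).*", "\\1", meta)
  annuli <- list()
  for (ln in grep("^comment annulus ", hdr, value = TRUE)) {
    parts <- strsplit(ln, "\\s+")[[1L]]
    annuli[[parts[3L]]] <- as.integer(parts[-(1:3)]) + 1L
  }
  vdat <- matrix(as.numeric(unlist(strsplit(lines[hdr_end + seq_len(n)],
                                            "\\s+"))), n, 6L, byrow = TRUE)
  fdat <- matrix(as.integer(unlist(strsplit(lines[hdr_end + n + seq_len(tt)],
                                            "\\s+"))), tt, 4L, byrow = TRUE)
  bv_surface(subject_id, phase, vdat[, 1:3], fdat[, 2:4] + 1L,
             names(SURFACE_LABEL_CODES)[vdat[, 4L]], as.integer(vdat[, 5L]),
             annuli, component = names(COMPONENT_CODES)[vdat[, 6L]],
             grid = NULL, validate = validate)
}

SUBJECT_COLUMNS <- c("subject_id", "group", "sex", "repair_type",
                     "age_at_repair", "age_at_cmr", "time_after_repair",
                     "height", "weight", "bsa", "symptomatic", "prvi", "prf")

#' Read and validate a subject table
#'
#' CSV with exactly the subject-record fields; a header is required and
#' missing values are rejected. Enum fields and the numeric invariants
#' (positive BSA, non-negative time after repair, PRF within 0-100) are
#' checked.
#'
#' @param path CSV file path.
#' @return data frame with one row per subject.
#' @export
read_subject_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SUBJECT_COLUMNS, names(df))
  if (length(missing_cols) > 0L)
    stop_bv("subject table lacks columns: ", paste(missing_cols, collapse = ", "))
  df <- df[, SUBJECT_COLUMNS]
  if (anyNA(df)) stop_bv("subject table contains missing values")
  if (!all(df$group %in% c("PVR", "NO_PVR")))
    stop_bv("group must be PVR or NO_PVR")
  if (!all(df$sex %in% c("M", "F"))) stop_bv("sex must be M or F")
  if (!all(df$repair_type %in% REPAIR_TYPES))
    stop_bv("repair_type must be one of ", paste(REPAIR_TYPES, collapse = ", "))
  df$symptomatic <- as.logical(df$symptomatic)
  if (anyNA(df$symptomatic)) stop_bv("symptomatic must be logical")
  if (any(df$bsa <= 0)) stop_bv("bsa must be positive")
  if (any(df$time_after_repair < 0)) stop_bv("time_after_repair must be >= 0")
  if (any(df$prf < 0 | df$prf > 100)) stop_bv("prf must be within [0, 100]")
  if (anyDuplicated(df$subject_id)) stop_bv("duplicate subject_id")
  df
}

#' Write a cohort to a directory
#'
#' Writes `subjects.csv`, per-subject ED/ES VTK meshes under `meshes/`,
#' and the generator configuration as JSON. Ground-truth arrays are
#' written to `ground_truth.json` when present.
#'
#' @param cohort a [generate_cohort()] result, or a list with
#'   `surfaces_ed`, `surfaces_es`, `records`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "meshes"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$records, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  for (i in seq_along(cohort$surfaces_ed)) {
    id <- cohort$records$subject_id[i]
    write_vtk_surface(cohort$surfaces_ed[[i]],
                      file.path(dir, "meshes", paste0(id, "_ED.vtk")))
    write_vtk_surface(cohort$surfaces_es[[i]],
                      file.path(dir, "meshes", paste0(id, "_ES.vtk")))
  }
  if (!is.null(cohort$config))
    jsonlite::write_json(cohort$config[setdiff(names(cohort$config),
                                               c("confounders"))],
                         file.path(dir, "config.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  if (!is.null(cohort$ground_truth)) {
    gt <- cohort$ground_truth
    keep <- c("coefficients", "field_norms", "lambdas", "true_ef",
              "volumes_ed", "scale", "background_sd")
    jsonlite::write_json(gt[intersect(keep, names(gt))],
                         file.path(dir, "ground_truth.json"),
                         digits = NA, force = TRUE)
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return list with `surfaces_ed`, `surfaces_es`, `records`.
#' @export
read_cohort <- function(dir) {
  records <- read_subject_table(file.path(dir, "subjects.csv"))
  ids <- records$subject_id
  surfaces_ed <- lapply(ids, function(id)
    read_vtk_surface(file.path(dir, "meshes", paste0(id, "_ED.vtk"))))
  surfaces_es <- lapply(ids, function(id)
    read_vtk_surface(file.path(dir, "meshes", paste0(id, "_ES.vtk"))))
  names(surfaces_ed) <- ids
  names(surfaces_es) <- ids
  list(surfaces_ed = surfaces_ed, surfaces_es = surfaces_es,
       records = records)
}
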