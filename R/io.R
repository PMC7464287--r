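## Plain-text outputs: trace/profile/scan CSV, per-run JSON records, and
## legacy-ASCII VTK PolyData for meshes and snapshots.

#' Write tip traces and conserved quantities as CSV
#'
#' Columns: `time_s`, `tip1_CT`, `tip2_CT`, `Ec`, and the per-field total
#' masses (`mass_CD`, ...).
#'
#' @param trajectory A [run()] result.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_traces_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "cdc42_trajectory"))
  d <- data.frame(time_s = trajectory$times,
                  tip1_CT = trajectory$tip1, tip2_CT = trajectory$tip2,
                  Ec = trajectory$Ec)
  m <- trajectory$mass
  colnames(m) <- paste0("mass_", colnames(m))
  write.csv(cbind(d, m), path, row.names = FALSE)
  invisible(path)
}

#' Write an arc-length profile as CSV
#' @param profile A [profile_vs_arclength()] result.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}

#' Write a one-run JSON record
#'
#' Parameters (non-reference values spelled out), seed, parameter hash,
#' state label and metrics — enough provenance to reproduce the run.
#'
#' @param trajectory A [run()] result.
#' @param label Optional [classify_state()] result to embed.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_run_json <- function(trajectory, label = NULL, path) {
  p <- trajectory$params
  rec <- list(
    params = unclass(p)[c(.rate_names, "h", "lambda", "L", "R",
                          "target_cell_area", "dt", "duration", "noise_mode")],
    seed = trajectory$provenance$seed,
    params_hash = trajectory$provenance$params_hash,
    n_nodes = trajectory$provenance$n_nodes)
  if (!is.null(label)) {
    rec$label <- label$label
    rec$metrics <- label[setdiff(names(label), "label")]
  }
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write scan results as CSV (lossless round trip)
#' @param scan A [run_scan()] result.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  stopifnot(inherits(scan, "scan_result"))
  d <- as.data.frame(scan)
  attr_line <- sprintf("# axes=%s,%s duration=%g replicates=%d base_hash=%s",
                       attr(scan, "axes")[1], attr(scan, "axes")[2],
                       attr(scan, "duration"), attr(scan, "replicates"),
                       attr(scan, "base_hash"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  write.csv(d, con, row.names = FALSE)
  invisible(path)
}

#' Read a scan CSV written by [write_scan_csv()]
#' @param path Input file.
#' @return A `scan_result` data.frame.
#' @export
read_scan_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#")) stop("not a scan CSV (missing header line)")
  kv <- strsplit(sub("^# ", "", hdr), " ")[[1]]
  kv <- strsplit(kv, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  d <- read.csv(path, skip = 1L, stringsAsFactors = FALSE)
  for (nm in c("asymmetry", "period_s")) d[[nm]] <- as.numeric(d[[nm]])
  structure(d, class = c("scan_result", "data.frame"),
            axes = strsplit(vals[["axes"]], ",")[[1]],
            duration = as.numeric(vals[["duration"]]),
            replicates = as.integer(vals[["replicates"]]),
            base_hash = vals[["base_hash"]])
}

#' Write a surface mesh (with per-node scalars) as legacy-ASCII VTK PolyData
#'
#' @param mesh A [build_mesh()] result.
#' @param path Output `.vtk` file.
#' @param point_data Named list of per-node numeric vectors to attach; the
#'   mesh's `s` and `area` fields are always included.
#' @return The path, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path, point_data = list()) {
  stopifnot(inherits(mesh, "surface_mesh"))
  point_data <- c(list(s = mesh$s, area = mesh$areas), point_data)
  .write_vtk(path, mesh$nodes, mesh$faces, point_data)
  invisible(path)
}

#' Write trajectory snapshots as a VTK PolyData series
#'
#' One file per recorded snapshot (`<prefix>_<index>.vtk`, times in a
#' companion `<prefix>_times.csv`), each carrying all six concentration
#' fields as per-node scalars.
#'
#' @param trajectory A [run()] result with snapshots.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_vtk_snapshots <- function(trajectory, dir, prefix = "snapshot") {
  sn <- trajectory$snapshots
  if (is.null(sn)) stop("trajectory has no snapshots")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mesh <- trajectory$mesh
  files <- character(length(sn$t))
  for (k in seq_along(sn$t)) {
    files[k] <- file.path(dir, sprintf("%s_%04d.vtk", prefix, k))
    .write_vtk(files[k], mesh$nodes, mesh$faces,
               list(CD = sn$CD[, k], CT = sn$CT[, k], CGAPI = sn$CGAPI[, k],
                    CGAPIIfast = sn$CGAPIIfast[, k],
                    CGAPIIslow = sn$CGAPIIslow[, k], CGEF = sn$CGEF[, k]))
  }
  write.csv(data.frame(index = seq_along(sn$t), time_s = sn$t),
            file.path(dir, paste0(prefix, "_times.csv")), row.names = FALSE)
  invisible(files)
}

.write_vtk <- function(path, nodes, faces, point_data) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(nodes)
  writeLines(c("# vtk DataFile Version 3.0",
               "cdc42sim surface mesh", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(format(nodes, digits = 9, trim = TRUE), 1, paste,
                   collapse = " "), con)
  nf <- nrow(faces)
  writeLines(sprintf("POLYGONS %d %d", nf, 4L * nf), con)
  writeLines(paste(3L, faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  for (nm in names(point_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(format(point_data[[nm]], digits = 9, trim = TRUE), con)
  }
}
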