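LABEL_CODES <- c(healthy = 0L, border_zone = 1L, scar = 2L)

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a shell as VTK legacy ASCII POLYDATA
#'
#' Node scalar fields are written as POINT_DATA SCALARS arrays; tissue
#' labels as an integer-coded array `label`
#' (healthy = 0, border_zone = 1, scar = 2). Output is byte-stable for
#' identical input.
#'
#' @param shell An [new_shell()] object.
#' @param path Output file.
#' @param fields Field names to include (default: all).
#' @export
write_vtk <- function(shell, path, fields = NULL) {
  nd <- shell$node_data
  avail <- setdiff(names(nd), c("node_id", "label"))
  fields <- fields %||% avail
  missing <- setdiff(fields, avail)
  if (length(missing)) {
    abort(sprintf("unknown field(s) %s; available: %s",
                  paste(missing, collapse = ", "),
                  if (length(avail)) paste(avail, collapse = ", ") else "(none)"))
  }
  n <- n_nodes(shell); m <- nrow(shell$triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "arimap shell", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", n)), con)
  writeLines(apply(shell$coords, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", m, 4 * m), con)
  if (m > 0) {
    writeLines(apply(shell$triangles - 1L, 1,
                     function(r) paste(c(3L, r), collapse = " ")), con)
  }
  has_label <- any(!is.na(nd$label))
  if (length(fields) || has_label) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    if (has_label) {
      writeLines(c("SCALARS label int 1", "LOOKUP_TABLE default"), con)
      writeLines(as.character(unname(LABEL_CODES[nd$label])), con)
    }
    for (f in fields) {
      writeLines(c(sprintf("SCALARS %s float 1", f), "LOOKUP_TABLE default"), con)
      writeLines(fmt_num(nd[[f]]), con)
    }
  }
  invisible(path)
}

#' Read a VTK legacy ASCII POLYDATA shell
#'
#' Supports the subset written by [write_vtk()]: POINTS, POLYGONS and
#' POINT_DATA SCALARS arrays (an integer `label` array is decoded back to
#' tissue labels).
#'
#' @param path VTK file.
#' @return An [new_shell()] object.
#' @export
read_vtk <- function(path) {
  if (!file.exists(path)) abort(sprintf("mesh file not found: %s", path))
  lines <- readLines(path)
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  ip <- grep("^POINTS", lines)[1]
  if (is.na(ip)) abort(sprintf("%s: no POINTS section", path))
  n <- as.integer(toks(lines[ip])[2])
  pts <- as.numeric(unlist(strsplit(trimws(lines[(ip + 1):(ip + n)]), "\\s+")))
  coords <- matrix(pts, ncol = 3, byrow = TRUE)
  ig <- grep("^POLYGONS", lines)[1]
  tri <- matrix(integer(), 0, 3)
  if (!is.na(ig)) {
    m <- as.integer(toks(lines[ig])[2])
    if (m > 0) {
      rows <- strsplit(trimws(lines[(ig + 1):(ig + m)]), "\\s+")
      tri <- t(vapply(rows, function(r) as.integer(r[2:4]) + 1L, integer(3)))
    }
  }
  labels <- NULL; fields <- list()
  isc <- grep("^SCALARS", lines)
  for (i in isc) {
    tk <- toks(lines[i])
    name <- tk[2]
    vals <- as.numeric(lines[(i + 2):(i + 1 + n)])
    if (name == "label") {
      labels <- names(LABEL_CODES)[match(as.integer(vals), LABEL_CODES)]
    } else {
      fields[[name]] <- vals
    }
  }
  new_shell(coords, tri, labels = labels, fields = fields)
}

#' Read an ASCII PLY mesh
#'
#' Minimal reader for ASCII PLY files with vertex x/y/z properties and
#' triangular faces.
#'
#' @param path PLY file.
#' @return An [new_shell()] object.
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) abort(sprintf("mesh file not found: %s", path))
  lines <- readLines(path)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) abort(sprintf("%s: not an ASCII PLY file", path))
  hdr <- lines[seq_len(endh)]
  nv <- as.integer(sub("element vertex\\s+", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face\\s+", "", grep("^element face", hdr, value = TRUE)))
  if (any(grepl("^format (binary)", hdr))) abort("binary PLY is not supported")
  vrows <- strsplit(trimws(lines[(endh + 1):(endh + nv)]), "\\s+")
  coords <- t(vapply(vrows, function(r) as.numeric(r[1:3]), numeric(3)))
  tri <- matrix(integer(), 0, 3)
  if (length(nf) && nf > 0) {
    frows <- strsplit(trimws(lines[(endh + nv + 1):(endh + nv + nf)]), "\\s+")
    tri <- t(vapply(frows, function(r) as.integer(r[2:4]) + 1L, integer(3)))
  }
  new_shell(coords, tri)
}

#' Write a case bundle to disk
#'
#' Canonical on-disk case format: JSON manifest + VTK legacy ASCII mesh +
#' long-format CSV electrograms + per-node label CSV. Coordinates in mm,
#' time in ms, voltage in mV; node and sample indices are 0-based on
#' disk. Writing is deterministic: identical cases yield byte-identical
#' bundles.
#'
#' @param case A `map_case`.
#' @param path Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_case <- function(case, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) abort(sprintf("cannot create directory %s", path))
  write_vtk(case$shell, file.path(path, "mesh.vtk"))
  labs <- case$shell$node_data$label
  readr::write_csv(
    tibble::tibble(node_id = seq_along(labs) - 1L, label = labs),
    file.path(path, "labels.csv"))
  recs <- case$records
  readr::write_csv(
    tibble::tibble(site_id = recs$site_id, x = recs$x, y = recs$y, z = recs$z),
    file.path(path, "sites.csv"))
  long <- tibble::tibble(
    site_id = rep(recs$site_id, lengths(recs$unipolar)),
    sample_index = unlist(lapply(lengths(recs$unipolar), seq_len)) - 1L,
    value_mV = unlist(recs$unipolar))
  readr::write_csv(long, file.path(path, "electrograms.csv"))
  if (!is.null(recs$bipolar)) {
    longb <- tibble::tibble(
      site_id = rep(recs$site_id, lengths(recs$bipolar)),
      sample_index = unlist(lapply(lengths(recs$bipolar), seq_len)) - 1L,
      value_mV = unlist(recs$bipolar))
    readr::write_csv(longb, file.path(path, "bipolar.csv"))
  }
  stim <- tibble::tibble(
    site_id = rep(recs$site_id, lengths(recs$stimulus_times)),
    stimulus_ms = unlist(recs$stimulus_times))
  readr::write_csv(stim, file.path(path, "stimuli.csv"))
  manifest <- list(
    case_id = case$case_id,
    pig = case$pig %||% NA,
    cycle_length_ms = case$cycle_length,
    pacing_chamber = case$pacing_chamber,
    pacing_site_xyz = as.numeric(case$pacing_site),
    sampling_rate_hz = case$sampling_rate,
    segment_ms = case$segment_ms,
    files = list(mesh = "mesh.vtk", labels = "labels.csv",
                 sites = "sites.csv", electrograms = "electrograms.csv",
                 bipolar = if (!is.null(recs$bipolar)) "bipolar.csv",
                 stimuli = "stimuli.csv"))
  mp <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(mp)
}

#' Read a case bundle
#'
#' Loads and validates a bundle written by [write_case()]. Missing files
#' raise a load error naming the file; invariant violations raise a
#' validation error naming the node or site.
#'
#' @param path Case directory.
#' @return A `map_case`.
#' @export
read_case <- function(path) {
  mp <- file.path(path, "manifest.json")
  if (!file.exists(mp)) abort(sprintf("manifest not found: %s", mp))
  man <- jsonlite::read_json(mp, simplifyVector = TRUE)
  need <- function(key) {
    fp <- file.path(path, man$files[[key]])
    if (is.null(man$files[[key]]) || !file.exists(fp)) {
      abort(sprintf("case file missing: %s (%s)", key,
                    man$files[[key]] %||% "unset"))
    }
    fp
  }
  mesh_path <- need("mesh")
  shell <- if (grepl("\\.ply$", mesh_path)) read_ply(mesh_path) else read_vtk(mesh_path)
  labs <- readr::read_csv(need("labels"), show_col_types = FALSE)
  shell$node_data$label <- labs$label[order(labs$node_id)]
  sites <- readr::read_csv(need("sites"), show_col_types = FALSE)
  long <- readr::read_csv(need("electrograms"), show_col_types = FALSE)
  uni <- split(long$value_mV[order(match(long$site_id, sites$site_id), long$sample_index)],
               factor(long$site_id[order(match(long$site_id, sites$site_id), long$sample_index)],
                      levels = sites$site_id))
  bip <- NULL
  if (!is.null(man$files$bipolar) && file.exists(file.path(path, man$files$bipolar))) {
    longb <- readr::read_csv(file.path(path, man$files$bipolar), show_col_types = FALSE)
    bip <- split(longb$value_mV[order(match(longb$site_id, sites$site_id), longb$sample_index)],
                 factor(longb$site_id[order(match(longb$site_id, sites$site_id), longb$sample_index)],
                        levels = sites$site_id))
  }
  stim <- readr::read_csv(need("stimuli"), show_col_types = FALSE)
  stl <- split(stim$stimulus_ms, factor(stim$site_id, levels = sites$site_id))
  records <- tibble::tibble(
    site_id = sites$site_id, x = sites$x, y = sites$y, z = sites$z,
    sampling_rate = man$sampling_rate_hz, segment_ms = man$segment_ms,
    unipolar = unname(uni),
    bipolar = if (!is.null(bip)) unname(bip),
    stimulus_times = unname(stl))
  case <- structure(list(
    case_id = man$case_id,
    pig = if (!is.null(man$pig) && !is.na(man$pig)) man$pig else NULL,
    shell = shell,
    records = records,
    pacing_site = as.numeric(man$pacing_site_xyz),
    pacing_chamber = man$pacing_chamber,
    cycle_length = man$cycle_length_ms,
    sampling_rate = man$sampling_rate_hz,
    segment_ms = man$segment_ms
  ), class = "map_case")
  validate_case(case)
  case
}

#' Export an annotated result shell
#'
#' Writes a shell with its scalar result fields (ARI, gradients,
#' interface distance, integer-coded labels) as a standard-viewer-loadable
#' VTK file.
#'
#' @param shell An [new_shell()] object.
#' @param path Output VTK file.
#' @param fields Fields to export (default all); unknown names error with
#'   the available list.
#' @export
export_result_shell <- function(shell, path, fields = NULL) {
  write_vtk(shell, path, fields = fields)
}
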