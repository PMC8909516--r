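# Scene persistence: one multi-page 32-bit-float TIFF per acquisition date
# (one page per band, in manifest band order) plus QA, label and DEM TIFFs and
# a plain-text manifest. The TIFF writer stores samples in [0, 1], so values
# are scaled by gain/offset recorded in the manifest; storage is float32, so
# round-trips are accurate to ~1e-7 of the value range, not bit-exact.

REFLECTANCE_SCALE <- 1.2

#' Write a scene to a directory
#'
#' @param stack A `reflectance_stack`.
#' @param labels A `label_raster`.
#' @param dem A `dem_raster`.
#' @param directory Output directory (created if absent).
#' @return Invisibly, the manifest path.
#' @seealso [read_scene()] for the inverse.
#' @export
write_scene <- function(stack, labels, dem, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  nt <- length(stack$dates)
  date_files <- sprintf("refl_doy%03d.tif", stack$dates)
  for (t in seq_len(nt)) {
    pages <- lapply(seq_along(stack$bands),
                    function(b) stack$values[t, b, , ] / REFLECTANCE_SCALE)
    tiff::writeTIFF(pages, file.path(directory, date_files[t]),
                    bits.per.sample = 32L)
  }
  qa_pages <- lapply(seq_len(nt), function(t) (stack$qa[t, , ]) * 1)
  tiff::writeTIFF(qa_pages, file.path(directory, "qa.tif"),
                  bits.per.sample = 32L)
  tiff::writeTIFF(labels$labels / 255, file.path(directory, "labels.tif"),
                  bits.per.sample = 32L)

  dem_offset <- min(dem$elevation)
  dem_scale <- max(dem$elevation) - dem_offset
  if (dem_scale == 0) dem_scale <- 1
  tiff::writeTIFF((dem$elevation - dem_offset) / dem_scale,
                  file.path(directory, "dem.tif"), bits.per.sample = 32L)

  manifest <- c(
    "format: ricegru-scene/1",
    paste0("n_rows: ", dim(stack$values)[3]),
    paste0("n_cols: ", dim(stack$values)[4]),
    paste0("cell_size: ", format(stack$cell_size, digits = 17)),
    paste0("geotransform: ", paste(format(stack$geotransform, digits = 17),
                                   collapse = ",")),
    paste0("bands: ", paste(stack$bands, collapse = ",")),
    paste0("reflectance_scale: ", format(REFLECTANCE_SCALE, digits = 17)),
    paste0("dates: ", paste(stack$dates, collapse = ",")),
    paste0("date_files: ", paste(date_files, collapse = ",")),
    "qa_file: qa.tif",
    "labels_file: labels.tif",
    "dem_file: dem.tif",
    paste0("dem_offset: ", format(dem_offset, digits = 17)),
    paste0("dem_scale: ", format(dem_scale, digits = 17))
  )
  manifest_path <- file.path(directory, "manifest.txt")
  writeLines(manifest, manifest_path)
  invisible(manifest_path)
}

parse_manifest <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexpr(": ", lines), invert = TRUE)
  out <- lapply(kv, `[[`, 2)
  names(out) <- vapply(kv, `[[`, character(1), 1)
  out
}

read_tif_pages <- function(path, what) {
  if (!file.exists(path))
    stopf("read_scene: missing %s file '%s'", what, path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages
}

#' Read a scene written by [write_scene()]
#'
#' @param manifest_path Path to the scene manifest (or the scene directory).
#' @return A list with `stack`, `labels`, `dem`, as from [simulate_scene()].
#' @export
read_scene <- function(manifest_path) {
  if (dir.exists(manifest_path))
    manifest_path <- file.path(manifest_path, "manifest.txt")
  if (!file.exists(manifest_path))
    stopf("read_scene: manifest '%s' not found", manifest_path)
  dirpath <- dirname(manifest_path)
  m <- parse_manifest(manifest_path)

  split_csv <- function(x) strsplit(x, ",", fixed = TRUE)[[1]]
  nr <- as.integer(m$n_rows); nc <- as.integer(m$n_cols)
  bands <- split_csv(m$bands)
  dates <- as.numeric(split_csv(m$dates))
  date_files <- split_csv(m$date_files)
  refl_scale <- as.numeric(m$reflectance_scale)
  if (length(date_files) != length(dates))
    stopf("read_scene: manifest lists %d dates but %d date files",
          length(dates), length(date_files))

  nt <- length(dates); nb <- length(bands)
  values <- array(NA_real_, dim = c(nt, nb, nr, nc),
                  dimnames = list(NULL, bands, NULL, NULL))
  for (t in seq_len(nt)) {
    pages <- read_tif_pages(file.path(dirpath, date_files[t]), "reflectance")
    if (length(pages) != nb)
      stopf("read_scene: '%s' has %d bands, manifest expects %d",
            date_files[t], length(pages), nb)
    for (b in seq_len(nb)) {
      pg <- pages[[b]]
      if (!identical(dim(pg), c(nr, nc)))
        stopf("read_scene: grid mismatch in '%s' (%s vs manifest %dx%d)",
              date_files[t], paste(dim(pg), collapse = "x"), nr, nc)
      values[t, b, , ] <- pg * refl_scale
    }
  }

  qa_pages <- read_tif_pages(file.path(dirpath, m$qa_file), "QA")
  if (length(qa_pages) != nt)
    stopf("read_scene: QA file has %d pages, manifest expects %d",
          length(qa_pages), nt)
  qa <- array(TRUE, dim = c(nt, nr, nc))
  for (t in seq_len(nt)) {
    if (!identical(dim(qa_pages[[t]]), c(nr, nc)))
      stopf("read_scene: grid mismatch in QA file")
    qa[t, , ] <- qa_pages[[t]] > 0.5
  }

  lab_page <- read_tif_pages(file.path(dirpath, m$labels_file), "label")[[1]]
  if (!identical(dim(lab_page), c(nr, nc)))
    stopf("read_scene: grid mismatch between labels (%s) and manifest (%dx%d)",
          paste(dim(lab_page), collapse = "x"), nr, nc)
  lab <- matrix(as.integer(round(lab_page * 255)), nr, nc)

  dem_page <- read_tif_pages(file.path(dirpath, m$dem_file), "DEM")[[1]]
  if (!identical(dim(dem_page), c(nr, nc)))
    stopf("read_scene: grid mismatch between DEM (%s) and manifest (%dx%d)",
          paste(dim(dem_page), collapse = "x"), nr, nc)
  dem <- dem_page * as.numeric(m$dem_scale) + as.numeric(m$dem_offset)

  cell_size <- as.numeric(m$cell_size)
  stack <- structure(list(
    values = values, qa = qa, dates = dates, bands = bands,
    geotransform = as.numeric(split_csv(m$geotransform)),
    cell_size = cell_size
  ), class = "reflectance_stack")
  labels <- structure(list(labels = lab, levels = LABEL_LEVELS),
                      class = "label_raster")
  dem <- structure(list(elevation = dem, cell_size = cell_size),
                   class = "dem_raster")
  list(stack = stack, labels = labels, dem = dem)
}
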