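#' Labeled segmentation volume
#'
#' A 3D grid of integer cell labels with anisotropic voxel spacing. Arrays are
#' stored with dimensions `(y, x, z)` so that each z-page matches one page of
#' a multi-page TIFF (rows = y, columns = x); all physical coordinates are
#' reported as `(x, y, z)` in micrometres. Voxel centres sit at
#' `(index - 0.5) * spacing` (1-based indices), so the first voxel's centre is
#' half a voxel in from the origin.
#'
#' @param labels 3D integer array, dimensions `(ny, nx, nz)`. All values
#'   must be >= 0; `background_label` marks exterior / unsegmented space.
#' @param spacing Voxel size in micrometres, length-3 `(x, y, z)`. Strictly
#'   positive.
#' @param background_label Integer label for background (default 0).
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(labels, spacing = c(1, 1, 1), background_label = 0L) {
  if (length(dim(labels)) != 3L) abort("`labels` must be a 3D array.")
  if (any(labels != round(labels))) abort("`labels` must be integer-valued.")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) abort("labels must be >= 0")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 strictly positive values (x, y, z) in um.")
  }
  if (!any(labels != background_label)) {
    abort("volume contains no non-background voxel")
  }
  structure(list(labels = labels, spacing = spacing,
                 background_label = as.integer(background_label)),
            class = "labeled_volume")
}

#' Wall-stain intensity volume
#'
#' Non-negative stain signal (arbitrary units in \[0, 1\]) on the same grid as
#' its paired [labeled_volume()].
#'
#' @param values 3D numeric array, same dimensions as the paired labels.
#' @param spacing Voxel size `(x, y, z)` in um; must match the paired volume.
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(values, spacing = c(1, 1, 1)) {
  if (length(dim(values)) != 3L) abort("`values` must be a 3D array.")
  storage.mode(values) <- "double"
  if (any(values < 0)) abort("intensities must be >= 0")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    abort("`spacing` must be 3 strictly positive values (x, y, z) in um.")
  }
  structure(list(values = values, spacing = spacing),
            class = "intensity_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<labeled_volume> %d x %d x %d (y,x,z), %d cells, spacing %s um\n",
              d[1], d[2], d[3],
              length(setdiff(unique(as.vector(x$labels)), x$background_label)),
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<intensity_volume> %d x %d x %d (y,x,z), range [%.3g, %.3g]\n",
              d[1], d[2], d[3], min(x$values), max(x$values)))
  invisible(x)
}

# physical centres (x, y, z in um) of voxels given linear indices into the
# (y, x, z) array
voxel_centers <- function(vol, idx) {
  ai <- arrayInd(idx, dim(vol$labels))
  sp <- vol$spacing
  cbind(x = (ai[, 2L] - 0.5) * sp[1],
        y = (ai[, 1L] - 0.5) * sp[2],
        z = (ai[, 3L] - 0.5) * sp[3])
}

check_pair <- function(vol, intensity) {
  if (!identical(dim(vol$labels), dim(intensity$values))) {
    abort(sprintf(
      "label volume %s and intensity volume %s have different shapes",
      paste(dim(vol$labels), collapse = "x"),
      paste(dim(intensity$values), collapse = "x")))
  }
  if (!isTRUE(all.equal(vol$spacing, intensity$spacing))) {
    abort("label and intensity volumes disagree on voxel spacing")
  }
  invisible(TRUE)
}

read_tiff_stack <- function(path, as_is) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = as_is)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , 1L] else p  # collapse grayscale-as-RGB
  })
  d <- dim(pages[[1]])
  array(unlist(pages, use.names = FALSE), dim = c(d[1], d[2], length(pages)))
}

#' Read a co-registered label / intensity volume pair
#'
#' Reads two multi-page grayscale TIFF stacks: integer segmentation labels and
#' wall-stain intensities. Page order is z; within a page rows are y and
#' columns are x.
#'
#' @param label_path Path to the label TIFF (8/16-bit integer).
#' @param intensity_path Path to the intensity TIFF (integer or 32-bit float;
#'   float values are expected in \[0, 1\]).
#' @param spacing Voxel size `(x, y, z)` in micrometres.
#' @param background_label Background label (default 0).
#' @return A list with elements `labels` ([labeled_volume()]) and
#'   `intensity` ([intensity_volume()]).
#' @export
read_volume_pair <- function(label_path, intensity_path, spacing = c(1, 1, 1),
                             background_label = 0L) {
  lab <- read_tiff_stack(label_path, as_is = TRUE)
  if (any(lab != round(lab))) {
    abort(sprintf("label stack '%s' contains non-integer values", label_path))
  }
  inten <- read_tiff_stack(intensity_path, as_is = FALSE)
  vol <- labeled_volume(lab, spacing, background_label)
  iv <- intensity_volume(inten, spacing)
  check_pair(vol, iv)
  list(labels = vol, intensity = iv)
}

#' Write a label / intensity volume pair as multi-page TIFFs
#'
#' Labels are written as 16-bit integers (exact round-trip, labels must be
#' < 65536); intensities as 32-bit float, and must lie in \[0, 1\].
#'
#' @param vol A [labeled_volume()].
#' @param intensity The paired [intensity_volume()].
#' @param label_path,intensity_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_volume_pair <- function(vol, intensity, label_path, intensity_path) {
  check_pair(vol, intensity)
  if (max(vol$labels) > 65535L) abort("labels exceed 16-bit range")
  if (max(intensity$values) > 1) abort("intensities must be in [0, 1] for storage")
  nz <- dim(vol$labels)[3]
  tiff::writeTIFF(lapply(seq_len(nz), function(z) vol$labels[, , z] / 65535),
                  label_path, bits.per.sample = 16L)
  tiff::writeTIFF(lapply(seq_len(nz), function(z) intensity$values[, , z]),
                  intensity_path, bits.per.sample = 32L)
  invisible(c(label_path, intensity_path))
}

facet_table_cols <- function() {
  c(cell_a = "integer", cell_b = "integer", n_faces = "integer",
    area = "double", centroid_x = "double", centroid_y = "double",
    centroid_z = "double", signal_density = "double",
    normal_x = "double", normal_y = "double", normal_z = "double",
    planarity = "double", angle_to_axis = "double", radial_angle = "double",
    depth = "double", radius = "double", region = "character",
    eligible = "logical", is_new_wall = "logical")
}

#' Write a facet table to CSV
#'
#' One row per facet. Columns: `cell_a`, `cell_b` (labels, `cell_a < cell_b`),
#' `n_faces` (voxel-face count), `area` (um^2), `centroid_x/y/z` (um),
#' `signal_density` (a.u.), `normal_x/y/z` (best-fit plane, unit),
#' `planarity`, `angle_to_axis`, `radial_angle` (degrees), `depth`, `radius`
#' (um), `region`, `eligible`, `is_new_wall`. Undefined angles are written as
#' empty cells (NA), never 0.
#'
#' @param facets Facet tibble from [extract_facets()] / [detect_divisions()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_facet_table <- function(facets, path) {
  cols <- names(facet_table_cols())
  missing_cols <- setdiff(cols, names(facets))
  for (mc in missing_cols) facets[[mc]] <- NA
  readr::write_csv(facets[cols], path, na = "")
  invisible(path)
}

#' Read a facet table written by [write_facet_table()]
#'
#' @param path CSV path.
#' @return A facet tibble.
#' @export
read_facet_table <- function(path) {
  spec <- facet_table_cols()
  rmap <- c(integer = "i", double = "d", character = "c", logical = "l")
  readr::read_csv(path,
                  col_types = paste(rmap[spec], collapse = ""),
                  na = c("", "NA"))
}
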