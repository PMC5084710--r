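# Facet extraction from a labeled volume: a facet is the full shared interface
# between two 6-connected cell labels, merged across all shared voxel faces.

# face records along one array axis; returns a list of vectors
faces_along_axis <- function(lab, val, sp, axis) {
  d <- dim(lab)
  n_ax <- d[axis]
  if (n_ax < 2L) {
    return(NULL)
  }
  idx_lo <- switch(axis,
    `1` = slice.index(lab, 1L) < n_ax,
    `2` = slice.index(lab, 2L) < n_ax,
    `3` = slice.index(lab, 3L) < n_ax
  )
  # linear indices of the "low" voxel of each candidate face
  stride <- c(1L, d[1L], d[1L] * d[2L])[axis]
  i_lo <- which(idx_lo)
  i_hi <- i_lo + stride
  keep <- lab[i_lo] != lab[i_hi]
  if (!any(keep)) return(NULL)
  i_lo <- i_lo[keep]
  i_hi <- i_hi[keep]
  ai <- arrayInd(i_lo, d)
  # physical face midpoint: voxel centre of the low voxel, shifted half a
  # voxel along the face axis. Array dims are (y, x, z); spacing is (x, y, z).
  cx <- (ai[, 2L] - 0.5) * sp[1]
  cy <- (ai[, 1L] - 0.5) * sp[2]
  cz <- (ai[, 3L] - 0.5) * sp[3]
  ax_sp <- c(sp[2], sp[1], sp[3])[axis]  # spacing along this array axis
  if (axis == 1L) cy <- cy + ax_sp / 2 else
  if (axis == 2L) cx <- cx + ax_sp / 2 else cz <- cz + ax_sp / 2
  area <- prod(sp) / ax_sp  # product of the two in-face spacings
  la <- lab[i_lo]; lb <- lab[i_hi]
  list(a = pmin(la, lb), b = pmax(la, lb),
       x = cx, y = cy, z = cz,
       area = rep(area, length(i_lo)),
       flank = (val[i_lo] + val[i_hi]) / 2)
}

#' Extract cell-cell facets from a segmented volume
#'
#' Finds every unordered pair of labels sharing 6-connected voxel faces and
#' merges all shared faces into one facet per pair. Per facet it records the
#' physical interface area, the area-weighted centroid of the face midpoints,
#' the wall-signal density (area-weighted mean, over face elements, of the
#' mean intensity of the two flanking voxels), and the best-fitting plane of
#' the face midpoints. Facets that involve the background label are extracted
#' but flagged ineligible (they can never be called as new walls).
#'
#' @param vol A [labeled_volume()].
#' @param intensity The paired [intensity_volume()].
#' @param min_face_elements Minimum number of shared voxel faces for a pair to
#'   count as a facet (default 5; suppresses single-voxel segmentation noise).
#' @param min_fit_points Minimum face midpoints for a plane fit (default 4);
#'   facets below it get `NA` normals.
#' @param keep_faces If `TRUE`, attach a list-column `faces` of per-facet face
#'   midpoint/area matrices.
#' @return A tibble, one row per facet: `cell_a < cell_b`, `n_faces`, `area`
#'   (um^2), `centroid_x/y/z` (um), `signal_density` (a.u.), `normal_x/y/z`,
#'   `planarity` (NA when the fit is degenerate), `eligible`.
#' @export
extract_facets <- function(vol, intensity, min_face_elements = 5L,
                           min_fit_points = 4L, keep_faces = FALSE) {
  check_pair(vol, intensity)
  lab <- vol$labels
  sp <- vol$spacing
  bg <- vol$background_label
  parts <- lapply(1:3, faces_along_axis, lab = lab, val = intensity$values,
                  sp = sp)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0L) {
    abort("no cell-cell interfaces found (single uniform label?)")
  }
  fc <- lapply(c("a", "b", "x", "y", "z", "area", "flank"), function(nm) {
    unlist(lapply(parts, `[[`, nm), use.names = FALSE)
  })
  names(fc) <- c("a", "b", "x", "y", "z", "area", "flank")
  M <- max(lab) + 1
  code <- fc$a * M + fc$b
  grp <- factor(code)
  agg <- rowsum(cbind(one = 1, area = fc$area,
                      ax = fc$area * fc$x, ay = fc$area * fc$y,
                      az = fc$area * fc$z, af = fc$area * fc$flank),
                group = grp, reorder = TRUE)
  codes <- as.numeric(rownames(agg))
  out <- tibble(
    cell_a = as.integer(codes %/% M),
    cell_b = as.integer(codes %% M),
    n_faces = as.integer(agg[, "one"]),
    area = unname(agg[, "area"]),
    centroid_x = unname(agg[, "ax"] / agg[, "area"]),
    centroid_y = unname(agg[, "ay"] / agg[, "area"]),
    centroid_z = unname(agg[, "az"] / agg[, "area"]),
    signal_density = unname(agg[, "af"] / agg[, "area"])
  )
  idx_by_facet <- split(seq_along(code), grp)
  fits <- lapply(idx_by_facet, function(ii) {
    if (length(ii) < min_fit_points) return(NULL)
    tryCatch(
      fit_plane(cbind(fc$x[ii], fc$y[ii], fc$z[ii]), min_points = min_fit_points),
      apexkit_degenerate_fit = function(e) NULL
    )
  })
  out$normal_x <- unname(vapply(fits, function(f) if (is.null(f)) NA_real_ else f$normal[1], 0))
  out$normal_y <- unname(vapply(fits, function(f) if (is.null(f)) NA_real_ else f$normal[2], 0))
  out$normal_z <- unname(vapply(fits, function(f) if (is.null(f)) NA_real_ else f$normal[3], 0))
  out$planarity <- unname(vapply(fits, function(f) if (is.null(f)) NA_real_ else f$planarity, 0))
  out$eligible <- out$cell_a != bg & out$cell_b != bg
  if (keep_faces) {
    out$faces <- unname(lapply(idx_by_facet, function(ii) {
      cbind(x = fc$x[ii], y = fc$y[ii], z = fc$z[ii], area = fc$area[ii])
    }))
  }
  out <- out[out$n_faces >= min_face_elements, , drop = FALSE]
  out
}

#' Call new walls by the weakest-for-both-cells rule
#'
#' A facet between cells a and b is called a new wall when its signal density
#' is minimal (within a relative tie tolerance) among the eligible facets of
#' a AND among the eligible facets of b. Facets touching the background are
#' never called. Ties call every tied facet.
#'
#' @param facets Facet tibble from [extract_facets()].
#' @param tie_tol Relative tolerance for density ties (default `1e-9`, i.e.
#'   essentially exact ties only).
#' @return The facet tibble with a logical `is_new_wall` column.
#' @export
call_new_walls <- function(facets, tie_tol = 1e-9) {
  n <- nrow(facets)
  elig <- which(facets$eligible)
  if (length(elig) == 0L) {
    facets$is_new_wall <- rep(FALSE, n)
    return(facets)
  }
  cells <- c(facets$cell_a[elig], facets$cell_b[elig])
  dens <- rep(facets$signal_density[elig], 2L)
  min_by_cell <- tapply(dens, cells, min)
  thr <- min_by_cell * (1 + tie_tol)
  key_a <- as.character(facets$cell_a)
  key_b <- as.character(facets$cell_b)
  facets$is_new_wall <- as.vector(facets$eligible &
    facets$signal_density <= thr[key_a] &
    facets$signal_density <= thr[key_b])
  facets$is_new_wall[is.na(facets$is_new_wall)] <- FALSE
  facets
}

#' Detect recent cell divisions and their 3D orientation
#'
#' Full pipeline: extract facets, call new walls by the
#' weakest-for-both-cells rule, and attach orientation angles (angle to the
#' stem main axis and radial angle, both from the facet's best-fitting-plane
#' normal) plus depth/radius coordinates in the meristem frame. If `regions`
#' is supplied each facet is also assigned a zone.
#'
#' @inheritParams extract_facets
#' @inheritParams call_new_walls
#' @param frame A [meristem_frame()].
#' @param regions Optional region tibble (see [default_regions()]).
#' @param min_radius Minimum centroid radius (um) for the radial angle to be
#'   defined (default 1).
#' @param verbose Print facet / call counts.
#' @return Facet tibble with `angle_to_axis`, `radial_angle` (degrees, `NA`
#'   when undefined), `depth`, `radius` (um), `region` (or `NA`), and
#'   `is_new_wall`.
#' @export
detect_divisions <- function(vol, intensity, frame, regions = NULL,
                             min_face_elements = 5L, tie_tol = 1e-9,
                             min_fit_points = 4L, min_radius = 1,
                             verbose = FALSE) {
  facets <- extract_facets(vol, intensity, min_face_elements = min_face_elements,
                           min_fit_points = min_fit_points)
  facets <- call_new_walls(facets, tie_tol = tie_tol)
  facets <- add_orientation(facets, frame, min_radius = min_radius)
  facets$region <- if (is.null(regions)) {
    NA_character_
  } else {
    classify_positions(facets$depth, facets$radius, regions)
  }
  if (verbose) {
    message(sprintf("%d facets (%d eligible), %d called as new walls",
                    nrow(facets), sum(facets$eligible), sum(facets$is_new_wall)))
  }
  facets
}

# vectorised angles + frame coordinates for a facet table
add_orientation <- function(facets, frame, min_radius = 1) {
  N <- cbind(facets$normal_x, facets$normal_y, facets$normal_z)
  C <- cbind(facets$centroid_x, facets$centroid_y, facets$centroid_z)
  facets$angle_to_axis <- fold_angle_deg(drop(N %*% frame$axis))
  rel <- sweep(C, 2L, frame$summit)
  ax_comp <- drop(rel %*% frame$axis)
  perp <- rel - outer(ax_comp, frame$axis)
  r <- sqrt(rowSums(perp^2))
  cosr <- rowSums(N * perp) / r
  ra <- fold_angle_deg(cosr)
  ra[!is.finite(r) | r < min_radius] <- NA_real_
  facets$radial_angle <- ra
  facets$depth <- -ax_comp
  facets$radius <- r
  facets
}
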