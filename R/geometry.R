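#' Meristem reference frame
#'
#' A reference frame for a shoot apex: the summit point and the unit vector of
#' the stem main axis (pointing from the stem base toward the summit). All
#' depth/radius coordinates and both orientation angles are defined relative
#' to this frame.
#'
#' @param summit Numeric length-3, summit position in micrometres (x, y, z).
#' @param axis Numeric length-3, main-axis direction; normalised internally.
#'   Must be non-zero.
#' @return An object of class `meristem_frame`: a list with elements `summit`
#'   and `axis` (unit vector).
#' @examples
#' meristem_frame(summit = c(50, 50, 60), axis = c(0, 0, 1))
#' @export
meristem_frame <- function(summit, axis = c(0, 0, 1)) {
  summit <- as.numeric(summit)
  axis <- as.numeric(axis)
  if (length(summit) != 3L || any(!is.finite(summit))) {
    abort("`summit` must be a finite length-3 numeric vector.")
  }
  if (length(axis) != 3L || any(!is.finite(axis))) {
    abort("`axis` must be a finite length-3 numeric vector.")
  }
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) abort("`axis` must be non-zero.")
  structure(list(summit = summit, axis = axis / nrm),
            class = "meristem_frame")
}

#' @export
print.meristem_frame <- function(x, ...) {
  cat("<meristem_frame>\n")
  cat("  summit (um):", format(x$summit, digits = 4), "\n")
  cat("  axis:       ", format(x$axis, digits = 4), "\n")
  invisible(x)
}

#' Best-fitting plane of a 3D point set
#'
#' Fits a plane by total least squares: the normal is the eigenvector of the
#' smallest eigenvalue of the centred second-moment matrix of the points, and
#' the plane passes through their centroid. The sign of the normal is
#' arbitrary; downstream angles fold it out.
#'
#' @param points Numeric matrix with 3 columns (x, y, z in micrometres) or an
#'   object coercible to one.
#' @param min_points Minimum number of points required (default 4).
#' @return An object of class `plane_fit`: list with `normal` (unit 3-vector),
#'   `centroid` (3-vector, um), `planarity` (ratio of smallest to middle
#'   eigenvalue of the scatter matrix; 0 for exactly planar points) and
#'   `n_points`.
#' @details Degenerate input (< `min_points` points, or points essentially
#'   collinear so the plane is not determined) raises an error with class
#'   `apexkit_degenerate_fit`; callers that tolerate degeneracy should catch
#'   it and mark the facet's angles as undefined.
#' @examples
#' pts <- cbind(runif(10), runif(10), 0)
#' fit_plane(pts)$normal   # ~ (0, 0, 1) up to sign
#' @export
fit_plane <- function(points, min_points = 4L) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) abort("`points` must have 3 columns (x, y, z).")
  n <- nrow(points)
  if (n < min_points) {
    abort(sprintf("plane fit needs >= %d points, got %d", min_points, n),
          class = "apexkit_degenerate_fit")
  }
  ctr <- colMeans(points)
  centred <- sweep(points, 2L, ctr)
  scatter <- crossprod(centred) / n
  eg <- eigen(scatter, symmetric = TRUE)
  # eigenvalues descending: lambda1 >= lambda2 >= lambda3
  lam <- pmax(eg$values, 0)
  if (lam[2] <= max(lam[1], .Machine$double.eps) * 1e-12) {
    abort("points are collinear (rank < 2): plane undetermined",
          class = "apexkit_degenerate_fit")
  }
  structure(list(
    normal = eg$vectors[, 3L],
    centroid = ctr,
    planarity = lam[3] / lam[2],
    n_points = n
  ), class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat("<plane_fit>", x$n_points, "points\n")
  cat("  normal:   ", format(x$normal, digits = 4), "\n")
  cat("  centroid: ", format(x$centroid, digits = 4), "\n")
  cat("  planarity:", format(x$planarity, digits = 4), "\n")
  invisible(x)
}

#' @export
tidy.plane_fit <- function(x, ...) {
  tibble(
    normal_x = x$normal[1], normal_y = x$normal[2], normal_z = x$normal[3],
    centroid_x = x$centroid[1], centroid_y = x$centroid[2],
    centroid_z = x$centroid[3],
    planarity = x$planarity, n_points = x$n_points
  )
}

fold_angle_deg <- function(cosine) {
  acos(pmin(1, pmax(0, abs(cosine)))) * 180 / pi
}

#' Angle between a wall plane and the stem main axis
#'
#' Defined as the angle between the wall's best-fitting-plane normal and the
#' main axis, folded into \[0, 90\] degrees. A transversal wall (plane
#' perpendicular to the axis) scores 0 degrees; a wall whose plane contains
#' the axis scores 90 degrees.
#'
#' @param fit A [fit_plane()] result, or a numeric length-3 normal vector.
#' @param frame A [meristem_frame()].
#' @return Angle in degrees, in \[0, 90\].
#' @export
angle_to_axis <- function(fit, frame) {
  n <- if (inherits(fit, "plane_fit")) fit$normal else as.numeric(fit)
  n <- n / sqrt(sum(n^2))
  fold_angle_deg(sum(n * frame$axis))
}

#' Radial angle of a wall plane
#'
#' Angle between the wall's plane normal and the unit radial direction at the
#' wall's centre of mass (the component of `centroid - summit` orthogonal to
#' the main axis), folded into \[0, 90\] degrees. A wall facing the central
#' axis (normal pointing radially) scores near 0; a wall whose plane contains
#' the radial direction scores 90.
#'
#' Undefined (returns `NA`) when the centroid lies within `min_radius` of the
#' axis, where no radial direction exists.
#'
#' @inheritParams angle_to_axis
#' @param centroid Wall centre of mass (um); defaults to the fit's centroid.
#' @param min_radius Minimum distance from the axis (um) for the radial
#'   direction to be defined. Default 1.
#' @return Angle in degrees in \[0, 90\], or `NA_real_` when undefined.
#' @export
radial_angle <- function(fit, frame, centroid = NULL, min_radius = 1) {
  if (inherits(fit, "plane_fit")) {
    n <- fit$normal
    if (is.null(centroid)) centroid <- fit$centroid
  } else {
    n <- as.numeric(fit)
    if (is.null(centroid)) abort("`centroid` required when `fit` is a bare normal.")
  }
  n <- n / sqrt(sum(n^2))
  rel <- centroid - frame$summit
  r_vec <- rel - sum(rel * frame$axis) * frame$axis
  r <- sqrt(sum(r_vec^2))
  if (!is.finite(r) || r < min_radius) return(NA_real_)
  fold_angle_deg(sum(n * r_vec / r))
}

#' Depth and radius of points in a meristem frame
#'
#' Depth is the axial distance below the summit (`(summit - point) . axis`,
#' positive below the summit); radius is the distance from the main axis.
#'
#' @param points Numeric matrix (n x 3) or length-3 vector of positions (um).
#' @param frame A [meristem_frame()].
#' @return A tibble with columns `depth` and `radius` (um), one row per point.
#' @examples
#' fr <- meristem_frame(c(0, 0, 100))
#' depth_and_radius(c(30, 0, 50), fr)  # depth 50, radius 30
#' @export
depth_and_radius <- function(points, frame) {
  points <- if (is.null(dim(points))) matrix(points, ncol = 3L) else as.matrix(points)
  rel <- sweep(points, 2L, frame$summit)
  ax_comp <- drop(rel %*% frame$axis)
  perp <- rel - outer(ax_comp, frame$axis)
  tibble(depth = -ax_comp, radius = sqrt(rowSums(perp^2)))
}

#' Estimate a meristem frame from a labeled volume
#'
#' Convenience default when no frame is supplied: the axis is taken as given
#' (default +z) and the summit is the mean position of the tissue voxels in
#' the top `top_um` micrometres of axial extent of the tissue.
#'
#' @param vol A [labeled_volume()].
#' @param axis Main-axis direction (default `c(0, 0, 1)`).
#' @param top_um Axial window used to average the summit position (um).
#' @return A [meristem_frame()].
#' @export
estimate_frame <- function(vol, axis = c(0, 0, 1), top_um = 2) {
  axis <- axis / sqrt(sum(axis^2))
  cc <- voxel_centers(vol, which(vol$labels != vol$background_label))
  proj <- drop(cc %*% axis)
  keep <- proj >= max(proj) - top_um
  meristem_frame(summit = colMeans(cc[keep, , drop = FALSE]), axis = axis)
}
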