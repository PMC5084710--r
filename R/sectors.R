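# Clonal sector analysis: align landmarked sectors from multiple apices into
# a common frame (summit at the origin, main axis along +z) and measure each
# sector's position, size and main-axis orientation.

# rotation matrix taking unit vector `a` onto unit vector `b` by the minimal
# rotation (about a x b); a == -b rotates by pi about a fixed horizontal axis
rotation_onto <- function(a, b) {
  a <- a / sqrt(sum(a^2))
  b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  s2 <- sum(v^2)
  if (s2 < 1e-24) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to a; pick the
    # most stable coordinate axis
    p <- diag(3)[, which.min(abs(a))]
    p <- p - sum(p * a) * a
    p <- p / sqrt(sum(p^2))
    return(2 * outer(p, p) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s2)
}

#' Align landmark points of one apex into the common frame
#'
#' Rigid transform: translates the summit to the origin and rotates the main
#' axis onto +z by the minimal rotation (about the mutual perpendicular). The
#' azimuth is left untouched — no azimuthal landmark exists across apices.
#' After alignment, depth below the summit is `-z` and radius is
#' `sqrt(x^2 + y^2)`.
#'
#' @param points n x 3 matrix (or length-3 vector) of landmark positions (um).
#' @param frame The apex's [meristem_frame()].
#' @return n x 3 matrix of aligned coordinates.
#' @examples
#' fr <- meristem_frame(c(5, 5, 5), c(0, 0, 1))
#' align_apex(c(5, 5, 0), fr)  # (0, 0, -5)
#' @export
align_apex <- function(points, frame) {
  points <- if (is.null(dim(points))) matrix(points, ncol = 3L) else as.matrix(points)
  R <- rotation_onto(frame$axis, c(0, 0, 1))
  out <- sweep(points, 2L, frame$summit) %*% t(R)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Measure one clonal sector from aligned landmarks
#'
#' From one landmark point per cell (aligned coordinates, see
#' [align_apex()]): centre of mass; principal axis (direction of greatest
#' scatter of the landmark cloud, sign-folded); vertical angle between the
#' principal axis and the stem main axis (+z), in \[0, 90\] degrees; radial
#' angle between the principal axis and the unit radial direction at the
#' centre of mass (undefined when the centre of mass lies within `min_radius`
#' of the axis); length as the extent (max - min) of the landmark projections
#' onto the principal axis; and the cell count. A single-point sector has an
#' undefined axis and angles, and length 0.
#'
#' @param cell_points n x 3 matrix of aligned landmark positions (um).
#' @param min_radius Minimum centre-of-mass radius (um) for the radial angle.
#' @return One-row tibble: `n_cells`, `com_x/y/z`, `axis_x/y/z`,
#'   `vertical_angle`, `sector_radial_angle` (degrees, `NA` when undefined),
#'   `length` (um), `depth`, `radius` (um, of the centre of mass).
#' @export
measure_sector <- function(cell_points, min_radius = 1) {
  pts <- if (is.null(dim(cell_points))) matrix(cell_points, ncol = 3L) else as.matrix(cell_points)
  n <- nrow(pts)
  com <- colMeans(pts)
  r_com <- sqrt(sum(com[1:2]^2))
  if (n < 2L) {
    ax <- c(NA_real_, NA_real_, NA_real_)
    vert <- NA_real_
    rad <- NA_real_
    len <- 0
  } else {
    centred <- sweep(pts, 2L, com)
    eg <- eigen(crossprod(centred) / n, symmetric = TRUE)
    ax <- eg$vectors[, 1L]  # direction of greatest scatter
    vert <- fold_angle_deg(ax[3L])
    rad <- if (r_com < min_radius) NA_real_ else {
      fold_angle_deg(sum(ax[1:2] * com[1:2]) / r_com)
    }
    proj <- drop(centred %*% ax)
    len <- max(proj) - min(proj)
  }
  tibble(n_cells = n,
         com_x = com[1], com_y = com[2], com_z = com[3],
         axis_x = ax[1], axis_y = ax[2], axis_z = ax[3],
         vertical_angle = vert, sector_radial_angle = rad,
         length = len, depth = -com[3], radius = r_com)
}

#' Align and measure all sectors of a landmark table
#'
#' @param landmarks Tibble with columns `apex_id`, `sector_id`, `x`, `y`, `z`
#'   (um, raw image coordinates).
#' @param frames Named list of [meristem_frame()] objects, one per `apex_id`.
#' @param regions Optional region tibble; when given, each sector's centre of
#'   mass is assigned a `region`.
#' @inheritParams measure_sector
#' @return Tibble of per-sector measurements (one row per apex x sector, see
#'   [measure_sector()]), plus `apex_id`, `sector_id` and optionally `region`.
#' @export
measure_sectors <- function(landmarks, frames, regions = default_regions(),
                            min_radius = 1) {
  need <- c("apex_id", "sector_id", "x", "y", "z")
  if (!all(need %in% names(landmarks))) {
    abort(paste("landmark table needs columns:", paste(need, collapse = ", ")))
  }
  out <- landmarks |>
    dplyr::group_by(.data$apex_id, .data$sector_id) |>
    dplyr::group_modify(function(df, key) {
      fr <- frames[[as.character(key$apex_id)]]
      if (is.null(fr)) abort(paste("no frame for apex", key$apex_id))
      measure_sector(align_apex(cbind(df$x, df$y, df$z), fr),
                     min_radius = min_radius)
    }) |>
    dplyr::ungroup()
  if (!is.null(regions)) {
    out$region <- classify_positions(out$depth, out$radius, regions)
  }
  out
}

#' Project sector landmarks for 2D display
#'
#' `vertical` mode views down the stem axis (drops z, keeping x/y).
#' `radial` mode projects each sector onto the plane through its centre of
#' mass and the stem axis, giving signed-radius / height coordinates `(r, z)`;
#' the sign follows the sector's centre-of-mass x-coordinate so that sectors
#' on the right and left of the vertical view stay on the right and left of
#' the radial view.
#'
#' @param landmarks Aligned landmark tibble with `apex_id`, `sector_id`,
#'   `x`, `y`, `z`.
#' @param mode `"vertical"` or `"radial"`.
#' @return Tibble `apex_id`, `sector_id`, `u`, `v` (um): `(x, y)` in vertical
#'   mode, `(signed r, z)` in radial mode.
#' @export
project_sectors <- function(landmarks, mode = c("vertical", "radial")) {
  mode <- match.arg(mode)
  if (mode == "vertical") {
    return(tibble(apex_id = landmarks$apex_id, sector_id = landmarks$sector_id,
                  u = landmarks$x, v = landmarks$y))
  }
  landmarks |>
    dplyr::group_by(.data$apex_id, .data$sector_id) |>
    dplyr::group_modify(function(df, key) {
      com <- c(mean(df$x), mean(df$y))
      r_com <- sqrt(sum(com^2))
      if (r_com < 1e-9) {
        warn(paste("sector", key$sector_id,
                   "centre of mass lies on the axis; radial sign set positive"))
        rhat <- c(1, 0)
        sgn <- 1
      } else {
        rhat <- com / r_com
        sgn <- if (com[1] >= 0) 1 else -1
      }
      tibble(u = sgn * (df$x * rhat[1] + df$y * rhat[2]), v = df$z)
    }) |>
    dplyr::ungroup()
}

#' Compare sector metrics between two groups, per region
#'
#' Runs a two-sided Mann-Whitney test per region for each requested sector
#' metric (vertical angle, radial angle, cell count, main-axis length).
#' Regions present in only one group are skipped with a warning.
#'
#' @param group_1,group_2 Sector-measurement tibbles from [measure_sectors()]
#'   (must carry a `region` column).
#' @param metrics Metric columns to compare.
#' @return Tibble: `region`, `metric`, `statistic` (U of group 1), `p.value`,
#'   `n1`, `n2`.
#' @export
compare_sector_stats <- function(group_1, group_2,
                                 metrics = c("vertical_angle",
                                             "sector_radial_angle",
                                             "n_cells", "length")) {
  regions <- sort(unique(c(group_1$region, group_2$region)))
  regions <- regions[!is.na(regions)]
  rows <- list()
  for (rg in regions) {
    g1 <- group_1[!is.na(group_1$region) & group_1$region == rg, , drop = FALSE]
    g2 <- group_2[!is.na(group_2$region) & group_2$region == rg, , drop = FALSE]
    if (nrow(g1) == 0L || nrow(g2) == 0L) {
      warn(paste("region", rg, "empty in one group; skipped"))
      next
    }
    for (m in metrics) {
      v1 <- g1[[m]][!is.na(g1[[m]])]
      v2 <- g2[[m]][!is.na(g2[[m]])]
      if (length(v1) == 0L || length(v2) == 0L) next
      mw <- mann_whitney(v1, v2)
      rows[[length(rows) + 1L]] <- tibble(
        region = rg, metric = m, statistic = mw$statistic,
        p.value = mw$p.value, n1 = mw$n1, n2 = mw$n2)
    }
  }
  if (length(rows) == 0L) {
    return(tibble(region = character(), metric = character(),
                  statistic = numeric(), p.value = numeric(),
                  n1 = integer(), n2 = integer()))
  }
  dplyr::bind_rows(rows)
}
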