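#' Default meristem zonation windows
#'
#' Depth/radius windows (um, relative to the summit and main axis) for the
#' apical region (AR), rib-meristem core (RC) and rib-meristem periphery
#' (RP): AR depth 0-30 / radius 0-40, RC depth 30-60 / radius 0-40, RP depth
#' 30-60 / radius 40-50. Windows are half-open `[min, max)` so the shared
#' boundaries belong unambiguously to the deeper / outer region.
#'
#' @return Tibble with columns `region`, `depth_min`, `depth_max`,
#'   `radius_min`, `radius_max`.
#' @export
default_regions <- function() {
  tibble(
    region = c("AR", "RC", "RP"),
    depth_min = c(0, 30, 30),
    depth_max = c(30, 60, 60),
    radius_min = c(0, 0, 40),
    radius_max = c(40, 40, 50)
  )
}

# vectorised region lookup; first matching region wins, NA when none matches
classify_positions <- function(depth, radius, regions) {
  validate_regions(regions)
  out <- rep(NA_character_, length(depth))
  n_hits <- integer(length(depth))
  for (i in seq_len(nrow(regions))) {
    hit <- !is.na(depth) & !is.na(radius) &
      depth >= regions$depth_min[i] & depth < regions$depth_max[i] &
      radius >= regions$radius_min[i] & radius < regions$radius_max[i]
    n_hits <- n_hits + hit
    out[hit & is.na(out)] <- regions$region[i]
  }
  if (any(n_hits > 1L)) {
    warn("overlapping region windows: first matching region wins")
  }
  out
}

validate_regions <- function(regions) {
  need <- c("region", "depth_min", "depth_max", "radius_min", "radius_max")
  if (!all(need %in% names(regions))) {
    abort(paste("regions table needs columns:", paste(need, collapse = ", ")))
  }
  if (any(regions$depth_min > regions$depth_max) ||
      any(regions$radius_min > regions$radius_max)) {
    abort("region windows must have min <= max")
  }
  invisible(regions)
}

#' Assign facets (or any positioned records) to meristem regions
#'
#' Adds `depth`, `radius` (if missing) and `region` columns. Classification
#' uses half-open windows `[min, max)`; records matching no region get `NA`.
#'
#' @param facets Tibble with centroid columns `centroid_x/y/z` (or existing
#'   `depth`/`radius` columns).
#' @param frame A [meristem_frame()]; only needed when depth/radius are absent.
#' @param regions Region window tibble (default [default_regions()]).
#' @return The input tibble with a `region` column.
#' @export
classify_facets <- function(facets, frame = NULL, regions = default_regions()) {
  if (!all(c("depth", "radius") %in% names(facets))) {
    if (is.null(frame)) abort("`frame` required to compute depth/radius")
    dr <- depth_and_radius(
      cbind(facets$centroid_x, facets$centroid_y, facets$centroid_z), frame)
    facets$depth <- dr$depth
    facets$radius <- dr$radius
  }
  facets$region <- classify_positions(facets$depth, facets$radius, regions)
  facets
}

# ---- Mann-Whitney U -------------------------------------------------------

# exact distribution of the doubled rank-sum of a size-n1 subset, by dynamic
# programming over the pooled doubled midranks (handles ties exactly)
ranksum_dist_counts <- function(r2, n1) {
  r2 <- sort(as.integer(r2))
  smax <- sum(r2[(length(r2) - n1 + 1L):length(r2)])
  f <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  f[1L, 1L] <- 1
  for (r in r2) {
    kmax <- n1
    for (k in kmax:1L) {
      nonzero <- which(f[k, ] > 0)
      nonzero <- nonzero[nonzero + r <= smax + 1L]
      if (length(nonzero)) {
        f[k + 1L, nonzero + r] <- f[k + 1L, nonzero + r] + f[k, nonzero]
      }
    }
  }
  f[n1 + 1L, ]  # counts indexed by doubled rank-sum s = index - 1
}

#' Mann-Whitney U test (exact under ties for small samples)
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test. When `min(n1, n2) <= 8`
#' (and `exact` is not `FALSE`) the p-value is computed by exact enumeration
#' of the permutation distribution of the rank sum — a dynamic programme over
#' midranks, so ties are handled exactly. Otherwise a tie-corrected normal
#' approximation with continuity correction is used. The two-sided exact
#' p-value is `min(1, 2 * min(P(R <= r), P(R >= r)))`.
#'
#' @param x,y Numeric samples.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact path; default
#'   `NULL` chooses by sample size.
#' @return Object of class `apexkit_mw`: `statistic` (U of `x`), `p.value`,
#'   `n1`, `n2`, `exact`, `method`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(10, 20, 30))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1L || n2 < 1L) abort("both samples must be non-empty")
  pooled <- c(x, y)
  rk <- rank(pooled)  # midranks
  r1 <- sum(rk[seq_len(n1)])
  u1 <- r1 - n1 * (n1 + 1) / 2
  use_exact <- if (is.null(exact)) min(n1, n2) <= 8L else isTRUE(exact)
  if (use_exact) {
    r2 <- as.integer(round(2 * rk))
    # enumerate over the smaller group for speed; U folds symmetrically
    if (n1 <= n2) {
      counts <- ranksum_dist_counts(r2, n1)
      obs <- as.integer(round(2 * r1))
    } else {
      counts <- ranksum_dist_counts(r2, n2)
      obs <- as.integer(round(2 * sum(rk[(n1 + 1L):(n1 + n2)])))
    }
    total <- sum(counts)
    s <- seq_along(counts) - 1L
    p_le <- sum(counts[s <= obs]) / total
    p_ge <- sum(counts[s >= obs]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration (tie-aware)"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- u1 - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation (tie-corrected, continuity-corrected)"
  }
  structure(list(statistic = u1, p.value = p, n1 = n1, n2 = n2,
                 exact = use_exact, method = method),
            class = "apexkit_mw")
}

#' @export
print.apexkit_mw <- function(x, ...) {
  cat("Mann-Whitney U test (", x$method, ")\n", sep = "")
  cat(sprintf("  U = %g, n = %d/%d, two-sided p = %.6g\n",
              x$statistic, x$n1, x$n2, x$p.value))
  invisible(x)
}

#' @export
tidy.apexkit_mw <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value,
         n1 = x$n1, n2 = x$n2, exact = x$exact, method = x$method)
}

#' Compare angle distributions between two samples
#'
#' Two-sided Mann-Whitney comparison of two sets of wall-orientation angles
#' (or any numeric samples). Thin wrapper over [mann_whitney()].
#'
#' @param sample_1,sample_2 Numeric vectors of angles (degrees); `NA`s
#'   (undefined angles) are dropped.
#' @inheritParams mann_whitney
#' @return An `apexkit_mw` object.
#' @export
compare_angles <- function(sample_1, sample_2, exact = NULL) {
  mann_whitney(sample_1, sample_2, exact = exact)
}

#' Compare one metric between two regions of a classified facet table
#'
#' Convenience wrapper: pulls the metric values of the called new walls in two
#' regions and runs [compare_angles()].
#'
#' @param facets Classified facet tibble (with `region` and `is_new_wall`).
#' @param region_1,region_2 Region names.
#' @param metric Column name, `"angle_to_axis"` or `"radial_angle"`.
#' @inheritParams mann_whitney
#' @return An `apexkit_mw` object.
#' @export
compare_zone_angles <- function(facets, region_1, region_2,
                                metric = "angle_to_axis", exact = NULL) {
  nw <- facets[facets$is_new_wall & !is.na(facets$region), , drop = FALSE]
  compare_angles(nw[[metric]][nw$region == region_1],
                 nw[[metric]][nw$region == region_2], exact = exact)
}

#' Boxplot-style summary of new-wall angles per region
#'
#' For each region (and optional grouping columns such as genotype or apex
#' id), summarises each orientation metric over the called new walls: count,
#' median, quartiles (midpoint-interpolated empirical quantiles, R type 5),
#' whisker bounds under the 1.5 x IQR rule (whiskers end at the most extreme
#' data point within the fences) and the list of outliers beyond them.
#' Undefined (`NA`) angle values are dropped per metric.
#'
#' @param facets Classified facet tibble.
#' @param metrics Metric columns to summarise.
#' @param group Optional character vector of extra grouping columns.
#' @param new_walls_only Restrict to called new walls (default `TRUE`).
#' @return Tibble: grouping columns, `metric`, `n`, `median`, `q1`, `q3`,
#'   `whisker_lo`, `whisker_hi`, and list-column `outliers`.
#' @export
summarize_by_region <- function(facets,
                                metrics = c("angle_to_axis", "radial_angle"),
                                group = NULL, new_walls_only = TRUE) {
  dat <- facets
  if (new_walls_only && "is_new_wall" %in% names(dat)) {
    dat <- dat[dat$is_new_wall, , drop = FALSE]
  }
  long <- tidyr::pivot_longer(
    dat[, c("region", group, metrics), drop = FALSE],
    cols = dplyr::all_of(metrics), names_to = "metric", values_to = "value")
  long <- long[!is.na(long$value), , drop = FALSE]
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("region", group, "metric")))) |>
    dplyr::summarise(box_stats(.data$value), .groups = "drop")
}

box_stats <- function(v) {
  q <- quantile(v, c(0.25, 0.5, 0.75), type = 5, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- v[v >= lo_fence & v <= hi_fence]
  tibble(
    n = length(v), median = q[2], q1 = q[1], q3 = q[3],
    whisker_lo = min(inside), whisker_hi = max(inside),
    outliers = list(sort(v[v < lo_fence | v > hi_fence]))
  )
}
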