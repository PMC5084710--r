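# Seeded synthetic-data generators: dome-shaped tessellated meristem volumes
# with planted divisions, clonal sectors with known axes, and toy genomes
# with positionally biased replicate ChIP peaks. Every generator is
# bit-reproducible given its seed and records ground truth.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) v / sqrt(sum(v^2))

# any unit vector perpendicular to `a`
perp3 <- function(a) {
  p <- diag(3)[, which.min(abs(a))]
  unit3(p - sum(p * a) * a)
}

# random unit vector on the sphere
random_unit <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

# tilt a unit vector by |N(0, sd_deg)| degrees in a uniform random azimuth
tilt_vector <- function(base, sd_deg) {
  if (sd_deg <= 0) return(base)
  theta <- abs(rnorm(1, 0, sd_deg)) * pi / 180
  phi <- runif(1, 0, 2 * pi)
  u <- perp3(base)
  v <- cross3(base, u)
  sin(theta) * (cos(phi) * u + sin(phi) * v) + cos(theta) * base
}

#' Division-planting specification rows
#'
#' One row per planting rule: how many divisions to plant in a depth/radius
#' window and from which plane-orientation distribution to draw their wall
#' normals. Modes: `"transversal"` (normal along the stem axis; wall
#' perpendicular to the axis), `"radial"` (normal along the radial direction;
#' wall facing the central axis — the peripheral, rib-zone-widening division
#' type), `"anticlinal"` (normal tangential; wall contains both the axis and
#' the radial direction), `"isotropic"` (uniform random normal). `angle_sd`
#' is the folded-normal tilt (degrees) applied around the mode's base
#' direction.
#'
#' @param n Number of divisions to plant.
#' @param mode Orientation mode (see above).
#' @param angle_sd Tilt standard deviation in degrees (default 10).
#' @param depth,radius Length-2 windows in um (half-open).
#' @param region Label stored with the ground truth.
#' @return One-row tibble.
#' @export
division_spec <- function(n, mode = c("isotropic", "transversal", "radial",
                                      "anticlinal"),
                          angle_sd = 10, depth = c(0, Inf),
                          radius = c(0, Inf), region = NA_character_) {
  mode <- match.arg(mode)
  tibble(region = region, n = as.integer(n), mode = mode, angle_sd = angle_sd,
         depth_min = depth[1], depth_max = depth[2],
         radius_min = radius[1], radius_max = radius[2])
}

#' Wild-type-like and mutant-like zonation planting schemes
#'
#' Wild-type-like: transversal divisions in the rib-meristem core (RC),
#' axis-facing radial divisions in the rib-meristem periphery (RP), anticlinal
#' divisions in the apical region (AR). Mutant-like: identical except the RC
#' draws from the RP's (radial) orientation distribution, abolishing the
#' core/periphery contrast.
#'
#' @param n_ar,n_rc,n_rp Divisions per region.
#' @param angle_sd Orientation tilt sd (degrees).
#' @return A division-spec tibble for [simulate_meristem()].
#' @export
wildtype_divisions <- function(n_ar = 60, n_rc = 85, n_rp = 85, angle_sd = 10) {
  dplyr::bind_rows(
    division_spec(n_ar, "anticlinal", angle_sd, depth = c(0, 30),
                  radius = c(0, 40), region = "AR"),
    division_spec(n_rc, "transversal", angle_sd, depth = c(30, 60),
                  radius = c(0, 40), region = "RC"),
    division_spec(n_rp, "radial", angle_sd, depth = c(30, 60),
                  radius = c(40, 50), region = "RP")
  )
}

#' @rdname wildtype_divisions
#' @export
mutant_divisions <- function(n_ar = 60, n_rc = 85, n_rp = 85, angle_sd = 10) {
  spec <- wildtype_divisions(n_ar, n_rc, n_rp, angle_sd)
  spec$mode[spec$region == "RC"] <- "radial"
  spec
}

#' Parameters for the synthetic meristem generator
#'
#' The default dome is a compact apex used for detection benchmarking:
#' 100 planted divisions among ~120 cells (most cells carry a recent
#' division, as in real tissue where every cell's weakest wall is its
#' newest), new/old wall intensity ratio 0.5 and voxel noise at 10% of the
#' old-wall intensity. For zonation studies use [zonation_sim_params()],
#' whose dome spans all three canonical regions.
#'
#' @param dome_radius Maximum tissue radius (um).
#' @param dome_height Axial tissue extent below the summit (um).
#' @param cap_drop How far (um) the paraboloid surface falls from the summit
#'   to the dome edge.
#' @param cell_diameter Target cell diameter (um); sets the cell count.
#' @param spacing Voxel spacing `(x, y, z)` in um.
#' @param divisions Division-spec tibble (see [division_spec()]).
#' @param old_intensity Old-wall stain level (a.u. in \[0, 1\]).
#' @param intensity_ratio New/old wall intensity ratio, in (0, 1\].
#' @param noise_sd Gaussian voxel noise, as a fraction of `old_intensity`.
#' @param interior_level Cell-interior stain level, fraction of
#'   `old_intensity`.
#' @param seed RNG seed fixing all randomness.
#' @return A parameter list of class `meristem_sim_params`.
#' @export
sim_meristem_params <- function(dome_radius = 28, dome_height = 40,
                                cap_drop = 12, cell_diameter = 9,
                                spacing = c(1, 1, 1),
                                divisions = division_spec(100, "isotropic"),
                                old_intensity = 0.7, intensity_ratio = 0.5,
                                noise_sd = 0.1, interior_level = 0.05,
                                seed = 1L) {
  if (intensity_ratio <= 0 || intensity_ratio > 1) {
    abort("`intensity_ratio` must be in (0, 1]")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  structure(list(dome_radius = dome_radius, dome_height = dome_height,
                 cap_drop = cap_drop, cell_diameter = cell_diameter,
                 spacing = spacing, divisions = divisions,
                 old_intensity = old_intensity,
                 intensity_ratio = intensity_ratio, noise_sd = noise_sd,
                 interior_level = interior_level, seed = as.integer(seed)),
            class = "meristem_sim_params")
}

#' @rdname sim_meristem_params
#' @param genotype `"wildtype"` or `"mutant"` planting scheme.
#' @param ... Overrides passed to [sim_meristem_params()].
#' @export
zonation_sim_params <- function(genotype = c("wildtype", "mutant"),
                                spacing = c(1, 1, 1), seed = 1L, ...) {
  genotype <- match.arg(genotype)
  div <- if (genotype == "wildtype") wildtype_divisions() else mutant_divisions()
  sim_meristem_params(dome_radius = 55, dome_height = 66, cap_drop = 22,
                      cell_diameter = 9, spacing = spacing, divisions = div,
                      seed = seed, ...)
}

# nearest-seed tessellation, chunked so distance blocks stay small;
# argmax of (p . s - |s|^2 / 2) over seeds s is the nearest seed
nearest_seed <- function(pts, seeds, chunk = 20000L) {
  ts <- t(seeds)
  s2h <- rowSums(seeds^2) / 2
  out <- integer(nrow(pts))
  i <- 1L
  while (i <= nrow(pts)) {
    j <- min(i + chunk - 1L, nrow(pts))
    score <- pts[i:j, , drop = FALSE] %*% ts
    score <- score - rep(s2h, each = j - i + 1L)
    out[i:j] <- max.col(score, ties.method = "first")
    i <- j + 1L
  }
  out
}

#' Simulate a segmented meristem volume with planted divisions
#'
#' Builds a paraboloid-capped tissue dome, tessellates it into cells by
#' nearest-seed partition, splits selected mother cells by planes drawn from
#' region-specific orientation distributions, and renders a wall-stain
#' intensity volume: old walls at `old_intensity`, planted (new) walls at
#' `intensity_ratio * old_intensity`, cell interiors near zero, plus Gaussian
#' voxel noise. The returned ground truth lists each planted wall's daughter
#' label pair and true plane normal.
#'
#' @param params A [sim_meristem_params()] list.
#' @return List of class `meristem_sim`: `labels` ([labeled_volume()]),
#'   `intensity` ([intensity_volume()]), `frame` ([meristem_frame()]),
#'   `truth` (tibble: `cell_a`, `cell_b`, `region`, `mode`,
#'   `normal_x/y/z`), `n_cells`, `params`.
#' @export
simulate_meristem <- function(params = sim_meristem_params()) {
  stopifnot(inherits(params, "meristem_sim_params"))
  with_seed(params$seed, simulate_meristem_impl(params))
}

simulate_meristem_impl <- function(p) {
  sp <- p$spacing
  margin <- 2  # um of background padding
  nx <- ceiling((2 * p$dome_radius + 2 * margin) / sp[1])
  ny <- ceiling((2 * p$dome_radius + 2 * margin) / sp[2])
  nz <- ceiling((p$dome_height + margin) / sp[3])
  d <- c(ny, nx, nz)
  # voxel centres
  cx <- (seq_len(nx) - 0.5) * sp[1]
  cy <- (seq_len(ny) - 0.5) * sp[2]
  cz <- (seq_len(nz) - 0.5) * sp[3]
  x0 <- nx * sp[1] / 2
  y0 <- ny * sp[2] / 2
  X <- array(rep(cx, each = ny), d)
  Y <- array(cy, d)
  Z <- array(rep(cz, each = ny * nx), d)
  R2 <- (X - x0)^2 + (Y - y0)^2
  surface <- p$dome_height - p$cap_drop * R2 / p$dome_radius^2
  mask <- which(R2 <= p$dome_radius^2 & Z <= surface)
  if (length(mask) == 0L) abort("empty tissue mask: check dome parameters")
  vox <- cbind(X[mask], Y[mask], Z[mask])
  voxel_volume <- prod(sp)
  n_cells <- round(length(mask) * voxel_volume / p$cell_diameter^3)
  n_div_total <- sum(p$divisions$n)
  if (n_cells < max(2L, n_div_total)) {
    abort(sprintf(paste("cell diameter %.3g um too large for this dome:",
                        "only %d cells for %d planted divisions"),
                  p$cell_diameter, n_cells, n_div_total))
  }
  seeds <- vox[sample.int(length(mask), n_cells), , drop = FALSE]
  assign_id <- nearest_seed(vox, seeds)
  lab <- array(0L, d)
  lab[mask] <- assign_id
  # per-cell voxel lists and centroids (in mask-local indexing)
  cell_vox <- split(seq_along(mask), assign_id)
  centroids <- t(vapply(cell_vox, function(ii) colMeans(vox[ii, , drop = FALSE]),
                        numeric(3)))
  summit <- c(x0, y0, p$dome_height)
  frame <- meristem_frame(summit, c(0, 0, 1))
  dr <- depth_and_radius(centroids, frame)
  next_label <- n_cells + 1L
  divided <- logical(n_cells)
  truth <- list()
  min_half <- 4L  # voxels per daughter
  for (k in seq_len(nrow(p$divisions))) {
    rule <- p$divisions[k, ]
    cand <- which(!divided &
                    dr$depth >= rule$depth_min & dr$depth < rule$depth_max &
                    dr$radius >= rule$radius_min & dr$radius < rule$radius_max &
                    vapply(cell_vox, length, 0L)[seq_len(n_cells)] >= 2L * min_half)
    if (length(cand) < rule$n) {
      abort(sprintf("division rule %d: only %d candidate cells for %d divisions",
                    k, length(cand), rule$n))
    }
    chosen <- cand[sample.int(length(cand), rule$n)]
    for (cell in chosen) {
      ctr <- centroids[cell, ]
      base <- switch(rule$mode,
        transversal = c(0, 0, 1),
        radial = {
          rv <- c(ctr[1] - x0, ctr[2] - y0, 0)
          if (sqrt(sum(rv^2)) < 1) perp3(c(0, 0, 1)) else unit3(rv)
        },
        anticlinal = {
          rv <- c(ctr[1] - x0, ctr[2] - y0, 0)
          if (sqrt(sum(rv^2)) < 1) perp3(c(0, 0, 1)) else
            unit3(cross3(c(0, 0, 1), unit3(rv)))
        },
        isotropic = random_unit()
      )
      nrm <- if (rule$mode == "isotropic") base else tilt_vector(base, rule$angle_sd)
      ii <- cell_vox[[cell]]
      side <- drop(sweep(vox[ii, , drop = FALSE], 2L, ctr) %*% nrm)
      upper <- side >= 0
      if (sum(upper) < min_half || sum(!upper) < min_half) {
        upper <- side >= median(side)  # fall back to a balanced cut
        if (sum(upper) < min_half || sum(!upper) < min_half) next
      }
      lab[mask[ii[upper]]] <- next_label
      cell_vox[[as.character(next_label)]] <- ii[upper]
      cell_vox[[cell]] <- ii[!upper]
      divided[cell] <- TRUE
      truth[[length(truth) + 1L]] <- tibble(
        cell_a = min(cell, next_label), cell_b = max(cell, next_label),
        region = rule$region, mode = rule$mode,
        normal_x = nrm[1], normal_y = nrm[2], normal_z = nrm[3])
      next_label <- next_label + 1L
    }
  }
  truth <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble(cell_a = integer(), cell_b = integer(), region = character(),
           mode = character(), normal_x = numeric(), normal_y = numeric(),
           normal_z = numeric())
  values <- render_intensity(lab, truth, p)
  list(
    labels = labeled_volume(lab, sp),
    intensity = intensity_volume(values, sp),
    frame = frame,
    truth = truth,
    n_cells = n_cells,
    params = p
  ) |> structure(class = "meristem_sim")
}

# stain rendering: per-voxel mix of old/new wall contacts
render_intensity <- function(lab, truth, p) {
  d <- dim(lab)
  M <- max(lab) + 1
  new_codes <- truth$cell_a * M + truth$cell_b
  n_new <- array(0L, d)
  n_old <- array(0L, d)
  for (axis in 1:3) {
    stride <- c(1L, d[1L], d[1L] * d[2L])[axis]
    i_lo <- which(slice.index(lab, axis) < d[axis])
    i_hi <- i_lo + stride
    keep <- lab[i_lo] != lab[i_hi]
    i_lo <- i_lo[keep]; i_hi <- i_hi[keep]
    code <- pmin(lab[i_lo], lab[i_hi]) * M + pmax(lab[i_lo], lab[i_hi])
    isnew <- code %in% new_codes
    n_new[i_lo] <- n_new[i_lo] + isnew
    n_new[i_hi] <- n_new[i_hi] + isnew
    n_old[i_lo] <- n_old[i_lo] + !isnew
    n_old[i_hi] <- n_old[i_hi] + !isnew
  }
  n_contact <- n_new + n_old
  wall_mix <- ifelse(n_contact > 0,
                     (n_old + p$intensity_ratio * n_new) / pmax(n_contact, 1L),
                     p$interior_level)
  values <- p$old_intensity * wall_mix
  values[lab == 0L] <- 0
  if (p$noise_sd > 0) {
    values <- values + rnorm(length(values), 0, p$noise_sd * p$old_intensity)
  }
  array(pmin(1, pmax(0, values)), d)
}

#' @export
print.meristem_sim <- function(x, ...) {
  cat("<meristem_sim>", x$n_cells, "cells,", nrow(x$truth),
      "planted divisions\n")
  print(x$labels)
  invisible(x)
}

#' Score detected new walls against a simulation's ground truth
#'
#' @param facets Facet tibble with `is_new_wall` (from [detect_divisions()]).
#' @param sim A [simulate_meristem()] result (or its `truth` tibble).
#' @return One-row tibble: `n_true`, `n_called`, `true_positives`, `recall`,
#'   `precision`.
#' @export
score_new_walls <- function(facets, sim) {
  truth <- if (inherits(sim, "meristem_sim")) sim$truth else sim
  true_keys <- paste(truth$cell_a, truth$cell_b)
  called <- facets[facets$is_new_wall, , drop = FALSE]
  called_keys <- paste(called$cell_a, called$cell_b)
  tp <- sum(called_keys %in% true_keys)
  tibble(n_true = nrow(truth), n_called = nrow(called), true_positives = tp,
         recall = tp / max(nrow(truth), 1L),
         precision = tp / max(nrow(called), 1L))
}

# ---- clonal sectors -------------------------------------------------------

#' Sector-planting specification rows
#'
#' @param n Sectors to plant in the window.
#' @param mode Growth-direction mode: `"vertical"` (along the stem axis),
#'   `"radial"` (along the radial direction at the sector origin) or
#'   `"tangential"`.
#' @param angle_sd Direction tilt sd (degrees).
#' @param depth,radius Origin windows (um).
#' @param region Label stored with the ground truth.
#' @return One-row tibble.
#' @export
sector_spec <- function(n, mode = c("vertical", "radial", "tangential"),
                        angle_sd = 10, depth = c(0, 30), radius = c(5, 40),
                        region = NA_character_) {
  mode <- match.arg(mode)
  tibble(region = region, n = as.integer(n), mode = mode, angle_sd = angle_sd,
         depth_min = depth[1], depth_max = depth[2],
         radius_min = radius[1], radius_max = radius[2])
}

default_sector_spec <- function(n = 15, angle_sd = 10) {
  # origin windows padded ~1 um inside the canonical region windows so the
  # measured centre of mass stays classifiable despite landmark jitter
  dplyr::bind_rows(
    sector_spec(n, "vertical", angle_sd, depth = c(6, 29), radius = c(6, 39),
                region = "AR"),
    sector_spec(n, "vertical", angle_sd, depth = c(31, 59), radius = c(6, 39),
                region = "RC"),
    sector_spec(n, "radial", angle_sd, depth = c(31, 59), radius = c(41, 49),
                region = "RP")
  )
}

#' Simulate clonal sectors across apices with known geometry
#'
#' Each sector is a chain of cell landmarks along a planted direction, with
#' isotropic Gaussian jitter on every landmark, grown from an origin sampled
#' in its region's depth/radius window. Sectors are distributed over
#' `n_apices` apices; each apex gets a random rigid frame (random summit,
#' random tilted axis), and landmarks are reported in raw apex coordinates
#' together with the per-apex [meristem_frame()] needed to align them.
#' Ground truth records each sector's actually sampled direction (vertical
#' and radial angles), ideal main-axis length `(n_cells - 1) * step` and cell
#' count.
#'
#' @param spec Sector-spec tibble (default: 15 vertical sectors in AR and RC,
#'   15 radial sectors in RP).
#' @param n_apices Number of apices to spread sectors over (default 5).
#' @param cells_range Min/max cells per sector (uniform; default 6-14).
#' @param step Landmark spacing along the growth direction (um, default 6).
#' @param jitter_sd Landmark jitter sd (um, default 1).
#' @param vertical_shift Extra tilt (degrees) added to every planted
#'   direction's polar angle — used to emulate a genotype with reoriented
#'   growth (default 0).
#' @param shift_regions Regions the shift applies to (default all).
#' @param seed RNG seed.
#' @return List of class `sector_sim`: `landmarks` (tibble `apex_id`,
#'   `sector_id`, `x`, `y`, `z`), `frames` (named list of frames), `truth`
#'   (tibble per sector: `region`, true angles, `true_length`, `n_cells`).
#' @export
simulate_sectors <- function(spec = default_sector_spec(), n_apices = 5,
                             cells_range = c(6, 14), step = 6, jitter_sd = 1,
                             vertical_shift = 0, shift_regions = NULL,
                             seed = 1L) {
  with_seed(seed, {
    frames <- list()
    apex_R <- list()
    for (a in seq_len(n_apices)) {
      axis <- unit3(c(rnorm(2, 0, 0.3), 1))
      summit <- runif(3, 40, 160)
      frames[[as.character(a)]] <- meristem_frame(summit, axis)
      apex_R[[a]] <- rotation_onto(c(0, 0, 1), axis)  # aligned -> raw
    }
    landmarks <- list()
    truth <- list()
    sector_id <- 0L
    for (k in seq_len(nrow(spec))) {
      rule <- spec[k, ]
      for (s in seq_len(rule$n)) {
        sector_id <- sector_id + 1L
        a <- ((sector_id - 1L) %% n_apices) + 1L
        depth <- runif(1, rule$depth_min, rule$depth_max)
        radius <- runif(1, rule$radius_min, rule$radius_max)
        phi <- runif(1, 0, 2 * pi)
        origin <- c(radius * cos(phi), radius * sin(phi), -depth)
        rhat <- unit3(c(origin[1], origin[2], 0))
        base <- switch(rule$mode,
                       vertical = c(0, 0, 1),
                       radial = rhat,
                       tangential = cross3(c(0, 0, 1), rhat))
        dir <- tilt_vector(base, rule$angle_sd)
        if (vertical_shift != 0 &&
            (is.null(shift_regions) || rule$region %in% shift_regions)) {
          ax_rot <- perp3(dir)
          th <- vertical_shift * pi / 180
          dir <- dir * cos(th) + cross3(ax_rot, dir) * sin(th) +
            ax_rot * sum(ax_rot * dir) * (1 - cos(th))
        }
        n_cells <- sample(cells_range[1]:cells_range[2], 1L)
        # chain centred on the origin so the sector's centre of mass stays in
        # the region window it was planted in
        offsets <- (seq_len(n_cells) - (n_cells + 1) / 2) * step
        ideal <- sweep(outer(offsets, dir), 2L, origin, `+`)
        pts <- ideal + matrix(rnorm(3 * n_cells, 0, jitter_sd), ncol = 3L)
        com_ideal <- colMeans(ideal)
        r_com <- sqrt(sum(com_ideal[1:2]^2))
        fr <- frames[[as.character(a)]]
        raw <- pts %*% t(apex_R[[a]])
        raw <- sweep(raw, 2L, fr$summit, `+`)
        landmarks[[sector_id]] <- tibble(
          apex_id = as.character(a), sector_id = sector_id,
          x = raw[, 1], y = raw[, 2], z = raw[, 3])
        truth[[sector_id]] <- tibble(
          apex_id = as.character(a), sector_id = sector_id,
          region = rule$region, mode = rule$mode,
          true_vertical = fold_angle_deg(dir[3]),
          true_radial = if (r_com < 1) NA_real_ else
            fold_angle_deg(sum(dir[1:2] * com_ideal[1:2]) / r_com),
          true_length = (n_cells - 1) * step,
          n_cells = n_cells)
      }
    }
    structure(list(landmarks = dplyr::bind_rows(landmarks),
                   frames = frames,
                   truth = dplyr::bind_rows(truth)),
              class = "sector_sim")
  })
}

# ---- toy genome and replicate peaks ---------------------------------------

#' Parameters for the toy genome / ChIP-peak generator
#'
#' @param n_chrom,chrom_length Number and length (nt) of chromosomes.
#' @param n_genes Total genes (split evenly across chromosomes),
#'   non-overlapping, random strands.
#' @param cds_length_range Uniform range of CDS lengths (nt).
#' @param utr5,utr3 UTR margins between transcript and CDS ends (nt).
#' @param gap_range Uniform range of intergenic gaps (nt) between transcript
#'   spans.
#' @param n_sites True binding sites.
#' @param site_bias Named probabilities for placing each true site in the
#'   promoter / transcribed / downstream zone of its (random) gene.
#' @param peak_width Nominal peak width (nt).
#' @param jitter_sd Per-replicate start/end jitter sd (nt); 0 reproduces the
#'   true sites exactly.
#' @param n_noise_per_rep Replicate-specific noise peaks (never consensus).
#' @param n_controls_per_rep Peaks per control replicate (placed away from
#'   true sites).
#' @param seed RNG seed.
#' @return Parameter list of class `genome_sim_params`.
#' @export
sim_genome_params <- function(n_chrom = 2L, chrom_length = 400000L,
                              n_genes = 60L,
                              cds_length_range = c(900, 2400),
                              utr5 = 150L, utr3 = 150L,
                              gap_range = c(5200, 9000),
                              n_sites = 50L,
                              site_bias = c(promoter = 0.6, transcribed = 0.1,
                                            downstream = 0.3),
                              peak_width = 250L, jitter_sd = 20,
                              n_noise_per_rep = 10L, n_controls_per_rep = 15L,
                              seed = 1L) {
  if (abs(sum(site_bias) - 1) > 1e-9) abort("`site_bias` must sum to 1")
  structure(as.list(environment()), class = "genome_sim_params")
}

#' Simulate a toy genome with genes and replicate ChIP peaks
#'
#' Random sequence; strand-assigned non-overlapping genes; `n_sites` true
#' binding sites placed per the positional bias; three treatment replicates
#' that each re-emit every true site with start/end jitter and a passing
#' q-value, plus replicate-specific noise peaks constructed never to form a
#' three-way consensus; three independent control replicates placed away from
#' the true sites.
#'
#' @param params A [sim_genome_params()] list.
#' @return List of class `genome_sim`: `genome`
#'   ([Biostrings::DNAStringSet]), `genes` (gene-model tibble), `treatment`
#'   and `controls` (lists of 3 peak tibbles), `truth` (tibble: `site_id`,
#'   `chrom`, `center`, `gene_id`, `zone`), `params`.
#' @export
simulate_genome_peaks <- function(params = sim_genome_params()) {
  stopifnot(inherits(params, "genome_sim_params"))
  with_seed(params$seed, simulate_genome_impl(params))
}

simulate_genome_impl <- function(p) {
  chroms <- paste0("chr", seq_len(p$n_chrom))
  genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), p$chrom_length, replace = TRUE),
          collapse = "")
  }, ""))
  names(genome) <- chroms
  per_chrom <- ceiling(p$n_genes / p$n_chrom)
  genes <- list()
  gid <- 0L
  for (ch in chroms) {
    cursor <- round(runif(1, 2000, 4000))
    for (g in seq_len(per_chrom)) {
      if (gid >= p$n_genes) break
      cds_len <- round(runif(1, p$cds_length_range[1], p$cds_length_range[2]))
      tlen <- p$utr5 + cds_len + p$utr3
      if (cursor + tlen + 2000 > p$chrom_length) break
      gid <- gid + 1L
      strand <- sample(c("+", "-"), 1L)
      ts <- cursor
      te <- cursor + tlen
      cs <- if (strand == "+") ts + p$utr5 else ts + p$utr3
      genes[[gid]] <- tibble(gene_id = sprintf("g%03d", gid), chrom = ch,
                             strand = strand, cds_start = cs,
                             cds_end = cs + cds_len,
                             transcript_start = ts, transcript_end = te)
      cursor <- te + round(runif(1, p$gap_range[1], p$gap_range[2]))
    }
  }
  genes <- dplyr::bind_rows(genes)
  if (nrow(genes) < p$n_genes) {
    abort("chromosomes too short for the requested gene count")
  }
  # true sites: zone-biased placement with a safety margin from zone edges
  margin <- 60L
  zones <- sample(names(p$site_bias), p$n_sites, replace = TRUE,
                  prob = p$site_bias)
  truth <- list()
  occupied <- list()  # per chrom: centers already used
  min_sep <- 2L * p$peak_width
  for (s in seq_len(p$n_sites)) {
    repeat {
      g <- genes[sample.int(nrow(genes), 1L), ]
      plus <- g$strand == "+"
      rng <- switch(zones[s],
        promoter = if (plus) c(g$cds_start - 3000L, g$transcript_start) else
          c(g$transcript_end, g$cds_end + 3000L),
        transcribed = c(g$transcript_start, g$transcript_end),
        downstream = if (plus) c(g$transcript_end, g$cds_end + 1500L) else
          c(g$cds_start - 1500L, g$transcript_start)
      )
      lo <- rng[1] + margin
      hi <- rng[2] - margin
      if (hi <= lo) next
      center <- round(runif(1, lo, hi))
      prev <- occupied[[g$chrom]]
      if (!is.null(prev) && any(abs(prev - center) < min_sep)) next
      occupied[[g$chrom]] <- c(prev, center)
      truth[[s]] <- tibble(site_id = sprintf("site%03d", s), chrom = g$chrom,
                           center = as.integer(center), gene_id = g$gene_id,
                           zone = zones[s])
      break
    }
  }
  truth <- dplyr::bind_rows(truth)
  half <- p$peak_width %/% 2L
  # forbidden zones for noise/control placement: true sites +/- peak width
  forbidden <- lapply(split(truth$center, truth$chrom), function(ctrs) {
    merge_intervals(ctrs - 2L * half - 1L, ctrs + 2L * half + 1L)
  })
  draw_clear_peaks <- function(n, width, extra_forbidden = list()) {
    out_ch <- character(n); out_s <- integer(n)
    placed <- extra_forbidden
    for (i in seq_len(n)) {
      repeat {
        ch <- sample(chroms, 1L)
        s <- round(runif(1, 1, p$chrom_length - width - 1))
        block <- merge_intervals(
          c(forbidden[[ch]]$start %||% integer(), placed[[ch]]$start %||% integer()),
          c(forbidden[[ch]]$end %||% integer(), placed[[ch]]$end %||% integer()))
        if (!any(overlaps_any(s, s + width, block))) {
          out_ch[i] <- ch; out_s[i] <- s
          placed[[ch]] <- merge_intervals(c(placed[[ch]]$start, s),
                                          c(placed[[ch]]$end, s + width))
          break
        }
      }
    }
    list(chrom = out_ch, start = out_s, placed = placed)
  }
  make_peaks <- function(chrom, start, end, prefix) {
    n <- length(start)
    tibble(chrom = chrom, start = as.integer(start), end = as.integer(end),
           name = sprintf("%s_%d", prefix, seq_len(n)),
           score = as.integer(round(runif(n, 100, 1000))), strand = ".",
           fold_enrichment = round(runif(n, 2, 15), 3),
           neg_log10_p = round(runif(n, 4, 35), 3),
           neg_log10_q = round(runif(n, 3, 30), 3),
           summit_offset = as.integer((end - start) %/% 2L),
           replicate_id = prefix)
  }
  treatment <- list()
  noise_placed <- list()
  for (r in 1:3) {
    js <- if (p$jitter_sd > 0) round(rnorm(nrow(truth), 0, p$jitter_sd)) else 0L
    je <- if (p$jitter_sd > 0) round(rnorm(nrow(truth), 0, p$jitter_sd)) else 0L
    ts_ <- pmax(truth$center - half + js, 0L)
    te_ <- truth$center + half + je
    te_ <- pmax(te_, ts_ + 10L)
    noise <- draw_clear_peaks(p$n_noise_per_rep, p$peak_width, noise_placed)
    noise_placed <- noise$placed  # noise peaks never overlap across replicates
    treatment[[r]] <- make_peaks(
      c(truth$chrom, noise$chrom),
      c(ts_, noise$start),
      c(te_, noise$start + p$peak_width),
      sprintf("t%d", r))
  }
  controls <- lapply(1:3, function(r) {
    ctl <- draw_clear_peaks(p$n_controls_per_rep, p$peak_width)
    make_peaks(ctl$chrom, ctl$start, ctl$start + p$peak_width,
               sprintf("c%d", r))
  })
  structure(list(genome = genome, genes = genes, treatment = treatment,
                 controls = controls, truth = truth, params = p),
            class = "genome_sim")
}

#' Write a genome simulation to standard files
#'
#' Emits the exact formats the analysis functions consume: `genome.fasta`,
#' `genes.gff3`, `treatment_1..3.narrowPeak`, `control_1..3.narrowPeak`, and
#' `truth.csv`.
#'
#' @param sim A [simulate_genome_peaks()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_genome_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genome = file.path(dir, "genome.fasta"),
    genes = file.path(dir, "genes.gff3"),
    treatment = file.path(dir, sprintf("treatment_%d.narrowPeak", 1:3)),
    controls = file.path(dir, sprintf("control_%d.narrowPeak", 1:3)),
    truth = file.path(dir, "truth.csv")
  )
  Biostrings::writeXStringSet(sim$genome, paths$genome)
  write_gene_models(sim$genes, paths$genes)
  for (r in 1:3) {
    write_narrowpeak(sim$treatment[[r]], paths$treatment[r])
    write_narrowpeak(sim$controls[[r]], paths$controls[r])
  }
  readr::write_csv(sim$truth, paths$truth)
  invisible(paths)
}
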