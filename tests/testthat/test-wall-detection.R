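make_two_block_volume <- function(i_left = 100, i_right = 100) {
  # two 2x2x2 cells sharing a 2x2 face along x, padded with background
  lab <- array(0L, c(4, 6, 4))
  lab[2:3, 2:3, 2:3] <- 1L
  lab[2:3, 4:5, 2:3] <- 2L
  val <- array(0, dim(lab))
  val[2:3, 2:3, 2:3] <- i_left
  val[2:3, 4:5, 2:3] <- i_right
  list(vol = labeled_volume(lab), iv = intensity_volume(val))
}

test_that("facet area, centroid and signal density follow the stated rules", {
  tb <- make_two_block_volume(100, 100)
  fac <- extract_facets(tb$vol, tb$iv, min_face_elements = 1L)
  inner <- fac[fac$cell_a == 1L & fac$cell_b == 2L, ]
  expect_equal(nrow(inner), 1L)
  expect_equal(inner$n_faces, 4L)
  expect_equal(inner$area, 4)              # 4 faces x 1 um^2
  expect_equal(inner$signal_density, 100)  # uniform flanks
  expect_equal(inner$centroid_x, 3)   # boundary plane x = 3 um
  expect_equal(inner$centroid_y, 2)   # voxel centres at 1.5 and 2.5 um
  expect_equal(inner$centroid_z, 2)
  # wall normal is the x direction
  expect_equal(abs(inner$normal_x), 1, tolerance = 1e-12)
  # background facets flagged ineligible
  expect_true(all(!fac$eligible[fac$cell_a == 0L]))

  tb2 <- make_two_block_volume(80, 120)
  fac2 <- extract_facets(tb2$vol, tb2$iv, min_face_elements = 1L)
  inner2 <- fac2[fac2$cell_a == 1L & fac2$cell_b == 2L, ]
  expect_equal(inner2$signal_density, 100)  # mean of the two flanking voxels
})

test_that("facet sets equal an exhaustive voxel-pair oracle", {
  for (seed in 1:3) {
    lab <- make_tess_volume(c(10, 10, 10), n_cells = 12, seed = seed)
    val <- array(runif(1000), dim(lab))
    fac <- extract_facets(labeled_volume(lab), intensity_volume(val),
                          min_face_elements = 1L)
    orc <- adjacency_oracle(lab, val)
    key_f <- paste(fac$cell_a, fac$cell_b)
    key_o <- paste(orc$cell_a, orc$cell_b)
    expect_setequal(key_f, key_o)
    m <- match(key_f, key_o)
    expect_equal(fac$n_faces, unname(orc$n_faces[m]))
    # isotropic spacing: area-weighted mean equals the plain mean
    expect_equal(fac$signal_density, unname(orc$mean_flank[m]),
                 tolerance = 1e-12)
  }
})

test_that("weakest-for-both-cells rule matches the triangle example", {
  # three cells arranged so every pair shares a facet
  lab <- array(0L, c(4, 4, 4))
  lab[3, 2:3, 2] <- 1L
  lab[3, 2:3, 3] <- 2L
  lab[2, 2:3, 2:3] <- 3L
  vol <- labeled_volume(lab)
  val <- array(0, dim(lab))
  iv <- intensity_volume(val)
  fac <- extract_facets(vol, iv, min_face_elements = 1L)
  # overwrite densities directly: A-B=10, A-C=20, B-C=30
  fac$signal_density[fac$cell_a == 1 & fac$cell_b == 2] <- 10
  fac$signal_density[fac$cell_a == 1 & fac$cell_b == 3] <- 20
  fac$signal_density[fac$cell_a == 2 & fac$cell_b == 3] <- 30
  called <- call_new_walls(fac)
  expect_true(called$is_new_wall[called$cell_a == 1 & called$cell_b == 2])
  expect_false(called$is_new_wall[called$cell_a == 1 & called$cell_b == 3])
  expect_false(called$is_new_wall[called$cell_a == 2 & called$cell_b == 3])

  # exact tie: A-B = A-C = 10 -> both minimal for A, but A-C fails for C
  fac$signal_density[fac$cell_a == 1 & fac$cell_b == 3] <- 10
  called <- call_new_walls(fac)
  expect_true(called$is_new_wall[called$cell_a == 1 & called$cell_b == 2])
  expect_true(called$is_new_wall[called$cell_a == 1 & called$cell_b == 3])
  expect_equal(called$is_new_wall, new_wall_oracle(called))
})

test_that("new-wall calls equal the per-cell minimum oracle on random volumes", {
  for (seed in 1:5) {
    lab <- make_tess_volume(c(12, 12, 12), n_cells = 18, seed = seed)
    set.seed(seed + 100)
    val <- array(runif(prod(dim(lab))), dim(lab))
    fac <- extract_facets(labeled_volume(lab), intensity_volume(val))
    called <- call_new_walls(fac)
    expect_identical(called$is_new_wall, new_wall_oracle(called))
  }
})

test_that("all-tied densities require mutual minimality, matching the oracle", {
  lab <- make_tess_volume(c(10, 10, 10), n_cells = 10, seed = 9)
  val <- array(1, dim(lab))
  fac <- extract_facets(labeled_volume(lab), intensity_volume(val),
                        min_face_elements = 1L)
  called <- call_new_walls(fac, tie_tol = 0)
  expect_identical(called$is_new_wall, new_wall_oracle(called, tie_tol = 0))
  # every eligible facet ties at density 1, so all eligible facets are called
  expect_true(all(called$is_new_wall[called$eligible]))
})

test_that("calls are invariant under monotone rescaling of signal densities", {
  lab <- make_tess_volume(c(12, 12, 12), n_cells = 15, seed = 4)
  set.seed(4)
  val <- array(runif(prod(dim(lab)), 0.1, 1), dim(lab))
  fac <- extract_facets(labeled_volume(lab), intensity_volume(val))
  f1 <- call_new_walls(fac)
  # affine voxel rescaling commutes with flank averaging
  f2 <- call_new_walls(extract_facets(labeled_volume(lab),
                                      intensity_volume(val * 3 + 0.5)))
  expect_identical(f1$is_new_wall, f2$is_new_wall)
  # arbitrary monotone map applied to the facet densities: only ranks matter
  fac3 <- fac
  fac3$signal_density <- exp(fac$signal_density)^2
  f3 <- call_new_walls(fac3)
  expect_identical(f1$is_new_wall, f3$is_new_wall)
})

test_that("a single cell surrounded by background yields no calls", {
  lab <- array(0L, c(5, 5, 5))
  lab[2:4, 2:4, 2:4] <- 1L
  fac <- call_new_walls(extract_facets(labeled_volume(lab),
                                       intensity_volume(array(0.5, c(5, 5, 5)))))
  expect_equal(sum(fac$is_new_wall), 0L)
})

test_that("noise-free planted divisions are recovered perfectly with accurate normals", {
  sim <- simulate_meristem(sim_meristem_params(
    dome_radius = 16, dome_height = 22, cap_drop = 8, cell_diameter = 8,
    divisions = division_spec(10, "isotropic"), noise_sd = 0, seed = 21))
  fac <- detect_divisions(sim$labels, sim$intensity, sim$frame)
  sc <- score_new_walls(fac, sim)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
  # recovered facet normals within 5 degrees of the planted plane normals
  called <- fac[fac$is_new_wall, ]
  m <- match(paste(called$cell_a, called$cell_b),
             paste(sim$truth$cell_a, sim$truth$cell_b))
  dot <- abs(called$normal_x * sim$truth$normal_x[m] +
             called$normal_y * sim$truth$normal_y[m] +
             called$normal_z * sim$truth$normal_z[m])
  expect_true(all(acos(pmin(1, dot)) * 180 / pi < 5))
})

test_that("indistinguishable new walls (ratio 1) are a negative control", {
  sim <- simulate_meristem(sim_meristem_params(
    dome_radius = 14, dome_height = 20, cap_drop = 6, cell_diameter = 7,
    divisions = division_spec(8, "isotropic"), intensity_ratio = 1,
    noise_sd = 0.05, seed = 3))
  fac <- detect_divisions(sim$labels, sim$intensity, sim$frame)
  sc <- score_new_walls(fac, sim)
  # with no intensity contrast the caller cannot beat chance
  expect_lt(sc$precision, 0.6)
})

test_that("planted orientation medians are reproduced within 5 degrees", {
  sim <- simulate_meristem(sim_meristem_params(
    dome_radius = 24, dome_height = 34, cap_drop = 10, cell_diameter = 9,
    divisions = dplyr::bind_rows(
      division_spec(20, "transversal", angle_sd = 8, depth = c(0, 17),
                    region = "core"),
      division_spec(20, "radial", angle_sd = 8, depth = c(17, 34),
                    radius = c(8, 24), region = "peri")),
    seed = 14))
  fac <- detect_divisions(sim$labels, sim$intensity, sim$frame)
  called <- fac[fac$is_new_wall, ]
  m <- match(paste(sim$truth$cell_a, sim$truth$cell_b),
             paste(called$cell_a, called$cell_b))
  truth_with_meas <- sim$truth[!is.na(m), ]
  meas <- called[m[!is.na(m)], ]
  planted_angle <- fold_angle_deg(truth_with_meas$normal_z)
  for (rg in c("core", "peri")) {
    sel <- truth_with_meas$region == rg
    expect_lt(abs(median(meas$angle_to_axis[sel]) -
                    median(planted_angle[sel])), 5)
  }
})
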