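# Independent brute-force oracles used to validate the package's fast paths.

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_perm_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  rk2 <- round(2 * rank(pooled))  # doubled midranks, integer
  combs <- utils::combn(length(pooled), n1)
  rsums <- apply(combs, 2L, function(ii) sum(rk2[ii]))
  obs <- sum(rk2[seq_len(n1)])
  p_le <- mean(rsums <= obs)
  p_ge <- mean(rsums >= obs)
  min(1, 2 * min(p_le, p_ge))
}

# direct per-cell minimum search for the weakest-for-both-cells rule
new_wall_oracle <- function(facets, tie_tol = 1e-9) {
  called <- logical(nrow(facets))
  for (i in seq_len(nrow(facets))) {
    if (!facets$eligible[i]) next
    ok <- TRUE
    for (cell in c(facets$cell_a[i], facets$cell_b[i])) {
      touching <- facets$eligible &
        (facets$cell_a == cell | facets$cell_b == cell)
      m <- min(facets$signal_density[touching])
      if (facets$signal_density[i] > m * (1 + tie_tol)) ok <- FALSE
    }
    called[i] <- ok
  }
  called
}

# exhaustive voxel-pair scan: counts of 6-connected shared faces per label
# pair, plus summed flank intensity (unweighted; isotropic spacing only)
adjacency_oracle <- function(lab, val) {
  d <- dim(lab)
  rec <- list()
  for (iy in seq_len(d[1])) for (ix in seq_len(d[2])) for (iz in seq_len(d[3])) {
    for (nb in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      jy <- iy + nb[1]; jx <- ix + nb[2]; jz <- iz + nb[3]
      if (jy > d[1] || jx > d[2] || jz > d[3]) next
      a <- lab[iy, ix, iz]; b <- lab[jy, jx, jz]
      if (a == b) next
      key <- paste(min(a, b), max(a, b))
      fl <- (val[iy, ix, iz] + val[jy, jx, jz]) / 2
      if (is.null(rec[[key]])) rec[[key]] <- c(0, 0)
      rec[[key]] <- rec[[key]] + c(1, fl)
    }
  }
  keys <- names(rec)
  tibble::tibble(
    cell_a = as.integer(sub(" .*", "", keys)),
    cell_b = as.integer(sub(".* ", "", keys)),
    n_faces = vapply(rec, `[`, 0, 1),
    mean_flank = vapply(rec, `[`, 0, 2) / vapply(rec, `[`, 0, 1)
  )
}

# per-base coverage-mask consensus oracle on a single toy chromosome
consensus_mask_oracle <- function(treatment, controls, chrom_len,
                                  q_max = 1e-3, min_overlap = 50L) {
  mask_of <- function(pk, q_filter) {
    m <- logical(chrom_len)
    if (q_filter) pk <- pk[pk$neg_log10_q >= -log10(q_max), , drop = FALSE]
    for (i in seq_len(nrow(pk))) {
      if (pk$end[i] > pk$start[i]) {
        m[(pk$start[i] + 1L):pk$end[i]] <- TRUE  # base j covers [j-1, j)
      }
    }
    m
  }
  all3 <- Reduce(`&`, lapply(treatment, mask_of, q_filter = TRUE))
  ctrl <- if (length(controls)) {
    Reduce(`|`, lapply(controls, mask_of, q_filter = FALSE))
  } else logical(chrom_len)
  r <- rle(all3)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_overlap
  out <- list()
  for (k in which(keep)) {
    if (any(ctrl[starts[k]:ends[k]])) next
    out[[length(out) + 1L]] <- c(starts[k] - 1L, ends[k])  # back to 0-based
  }
  if (length(out) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(start = m[, 1], end = m[, 2])
}

# exact two-sided Fisher p by hypergeometric enumeration over all tables
# with the observed margins
fisher_enum_oracle <- function(tab) {
  m <- sum(tab[1, ])   # size of set a
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])   # size of set b
  kk <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(kk, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small nearest-seed box tessellation with a 1-voxel background border,
# written independently of the package's generator
make_tess_volume <- function(dims = c(12, 12, 12), n_cells = 15, seed = 1) {
  set.seed(seed)
  interior <- expand.grid(y = 2:(dims[1] - 1), x = 2:(dims[2] - 1),
                          z = 2:(dims[3] - 1))
  seeds <- interior[sample.int(nrow(interior), n_cells), ]
  lab <- array(0L, dims)
  for (i in seq_len(nrow(interior))) {
    p <- as.numeric(interior[i, ])
    d2 <- (seeds$y - p[1])^2 + (seeds$x - p[2])^2 + (seeds$z - p[3])^2
    lab[p[1], p[2], p[3]] <- which.min(d2)
  }
  lab
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)
  ), 3, 3, byrow = TRUE)
}
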