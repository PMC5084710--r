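# Monte Carlo positional enrichment of peak centers in promoter / downstream
# windows versus transcribed regions, against random placement within the
# attributed genes' extended spans.

# Partition the union of the genes' extended spans into elementary intervals
# of constant zone; returns a lookup table used both to classify positions
# and to sample null centers uniformly within the union.
build_zone_index <- function(genes, upstream = 3000L, downstream = 1500L) {
  win <- attribution_window(genes, upstream, downstream)
  lo <- pmax(win$lo, 0)
  hi <- win$hi
  rows <- list()
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    un <- merge_intervals(lo[gi], hi[gi])
    cuts <- sort(unique(c(un$start, un$end, lo[gi], hi[gi],
                          genes$transcript_start[gi], genes$transcript_end[gi])))
    for (k in seq_along(un$start)) {
      bp <- cuts[cuts >= un$start[k] & cuts <= un$end[k]]
      a <- bp[-length(bp)]
      b <- bp[-1L]
      keep <- b > a
      a <- a[keep]; b <- b[keep]
      if (length(a) == 0L) next
      zone <- character(length(a))
      gene_row <- integer(length(a))
      for (e in seq_along(a)) {
        pos <- a[e]
        cand <- gi[lo[gi] <= pos & pos < hi[gi]]
        trans <- cand[genes$transcript_start[cand] <= pos &
                      pos < genes$transcript_end[cand]]
        if (length(trans)) {
          zone[e] <- "transcribed"; gene_row[e] <- trans[1]
        } else {
          zc <- vapply(cand, function(j) classify_zone(pos, genes[j, ]), "")
          prom <- cand[zc == "promoter"]
          if (length(prom)) {
            zone[e] <- "promoter"; gene_row[e] <- prom[1]
          } else {
            zone[e] <- "downstream"; gene_row[e] <- cand[1]
          }
        }
      }
      rows[[length(rows) + 1L]] <- tibble(chrom = ch, a = a, b = b,
                                          zone = zone, gene_row = gene_row)
    }
  }
  idx <- dplyr::bind_rows(rows)
  idx$len <- idx$b - idx$a
  idx$cum_before <- cumsum(c(0, idx$len))[seq_len(nrow(idx))]
  attr(idx, "total_len") <- sum(idx$len)
  idx
}

# classify observed (chrom, pos) pairs against a zone index; NA when a
# position falls outside the union
lookup_zone_rows <- function(index, chrom, pos) {
  out <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    sub <- which(index$chrom == ch)
    if (length(sub) == 0L) next
    r <- findInterval(pos[sel], index$a[sub])
    ok <- r >= 1L & pos[sel] < index$b[sub][pmax(r, 1L)]
    out[sel[ok]] <- sub[r[ok]]
  }
  out
}

#' Monte Carlo positional enrichment of peak centers
#'
#' Classifies each observed peak center as promoter (5' of the transcript of
#' an attributed gene), transcribed (within a transcript) or downstream (3'
#' of a transcript); positions covered by several genes resolve with priority
#' transcribed > promoter > downstream. The null distribution places the same
#' number of centers uniformly at random within the union of the attributed
#' genes' extended spans (CDS minus `upstream` to CDS plus `downstream`,
#' strand-adjusted) and classifies them identically. The test statistic is
#' the promoter + downstream count and
#' `p = (1 + #\{sims with statistic >= observed\}) / (n_sims + 1)`, so `p`
#' is bounded below by `1/(n_sims + 1)`.
#'
#' @param regions Consensus-region tibble (`chrom`, `center`), or any tibble
#'   of observed centers.
#' @param genes Gene-model tibble of the attributed genes.
#' @param upstream,downstream Window sizes in nt (defaults 3000, 1500).
#' @param n_sims Number of simulations (default 10000, minimum 100).
#' @param seed Optional RNG seed (see [with_seed()]).
#' @param positions Also record transcript-relative positions of observed and
#'   simulated centers for position histograms (default `TRUE`; turn off for
#'   tight simulation loops).
#' @return Object of class `apexkit_enrichment`: observed per-center tibble,
#'   zone counts, `statistic`, `null_stats`, `n_sims`, `p_value`, and (when
#'   `positions = TRUE`) transcript-relative observed and null positions.
#' @export
positional_enrichment <- function(regions, genes, upstream = 3000L,
                                  downstream = 1500L, n_sims = 10000L,
                                  seed = NULL, positions = TRUE) {
  if (nrow(regions) == 0L) abort("no regions to test")
  if (n_sims < 100L) abort("n_sims must be at least 100")
  index <- build_zone_index(genes, upstream, downstream)
  total_len <- attr(index, "total_len")
  rows_all <- lookup_zone_rows(index, regions$chrom, regions$center)
  if (anyNA(rows_all)) {
    warn(sprintf("%d observed centers outside the attributed spans dropped",
                 sum(is.na(rows_all))))
  }
  keep <- !is.na(rows_all)
  obs_rows <- rows_all[keep]
  obs_centers <- regions$center[keep]
  n_obs <- length(obs_rows)
  if (n_obs == 0L) abort("no observed center lies within the attributed spans")
  obs_zone <- index$zone[obs_rows]
  statistic <- sum(obs_zone != "transcribed")
  sim <- with_seed(seed, {
    u <- runif(n_sims * n_obs) * total_len
    r <- findInterval(u, index$cum_before)
    list(rows = r,
         pos = floor(index$a[r] + (u - index$cum_before[r])))
  })
  sim_nontrans <- index$zone[sim$rows] != "transcribed"
  sim_stats <- colSums(matrix(sim_nontrans, nrow = n_obs))
  p <- (1 + sum(sim_stats >= statistic)) / (n_sims + 1)
  res <- list(
    observed = tibble(zone = obs_zone,
                      gene_id = genes$gene_id[index$gene_row[obs_rows]]),
    zone_counts = table(factor(obs_zone,
                               c("promoter", "transcribed", "downstream"))),
    statistic = statistic, null_stats = sim_stats,
    n_obs = n_obs, n_sims = n_sims, p_value = p
  )
  if (positions) {
    rel_of <- function(rows, pos) {
      g <- genes[index$gene_row[rows], ]
      plus <- g$strand == "+"
      tibble(
        zone = index$zone[rows],
        rel_start = ifelse(plus, pos - g$transcript_start,
                           (g$transcript_end - 1L) - pos),
        rel_end = ifelse(plus, pos - (g$transcript_end - 1L),
                         g$transcript_start - pos))
    }
    res$observed_positions <- rel_of(obs_rows, obs_centers)
    res$null_positions <- rel_of(sim$rows, sim$pos)
  }
  structure(res, class = "apexkit_enrichment")
}

#' @export
print.apexkit_enrichment <- function(x, ...) {
  cat("<positional enrichment>", x$n_obs, "peak centers,",
      x$n_sims, "simulations\n")
  print(x$zone_counts)
  cat(sprintf("  statistic (promoter+downstream) = %d, p = %.4g\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' @export
glance.apexkit_enrichment <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_sims = x$n_sims, statistic = x$statistic,
         null_mean = mean(x$null_stats), p.value = x$p_value)
}

#' @export
tidy.apexkit_enrichment <- function(x, ...) {
  obs <- as.integer(x$zone_counts)
  zones <- names(x$zone_counts)
  null_frac <- vapply(zones, function(z) {
    if (is.null(x$null_positions)) NA_real_ else
      mean(x$null_positions$zone == z)
  }, 0)
  tibble(zone = zones, observed = obs,
         null_expected = null_frac * x$n_obs)
}

#' Export observed and random-control sequence windows for motif discovery
#'
#' Writes two FASTA files: sequences of `half_width` nt either side of each
#' observed consensus-region center (window width `2 * half_width + 1`), and
#' a control set of `control_factor` times as many windows of the same width
#' centered at uniformly random genome positions (chromosomes sampled
#' proportionally to length). Windows running over a chromosome end are
#' clipped with a warning.
#'
#' @param regions Consensus-region tibble (`chrom`, `center`).
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param observed_path,control_path Output FASTA paths.
#' @param half_width Half window width in nt (default 75).
#' @param control_factor Control set size multiplier (default 10).
#' @param seed Optional RNG seed; fixed seed gives byte-identical control
#'   files.
#' @return Invisibly, a list with the two paths and the window tables.
#' @export
export_motif_sequences <- function(regions, genome, observed_path,
                                   control_path, half_width = 75L,
                                   control_factor = 10L, seed = NULL) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing_chr <- setdiff(unique(regions$chrom), names(genome))
  if (length(missing_chr)) {
    abort(paste("genome lacks chromosome(s):",
                paste(missing_chr, collapse = ", ")))
  }
  clip_windows <- function(chrom, center, label) {
    len <- Biostrings::width(genome)[match(chrom, names(genome))]
    s <- center + 1L - half_width  # 1-based inclusive
    e <- center + 1L + half_width
    clipped <- s < 1L | e > len
    if (any(clipped)) {
      warn(sprintf("%d %s window(s) clipped at chromosome bounds",
                   sum(clipped), label))
    }
    tibble(chrom = chrom, start = pmax(s, 1L), end = pmin(e, len))
  }
  obs <- clip_windows(regions$chrom, regions$center, "observed")
  obs_seq <- Biostrings::DNAStringSet(vapply(seq_len(nrow(obs)), function(i) {
    as.character(Biostrings::subseq(genome[[obs$chrom[i]]],
                                    obs$start[i], obs$end[i]))
  }, ""))
  names(obs_seq) <- sprintf("obs_%d_%s:%d-%d", seq_len(nrow(obs)),
                            obs$chrom, obs$start, obs$end)
  n_ctrl <- control_factor * nrow(regions)
  ctrl <- with_seed(seed, {
    lens <- Biostrings::width(genome)
    chrom <- sample(names(genome), n_ctrl, replace = TRUE,
                    prob = lens / sum(lens))
    center <- floor(runif(n_ctrl) * lens[match(chrom, names(genome))])
    clip_windows(chrom, as.integer(center), "control")
  })
  ctrl_seq <- Biostrings::DNAStringSet(vapply(seq_len(nrow(ctrl)), function(i) {
    as.character(Biostrings::subseq(genome[[ctrl$chrom[i]]],
                                    ctrl$start[i], ctrl$end[i]))
  }, ""))
  names(ctrl_seq) <- sprintf("ctrl_%d_%s:%d-%d", seq_len(nrow(ctrl)),
                             ctrl$chrom, ctrl$start, ctrl$end)
  Biostrings::writeXStringSet(obs_seq, observed_path)
  Biostrings::writeXStringSet(ctrl_seq, control_path)
  invisible(list(observed_path = observed_path, control_path = control_path,
                 observed = obs, control = ctrl))
}

#' Fisher's exact test for overlap of two gene sets
#'
#' Builds the 2x2 membership table of two gene sets within a common universe
#' and runs a two-sided Fisher's exact test (the p-value sums hypergeometric
#' probabilities no larger than the observed table's).
#'
#' @param set_a,set_b Character vectors of gene ids, subsets of `universe`.
#' @param universe Character vector of all gene ids considered.
#' @return List: `odds_ratio` (conditional MLE), `p.value`, `table`.
#' @export
overlap_fisher <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) abort("empty universe")
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort("both sets must be subsets of the universe")
  }
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)), 2L, 2L,
                dimnames = list(a = c("in", "out"), b = c("in", "out")))
  ft <- fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p.value = ft$p.value, table = tab)
}
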