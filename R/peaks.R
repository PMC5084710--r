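# Replicate-consensus ChIP-seq peak selection, strand-aware gene attribution,
# Monte Carlo positional enrichment and motif-input sequence export.
# All genomic coordinates are 0-based half-open (narrowPeak/BED convention);
# GFF3 is converted on input/output.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards. With `seed = NULL` the code runs on the current RNG
#' stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Read an ENCODE narrowPeak file
#'
#' 10-column BED-derived format: chrom, start, end (0-based half-open), name,
#' score, strand, fold_enrichment (signalValue), -log10 p, -log10 q,
#' summit_offset (nt from start, -1 when absent).
#'
#' @param path File path.
#' @param replicate_id Optional id stored in a `replicate_id` column.
#' @return Tibble with the columns above.
#' @export
read_narrowpeak <- function(path, replicate_id = NA_character_) {
  pk <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand",
                  "fold_enrichment", "neg_log10_p", "neg_log10_q",
                  "summit_offset"),
    col_types = "ciicicdddi", comment = "#")
  pk$replicate_id <- replicate_id
  pk
}

#' Write peaks as narrowPeak
#'
#' @param peaks Tibble as returned by [read_narrowpeak()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_narrowpeak <- function(peaks, path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "fold_enrichment", "neg_log10_p", "neg_log10_q", "summit_offset")
  readr::write_tsv(peaks[cols], path, col_names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects `gene` features (transcript span, with an `ID`) and `CDS` features
#' carrying `Parent` pointing at the gene. GFF3 1-based closed coordinates are
#' converted to 0-based half-open. Genes without a CDS, or whose CDS falls
#' outside the gene span, are skipped with a warning.
#'
#' @param path GFF3 path.
#' @return Tibble: `gene_id`, `chrom`, `strand`, `cds_start`, `cds_end`,
#'   `transcript_start`, `transcript_end` (0-based half-open).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  parent <- vapply(cds$Parent, function(p) as.character(p)[1], "")
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    gid <- as.character(g$ID)
    ci <- cds[parent == gid, , drop = FALSE]
    if (nrow(ci) == 0L) {
      warn(paste("gene", gid, "has no CDS; skipped"))
      return(NULL)
    }
    cs <- min(ci$start) - 1L
    ce <- max(ci$end)
    ts <- g$start - 1L
    te <- g$end
    if (cs < ts || ce > te) {
      warn(paste("gene", gid, "has CDS outside its span; skipped"))
      return(NULL)
    }
    tibble(gene_id = gid, chrom = as.character(g$seqnames),
           strand = as.character(g$strand),
           cds_start = cs, cds_end = ce,
           transcript_start = ts, transcript_end = te)
  })
  dplyr::bind_rows(out)
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gene_models()]: emits one `gene` and one `CDS` feature per
#' gene, converting 0-based half-open back to GFF3 1-based closed.
#'
#' @param genes Gene-model tibble (see [read_gene_models()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_models <- function(genes, path) {
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$transcript_start + 1L, genes$transcript_end),
    strand = genes$strand, type = "gene", ID = genes$gene_id)
  cds_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$cds_start + 1L, genes$cds_end),
    strand = genes$strand, type = "CDS", phase = 0L,
    ID = paste0(genes$gene_id, ".cds"), Parent = genes$gene_id)
  rtracklayer::export(c(gene_gr, cds_gr), path, format = "gff3")
  invisible(path)
}

# merge sorted-or-not intervals (0-based half-open) into disjoint runs
merge_intervals <- function(start, end) {
  if (length(start) == 0L) return(list(start = integer(), end = integer()))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

# does each query interval [s, e) overlap any of the merged intervals?
overlaps_any <- function(s, e, merged) {
  if (length(merged$start) == 0L) return(rep(FALSE, length(s)))
  idx <- findInterval(s, merged$start)
  over_left <- idx >= 1L & ifelse(idx >= 1L, merged$end[pmax(idx, 1L)] > s, FALSE)
  nxt <- idx + 1L
  over_right <- nxt <= length(merged$start) &
    merged$start[pmin(nxt, length(merged$start))] < e
  over_left | over_right
}

#' Replicate-consensus peak regions
#'
#' Sweep-line intersection of peak calls across treatment replicates: a
#' consensus region is a maximal interval covered by at least one peak with
#' q <= `q_max` in every treatment replicate, at least `min_overlap` nt long,
#' and overlapping (by >= 1 nt) no control-replicate peak. Controls are used
#' as called, with no q filter. `center` is the midpoint of the intersection.
#'
#' @param treatment List of treatment-replicate peak tibbles
#'   (see [read_narrowpeak()]); the canonical design has 3.
#' @param controls List of control-replicate peak tibbles (may be empty).
#' @param q_max Per-replicate q-value threshold (default `1e-3`).
#' @param min_overlap Minimum consensus length in nt (default 50).
#' @param n_required Number of replicates that must cover a region; default
#'   all of them. A warning is issued when `length(treatment) != 3`.
#' @return Tibble: `chrom`, `start`, `end` (0-based half-open), `length`,
#'   `center`, and `source_peaks` (list-column: one overlapping q-passing peak
#'   name per replicate).
#' @export
consensus_regions <- function(treatment, controls = list(), q_max = 1e-3,
                              min_overlap = 50L, n_required = NULL) {
  n_rep <- length(treatment)
  if (n_rep == 0L) abort("no treatment replicates given")
  if (n_rep != 3L) {
    warn(sprintf("%d treatment replicates (canonical design has 3); requiring %s",
                 n_rep, n_required %||% "all"))
  }
  n_required <- n_required %||% n_rep
  q_min_score <- -log10(q_max)
  passing <- lapply(treatment, function(pk) {
    pk[pk$neg_log10_q >= q_min_score, , drop = FALSE]
  })
  chroms <- sort(unique(unlist(lapply(passing, function(p) p$chrom))))
  ctrl_all <- if (length(controls)) dplyr::bind_rows(controls) else NULL
  out <- list()
  for (ch in chroms) {
    merged <- lapply(passing, function(pk) {
      pc <- pk[pk$chrom == ch, , drop = FALSE]
      merge_intervals(pc$start, pc$end)
    })
    if (sum(vapply(merged, function(m) length(m$start) > 0L, TRUE)) < n_required) next
    ev_pos <- unlist(lapply(merged, function(m) c(m$start, m$end)))
    ev_delta <- unlist(lapply(merged, function(m)
      c(rep(1L, length(m$start)), rep(-1L, length(m$end)))))
    o <- order(ev_pos, -ev_delta)  # starts before ends at the same position
    ev_pos <- ev_pos[o]; ev_delta <- ev_delta[o]
    cov <- cumsum(ev_delta)
    seg_s <- ev_pos[-length(ev_pos)]
    seg_e <- ev_pos[-1L]
    keep <- cov[-length(cov)] >= n_required & seg_e > seg_s
    if (!any(keep)) next
    segs <- merge_intervals(seg_s[keep], seg_e[keep])  # join abutting segments
    len <- segs$end - segs$start
    sel <- len >= min_overlap
    if (!any(sel)) next
    s <- segs$start[sel]; e <- segs$end[sel]
    if (!is.null(ctrl_all)) {
      cc <- ctrl_all[ctrl_all$chrom == ch, , drop = FALSE]
      cm <- merge_intervals(cc$start, cc$end)
      drop_reg <- overlaps_any(s, e, cm)
      s <- s[drop_reg == FALSE]; e <- e[drop_reg == FALSE]
    }
    if (length(s) == 0L) next
    src <- lapply(seq_along(s), function(i) {
      vapply(passing, function(pk) {
        pc <- pk[pk$chrom == ch & pk$start < e[i] & pk$end > s[i], , drop = FALSE]
        if (nrow(pc) == 0L) NA_character_ else pc$name[1]
      }, "")
    })
    out[[length(out) + 1L]] <- tibble(
      chrom = ch, start = s, end = e, length = e - s,
      center = (s + e) %/% 2L, source_peaks = src)
  }
  if (length(out) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  length = integer(), center = integer(),
                  source_peaks = list()))
  }
  dplyr::bind_rows(out)
}

# strand-aware attribution window of one gene table, 0-based half-open
attribution_window <- function(genes, upstream, downstream) {
  plus <- genes$strand == "+"
  lo <- ifelse(plus, genes$cds_start - upstream, genes$cds_start - downstream)
  hi <- ifelse(plus, genes$cds_end + downstream, genes$cds_end + upstream)
  list(lo = lo, hi = hi)
}

#' Attribute consensus regions to gene models
#'
#' A region is attributed to a gene when the region's center lies within the
#' gene's strand-adjusted window — `upstream` nt 5' of the coding sequence to
#' `downstream` nt 3' of it — and no other gene's CDS lies entirely between
#' the center and the gene's CDS (on the same chromosome, strand-agnostic).
#' A region may be attributed to several flanking genes.
#'
#' @param regions Consensus-region tibble (needs `chrom` and `center`).
#' @param genes Gene-model tibble (see [read_gene_models()]).
#' @param upstream,downstream Window sizes in nt (defaults 3000 and 1500).
#' @param anchor `"center"` (default) tests the region center;
#'   `"any"` attributes when any part of the region overlaps the window.
#' @return Tibble: one row per (region, gene) attribution, with `chrom`,
#'   `start`, `end`, `center`, `gene_id`, `strand`, `zone` (promoter /
#'   transcribed / downstream relative to the transcript), `rel_start`,
#'   `rel_end` (center position in transcript-oriented coordinates, nt
#'   relative to transcript start and end; negative upstream of the start).
#' @export
assign_to_genes <- function(regions, genes, upstream = 3000L,
                            downstream = 1500L, anchor = c("center", "any")) {
  anchor <- match.arg(anchor)
  bad <- genes$cds_end <= genes$cds_start |
    genes$cds_start < genes$transcript_start |
    genes$cds_end > genes$transcript_end
  if (any(bad)) {
    warn(sprintf("%d malformed gene spans skipped", sum(bad)))
    genes <- genes[!bad, , drop = FALSE]
  }
  win <- attribution_window(genes, upstream, downstream)
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]
    ctr <- regions$center[i]
    on_chrom <- which(genes$chrom == ch)
    if (length(on_chrom) == 0L) next
    in_win <- if (anchor == "center") {
      ctr >= win$lo[on_chrom] & ctr < win$hi[on_chrom]
    } else {
      regions$start[i] < win$hi[on_chrom] & regions$end[i] > win$lo[on_chrom]
    }
    for (j in on_chrom[in_win]) {
      g <- genes[j, ]
      # intervening-CDS exclusion, always relative to the center
      gap_lo <- if (ctr < g$cds_start) ctr else g$cds_end
      gap_hi <- if (ctr < g$cds_start) g$cds_start else ctr
      if (ctr < g$cds_start || ctr >= g$cds_end) {
        others <- on_chrom[on_chrom != j]
        if (any(genes$cds_start[others] >= gap_lo &
                genes$cds_end[others] <= gap_hi)) next
      }
      zone <- classify_zone(ctr, g)
      rel <- transcript_relative(ctr, g)
      rows[[length(rows) + 1L]] <- tibble(
        chrom = ch, start = regions$start[i], end = regions$end[i],
        center = ctr, gene_id = g$gene_id, strand = g$strand,
        zone = zone, rel_start = rel[1], rel_end = rel[2])
    }
  }
  if (length(rows) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  center = integer(), gene_id = character(),
                  strand = character(), zone = character(),
                  rel_start = integer(), rel_end = integer()))
  }
  dplyr::bind_rows(rows)
}

# zone of a point relative to one gene's transcript (strand-aware)
classify_zone <- function(pos, gene) {
  inside <- pos >= gene$transcript_start & pos < gene$transcript_end
  if (inside) return("transcribed")
  if (gene$strand == "+") {
    if (pos < gene$transcript_start) "promoter" else "downstream"
  } else {
    if (pos >= gene$transcript_end) "promoter" else "downstream"
  }
}

# center position in transcript-oriented coordinates: nt relative to the
# transcript start (negative = upstream) and to the transcript end
transcript_relative <- function(pos, gene) {
  if (gene$strand == "+") {
    c(pos - gene$transcript_start, pos - (gene$transcript_end - 1L))
  } else {
    c((gene$transcript_end - 1L) - pos, gene$transcript_start - pos)
  }
}
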