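# a toy gene set: per gene the extended span is 7000 nt (promoter 2750,
# transcribed 3000, downstream 1250)
enrich_genes <- function(n = 10, gap = 12000L) {
  start <- 5000L + gap * (seq_len(n) - 1L)
  tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n)), chrom = "c1", strand = "+",
    cds_start = start, cds_end = start + 2500L,
    transcript_start = start - 250L, transcript_end = start + 2750L)
}

test_that("zone classification and the Monte Carlo p behave as specified", {
  genes <- enrich_genes()
  # all 50 observed centers in promoter windows -> maximal statistic,
  # minimal p (a simulated set of 50 almost never avoids every transcript)
  obs <- tibble::tibble(
    chrom = "c1",
    center = rep(genes$cds_start, 5) - rep(c(500L, 1000L, 1500L, 2000L, 2500L),
                                           each = nrow(genes)))
  en <- positional_enrichment(obs, genes, n_sims = 2000, seed = 1)
  expect_equal(en$statistic, nrow(obs))
  expect_equal(en$p_value, 1 / 2001)
  expect_true(all(en$observed$zone == "promoter"))

  # a single region inside the transcribed span: statistic 0, p = 1
  one <- tibble::tibble(chrom = "c1", center = genes$cds_start[1] + 500L)
  en1 <- positional_enrichment(one, genes[1, ], n_sims = 200, seed = 2)
  expect_equal(en1$statistic, 0L)
  expect_equal(en1$p_value, 1)
  expect_equal(en1$observed$zone, "transcribed")

  # p is bounded below by 1/(n_sims + 1) and seeded runs are reproducible
  expect_gte(en$p_value, 1 / (en$n_sims + 1))
  en_b <- positional_enrichment(obs, genes, n_sims = 2000, seed = 1)
  expect_identical(en_b$null_stats, en$null_stats)
  expect_error(positional_enrichment(obs[0, ], genes), "no regions")
  expect_error(positional_enrichment(obs, genes, n_sims = 50), "at least 100")
})

test_that("null centers land only in the extended spans, classified consistently", {
  genes <- enrich_genes(6)
  obs <- tibble::tibble(chrom = "c1", center = genes$cds_start - 500L)
  en <- positional_enrichment(obs, genes, n_sims = 300, seed = 9)
  np <- en$null_positions
  # every simulated center classifies into one of the three zones
  expect_true(all(np$zone %in% c("promoter", "transcribed", "downstream")))
  # transcript-relative coordinates are consistent with the zones
  expect_true(all(np$rel_start[np$zone == "promoter"] < 0))
  expect_true(all(np$rel_start[np$zone == "transcribed"] >= 0))
  expect_true(all(np$rel_end[np$zone == "transcribed"] <= 0))
  expect_true(all(np$rel_end[np$zone == "downstream"] > 0))
  # null zone fractions track the zone length fractions
  expect_equal(mean(np$zone == "transcribed"), 3000 / 7000, tolerance = 0.05)
  expect_equal(mean(np$zone == "promoter"), 2750 / 7000, tolerance = 0.05)
})

test_that("transcribed takes priority where extended spans overlap", {
  genes <- tibble::tibble(
    gene_id = c("near", "host"), chrom = "c1", strand = "+",
    cds_start = c(1000L, 6000L), cds_end = c(2000L, 9000L),
    transcript_start = c(900L, 5900L), transcript_end = c(2100L, 9100L))
  # 3000 nt downstream window of "near" reaches into "host"'s transcript
  obs <- tibble::tibble(chrom = "c1", center = 6500L)
  en <- positional_enrichment(obs, genes, n_sims = 200, seed = 3)
  expect_equal(en$observed$zone, "transcribed")
  expect_equal(en$observed$gene_id, "host")
})

test_that("p-values under the null generator are roughly uniform", {
  genes <- enrich_genes(8)
  index <- build_zone_index(genes)
  total <- attr(index, "total_len")
  set.seed(11)
  ps <- vapply(1:120, function(i) {
    u <- runif(40) * total
    r <- findInterval(u, index$cum_before)
    obs <- tibble::tibble(chrom = index$chrom[r],
                          center = as.integer(floor(index$a[r] +
                                                      (u - index$cum_before[r]))))
    positional_enrichment(obs, genes, n_sims = 100, positions = FALSE)$p_value
  }, 0)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.7)
  expect_gt(mean(ps < 0.25), 0.1)
  expect_gt(mean(ps > 0.75), 0.1)
})

test_that("motif sequence export writes the specified windows", {
  # genome of A with a C at each observed center
  chr <- rep("A", 4000)
  centers <- c(500L, 2600L)
  chr[centers + 1L] <- "C"
  genome <- Biostrings::DNAStringSet(paste(chr, collapse = ""))
  names(genome) <- "c1"
  regions <- tibble::tibble(chrom = "c1", center = centers)
  op <- withr::local_tempfile(fileext = ".fasta")
  cp <- withr::local_tempfile(fileext = ".fasta")
  suppressWarnings(  # a few random controls clip at this short genome's ends
    export_motif_sequences(regions, genome, op, cp, half_width = 75,
                           control_factor = 10, seed = 4))
  obs <- Biostrings::readDNAStringSet(op)
  expect_equal(length(obs), 2L)
  expect_true(all(Biostrings::width(obs) == 151))
  # the planted C sits exactly at the window midpoint
  expect_true(all(vapply(obs, function(s)
    as.character(Biostrings::subseq(s, 76, 76)), "") == "C"))
  ctrl <- Biostrings::readDNAStringSet(cp)
  expect_equal(length(ctrl), 20L)

  # fixed seed: byte-identical control file
  cp2 <- withr::local_tempfile(fileext = ".fasta")
  suppressWarnings(
    export_motif_sequences(regions, genome, op, cp2, half_width = 75,
                           control_factor = 10, seed = 4))
  expect_identical(readLines(cp), readLines(cp2))

  # degenerate half_width 0 gives 1-nt records
  op0 <- withr::local_tempfile(fileext = ".fasta")
  cp0 <- withr::local_tempfile(fileext = ".fasta")
  suppressWarnings(
    export_motif_sequences(regions, genome, op0, cp0, half_width = 0, seed = 1))
  expect_true(all(Biostrings::width(Biostrings::readDNAStringSet(op0)) == 1))

  # windows over the chromosome edge are clipped with a warning
  edge <- tibble::tibble(chrom = "c1", center = 10L)
  ope <- withr::local_tempfile(fileext = ".fasta")
  cpe <- withr::local_tempfile(fileext = ".fasta")
  w <- capture_warnings(
    export_motif_sequences(edge, genome, ope, cpe, half_width = 75, seed = 1))
  expect_true(any(grepl("observed window\\(s\\) clipped", w)))
  expect_lt(Biostrings::width(Biostrings::readDNAStringSet(ope))[1], 151)
  expect_error(
    export_motif_sequences(tibble::tibble(chrom = "cX", center = 5L),
                           genome, ope, cpe, seed = 1),
    "lacks chromosome")
})

test_that("planted positional bias is recovered through the full pipeline", {
  sim <- simulate_genome_peaks(sim_genome_params(
    site_bias = c(promoter = 1, transcribed = 0, downstream = 0),
    n_sites = 50L, seed = 17))
  cr <- consensus_regions(sim$treatment, sim$controls)
  at <- assign_to_genes(cr, sim$genes)
  genes <- sim$genes[sim$genes$gene_id %in% at$gene_id, ]
  en <- positional_enrichment(cr, genes, n_sims = 1000, seed = 17)
  expect_lte(en$p_value, 1e-3)
})
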