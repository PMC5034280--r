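test_that("caller finds isolated peaks and ignores featureless tracks", {
  expect_equal(nrow(call_nucleosomes(toy_track(rep(1, 5000)))), 0)
  tr <- toy_track(bump(5000, 500, height = 2))
  calls <- call_nucleosomes(tr)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$dyad, 500)
  expect_error(call_nucleosomes(toy_track(rep(1, 100),
                                          normalization = "none")),
               "normalized")
})

test_that("caller matches an exhaustive local-maximum scan for separated bumps", {
  v <- bump(5000, 1000, 2) + bump(5000, 1300, 2)   # 300 bp apart
  tr <- toy_track(v)
  calls <- call_nucleosomes(tr, min_spacing = 147)
  # oracle: exhaustive scan of the discretized track
  idx <- 2:(length(v) - 1)
  oracle <- idx[v[idx] > v[idx - 1] & v[idx] >= v[idx + 1] &
                  v[idx] >= 0.25] - 1
  expect_equal(sort(calls$dyad), sort(oracle))
  expect_equal(sort(calls$dyad), c(1000, 1300))
})

test_that("greedy exclusion keeps the taller of two close peaks", {
  v <- bump(5000, 1000, 3) + bump(5000, 1100, 2)   # 100 bp < min_spacing
  calls <- call_nucleosomes(toy_track(v), min_spacing = 147)
  expect_equal(nrow(calls[calls$dyad > 900 & calls$dyad < 1200, ]), 1)
  expect_lt(abs(calls$dyad[which.max(calls$peak_height)] - 1000), 5)
})

test_that("sub-threshold peaks are not called", {
  v <- bump(5000, 1000, 2) + bump(5000, 2000, 0.2)
  calls <- call_nucleosomes(toy_track(v), min_height = 0.25)
  expect_equal(calls$dyad, 1000)
})

test_that("occupancy score is the log10 of estimated reads at the peak and monotone", {
  tr <- toy_track(bump(5000, 500, 2), total_fragments = 1000)
  calls <- call_nucleosomes(tr)
  dens <- 1000 / 5000
  expect_equal(calls$occupancy_score,
               log10(calls$peak_height * dens * 147 + 1))
  tr2 <- toy_track(bump(5000, 500, 4), total_fragments = 1000)
  expect_gt(call_nucleosomes(tr2)$occupancy_score, calls$occupancy_score)
})

test_that("+1/-1 assignment follows the TSS-overlap rule on both strands", {
  calls <- data.frame(chrom = "chr1", dyad = c(850L, 1030L),
                      peak_height = c(1, 1), occupancy_score = c(1, 1))
  gp <- data.frame(chrom = "chr1", tss = 1000L, strand = "+")
  fl <- assign_flanking_nucleosomes(calls, gp)
  expect_equal(fl$plus1$dyad, 1030)      # footprint [957,1104) overlaps TSS
  expect_equal(fl$minus1$dyad, 850)
  # minus-strand mirror
  calls_m <- data.frame(chrom = "chr1", dyad = c(4970L, 5150L),
                        peak_height = c(1, 1), occupancy_score = c(1, 1))
  gm <- data.frame(chrom = "chr1", tss = 5000L, strand = "-")
  fm <- assign_flanking_nucleosomes(calls_m, gm)
  expect_equal(fm$plus1$dyad, 4970)
  expect_equal(fm$minus1$dyad, 5150)
})

test_that("+1 rescue window catches downstream-shifted calls, else absent", {
  calls <- data.frame(chrom = "chr1", dyad = 1150L, peak_height = 1,
                      occupancy_score = 1)
  g <- data.frame(chrom = "chr1", tss = 1000L, strand = "+")
  fl <- assign_flanking_nucleosomes(calls, g, rescue_bp = 200L)
  expect_equal(fl$plus1$dyad, 1150)      # 150 bp downstream, no overlap
  calls2 <- data.frame(chrom = "chr1", dyad = 1300L, peak_height = 1,
                       occupancy_score = 1)
  expect_null(assign_flanking_nucleosomes(calls2, g, rescue_bp = 200L)$plus1)
  # upstream-only call never becomes +1
  calls3 <- data.frame(chrom = "chr1", dyad = 850L, peak_height = 1,
                       occupancy_score = 1)
  fl3 <- assign_flanking_nucleosomes(calls3, g)
  expect_null(fl3$plus1)
  expect_null(fl3$minus1)
})

test_that("NFR edge arithmetic matches footprint geometry on both strands", {
  # + strand: -1 dyad 850 => footprint [777,924); +1 dyad 1030 => [957,1104)
  nfr <- define_nfr(1030L, 850L, "+")
  expect_equal(nfr$start, 924)
  expect_equal(nfr$end, 957)
  expect_equal(nfr$width, 33)
  # minus-strand mirror gives identical width
  nfr_m <- define_nfr(5000L - 1030L + 5000L, 5000L - 850L + 5000L, "-")
  expect_equal(nfr_m$width, 33)
  # overlapping footprints clamp to empty at the midpoint
  ov <- define_nfr(1000L, 900L, "+")
  expect_equal(ov$width, 0)
  expect_equal(ov$start, ov$end)
})

test_that("region counting uses midpoints with half-open bounds and RPM scaling", {
  f <- make_frags(c(100, 200, 300), c(200, 300, 400))  # midpoints 150,250,350
  expect_equal(count_region_reads(f, "chr1", 150, 250, 1e6), 1)
  expect_equal(count_region_reads(f, "chr1", 151, 250, 1e6), 0)
  expect_equal(count_region_reads(f, "chr1", 150, 251, 1e6), 2)
  expect_equal(count_region_reads(f, "chr1", 0, 1000, 3), 3 * 1e6 / 3)
  expect_equal(count_region_reads(f, "chr1", 500, 500, 1e6), 0)
  expect_equal(count_region_reads(f, "chr2", 0, 1000, 1e6), 0)
})

test_that("architecture table recovers truth geometry on synthetic data", {
  sim <- small_sim()
  tr <- normalize_track(compute_occupancy(sim$fragments$Gln,
                                          sim$chrom_sizes))
  calls <- call_nucleosomes(tr)
  arch <- build_gene_architecture(sim$genes, calls, sim$fragments)
  expect_true(all(!is.na(arch$nfr_width)))
  expect_true(all(arch$nfr_width >= 0))
  expect_gte(evaluate_nfr_overlap(sim$truth, arch)$rate, 0.95)
  # every +1 footprint overlaps its TSS or sits in the rescue window
  off <- ifelse(arch$strand == "+", 1, -1) *
    (arch$plus1_dyad - sim$genes$tss[match(arch$gene_id,
                                           sim$genes$gene_id)])
  expect_true(all(abs(off) <= 73 | (off > 73 & off <= 200)))
})

test_that("strand reflection leaves widths and scores unchanged", {
  # reflect the whole toy system: coordinates x -> L-1-x, strands flipped
  sim <- small_sim()
  L <- unname(sim$chrom_sizes["chr1"])
  fr <- sim$fragments$Gln
  fr_flip <- data.frame(chrom = fr$chrom, start = L - fr$end,
                        end = L - fr$start, name = fr$name, score = 0L,
                        strand = ifelse(fr$strand == "+", "-", "+"))
  genes_flip <- sim$genes
  genes_flip$tss <- L - 1L - sim$genes$tss
  genes_flip$stop_codon <- L - 1L - sim$genes$stop_codon
  genes_flip$strand <- ifelse(sim$genes$strand == "+", "-", "+")

  tr <- normalize_track(compute_occupancy(fr, sim$chrom_sizes))
  trf <- normalize_track(compute_occupancy(fr_flip, sim$chrom_sizes))
  calls <- call_nucleosomes(tr)
  callsf <- call_nucleosomes(trf)
  arch <- build_gene_architecture(sim$genes, calls,
                                  list(Gln = fr))
  archf <- build_gene_architecture(genes_flip, callsf,
                                   list(Gln = fr_flip))
  m <- merge(arch[, c("gene_id", "nfr_width", "Gln_NFR_raw")],
             archf[, c("gene_id", "nfr_width", "Gln_NFR_raw")],
             by = "gene_id")
  ok <- !is.na(m$nfr_width.x) & !is.na(m$nfr_width.y)
  expect_gt(mean(ok), 0.9)
  expect_true(all(abs(m$nfr_width.x[ok] - m$nfr_width.y[ok]) <= 1))
  expect_true(all(abs(m$Gln_NFR_raw.x[ok] - m$Gln_NFR_raw.y[ok]) <= 2))
})
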