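chrom1 <- c(chr1 = 10000L)

test_that("BED loading validates coordinates, lengths and chromosomes", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t247\tf1\t0\t+",
               "chr1\t500\t800\tf2\t0\t-",     # length 300: dropped
               "chr1\t900\t1050\tf3\t0\t+"), path)
  expect_message(frags <- load_fragments(path, chrom1), "dropped 1")
  expect_equal(nrow(frags), 2)
  expect_equal(frags$end[1] - frags$start[1], 147)
  expect_equal(attr(frags, "n_dropped_length"), 1L)

  writeLines("chr9\t1\t150\tf\t0\t+", path)
  expect_error(load_fragments(path, chrom1), "chr9")
  writeLines("chr1\tx\t150\tf\t0\t+", path)
  expect_error(load_fragments(path, chrom1), "line 1")
  writeLines(character(0), path)
  expect_warning(empty <- load_fragments(path, chrom1), "no fragments")
  expect_equal(nrow(empty), 0)
})

test_that("SAM input is converted to fragments (paired and single-end)", {
  path <- withr::local_tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chr1\tLN:10000")
  seq50 <- strrep("A", 50); q50 <- strrep("I", 50)
  writeLines(c(
    hdr,
    # proper pair: fragment chr1:[1000,1150) (1-based POS 1001, TLEN 150)
    sprintf("p1\t99\tchr1\t1001\t60\t50M\t=\t1101\t150\t%s\t%s", seq50, q50),
    sprintf("p1\t147\tchr1\t1101\t60\t50M\t=\t1001\t-150\t%s\t%s", seq50, q50),
    # single-end forward at POS 2001: dyad 2000+73, core [2000,2147)
    sprintf("s1\t0\tchr1\t2001\t60\t50M\t*\t0\t0\t%s\t%s", seq50, q50)),
    path)
  frags <- load_fragments(path, chrom1)
  expect_equal(nrow(frags), 2)
  pp <- frags[frags$name == "p1", ]
  expect_equal(pp$start, 1000L)
  expect_equal(pp$end, 1150L)
  se <- frags[frags$name == "s1", ]
  expect_equal(se$start, 2000L)
  expect_equal(se$end - se$start, 147L)
})

test_that("occupancy peaks at the fragment midpoint and is linear", {
  f1 <- make_frags(100, 247)
  t1 <- compute_occupancy(f1, chrom1, bandwidth = 20)
  expect_equal(which.max(t1$cov$chr1) - 1L, 173L)   # midpoint of [100,247)
  # two identical fragments => exactly twice the single-fragment track
  t2 <- compute_occupancy(make_frags(c(100, 100), c(247, 247)), chrom1, 20)
  expect_equal(t2$cov$chr1, 2 * t1$cov$chr1)
  # linearity across a union of fragment sets
  fa <- make_frags(c(1000, 3000), c(1150, 3150))
  fb <- make_frags(c(5000, 7000), c(5150, 7150))
  tu <- compute_occupancy(rbind(fa, fb), chrom1, 20)
  ta <- compute_occupancy(fa, chrom1, 20)
  tb <- compute_occupancy(fb, chrom1, 20)
  expect_equal(tu$cov$chr1, ta$cov$chr1 + tb$cov$chr1)
})

test_that("track mass equals fragment count away from edges", {
  f <- make_frags(c(1000, 2000, 3000), c(1150, 2150, 3150))
  t <- compute_occupancy(f, chrom1, bandwidth = 20)
  expect_equal(sum(t$cov$chr1), 3, tolerance = 1e-9)
  expect_error(compute_occupancy(make_frags(integer(0), integer(0)), chrom1),
               "no usable fragments")
})

test_that("translation equivariance holds in the interior", {
  f <- make_frags(c(2000, 2100), c(2150, 2250))
  k <- 500L
  fs <- make_frags(f$start + k, f$end + k)
  t0 <- compute_occupancy(f, chrom1, 20)$cov$chr1
  t1 <- compute_occupancy(fs, chrom1, 20)$cov$chr1
  inner <- 1000:4000
  expect_equal(t1[inner + k], t0[inner])
})

test_that("normalization modes behave as defined and are idempotent", {
  tr <- toy_track(c(1, 2, 3, 4), total_fragments = 10,
                  normalization = "none")
  n1 <- normalize_track(tr, "genome_mean_one")
  expect_equal(n1$cov$chr1, c(0.4, 0.8, 1.2, 1.6))
  expect_equal(mean(n1$cov$chr1), 1, tolerance = 1e-9)
  n2 <- normalize_track(n1, "genome_mean_one")
  expect_equal(n2$cov$chr1, n1$cov$chr1)
  const <- normalize_track(toy_track(rep(5, 100), normalization = "none"))
  expect_true(all(abs(const$cov$chr1 - 1) < 1e-12))
  pm <- normalize_track(tr, "per_million")
  expect_equal(pm$cov$chr1, c(1, 2, 3, 4) * 1e5)
  expect_equal(normalize_track(pm, "per_million")$cov$chr1, pm$cov$chr1)
  expect_error(normalize_track(toy_track(rep(0, 10), normalization = "none")),
               "all-zero")
})

test_that("genome-wide mean is 1 after mean normalization on real-shaped data", {
  sim <- small_sim()
  tr <- normalize_track(compute_occupancy(sim$fragments$Gln, sim$chrom_sizes))
  gm <- sum(vapply(tr$cov, sum, numeric(1))) / tr$genome_length
  expect_equal(gm, 1, tolerance = 1e-9)
})

test_that("uniform midpoints give a flat normalized track within sampling noise", {
  # oracle: per-bp smoothed count of n uniform midpoints has mean n/L and
  # variance <= n * p * sum(k^2) with p = 1/L; 3 sd bounds the interior
  set.seed(99)
  n <- 1000L; L <- 10000L
  mids <- sample.int(L, n, replace = TRUE) - 1L
  f <- make_frags(mids - 50L, mids + 50L)
  tr <- normalize_track(compute_occupancy(f, c(chr1 = L), bandwidth = 20))
  kern <- dnorm(seq(-80, 80), sd = 20); kern <- kern / sum(kern)
  sd_smooth <- sqrt(n * (1 / L) * sum(kern^2)) * (L / n)  # after mean-one scaling
  interior <- tr$cov$chr1[500:9500]
  expect_true(mean(abs(interior - 1) <= 3 * sd_smooth) > 0.99)
})

test_that("condition labels ride along and swapping labels swaps tracks", {
  sim <- small_sim()
  ta <- compute_occupancy(sim$fragments$Gln, sim$chrom_sizes,
                          condition = "Gln")
  tb <- compute_occupancy(sim$fragments$Gln, sim$chrom_sizes,
                          condition = "Pro")
  expect_identical(ta$cov, tb$cov)
  expect_equal(ta$condition, "Gln")
  expect_equal(tb$condition, "Pro")
})

test_that("bedGraph round-trips the non-zero intervals", {
  tr <- toy_track(c(0, 0, 1.5, 1.5, 0, 2, 0, 0), total_fragments = 5)
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, path)
  lines <- read.table(path, sep = "\t")
  expect_equal(nrow(lines), 2)
  expect_equal(lines$V2, c(2, 5))
  expect_equal(lines$V3, c(4, 6))
  expect_equal(lines$V4, c(1.5, 2))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$total_fragments, 5)
})
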