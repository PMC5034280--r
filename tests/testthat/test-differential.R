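test_that("NFR ratio definition, identity and reciprocal symmetry", {
  r <- nfr_ratio(10, 5, pseudocount = 0)
  expect_equal(r$ratio, 2)
  expect_equal(r$log2_ratio, 1)
  expect_equal(r$direction, "activated")
  expect_equal(nfr_ratio(7, 7)$direction, "none")
  ab <- nfr_ratio(11, 4)$ratio * nfr_ratio(4, 11)$ratio
  expect_equal(ab, 1, tolerance = 1e-12)
  expect_equal(nfr_ratio(3, 9)$direction, "repressed")
  expect_error(nfr_ratio(-1, 5), ">= 0")
})

test_that("scaled chi-square matches the sum((O-E)^2/E) oracle on random tables", {
  set.seed(1234)
  for (i in 1:1000) {
    rt <- sample(100:5000, 1); ct <- sample(100:5000, 1)
    a <- sample.int(rt, 1) - 1L; c_ <- sample.int(ct, 1) - 1L
    got <- scaled_chisq(a, rt, c_, ct)
    want <- oracle_chisq(a, rt - a, c_, ct - c_)
    expect_equal(got$chi2_stat, want, tolerance = 1e-9)
    expect_equal(got$p_value, pchisq(want, 1, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("chi-square degenerate and scaling behavior", {
  eq <- scaled_chisq(50, 1000, 100, 2000)   # equal proportions
  expect_equal(eq$chi2_stat, 0, tolerance = 1e-12)
  expect_equal(eq$p_value, 1)
  z <- scaled_chisq(0, 1000, 0, 2000)
  expect_equal(z$chi2_stat, 0)
  expect_equal(z$p_value, 1)
  expect_true(z$degenerate)
  x1 <- scaled_chisq(50, 1000, 100, 2000 - 1000)  # [[50,950],[100,900]]
  expect_equal(x1$chi2_stat, oracle_chisq(50, 950, 100, 900),
               tolerance = 1e-9)
  x2 <- scaled_chisq(100, 2000, 200, 2000)        # all four cells doubled
  expect_equal(x2$chi2_stat, 2 * x1$chi2_stat, tolerance = 1e-9)
  expect_lt(x2$p_value, x1$p_value)
  expect_error(scaled_chisq(10, 5, 1, 10), "exceed")
})

test_that("BH adjustment equals the min-over-suffix oracle on exhaustive grids", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  grid <- seq(0.05, 1, by = 0.05)
  # all multisets up to length 4 on the 0.05 grid (order is immaterial:
  # both routes are permutation-equivariant, checked separately below)
  for (len in 1:4) {
    combos <- utils::combn(length(grid) + len - 1, len)
    vals <- matrix(grid[combos - (seq_len(len) - 1)], nrow = len)
    for (j in seq_len(ncol(vals))) {
      p <- vals[, j]
      expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    }
  }
  # random multisets at lengths 5..8
  set.seed(7)
  for (len in 5:8) for (k in 1:250) {
    p <- sample(grid, len, replace = TRUE)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # permutation equivariance and sorted-order monotonicity
  p <- c(0.4, 0.05, 0.2, 0.05, 0.9)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  q <- bh_adjust(sort(runif(20)))
  expect_true(all(diff(sort(q)) >= -1e-12))
})

test_that("significance filter requires both the fold and the q condition", {
  res <- data.frame(gene_id = c("a", "b", "c"),
                    log2_ratio = c(1.5, 0.9, 2.0),
                    q = c(1e-40, 1e-40, 1e-20))
  sig <- significant_calls(res)     # defaults: fold 1, q < 1e-30
  expect_equal(sig$gene_id, "a")
  expect_equal(sig$call, "activated")
  sig2 <- significant_calls(data.frame(gene_id = "d", log2_ratio = -1.4,
                                       q = 1e-35))
  expect_equal(sig2$call, "repressed")
})

test_that("decile classes split top and bottom 10% with deterministic ties", {
  vals <- seq_len(100)
  cls <- decile_classes(vals, sprintf("g%03d", 1:100))
  expect_equal(sum(cls$class == "high"), 10)
  expect_equal(sum(cls$class == "low"), 10)
  expect_true(all(cls$value[cls$class == "high"] > 90))
  expect_true(all(cls$value[cls$class == "low"] <= 10))
  # monotone relabeling (rank-preserving) leaves classes unchanged
  cls2 <- decile_classes(log1p(vals), sprintf("g%03d", 1:100))
  expect_equal(cls$class, cls2$class)
  # all-equal values: classes still sized by the gene-id tie rule
  expect_warning(tied <- decile_classes(rep(1, 20), sprintf("g%02d", 1:20)),
                 "ties")
  expect_equal(sum(tied$class == "high"), 2)
  expect_equal(sum(tied$class == "low"), 2)
  expect_equal(tied$gene_id[tied$class == "low"], c("g01", "g02"))
  expect_error(decile_classes(1:5, letters[1:5]), "at least 10")
})

test_that("correlation report: exact linear cases and a null simulation", {
  expect_equal(correlation_report(1:10, 2 * (1:10) + 1)$r_squared, 1)
  expect_equal(correlation_report(c(1, 2, 3), c(6, 4, 2))$pearson_r, -1)
  cz <- correlation_report(rep(1, 5), 1:5)
  expect_true(cz$zero_variance)
  expect_true(is.na(cz$pearson_r))
  set.seed(11)
  cr <- correlation_report(rnorm(10000), rnorm(10000))
  expect_lt(cr$r_squared, 0.01)
  # incomplete pairs are dropped and counted
  cd <- correlation_report(c(1, 2, 3, NA, 5), c(2, 4, 6, 8, NA))
  expect_equal(cd$n, 3)
  expect_equal(cd$n_dropped, 2)
})

test_that("Wilcoxon comparison matches exhaustive permutation for small groups", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  got <- wilcoxon_compare(a, b)
  expect_equal(got$p_value, oracle_wilcox_p(a, b), tolerance = 1e-12)
  expect_equal(got$p_value, 0.1)            # 2/20 assignments as extreme
  set.seed(3)
  for (k in 1:20) {
    x <- rnorm(sample(3:6, 1))       # continuous draws: tie-free
    y <- rnorm(sample(3:6, 1), mean = runif(1, -1, 1))
    expect_equal(wilcoxon_compare(x, y)$p_value, oracle_wilcox_p(x, y),
                 tolerance = 1e-12)
  }
  same <- wilcoxon_compare(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p_value, 1)
  expect_equal(same$stars, "")
})

test_that("star coding follows the 0.05 / 0.01 / 0.001 thresholds", {
  star_of <- function(p) {
    # force a comparison with a known p by injecting into the coder via
    # groups engineered to produce it is impractical; test the rule directly
    if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  }
  got <- wilcoxon_compare(1:10, 101:110)
  expect_equal(got$stars, star_of(got$p_value))
  expect_true(got$p_value < 0.001)
  mid <- wilcoxon_compare(c(1, 2, 3), c(2.5, 3.5, 4.5))
  expect_equal(mid$stars, star_of(mid$p_value))
})

test_that("differential table integrates ratio, chi-square, BH and calls", {
  sim <- small_sim()
  tr <- normalize_track(compute_occupancy(sim$fragments$Gln,
                                          sim$chrom_sizes))
  arch <- build_gene_architecture(sim$genes, call_nucleosomes(tr),
                                  sim$fragments)
  res <- diff_nfr(arch, "Gln", "Pro", q_max = 0.05)
  expect_true(all(c("ratio", "log2_ratio", "chi2", "p", "q", "call") %in%
                    names(res)))
  expect_true(all(res$ratio > 0))
  expect_equal(res$log2_ratio, log2(res$ratio))
  expect_equal(res$q, bh_adjust(res$p))
  # condition-swap anti-symmetry: signs flip, chi2/p/q unchanged
  swapped <- diff_nfr(arch, "Pro", "Gln", q_max = 0.05)
  expect_equal(swapped$log2_ratio, -res$log2_ratio, tolerance = 1e-12)
  expect_equal(swapped$chi2, res$chi2, tolerance = 1e-9)
  expect_equal(swapped$q, res$q, tolerance = 1e-12)
  flip <- c(activated = "repressed", repressed = "activated", NS = "NS")
  expect_equal(unname(flip[res$call]), swapped$call)
})

test_that("class x TATA contingency table is well formed", {
  sim <- small_sim()
  cls <- decile_classes(seq_len(nrow(sim$genes)), sim$genes$gene_id)
  tab <- class_tata_table(cls, sim$genes)
  expect_equal(sum(tab), nrow(sim$genes))
  expect_true(all(rownames(tab) %in% c("high", "low", "mid")))
})
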