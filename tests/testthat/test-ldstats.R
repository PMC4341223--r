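test_that("allelic r reproduces hand-evaluated haplotype tables", {
  # linkage equilibrium
  expect_equal(allele_r(0.25, 0.5, 0.5), 0)
  # complete association: only MN and mn haplotypes
  expect_equal(allele_r(0.5, 0.5, 0.5), 1)
  # counts MN=35, Mn=25, mN=15, mn=25 (n = 100)
  r <- allele_r(0.35, 0.6, 0.5)
  expect_equal(r, 0.05 / sqrt(0.06))
  # and against the Pearson-indicator oracle on the explicit 100 haplotypes
  H <- cbind(rep(c(1, 1, 0, 0), c(35, 25, 15, 25)),
             rep(c(1, 0, 1, 0), c(35, 25, 15, 25)))
  expect_equal(r, oracle_r(H, 1, 2), tolerance = 1e-12)
  expect_error(allele_r(0.5, 1, 0.5), "monomorphic")
})

test_that("r equals the Pearson-indicator oracle on random panels", {
  set.seed(31)
  for (k in 1:100) {
    n <- sample(10:60, 1)
    p <- random_panel(n_ind = n, m = 2, seed = 1000 + k)
    tab <- pairwise_ld(p)
    expect_equal(tab$r, oracle_r(p$alleles, 1, 2), tolerance = 1e-12)
  }
})

test_that("r responds to allele relabelling as a correlation must", {
  p <- random_panel(n_ind = 40, m = 2, seed = 77)
  r0 <- pairwise_ld(p)$r
  flip1 <- p; flip1$alleles[, 1] <- 1L - flip1$alleles[, 1]
  expect_equal(pairwise_ld(flip1)$r, -r0, tolerance = 1e-12)
  flip2 <- flip1; flip2$alleles[, 2] <- 1L - flip2$alleles[, 2]
  expect_equal(pairwise_ld(flip2)$r, r0, tolerance = 1e-12)
  expect_equal(pairwise_ld(flip1)$r2, r0^2, tolerance = 1e-12)
})

test_that("D' matches hand evaluation and its boundary cases", {
  expect_equal(d_prime(0.25, 0.5, 0.5), 0)
  # counts MN=35, Mn=25, mN=15, mn=25: D = 0.05, Dmax = 0.2
  expect_equal(d_prime(0.35, 0.6, 0.5), 0.25)
  # one haplotype class absent (mN = 0): border of the simplex
  # counts MN=30, Mn=20, mn=50: f_M=0.5, f_N=0.3, D=0.15, Dmax=0.15
  expect_equal(d_prime(0.3, 0.5, 0.3), 1)
  expect_error(d_prime(0.2, 0.5, 0), "monomorphic")
})

test_that("pairwise tables respect the distance cap and chromosomes", {
  H <- random_panel(n_ind = 20, m = 3, seed = 41)$alleles
  p <- make_panel(H, pos = c(10e3, 30e3, 5.02e6))
  tab <- pairwise_ld(p, max_pair_distance = 5e6)
  # (s1,s2) 20 kb and (s2,s3) 4.99 Mb pass; (s1,s3) 5.01 Mb is cut
  expect_equal(nrow(tab), 2)
  expect_equal(tab$dist, c(20e3, 4.99e6))
  # an exact 5 Mb separation is excluded (strict cap)
  p2 <- make_panel(H[, 1:2], pos = c(10e3, 5.01e6))
  expect_equal(nrow(pairwise_ld(p2, max_pair_distance = 5e6)), 0)

  # no inter-chromosome pairs
  p3 <- make_panel(H, pos = c(10e3, 20e3, 15e3), chrom = c(1L, 1L, 2L))
  tab3 <- pairwise_ld(p3)
  expect_equal(tab3$snp_i, "s1")
  expect_equal(tab3$snp_j, "s2")

  # duplicating every individual leaves frequencies, hence r, unchanged
  p4 <- make_panel(H, pos = c(1e4, 2e4, 3e4))
  p4_dup <- make_panel(rbind(H, H), pos = c(1e4, 2e4, 3e4))
  expect_equal(pairwise_ld(p4_dup)$r, pairwise_ld(p4)$r)

  expect_error(pairwise_ld(make_panel(cbind(H[, 1], 0L))), "monomorphic")
})

test_that("decay curves average r-squared in half-open 25-kb bins", {
  # three pairs engineered into two bins via positions on one chromosome
  tab <- data.frame(snp_i = c("a", "a", "b"), snp_j = c("b", "c", "c"),
                    chrom = 1L, dist = c(10e3, 40e3, 30e3),
                    r2 = c(0.4, 0.1, 0.2))
  cv <- decay_curve(tab, categories = NULL, bin_width = 25e3)
  expect_equal(cv$bin_lo, c(0, 25e3))
  expect_equal(cv$mean_r2, c(0.4, 0.15))
  expect_equal(cv$n_pairs, c(1L, 2L))
  # all pairs at one distance: single bin, arithmetic mean
  tab2 <- data.frame(chrom = 1L, dist = 12e3, r2 = c(0.4, 0.2))
  cv2 <- decay_curve(tab2)
  expect_equal(nrow(cv2), 1)
  expect_equal(cv2$mean_r2, 0.3)
  # bin means stay inside the member range
  p <- random_panel(n_ind = 25, m = 12, seed = 55)
  cv3 <- decay_curve(pairwise_ld(p))
  expect_true(all(cv3$n_pairs > 0))
  expect_true(all(cv3$mean_r2 >= 0 & cv3$mean_r2 <= 1))
})

test_that("the r2 < 0.2 distance is the first crossing's bin midpoint", {
  curve <- data.frame(category = "all",
                      bin_lo = (0:4) * 25e3, bin_hi = (1:5) * 25e3,
                      mid = (0:4) * 25e3 + 12.5e3,
                      mean_r2 = c(0.35, 0.25, 0.18, 0.21, 0.15),
                      n_pairs = 5L)
  expect_equal(d_threshold_distance(curve, 0.2), 62.5e3)  # rebound ignored
  high <- curve; high$mean_r2 <- high$mean_r2 + 1
  expect_true(is.na(d_threshold_distance(high, 0.2)))
  low <- curve; low$mean_r2[1] <- 0.1
  expect_equal(d_threshold_distance(low, 0.2), 12.5e3)
})

test_that("adjacent-SNP summaries use strict thresholds and the map", {
  # single pair: mean equals its r2
  p <- random_panel(n_ind = 30, m = 2, seed = 61)
  s <- adjacent_ld_summary(p)
  expect_equal(s$n_pairs, 1)
  expect_equal(s$mean_r2, pairwise_ld(p)$r2)
  # r2 values match the indicator oracle pair by pair
  q <- random_panel(n_ind = 25, m = 6, seed = 62)
  s2 <- adjacent_ld_summary(q)
  r2_oracle <- vapply(1:5, function(i) oracle_r(q$alleles, i, i + 1)^2,
                      numeric(1))
  expect_equal(s2$mean_r2, mean(r2_oracle), tolerance = 1e-12)
  expect_equal(unname(s2$frac_gt), c(mean(r2_oracle > 0.2), mean(r2_oracle > 0.3)))
  # strict inequality at the threshold itself
  dup <- make_panel(cbind(q$alleles[, 1], q$alleles[, 1]))
  s3 <- adjacent_ld_summary(dup, thresholds = 1)
  expect_equal(unname(s3$frac_gt), 0)   # r2 = 1 is not > 1
  # adjacency ignores the pairwise distance cap
  far <- make_panel(q$alleles[, 1:2], pos = c(1e4, 9e6))
  expect_equal(adjacent_ld_summary(far)$n_pairs, 1)
  expect_error(adjacent_ld_summary(make_panel(q$alleles[, 1, drop = FALSE])),
               "fewer than 2")
})
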