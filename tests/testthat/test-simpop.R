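test_that("configuration validation rejects degenerate settings", {
  expect_error(tiny_cfg(base_pop_size = 0), "base population")
  expect_error(tiny_cfg(line_sizes = c(B = 1L, C = 30L, D = 30L)), "at least 2")
  expect_error(tiny_cfg(chrom_categories = c("macro", "giant")), "macro")
  expect_error(sim_config(chrom_lengths_bp = c(8e6, 4e6),
                          chrom_categories = c("macro", "micro"),
                          recomb_rate_cM_per_Mb = c(macro = -1, micro = 6.4)),
               "non-negative")
})

test_that("the whole simulation is reproducible from its seed", {
  cfg <- tiny_cfg(seed = 42)
  run <- function() {
    base <- simulate_base(cfg)
    lines <- diverge_lines(base, cfg)
    cross <- make_cross(lines$B, lines$C, lines$D, cfg, n_offspring = 30)
    list(base, lines, cross)
  }
  expect_identical(run(), run())
})

test_that("base panels segregate and LD responds to recombination rate", {
  cfg0 <- tiny_cfg(seed = 9,
                   chrom_lengths_bp = 6e6, chrom_categories = "micro",
                   n_snps_per_chrom = 150L,
                   recomb_rate_cM_per_Mb = c(micro = 0))
  cfg6 <- tiny_cfg(seed = 9,
                   chrom_lengths_bp = 6e6, chrom_categories = "micro",
                   n_snps_per_chrom = 150L,
                   recomb_rate_cM_per_Mb = c(micro = 6.4))
  b0 <- simulate_base(cfg0)
  b6 <- simulate_base(cfg6)
  f0 <- colMeans(b0$alleles); f6 <- colMeans(b6$alleles)
  expect_true(all(f0 > 0 & f0 < 1))
  expect_true(all(f6 > 0 & f6 < 1))
  short_r2 <- function(p) {
    tab <- pairwise_ld(p, max_pair_distance = 1e5)
    mean(tab$r2)
  }
  expect_gt(short_r2(b0), short_r2(b6))
})

test_that("a single candidate site yields a valid degenerate panel", {
  cfg <- tiny_cfg(seed = 2, chrom_lengths_bp = 1e6,
                  chrom_categories = "macro", n_snps_per_chrom = 1L,
                  burnin_generations = 5L)
  b <- simulate_base(cfg)
  expect_s3_class(b, "haplotype_panel")
  expect_lte(n_snps(b), 1L)
})

test_that("zero divergence gives undifferentiated subsamples of the base", {
  cfg <- tiny_cfg(seed = 5)
  base <- simulate_base(cfg)
  lines <- diverge_lines(base, cfg, divergence_generations = 0)
  expect_equal(n_individuals(lines$B), 50)
  keep <- Reduce(`&`, lapply(lines, function(p) {
    f <- colMeans(p$alleles); f > 0.05 & f < 0.95
  }))
  f <- mean_fst(lines, snps = base$map$id[keep])
  expect_lt(abs(f), 0.05)
})

test_that("differentiation does not decrease with divergence time", {
  fst_at <- function(seed, t) {
    cfg <- tiny_cfg(seed = seed, chrom_lengths_bp = 5e6,
                    chrom_categories = "macro", n_snps_per_chrom = 80L,
                    base_pop_size = 40L, burnin_generations = 15L,
                    line_sizes = c(B = 30L, C = 30L, D = 30L),
                    line_wf_sizes = c(B = 25L, C = 25L, D = 25L))
    base <- simulate_base(cfg)
    lines <- diverge_lines(base, cfg, divergence_generations = t)
    keep <- Reduce(`&`, lapply(lines, function(p) {
      f <- colMeans(p$alleles); f > 0.05 & f < 0.95
    }))
    mean_fst(lines, snps = base$map$id[keep])
  }
  seeds <- 1:10
  f_short <- vapply(seeds, fst_at, numeric(1), t = 8)
  f_long <- vapply(seeds + 100, fst_at, numeric(1), t = 16)
  expect_gt(mean(f_long), mean(f_short))
})

test_that("three-way cross carries exactly half line-B material", {
  cfg <- tiny_cfg(seed = 11)
  base <- simulate_base(cfg)
  lines <- diverge_lines(base, cfg)
  cross <- make_cross(lines$B, lines$C, lines$D, cfg, n_offspring = 120)
  of <- origin_fractions(cross)
  # one intact B gamete per offspring: exactly 50% per individual
  expect_true(all(of$per_individual$B == 0.5))
  expect_equal(sum(of$overall), 1)
  # maternal C/D contributions: 25% each in expectation
  expect_lt(abs(of$overall["C"] - 0.25), 0.05)
  expect_lt(abs(of$overall["D"] - 0.25), 0.05)
})

test_that("without recombination maternal gametes are whole C or D haplotypes", {
  cfg <- tiny_cfg(seed = 13,
                  chrom_lengths_bp = c(8e6, 4e6),
                  chrom_categories = c("macro", "micro"),
                  recomb_rate_cM_per_Mb = c(macro = 0, micro = 0))
  base <- simulate_base(cfg)
  lines <- diverge_lines(base, cfg)
  cross <- make_cross(lines$B, lines$C, lines$D, cfg, n_offspring = 40)
  for (i in seq_len(40)) {
    for (ch in 1:2) {
      o <- cross$origin[2L * i, cross$map$chrom == ch]
      expect_length(unique(o), 1)
      expect_true(unique(o) %in% c("C", "D"))
    }
  }
})

test_that("mismatched maps are rejected by the cross", {
  cfg <- tiny_cfg(seed = 3)
  base <- simulate_base(cfg)
  lines <- diverge_lines(base, cfg)
  off <- subset_snps(lines$D, seq_len(n_snps(lines$D) - 1))
  expect_error(make_cross(lines$B, lines$C, off, cfg), "identical snp map")
})

test_that("divergence calibration reaches the target differentiation", {
  cfg <- tiny_cfg(seed = 21)
  base <- simulate_base(cfg)
  cal <- calibrate_divergence(base, cfg, target_fst = 0.2,
                              generations = c(10L, 25L, 40L, 60L))
  expect_false(is.na(cal$generations))
  lines <- diverge_lines(base, cfg, divergence_generations = cal$generations)
  keep <- Reduce(`&`, lapply(lines, function(p) {
    f <- colMeans(p$alleles); f >= 0.05 & f <= 0.95
  }))
  expect_gt(mean_fst(lines, snps = base$map$id[keep]), 0.2)
})
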