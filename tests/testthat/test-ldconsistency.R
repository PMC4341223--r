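test_that("allele orientation restores a shared labelling", {
  a <- random_panel(n_ind = 20, m = 8, seed = 91, label = "a")
  b <- a
  b$label <- "b"
  # already consistent: untouched
  expect_identical(orient_alleles(list(a, b))[[2]]$alleles, b$alleles)
  # flip labels + codes of three SNPs in b; orientation must undo it
  flip <- c(2, 5, 7)
  b$alleles[, flip] <- 1L - b$alleles[, flip]
  a0 <- b$map$allele0[flip]
  b$map$allele0[flip] <- b$map$allele1[flip]
  b$map$allele1[flip] <- a0
  fixed <- orient_alleles(list(a, b))[[2]]
  expect_equal(fixed$alleles, a$alleles)
  expect_equal(fixed$map$allele0, a$map$allele0)
  # irreconcilable labels are fatal
  bad <- b; bad$map$allele1[1] <- "T"
  expect_error(orient_alleles(list(a, bad)), "irreconcilable")
})

test_that("consistency bins are orientation-invariant and self-correlate to 1", {
  p <- random_panel(n_ind = 30, m = 10, seed = 101)
  self <- correlation_of_r(p, p, bin_width = 20e3)
  expect_true(all(abs(self$cor_r[self$n_pairs >= 2] - 1) < 1e-12))

  q <- random_panel(n_ind = 25, m = 10, seed = 102, label = "q")
  base_bins <- correlation_of_r(p, q, bin_width = 20e3)
  # flip an arbitrary label pattern in q; bins must not change
  qf <- q
  flip <- c(1, 4, 9)
  qf$alleles[, flip] <- 1L - qf$alleles[, flip]
  a0 <- qf$map$allele0[flip]
  qf$map$allele0[flip] <- qf$map$allele1[flip]
  qf$map$allele1[flip] <- a0
  expect_equal(correlation_of_r(p, qf, bin_width = 20e3), base_bins)
})

test_that("binned correlation of r equals an explicit Pearson computation", {
  p <- random_panel(n_ind = 30, m = 12, seed = 111)
  q <- random_panel(n_ind = 35, m = 12, seed = 112, label = "q")
  got <- correlation_of_r(p, q, bin_width = 30e3)
  # independent route: oracle r per pair in both panels, explicit Pearson
  m <- 12
  pr <- list()
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    d <- p$map$pos[j] - p$map$pos[i]
    pr[[length(pr) + 1]] <- c(d, oracle_r(p$alleles, i, j),
                              oracle_r(q$alleles, i, j))
  }
  pr <- do.call(rbind, pr)
  pearson <- function(x, y) {
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (k in seq_len(nrow(got))) {
    sel <- pr[, 1] >= got$bin_lo[k] & pr[, 1] < got$bin_hi[k]
    expect_equal(got$cor_r[k], pearson(pr[sel, 2], pr[sel, 3]),
                 tolerance = 1e-10)
    expect_equal(got$n_pairs[k], sum(sel))
  }
})

test_that("bins with fewer than two pairs report no correlation", {
  p <- random_panel(n_ind = 20, m = 2, seed = 121)
  out <- correlation_of_r(p, p, bin_width = 20e3)
  expect_true(is.na(out$cor_r[out$n_pairs < 2][1]))
})

test_that("pooling identical lines reproduces each line's LD exactly", {
  b <- random_panel(n_ind = 30, m = 8, seed = 131, label = "B")
  pred <- predict_crossbred_ld(b, b, b, weights = c(1, 1, 1), n_total = 90,
                               seed = 5)
  expect_equal(pred$pairs$r, pairwise_ld(b)$r, tolerance = 1e-12)
})

test_that("pooling two opposite fixed lines creates complete LD", {
  # line 1 fixed for haplotype MN, line 2 fixed for mn, equal weights
  one <- make_panel(matrix(1L, 20, 2), label = "B")
  zero <- make_panel(matrix(0L, 20, 2), label = "C")
  pred <- predict_crossbred_ld(one, zero, zero, weights = c(1, 1, 0),
                               n_total = 20, seed = 3)
  expect_equal(pred$pairs$f_M, 0.5)
  expect_equal(pred$pairs$f_MN, 0.5)
  expect_equal(pred$pairs$r, 1)
})

test_that("degenerate weights reduce the pool to one line", {
  b <- random_panel(n_ind = 20, m = 6, seed = 141, label = "B")
  c_ <- random_panel(n_ind = 20, m = 6, seed = 142, label = "C")
  d <- random_panel(n_ind = 20, m = 6, seed = 143, label = "D")
  pred <- predict_crossbred_ld(b, c_, d, weights = c(1, 0, 0), n_total = 20,
                               seed = 7)
  expect_equal(pred$pairs$r, pairwise_ld(b)$r)
})

test_that("pooled frequencies are the weighted means of line frequencies", {
  b <- random_panel(n_ind = 12, m = 9, seed = 151, label = "B")
  c_ <- random_panel(n_ind = 12, m = 9, seed = 152, label = "C")
  d <- random_panel(n_ind = 12, m = 9, seed = 153, label = "D")
  pool <- pool_panels(list(b, c_, d), n_sample = c(6, 3, 3), seed = 9)
  sampled <- split(pool$samples, sub("\\..*", "", pool$samples))
  expect_equal(lengths(sampled)[c("B", "C", "D")], c(B = 6L, C = 3L, D = 3L))
  # counting identity, exact: pooled frequency = weighted mean of the
  # sampled line frequencies
  fB <- colMeans(subset_individuals(pool, 1:6)$alleles)
  fC <- colMeans(subset_individuals(pool, 7:9)$alleles)
  fD <- colMeans(subset_individuals(pool, 10:12)$alleles)
  expect_equal(colMeans(pool$alleles), (6 * fB + 3 * fC + 3 * fD) / 12)
})
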