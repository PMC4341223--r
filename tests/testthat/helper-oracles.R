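# Independent oracles used to cross-check the analytical statistics.

# r as the Pearson correlation of the two SNPs' 0/1 allele indicators.
oracle_r <- function(H, i, j) stats::cor(H[, i], H[, j])

# Hardy-Weinberg exact test by direct enumeration of the conditional
# distribution of heterozygote counts (closed-form multinomial /
# allele-count formula; no recurrence, no renormalization).
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_A <- 2 * n_AA + n_Aa
  n_a <- 2 * n - n_A
  if (n_A == 0 || n_a == 0) return(1)
  hets <- seq(n_A %% 2, min(n_A, n_a), by = 2)
  lp <- vapply(hets, function(h) {
    hom_A <- (n_A - h) / 2
    hom_a <- (n_a - h) / 2
    lfactorial(n) - lfactorial(hom_A) - lfactorial(h) - lfactorial(hom_a) +
      h * log(2) + lfactorial(n_A) + lfactorial(n_a) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(lp)
  sum(p[p <= p[match(n_Aa, hets)] * (1 + 1e-12)])
}

# Fine-grid normalized-likelihood bounds on D' (10^4 grid points).
oracle_dprime_ci <- function(counts, tails = 0.05, points = 10001L) {
  n <- sum(counts)
  fM <- (counts[1] + counts[2]) / n
  fN <- (counts[1] + counts[3]) / n
  D <- counts[1] / n - fM * fN
  dmax <- if (D >= 0) min(fM * (1 - fN), (1 - fM) * fN) else
                      min(fM * fN, (1 - fM) * (1 - fN))
  dp <- seq(0, 1, length.out = points)
  Dg <- (if (D >= 0) 1 else -1) * dp * dmax
  pr <- rbind(fM * fN + Dg, fM * (1 - fN) - Dg,
              (1 - fM) * fN - Dg, (1 - fM) * (1 - fN) + Dg)
  pr[pr < 1e-12] <- 1e-12
  ll <- colSums(counts * log(pr))
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  cum <- cumsum(w)
  c(lower = dp[which(cum >= tails)[1]],
    upper = dp[which(cum >= 1 - tails)[1]])
}

# Weir & Cockerham (1984) theta, transcribed equation by equation.
oracle_wc_fst <- function(sizes, freqs, hets) {
  r <- length(sizes)
  nbar <- sum(sizes) / r
  CV <- sum(sizes^2)
  nc <- (r * nbar - CV / (r * nbar)) / (r - 1)
  pbar <- sum(sizes * freqs) / (r * nbar)
  ssq <- sum(sizes * (freqs - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(sizes * hets) / (r * nbar)
  a_comp <- (nbar / nc) * (ssq - (1 / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * ssq - hbar / 4))
  b_comp <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
    ((r - 1) / r) * ssq - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c_comp <- hbar / 2
  a_comp / (a_comp + b_comp + c_comp)
}
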