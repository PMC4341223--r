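#' Likelihood-based confidence bounds on D'
#'
#' Normalized-likelihood interval for D' of a SNP pair, the construction
#' behind Gabriel-style block calling: with allele frequencies fixed at
#' their sample estimates and D signed toward the observed D, the
#' multinomial likelihood of the four observed haplotype counts is
#' evaluated on a grid of D' in \[0, 1\], normalized, and cut at the
#' requested probability mass in each tail (default 5%).
#'
#' @param counts haplotype counts `c(MN, Mn, mN, mn)` for alleles M/m at
#'   the first SNP and N/n at the second.
#' @param tails probability mass cut from each tail (default 0.05).
#' @param grid_points number of grid points on \[0, 1\] (default 101).
#' @return list with `lower`, `upper` (grid values), `d_prime` (point
#'   estimate) and `n` (total count).
#' @export
dprime_ci <- function(counts, tails = 0.05, grid_points = 101L) {
  stopifnot(length(counts) == 4, all(counts >= 0), tails > 0, tails < 0.5,
            grid_points >= 2)
  n <- sum(counts)
  if (n < 2) stop("need at least 2 haplotypes")
  f_M <- (counts[1] + counts[2]) / n
  f_N <- (counts[1] + counts[3]) / n
  if (f_M <= 0 || f_M >= 1 || f_N <= 0 || f_N >= 1)
    stop("D' confidence bounds are undefined for monomorphic SNPs")
  D <- counts[1] / n - f_M * f_N
  s <- if (D >= 0) 1 else -1
  dmax <- if (D >= 0) min(f_M * (1 - f_N), (1 - f_M) * f_N) else
                      min(f_M * f_N, (1 - f_M) * (1 - f_N))
  grid <- seq(0, 1, length.out = grid_points)
  Dg <- s * grid * dmax
  eps <- 1e-12
  p11 <- pmax(f_M * f_N + Dg, eps)
  p10 <- pmax(f_M * (1 - f_N) - Dg, eps)
  p01 <- pmax((1 - f_M) * f_N - Dg, eps)
  p00 <- pmax((1 - f_M) * (1 - f_N) + Dg, eps)
  ll <- counts[1] * log(p11) + counts[2] * log(p10) +
        counts[3] * log(p01) + counts[4] * log(p00)
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  cum <- cumsum(w)
  list(lower = grid[which(cum >= tails)[1]],
       upper = grid[which(cum >= 1 - tails)[1]],
       d_prime = d_prime(counts[1] / n, f_M, f_N), n = n)
}

#' Rules for Gabriel-style block calling
#'
#' A pair is in "strong LD" when its D' upper confidence bound exceeds
#' `strong_upper` and its lower bound exceeds `strong_lower`; it shows
#' "strong recombination" when the upper bound is below `recomb_upper`;
#' all other pairs are uninformative.  A candidate span whose outermost
#' pair is in strong LD is accepted when the strong-LD fraction of its
#' informative pairs reaches the acceptance fraction: `accept_frac` for
#' spans of 4+ SNPs, `accept_frac_3` for 3-SNP spans; 2-SNP spans need
#' only their single pair in strong LD.
#'
#' @param strong_upper,strong_lower,recomb_upper D' bound thresholds.
#' @param accept_frac,accept_frac_3 acceptance fractions by span size.
#' @param tails,grid_points passed to [dprime_ci()].
#' @return list of class `gabriel_rules`.
#' @export
gabriel_rules <- function(strong_upper = 0.98, strong_lower = 0.70,
                          recomb_upper = 0.90, accept_frac = 0.95,
                          accept_frac_3 = 0.80, tails = 0.05,
                          grid_points = 101L) {
  structure(list(strong_upper = strong_upper, strong_lower = strong_lower,
                 recomb_upper = recomb_upper, accept_frac = accept_frac,
                 accept_frac_3 = accept_frac_3, tails = tails,
                 grid_points = grid_points),
            class = "gabriel_rules")
}

## Vectorized D' CI over many pairs (one chromosome).  Same grid
## construction as dprime_ci(), chunked to bound memory.
.dprime_ci_pairs <- function(H, ii, jj, tails, grid_points) {
  nh <- nrow(H)
  p <- colMeans(H)
  f_MN <- crossprod(H)[cbind(ii, jj)] / nh
  f_M <- p[ii]; f_N <- p[jj]
  D <- f_MN - f_M * f_N
  s <- ifelse(D >= 0, 1, -1)
  dmax <- ifelse(D >= 0, pmin(f_M * (1 - f_N), (1 - f_M) * f_N),
                 pmin(f_M * f_N, (1 - f_M) * (1 - f_N)))
  grid <- seq(0, 1, length.out = grid_points)
  n11 <- round(f_MN * nh)
  n10 <- round((f_M - f_MN) * nh)
  n01 <- round((f_N - f_MN) * nh)
  n00 <- nh - n11 - n10 - n01
  np <- length(ii)
  lower <- numeric(np); upper <- numeric(np)
  eps <- 1e-12
  chunk <- max(1L, floor(2e6 / grid_points))
  for (lo in seq(1L, np, by = chunk)) {
    sel <- lo:min(np, lo + chunk - 1L)
    Dg <- outer(s[sel] * dmax[sel], grid)          # pairs x grid
    p11 <- pmax(f_M[sel] * f_N[sel] + Dg, eps)
    p10 <- pmax(f_M[sel] * (1 - f_N[sel]) - Dg, eps)
    p01 <- pmax((1 - f_M[sel]) * f_N[sel] - Dg, eps)
    p00 <- pmax((1 - f_M[sel]) * (1 - f_N[sel]) + Dg, eps)
    ll <- n11[sel] * log(p11) + n10[sel] * log(p10) +
          n01[sel] * log(p01) + n00[sel] * log(p00)
    w <- exp(ll - apply(ll, 1, max))
    w <- w / rowSums(w)
    cum <- t(apply(w, 1, cumsum))
    lower[sel] <- grid[max.col(cum >= tails, ties.method = "first")]
    upper[sel] <- grid[max.col(cum >= 1 - tails, ties.method = "first")]
  }
  list(lower = lower, upper = upper)
}

#' Gabriel-style haploblocks
#'
#' Classifies every within-cap SNP pair from its D' confidence bounds,
#' takes every strong-LD pair as a candidate block span, and accepts
#' candidates greedily in order of decreasing bp span (ties: more SNPs,
#' then leftmost) provided they do not overlap an accepted block and
#' meet the acceptance rule of [gabriel_rules()].  Blocks never span
#' chromosome boundaries and their member SNPs are map-contiguous.
#'
#' @param panel a post-QC [haplotype_panel()].
#' @param rules a [gabriel_rules()].
#' @param max_pair_distance bp cap on pair evaluation (default 5 Mb);
#'   pairs beyond the cap are treated as uninformative.
#' @return data.frame of class `block_set`: `chrom`, `start_bp`,
#'   `end_bp`, `span_bp`, `n_snps`, `first_snp`, `last_snp`.
#' @export
gabriel_blocks <- function(panel, rules = gabriel_rules(),
                           max_pair_distance = 5e6) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(rules, "gabriel_rules"))
  freq <- colMeans(panel$alleles)
  if (any(freq <= 0 | freq >= 1))
    stop("panel contains monomorphic SNPs; run QC first")
  res <- list(); k <- 0L
  for (ch in sort(unique(panel$map$chrom))) {
    cols <- which(panel$map$chrom == ch)
    m <- length(cols)
    if (m < 2) next
    pos <- panel$map$pos[cols]
    prs <- .pair_indices(pos, max_pair_distance)
    if (length(prs$i) == 0) next
    H <- panel$alleles[, cols, drop = FALSE]
    ci <- .dprime_ci_pairs(H, prs$i, prs$j, rules$tails, rules$grid_points)
    ## classification matrices over local indices: 1 strong, -1 recomb, 0 other
    cls <- matrix(NA_integer_, m, m)
    cls[cbind(prs$i, prs$j)] <-
      ifelse(ci$upper > rules$strong_upper & ci$lower > rules$strong_lower, 1L,
             ifelse(ci$upper < rules$recomb_upper, -1L, 0L))
    strong <- which(cls == 1L, arr.ind = TRUE)
    if (nrow(strong) == 0) next
    cand <- data.frame(i = strong[, 1], j = strong[, 2])
    cand$span <- pos[cand$j] - pos[cand$i]
    cand$size <- cand$j - cand$i + 1L
    cand <- cand[order(-cand$span, -cand$size, cand$i), ]
    taken <- rep(FALSE, m)
    for (b in seq_len(nrow(cand))) {
      i <- cand$i[b]; j <- cand$j[b]
      if (any(taken[i:j])) next
      sub <- cls[i:j, i:j]
      inf <- sub[!is.na(sub) & sub != 0L]
      n_inf <- length(inf)
      n_strong <- sum(inf == 1L)
      size <- cand$size[b]
      need <- if (size == 2L) 0 else if (size == 3L) rules$accept_frac_3
              else rules$accept_frac
      ok <- if (size == 2L) TRUE else n_inf > 0 && n_strong / n_inf >= need
      if (!ok) next
      taken[i:j] <- TRUE
      k <- k + 1L
      res[[k]] <- data.frame(chrom = ch, start_bp = pos[i], end_bp = pos[j],
                             span_bp = pos[j] - pos[i], n_snps = size,
                             first_snp = panel$map$id[cols[i]],
                             last_snp = panel$map$id[cols[j]],
                             stringsAsFactors = FALSE)
    }
  }
  out <- if (k == 0L)
    data.frame(chrom = integer(0), start_bp = integer(0), end_bp = integer(0),
               span_bp = integer(0), n_snps = integer(0),
               first_snp = character(0), last_snp = character(0))
  else do.call(rbind, res)
  out <- out[order(out$chrom, out$start_bp), ]
  rownames(out) <- NULL
  class(out) <- c("block_set", "data.frame")
  out
}

#' Haploblock summary statistics
#'
#' The usual descriptive table of a block set: median and maximum block
#' span (kb), genome coverage (Mb, sum of spans), total SNPs inside
#' blocks (TSNPs), their percentage of the analysed SNPs (BSNPs%), the
#' mean, SD and maximum of per-block SNP counts, and — when the total
#' autosome length is known — coverage as a percentage of the genome.
#'
#' @param blocks a block set from [gabriel_blocks()] (or any data.frame
#'   with `span_bp` and `n_snps`).
#' @param n_snps_total number of post-QC SNPs in the analysed panel.
#' @param genome_bp total length of the analysed autosomes in bp
#'   (optional).
#' @return list with `n_blocks`, `median_kb`, `max_kb`, `coverage_mb`,
#'   `tsnps`, `bsnps_pct`, `mean_nbsnps`, `sd_nbsnps`, `max_nbsnps`,
#'   `coverage_pct` (NA without `genome_bp`).  Zero-filled for an empty
#'   block set.
#' @export
block_summary <- function(blocks, n_snps_total, genome_bp = NULL) {
  stopifnot(n_snps_total > 0)
  if (nrow(blocks) == 0)
    return(list(n_blocks = 0L, median_kb = 0, max_kb = 0, coverage_mb = 0,
                tsnps = 0L, bsnps_pct = 0, mean_nbsnps = 0, sd_nbsnps = 0,
                max_nbsnps = 0L,
                coverage_pct = if (is.null(genome_bp)) NA_real_ else 0))
  cov_bp <- sum(as.numeric(blocks$span_bp))
  list(n_blocks = nrow(blocks),
       median_kb = stats::median(blocks$span_bp) / 1e3,
       max_kb = max(blocks$span_bp) / 1e3,
       coverage_mb = cov_bp / 1e6,
       tsnps = sum(blocks$n_snps),
       bsnps_pct = 100 * sum(blocks$n_snps) / n_snps_total,
       mean_nbsnps = mean(blocks$n_snps),
       sd_nbsnps = stats::sd(blocks$n_snps),
       max_nbsnps = max(blocks$n_snps),
       coverage_pct = if (is.null(genome_bp)) NA_real_
                      else 100 * cov_bp / genome_bp)
}
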