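#' Per-SNP minor allele frequencies
#'
#' @param panel a [haplotype_panel()].
#' @return Named numeric vector of MAF = min(p, 1 - p) per SNP.
#' @export
snp_maf <- function(panel) {
  p <- colMeans(panel$alleles)
  stats::setNames(pmin(p, 1 - p), panel$map$id)
}

#' MAF spectrum
#'
#' Histogram of per-SNP minor allele frequencies over half-open bins of
#' \[0, 0.5\]; the last bin is closed so MAF = 0.5 is counted.
#'
#' @param panel a [haplotype_panel()].
#' @param bin_width bin width on the MAF axis (default 0.05).
#' @return data.frame with `bin_lo`, `bin_hi`, `count`.
#' @export
maf_spectrum <- function(panel, bin_width = 0.05) {
  stopifnot(bin_width > 0, bin_width <= 0.5)
  maf <- snp_maf(panel)
  lo <- seq(0, 0.5 - bin_width / 2, by = bin_width)
  bin <- pmin(floor(maf / bin_width), length(lo) - 1L)
  data.frame(bin_lo = lo, bin_hi = pmin(lo + bin_width, 0.5),
             count = as.integer(tabulate(bin + 1L, nbins = length(lo))))
}

#' Weir-Cockerham F_st for one SNP
#'
#' The Weir & Cockerham (1984) variance-component estimator theta-hat =
#' a / (a + b + c) for unequal sample sizes, computed from per-line
#' sample sizes, allele frequencies and observed heterozygote
#' proportions.  The estimator can be slightly negative in finite
#' samples; it is undefined (NA) when the SNP is monomorphic across all
#' lines.
#'
#' @param n diploid sample size per line.
#' @param p frequency of the counted allele per line.
#' @param het observed heterozygote proportion per line.
#' @return theta-hat, or NA when undefined.
#' @export
wc_fst <- function(n, p, het) {
  stopifnot(length(n) == length(p), length(n) == length(het), length(n) >= 2,
            all(n >= 1))
  r <- length(n)
  n_bar <- mean(n)
  n_c <- (r * n_bar - sum(n^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n * p) / (r * n_bar)
  if (p_bar <= 0 || p_bar >= 1) return(NA_real_)
  s2 <- sum(n * (p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n * het) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  denom <- a + b + cc
  if (denom == 0) return(NA_real_)
  a / denom
}

#' Per-SNP F_st across populations
#'
#' @param panels list of [haplotype_panel()]s sharing the SNPs in
#'   `snps` (oriented so allele codes agree).
#' @param snps SNP ids to evaluate; defaults to [common_snps()] of the
#'   panels.
#' @return data.frame with `id` and `theta` (NA where undefined), plus
#'   per-line allele-frequency columns.
#' @export
fst_table <- function(panels, snps = NULL) {
  stopifnot(length(panels) >= 2)
  if (is.null(snps)) snps <- common_snps(panels)
  sub <- lapply(panels, subset_snps, snps = snps)
  snps <- sub[[1]]$map$id          # map order
  if (length(snps) == 0) stop("empty SNP set")
  n <- vapply(sub, n_individuals, integer(1))
  gv <- lapply(sub, function(p) genotype_view(p)$geno)
  pmat <- vapply(gv, function(g) colMeans(g) / 2, numeric(length(snps)))
  hmat <- vapply(gv, function(g) colMeans(g == 1L), numeric(length(snps)))
  if (length(snps) == 1) { pmat <- t(pmat); hmat <- t(hmat) }
  theta <- vapply(seq_along(snps), function(i)
    wc_fst(n, pmat[i, ], hmat[i, ]), numeric(1))
  out <- data.frame(id = snps, theta = theta, stringsAsFactors = FALSE)
  freq <- as.data.frame(pmat)
  names(freq) <- paste0("p_", vapply(sub, function(p) p$label, ""))
  cbind(out, freq)
}

#' Mean F_st across SNPs
#'
#' Arithmetic mean of per-SNP Weir-Cockerham theta over defined SNPs
#' (`mode = "average"`, the default), or the ratio-of-averages variant
#' sum(a) / sum(a + b + c) (`mode = "ratio"`), the more common
#' genome-wide convention.
#'
#' @inheritParams fst_table
#' @param mode `"average"` or `"ratio"`.
#' @return Mean theta (numeric scalar).
#' @export
mean_fst <- function(panels, snps = NULL, mode = c("average", "ratio")) {
  mode <- match.arg(mode)
  stopifnot(length(panels) >= 2)
  if (is.null(snps)) snps <- common_snps(panels)
  if (length(snps) == 0) stop("empty SNP set")
  if (mode == "average") {
    tab <- fst_table(panels, snps)
    th <- tab$theta[!is.na(tab$theta)]
    if (length(th) == 0) stop("no SNP with defined F_st")
    return(mean(th))
  }
  ## ratio-of-averages: accumulate the a and a+b+c components
  sub <- lapply(panels, subset_snps, snps = snps)
  n <- vapply(sub, n_individuals, integer(1))
  gv <- lapply(sub, function(p) genotype_view(p)$geno)
  num <- 0; den <- 0
  r <- length(panels)
  n_bar <- mean(n)
  n_c <- (r * n_bar - sum(n^2) / (r * n_bar)) / (r - 1)
  for (i in seq_along(snps)) {
    p <- vapply(gv, function(g) mean(g[, i]) / 2, numeric(1))
    het <- vapply(gv, function(g) mean(g[, i] == 1L), numeric(1))
    p_bar <- sum(n * p) / (r * n_bar)
    if (p_bar <= 0 || p_bar >= 1) next
    s2 <- sum(n * (p - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n * het) / (r * n_bar)
    a <- (n_bar / n_c) *
      (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
    b <- (n_bar / (n_bar - 1)) *
      (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    num <- num + a
    den <- den + a + b + h_bar / 2
  }
  if (den == 0) stop("no SNP with defined F_st")
  num / den
}
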