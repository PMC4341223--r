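#' Allelic correlation r between two SNPs
#'
#' r = (f(MN) - f(M) f(N)) / sqrt(f(M) f(m) f(N) f(n)), the correlation
#' between alleles at two SNPs computed from phased haplotype
#' frequencies; it equals the Pearson correlation of the two SNPs' 0/1
#' allele indicators across the haplotype sample.  Vectorized.
#'
#' @param f_MN observed frequency of the two-locus haplotype carrying
#'   allele M at the first SNP and N at the second.
#' @param f_M,f_N allele frequencies of M and N (strictly inside (0,1)).
#' @return r in \[-1, 1\].
#' @export
allele_r <- function(f_MN, f_M, f_N) {
  if (any(f_M <= 0 | f_M >= 1 | f_N <= 0 | f_N >= 1))
    stop("LD is undefined for monomorphic SNPs; pre-filter the panel")
  if (any(f_MN < -1e-12 | f_MN - pmin(f_M, f_N) > 1e-12))
    stop("f_MN must lie in [0, min(f_M, f_N)]")
  r <- (f_MN - f_M * f_N) / sqrt(f_M * (1 - f_M) * f_N * (1 - f_N))
  pmin(1, pmax(-1, r))   # guard rounding at the |r| = 1 boundary
}

#' Normalized disequilibrium D'
#'
#' D = f(MN) - f(M) f(N); D' = |D| / D_max, where D_max is the largest
#' |D| compatible with the allele frequencies in the direction of the
#' observed D.  Vectorized.
#'
#' @inheritParams allele_r
#' @return D' in \[0, 1\].
#' @export
d_prime <- function(f_MN, f_M, f_N) {
  if (any(f_M <= 0 | f_M >= 1 | f_N <= 0 | f_N >= 1))
    stop("LD is undefined for monomorphic SNPs; pre-filter the panel")
  D <- f_MN - f_M * f_N
  dmax <- ifelse(D >= 0,
                 pmin(f_M * (1 - f_N), (1 - f_M) * f_N),
                 pmin(f_M * f_N, (1 - f_M) * (1 - f_N)))
  out <- ifelse(D == 0, 0, abs(D) / dmax)
  pmin(out, 1)
}

## Pair indices (i, j), j > i, with 0 < pos_j - pos_i < cap, for one
## chromosome of strictly increasing positions.
.pair_indices <- function(pos, cap) {
  m <- length(pos)
  if (m < 2) return(list(i = integer(0), j = integer(0)))
  ## positions are integers: pos_j - pos_i < cap  <=>  pos_j <= pos_i + cap - 0.5
  jmax <- findInterval(pos + cap - 0.5, pos)
  lens <- pmax(jmax - seq_len(m), 0L)
  i <- rep.int(seq_len(m), lens)
  j <- i + sequence(lens)
  list(i = i, j = j)
}

#' Pairwise LD table within a distance cap
#'
#' Computes, for every within-chromosome SNP pair closer than
#' `max_pair_distance`, the two-locus haplotype frequency, allele
#' frequencies, r, r-squared, D and D' by direct counting from the
#' phased haplotype matrix.
#'
#' @param panel a post-QC [haplotype_panel()] whose SNPs are all
#'   polymorphic.
#' @param max_pair_distance bp cap on inter-SNP distance (default 5 Mb).
#' @return data.frame with columns `snp_i`, `snp_j`, `chrom`, `dist`,
#'   `f_MN`, `f_M`, `f_N`, `r`, `r2`, `D`, `d_prime`.
#' @export
pairwise_ld <- function(panel, max_pair_distance = 5e6) {
  stopifnot(inherits(panel, "haplotype_panel"), max_pair_distance > 0)
  empty <- data.frame(snp_i = character(0), snp_j = character(0),
                      chrom = integer(0), dist = integer(0),
                      f_MN = numeric(0), f_M = numeric(0), f_N = numeric(0),
                      r = numeric(0), r2 = numeric(0), D = numeric(0),
                      d_prime = numeric(0))
  if (n_snps(panel) == 0 || n_individuals(panel) == 0) return(empty)
  freq <- colMeans(panel$alleles)
  if (any(freq <= 0 | freq >= 1))
    stop("panel contains monomorphic SNPs; LD is undefined for them ",
         "(run QC first)")
  out <- vector("list", length(unique(panel$map$chrom)))
  k <- 0L
  for (ch in sort(unique(panel$map$chrom))) {
    cols <- which(panel$map$chrom == ch)
    prs <- .pair_indices(panel$map$pos[cols], max_pair_distance)
    if (length(prs$i) == 0) next
    H <- panel$alleles[, cols, drop = FALSE]
    nh <- nrow(H)
    fMN <- crossprod(H) / nh
    p <- freq[cols]
    ii <- prs$i; jj <- prs$j
    f_MN <- fMN[cbind(ii, jj)]
    f_M <- p[ii]; f_N <- p[jj]
    r <- allele_r(f_MN, f_M, f_N)
    k <- k + 1L
    out[[k]] <- data.frame(
      snp_i = panel$map$id[cols[ii]], snp_j = panel$map$id[cols[jj]],
      chrom = ch, dist = panel$map$pos[cols[jj]] - panel$map$pos[cols[ii]],
      f_MN = f_MN, f_M = f_M, f_N = f_N, r = r, r2 = r^2,
      D = f_MN - f_M * f_N, d_prime = d_prime(f_MN, f_M, f_N),
      stringsAsFactors = FALSE)
  }
  if (k == 0L) return(empty)
  do.call(rbind, out[seq_len(k)])
}

#' Chicken autosome size categories
#'
#' The conventional grouping of chicken autosomes: GGA1-5 macro-,
#' GGA6-10 intermediate and GGA11-38 micro-chromosomes.
#'
#' @param chroms integer chromosome numbers.
#' @return Named character vector chromosome -> category.
#' @export
gga_categories <- function(chroms = 1:38) {
  cat <- ifelse(chroms <= 5, "macro",
                ifelse(chroms <= 10, "intermediate", "micro"))
  stats::setNames(cat, chroms)
}

.category_of <- function(chrom, categories) {
  if (is.null(categories)) return(rep("all", length(chrom)))
  out <- unname(categories[as.character(chrom)])
  if (anyNA(out)) stop("chromosome(s) without a category: ",
                       paste(unique(chrom[is.na(out)]), collapse = ", "))
  out
}

#' LD-decay curve: mean r-squared in distance bins
#'
#' Averages r-squared over half-open distance bins \[0, w), \[w, 2w), ...
#' separately per chromosome category.  Empty bins are omitted.
#'
#' @param pairs a pairwise LD table from [pairwise_ld()].
#' @param categories named vector chromosome -> category (e.g.
#'   [gga_categories()]), or NULL for a single pooled curve.
#' @param bin_width bin width in bp (default 25 kb).
#' @return data.frame with `category`, `bin_lo`, `bin_hi`, `mid`,
#'   `mean_r2`, `n_pairs`, sorted by category then distance.
#' @export
decay_curve <- function(pairs, categories = NULL, bin_width = 25000) {
  stopifnot(bin_width > 0)
  if (nrow(pairs) == 0)
    return(data.frame(category = character(0), bin_lo = numeric(0),
                      bin_hi = numeric(0), mid = numeric(0),
                      mean_r2 = numeric(0), n_pairs = integer(0)))
  cat <- .category_of(pairs$chrom, categories)
  bin <- floor(pairs$dist / bin_width)
  key <- paste(cat, bin, sep = "\r")
  mean_r2 <- tapply(pairs$r2, key, mean)
  n <- tapply(pairs$r2, key, length)
  parts <- strsplit(names(mean_r2), "\r", fixed = TRUE)
  out <- data.frame(category = vapply(parts, `[`, "", 1),
                    bin_lo = as.numeric(vapply(parts, `[`, "", 2)) * bin_width,
                    stringsAsFactors = FALSE)
  out$bin_hi <- out$bin_lo + bin_width
  out$mid <- out$bin_lo + bin_width / 2
  out$mean_r2 <- as.numeric(mean_r2)
  out$n_pairs <- as.integer(n)
  out <- out[order(out$category, out$bin_lo), ]
  rownames(out) <- NULL
  out
}

#' Distance at which the decay curve first drops below a threshold
#'
#' Scans the populated bins of a single decay curve in order of
#' increasing distance and returns the midpoint of the first bin whose
#' mean r-squared falls below the threshold; the first crossing wins
#' even if the curve later rebounds.
#'
#' @param curve one category's rows of a [decay_curve()] result.
#' @param threshold r-squared threshold (default 0.2).
#' @return Distance in bp, or `NA` if the curve never drops below the
#'   threshold.
#' @export
d_threshold_distance <- function(curve, threshold = 0.2) {
  if (nrow(curve) == 0) return(NA_real_)
  if (length(unique(curve$category)) > 1)
    stop("pass a single category's curve (filter first)")
  curve <- curve[order(curve$bin_lo), ]
  hit <- which(curve$mean_r2 < threshold)
  if (length(hit) == 0) return(NA_real_)
  curve$mid[hit[1]]
}

#' LD between adjacent SNPs
#'
#' Summarizes r-squared over all pairs of map-adjacent SNPs (per
#' chromosome).  Adjacency is a property of the post-QC map, so
#' adjacent pairs farther apart than any pairwise distance cap are
#' still included.  Threshold fractions use strict inequality.
#'
#' @param panel a post-QC [haplotype_panel()] (all SNPs polymorphic).
#' @param thresholds r-squared thresholds for the exceedance fractions.
#' @return list with `n_pairs`, `mean_r2` and `frac_gt` (named vector of
#'   fractions of pairs with r-squared strictly above each threshold).
#' @export
adjacent_ld_summary <- function(panel, thresholds = c(0.2, 0.3)) {
  freq <- colMeans(panel$alleles)
  if (any(freq <= 0 | freq >= 1))
    stop("panel contains monomorphic SNPs; run QC first")
  r2 <- numeric(0)
  for (ch in sort(unique(panel$map$chrom))) {
    cols <- which(panel$map$chrom == ch)
    if (length(cols) < 2) next
    H <- panel$alleles[, cols, drop = FALSE]
    i <- seq_len(length(cols) - 1L)
    f_MN <- colMeans(H[, i, drop = FALSE] * H[, i + 1L, drop = FALSE])
    r2 <- c(r2, allele_r(f_MN, freq[cols[i]], freq[cols[i + 1L]])^2)
  }
  if (length(r2) == 0)
    stop("no adjacent SNP pairs: every chromosome has fewer than 2 SNPs")
  list(n_pairs = length(r2), mean_r2 = mean(r2),
       frac_gt = stats::setNames(vapply(thresholds, function(t) mean(r2 > t),
                                        numeric(1)),
                                 paste0("r2_gt_", thresholds)))
}
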