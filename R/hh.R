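#' Sliding-window haplotype homozygosity
#'
#' The probability of drawing two identical haplotypes from a window:
#' for every window of `window` bp advanced by `step` bp (anchored at
#' position 0 of each chromosome, half-open \[start, start + window)),
#' the distinct allele strings over the window's SNPs are counted across
#' all 2n haplotypes and HH is the sum of squared haplotype sample
#' frequencies.  Windows containing no SNP are skipped.
#'
#' @param panel a post-QC phased [haplotype_panel()].
#' @param window window width in bp (default 250 kb).
#' @param step step size in bp (default 25 kb).
#' @return data.frame with `chrom`, `start`, `end`, `n_snps`, `hh`;
#'   `hh` lies in \[1/(2n), 1\].
#' @export
haplotype_homozygosity <- function(panel, window = 250000, step = 25000) {
  stopifnot(inherits(panel, "haplotype_panel"), window > 0, step > 0)
  nh <- nrow(panel$alleles)
  if (nh == 0) stop("panel has no individuals")
  out <- list(); k <- 0L
  for (ch in sort(unique(panel$map$chrom))) {
    cols <- which(panel$map$chrom == ch)
    pos <- panel$map$pos[cols]
    starts <- seq(0, max(pos), by = step)
    for (s in starts) {
      in_win <- cols[pos >= s & pos < s + window]
      if (length(in_win) == 0) next
      key <- do.call(paste, c(as.data.frame(panel$alleles[, in_win, drop = FALSE]),
                              sep = ""))
      p <- table(key) / nh
      k <- k + 1L
      out[[k]] <- data.frame(chrom = ch, start = s, end = s + window,
                             n_snps = length(in_win), hh = sum(p^2))
    }
  }
  if (k == 0L)
    return(data.frame(chrom = integer(0), start = numeric(0), end = numeric(0),
                      n_snps = integer(0), hh = numeric(0)))
  do.call(rbind, out)
}
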