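#' Orient allele codes consistently across panels
#'
#' The sign of r is only comparable between populations under a shared
#' allele labelling.  Taking the first panel's map as the anchor, every
#' shared SNP whose allele0/allele1 labels are swapped in another panel
#' has its 0/1 codes flipped (and labels swapped) there; SNPs with
#' irreconcilable label sets raise an error naming them.
#'
#' @param panels list of [haplotype_panel()] objects.
#' @return The list of panels, consistently labelled at all shared SNPs.
#' @export
orient_alleles <- function(panels) {
  stopifnot(length(panels) >= 2)
  anchor <- panels[[1]]$map
  for (k in seq_along(panels)[-1]) {
    p <- panels[[k]]
    hit <- match(p$map$id, anchor$id)
    shared <- which(!is.na(hit))
    if (length(shared) == 0) next
    a <- anchor[hit[shared], ]
    same <- p$map$allele0[shared] == a$allele0 & p$map$allele1[shared] == a$allele1
    swap <- p$map$allele0[shared] == a$allele1 & p$map$allele1[shared] == a$allele0
    if (any(!(same | swap)))
      stop("irreconcilable allele labels in panel ", p$label, " at: ",
           paste(utils::head(p$map$id[shared][!(same | swap)], 5),
                 collapse = ", "))
    flip <- shared[swap & !same]   # identical labels (A/A) need no flip
    if (length(flip)) {
      p$alleles[, flip] <- 1L - p$alleles[, flip]
      a0 <- p$map$allele0[flip]
      p$map$allele0[flip] <- p$map$allele1[flip]
      p$map$allele1[flip] <- a0
      panels[[k]] <- p
    }
  }
  panels
}

#' Consistency of LD between two populations
#'
#' Pearson correlation, over shared SNP pairs in half-open distance
#' bins, of the signed r values computed in each population — high
#' positive values mean the two populations agree in both the level and
#' the phase of LD.  Panels are first restricted to their common
#' polymorphic SNPs and allele-oriented so that r signs are comparable.
#'
#' @param pop_a,pop_b post-QC [haplotype_panel()] objects.
#' @param categories named vector chromosome -> category, or NULL to
#'   pool all chromosomes.
#' @param bin_width bin width in bp (default 50 kb).
#' @param max_pair_distance bp cap on pair distance (default 5 Mb).
#' @return data.frame with `category`, `bin_lo`, `bin_hi`, `mid`,
#'   `cor_r`, `n_pairs`; `cor_r` is NA for bins with fewer than 2 pairs.
#' @export
correlation_of_r <- function(pop_a, pop_b, categories = NULL,
                             bin_width = 50000, max_pair_distance = 5e6) {
  ids <- common_snps(list(pop_a, pop_b))
  if (length(ids) == 0) stop("no common SNPs between the two panels")
  pan <- orient_alleles(list(subset_snps(pop_a, ids), subset_snps(pop_b, ids)))
  poly <- lapply(pan, function(p) {
    f <- colMeans(p$alleles)
    p$map$id[f > 0 & f < 1]
  })
  ids <- intersect(poly[[1]], poly[[2]])
  if (length(ids) < 2) stop("fewer than 2 common polymorphic SNPs")
  pan <- lapply(pan, subset_snps, snps = ids)
  ta <- pairwise_ld(pan[[1]], max_pair_distance)
  tb <- pairwise_ld(pan[[2]], max_pair_distance)
  key_a <- paste(ta$snp_i, ta$snp_j)
  key_b <- paste(tb$snp_i, tb$snp_j)
  hit <- match(key_a, key_b)
  ok <- !is.na(hit)
  if (!any(ok)) stop("no shared SNP pairs within the distance cap")
  da <- ta[ok, ]
  rb <- tb$r[hit[ok]]
  cat <- .category_of(da$chrom, categories)
  bin <- floor(da$dist / bin_width)
  key <- paste(cat, bin, sep = "\r")
  spl <- split(seq_len(nrow(da)), key)
  parts <- strsplit(names(spl), "\r", fixed = TRUE)
  out <- data.frame(category = vapply(parts, `[`, "", 1),
                    bin_lo = as.numeric(vapply(parts, `[`, "", 2)) * bin_width,
                    stringsAsFactors = FALSE)
  out$bin_hi <- out$bin_lo + bin_width
  out$mid <- out$bin_lo + bin_width / 2
  out$cor_r <- vapply(spl, function(idx) {
    if (length(idx) < 2) return(NA_real_)
    suppressWarnings(stats::cor(da$r[idx], rb[idx]))
  }, numeric(1))
  out$n_pairs <- vapply(spl, length, integer(1))
  out <- out[order(out$category, out$bin_lo), ]
  rownames(out) <- NULL
  out
}

#' Predict crossbred LD from pooled pure-line haplotypes
#'
#' Builds an in-silico combined population by sampling individuals from
#' the three pure lines in the given proportions (defaults 2:1:1,
#' mirroring the expected 50/25/25% autosomal contributions of lines B,
#' C and D to the three-way cross) and pooling their haplotypes, then
#' returns the pairwise LD table of the pooled panel.  Pooled allele and
#' haplotype frequencies equal the weighted means of the line
#' frequencies, so this predicts the LD of the crossbred population
#' without breeding it.
#'
#' @param line_b,line_c,line_d pure-line [haplotype_panel()]s sharing a
#'   SNP map (orient first if labels may differ).
#' @param weights positive pooling weights for B, C, D (default 2:1:1).
#' @param n_total total individuals in the combined panel (default 400,
#'   i.e. 200/100/100 under the default weights).
#' @param seed integer seed for the sampling step.
#' @param max_pair_distance bp cap on pair distance.
#' @return list with `panel` (the pooled [haplotype_panel()], labelled
#'   `"cBCD"`) and `pairs` (its [pairwise_ld()] table).
#' @export
predict_crossbred_ld <- function(line_b, line_c, line_d,
                                 weights = c(2, 1, 1), n_total = 400,
                                 seed = 1L, max_pair_distance = 5e6) {
  stopifnot(length(weights) == 3, all(weights >= 0), sum(weights) > 0,
            n_total >= 2)
  n_per <- round(n_total * weights / sum(weights))
  pooled <- pool_panels(list(line_b, line_c, line_d), n_sample = n_per,
                        seed = seed, label = "cBCD")
  f <- colMeans(pooled$alleles)
  poly <- which(f > 0 & f < 1)
  pooled <- subset_snps(pooled, poly)
  list(panel = pooled, pairs = pairwise_ld(pooled, max_pair_distance))
}
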