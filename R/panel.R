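#' Phased haplotype panel
#'
#' The central container of the package: a matrix of phased 0/1 alleles
#' (two haplotype rows per diploid individual) together with an ordered
#' SNP map.  Every statistic in the package (pairwise LD, decay curves,
#' haploblocks, haplotype homozygosity, F_st) is computed from this
#' object.
#'
#' @param alleles integer matrix of 0/1 alleles with `2 * n_individuals`
#'   rows and one column per SNP.  Rows `2i - 1` and `2i` are the two
#'   haplotypes of individual `i`.
#' @param map data.frame with columns `id`, `chrom` (integer), `pos`
#'   (1-based bp, strictly increasing within each chromosome),
#'   `allele0`, `allele1` (the labels coded 0 and 1).
#' @param label population label, e.g. `"B"` or `"BCD"`.
#' @param origin optional character matrix of the same shape as
#'   `alleles` giving the line of origin (`"B"`, `"C"` or `"D"`) of each
#'   allele copy; recorded by [make_cross()].
#' @param samples optional character vector of individual ids (length
#'   `nrow(alleles) / 2`).
#'
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, map, label = "pop", origin = NULL,
                            samples = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) %% 2L != 0L)
    stop("'alleles' must have an even number of rows (two haplotypes per individual)")
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  req <- c("id", "chrom", "pos", "allele0", "allele1")
  if (!all(req %in% names(map)))
    stop("'map' must have columns: ", paste(req, collapse = ", "))
  map <- map[req]
  map$id <- as.character(map$id)
  map$chrom <- as.integer(map$chrom)
  map$pos <- as.integer(map$pos)
  map$allele0 <- as.character(map$allele0)
  map$allele1 <- as.character(map$allele1)
  if (ncol(alleles) != nrow(map))
    stop("number of allele columns (", ncol(alleles),
         ") does not match number of map rows (", nrow(map), ")")
  if (anyNA(alleles) || !all(alleles == 0L | alleles == 1L))
    stop("'alleles' must contain only 0/1 (phased, no missing calls)")
  if (anyDuplicated(map$id))
    stop("duplicated SNP ids in map")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  n <- nrow(alleles) %/% 2L
  if (is.null(samples))
    samples <- if (n == 0L) character(0) else paste0(label, "_", seq_len(n))
  if (length(samples) != n) stop("'samples' must have one id per individual")
  if (!is.null(origin)) {
    origin <- as.matrix(origin)
    if (!identical(dim(origin), dim(alleles)))
      stop("'origin' must have the same dimensions as 'alleles'")
  }
  structure(
    list(alleles = alleles, map = map, label = as.character(label),
         origin = origin, samples = as.character(samples)),
    class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> population", x$label, "\n")
  cat("  ", n_individuals(x), "individuals (", nrow(x$alleles), "haplotypes ),",
      n_snps(x), "SNPs on", length(unique(x$map$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Number of individuals in a panel
#' @param panel a [haplotype_panel()].
#' @return integer count.
#' @export
n_individuals <- function(panel) nrow(panel$alleles) %/% 2L

#' Number of SNPs in a panel
#' @param panel a [haplotype_panel()].
#' @return integer count.
#' @export
n_snps <- function(panel) ncol(panel$alleles)

#' Subset a panel to a set of SNPs
#'
#' @param panel a [haplotype_panel()].
#' @param snps SNP ids (character) or column indices (integer/logical).
#'   Map order is preserved regardless of the order given.
#' @return A [haplotype_panel()] restricted to those SNPs.
#' @export
subset_snps <- function(panel, snps) {
  if (is.character(snps)) {
    idx <- which(panel$map$id %in% snps)
    if (length(idx) < length(unique(snps)))
      stop("some SNP ids not present in panel ", panel$label)
  } else {
    idx <- which(seq_len(n_snps(panel)) %in% seq_len(n_snps(panel))[snps])
  }
  idx <- sort(idx)
  haplotype_panel(panel$alleles[, idx, drop = FALSE], panel$map[idx, ],
                  label = panel$label,
                  origin = if (!is.null(panel$origin)) panel$origin[, idx, drop = FALSE],
                  samples = panel$samples)
}

#' Subset a panel to a set of individuals
#'
#' @param panel a [haplotype_panel()].
#' @param idx individual indices (not haplotype rows).
#' @return A [haplotype_panel()] with those individuals, in the order given.
#' @export
subset_individuals <- function(panel, idx) {
  idx <- as.integer(idx)
  if (any(idx < 1L | idx > n_individuals(panel)))
    stop("individual index out of range")
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  haplotype_panel(panel$alleles[rows, , drop = FALSE], panel$map,
                  label = panel$label,
                  origin = if (!is.null(panel$origin)) panel$origin[rows, , drop = FALSE],
                  samples = panel$samples[idx])
}

#' Unphased genotype view of a panel
#'
#' Collapses the two phased haplotypes of each individual into 0/1/2
#' genotype counts, optionally overlaying missingness.  Quality control
#' operates on this view; a fully phased panel has call rate 1 at every
#' SNP.
#'
#' @param panel a [haplotype_panel()].
#' @return list with `geno` (n_individuals x n_snps integer matrix, NA
#'   for missing) and `call_rate` (per-SNP fraction of non-missing
#'   calls).
#' @export
genotype_view <- function(panel) {
  H <- panel$alleles
  odd <- seq(1L, nrow(H), by = 2L)
  geno <- H[odd, , drop = FALSE] + H[odd + 1L, , drop = FALSE]
  rownames(geno) <- panel$samples
  colnames(geno) <- panel$map$id
  list(geno = geno, call_rate = rep(1, ncol(geno)))
}

#' Inject missing genotype calls
#'
#' Sets a random fraction of genotype calls to NA.  Used to exercise the
#' call-rate and Mendelian-consistency filters of [run_qc()]; phased
#' panels themselves never carry missing data.
#'
#' @param geno genotype matrix from [genotype_view()].
#' @param rate per-call missingness probability.
#' @param seed integer seed.
#' @return The genotype matrix with NAs injected.
#' @export
inject_missingness <- function(geno, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  set.seed(as.integer(seed))
  geno[matrix(stats::runif(length(geno)) < rate, nrow(geno))] <- NA_integer_
  geno
}

#' Pool several panels into one
#'
#' Stacks the haplotypes of panels sharing an identical SNP map,
#' optionally sampling a fixed number of individuals from each panel
#' first.  This is the combined-population construction used to predict
#' crossbred LD from pure-line genotypes.
#'
#' @param panels list of [haplotype_panel()] objects with identical maps.
#' @param n_sample optional integer vector: number of individuals to
#'   sample (without replacement) from each panel before pooling.
#' @param seed integer seed for the sampling step.
#' @param label label for the pooled panel.
#' @return A [haplotype_panel()] containing the pooled haplotypes.
#' @export
pool_panels <- function(panels, n_sample = NULL, seed = NULL, label = "pooled") {
  stopifnot(length(panels) >= 1)
  m0 <- panels[[1]]$map
  for (p in panels[-1]) {
    if (!identical(p$map[c("id", "chrom", "pos")], m0[c("id", "chrom", "pos")]))
      stop("panels do not share an identical snp map; intersect with common_snps() first")
    if (!identical(p$map$allele0, m0$allele0) || !identical(p$map$allele1, m0$allele1))
      stop("panels do not share allele labels; run orient_alleles() first")
  }
  if (!is.null(n_sample)) {
    stopifnot(length(n_sample) == length(panels))
    if (!is.null(seed)) set.seed(as.integer(seed))
    panels <- lapply(seq_along(panels), function(k) {
      nk <- n_individuals(panels[[k]])
      if (n_sample[k] > nk)
        stop("cannot sample ", n_sample[k], " individuals from panel of ", nk)
      subset_individuals(panels[[k]], sample.int(nk, n_sample[k]))
    })
  }
  haplotype_panel(do.call(rbind, lapply(panels, `[[`, "alleles")), m0,
                  label = label,
                  samples = unlist(lapply(panels, function(p)
                    if (n_individuals(p) == 0L) character(0)
                    else paste0(p$label, ".", p$samples))))
}
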