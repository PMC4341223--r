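#' SNP quality-control thresholds
#'
#' Defaults follow standard practice for commercial SNP-array data:
#' call rate >= 90%, MAF >= 0.05, Mendelian inconsistency <= 0.001 and
#' (pure lines only) a Hardy-Weinberg exact-test p-value >= 0.001.
#' Crossbred populations are strongly out of Hardy-Weinberg equilibrium
#' by construction, so `apply_hwe` should be `FALSE` for them.
#'
#' @param min_call_rate minimum per-SNP call rate.
#' @param min_maf minimum minor allele frequency (computed on
#'   non-missing calls).
#' @param max_mendel_rate maximum fraction of inconsistent
#'   parent-offspring comparisons; the filter is skipped when no
#'   pedigree is supplied.
#' @param hwe_alpha significance level of the Hardy-Weinberg exact test.
#' @param excluded_chroms integer chromosomes removed outright (e.g.
#'   sparsely covered micro-chromosomes).
#' @param apply_hwe logical; apply the HWE filter?
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.9, min_maf = 0.05,
                          max_mendel_rate = 0.001, hwe_alpha = 0.001,
                          excluded_chroms = integer(0), apply_hwe = TRUE) {
  fr <- c(min_call_rate = min_call_rate, min_maf = min_maf,
          max_mendel_rate = max_mendel_rate, hwe_alpha = hwe_alpha)
  if (any(fr < 0 | fr > 1))
    stop("all QC thresholds must lie in [0, 1]")
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 max_mendel_rate = max_mendel_rate, hwe_alpha = hwe_alpha,
                 excluded_chroms = as.integer(excluded_chroms),
                 apply_hwe = isTRUE(apply_hwe)),
            class = "qc_thresholds")
}

#' Hardy-Weinberg exact test
#'
#' Exact test conditioning on the observed allele counts: the p-value is
#' the sum of probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed table (computed with
#' the standard stable recurrence over heterozygote counts).
#' Monomorphic SNPs return p = 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("total genotype count must be positive")
  n_A <- 2L * n_AA + n_Aa
  n_a <- 2L * n_aa + n_Aa
  if (n_A == 0L || n_a == 0L) return(1)
  rare <- min(n_A, n_a)
  hets <- seq(rare %% 2L, rare, by = 2L)
  probs <- numeric(length(hets))
  mid <- which.min(abs(hets - rare * (n_A + n_a - rare) / (n_A + n_a)))
  probs[mid] <- 1
  ## recurrence on unnormalized probabilities:
  ## P(h+2)/P(h) = 4 * homR(h) * homC(h) / ((h+2)(h+1))
  ## where homR = (rare - h)/2, homC = n - h - homR
  if (mid < length(hets)) for (i in mid:(length(hets) - 1L)) {
    h <- hets[i]
    hr <- (rare - h) / 2
    hc <- n - h - hr
    probs[i + 1L] <- probs[i] * 4 * hr * hc / ((h + 2) * (h + 1))
  }
  if (mid > 1L) for (i in mid:2L) {
    h <- hets[i]
    hr <- (rare - h) / 2
    hc <- n - h - hr
    probs[i - 1L] <- probs[i] * h * (h - 1) / (4 * (hr + 1) * (hc + 1))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hets)]
  if (is.na(p_obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

## Allowed offspring genotypes given two parental genotypes (NA parent
## treated by duo rules).  Encoded as a 3x3x3 logical lookup.
.trio_ok <- local({
  gam <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  arr <- array(FALSE, c(3, 3, 3))
  for (gs in 0:2) for (gd in 0:2) {
    poss <- unique(outer(gam[[gs + 1L]], gam[[gd + 1L]], `+`))
    arr[gs + 1L, gd + 1L, poss + 1L] <- TRUE
  }
  arr
})

#' Per-SNP Mendelian inconsistency rate
#'
#' For every offspring in the pedigree with at least one genotyped
#' parent, the offspring genotype is checked against the parental
#' genotype(s): duo rules (opposite homozygotes are incompatible) when
#' one parent is genotyped, full trio rules when both are.  The rate is
#' the fraction of checkable comparisons that are inconsistent;
#' comparisons with a missing offspring or with no genotyped parent are
#' excluded from the denominator.
#'
#' @param geno genotype matrix (individuals x SNPs, values 0/1/2/NA)
#'   with rownames giving individual ids.
#' @param pedigree data.frame with columns `id`, `sire`, `dam` (NA or
#'   missing ids allowed for unknown/external parents).
#' @return Named numeric vector of per-SNP inconsistency rates (NaN for
#'   SNPs with no checkable comparison).
#' @export
mendel_rates <- function(geno, pedigree) {
  stopifnot(all(c("id", "sire", "dam") %in% names(pedigree)))
  if (is.null(rownames(geno))) stop("'geno' must have individual ids as rownames")
  off <- match(pedigree$id, rownames(geno))
  sire <- match(pedigree$sire, rownames(geno))
  dam <- match(pedigree$dam, rownames(geno))
  use <- !is.na(off) & (!is.na(sire) | !is.na(dam))
  if (!any(use)) stop("pedigree contains no genotyped parent-offspring pair")
  off <- off[use]; sire <- sire[use]; dam <- dam[use]
  m <- ncol(geno)
  bad <- integer(m); tot <- integer(m)
  for (k in seq_along(off)) {
    go <- geno[off[k], ]
    gs <- if (is.na(sire[k])) rep(NA_integer_, m) else geno[sire[k], ]
    gd <- if (is.na(dam[k])) rep(NA_integer_, m) else geno[dam[k], ]
    trio <- !is.na(go) & !is.na(gs) & !is.na(gd)
    duo_s <- !is.na(go) & !is.na(gs) & is.na(gd)
    duo_d <- !is.na(go) & is.na(gs) & !is.na(gd)
    chk <- trio | duo_s | duo_d
    inc <- logical(m)
    if (any(trio))
      inc[trio] <- !.trio_ok[cbind(gs[trio] + 1L, gd[trio] + 1L, go[trio] + 1L)]
    if (any(duo_s)) inc[duo_s] <- abs(go[duo_s] - gs[duo_s]) == 2L
    if (any(duo_d)) inc[duo_d] <- abs(go[duo_d] - gd[duo_d]) == 2L
    tot <- tot + chk
    bad <- bad + inc
  }
  stats::setNames(bad / tot, colnames(geno))
}

#' Per-population SNP quality control with attrition report
#'
#' Applies the filters in a fixed order — excluded chromosomes,
#' Mendelian inconsistency, uncalled SNPs (call rate 0), monomorphic
#' SNPs, call rate, MAF, Hardy-Weinberg (when enabled) — attributing
#' each SNP to the first stage it fails, and returns the filtered panel
#' plus a stage-by-stage report.  Total removals therefore depend on
#' the stage order for SNPs failing several filters; the report always
#' reflects first-failure attribution.
#'
#' @param panel a [haplotype_panel()].
#' @param thresholds a [qc_thresholds()].
#' @param pedigree optional pedigree data.frame (see [mendel_rates()]);
#'   without it the Mendelian stage is reported as not applied.
#' @param genotypes optional genotype matrix (individuals x SNPs,
#'   0/1/2/NA) overriding [genotype_view()] of the panel — this is the
#'   unphased view in which missingness can exist.
#' @return list with `panel` (filtered), `report` (data.frame: stage,
#'   removed, remaining; removed is NA for stages not applied) and
#'   `kept` (SNP ids retained).
#' @export
run_qc <- function(panel, thresholds = qc_thresholds(), pedigree = NULL,
                   genotypes = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"),
            inherits(thresholds, "qc_thresholds"))
  geno <- if (is.null(genotypes)) genotype_view(panel)$geno else genotypes
  if (ncol(geno) != n_snps(panel))
    stop("'genotypes' must have one column per panel SNP")
  m <- n_snps(panel)
  alive <- rep(TRUE, m)
  report <- data.frame(stage = character(0), removed = integer(0),
                       remaining = integer(0))
  note <- function(stage, fail) {
    fail <- fail & alive
    alive <<- alive & !fail
    report <<- rbind(report, data.frame(
      stage = stage, removed = if (is.null(fail)) NA_integer_ else sum(fail),
      remaining = sum(alive)))
  }
  skip <- function(stage) {
    report <<- rbind(report, data.frame(stage = stage, removed = NA_integer_,
                                        remaining = sum(alive)))
  }

  note("excluded_chromosomes", panel$map$chrom %in% thresholds$excluded_chroms)

  if (!is.null(pedigree)) {
    mr <- mendel_rates(geno, pedigree)
    note("mendelian_inconsistency",
         !is.nan(mr) & mr > thresholds$max_mendel_rate)
  } else skip("mendelian_inconsistency")

  call_rate <- colMeans(!is.na(geno))
  note("uncalled", call_rate == 0)

  p <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  note("monomorphic", !is.na(maf) & maf == 0)
  note("call_rate", call_rate < thresholds$min_call_rate)
  note("maf", !is.na(maf) & maf < thresholds$min_maf)

  if (thresholds$apply_hwe) {
    idx <- which(alive)
    pv <- vapply(idx, function(j) {
      g <- geno[, j]
      hwe_test(sum(g == 2L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
               sum(g == 0L, na.rm = TRUE))
    }, numeric(1))
    fail <- rep(FALSE, m)
    fail[idx] <- pv < thresholds$hwe_alpha
    note("hwe", fail)
  } else skip("hwe")

  attr(report, "initial") <- m
  list(panel = subset_snps(panel, which(alive)), report = report,
       kept = panel$map$id[alive])
}
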