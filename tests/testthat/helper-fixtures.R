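# A 20-individual, 8-SNP fixture engineered so that exactly one SNP fails
# each applicable QC stage (first-failure attribution).
qc_fixture <- function() {
  n <- 20
  parents <- paste0("p", 1:10)
  offspring <- paste0("o", 1:10)
  geno <- matrix(NA_integer_, n, 8,
                 dimnames = list(c(parents, offspring), paste0("s", 1:8)))
  geno[, 1] <- rep(0:1, 10)                    # excluded chromosome (chrom 16)
  geno[, 2] <- c(rep(2L, 10), rep(0L, 10))     # every duo inconsistent
  geno[, 3] <- NA_integer_                     # never called
  geno[, 4] <- 0L                              # monomorphic
  geno[, 5] <- c(rep(c(0L, 1L), 5), rep(NA_integer_, 10))  # call rate 0.5
  geno[, 6] <- c(1L, rep(0L, 19))              # MAF 0.025
  geno[, 7] <- rep(c(0L, 2L), 10)              # HWE: no hets at MAF 0.5
  geno[, 8] <- rep(c(0L, 1L, 1L, 2L), 5)       # passes everything
  # Mendelian consistency elsewhere: parent/offspring pairs share genotypes
  # by construction (columns are constant or repeat with period 10/pattern 2).
  ped <- data.frame(id = offspring, sire = parents, dam = NA)
  # phased panel consistent with the non-missing genotypes
  H <- matrix(0L, 2 * n, 8)
  g0 <- geno; g0[is.na(g0)] <- 1L
  H[seq(1, 2 * n, 2), ] <- (g0 >= 1L) * 1L
  H[seq(2, 2 * n, 2), ] <- (g0 == 2L) * 1L
  panel <- haplotype_panel(H, data.frame(id = paste0("s", 1:8),
                                         chrom = c(16L, rep(1L, 7)),
                                         pos = c(100L, 100L + 100L * (1:7)),
                                         allele0 = "A", allele1 = "G"),
                           label = "fixture", samples = rownames(geno))
  list(panel = panel, geno = geno, ped = ped)
}
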