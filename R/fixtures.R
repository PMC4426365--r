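# packaged reference fixtures

#' Published pairwise fixed-difference matrices for the NOD substrains
#'
#' The exome-wide pairwise counts of SNPs and of short indels
#' distinguishing the five NOD substrains (BomTac, MrkTac, ShiJcl,
#' ShiLtDvs, ShiLt), packaged as labeled TSV fixtures and loaded into
#' validated [DistanceMatrix-class] objects.
#'
#' @return List with elements `SNP` and `indel`.
#' @export
#' @examples
#' distanceSummary(table1Matrices()$SNP)
table1Matrices <- function() {
  dir <- system.file("extdata", package = "SubstrainDrift")
  list(SNP = readDistanceTsv(file.path(dir, "table1_snp.tsv"), "SNP"),
       indel = readDistanceTsv(file.path(dir, "table1_indel.tsv"), "indel"))
}

#' Demo genotype table matching the published NOD exome tally
#'
#' A synthetic five-substrain genotype table whose totals match the
#' published NOD exome screen: 172 SNPs and 55 short indels (227
#' variants), of which 64 SNPs and 2 indels are coding. The per-category
#' consequence labels and the substrain distribution patterns are
#' synthetic (the published per-variant assignments live in
#' supplementary material not packaged here); only the totals are
#' reference values. Construction is deterministic.
#'
#' @return A [GenotypeTable-class] with 227 variants.
#' @export
consequenceDemoTable <- function() {
  strains <- c("BomTac", "MrkTac", "ShiJcl", "ShiLtDvs", "ShiLt")
  nSnp <- 172L; nIndel <- 55L
  nSnpCoding <- 64L; nIndelCoding <- 2L
  n <- nSnp + nIndel
  cls <- rep(c("SNP", "indel"), c(nSnp, nIndel))
  coding <- c(rep(c(TRUE, FALSE), c(nSnpCoding, nSnp - nSnpCoding)),
              rep(c(TRUE, FALSE), c(nIndelCoding, nIndel - nIndelCoding)))
  consequence <- character(n)
  cyc <- function(set, k) set[(seq_len(k) - 1L) %% length(set) + 1L]
  consequence[cls == "SNP" & coding] <- cyc(CODING_CONSEQUENCES, nSnpCoding)
  consequence[cls == "SNP" & !coding] <-
    cyc(NONCODING_CONSEQUENCES, nSnp - nSnpCoding)
  consequence[cls == "indel" & coding] <-
    cyc(CODING_INDEL_CONSEQUENCES, nIndelCoding)
  consequence[cls == "indel" & !coding] <-
    cyc(NONCODING_CONSEQUENCES, nIndel - nIndelCoding)
  ref <- rep(c("A", "C", "G", "T"), length.out = n)
  alt <- rep(c("G", "T", "A", "C"), length.out = n)
  alt[cls == "indel"] <- paste0(ref[cls == "indel"], "A")
  calls <- matrix(0L, n, length(strains),
                  dimnames = list(NULL, strains))
  # cycle variants through single-substrain and two-substrain patterns
  for (i in seq_len(n)) {
    j <- (i - 1L) %% length(strains) + 1L
    calls[i, j] <- 1L
    if (i %% 3L == 0L) calls[i, (j %% length(strains)) + 1L] <- 1L
  }
  variants <- data.frame(chrom = rep("chr1", n), pos = seq_len(n) * 1000,
                         ref = ref, alt = alt, class = cls,
                         consequence = consequence, coding = coding)
  new("GenotypeTable", variants = variants, calls = calls)
}
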