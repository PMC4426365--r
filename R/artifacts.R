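# pooled-capture artifact rates: sequencing error vs "jumping PCR"

#' Select loci covered deeply in every substrain
#'
#' A locus is kept iff every substrain's total read count at that locus
#' is at least `minDepth` (default 100, the conventional cutoff for
#' read-level artifact-rate estimation).
#'
#' @param p a [PileupCounts-class].
#' @param minDepth minimum per-substrain depth (>= 1).
#' @return data.frame with columns `chrom`, `pos` of the kept loci.
#' @export
selectHighCoverage <- function(p, minDepth = 100) {
  stopifnot(is(p, "PileupCounts"))
  if (minDepth < 1) sdStop("minDepth must be >= 1", "parameterError")
  ct <- pileupData(p)
  tot <- rowSums(ct[, BASES])
  agg <- stats::aggregate(tot, by = list(chrom = ct$chrom, pos = ct$pos), min)
  keep <- agg[agg$x >= minDepth, c("chrom", "pos")]
  keep <- keep[order(keep$chrom, keep$pos), , drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' Estimate sequencing-error and jumping-PCR rates from pileups
#'
#' For each selected locus and focal substrain, reads are split into
#' three buckets: the focal substrain's own (major) allele; bases that
#' are the major allele of another substrain in the same capture pool
#' (the template-switching, "jumping PCR" signal); and all remaining
#' bases (sequencing error). A base that is both another in-pool major
#' and a possible miscall is assigned to the jump bucket. Per cell,
#' focal + jump + error frequencies sum to exactly 1.
#'
#' At a locus where every in-pool substrain shares the focal allele the
#' jump bucket is undefined; such cells are excluded from the jump
#' summaries but still contribute to the error summaries. The
#' `errorRate` column rescales the error-bucket frequency to a per-base
#' miscall rate (3 alternative bases, of which `nJumpBases` were
#' diverted to the jump bucket), and `jumpCorrected` subtracts the
#' expected miscall contribution from the jump bucket
#' (`jumpFreq - errorFreq/3`).
#'
#' @param p a [PileupCounts-class].
#' @param loci data.frame with `chrom`, `pos` (e.g. from
#'   [selectHighCoverage()]).
#' @param truth a [GenotypeTable-class] giving every substrain's major
#'   allele at each locus.
#' @return Object of class `artifactRates`: list with `cells` (one row
#'   per locus x substrain) and `summary` (min/max/mean of jump and
#'   error frequencies, and `nLociUsed`).
#' @export
estimateArtifactRates <- function(p, loci, truth) {
  stopifnot(is(p, "PileupCounts"), is(truth, "GenotypeTable"))
  ct <- pileupData(p)
  pools <- poolAssignments(p)
  members <- unlist(pools, use.names = FALSE)
  poolOf <- setNames(rep(names(pools), lengths(pools)), members)
  v <- variantInfo(truth)
  calls <- callsMatrix(truth)
  strains <- colnames(calls)
  vKey <- paste(v$chrom, v$pos)

  rows <- list()
  for (r in seq_len(nrow(loci))) {
    key <- paste(loci$chrom[r], loci$pos[r])
    vi <- match(key, vKey)
    if (is.na(vi))
      sdStop(sprintf("locus %s:%s absent from the genotype table",
                     loci$chrom[r], loci$pos[r]), "inputError")
    alleles <- setNames(ifelse(calls[vi, strains] == 1L, v$alt[vi], v$ref[vi]),
                        strains)
    sub <- ct[ct$chrom == loci$chrom[r] & ct$pos == loci$pos[r], , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      s <- sub$substrain[i]
      if (!s %in% strains) next
      own <- alleles[[s]]
      mates <- setdiff(members[poolOf[members] == poolOf[[s]]], s)
      mates <- intersect(mates, strains)
      jumpBases <- setdiff(unique(alleles[mates]), own)
      cnt <- as.numeric(sub[i, BASES])
      names(cnt) <- BASES
      total <- sum(cnt)
      if (total == 0) next
      focalCount <- cnt[[own]]
      jumpCount <- if (length(jumpBases)) sum(cnt[jumpBases]) else 0
      errorCount <- total - focalCount - jumpCount
      focalFreq <- focalCount / total
      jumpFreq <- jumpCount / total
      errorFreq <- errorCount / total
      nJump <- length(jumpBases)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = loci$chrom[r], pos = loci$pos[r], substrain = s,
        depth = total, focalCount = focalCount, jumpCount = jumpCount,
        errorCount = errorCount,
        focalFreq = focalFreq, jumpFreq = jumpFreq,
        errorFreq = errorFreq, nJumpBases = nJump,
        jumpDefined = nJump > 0L,
        errorRate = errorFreq * 3 / (3 - nJump),
        jumpCorrected = if (nJump > 0L) jumpFreq - errorFreq / 3 else NA_real_)
    }
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  jd <- cells[cells$jumpDefined, , drop = FALSE]
  summ <- list(
    jump = list(min = if (nrow(jd)) min(jd$jumpFreq) else NA_real_,
                max = if (nrow(jd)) max(jd$jumpFreq) else NA_real_,
                mean = if (nrow(jd)) mean(jd$jumpFreq) else NA_real_,
                nCells = nrow(jd)),
    error = list(min = min(cells$errorFreq), max = max(cells$errorFreq),
                 mean = mean(cells$errorFreq), nCells = nrow(cells)),
    errorRateMean = mean(cells$errorRate),
    nLociUsed = nrow(unique(cells[, c("chrom", "pos")])))
  structure(list(cells = cells, summary = summ), class = "artifactRates")
}

#' @export
print.artifactRates <- function(x, ...) {
  s <- x$summary
  cat("Pooled-capture artifact rates over", s$nLociUsed, "loci\n")
  if (!is.na(s$jump$mean))
    cat(sprintf("  jumping PCR:      %.2g%% - %.2g%% (mean %.2g%%) over %d cells\n",
                100 * s$jump$min, 100 * s$jump$max, 100 * s$jump$mean,
                s$jump$nCells))
  cat(sprintf("  sequencing error: %.2g%% - %.2g%% (mean %.2g%%) over %d cells\n",
              100 * s$error$min, 100 * s$error$max, 100 * s$error$mean,
              s$error$nCells))
  invisible(x)
}

#' Read or write PileupCounts as TSV
#'
#' Columns: chrom, pos, substrain, count_A, count_C, count_G, count_T.
#' Pool membership is stored in a sibling JSON file when writing and can
#' be supplied on read.
#'
#' @param p a [PileupCounts-class].
#' @param path TSV file path.
#' @param pools named list of capture pools (read path).
#' @return `readPileupTsv` returns a [PileupCounts-class];
#'   `writePileupTsv` returns `path` invisibly.
#' @export
writePileupTsv <- function(p, path) {
  stopifnot(is(p, "PileupCounts"))
  ct <- pileupData(p)
  names(ct)[match(BASES, names(ct))] <- paste0("count_", BASES)
  write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(poolAssignments(p), paste0(path, ".pools.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname writePileupTsv
#' @export
readPileupTsv <- function(path, pools = NULL) {
  ct <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  names(ct) <- sub("^count_", "", names(ct))
  ct$pos <- as.numeric(ct$pos)
  if (is.null(pools)) {
    pj <- paste0(path, ".pools.json")
    if (!file.exists(pj))
      sdStop("no pool membership: supply 'pools' or a .pools.json sibling",
             "inputError")
    pools <- lapply(jsonlite::read_json(pj, simplifyVector = TRUE), as.character)
  }
  new("PileupCounts", counts = ct, pools = pools)
}

#' Write artifact-rate estimates as JSON
#'
#' @param x an `artifactRates` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeArtifactJson <- function(x, path) {
  stopifnot(inherits(x, "artifactRates"))
  jsonlite::write_json(list(summary = x$summary, cells = x$cells), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
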