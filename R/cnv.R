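# deletion calling from ordered probe intensities

#' Center raw probe tracks by the per-probe median
#'
#' Each cell becomes raw intensity minus the median across substrains at
#' that probe, so copy-neutral cells center near zero while a deletion
#' private to a minority of substrains stands out. A shift shared by a
#' majority of substrains is absorbed into the median and masked; probes
#' where the across-substrain median strays far from the track baseline
#' trigger a warning to that effect.
#'
#' @param raw an [IntensityTrack-class] (or probes data.frame plus
#'   matrix) of raw intensities for at least 3 substrains.
#' @return An [IntensityTrack-class] of centered intensities.
#' @export
scaleIntensities <- function(raw) {
  stopifnot(is(raw, "IntensityTrack"))
  m <- intensityValues(raw)
  if (ncol(m) < 3L)
    sdStop("per-probe median centering needs at least 3 substrains",
           "inputError")
  med <- apply(m, 1L, median)
  centered <- m - med
  # a step change in the median series means most substrains shift
  # together across those probes; centering absorbs such shared shifts
  if (length(med) > 2L) {
    d <- diff(med)
    dev <- abs(d - median(d))
    if (any(dev > max(8 * mad(d), 1e-6)))
      warning("per-probe median steps sharply within the track: ",
              "copy-number changes shared by most substrains are masked ",
              "by median centering")
  }
  new("IntensityTrack", probes = probeInfo(raw), intensities = centered)
}

#' Call deletions as runs of depressed probe intensity
#'
#' Per substrain and chromosome, maximal runs of at least `minRun`
#' consecutive probes with intensity below `threshold` become deletion
#' calls. Calls with identical probe spans in different substrains are
#' merged into one call carrying the substrain set. Reported positions
#' are those of the first and last probe in the run: the true breakpoints
#' bracket, but are not equal to, the probe span. With `gains = TRUE` a
#' mirrored scan above `-threshold` reports duplications as well.
#'
#' @param track an [IntensityTrack-class] of centered intensities.
#' @param threshold call threshold, negative (default -0.5).
#' @param minRun minimum probes per call (default 3).
#' @param gains also scan for mirrored positive runs.
#' @return data.frame with one row per call: `chrom`, `startIndex`,
#'   `endIndex`, `startPos`, `endPos`, `substrains` (comma-separated),
#'   `nProbes`, `meanShift`, `type`.
#' @export
#' @examples
#' tr <- simulateIntensities(1:40 * 1000, c("A", "B", "C", "D", "E"),
#'   deletions = list(list(substrains = "B", from = 10, to = 22, shift = -2)),
#'   noiseSd = 0.1, seed = 1)
#' callDeletions(tr)
callDeletions <- function(track, threshold = -0.5, minRun = 3L,
                          gains = FALSE) {
  stopifnot(is(track, "IntensityTrack"))
  if (threshold >= 0) sdStop("threshold must be negative", "parameterError")
  if (minRun < 2) sdStop("minRun must be >= 2", "parameterError")
  probes <- probeInfo(track)
  m <- intensityValues(track)
  scan <- function(flag, type) {
    rows <- list()
    for (s in colnames(m)) {
      for (ch in unique(probes$chrom)) {
        idx <- which(probes$chrom == ch)
        r <- rle(flag[idx, s])
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (k in which(r$values & r$lengths >= minRun)) {
          ii <- idx[starts[k]:ends[k]]
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = ch, startIndex = ii[1L], endIndex = ii[length(ii)],
            startPos = probes$pos[ii[1L]], endPos = probes$pos[ii[length(ii)]],
            substrain = s, nProbes = length(ii),
            meanShift = mean(m[ii, s]), type = type)
        }
      }
    }
    rows
  }
  rows <- scan(m < threshold, "deletion")
  if (gains) rows <- c(rows, scan(m > -threshold, "gain"))
  if (!length(rows)) {
    return(data.frame(chrom = character(0), startIndex = integer(0),
                      endIndex = integer(0), startPos = numeric(0),
                      endPos = numeric(0), substrains = character(0),
                      nProbes = integer(0), meanShift = numeric(0),
                      type = character(0)))
  }
  calls <- do.call(rbind, rows)
  # merge identical spans across substrains
  key <- paste(calls$chrom, calls$startIndex, calls$endIndex, calls$type)
  merged <- lapply(split(calls, key), function(g) {
    g <- g[order(g$substrain), , drop = FALSE]
    data.frame(chrom = g$chrom[1L], startIndex = g$startIndex[1L],
               endIndex = g$endIndex[1L], startPos = g$startPos[1L],
               endPos = g$endPos[1L],
               substrains = paste(g$substrain, collapse = ","),
               nProbes = g$nProbes[1L], meanShift = mean(g$meanShift),
               type = g$type[1L])
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$chrom, out$startIndex, out$substrains), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write CNV calls as BED plus a JSON report
#'
#' BED intervals are 0-based half-open, converted from the 1-based
#' inclusive probe positions of the calls; the name field carries the
#' substrain set and the score the mean intensity shift.
#'
#' @param calls data.frame from [callDeletions()].
#' @param path output BED path; a `.json` sibling carries the full call
#'   records.
#' @return `path`, invisibly.
#' @export
writeCnvBed <- function(calls, path) {
  bed <- data.frame(chrom = calls$chrom,
                    start = format(calls$startPos - 1, scientific = FALSE,
                                   trim = TRUE),
                    end = format(calls$endPos, scientific = FALSE, trim = TRUE),
                    name = paste0(calls$type, ":", calls$substrains),
                    score = sprintf("%.4f", calls$meanShift),
                    strand = ".")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  jsonlite::write_json(calls, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read or write an IntensityTrack as TSV
#'
#' Columns: chrom, pos, then one intensity column per substrain.
#'
#' @param track an [IntensityTrack-class].
#' @param path file path.
#' @return `readIntensityTsv` returns an [IntensityTrack-class];
#'   `writeIntensityTsv` returns `path` invisibly.
#' @export
writeIntensityTsv <- function(track, path) {
  stopifnot(is(track, "IntensityTrack"))
  df <- cbind(probeInfo(track), as.data.frame(intensityValues(track)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeIntensityTsv
#' @export
readIntensityTsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("chrom", "pos")), drop = FALSE])
  new("IntensityTrack", probes = df[, c("chrom", "pos")], intensities = m)
}
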