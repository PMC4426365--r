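# fixation-rate estimation from pairwise coding distances

#' Per-pair fixation-rate range from a distance matrix and schedule
#'
#' For every substrain pair, the number of fixed differences divided by
#' the elapsed separation time. By default the divisor is twice the years
#' since the pair's split, because both lineages accumulate mutations
#' independently; set `singleLineage = TRUE` to divide by elapsed years
#' once (the convention that treats the pairwise count as a single rate
#' per calendar year of separation).
#'
#' @param distances a [DistanceMatrix-class] (typically the coding class).
#' @param schedule a [SeparationSchedule-class] covering the same
#'   substrains; its sampling year must postdate every split.
#' @param singleLineage logical; divide by 1x instead of 2x elapsed years.
#' @return Object of class `rateEstimate`: list with `perYearMin`,
#'   `perYearMax`, `perGenerationMin`, `perGenerationMax`, `pairsUsed`
#'   (data.frame of per-pair distances, years and rates) and
#'   `generationsPerYear`. Values are unrounded; rounding to 2 decimals
#'   (half-up) is applied only when printing.
#' @export
fixationRate <- function(distances, schedule, singleLineage = FALSE) {
  stopifnot(is(distances, "DistanceMatrix"), is(schedule, "SeparationSchedule"))
  labs <- substrainNames(distances)
  if (!all(labs %in% substrainNames(schedule)))
    sdStop("schedule does not cover all substrains in the distance matrix",
           "inputError")
  yrs <- separationYears(schedule)[labs, labs]
  if (any(yrs[upper.tri(yrs)] <= 0))
    sdStop("zero or negative separation time for some pair", "inputError")
  vals <- distanceValues(distances)
  pairs <- combn(sort(labs), 2L)
  divisor <- if (singleLineage) 1 else 2
  df <- data.frame(a = pairs[1L, ], b = pairs[2L, ],
                   distance = vals[cbind(pairs[1L, ], pairs[2L, ])],
                   years = yrs[cbind(pairs[1L, ], pairs[2L, ])])
  df$perYear <- df$distance / (divisor * df$years)
  gpy <- generationsPerYear(schedule)
  structure(list(perYearMin = min(df$perYear), perYearMax = max(df$perYear),
                 perGenerationMin = min(df$perYear) / gpy,
                 perGenerationMax = max(df$perYear) / gpy,
                 pairsUsed = df, generationsPerYear = gpy),
            class = "rateEstimate")
}

#' Convert a per-year fixation-rate range to per-generation
#'
#' Divides the endpoints of a per-year rate range by the number of
#' generations per year and reports both scales rounded half-up to two
#' decimals, the conventional reporting precision for such ranges.
#'
#' @param perYearMin,perYearMax endpoints of the per-year range.
#' @param generationsPerYear generations per calendar year (default 4).
#' @return Object of class `rateEstimate` (see [fixationRate()]) without
#'   per-pair detail.
#' @export
#' @examples
#' r <- rateRange(0.74, 1.22)
#' print(r)  # per generation: 0.19 - 0.31
rateRange <- function(perYearMin, perYearMax, generationsPerYear = 4) {
  if (perYearMin > perYearMax) sdStop("min exceeds max", "parameterError")
  if (generationsPerYear <= 0)
    sdStop("generationsPerYear must be positive", "parameterError")
  structure(list(perYearMin = perYearMin, perYearMax = perYearMax,
                 perGenerationMin = perYearMin / generationsPerYear,
                 perGenerationMax = perYearMax / generationsPerYear,
                 pairsUsed = NULL, generationsPerYear = generationsPerYear),
            class = "rateEstimate")
}

#' @export
print.rateEstimate <- function(x, ...) {
  cat(sprintf("fixed differences per year of separation: %.2f - %.2f\n",
              roundHalfUp(x$perYearMin, 2), roundHalfUp(x$perYearMax, 2)))
  cat(sprintf("per generation (%g generations/year):     %.2f - %.2f\n",
              x$generationsPerYear,
              roundHalfUp(x$perGenerationMin, 2),
              roundHalfUp(x$perGenerationMax, 2)))
  if (!is.null(x$pairsUsed))
    cat("  based on", nrow(x$pairsUsed), "substrain pairs\n")
  invisible(x)
}
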