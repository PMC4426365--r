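# dated substrain genealogies

# depth in years of every node below the root (root = 0); works for
# multifurcating trees
nodeDepths <- function(tree) {
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  depth <- rep(NA_real_, nNode)
  root <- nTip + 1L
  depth[root] <- 0
  # edges in preorder: repeatedly sweep until all assigned (trees are small)
  edge <- tree$edge
  repeat {
    todo <- is.na(depth[edge[, 2L]]) & !is.na(depth[edge[, 1L]])
    if (!any(todo)) break
    depth[edge[todo, 2L]] <- depth[edge[todo, 1L]] + tree$edge.length[todo]
  }
  depth
}

#' Construct a dated substrain genealogy
#'
#' @param tree an [ape::phylo] tree whose edge lengths are in calendar
#'   years; may be multifurcating. All tips must be equidistant from the
#'   root (every substrain is sampled in the same year).
#' @param rootYear calendar year of the first split.
#' @param samplingYear calendar year the substrains were sampled. Defaults
#'   to `rootYear` plus the root-to-tip span of `tree`.
#' @param generationsPerYear breeding generations per calendar year;
#'   mouse colonies are conventionally bred at four generations per year.
#' @return A [SeparationSchedule-class] object.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:10,B:10):5,C:15);")
#' SeparationSchedule(tr, rootYear = 1999)
SeparationSchedule <- function(tree, rootYear, samplingYear = NULL,
                               generationsPerYear = 4) {
  if (!inherits(tree, "phylo")) sdStop("'tree' must be a phylo object", "inputError")
  if (is.null(tree$edge.length))
    sdStop("schedule tree must carry edge lengths in years", "inputError")
  if (length(tree$tip.label) < 2L)
    sdStop("a separation schedule needs at least 2 substrains", "inputError")
  if (is.null(samplingYear)) {
    d <- nodeDepths(tree)
    samplingYear <- rootYear + max(d[seq_along(tree$tip.label)])
  }
  new("SeparationSchedule", tree = tree, rootYear = rootYear,
      samplingYear = samplingYear, generationsPerYear = generationsPerYear)
}

#' Read a dated genealogy from a newick string or file
#'
#' @param newick a newick string (edge lengths in years) or path to a file
#'   containing one.
#' @inheritParams SeparationSchedule
#' @return A [SeparationSchedule-class] object.
#' @export
scheduleFromNewick <- function(newick, rootYear, samplingYear = NULL,
                               generationsPerYear = 4) {
  tr <- if (file.exists(newick)) ape::read.tree(file = newick)
        else ape::read.tree(text = newick)
  if (is.null(tr)) sdStop("could not parse newick genealogy", "parseError")
  SeparationSchedule(tr, rootYear, samplingYear, generationsPerYear)
}

#' Read or write a SeparationSchedule as JSON
#'
#' The JSON document stores the newick genealogy together with its root
#' year, sampling year and generations/year, so a full schedule
#' round-trips through one small config file.
#'
#' @param path file path.
#' @param schedule a [SeparationSchedule-class] object.
#' @return `readScheduleJson` returns a [SeparationSchedule-class];
#'   `writeScheduleJson` returns `path` invisibly.
#' @export
readScheduleJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("newick", "root_year", "sampling_year", "generations_per_year")
  if (!all(need %in% names(x)))
    sdStop(paste("schedule JSON must contain:", paste(need, collapse = ", ")),
           "parseError")
  scheduleFromNewick(x$newick, x$root_year, x$sampling_year,
                     x$generations_per_year)
}

#' @rdname readScheduleJson
#' @export
writeScheduleJson <- function(schedule, path) {
  stopifnot(is(schedule, "SeparationSchedule"))
  jsonlite::write_json(
    list(newick = ape::write.tree(schedule@tree),
         root_year = schedule@rootYear,
         sampling_year = schedule@samplingYear,
         generations_per_year = schedule@generationsPerYear),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Default NOD substrain separation schedule
#'
#' Encodes the separation history of the five NOD substrains as far as it
#' is documented: the BomTac progenitors and the Lt lineage left the
#' Japanese source colony in 1984, the MrkTac progenitors around 1985
#' (exact year undocumented; mid-1980s transfer via UCLA/Merck), ShiJcl
#' continues the source colony, and ShiLtDvs was separated from ShiLt in
#' 1992. Substrains are sampled in 2014 and bred at four generations per
#' year. All values can be overridden by supplying your own schedule via
#' [SeparationSchedule()], [scheduleFromNewick()] or [readScheduleJson()].
#'
#' @param generationsPerYear generations per calendar year (default 4).
#' @return A [SeparationSchedule-class] for substrains BomTac, MrkTac,
#'   ShiJcl, ShiLtDvs, ShiLt.
#' @export
#' @examples
#' separationYears(nodSchedule())
nodSchedule <- function(generationsPerYear = 4) {
  nwk <- "((ShiLt:22,ShiLtDvs:22):8,(MrkTac:29,ShiJcl:29):1,BomTac:30);"
  scheduleFromNewick(nwk, rootYear = 1984, samplingYear = 2014,
                     generationsPerYear = generationsPerYear)
}

#' Pairwise years since separation
#'
#' Years elapsed since each pair of substrains last shared a colony,
#' i.e. sampling year minus the date of their most recent common ancestor.
#'
#' @param schedule a [SeparationSchedule-class].
#' @return Symmetric numeric matrix of years, zero diagonal.
#' @export
separationYears <- function(schedule) {
  stopifnot(is(schedule, "SeparationSchedule"))
  tr <- schedule@tree
  tips <- tr$tip.label
  n <- length(tips)
  d <- nodeDepths(tr)
  span <- schedule@samplingYear - schedule@rootYear
  out <- matrix(0, n, n, dimnames = list(tips, tips))
  if (n >= 2) {
    mrca <- ape::mrca(tr)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      yrs <- span - d[mrca[i, j]]
      out[i, j] <- out[j, i] <- yrs
    }
  }
  out
}

# edge lengths of the schedule tree in generations
branchGenerations <- function(schedule) {
  schedule@tree$edge.length * schedule@generationsPerYear
}
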