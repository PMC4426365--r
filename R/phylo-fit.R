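# maximum-likelihood tree fitting (free and clock) and the clock LRT

hammingMatrix <- function(aln) {
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- mean(aln[i, ] != aln[j, ])
  d
}

# internal: pruner-ready pieces for one alignment
alignmentContext <- function(aln) {
  pat <- alignmentPatterns(aln)
  list(labels = rownames(aln), states = pat$states, weights = pat$weights,
       nTip = nrow(aln))
}

ctxStates <- function(ctx, tree) {
  # rows of the pattern matrix in the tree's tip numbering
  idx <- match(tree$tip.label, ctx$labels)
  if (length(idx) != ctx$nTip || anyNA(idx))
    sdStop("tree tips do not match the alignment labels", "inputError")
  ctx$states[idx, , drop = FALSE]
}

optimBlTree <- function(ctx, tree, eig, bl0 = NULL, tol = 1e-8,
                        maxCycles = 60L, brentTol = 1e-7) {
  tr <- ape::reorder.phylo(tree, "postorder")
  if (is.null(bl0)) bl0 <- if (!is.null(tr$edge.length)) pmax(tr$edge.length, 1e-4)
                           else rep(0.05, nrow(tr$edge))
  fit <- cppOptimBl(tr$edge, ctx$nTip, bl0, ctxStates(ctx, tr), ctx$weights,
                    eig$A, eig$Ainv, eig$lam, eig$pi, tol, maxCycles, brentTol)
  tr$edge.length <- fit$bl
  list(tree = tr, lnl = fit$lnl)
}

clockLayout <- function(tree) {
  # preorder internal nodes and parent pointers for height parameterization
  tr <- ape::reorder.phylo(tree, "postorder")
  nTip <- length(tr$tip.label)
  nNode <- max(tr$edge)
  parentOf <- integer(nNode)
  parentOf[tr$edge[, 2L]] <- tr$edge[, 1L]
  root <- nTip + 1L
  depth <- integer(nNode); depth[root] <- 0L
  for (e in rev(seq_len(nrow(tr$edge))))   # reverse postorder = preorder
    depth[tr$edge[e, 2L]] <- depth[tr$edge[e, 1L]] + 1L
  internal <- (nTip + 1L):nNode
  preorderInt <- internal[order(depth[internal], internal)]
  list(tree = tr, preorderInt = preorderInt, parentOf = parentOf)
}

optimClockTree <- function(ctx, tree, eig, par0 = NULL, tol = 1e-8,
                           maxCycles = 200L, brentTol = 1e-7) {
  lay <- clockLayout(tree)
  nInt <- length(lay$preorderInt)
  if (is.null(par0)) par0 <- c(0.1, rep(0.7, nInt - 1L))
  fit <- cppOptimClock(lay$tree$edge, ctx$nTip, lay$preorderInt,
                       lay$parentOf, par0, ctxStates(ctx, lay$tree),
                       ctx$weights, eig$A, eig$Ainv, eig$lam, eig$pi,
                       tol, maxCycles, brentTol)
  tr <- lay$tree
  tr$edge.length <- fit$bl
  list(tree = tr, lnl = fit$lnl, par = fit$par)
}

# profile-estimate exchangeabilities (last fixed at 1) on one topology
estimateExchangeabilities <- function(ctx, tree, freqs, init = rep(1, 5)) {
  bl <- NULL
  obj <- function(logr) {
    eig <- gtrEigen(gtrParams(freqs, c(exp(logr), 1)))
    fit <- optimBlTree(ctx, tree, eig, bl0 = bl, tol = 1e-4,
                       maxCycles = 5L, brentTol = 1e-3)
    bl <<- fit$tree$edge.length
    -fit$lnl
  }
  opt <- optim(log(init), obj, method = "Nelder-Mead",
               control = list(maxit = 150, reltol = 1e-7))
  c(exp(opt$par), 1)
}

#' Maximum-likelihood phylogeny under GTR
#'
#' Enumerates every topology for the alignment's taxa (unrooted for the
#' free model, rooted for the clock model), optimizes branch lengths
#' (free) or node heights (clock; heights are nested so the tree stays
#' ultrametric) on each, and returns the highest-likelihood fit.
#' Exhaustive enumeration keeps the search deterministic and is feasible
#' for the small substrain panels this package targets; fits are refused
#' beyond 8 taxa.
#'
#' Base frequencies default to the empirical alignment frequencies;
#' exchangeabilities are profile-estimated once on a neighbor-joining
#' starting topology and held fixed during topology enumeration, with the
#' winning topology then re-optimized. Supplying `params` skips all model
#' estimation.
#'
#' @param aln character matrix, taxa x sites (see
#'   [genotypeToAlignment()]), 3 to 8 taxa.
#' @param constraint `"free"` (unrooted, 2n-3 branch lengths) or
#'   `"clock"` (rooted ultrametric, n-1 node heights).
#' @param params optional [gtrParams()]; when NULL the model is estimated
#'   from the data.
#' @param tol convergence tolerance in log-likelihood units.
#' @return List with `tree` (an [ape::phylo]; ultrametric if clock),
#'   `params`, `lnL`, `constraint` and `nTopologies`.
#' @export
mlFit <- function(aln, constraint = c("free", "clock"), params = NULL,
                  tol = 1e-8) {
  constraint <- match.arg(constraint)
  nTip <- nrow(aln)
  if (nTip < 3L) sdStop("ML fitting needs at least 3 taxa", "inputError")
  if (nTip > 8L)
    sdStop("refusing ML fit for more than 8 taxa (exhaustive topology enumeration)",
           "inputError")
  ctx <- alignmentContext(aln)
  if (is.null(params)) {
    freqs <- baseFrequencies(aln)
    start <- njTree(hammingMatrix(aln))
    rates <- estimateExchangeabilities(ctx, start, freqs)
    params <- gtrParams(freqs, rates)
  }
  eig <- gtrEigen(params)
  topos <- phangorn::allTrees(nTip, rooted = constraint == "clock",
                              tip.label = rownames(aln))
  # materialize: multiPhylo stores tip labels centrally, plain iteration
  # would yield label-less trees
  topos <- lapply(seq_along(topos), function(k) topos[[k]])
  if (constraint == "free") {
    best <- NULL
    for (tp in topos) {
      fit <- optimBlTree(ctx, tp, eig, bl0 = rep(0.05, nrow(tp$edge)),
                         tol = tol, maxCycles = 100L)
      if (is.null(best) || fit$lnl > best$lnl) best <- fit
    }
  } else {
    # loose screening pass over all rooted topologies, then refine leaders
    loose <- lapply(topos, function(tp)
      optimClockTree(ctx, tp, eig, tol = 1e-3, maxCycles = 8L,
                     brentTol = 1e-3))
    lnls <- vapply(loose, `[[`, 0, "lnl")
    keep <- order(lnls, decreasing = TRUE)
    keep <- keep[lnls[keep] >= max(lnls) - 3 | seq_along(keep) <= 5L]
    best <- NULL
    for (k in keep) {
      fit <- optimClockTree(ctx, topos[[k]], eig, par0 = loose[[k]]$par,
                            tol = tol, maxCycles = 300L)
      if (is.null(best) || fit$lnl > best$lnl) best <- fit
    }
  }
  list(tree = best$tree, params = params, lnL = best$lnl,
       constraint = constraint, nTopologies = length(topos))
}

#' Likelihood-ratio test of the molecular clock
#'
#' Fits the free and clock-constrained GTR maximum-likelihood trees on
#' the same alignment (sharing the estimated substitution model, so the
#' clock model is nested in the free model) and compares them:
#' statistic = 2(lnL_free - lnL_clock), with n - 2 degrees of freedom
#' (2n-3 branch lengths versus n-1 node heights), referred to the
#' chi-squared upper tail.
#'
#' @inheritParams mlFit
#' @return Object of class `clockLRT`: list with `lnLFree`, `lnLClock`,
#'   `statistic`, `df`, `pValue`, `freeFit`, `clockFit`.
#' @export
clockLRT <- function(aln, params = NULL, tol = 1e-8) {
  nTip <- nrow(aln)
  if (is.null(params)) {
    ctx <- alignmentContext(aln)
    freqs <- baseFrequencies(aln)
    start <- njTree(hammingMatrix(aln))
    rates <- estimateExchangeabilities(ctx, start, freqs)
    params <- gtrParams(freqs, rates)
  }
  free <- mlFit(aln, "free", params = params, tol = tol)
  clock <- mlFit(aln, "clock", params = params, tol = tol)
  if (free$lnL < clock$lnL) {
    # optimizer safeguard: the clock tree is a valid free tree, so restart
    # the free optimization from the clock solution
    ctx <- alignmentContext(aln)
    eig <- gtrEigen(params)
    unrooted <- ape::unroot(clock$tree)
    refit <- optimBlTree(ctx, unrooted, eig, tol = tol, maxCycles = 200L)
    if (refit$lnl > free$lnL) {
      free$tree <- refit$tree
      free$lnL <- refit$lnl
    }
  }
  stat <- 2 * (free$lnL - clock$lnL)
  if (stat < -1e-6)
    sdStop("optimizer failure: clock likelihood exceeds free likelihood",
           "optimError")
  stat <- max(stat, 0)
  df <- nTip - 2L
  structure(list(lnLFree = free$lnL, lnLClock = clock$lnL, statistic = stat,
                 df = df, pValue = pchisq(stat, df, lower.tail = FALSE),
                 freeFit = free, clockFit = clock),
            class = "clockLRT")
}

#' @export
print.clockLRT <- function(x, ...) {
  cat("Molecular-clock likelihood-ratio test\n")
  cat(sprintf("  lnL free:  %.4f\n  lnL clock: %.4f\n", x$lnLFree, x$lnLClock))
  cat(sprintf("  2*dlnL = %.4f on %d df, P = %.4g\n", x$statistic, x$df,
              x$pValue))
  invisible(x)
}
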