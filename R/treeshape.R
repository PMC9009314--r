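#' Decompose a rooted binary tree into splits
#'
#' For every internal node of a rooted binary tree, records the pair (n, i):
#' the number of tips in the node's subtree and the number of tips in one
#' child, using a canonical child ordering (the child containing the
#' lexicographically smallest tip label is taken first). The beta-splitting
#' likelihood is symmetric in i and n - i, so the ordering does not affect
#' estimation.
#'
#' @param tree a rooted binary \code{phylo} object.
#' @return A data.frame with integer columns \code{n} (tips in the subtree,
#'   >= 2) and \code{i} (tips in the canonical first child, in 1..n-1), one
#'   row per internal node.
#' @examples
#' extractSplits(readNewick("((A,B),(C,D));"))
#' @export
extractSplits <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  nt <- length(tree$tip.label)
  if (!ape::is.rooted(tree) || !ape::is.binary.phylo(tree))
    stop("unsupported topology: tree contains polytomies; ",
         "resolve them (e.g. ape::multi2di) before estimating beta",
         call. = FALSE)
  nn <- tree$Nnode
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  # tips and smallest tip label per subtree, by postorder accumulation
  ntips <- c(rep(1L, nt), integer(nn))
  minlab <- c(tree$tip.label, character(nn))
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(ord))) {
    p <- ord[k, 1L]; ch <- ord[k, 2L]
    ntips[p] <- ntips[p] + ntips[ch]
    if (minlab[p] == "" || minlab[ch] < minlab[p]) minlab[p] <- minlab[ch]
  }
  internal <- as.integer(names(children))
  n <- ntips[internal]
  i <- vapply(seq_along(internal), function(k) {
    ch <- children[[k]]
    first <- ch[order(minlab[ch])][1L]
    ntips[first]
  }, integer(1L))
  data.frame(n = as.integer(n), i = as.integer(i))
}

#' Log-likelihood of splits under the beta-splitting model
#'
#' Aldous' beta-splitting model assigns a subtree of n tips the probability
#' q_n(i; beta) = w_n(i; beta) / sum_j w_n(j; beta) of splitting into child
#' subtrees of i and n - i tips, with
#' w_n(i; beta) = Gamma(beta+1+i) Gamma(beta+1+n-i) /
#' (Gamma(i+1) Gamma(n-i+1)). The tree log-likelihood is the sum of
#' log q_n(i) over internal nodes, computed in log space via
#' \code{lgamma}. beta = 0 recovers the Yule model, beta = -1.5 the PDA
#' model, and beta -> -2 maximal imbalance.
#'
#' @param splits data.frame as returned by \code{\link{extractSplits}}.
#' @param beta numeric scalar, must exceed -2.
#' @return The log-likelihood (a finite number <= 0); splits with n = 2
#'   contribute zero.
#' @examples
#' betaLogLik(data.frame(n = 4L, i = 2L), 0)  # log(1/3): Yule is uniform
#' @export
betaLogLik <- function(splits, beta) {
  stopifnot(is.numeric(beta), length(beta) == 1L)
  if (beta <= -2) stop("domain error: beta must be > -2", call. = FALSE)
  if (!nrow(splits)) return(0)
  if (any(splits$i < 1L | splits$i > splits$n - 1L))
    stop("invalid split: i must lie in 1..n-1", call. = FALSE)
  logw <- function(n, i)
    lgamma(beta + 1 + i) + lgamma(beta + 1 + n - i) -
      lgamma(i + 1) - lgamma(n - i + 1)
  total <- 0
  for (n in unique(splits$n)) {
    if (n == 2L) next
    j <- seq_len(n - 1L)
    lw <- logw(n, j)
    lz <- max(lw) + log(sum(exp(lw - max(lw))))
    i <- splits$i[splits$n == n]
    total <- total + sum(lw[i] - lz)
  }
  total
}

#' Estimate tree balance via the beta-splitting model
#'
#' Maximum-likelihood estimate of Aldous' beta for a rooted binary cell
#' phylogeny, used to decide which ancestry-annotation strategy fits the
#' tree. Trees with beta below the threshold (default -1.5, the PDA point)
#' are classified \code{"unbalanced"} (ladder-like) and should be annotated
#' with \code{\link{unbalancedAnnotation}}; trees above it are
#' \code{"balanced"} (Yule-like) and suit \code{\link{balancedAnnotation}}.
#'
#' The likelihood is maximized by one-dimensional bounded optimization over
#' \code{bounds} to a tolerance of 1e-4; \code{atBound} is set when the
#' optimum lies within 1e-3 of a bound (perfect caterpillars and perfectly
#' balanced trees push the estimate to the boundary). An estimate exactly at
#' the threshold is classified balanced.
#'
#' @param tree a rooted binary \code{phylo} with at least 4 tips.
#' @param threshold classification threshold on beta (default -1.5).
#' @param bounds numeric length-2 search interval; the model requires
#'   beta > -2 and +10 is effectively the balanced asymptote.
#' @return A \code{\linkS4class{BetaEstimate}}.
#' @examples
#' treeBalance(ape::stree(32, "balanced"))
#' @export
treeBalance <- function(tree, threshold = -1.5, bounds = c(-1.999, 10)) {
  stopifnot(length(bounds) == 2L, bounds[1L] > -2, bounds[1L] < bounds[2L])
  tree <- validateTree(tree)
  if (length(tree$tip.label) < 4L)
    stop("insufficient data: beta estimation needs at least 4 tips",
         call. = FALSE)
  splits <- extractSplits(tree)
  opt <- stats::optimize(function(b) betaLogLik(splits, b),
                         lower = bounds[1L], upper = bounds[2L],
                         maximum = TRUE, tol = 1e-4)
  bhat <- opt$maximum
  # optimize() never returns the exact bounds; snap when the likelihood at
  # the bound is at least as good, so atBound is meaningful
  for (b in bounds) {
    if (abs(bhat - b) < 5e-3 && betaLogLik(splits, b) >= opt$objective) {
      bhat <- b
      opt$objective <- betaLogLik(splits, b)
    }
  }
  new("BetaEstimate",
      betaHat = bhat, logLik = opt$objective,
      shape = if (bhat < threshold) "unbalanced" else "balanced",
      threshold = threshold,
      atBound = min(abs(bhat - bounds)) < 1e-3,
      bounds = as.numeric(bounds),
      nTips = length(tree$tip.label))
}
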