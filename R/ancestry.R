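#' Mean within-clade genetic dissimilarity
#'
#' Genetic dissimilarity of a set of cells on a phylogeny, defined as the
#' mean patristic distance (sum of branch lengths along the tree path) over
#' all unordered pairs of tips. A singleton has dissimilarity zero. Trees
#' without branch lengths are given unit lengths, so the measure degrades to
#' a node-count distance for topology-only trees.
#'
#' @param tree a \code{phylo} object.
#' @param tips character vector of tip labels (cells), a subset of the
#'   tree's tips.
#' @return A non-negative number.
#' @examples
#' tr <- readNewick("((A:1,B:1):1,C:1);")
#' cladeDissimilarity(tr, c("A", "B", "C"))  # mean(2, 3, 3) = 8/3
#' @export
cladeDissimilarity <- function(tree, tips) {
  tree <- validateTree(tree)
  bad <- setdiff(tips, tree$tip.label)
  if (length(bad))
    stop("validation error: unknown tip(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (length(tips) < 2L) return(0)
  D <- stats::cophenetic(tree)[tips, tips]
  mean(D[upper.tri(D)])
}

# enumerate clades: per internal node, its tip-label set; optionally tips
# themselves as singleton clades. Returns list(node=, tips=, size=, diss=).
enumerateClades <- function(tree, includeSingletons = FALSE,
                            includeRoot = FALSE) {
  nt <- length(tree$tip.label)
  D <- stats::cophenetic(tree)
  nodes <- (nt + 1L):(nt + tree$Nnode)
  root <- nt + 1L
  if (!includeRoot) nodes <- setdiff(nodes, root)
  cl <- lapply(nodes, function(nd) {
    tp <- tree$tip.label[descendantTips(tree, nd)]
    list(node = nd, tips = tp, size = length(tp),
         diss = if (length(tp) > 1L)
           mean(D[tp, tp][upper.tri(D[tp, tp])]) else 0)
  })
  if (includeSingletons)
    cl <- c(cl, lapply(seq_len(nt), function(i)
      list(node = i, tips = tree$tip.label[i], size = 1L, diss = 0)))
  cl
}

descendantTips <- function(tree, node) {
  nt <- length(tree$tip.label)
  if (node <= nt) return(node)
  out <- integer(0)
  stack <- node
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    ch <- children[[as.character(nd)]]
    tipch <- ch[ch <= nt]
    out <- c(out, tipch)
    stack <- c(stack, ch[ch > nt])
  }
  out
}

annotationFromClades <- function(tree, cladeTips, normals, allCells,
                                 provenance, unassignedAs = "unassigned") {
  labels <- stats::setNames(rep(unassignedAs, length(allCells)), allCells)
  for (k in seq_along(cladeTips))
    labels[cladeTips[[k]]] <- paste0("ancestry_", k)
  labels[intersect(normals, allCells)] <- "normal"
  AncestryAnnotation(labels, provenance = provenance)
}

#' Partition a balanced phylogeny into genetic ancestries
#'
#' Clade-based ancestry annotation for balanced (Yule-like) cell
#' phylogenies. The first two ancestries are found jointly: over all
#' disjoint pairs of clades whose sizes satisfy the constraints (each clade
#' at least \code{minEachFrac} of the cells, jointly at least
#' \code{minTotalFrac}), the pair with the least summed within-clade genetic
#' dissimilarity is selected. Further ancestries (up to \code{nClades}) are
#' then picked iteratively as the largest clade disjoint from all selected
#' ones, ties broken by least dissimilarity and then by node number. Cells
#' in no selected clade are labelled \code{"unassigned"}; normal cells are
#' excluded from clade candidacy and labelled \code{"normal"}.
#'
#' The default \code{minTotalFrac = 0.75} suits tumors dominated by two
#' major clones. When the phylogeny holds \code{nClades} clades of roughly
#' equal size, two disjoint clades can only cover about 2/\code{nClades} of
#' the cells, so the constraint must be lowered (e.g. to 0.66 for three
#' equal clades) for a feasible, full-clade solution; see the vignette.
#'
#' @param tree a \code{phylo} object.
#' @param nClades desired number of ancestries (default 3).
#' @param minTotalFrac minimum fraction of (non-normal) cells the first two
#'   clades must jointly cover (default 0.75).
#' @param minEachFrac minimum fraction of cells per clade in the first pair
#'   (default 0.1).
#' @param normalCells cell IDs excluded from candidacy and labelled
#'   \code{"normal"}.
#' @param provenance source tag for the annotation.
#' @return An \code{\linkS4class{AncestryAnnotation}} with labels
#'   \code{ancestry_1..ancestry_k} in selection order.
#' @seealso \code{\link{unbalancedAnnotation}}, \code{\link{treeBalance}}
#' @export
balancedAnnotation <- function(tree, nClades = 3, minTotalFrac = 0.75,
                               minEachFrac = 0.1,
                               normalCells = character(),
                               provenance = "balancedAnnotation") {
  tree <- validateTree(tree)
  stopifnot(nClades >= 2, minTotalFrac > 0, minTotalFrac <= 1,
            nClades * minEachFrac <= 1)
  allCells <- tree$tip.label
  work <- tree
  if (length(normalCells))
    work <- ape::drop.tip(tree, intersect(normalCells, tree$tip.label))
  N <- length(work$tip.label)
  if (N < 2 * nClades)
    stop("validation error: need at least 2*nClades non-normal tips",
         call. = FALSE)
  cl <- enumerateClades(work)
  sizes <- vapply(cl, `[[`, integer(1L), "size")
  diss <- vapply(cl, `[[`, numeric(1L), "diss")
  tipsets <- lapply(cl, `[[`, "tips")
  eligible <- sizes >= minEachFrac * N
  # step 1: best disjoint pair under the size constraints
  best <- NULL
  idx <- which(eligible)
  for (a in idx) for (b in idx) {
    if (b <= a) next
    if (sizes[a] + sizes[b] < minTotalFrac * N) next
    if (length(intersect(tipsets[[a]], tipsets[[b]]))) next
    cand <- list(a = a, b = b, d = diss[a] + diss[b],
                 sz = sizes[a] + sizes[b])
    if (is.null(best) ||
        cand$d < best$d - 1e-12 ||
        (abs(cand$d - best$d) <= 1e-12 && cand$sz > best$sz) ||
        (abs(cand$d - best$d) <= 1e-12 && cand$sz == best$sz &&
         min(cl[[cand$a]]$node, cl[[cand$b]]$node) <
           min(cl[[best$a]]$node, cl[[best$b]]$node)))
      best <- cand
  }
  if (is.null(best)) {
    anyPair <- any(vapply(idx, function(a) any(vapply(idx, function(b)
      b > a && !length(intersect(tipsets[[a]], tipsets[[b]])),
      logical(1L))), logical(1L)))
    stop("constraint infeasible: no disjoint clade pair satisfies ",
         if (anyPair) sprintf("joint coverage >= %.2f of cells (minTotalFrac)",
                              minTotalFrac)
         else sprintf("per-clade size >= %.2f of cells (minEachFrac)",
                      minEachFrac), call. = FALSE)
  }
  pair <- c(best$a, best$b)
  pair <- pair[order(vapply(cl[pair], `[[`, integer(1L), "node"))]
  selected <- pair
  # steps 2..k: largest remaining disjoint clade
  while (length(selected) < nClades) {
    used <- unlist(tipsets[selected])
    free <- which(vapply(tipsets, function(tp)
      !length(intersect(tp, used)), logical(1L)))
    if (!length(free))
      stop("constraint infeasible: no clade disjoint from the selected ",
           "ancestries remains (requested nClades = ", nClades, ")",
           call. = FALSE)
    ord <- free[order(-sizes[free], diss[free],
                      vapply(cl[free], `[[`, integer(1L), "node"))]
    selected <- c(selected, ord[1L])
  }
  annotationFromClades(tree, tipsets[selected], normalCells, allCells,
                       provenance)
}

#' Partition a ladder-like phylogeny into equal-sized ancestries
#'
#' Ancestry annotation for unbalanced (caterpillar-like) phylogenies, where
#' nested clades make the balanced pair search degenerate. The tree is cut
#' into \code{nClades} groups of similar size: at each step the clade of
#' the remaining tree whose size is nearest to (remaining cells)/(remaining
#' groups) is removed, ties broken by least within-clade genetic
#' dissimilarity and then by node number; after \code{nClades - 1} cuts the
#' remaining cells form the final ancestry. Every cell receives a label
#' (there is no \code{"unassigned"}); normal cells are excluded from
#' candidacy and labelled \code{"normal"}.
#'
#' @inheritParams balancedAnnotation
#' @return An \code{\linkS4class{AncestryAnnotation}}.
#' @examples
#' tr <- ape::stree(9, "left")  # 9-tip caterpillar
#' tr$tip.label <- paste0("c", 1:9)
#' table(ancestryLabels(unbalancedAnnotation(tr, nClades = 3)))
#' @export
unbalancedAnnotation <- function(tree, nClades = 3,
                                 normalCells = character(),
                                 provenance = "unbalancedAnnotation") {
  tree <- validateTree(tree)
  stopifnot(nClades >= 1)
  allCells <- tree$tip.label
  work <- tree
  if (length(normalCells))
    work <- ape::drop.tip(tree, intersect(normalCells, tree$tip.label))
  if (nClades > length(work$tip.label))
    stop("validation error: nClades exceeds the number of non-normal tips",
         call. = FALSE)
  groups <- list()
  remaining <- work
  for (g in seq_len(nClades - 1L)) {
    nRem <- length(remaining$tip.label)
    groupsLeft <- nClades - g + 1L
    target <- nRem / groupsLeft
    cl <- enumerateClades(remaining, includeSingletons = TRUE)
    sizes <- vapply(cl, `[[`, integer(1L), "size")
    # a cut must leave at least one tip per remaining group
    ok <- sizes <= nRem - (groupsLeft - 1L)
    cl <- cl[ok]; sizes <- sizes[ok]
    diss <- vapply(cl, `[[`, numeric(1L), "diss")
    nodeid <- vapply(cl, `[[`, integer(1L), "node")
    ord <- order(abs(sizes - target), diss, nodeid)
    pick <- cl[[ord[1L]]]
    groups[[g]] <- pick$tips
    keep <- setdiff(remaining$tip.label, pick$tips)
    if (length(keep) >= 2L) {
      remaining <- ape::drop.tip(remaining, pick$tips)
    } else {
      remaining <- list(tip.label = keep)  # single tip: final group only
    }
  }
  groups[[nClades]] <- remaining$tip.label
  annotationFromClades(tree, groups, normalCells, allCells, provenance)
}

#' Annotate genetic ancestries, choosing the strategy from tree shape
#'
#' Convenience wrapper: estimates beta-splitting balance with
#' \code{\link{treeBalance}} and dispatches to
#' \code{\link{balancedAnnotation}} or \code{\link{unbalancedAnnotation}}
#' accordingly (or honours an explicit \code{mode}).
#'
#' @inheritParams balancedAnnotation
#' @param mode \code{"auto"} (default), \code{"balanced"} or
#'   \code{"unbalanced"}.
#' @param threshold beta threshold passed to \code{treeBalance}.
#' @return An \code{\linkS4class{AncestryAnnotation}}.
#' @export
annotateAncestries <- function(tree, mode = c("auto", "balanced",
                                              "unbalanced"),
                               nClades = 3, minTotalFrac = 0.75,
                               minEachFrac = 0.1,
                               normalCells = character(),
                               threshold = -1.5,
                               provenance = NULL) {
  mode <- match.arg(mode)
  if (mode == "auto")
    mode <- if (treeShape(treeBalance(tree, threshold = threshold)) ==
                "balanced") "balanced" else "unbalanced"
  if (is.null(provenance)) provenance <- paste0(mode, "Annotation")
  if (mode == "balanced")
    balancedAnnotation(tree, nClades = nClades, minTotalFrac = minTotalFrac,
                       minEachFrac = minEachFrac, normalCells = normalCells,
                       provenance = provenance)
  else
    unbalancedAnnotation(tree, nClades = nClades, normalCells = normalCells,
                         provenance = provenance)
}
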