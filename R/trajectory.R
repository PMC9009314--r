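#' @importFrom rlang .data
NULL

#' Rank genes by differential expression between ancestries
#'
#' Ranks genes by the Kruskal-Wallis H statistic across the genetic
#' ancestry groups (midrank ties, with the usual tie correction). Cells
#' labelled \code{"normal"} or \code{"unassigned"} do not form groups.
#' Genes expressed (non-zero) in fewer than \code{minCells} of the grouped
#' cells are removed before ranking; constant genes score H = 0 and sort
#' last. Ties in H are ordered by gene ID, making the ranking
#' deterministic.
#'
#' @param expr numeric matrix, genes x cells (normalized expression).
#' @param ann an \code{\linkS4class{AncestryAnnotation}}; at least two
#'   ancestries with three or more cells each are required.
#' @param minCells minimum number of grouped cells with non-zero expression
#'   for a gene to enter the ranking (default 3).
#' @return A data.frame with columns \code{gene}, \code{statistic} (H) and
#'   \code{pValue} (chi-square approximation), sorted by decreasing H.
#' @export
rankGenes <- function(expr, ann, minCells = 3) {
  lab <- ancestryLabels(ann)
  lab <- lab[!(lab %in% SPECIAL_LABELS)]
  lab <- lab[names(lab) %in% colnames(expr)]
  sizes <- table(lab)
  groups <- names(sizes)[sizes >= 3L]
  if (length(groups) < 2L)
    stop("grouping error: need at least 2 ancestries with >= 3 cells each",
         call. = FALSE)
  lab <- lab[lab %in% groups]
  X <- expr[, names(lab), drop = FALSE]
  X <- X[rowSums(X != 0) >= minCells, , drop = FALSE]
  g <- factor(lab)
  N <- ncol(X)
  ng <- as.vector(table(g))
  H <- apply(X, 1L, function(x) {
    if (all(x == x[1L])) return(0)
    r <- rank(x)
    rbar <- tapply(r, g, mean)
    h <- 12 / (N * (N + 1)) * sum(ng * (rbar - (N + 1) / 2)^2)
    ties <- table(x)
    corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
    h / corr
  })
  p <- stats::pchisq(H, df = length(groups) - 1L, lower.tail = FALSE)
  out <- data.frame(gene = rownames(X), statistic = as.numeric(H),
                    pValue = as.numeric(p))
  out[order(-out$statistic, out$gene), , drop = FALSE]
}

# deterministic minimum spanning tree (Kruskal; ties broken by the
# lexicographically smallest cell-ID pair). d: full symmetric distance
# matrix with dimnames. Returns edge data.frame(from, to, length) with
# from/to unordered.
mstEdges <- function(d) {
  ids <- rownames(d)
  n <- length(ids)
  ii <- which(upper.tri(d), arr.ind = TRUE)
  # order cell pairs so 'a' is lexicographically smaller
  a <- ids[ii[, 1L]]; b <- ids[ii[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  w <- d[ii]
  ord <- order(w, a, b)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  idx <- stats::setNames(seq_len(n), ids)
  from <- character(n - 1L); to <- character(n - 1L); len <- numeric(n - 1L)
  k <- 0L
  for (e in ord) {
    ra <- find(idx[[a[e]]]); rb <- find(idx[[b[e]]])
    if (ra == rb) next
    parent[ra] <- rb
    k <- k + 1L
    from[k] <- a[e]; to[k] <- b[e]; len[k] <- w[e]
    if (k == n - 1L) break
  }
  data.frame(from = from, to = to, length = len)
}

#' Build a deterministic expression trajectory and assign states
#'
#' A reproducible stand-in for model-based trajectory tools: (1) the
#' expression matrix is restricted to the given genes and each gene is
#' z-scored; (2) cells are projected onto \code{nDims} principal components
#' with a fixed sign convention (the largest-magnitude loading of each
#' component is made positive); (3) a minimum spanning tree is built over
#' pairwise Euclidean distances, ties broken by lexicographic cell-ID
#' pairs; (4) pseudotime is the path length from the root cell (normally a
#' non-cancerous cell, pseudotime 0) along the tree; (5) the tree is
#' decomposed into maximal unbranched paths delimited by the root, leaves
#' and branch vertices (degree >= 3) -- each path is one expression state,
#' with branch vertices belonging to their rootward path; (6) states
#' smaller than \code{max(3, ceiling(0.05 * n))} cells are merged into
#' their rootward neighbor, and states are renumbered 1..K by increasing
#' mean pseudotime.
#'
#' States produced this way are analogous to, but not identical with, the
#' states of model-based trajectory tools such as Monocle.
#'
#' @param expr numeric matrix, genes x cells.
#' @param genes character vector of gene IDs to use (length >= nDims).
#' @param rootCell cell ID to place at pseudotime zero.
#' @param nDims number of principal components (default 2).
#' @return A \code{\linkS4class{StateAssignment}}.
#' @export
buildTrajectory <- function(expr, genes, rootCell, nDims = 2) {
  stopifnot(is.matrix(expr))
  if (!rootCell %in% colnames(expr))
    stop("validation error: root cell '", rootCell,
         "' not in the expression matrix", call. = FALSE)
  genes <- intersect(genes, rownames(expr))
  if (length(genes) < nDims)
    stop("validation error: need at least nDims genes", call. = FALSE)
  n <- ncol(expr)
  if (n < 3L)
    stop("validation error: need at least 3 cells", call. = FALSE)
  X <- t(expr[genes, , drop = FALSE])      # cells x genes
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, sd, "/")
  nDims <- min(nDims, n - 1L, ncol(Z))
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE, rank. = nDims)
  S <- pc$x[, seq_len(nDims), drop = FALSE]
  for (j in seq_len(nDims)) {               # fixed sign convention
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) S[, j] <- -S[, j]
  }
  rownames(S) <- colnames(expr)
  D <- as.matrix(stats::dist(S))
  edges <- mstEdges(D)

  adj <- split(c(edges$to, edges$from), c(edges$from, edges$to))
  ew <- stats::setNames(edges$length,
                        paste(pmin(edges$from, edges$to),
                              pmax(edges$from, edges$to)))
  cellsAll <- rownames(S)
  deg <- vapply(adj[cellsAll], length, integer(1L))
  names(deg) <- cellsAll

  # BFS from the root: parents, pseudotime, path (state) ids
  parent <- stats::setNames(rep(NA_character_, n), cellsAll)
  pt <- stats::setNames(rep(NA_real_, n), cellsAll)
  path <- stats::setNames(rep(NA_integer_, n), cellsAll)
  pt[rootCell] <- 0
  nPaths <- 0L
  queue <- rootCell
  rootChildren <- sort(adj[[rootCell]])
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    nb <- sort(setdiff(adj[[v]], parent[v]))
    for (u in nb) {
      parent[u] <- v
      pt[u] <- pt[v] + ew[[paste(min(u, v), max(u, v))]]
      startNew <- identical(v, rootCell) || deg[[v]] >= 3L
      if (startNew) {
        nPaths <- nPaths + 1L
        path[u] <- nPaths
      } else {
        path[u] <- path[v]
      }
      queue <- c(queue, u)
    }
  }
  # the root belongs to the path toward its first (smallest-ID) child;
  # branch vertices already carry their rootward path via their parent edge
  path[rootCell] <- if (length(rootChildren)) path[[rootChildren[1L]]] else {
    nPaths <- max(nPaths, 1L); 1L
  }

  # merge undersized states into their rootward neighbor
  minSize <- max(3, ceiling(0.05 * n))
  repeat {
    tab <- table(path)
    if (length(tab) <= 1L) break
    small <- as.integer(names(tab)[tab < minSize])
    if (!length(small)) break
    meanPt <- tapply(pt, path, mean)
    o <- order(tab[as.character(small)], meanPt[as.character(small)], small)
    s <- small[o[1L]]
    members <- names(path)[path == s]
    topCell <- members[which.min(pt[members])]
    if (!is.na(parent[topCell]) && path[[parent[topCell]]] != s) {
      tgt <- path[[parent[topCell]]]
    } else {
      # state contains the root: absorb the adjacent state with the
      # smallest mean pseudotime
      nbStates <- unique(unlist(lapply(members, function(v)
        path[adj[[v]]])))
      nbStates <- setdiff(nbStates, s)
      tgt <- nbStates[which.min(meanPt[as.character(nbStates)])]
    }
    path[path == s] <- tgt
  }
  meanPt <- tapply(pt, path, mean)
  newId <- stats::setNames(seq_along(meanPt), names(sort(meanPt)))
  states <- as.integer(newId[as.character(path)])
  names(states) <- names(path)

  dirEdges <- data.frame(from = parent[!is.na(parent)],
                         to = names(parent)[!is.na(parent)])
  dirEdges$length <- pt[dirEdges$to] - pt[dirEdges$from]
  rownames(dirEdges) <- NULL
  new("StateAssignment", states = states, pseudotime = pt,
      rootCell = rootCell, geneScale = length(genes),
      coordinates = S, mstEdges = dirEdges)
}

uniqueFractions <- function(states, ann, excludeLabels) {
  lab <- ancestryLabels(ann)
  st <- cellStates(states)
  common <- intersect(names(st), names(lab))
  keep <- common[!(lab[common] %in% excludeLabels)]
  if (!length(keep)) stop("no eligible cells for concordance", call. = FALSE)
  table(state = st[keep], ancestry = lab[keep])
}

#' Sub-concordance index (SCI) of one genetic ancestry
#'
#' Counts the expression states that are largely unique to the given
#' ancestry. Under the default state-composition definition, a state counts
#' when more than a fraction \code{u} (default 0.8) of its cells belong to
#' the ancestry. The alternative ancestry-coverage definition
#' (\code{mode = "ancestry-coverage"}) instead counts states holding more
#' than \code{u} of the ancestry's cells. Normal cells (which trivially
#' share one state) and unassigned cells are excluded from both numerator
#' and denominator.
#'
#' An SCI of zero means the ancestry has no expression state of its own; a
#' value above one means its cells subdivide into several distinct
#' expression states (divergent expression evolution).
#'
#' @param states a \code{\linkS4class{StateAssignment}}.
#' @param ann an \code{\linkS4class{AncestryAnnotation}}.
#' @param ancestry the ancestry label to score.
#' @param u uniqueness threshold in (0, 1), strict (default 0.8).
#' @param mode \code{"state-composition"} (default) or
#'   \code{"ancestry-coverage"}.
#' @param excludeLabels labels excluded from the computation.
#' @return A non-negative integer count.
#' @export
sci <- function(states, ann, ancestry, u = 0.8,
                mode = c("state-composition", "ancestry-coverage"),
                excludeLabels = c("normal", "unassigned")) {
  mode <- match.arg(mode)
  if (!ancestry %in% ancestryLabels(ann))
    stop("validation error: unknown ancestry '", ancestry, "'",
         call. = FALSE)
  tab <- uniqueFractions(states, ann, excludeLabels)
  if (!ancestry %in% colnames(tab)) return(0L)
  cnt <- tab[, ancestry]
  if (mode == "state-composition") {
    frac <- cnt / rowSums(tab)
  } else {
    frac <- cnt / sum(cnt)
  }
  sum(frac > u)
}

#' Overall concordance index (OCI)
#'
#' The fraction of expression states that are largely unique (at the strict
#' threshold \code{u}) to any single genetic ancestry. The state(s) holding
#' the normal cells count in the denominator and may count as unique to
#' \code{"normal"}; unassigned cells are excluded entirely. OCI near one
#' indicates divergent expression evolution tracking genetic ancestry; OCI
#' near zero indicates convergent expression states shared across
#' ancestries.
#'
#' @inheritParams sci
#' @return A number in [0, 1].
#' @export
oci <- function(states, ann, u = 0.8, excludeLabels = "unassigned") {
  tab <- uniqueFractions(states, ann, excludeLabels)
  frac <- tab / rowSums(tab)
  mean(apply(frac, 1L, max) > u)
}

#' Concordance of genetic ancestry and expression state across gene scales
#'
#' The full trajectory sweep: for every ancestry annotation and every gene
#' scale, genes are ranked by differential expression between that
#' annotation's ancestries, the trajectory is rebuilt from the top genes,
#' and the per-ancestry SCI and whole-tumor OCI are recorded. By default
#' the sweep starts at the 200 most differential genes and grows in steps
#' of 100 up to 1,000; a small gene scale concentrates the ancestry signal
#' while large scales dilute it with genes that do not track ancestry.
#'
#' @param expr numeric matrix, genes x cells.
#' @param annotations an \code{\linkS4class{AncestryAnnotation}} or a list
#'   of them (e.g. from different phylogenies).
#' @param rootCell cell placed at pseudotime zero (normally a normal cell).
#' @param scales integer vector of gene scales (default
#'   \code{seq(200, 1000, 100)}); scales beyond the number of rankable
#'   genes are dropped with a warning.
#' @param u uniqueness threshold for SCI/OCI (default 0.8).
#' @param nDims,minCells passed to \code{\link{buildTrajectory}} and
#'   \code{\link{rankGenes}}.
#' @param outDir optional directory for per-scale trajectory plots and
#'   SCI/OCI-versus-scale line plots.
#' @return A \code{\linkS4class{ConcordanceReport}}.
#' @export
phyloTrajectory <- function(expr, annotations, rootCell,
                            scales = seq(200L, 1000L, 100L), u = 0.8,
                            nDims = 2, minCells = 3, outDir = NULL) {
  if (is(annotations, "AncestryAnnotation"))
    annotations <- list(annotations)
  if (!length(annotations))
    stop("validation error: empty annotation list", call. = FALSE)
  nm <- make.unique(vapply(annotations, provenance, character(1L)))
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  sciRows <- list(); ociRows <- list()
  for (k in seq_along(annotations)) {
    ann <- annotations[[k]]
    ranking <- rankGenes(expr, ann, minCells = minCells)
    useScales <- scales[scales <= nrow(ranking)]
    if (length(useScales) < length(scales))
      warning("only ", nrow(ranking), " rankable genes: scales truncated")
    ancestries <- sort(setdiff(unique(ancestryLabels(ann)), SPECIAL_LABELS))
    for (sc in useScales) {
      st <- buildTrajectory(expr, ranking$gene[seq_len(sc)], rootCell,
                            nDims = nDims)
      for (a in ancestries)
        sciRows[[length(sciRows) + 1L]] <- data.frame(
          annotation = nm[k], scale = sc, ancestry = a,
          sci = sci(st, ann, a, u = u))
      tab <- uniqueFractions(st, ann, "unassigned")
      nUnique <- sum(apply(tab / rowSums(tab), 1L, max) > u)
      ociRows[[length(ociRows) + 1L]] <- data.frame(
        annotation = nm[k], scale = sc, oci = nUnique / nrow(tab),
        nStates = nrow(tab), nUnique = nUnique)
      if (!is.null(outDir))
        plotTrajectory(st, ann,
                       file = file.path(outDir,
                                        sprintf("trajectory_%s_%d.pdf",
                                                nm[k], sc)))
    }
  }
  report <- new("ConcordanceReport",
                sci = do.call(rbind, sciRows),
                oci = do.call(rbind, ociRows),
                u = u, scales = as.numeric(unique(unlist(scales))))
  if (!is.null(outDir)) plotConcordance(report, outDir)
  report
}

#' Plot an expression trajectory colored by genetic ancestry
#'
#' Scatter of cells in the trajectory embedding with the spanning-tree
#' edges, colored by ancestry and shaped by expression state.
#'
#' @param states a \code{\linkS4class{StateAssignment}}.
#' @param ann an \code{\linkS4class{AncestryAnnotation}}.
#' @param file optional PDF path.
#' @return The \code{ggplot} object, invisibly when written to a file.
#' @export
plotTrajectory <- function(states, ann, file = NULL) {
  S <- states@coordinates
  lab <- ancestryLabels(ann)
  df <- data.frame(cell = rownames(S), x = S[, 1L],
                   y = if (ncol(S) > 1L) S[, 2L] else 0,
                   state = factor(cellStates(states)[rownames(S)]),
                   ancestry = ifelse(rownames(S) %in% names(lab),
                                     lab[rownames(S)], "unassigned"))
  ed <- states@mstEdges
  seg <- data.frame(x = S[ed$from, 1L], y = if (ncol(S) > 1L)
                      S[ed$from, 2L] else 0,
                    xend = S[ed$to, 1L], yend = if (ncol(S) > 1L)
                      S[ed$to, 2L] else 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          color = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(color = .data$ancestry,
                                     shape = .data$state), size = 2) +
    ggplot2::labs(x = "component 1", y = "component 2",
                  title = sprintf("gene scale %d", states@geneScale)) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    grDevices::pdf(file, width = 6, height = 5)
    print(p)
    grDevices::dev.off()
    return(invisible(p))
  }
  p
}

# SCI-versus-scale and OCI-versus-scale line plots for a report
plotConcordance <- function(report, outDir) {
  sciDf <- sciTable(report)
  p1 <- ggplot2::ggplot(sciDf, ggplot2::aes(x = .data$scale, y = .data$sci,
                                            color = .data$ancestry)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~annotation) +
    ggplot2::labs(x = "number of genes", y = "SCI") +
    ggplot2::theme_minimal()
  ociDf <- ociTable(report)
  p2 <- ggplot2::ggplot(ociDf, ggplot2::aes(x = .data$scale, y = .data$oci,
                                            color = .data$annotation)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "number of genes", y = "OCI") +
    ggplot2::theme_minimal()
  grDevices::pdf(file.path(outDir, "sci_by_scale.pdf"), width = 7,
                 height = 5)
  print(p1)
  grDevices::dev.off()
  grDevices::pdf(file.path(outDir, "oci_by_scale.pdf"), width = 7,
                 height = 5)
  print(p2)
  grDevices::dev.off()
  invisible(NULL)
}
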