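#' Simulate a cell phylogeny with known ancestry structure
#'
#' Generates a rooted binary phylogeny of \code{nCells} cancer cells plus
#' \code{nNormal} normal cells, with \code{nAncestries} well-separated
#' clades as the true genetic ancestries. Cancer cells are split into
#' near-equal groups; each group's subtree is built by recursive even
#' splits (\code{treeMode = "balanced"}) or as a caterpillar
#' (\code{treeMode = "unbalanced"}), the group subtrees are joined by a
#' backbone whose long edges (\code{interCladeLength}) separate the clades
#' by an order of magnitude more than the within-clade edges
#' (\code{intraCladeLength}), and the normal cells attach as a shallow
#' outgroup at the root. Everything is reproducible from \code{seed}.
#'
#' @param nCells number of cancer cells (default 60).
#' @param nNormal number of normal cells (default 3).
#' @param nAncestries number of true ancestries (default 3).
#' @param treeMode \code{"balanced"} or \code{"unbalanced"}.
#' @param intraCladeLength mean within-clade edge length (default 0.1;
#'   edges are drawn uniformly in +/- 50\% of it).
#' @param interCladeLength backbone edge length separating clades
#'   (default 10).
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @return A list with \code{tree} (a \code{phylo}) and \code{ancestry}
#'   (named character vector of true labels, \code{ancestry_1..k} and
#'   \code{normal}).
#' @export
simulateTree <- function(nCells = 60, nNormal = 3, nAncestries = 3,
                         treeMode = c("balanced", "unbalanced"),
                         intraCladeLength = 0.1, interCladeLength = 10,
                         seed = NULL) {
  treeMode <- match.arg(treeMode)
  if (nCells < 2 * nAncestries)
    stop("validation error: need nCells >= 2 * nAncestries", call. = FALSE)
  if (nNormal < 1)
    stop("validation error: need at least one normal cell", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cellIds <- sprintf("cell_%03d", seq_len(nCells))
  groupOf <- sort(rep_len(seq_len(nAncestries), nCells))
  rlen <- function(k) stats::runif(k, 0.5 * intraCladeLength,
                                   1.5 * intraCladeLength)
  subNewick <- function(tips) {
    build <- function(tp) {
      if (length(tp) == 1L) return(sprintf("%s:%.6f", tp, rlen(1L)))
      if (treeMode == "balanced") {
        h <- ceiling(length(tp) / 2)
        sprintf("(%s,%s):%.6f", build(tp[seq_len(h)]), build(tp[-seq_len(h)]),
                rlen(1L))
      } else {
        sprintf("(%s,%s):%.6f", build(tp[-length(tp)]),
                sprintf("%s:%.6f", tp[length(tp)], rlen(1L)), rlen(1L))
      }
    }
    build(tips)
  }
  # each clade subtree hangs from a long root edge so that between-clade
  # patristic distances exceed within-clade ones by >= interCladeLength/
  # intraCladeLength
  clades <- vapply(seq_len(nAncestries), function(g)
    sprintf("%s:%.6f", sub(":[0-9.]+$", "", subNewick(cellIds[groupOf == g])),
            interCladeLength), character(1L))
  backbone <- clades[1L]
  for (g in seq_len(nAncestries)[-1L])
    backbone <- sprintf("(%s,%s):%.6f", backbone, clades[g],
                        interCladeLength)
  normalIds <- sprintf("normal_%02d", seq_len(nNormal))
  normClade <- if (nNormal == 1L) {
    sprintf("%s:0.010000", normalIds)
  } else {
    out <- sprintf("%s:0.010000", normalIds[1L])
    for (k in 2:nNormal)
      out <- sprintf("(%s,%s:0.010000):0.010000", out, normalIds[k])
    out
  }
  txt <- sprintf("(%s,%s);", backbone, normClade)
  tree <- readNewick(txt)
  ancestry <- stats::setNames(c(paste0("ancestry_", groupOf),
                                rep("normal", nNormal)),
                              c(cellIds, normalIds))
  list(tree = tree, ancestry = ancestry[tree$tip.label])
}

#' Simulate a genotype-call matrix on a phylogeny
#'
#' Places one somatic mutation per site on a random edge of the cancer part
#' of the tree (sampled with probability proportional to edge length,
#' excluding edges ancestral to normal cells, so normal cells are
#' all-reference before corruption). A cell carries \code{ALT} at a site
#' iff the site's mutation lies on its root path. Sequencing noise is then
#' applied per call: true \code{ALT} calls flip to \code{REF} with
#' probability \code{fnRate} (allelic dropout / false negatives) and any
#' call becomes \code{MISSING} with probability \code{missingRate},
#' emulating the heavy missingness of scRNA-seq-derived SNV calls.
#'
#' @param tree a rooted \code{phylo} whose tips are cells.
#' @param ancestry named character vector of true labels (cells labelled
#'   \code{"normal"} are protected from mutations).
#' @param nSites number of SNV sites (default 150).
#' @param fnRate false-negative rate for mutant calls (default 0.2).
#' @param missingRate missing-call rate (default 0.4).
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @return A \code{\linkS4class{GenotypeMatrix}} (sites x cells) with the
#'   normal cells designated.
#' @export
simulateGenotypes <- function(tree, ancestry, nSites = 150, fnRate = 0.2,
                              missingRate = 0.4, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), fnRate >= 0, fnRate <= 1,
            missingRate >= 0, missingRate <= 1)
  if (!is.null(seed)) set.seed(seed)
  tips <- tree$tip.label
  normals <- names(ancestry)[ancestry == "normal"]
  nt <- length(tips)
  # edges on the root path of any normal tip are mutation-free
  paths <- ape::nodepath(tree)
  names(paths) <- tips
  edgeKey <- paste(tree$edge[, 1L], tree$edge[, 2L])
  onPath <- function(tip) {
    p <- paths[[tip]]
    paste(p[-length(p)], p[-1L])
  }
  forbidden <- unique(unlist(lapply(normals, onPath)))
  allowed <- which(!(edgeKey %in% forbidden))
  wts <- tree$edge.length[allowed]
  mutEdge <- allowed[sample.int(length(allowed), nSites, replace = TRUE,
                                prob = wts)]
  # cells below each mutated edge are ALT
  m <- matrix("REF", nSites, nt,
              dimnames = list(sprintf("site_%03d", seq_len(nSites)), tips))
  tipEdges <- lapply(tips, function(tp) match(onPath(tp), edgeKey))
  for (s in seq_len(nSites)) {
    alt <- tips[vapply(tipEdges, function(e) mutEdge[s] %in% e,
                       logical(1L))]
    m[s, alt] <- "ALT"
  }
  if (fnRate > 0) {
    isAlt <- m == "ALT"
    flip <- isAlt & matrix(stats::runif(length(m)) < fnRate, nSites, nt)
    m[flip] <- "REF"
  }
  if (missingRate > 0) {
    miss <- matrix(stats::runif(length(m)) < missingRate, nSites, nt)
    m[miss] <- "MISSING"
  }
  GenotypeMatrix(m, normalCells = intersect(normals, tips))
}

#' Simulate an expression matrix with ancestry-linked programs
#'
#' Draws log-normal background expression for every gene and cell
#' (\code{meanlog = 0}, \code{sdlog = 0.5}) and superimposes
#' ancestry-specific programs: the signal genes are divided evenly among
#' the ancestries and each ancestry's program shifts its assigned genes'
#' \code{meanlog} by \code{effectSize} in that ancestry's cells. Normal
#' cells keep the background program. Convergent expression evolution is
#' emulated by re-drawing a fraction \code{convergenceFrac} of the
#' \code{convergenceFrom} ancestry's cells from the \code{convergenceTo}
#' ancestry's program, so that one expression state ends up shared by two
#' genetically distinct ancestries (the invaded ancestry then loses its
#' unique state). The true program of every cell is returned.
#'
#' @param ancestry named character vector of true ancestry labels.
#' @param nGenes total genes (default 1200).
#' @param nSignalGenes genes carrying ancestry signal (default 120).
#' @param effectSize mean log-expression shift of a program's genes
#'   (default 3).
#' @param convergenceFrac fraction of \code{convergenceFrom} cells
#'   expressing the \code{convergenceTo} program (default 0).
#' @param convergenceFrom,convergenceTo ancestry labels for the convergence
#'   regime (defaults \code{"ancestry_1"} and \code{"ancestry_2"}).
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @return A list with \code{expression} (genes x cells matrix),
#'   \code{programs} (named character, true program per cell) and
#'   \code{signalGenes} (named list per ancestry).
#' @export
simulateExpression <- function(ancestry, nGenes = 1200, nSignalGenes = 120,
                               effectSize = 3, convergenceFrac = 0,
                               convergenceFrom = "ancestry_1",
                               convergenceTo = "ancestry_2", seed = NULL) {
  stopifnot(nSignalGenes <= nGenes, convergenceFrac >= 0,
            convergenceFrac <= 1)
  if (!is.null(seed)) set.seed(seed)
  cellsAll <- names(ancestry)
  ancLabels <- sort(setdiff(unique(ancestry), "normal"))
  genes <- sprintf("gene_%04d", seq_len(nGenes))
  perAnc <- split(seq_len(nSignalGenes),
                  sort(rep_len(seq_along(ancLabels), nSignalGenes)))
  signalGenes <- stats::setNames(lapply(perAnc, function(i) genes[i]),
                                 ancLabels)
  programs <- ancestry
  if (convergenceFrac > 0 && convergenceFrom %in% ancLabels &&
      convergenceTo %in% ancLabels) {
    donor <- names(ancestry)[ancestry == convergenceFrom]
    k <- floor(convergenceFrac * length(donor))
    if (k > 0) programs[sample(donor, k)] <- convergenceTo
  }
  meanlog <- matrix(0, nGenes, length(cellsAll),
                    dimnames = list(genes, cellsAll))
  for (a in ancLabels) {
    cc <- names(programs)[programs == a]
    if (length(cc)) meanlog[signalGenes[[a]], cc] <- effectSize
  }
  expr <- matrix(stats::rlnorm(nGenes * length(cellsAll),
                               meanlog = as.vector(meanlog), sdlog = 0.5),
                 nGenes, length(cellsAll),
                 dimnames = list(genes, cellsAll))
  list(expression = expr, programs = programs, signalGenes = signalGenes)
}

#' Simulate a complete tumor dataset with ground truth
#'
#' One-call generator of a coupled phylogeny, genotype matrix and
#' expression matrix from a single seed. Three presets fix the expression
#' regime: \code{"concordant"} (strong ancestry-specific programs,
#' \code{effectSize = 3}, no convergence -- expression states track
#' ancestry), \code{"convergent"} (half of one ancestry's cells adopt
#' another ancestry's program, \code{convergenceFrac = 0.5} -- a shared
#' expression state appears) and \code{"null"} (\code{effectSize = 0}, no
#' ancestry signal at all). Any generator parameter can be overridden via
#' \code{...}.
#'
#' @param preset \code{"concordant"}, \code{"convergent"} or \code{"null"}.
#' @param seed integer seed driving all three generators.
#' @param ... overrides passed to \code{\link{simulateTree}},
#'   \code{\link{simulateGenotypes}} and
#'   \code{\link{simulateExpression}} (matched by argument name).
#' @return A \code{\linkS4class{ClonalSim}}.
#' @examples
#' sim <- simulateTumor("concordant", seed = 1)
#' sim
#' @export
simulateTumor <- function(preset = c("concordant", "convergent", "null"),
                          seed = 1, ...) {
  preset <- match.arg(preset)
  p <- list(nCells = 60, nNormal = 3, nAncestries = 3,
            treeMode = "balanced", intraCladeLength = 0.1,
            interCladeLength = 10, nSites = 150, fnRate = 0.2,
            missingRate = 0.4, nGenes = 1200, nSignalGenes = 120,
            effectSize = 3, convergenceFrac = 0,
            convergenceFrom = "ancestry_1", convergenceTo = "ancestry_2")
  if (preset == "convergent") p$convergenceFrac <- 0.5
  if (preset == "null") p$effectSize <- 0
  dots <- list(...)
  p[names(dots)] <- dots
  p$seed <- seed
  ts <- simulateTree(p$nCells, p$nNormal, p$nAncestries, p$treeMode,
                     p$intraCladeLength, p$interCladeLength, seed = seed)
  g <- simulateGenotypes(ts$tree, ts$ancestry, p$nSites, p$fnRate,
                         p$missingRate, seed = seed + 1L)
  e <- simulateExpression(ts$ancestry, p$nGenes, p$nSignalGenes,
                          p$effectSize, p$convergenceFrac,
                          p$convergenceFrom, p$convergenceTo,
                          seed = seed + 2L)
  p$preset <- preset
  new("ClonalSim", tree = ts$tree, ancestry = ts$ancestry,
      programs = e$programs, signalGenes = e$signalGenes, genotypes = g,
      expression = e$expression, params = p)
}

#' Write a simulated tumor to the package's file formats
#'
#' Writes \code{tree.nwk}, \code{genotypes.tsv}, \code{expression.tsv} and
#' \code{truth.tsv} (cell, true ancestry, true program) into a directory,
#' in exactly the formats the readers accept, so simulations double as
#' file-level fixtures.
#'
#' @param sim a \code{\linkS4class{ClonalSim}}.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ape::write.tree(sim@tree, file.path(dir, "tree.nwk"))
  writeGenotypeMatrix(sim@genotypes, file.path(dir, "genotypes.tsv"))
  writeExpressionMatrix(sim@expression, file.path(dir, "expression.tsv"))
  utils::write.table(
    data.frame(cell = names(sim@ancestry), ancestry = unname(sim@ancestry),
               program = unname(sim@programs[names(sim@ancestry)])),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
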