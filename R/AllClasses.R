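#' @import methods
NULL

GENOTYPE_CALLS <- c("REF", "ALT", "HET", "MISSING")
SPECIAL_LABELS <- c("normal", "unassigned")

#' GenotypeMatrix: single-cell genotype calls at SNV sites
#'
#' A sites-by-cells matrix of genotype calls, each one of \code{"REF"},
#' \code{"ALT"}, \code{"HET"} or \code{"MISSING"}, together with the set of
#' cells designated as non-cancerous (normal). Normal cells anchor the SNV
#' quality filter (\code{\link{filterSNVs}}): in scRNA-seq-derived calls a
#' site is only trusted when the normal cells agree on a homozygous-reference
#' genotype.
#'
#' @slot calls character matrix, sites in rows, cells in columns, values in
#'   \code{REF/ALT/HET/MISSING}; dimnames are site and cell identifiers.
#' @slot normalCells character vector of cell identifiers flagged as normal
#'   (a subset of the column names, possibly empty).
#'
#' @seealso \code{\link{readGenotypeMatrix}}, \code{\link{filterSNVs}},
#'   \code{\link{filterCells}}
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix",
  representation(calls = "matrix", normalCells = "character"))

setValidity("GenotypeMatrix", function(object) {
  m <- object@calls
  if (!is.character(m)) return("'calls' must be a character matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("'calls' must have site (row) and cell (column) names")
  if (anyDuplicated(rownames(m))) return("duplicate site IDs")
  if (anyDuplicated(colnames(m))) return("duplicate cell IDs")
  bad <- setdiff(unique(as.vector(m)), GENOTYPE_CALLS)
  if (length(bad))
    return(paste0("invalid genotype call(s): ", paste(bad, collapse = ", ")))
  if (!all(object@normalCells %in% colnames(m)))
    return("normalCells must be a subset of the cell IDs")
  if (anyDuplicated(object@normalCells)) return("duplicate normal cell IDs")
  TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param calls character matrix (sites x cells) with values
#'   \code{REF/ALT/HET/MISSING}; \code{NA} entries are converted to
#'   \code{MISSING}.
#' @param normalCells character vector of normal cell IDs (subset of the
#'   column names).
#' @return A \code{\linkS4class{GenotypeMatrix}}.
#' @examples
#' m <- matrix(c("REF", "ALT", "REF", "MISSING"), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("n1", "c1")))
#' GenotypeMatrix(m, normalCells = "n1")
#' @export
GenotypeMatrix <- function(calls, normalCells = character()) {
  if (is.data.frame(calls)) calls <- as.matrix(calls)
  calls[is.na(calls)] <- "MISSING"
  new("GenotypeMatrix", calls = calls,
      normalCells = as.character(normalCells))
}

#' AncestryAnnotation: per-cell genetic ancestry labels
#'
#' Maps every cell to one label. Ordinary labels name genetic ancestries
#' (groups of genetically similar cells, a proxy for tumor clones); the two
#' special labels are \code{"normal"} (non-cancerous cells) and
#' \code{"unassigned"} (cells outside every selected clade).
#'
#' @slot labels named character vector: names are cell IDs, values labels.
#' @slot provenance character scalar describing where the annotation came
#'   from (tree or file of origin); free text.
#'
#' @seealso \code{\link{balancedAnnotation}},
#'   \code{\link{unbalancedAnnotation}}, \code{\link{readAnnotation}}
#' @exportClass AncestryAnnotation
setClass("AncestryAnnotation",
  representation(labels = "character", provenance = "character"))

setValidity("AncestryAnnotation", function(object) {
  lab <- object@labels
  if (is.null(names(lab)) || any(!nzchar(names(lab))))
    return("every label must be named by a cell ID")
  if (anyDuplicated(names(lab)))
    return("each cell must carry exactly one label")
  if (!any(!(lab %in% SPECIAL_LABELS)))
    return("at least one non-special ancestry label is required")
  if (length(object@provenance) != 1L)
    return("'provenance' must be a single string")
  TRUE
})

#' Construct an AncestryAnnotation
#'
#' @param labels named character vector (cell ID -> label).
#' @param provenance single string recording the source (default "manual").
#' @return An \code{\linkS4class{AncestryAnnotation}}.
#' @examples
#' AncestryAnnotation(c(c1 = "ancestry_1", c2 = "ancestry_1",
#'                      c3 = "ancestry_2", n1 = "normal"))
#' @export
AncestryAnnotation <- function(labels, provenance = "manual") {
  new("AncestryAnnotation", labels = labels,
      provenance = as.character(provenance))
}

#' BetaEstimate: maximum-likelihood fit of the beta-splitting model
#'
#' Result of \code{\link{treeBalance}}: the MLE of Aldous' beta parameter for
#' a rooted binary tree, its log-likelihood, and the derived shape class.
#' Trees with \code{betaHat} below the threshold (default -1.5, the PDA
#' model) are called \code{"unbalanced"}; otherwise \code{"balanced"}
#' (Yule-like).
#'
#' @slot betaHat numeric, the MLE (within the search bounds, beta > -2).
#' @slot logLik numeric, log-likelihood at the MLE.
#' @slot shape \code{"balanced"} or \code{"unbalanced"}.
#' @slot threshold numeric classification threshold.
#' @slot atBound logical, TRUE when the MLE sits within 1e-3 of a search
#'   bound (the likelihood is monotone over the interval).
#' @slot bounds numeric length-2 search interval.
#' @slot nTips integer number of tips used.
#' @exportClass BetaEstimate
setClass("BetaEstimate",
  representation(betaHat = "numeric", logLik = "numeric", shape = "character",
                 threshold = "numeric", atBound = "logical",
                 bounds = "numeric", nTips = "integer"))

setValidity("BetaEstimate", function(object) {
  if (!object@shape %in% c("balanced", "unbalanced"))
    return("shape must be 'balanced' or 'unbalanced'")
  want <- if (object@betaHat < object@threshold) "unbalanced" else "balanced"
  if (object@shape != want)
    return("shape inconsistent with betaHat and threshold")
  TRUE
})

#' StateAssignment: expression states and pseudotime for one gene scale
#'
#' Per-cell expression state and pseudotime from the deterministic
#' trajectory (principal components + minimum spanning tree) built by
#' \code{\link{buildTrajectory}}. The designated root cell (normally a
#' non-cancerous cell) has pseudotime zero; states are maximal unbranched
#' segments of the spanning tree, numbered 1..K by increasing mean
#' pseudotime.
#'
#' @slot states named integer vector, cell ID -> state (>= 1).
#' @slot pseudotime named numeric vector, cell ID -> distance from the root
#'   along the spanning tree.
#' @slot rootCell character scalar, the root cell ID.
#' @slot geneScale integer, number of genes the trajectory was built on.
#' @slot coordinates numeric matrix (cells x dims) of the reduced-dimension
#'   embedding, for plotting.
#' @slot mstEdges data.frame with columns \code{from}, \code{to},
#'   \code{length}: the spanning-tree edges directed away from the root.
#' @exportClass StateAssignment
setClass("StateAssignment",
  representation(states = "integer", pseudotime = "numeric",
                 rootCell = "character", geneScale = "integer",
                 coordinates = "matrix", mstEdges = "data.frame"))

setValidity("StateAssignment", function(object) {
  if (!identical(sort(names(object@states)), sort(names(object@pseudotime))))
    return("states and pseudotime must cover the same cells")
  if (!object@rootCell %in% names(object@states))
    return("root cell missing from the assignment")
  if (abs(object@pseudotime[[object@rootCell]]) > 1e-12)
    return("root cell must have pseudotime 0")
  if (length(object@states) && min(object@states) < 1L)
    return("state IDs must be >= 1")
  if (any(object@pseudotime < 0)) return("pseudotime must be >= 0")
  TRUE
})

#' ConcordanceReport: SCI and OCI across gene scales and annotations
#'
#' Summary of a trajectory sweep (\code{\link{phyloTrajectory}}): for every
#' (annotation, gene scale) pair, the per-ancestry sub-concordance index
#' (SCI; number of expression states composed of more than a fraction
#' \code{u} of that ancestry's cells) and the overall concordance index
#' (OCI; fraction of all states unique to a single ancestry).
#'
#' @slot sci data.frame with columns \code{annotation}, \code{scale},
#'   \code{ancestry}, \code{sci}.
#' @slot oci data.frame with columns \code{annotation}, \code{scale},
#'   \code{oci}, \code{nStates}, \code{nUnique}.
#' @slot u numeric uniqueness threshold (strict, default 0.8).
#' @slot scales numeric vector of gene scales used.
#' @exportClass ConcordanceReport
setClass("ConcordanceReport",
  representation(sci = "data.frame", oci = "data.frame", u = "numeric",
                 scales = "numeric"))

setValidity("ConcordanceReport", function(object) {
  need <- c("annotation", "scale", "ancestry", "sci")
  if (!all(need %in% names(object@sci)))
    return("sci table must have annotation/scale/ancestry/sci columns")
  need <- c("annotation", "scale", "oci", "nStates", "nUnique")
  if (!all(need %in% names(object@oci)))
    return("oci table must have annotation/scale/oci/nStates/nUnique columns")
  with(object@oci,
       if (any(abs(oci - nUnique / nStates) > 1e-9))
         return("oci must equal nUnique / nStates"))
  TRUE
})

#' ClonalSim: a simulated tumor with known ground truth
#'
#' Container returned by \code{\link{simulateTumor}}: a coupled cell
#' phylogeny, genotype matrix and expression matrix generated from one seed,
#' together with the true ancestry and true expression program of every
#' cell. The true program differs from the ancestry only for cells subject
#' to convergent expression evolution.
#'
#' @slot tree an \code{ape} \code{phylo} object (rooted, binary, tips =
#'   cells).
#' @slot ancestry named character vector: true ancestry label per cell
#'   (including \code{"normal"}).
#' @slot programs named character vector: true expression program per cell.
#' @slot signalGenes named list: ancestry label -> character vector of the
#'   genes its program up-shifts.
#' @slot genotypes \code{\linkS4class{GenotypeMatrix}}.
#' @slot expression numeric matrix, genes x cells.
#' @slot params list of the generator parameters (including the seed).
#' @exportClass ClonalSim
setClass("ClonalSim",
  representation(tree = "ANY", ancestry = "character", programs = "character",
                 signalGenes = "list", genotypes = "GenotypeMatrix",
                 expression = "matrix", params = "list"))

setValidity("ClonalSim", function(object) {
  if (!inherits(object@tree, "phylo")) return("tree must be a 'phylo' object")
  if (!setequal(object@tree$tip.label, names(object@ancestry)))
    return("ancestry must label exactly the tree tips")
  if (!setequal(names(object@programs), names(object@ancestry)))
    return("programs must cover the same cells as ancestry")
  TRUE
})
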