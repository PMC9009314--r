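#' Accessor generics
#'
#' Small accessor generics for the package's S4 classes: \code{cells} and
#' \code{sites} return identifiers, \code{calls} the genotype call matrix,
#' \code{normalCells} the designated normal cells, \code{ancestryLabels} the
#' named label vector, \code{provenance} the annotation source tag,
#' \code{betaHat} / \code{treeShape} the beta-splitting estimate and shape
#' class, \code{cellStates} / \code{pseudotime} the per-cell trajectory
#' results, and \code{sciTable} / \code{ociTable} the concordance tables.
#'
#' @param x an object of the matching class.
#' @return See the individual class documentation.
#' @name accessors
#' @aliases cells sites calls normalCells ancestryLabels provenance betaHat
#'   treeShape cellStates pseudotime sciTable ociTable
NULL

#' @rdname accessors
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))

#' @rdname accessors
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))

#' @rdname accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname accessors
#' @export
setGeneric("normalCells", function(x) standardGeneric("normalCells"))

#' @rdname accessors
#' @export
setGeneric("ancestryLabels", function(x) standardGeneric("ancestryLabels"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("betaHat", function(x) standardGeneric("betaHat"))

#' @rdname accessors
#' @export
setGeneric("treeShape", function(x) standardGeneric("treeShape"))

#' @rdname accessors
#' @export
setGeneric("cellStates", function(x) standardGeneric("cellStates"))

#' @rdname accessors
#' @export
setGeneric("pseudotime", function(x) standardGeneric("pseudotime"))

#' @rdname accessors
#' @export
setGeneric("sciTable", function(x) standardGeneric("sciTable"))

#' @rdname accessors
#' @export
setGeneric("ociTable", function(x) standardGeneric("ociTable"))

setMethod("cells", "GenotypeMatrix", function(x) colnames(x@calls))
setMethod("sites", "GenotypeMatrix", function(x) rownames(x@calls))
setMethod("calls", "GenotypeMatrix", function(x) x@calls)
setMethod("normalCells", "GenotypeMatrix", function(x) x@normalCells)

setMethod("cells", "AncestryAnnotation", function(x) names(x@labels))
setMethod("ancestryLabels", "AncestryAnnotation", function(x) x@labels)
setMethod("provenance", "AncestryAnnotation", function(x) x@provenance)

setMethod("betaHat", "BetaEstimate", function(x) x@betaHat)
setMethod("treeShape", "BetaEstimate", function(x) x@shape)

setMethod("cells", "StateAssignment", function(x) names(x@states))
setMethod("cellStates", "StateAssignment", function(x) x@states)
setMethod("pseudotime", "StateAssignment", function(x) x@pseudotime)

setMethod("sciTable", "ConcordanceReport", function(x) x@sci)
setMethod("ociTable", "ConcordanceReport", function(x) x@oci)

setMethod("show", "GenotypeMatrix", function(object) {
  cat(sprintf("GenotypeMatrix: %d sites x %d cells (%d normal)\n",
              nrow(object@calls), ncol(object@calls),
              length(object@normalCells)))
  tab <- table(factor(object@calls, levels = GENOTYPE_CALLS))
  cat("  calls:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
})

setMethod("show", "AncestryAnnotation", function(object) {
  tab <- sort(table(object@labels), decreasing = TRUE)
  cat(sprintf("AncestryAnnotation: %d cells [%s]\n", length(object@labels),
              object@provenance))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n",
      sep = "")
})

setMethod("show", "BetaEstimate", function(object) {
  cat(sprintf(
    "Beta-splitting estimate: beta = %.4f (%s tree; threshold %.2f)%s\n",
    object@betaHat, object@shape, object@threshold,
    if (object@atBound) " [at search bound]" else ""))
  cat(sprintf("  log-likelihood %.4f on %d tips\n", object@logLik,
              object@nTips))
  cat(sprintf("  suggested annotation: %sAnnotation()\n",
              if (object@shape == "balanced") "balanced" else "unbalanced"))
})

setMethod("show", "StateAssignment", function(object) {
  tab <- table(object@states)
  cat(sprintf(
    "StateAssignment: %d cells, %d state(s), gene scale %d, root '%s'\n",
    length(object@states), length(tab), object@geneScale, object@rootCell))
  cat("  state sizes:", paste(tab, collapse = ", "), "\n")
})

setMethod("show", "ConcordanceReport", function(object) {
  cat(sprintf(
    "ConcordanceReport: %d annotation(s), %d gene scale(s), u = %.2f\n",
    length(unique(object@oci$annotation)), length(object@scales), object@u))
  print(object@oci, row.names = FALSE)
})

setMethod("show", "ClonalSim", function(object) {
  p <- object@params
  cat(sprintf(
    "ClonalSim: %d cells (%d normal), %d ancestries, %s tree\n",
    length(object@ancestry), sum(object@ancestry == "normal"),
    length(setdiff(unique(object@ancestry), "normal")), p$treeMode))
  cat(sprintf("  %d SNV sites, %d genes (%d with ancestry signal), seed %s\n",
              nrow(object@genotypes@calls), nrow(object@expression),
              length(unlist(object@signalGenes)),
              format(p$seed)))
})
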