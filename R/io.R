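#' Read a rooted cell phylogeny from Newick text
#'
#' Parses a Newick string or file via \code{ape} and validates it as a cell
#' phylogeny: tips must carry unique, non-empty cell identifiers. Trees
#' written without branch lengths (e.g. mutation-tree output that carries
#' topology only) are given unit lengths on every edge so that patristic
#' distances degrade gracefully to node-count distances.
#'
#' @param x a Newick string, or the path of a file containing one tree.
#' @return An \code{ape} \code{phylo} object with branch lengths.
#' @examples
#' tr <- readNewick("((A:1,B:1):1,(C:1,D:1):1);")
#' tr$tip.label
#' @export
readNewick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  parseProblem <- character()
  tr <- withCallingHandlers(
    tryCatch(if (file.exists(x) && !grepl("\\(", x))
               ape::read.tree(file = x) else ape::read.tree(text = x),
             error = function(e) {
               parseProblem <<- conditionMessage(e)
               NULL
             }),
    warning = function(w) {
      parseProblem <<- c(parseProblem, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (is.null(tr))
    stop("Newick parse failure: ",
         if (length(parseProblem)) paste(parseProblem, collapse = "; ")
         else "no tree found", call. = FALSE)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  validateTree(tr)
}

validateTree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylogenetic tree", call. = FALSE)
  if (any(!nzchar(tr$tip.label)))
    stop("validation error: empty tip label", call. = FALSE)
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup))
    stop("validation error: duplicate tip label(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(1, nrow(tr$edge))
  } else if (any(is.na(tr$edge.length)) || any(tr$edge.length < 0)) {
    stop("validation error: branch lengths must all be present and >= 0",
         call. = FALSE)
  }
  tr
}

#' Write a phylogeny as Newick
#'
#' @param tree a \code{phylo} object.
#' @param file output path, or \code{""} to return the Newick string.
#' @return The Newick string, invisibly when written to a file.
#' @export
writeNewick <- function(tree, file = "") {
  out <- ape::write.tree(tree, file = file)
  if (nzchar(file)) invisible(readLines(file, n = 1L)) else out
}

#' Read and write genotype-call matrices
#'
#' The genotype TSV dialect is: a header row of cell IDs, a first column of
#' site IDs, and calls written as the symbols \code{REF}, \code{ALT},
#' \code{HET} or \code{NA} (missing). \code{readGenotypeMatrix} converts
#' \code{NA} to the internal \code{MISSING} call.
#'
#' @param file path of the TSV file.
#' @param normalCells character vector of normal cell IDs.
#' @return \code{readGenotypeMatrix}: a
#'   \code{\linkS4class{GenotypeMatrix}}; \code{writeGenotypeMatrix}: the
#'   file path, invisibly.
#' @export
readGenotypeMatrix <- function(file, normalCells = character()) {
  df <- utils::read.delim(file, header = TRUE, row.names = 1L,
                          check.names = FALSE, colClasses = "character",
                          na.strings = character())
  m <- as.matrix(df)
  m[m == "NA" | m == ""] <- "MISSING"
  GenotypeMatrix(m, normalCells = normalCells)
}

#' @rdname readGenotypeMatrix
#' @param g a \code{GenotypeMatrix}.
#' @export
writeGenotypeMatrix <- function(g, file) {
  m <- calls(g)
  m[m == "MISSING"] <- "NA"
  df <- data.frame(site = rownames(m), m, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a normalized expression matrix
#'
#' Accepts either a TSV (genes in rows with a leading gene-ID column, cells
#' in columns) or a MatrixMarket file with companion one-column text files
#' listing the gene and cell identifiers.
#'
#' @param file path of the TSV or \code{.mtx} file.
#' @param genesFile,cellsFile for MatrixMarket input, the companion files of
#'   gene and cell IDs (one per line).
#' @return A numeric matrix, genes x cells.
#' @export
readExpressionMatrix <- function(file, genesFile = NULL, cellsFile = NULL) {
  if (grepl("\\.mtx$", file, ignore.case = TRUE)) {
    if (is.null(genesFile) || is.null(cellsFile))
      stop("MatrixMarket input needs 'genesFile' and 'cellsFile'",
           call. = FALSE)
    m <- as.matrix(Matrix::readMM(file))
    rownames(m) <- readLines(genesFile)
    colnames(m) <- readLines(cellsFile)
  } else {
    m <- as.matrix(utils::read.delim(file, header = TRUE, row.names = 1L,
                                     check.names = FALSE))
  }
  storage.mode(m) <- "double"
  if (anyDuplicated(rownames(m)))
    stop("validation error: duplicate gene IDs", call. = FALSE)
  m
}

#' @rdname readExpressionMatrix
#' @param expr numeric matrix, genes x cells.
#' @export
writeExpressionMatrix <- function(expr, file) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read and write ancestry annotations
#'
#' The annotation format is a two-column TSV, \code{cell<TAB>label}, with a
#' header line. Annotation files are round-trippable so that automatic
#' annotations can be manually edited and re-loaded for expert refinement.
#'
#' @param file path of the TSV file.
#' @param provenance source tag to record (defaults to the file name).
#' @return \code{readAnnotation}: an
#'   \code{\linkS4class{AncestryAnnotation}}; \code{writeAnnotation}: the
#'   file path, invisibly.
#' @export
readAnnotation <- function(file, provenance = basename(file)) {
  df <- utils::read.delim(file, header = TRUE, colClasses = "character")
  if (ncol(df) < 2L)
    stop("annotation file must have two columns: cell<TAB>label",
         call. = FALSE)
  AncestryAnnotation(stats::setNames(df[[2L]], df[[1L]]),
                     provenance = provenance)
}

#' @rdname readAnnotation
#' @param ann an \code{AncestryAnnotation}.
#' @export
writeAnnotation <- function(ann, file) {
  df <- data.frame(cell = cells(ann), label = unname(ancestryLabels(ann)))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Quality-filter SNV sites against the normal cells
#'
#' Removes sites that cannot be trusted as somatic markers: a site is
#' dropped when (a) every normal cell is \code{MISSING} there, (b) the
#' non-missing normal calls disagree with each other, (c) the normal
#' consensus is \code{HET} or \code{ALT} (potential germline
#' heterozygosity), or (d) the fraction of non-missing calls across all
#' cells falls below \code{completenessCutoff}. Site order is preserved and
#' the filter is idempotent.
#'
#' @param g a \code{\linkS4class{GenotypeMatrix}} with at least one normal
#'   cell designated.
#' @param completenessCutoff required fraction of unambiguous (non-missing)
#'   base assignments among all cells, in (0, 1]. Default 0.7.
#' @return The filtered \code{GenotypeMatrix}.
#' @examples
#' m <- matrix(c("REF","REF","ALT","MISSING",
#'               "MISSING","MISSING","ALT","REF"), 2, 4, byrow = TRUE,
#'             dimnames = list(c("s1","s2"), c("n1","n2","c1","c2")))
#' g <- GenotypeMatrix(m, normalCells = c("n1","n2"))
#' sites(filterSNVs(g, 0.5))   # s2 dropped: all normals missing
#' @export
filterSNVs <- function(g, completenessCutoff = 0.7) {
  stopifnot(is(g, "GenotypeMatrix"),
            completenessCutoff > 0, completenessCutoff <= 1)
  nrm <- normalCells(g)
  if (!length(nrm))
    stop("configuration error: no normal cells designated", call. = FALSE)
  m <- calls(g)
  keep <- vapply(seq_len(nrow(m)), function(i) {
    nc <- m[i, nrm]
    obs <- nc[nc != "MISSING"]
    if (!length(obs)) return(FALSE)                 # (a) normals all missing
    if (length(unique(obs)) > 1L) return(FALSE)     # (b) normals disagree
    if (obs[1L] != "REF") return(FALSE)             # (c) consensus HET/ALT
    mean(m[i, ] != "MISSING") >= completenessCutoff # (d) completeness
  }, logical(1L))
  GenotypeMatrix(m[keep, , drop = FALSE], normalCells = nrm)
}

#' Remove low-quality cells from a genotype matrix
#'
#' Excludes cells whose fraction of missing SNV calls is strictly greater
#' than \code{maxMissingFraction} (default 0.5, i.e. cells with >50\%
#' missing sites). The normal-cell set is updated accordingly; cell order is
#' preserved.
#'
#' @param g a \code{\linkS4class{GenotypeMatrix}} with at least one site.
#' @param maxMissingFraction maximum tolerated missing fraction per cell.
#' @return The filtered \code{GenotypeMatrix}.
#' @export
filterCells <- function(g, maxMissingFraction = 0.5) {
  stopifnot(is(g, "GenotypeMatrix"))
  m <- calls(g)
  if (nrow(m) == 0L)
    stop("filterCells needs at least one site", call. = FALSE)
  frac <- colMeans(m == "MISSING")
  keep <- frac <= maxMissingFraction
  if (!any(keep))
    stop("empty result: every cell exceeds the missing-data threshold",
         call. = FALSE)
  GenotypeMatrix(m[, keep, drop = FALSE],
                 normalCells = intersect(normalCells(g), colnames(m)[keep]))
}
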