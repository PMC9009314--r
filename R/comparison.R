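#' Contingency table of two ancestry annotations
#'
#' Cross-tabulates the ancestry labels of the cells shared by two
#' annotations. Cells labelled \code{"normal"} or \code{"unassigned"} are
#' not genetic ancestries and are excluded by default; rows and columns
#' whose counts are all zero are dropped.
#'
#' @param a,b \code{\linkS4class{AncestryAnnotation}} objects sharing at
#'   least two cells.
#' @param includeSpecial include \code{normal}/\code{unassigned} labels
#'   (default FALSE).
#' @return A base \code{table}, rows = labels of \code{a}, columns = labels
#'   of \code{b}.
#' @export
buildContingency <- function(a, b, includeSpecial = FALSE) {
  la <- ancestryLabels(a); lb <- ancestryLabels(b)
  shared <- intersect(names(la), names(lb))
  if (!includeSpecial)
    shared <- shared[!(la[shared] %in% SPECIAL_LABELS) &
                     !(lb[shared] %in% SPECIAL_LABELS)]
  if (length(shared) < 2L)
    stop("degenerate table: fewer than 2 shared (non-special) cells",
         call. = FALSE)
  tab <- table(la[shared], lb[shared])
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("degenerate table: fewer than 2 distinct labels on an axis",
         call. = FALSE)
  tab
}

#' Agreement statistics for an ancestry contingency table
#'
#' Pearson chi-square test of independence (no continuity correction, no
#' simulation) and the Cramer's V effect size,
#' V = sqrt(chi2 / (n * (min(r, c) - 1))). Agreement between two
#' annotations is considered supported when V > 0.2 and p < 0.01. A warning
#' is emitted when any expected count falls below 5 (the asymptotic p-value
#' is then unreliable).
#'
#' @param tab a contingency table (matrix of counts) with at least two rows
#'   and columns and no all-zero margin.
#' @return A list with elements \code{cramersV}, \code{chi2}, \code{dof},
#'   \code{pValue}, \code{n} and logical \code{supported}.
#' @examples
#' agreementStat(matrix(c(8, 2, 2, 8), 2))  # chi2 = 7.2, V = 0.6
#' @export
agreementStat <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("degenerate table: need at least a 2x2 table", call. = FALSE)
  n <- sum(tab)
  if (n < 2L) stop("degenerate table: fewer than 2 cells", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected == 0))
    stop("degenerate table: an all-zero margin gives expected count 0",
         call. = FALSE)
  if (any(expected < 5))
    warning("expected count < 5 in the contingency table; ",
            "chi-square p-value is approximate")
  chi2 <- sum((tab - expected)^2 / expected)
  dof <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  p <- stats::pchisq(chi2, dof, lower.tail = FALSE)
  v <- sqrt(chi2 / (n * (min(dim(tab)) - 1L)))
  list(cramersV = v, chi2 = chi2, dof = dof, pValue = p, n = n,
       supported = v > 0.2 && p < 0.01)
}

# exact maximum-overlap one-to-one matching of column labels onto row
# labels of a contingency table; exhaustive for small label counts, greedy
# beyond that. Returns named character: column label -> row label (NA when
# unmatched).
matchLabels <- function(tab) {
  r <- nrow(tab); c <- ncol(tab)
  if (min(r, c) <= 8L) {
    if (c <= r) {
      perms <- permutations(r, c)
      scores <- apply(perms, 1L, function(p)
        sum(tab[cbind(p, seq_len(c))]))
      p <- perms[which.max(scores), ]
      stats::setNames(rownames(tab)[p], colnames(tab))
    } else {
      perms <- permutations(c, r)
      scores <- apply(perms, 1L, function(p)
        sum(tab[cbind(seq_len(r), p)]))
      p <- perms[which.max(scores), ]
      out <- stats::setNames(rep(NA_character_, c), colnames(tab))
      out[colnames(tab)[p]] <- rownames(tab)
      out
    }
  } else {
    out <- stats::setNames(rep(NA_character_, c), colnames(tab))
    t2 <- tab
    for (k in seq_len(min(r, c))) {
      ij <- which(t2 == max(t2), arr.ind = TRUE)[1L, ]
      out[colnames(tab)[ij[2L]]] <- rownames(tab)[ij[1L]]
      t2[ij[1L], ] <- -1; t2[, ij[2L]] <- -1
    }
    out
  }
}

# all ordered selections of k elements out of 1..n (rows of a matrix)
permutations <- function(n, k) {
  if (k == 0L) return(matrix(integer(0), 1L, 0L))
  sub <- permutations(n, k - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    keep <- sub[rowSums(sub == i) == 0L, , drop = FALSE]
    cbind(i, keep, deparse.level = 0)
  }))
}

#' Align one annotation's ancestry labels onto another's
#'
#' Ancestry labels are arbitrary (\code{ancestry_1} from one phylogeny need
#' not be \code{ancestry_1} from another): this renames the labels of
#' \code{b} by the maximum-overlap one-to-one matching against the labels
#' of \code{a} on their contingency table. Special labels
#' (\code{normal}, \code{unassigned}) map to themselves; labels of \code{b}
#' without a partner keep their name with the annotation's provenance
#' appended.
#'
#' @param a the reference \code{\linkS4class{AncestryAnnotation}}.
#' @param b the annotation to rename.
#' @return \code{b} with relabelled ancestries.
#' @export
alignLabels <- function(a, b) {
  tab <- buildContingency(a, b)
  mapping <- matchLabels(tab)  # b labels -> a labels
  lb <- ancestryLabels(b)
  out <- lb
  for (lab in unique(lb)) {
    if (lab %in% SPECIAL_LABELS) next
    tgt <- if (lab %in% names(mapping)) mapping[[lab]] else NA_character_
    out[lb == lab] <- if (is.na(tgt))
      paste0(lab, ".", provenance(b)) else tgt
  }
  AncestryAnnotation(out, provenance = provenance(b))
}

#' Consensus of several ancestry annotations
#'
#' Aligns the labels of every annotation to the first one (maximum-overlap
#' one-to-one matching on the pairwise contingency table) and then takes,
#' for each cell, the majority label across the aligned annotations. Ties
#' give \code{"unassigned"}; cells absent from some annotations are voted
#' on by those that include them.
#'
#' @param annotations list of at least two
#'   \code{\linkS4class{AncestryAnnotation}} objects; all must share cells
#'   with the first.
#' @return An \code{\linkS4class{AncestryAnnotation}} with provenance
#'   \code{"consensus"}.
#' @export
consensusAnnotation <- function(annotations) {
  stopifnot(length(annotations) >= 2L)
  ref <- annotations[[1L]]
  aligned <- c(list(ref), lapply(annotations[-1L], function(b) {
    ok <- length(intersect(cells(ref), cells(b))) > 0L
    if (!ok)
      stop("alignment error: annotation '", provenance(b),
           "' shares no cells with the reference", call. = FALSE)
    alignLabels(ref, b)
  }))
  allCells <- sort(unique(unlist(lapply(aligned, cells))))
  votes <- vapply(allCells, function(cc) {
    v <- unlist(lapply(aligned, function(ann) {
      l <- ancestryLabels(ann)
      if (cc %in% names(l)) l[[cc]] else NULL
    }))
    tab <- sort(table(v), decreasing = TRUE)
    if (length(tab) > 1L && tab[1L] == tab[2L]) "unassigned"
    else names(tab)[1L]
  }, character(1L))
  AncestryAnnotation(stats::setNames(votes, allCells),
                     provenance = "consensus")
}

#' Compare ancestry annotations across phylogenies
#'
#' Pairwise agreement of two or more ancestry annotations, including the
#' consensus annotation: for every pair, the contingency table over shared
#' cells is tested (chi-square) and summarized by Cramer's V. Trajectory
#' analysis downstream is recommended only when annotations agree; a
#' warning is emitted when any pair is unsupported (V <= 0.2 or p >= 0.01).
#'
#' @param annotations list of at least two
#'   \code{\linkS4class{AncestryAnnotation}} objects.
#' @param includeConsensus append the consensus annotation to the
#'   comparison (default TRUE).
#' @return A list with \code{pairs}, a data.frame of pairwise statistics
#'   (columns \code{annotationA}, \code{annotationB}, \code{cramersV},
#'   \code{chi2}, \code{dof}, \code{pValue}, \code{n}, \code{supported}),
#'   and \code{consensus}, the consensus annotation (or NULL).
#' @export
ancestryComparison <- function(annotations, includeConsensus = TRUE) {
  stopifnot(length(annotations) >= 2L)
  cons <- NULL
  if (includeConsensus) {
    cons <- consensusAnnotation(annotations)
    annotations <- c(annotations, list(cons))
  }
  nm <- vapply(annotations, provenance, character(1L))
  nm <- make.unique(nm)
  rows <- list()
  for (i in seq_along(annotations)) for (j in seq_along(annotations)) {
    if (j <= i) next
    st <- agreementStat(buildContingency(annotations[[i]],
                                         annotations[[j]]))
    rows[[length(rows) + 1L]] <- data.frame(
      annotationA = nm[i], annotationB = nm[j], cramersV = st$cramersV,
      chi2 = st$chi2, dof = st$dof, pValue = st$pValue, n = st$n,
      supported = st$supported)
  }
  pairs <- do.call(rbind, rows)
  if (any(!pairs$supported))
    warning("some annotation pairs show no supported agreement ",
            "(V <= 0.2 or p >= 0.01); interpret downstream trajectory ",
            "concordance with caution")
  list(pairs = pairs, consensus = cons)
}

#' Heatmap of aligned ancestry annotations
#'
#' Lays out cells (columns) against annotations plus the consensus (rows),
#' with colors keyed by the aligned ancestry labels; cells are ordered by
#' consensus label and then by cell ID. A companion TSV of the plotted
#' label matrix is written next to the figure when \code{file} is given.
#'
#' @param annotations list of \code{\linkS4class{AncestryAnnotation}}
#'   objects (>= 2).
#' @param consensus optional precomputed consensus; computed internally
#'   when NULL.
#' @param file optional PDF path; a TSV with the same base name is written
#'   alongside.
#' @return Invisibly, a list with the label matrix (\code{matrix}) and the
#'   \code{ggplot} object (\code{plot}).
#' @export
agreementHeatmap <- function(annotations, consensus = NULL, file = NULL) {
  stopifnot(length(annotations) >= 2L)
  if (is.null(consensus)) consensus <- consensusAnnotation(annotations)
  ref <- annotations[[1L]]
  aligned <- c(list(ref), lapply(annotations[-1L], alignLabels, a = ref),
               list(consensus))
  nm <- make.unique(vapply(aligned, provenance, character(1L)))
  cl <- ancestryLabels(consensus)
  ord <- names(cl)[order(cl, names(cl))]
  mat <- do.call(rbind, lapply(aligned, function(ann) {
    l <- ancestryLabels(ann)
    out <- stats::setNames(rep(NA_character_, length(ord)), ord)
    out[intersect(ord, names(l))] <- l[intersect(ord, names(l))]
    out
  }))
  rownames(mat) <- nm
  df <- data.frame(
    annotation = factor(rep(nm, times = ncol(mat)), levels = rev(nm)),
    cell = factor(rep(colnames(mat), each = nrow(mat)), levels = ord),
    label = as.vector(mat))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cell,
                                        y = .data$annotation,
                                        fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "cell (ordered by consensus ancestry)", y = NULL,
                  fill = "ancestry") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
  if (!is.null(file)) {
    grDevices::pdf(file, width = 8, height = 1 + 0.5 * nrow(mat))
    print(p)
    grDevices::dev.off()
    tsv <- sub("\\.pdf$", ".tsv", file)
    utils::write.table(data.frame(annotation = rownames(mat), mat,
                                  check.names = FALSE),
                       tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(matrix = mat, plot = p))
}
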