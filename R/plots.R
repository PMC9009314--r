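#' Plot a phylogeny with genetic ancestries mapped onto the tips
#'
#' Renders the cell phylogeny with tip labels colored by ancestry so the
#' annotation can be confirmed visually before any downstream analysis.
#'
#' @param tree a \code{phylo} object.
#' @param ann an \code{\linkS4class{AncestryAnnotation}} covering the tips.
#' @param file optional PDF path.
#' @param ... further arguments passed to \code{ape::plot.phylo}.
#' @return Invisibly, the named color vector used for the tips.
#' @export
plotAncestryTree <- function(tree, ann, file = NULL, ...) {
  lab <- ancestryLabels(ann)
  tips <- tree$tip.label
  tipLab <- ifelse(tips %in% names(lab), lab[tips], "unassigned")
  lv <- sort(unique(tipLab))
  pal <- stats::setNames(grDevices::hcl.colors(max(3L, length(lv)),
                                               "Dark 3")[seq_along(lv)], lv)
  pal["normal"] <- "grey40"
  pal["unassigned"] <- "grey75"
  cols <- pal[tipLab]
  draw <- function() {
    ape::plot.phylo(tree, tip.color = unname(cols), cex = 0.6,
                    no.margin = TRUE, ...)
    graphics::legend("bottomleft", legend = names(pal)[names(pal) %in% lv],
                     text.col = pal[names(pal) %in% lv], bty = "n",
                     cex = 0.8)
  }
  if (!is.null(file)) {
    grDevices::pdf(file, width = 6,
                   height = max(4, length(tips) * 0.12))
    draw()
    grDevices::dev.off()
  } else {
    draw()
  }
  invisible(stats::setNames(cols, tips))
}
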