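# shared fixtures built in code

# three well-separated clades (sizes per `sizes`), intra-clade edges
# `intra`, backbone edges `inter`; returns list(tree, truth labels)
separatedCladesTree <- function(sizes = c(4, 4, 4), intra = 0.1,
                                inter = 10) {
  ids <- sprintf("c%02d", seq_len(sum(sizes)))
  groups <- rep(seq_along(sizes), sizes)
  cater <- function(tips, len) {
    out <- sprintf("%s:%f", tips[1L], len)
    for (tp in tips[-1L])
      out <- sprintf("(%s,%s:%f):%f", out, tp, len, len)
    out
  }
  clades <- vapply(seq_along(sizes), function(g)
    sprintf("%s:%f", sub(":[0-9.]+$", "", cater(ids[groups == g], intra)),
            inter), character(1L))
  bb <- clades[1L]
  for (g in seq_along(sizes)[-1L])
    bb <- sprintf("(%s,%s):%f", bb, clades[g], inter)
  list(tree = readNewick(paste0(bb, ";")),
       truth = stats::setNames(paste0("ancestry_", groups), ids))
}

# caterpillar with cells labelled c01.., unit branch lengths
caterpillar <- function(n) {
  tr <- ape::stree(n, "left")
  tr$tip.label <- sprintf("c%02d", seq_len(n))
  validateTreeForTest(tr)
}

validateTreeForTest <- function(tr) {
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

# genotype matrix from a compact character spec: rows = sites, entries
# R/A/H/M for REF/ALT/HET/MISSING
gm <- function(rows, cellIds, normalCells = character()) {
  dict <- c(R = "REF", A = "ALT", H = "HET", M = "MISSING")
  m <- do.call(rbind, lapply(rows, function(r)
    dict[strsplit(r, "")[[1L]]]))
  dimnames(m) <- list(sprintf("site_%02d", seq_along(rows)), cellIds)
  GenotypeMatrix(m, normalCells = normalCells)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
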