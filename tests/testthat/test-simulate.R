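test_that("simulated trees are reproducible and classify by mode", {
  a <- simulateTree(nCells = 32, nNormal = 2, treeMode = "unbalanced",
                    seed = 10)
  b <- simulateTree(nCells = 32, nNormal = 2, treeMode = "unbalanced",
                    seed = 10)
  expect_identical(writeNewick(a$tree), writeNewick(b$tree))
  expect_identical(a$ancestry, b$ancestry)
  expect_identical(treeShape(treeBalance(a$tree)), "unbalanced")
  bal <- simulateTree(nCells = 32, nNormal = 2, treeMode = "balanced",
                      seed = 10)
  expect_identical(treeShape(treeBalance(bal$tree)), "balanced")
  expect_error(simulateTree(nCells = 4, nAncestries = 3), "nCells")
})

test_that("noiseless genotypes are tree-compatible and normals all-REF", {
  fx <- simulateTree(nCells = 20, nNormal = 2, seed = 5)
  g <- simulateGenotypes(fx$tree, fx$ancestry, nSites = 80, fnRate = 0,
                         missingRate = 0, seed = 5)
  m <- calls(g)
  expect_true(all(m %in% c("REF", "ALT")))
  expect_true(all(m[, normalCells(g)] == "REF"))
  # perfect-data sites are nested or disjoint (no homoplasy): for any two
  # sites the ALT cell sets must not properly overlap
  altSets <- apply(m == "ALT", 1L, which, simplify = FALSE)
  for (i in seq_along(altSets)) for (j in seq_len(i - 1L)) {
    ov <- length(intersect(altSets[[i]], altSets[[j]]))
    expect_true(ov == 0 || ov == length(altSets[[i]]) ||
                  ov == length(altSets[[j]]))
  }
})

test_that("missingness matches the nominal rate and kills all cells at 1", {
  fx <- simulateTree(nCells = 40, nNormal = 2, seed = 6)
  g <- simulateGenotypes(fx$tree, fx$ancestry, nSites = 120,
                         missingRate = 0.4, seed = 6)
  frac <- mean(calls(g) == "MISSING")
  n <- length(calls(g))
  se <- sqrt(0.4 * 0.6 / n)
  expect_lt(abs(frac - 0.4), 3 * se)
  gAll <- simulateGenotypes(fx$tree, fx$ancestry, nSites = 20,
                            missingRate = 1, seed = 6)
  expect_error(filterCells(gAll, 0.5), "empty result")
})

test_that("simulated expression carries ancestry programs", {
  fx <- simulateTree(nCells = 30, nNormal = 2, seed = 7)
  e <- simulateExpression(fx$ancestry, nGenes = 400, nSignalGenes = 60,
                          effectSize = 3, seed = 7)
  expect_identical(dim(e$expression), c(400L, 32L))
  expect_true(all(e$expression >= 0))
  # signal genes of ancestry_1 are high in its cells, background elsewhere
  a1cells <- names(fx$ancestry)[fx$ancestry == "ancestry_1"]
  others <- names(fx$ancestry)[fx$ancestry == "ancestry_3"]
  sg <- e$signalGenes[["ancestry_1"]]
  expect_gt(mean(log(e$expression[sg, a1cells])),
            mean(log(e$expression[sg, others])) + 2)
  # convergence reassigns donor cells to the recipient program
  e2 <- simulateExpression(fx$ancestry, nGenes = 100, nSignalGenes = 30,
                           convergenceFrac = 0.5, seed = 7)
  donors <- names(fx$ancestry)[fx$ancestry == "ancestry_1"]
  conv <- donors[e2$programs[donors] == "ancestry_2"]
  expect_identical(length(conv), as.integer(floor(0.5 * length(donors))))
  expect_true(all(e2$programs[setdiff(names(fx$ancestry), donors)] ==
                    fx$ancestry[setdiff(names(fx$ancestry), donors)]))
})

test_that("null expression shows no differential signal after Bonferroni", {
  sim <- simulateTumor("null", seed = 1)
  ann <- AncestryAnnotation(sim@ancestry, provenance = "truth")
  rk <- rankGenes(sim@expression, ann)
  expect_gte(min(p.adjust(rk$pValue, "bonferroni")), 0.01)
})

test_that("simulateTumor is seed-reproducible and writes readable files", {
  s1 <- simulateTumor("concordant", seed = 4, nCells = 18, nNormal = 1,
                      nGenes = 100, nSignalGenes = 30, nSites = 40)
  s2 <- simulateTumor("concordant", seed = 4, nCells = 18, nNormal = 1,
                      nGenes = 100, nSignalGenes = 30, nSites = 40)
  expect_identical(calls(s1@genotypes), calls(s2@genotypes))
  expect_identical(s1@expression, s2@expression)
  expect_identical(writeNewick(s1@tree), writeNewick(s2@tree))

  d <- withr::local_tempdir()
  writeSimulation(s1, d)
  tr <- readNewick(file.path(d, "tree.nwk"))
  expect_setequal(tr$tip.label, names(s1@ancestry))
  g <- readGenotypeMatrix(file.path(d, "genotypes.tsv"),
                          normalCells = normalCells(s1@genotypes))
  expect_identical(calls(g), calls(s1@genotypes))
  ex <- readExpressionMatrix(file.path(d, "expression.tsv"))
  expect_equal(ex, s1@expression, tolerance = 1e-6)
  truth <- utils::read.delim(file.path(d, "truth.tsv"))
  expect_setequal(truth$cell, names(s1@ancestry))
})

test_that("true ancestries are recovered from the noiseless tree", {
  for (s in 1:5) {
    fx <- simulateTree(nCells = 30, nNormal = 2, seed = s)
    nrm <- names(fx$ancestry)[fx$ancestry == "normal"]
    truth <- fx$ancestry[fx$ancestry != "normal"]
    ann <- balancedAnnotation(fx$tree, 3, minTotalFrac = 0.66,
                              normalCells = nrm)
    expect_equal(ari(ancestryLabels(ann)[names(truth)], truth), 1)
  }
})
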