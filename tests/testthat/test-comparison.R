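mkAnn <- function(labels, ids = sprintf("c%02d", seq_along(labels)),
                  prov = "t") {
  AncestryAnnotation(stats::setNames(labels, ids), provenance = prov)
}

# first-principles chi-square + Cramer's V, independent of agreementStat
chisqOracle <- function(tab) {
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - e)^2 / e)
  list(chi2 = chi2,
       p = pchisq(chi2, (nrow(tab) - 1) * (ncol(tab) - 1),
                  lower.tail = FALSE),
       v = sqrt(chi2 / (n * (min(dim(tab)) - 1))))
}

test_that("contingency tables count shared cells by label pair", {
  a <- mkAnn(rep(c("A1", "A2"), each = 10))
  b <- mkAnn(rep(c("B1", "B2"), each = 10))
  tab <- buildContingency(a, b)
  expect_equal(unclass(tab), matrix(c(10L, 0L, 0L, 10L), 2,
               dimnames = list(c("A1", "A2"), c("B1", "B2"))),
               ignore_attr = TRUE)

  a2 <- mkAnn(c(rep("A1", 8), rep("A2", 2)))
  b2 <- mkAnn(c(rep("B1", 6), rep("B2", 4)))
  expect_equal(as.vector(buildContingency(a2, b2)), c(6, 0, 2, 2))

  disjoint <- mkAnn(rep(c("A1", "A2"), 3), ids = paste0("z", 1:6))
  expect_error(buildContingency(a, disjoint), "shared")
  # normal/unassigned excluded by default
  a3 <- mkAnn(c("A1", "A1", "A2", "A2", "normal", "unassigned"))
  b3 <- mkAnn(c("B1", "B1", "B2", "B2", "B1", "B2"))
  expect_equal(sum(buildContingency(a3, b3)), 4)
  expect_equal(sum(buildContingency(a3, b3, includeSpecial = TRUE)), 6)
})

test_that("agreement statistics match hand-computed examples", {
  st <- suppressWarnings(agreementStat(matrix(c(8, 2, 2, 8), 2)))
  expect_equal(st$chi2, 7.2, tolerance = 1e-12)
  expect_equal(st$cramersV, 0.6, tolerance = 1e-12)
  expect_identical(st$dof, 1L)

  diag <- suppressWarnings(agreementStat(matrix(c(10, 0, 0, 10), 2)))
  expect_equal(diag$cramersV, 1)
  unif <- agreementStat(matrix(5, 2, 2))
  expect_equal(unif$chi2, 0)
  expect_equal(unif$cramersV, 0)
  expect_false(unif$supported)
  expect_error(agreementStat(matrix(c(1, 1, 0, 0), 2, byrow = TRUE)),
               "degenerate|zero")
})

test_that("agreement statistics equal a first-principles oracle and are
          label-permutation invariant", {
  set.seed(9)
  for (k in 1:100) {
    r <- sample(2:4, 1); cc <- sample(2:4, 1)
    tab <- matrix(rpois(r * cc, 8) + 1, r, cc)
    st <- suppressWarnings(agreementStat(tab))
    or <- chisqOracle(tab)
    expect_equal(st$chi2, or$chi2, tolerance = 1e-9)
    expect_equal(st$pValue, or$p, tolerance = 1e-9)
    expect_equal(st$cramersV, or$v, tolerance = 1e-9)
    expect_gte(st$cramersV, 0); expect_lte(st$cramersV, 1)
    perm <- tab[sample(r), sample(cc), drop = FALSE]
    expect_equal(suppressWarnings(agreementStat(perm))$cramersV,
                 st$cramersV, tolerance = 1e-9)
    # cross-check against stats::chisq.test without continuity correction
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(st$chi2, unname(ct$statistic), tolerance = 1e-9)
  }
})

test_that("consensus equals the input under unanimity and absorbs label
          permutations", {
  a <- mkAnn(rep(c("ancestry_1", "ancestry_2"), each = 8), prov = "a")
  expect_identical(ancestryLabels(consensusAnnotation(list(a, a, a))),
                   ancestryLabels(a))
  # same partition, permuted label names
  b <- mkAnn(rep(c("ancestry_2", "ancestry_1"), each = 8), prov = "b")
  cons <- consensusAnnotation(list(a, b))
  expect_identical(ancestryLabels(cons), ancestryLabels(a))
})

test_that("consensus takes cellwise majorities and ties go unassigned", {
  a <- mkAnn(c(rep("A1", 6), rep("A2", 6)), prov = "a")
  lb <- c(rep("A1", 6), rep("A2", 6)); lb[1] <- "A2"
  b <- mkAnn(lb, prov = "b")
  cons <- consensusAnnotation(list(a, b, a))   # 2-of-3 majority for c01
  expect_identical(unname(ancestryLabels(cons)[["c01"]]), "A1")
  cons2 <- consensusAnnotation(list(a, b))     # 1-1 tie for c01
  expect_identical(unname(ancestryLabels(cons2)[["c01"]]), "unassigned")
})

test_that("ancestryComparison reports all pairs including the consensus", {
  a <- mkAnn(rep(c("A1", "A2"), each = 10), prov = "treeA")
  lb <- rep(c("B1", "B2"), each = 10); lb[10] <- "B2"
  b <- mkAnn(lb, prov = "treeB")
  res <- suppressWarnings(ancestryComparison(list(a, b)))
  expect_identical(nrow(res$pairs), 3L)  # A-B, A-consensus, B-consensus
  expect_true(all(res$pairs$cramersV >= 0 & res$pairs$cramersV <= 1))
  expect_s4_class(res$consensus, "AncestryAnnotation")
})

test_that("agreement heatmap lays out one row per annotation + consensus", {
  a <- mkAnn(rep(c("A1", "A2"), each = 5), prov = "a")
  b <- mkAnn(rep(c("B1", "B2"), each = 5), prov = "b")
  d <- withr::local_tempdir()
  out <- agreementHeatmap(list(a, b), file = file.path(d, "h.pdf"))
  expect_identical(dim(out$matrix), c(3L, 10L))
  expect_true(file.exists(file.path(d, "h.pdf")))
  expect_true(file.exists(file.path(d, "h.tsv")))
})
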