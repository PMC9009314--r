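mkStates <- function(states, pt = NULL, root = names(states)[1]) {
  if (is.null(pt))
    pt <- stats::setNames(seq_along(states) - 1, names(states))
  st <- as.integer(states)
  names(st) <- names(states)
  new("StateAssignment", states = st, pseudotime = pt, rootCell = root,
      geneScale = 10L,
      coordinates = matrix(0, length(states), 2,
                           dimnames = list(names(states), NULL)),
      mstEdges = data.frame(from = character(), to = character(),
                            length = numeric()))
}

test_that("Kruskal-Wallis ranking matches stats::kruskal.test", {
  # two clean groups of 5: H = 75/11
  expr <- rbind(gene_a = c(1:5, 6:10), gene_b = rnorm(10, 5))
  colnames(expr) <- sprintf("c%02d", 1:10)
  ann <- AncestryAnnotation(stats::setNames(
    rep(c("ancestry_1", "ancestry_2"), each = 5), colnames(expr)))
  rk <- rankGenes(expr, ann, minCells = 1)
  expect_equal(rk$statistic[rk$gene == "gene_a"], 75 / 11,
               tolerance = 1e-12)
  # oracle on noisy genes with ties
  set.seed(21)
  expr2 <- matrix(sample(0:4, 30 * 12, replace = TRUE), 30, 12,
                  dimnames = list(sprintf("g%02d", 1:30),
                                  sprintf("c%02d", 1:12)))
  ann2 <- AncestryAnnotation(stats::setNames(
    rep(c("ancestry_1", "ancestry_2", "ancestry_3"), each = 4),
    colnames(expr2)))
  rk2 <- rankGenes(expr2, ann2, minCells = 1)
  g <- factor(rep(1:3, each = 4))
  for (gene in sample(rk2$gene, 10)) {
    x <- expr2[gene, ]
    if (all(x == x[1])) next
    expect_equal(rk2$statistic[rk2$gene == gene],
                 unname(kruskal.test(x, g)$statistic), tolerance = 1e-9)
  }
  # constant gene scores 0 and sorts last; equal genes tie-break by ID
  expr3 <- rbind(expr, flat = rep(2, 10))
  rk3 <- rankGenes(expr3, ann, minCells = 1)
  expect_identical(rk3$gene[nrow(rk3)], "flat")
  expect_identical(rk3$statistic[rk3$gene == "flat"], 0)
})

test_that("rankGenes needs two eligible groups and filters rare genes", {
  expr <- matrix(rnorm(20, 5), 4, 5,
                 dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
  ann <- AncestryAnnotation(stats::setNames(
    c(rep("ancestry_1", 4), "ancestry_2"), colnames(expr)))
  expect_error(rankGenes(expr, ann), "2 ancestries")
  expr2 <- matrix(rlnorm(60), 6, 10,
                  dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
  expr2[1, ] <- 0; expr2[1, 1] <- 1   # expressed in 1 cell only
  ann2 <- AncestryAnnotation(stats::setNames(
    rep(c("ancestry_1", "ancestry_2"), each = 5), colnames(expr2)))
  expect_false("g1" %in% rankGenes(expr2, ann2, minCells = 3)$gene)
})

test_that("a collinear expression cloud gives one state rooted at zero", {
  expr <- rbind(g1 = c(0, 1, 2), g2 = c(0, 2, 4))
  colnames(expr) <- c("cA", "cB", "cC")
  st <- buildTrajectory(expr, c("g1", "g2"), "cA")
  expect_identical(unname(cellStates(st)), rep(1L, 3))
  pt <- pseudotime(st)
  expect_identical(unname(pt[["cA"]]), 0)
  expect_true(pt[["cB"]] > 0 && pt[["cC"]] > pt[["cB"]])
  expect_error(buildTrajectory(expr, c("g1", "g2"), "nope"), "root")
})

test_that("a Y-shaped cloud decomposes into three states at the branch", {
  set.seed(4)
  arm <- function(dx, dy, tag) {
    t <- seq(0.5, 10, length.out = 20)
    cbind(t * dx, t * dy) + matrix(rnorm(40, sd = 0.05), 20)
  }
  coords <- rbind(arm(-1, 0), arm(1, 1), arm(1, -1))
  rownames(coords) <- sprintf("c%02d", 1:60)
  # two genes whose expression IS the coordinate pair (plus a constant)
  expr <- rbind(g1 = coords[, 1], g2 = coords[, 2], g3 = rnorm(60, 10))
  colnames(expr) <- rownames(coords)
  root <- rownames(coords)[which.min(coords[, 1])]
  st <- buildTrajectory(expr, c("g1", "g2"), root)
  expect_identical(length(unique(cellStates(st))), 3L)
  # arms map to states coherently (the junction cell itself may join the
  # rootward path, so agreement is near- but not always exactly perfect)
  armId <- rep(1:3, each = 20)
  expect_gt(ari(cellStates(st)[rownames(coords)], armId), 0.85)
})

test_that("pseudotime satisfies the spanning-tree triangle equality", {
  sim <- simulateTumor("concordant", seed = 8, nGenes = 300,
                       nSignalGenes = 60)
  root <- names(sim@ancestry)[sim@ancestry == "normal"][1]
  st <- buildTrajectory(sim@expression, rownames(sim@expression)[1:150],
                        root)
  pt <- pseudotime(st)
  ed <- st@mstEdges
  expect_equal(pt[ed$to], pt[ed$from] + ed$length, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(pt >= 0))
  # deterministic: same input, same result
  st2 <- buildTrajectory(sim@expression, rownames(sim@expression)[1:150],
                         root)
  expect_identical(cellStates(st), cellStates(st2))
  expect_identical(pseudotime(st), pseudotime(st2))
})

test_that("SCI counts states unique to an ancestry (worked example)", {
  # state 4 is >80% ancestry_3; states 1-3 are mixed
  states <- c(rep(1, 10), rep(2, 10), rep(3, 10), rep(4, 10))
  lab <- c(rep(c("ancestry_1", "ancestry_2", "ancestry_3"), c(4, 4, 2)),
           rep(c("ancestry_1", "ancestry_2", "ancestry_3"), c(5, 3, 2)),
           rep(c("ancestry_1", "ancestry_2", "ancestry_3"), c(3, 5, 2)),
           rep(c("ancestry_1", "ancestry_3"), c(1, 9)))
  ids <- sprintf("c%02d", seq_along(states))
  names(states) <- ids
  ann <- AncestryAnnotation(stats::setNames(lab, ids))
  st <- mkStates(states)
  expect_identical(sci(st, ann, "ancestry_3"), 1L)
  expect_identical(sci(st, ann, "ancestry_1"), 0L)
  expect_identical(sci(st, ann, "ancestry_2"), 0L)
  expect_error(sci(st, ann, "ancestry_9"), "unknown ancestry")
  # an ancestry owning two pure states scores 2
  st2 <- mkStates(stats::setNames(rep(1:3, each = 4), sprintf("d%02d", 1:12)))
  ann2 <- AncestryAnnotation(stats::setNames(
    rep(c("ancestry_1", "ancestry_1", "ancestry_2"), each = 4),
    sprintf("d%02d", 1:12)))
  expect_identical(sci(st2, ann2, "ancestry_1"), 2L)
})

test_that("OCI is the fraction of single-ancestry states", {
  # 4 states, exactly one unique -> 0.25
  states <- stats::setNames(rep(1:4, each = 10), sprintf("c%02d", 1:40))
  lab <- c(rep(c("ancestry_1", "ancestry_2"), 15),
           rep("ancestry_1", 10))
  ann <- AncestryAnnotation(stats::setNames(lab, names(states)))
  expect_equal(oci(mkStates(states), ann), 0.25)
  # all mixed -> 0; all pure -> 1
  annMix <- AncestryAnnotation(stats::setNames(
    rep(c("ancestry_1", "ancestry_2"), 20), names(states)))
  expect_equal(oci(mkStates(states), annMix), 0)
  annPure <- AncestryAnnotation(stats::setNames(
    rep(paste0("ancestry_", 1:4), each = 10), names(states)))
  expect_equal(oci(mkStates(states), annPure), 1)
})

test_that("SCI and OCI are invariant to state relabeling and monotone
          non-increasing in the uniqueness threshold", {
  set.seed(14)
  states <- stats::setNames(sample(1:5, 50, replace = TRUE),
                            sprintf("c%02d", 1:50))
  ann <- AncestryAnnotation(stats::setNames(
    sample(paste0("ancestry_", 1:3), 50, replace = TRUE), names(states)))
  st <- mkStates(states)
  relab <- stats::setNames(c(3L, 5L, 1L, 2L, 4L)[states], names(states))
  stR <- mkStates(relab)
  for (a in paste0("ancestry_", 1:3))
    expect_identical(sci(st, ann, a), sci(stR, ann, a))
  expect_equal(oci(st, ann), oci(stR, ann))
  us <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  for (a in paste0("ancestry_", 1:3)) {
    sc <- vapply(us, function(u) sci(st, ann, a, u = u), integer(1))
    expect_true(all(diff(sc) <= 0))
  }
  oc <- vapply(us, function(u) oci(st, ann, u = u), numeric(1))
  expect_true(all(diff(oc) <= 0))
  # with u >= 0.5 a state is unique to at most one ancestry
  tabs <- table(states, ancestryLabels(ann)[names(states)])
  sumSci <- sum(vapply(paste0("ancestry_", 1:3),
                       function(a) sci(st, ann, a), integer(1)))
  frac <- tabs / rowSums(tabs)
  expect_identical(sumSci, sum(apply(frac, 1, max) > 0.8))
})

test_that("the sweep covers the default gene scales once each", {
  sim <- simulateTumor("concordant", seed = 2)
  nrm <- names(sim@ancestry)[sim@ancestry == "normal"]
  truthAnn <- AncestryAnnotation(sim@ancestry, provenance = "truth")
  rep <- phyloTrajectory(sim@expression, truthAnn, nrm[1],
                         scales = c(200, 600, 1000))
  ot <- ociTable(rep)
  expect_identical(ot$scale, c(200, 600, 1000))
  expect_identical(nrow(sciTable(rep)), 9L)  # 3 ancestries x 3 scales
  expect_true(all(ot$nUnique <= ot$nStates))
  expect_equal(ot$oci, ot$nUnique / ot$nStates)
  # scales beyond the rankable genes are truncated with a warning
  expect_warning(
    phyloTrajectory(sim@expression[1:150, ], truthAnn, nrm[1],
                    scales = c(100, 5000)),
    "truncated")
})
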