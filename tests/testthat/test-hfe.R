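test_that("taxon aggregation sums children bottom-up and conserves mass", {
  tr <- tinyTree()
  v <- matrix(c(0.1, 0.3, 0.6,
                0.2, 0.0, 0.8), nrow = 2, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("otu1", "otu2", "otu3")))
  ext <- aggregateTaxa(makeTable(v, normalized = TRUE), tr)
  X <- abundances(ext)
  expect_equal(ncol(X), 3 + 8)  # m + m'
  fam <- "k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__Lachnospiraceae"
  genus <- paste0(fam, ";g__Blautia")
  # genus sums its two OTUs
  expect_equal(unname(X[, genus]), c(0.4, 0.2))
  # family = genus aggregate + incomplete-leaf OTU3
  expect_equal(unname(X[, fam]), c(1.0, 1.0))
  # single-kingdom table: kingdom aggregate is exactly 1 per sample
  expect_equal(unname(X[, "k__Bacteria"]), c(1, 1))
  # OTU columns pass through unchanged
  expect_equal(X[, c("otu1", "otu2", "otu3")], v)
  v2 <- cbind(v * 0.9, stray = c(0.1, 0.1))
  expect_error(aggregateTaxa(makeTable(v2, normalized = TRUE), tr), "stray")
})

test_that("every internal column equals the sum of its OTU descendants", {
  tr <- randomTaxonomy(60, incompleteFraction = 0.3, seed = 9)
  ds <- generateDataset(tr, nSamples = 15, seed = 9)
  X <- abundances(aggregateTaxa(ds$table, tr))
  desc <- taxhfe:::.otuDescendants(tr)
  for (node in sample(tr@nodes$id, 20)) {
    expect_equal(X[, node],
                 rowSums(X[, desc[[node]], drop = FALSE]),
                 tolerance = 1e-9)
  }
})

test_that("correlation filter discards children above theta, strictly", {
  # micro-tree: P under K; otuA and otuC under P; otuB under K
  tr <- buildTaxonomy(c("otuA", "otuB", "otuC"),
                      c(otuA = "k__K; p__P", otuB = "k__K", otuC = "k__K; p__P"))
  X <- cbind(`k__K` = c(1, 2, 3, 4, 10),
             `k__K;p__P` = c(1, 2, 3, 4, 10),  # identical to parent
             otuA = c(1, 2, 3, 4, 0),          # rho = -10/sqrt(500)
             otuB = c(2, 2, 2, 2, 2),          # zero variance
             otuC = c(4, 3, 2, 1, 0))          # strongly anticorrelated
  rownames(X) <- sprintf("S%d", 1:5)
  ext <- makeTable(X, normalized = FALSE)
  res <- correlationFilter(ext, tr, theta = 0.7)
  expect_equal(res$s1, 1)
  expect_setequal(res$retained, c("k__K", "otuA", "otuB", "otuC"))
  expect_equal(unname(res$rho["k__K;p__P"]), 1)
  expect_equal(unname(res$rho["otuA"]), -10 / sqrt(500), tolerance = 1e-12)
  expect_equal(unname(res$rho["otuB"]), 0)  # undefined Pearson -> 0, kept
  expect_lt(res$rho["otuC"], -0.8)
  expect_error(correlationFilter(ext, tr, theta = 0), "theta")
  expect_error(correlationFilter(ext, tr, theta = 1), "theta")
})

test_that("rho equal to theta keeps the child (strict discard rule)", {
  tr <- buildTaxonomy("otuA", c(otuA = "k__K"))
  # craft child with rho exactly 1 against parent, then theta = 1 invalid;
  # instead check boundary via rho < theta kept, rho > theta dropped
  X <- cbind(`k__K` = c(1, 2, 3, 4), otuA = c(1, 2, 3, 4))
  rownames(X) <- sprintf("S%d", 1:4)
  res <- correlationFilter(makeTable(X, normalized = FALSE), tr, theta = 0.99)
  expect_equal(res$s1, 1)   # rho 1 > 0.99
  X2 <- cbind(`k__K` = c(1, 2, 3, 4), otuA = c(1, 2, 4, 3))
  rownames(X2) <- sprintf("S%d", 1:4)
  ext2 <- makeTable(X2, normalized = FALSE)
  rho <- unname(correlationFilter(ext2, tr, theta = 0.5)$rho["otuA"])
  res2 <- correlationFilter(ext2, tr, theta = rho)
  expect_equal(res2$s1, 0)  # rho == theta is kept (strictly-greater rule)
})

test_that("raising theta never increases the discard count", {
  tr <- randomTaxonomy(50, incompleteFraction = 0.2, seed = 21)
  ds <- generateDataset(tr, nSamples = 30, seed = 21)
  ext <- aggregateTaxa(ds$table, tr)
  s1s <- vapply(c(0.3, 0.5, 0.7, 0.9),
                function(th) correlationFilter(ext, tr, th)$s1, numeric(1))
  expect_true(all(diff(s1s) <= 0))
})

# two root-to-leaf paths sharing their upper nodes, with feature columns
# crafted to fixed information gains (weak = 1 - H(0.2) ~ 0.278, strong = 1)
pathFixture <- function(weakIG = FALSE) {
  tr <- buildTaxonomy(c("o1", "o2"),
    c(o1 = "k__K; p__P; c__C; o__O; f__F; g__G1; s__s1",
      o2 = "k__K; p__P; c__C; o__O; f__F; g__G2; s__s2"))
  fam <- "k__K;p__P;c__C;o__O;f__F"
  weak <- splitColumn(40, aLeft = 16, nLeft = 20)
  strong <- splitColumn(40, aLeft = 20, nLeft = 20)
  cols <- list()
  cols[[fam]] <- weak$values
  cols[[paste0(fam, ";g__G1")]] <- if (weakIG) strong$values else weak$values
  cols[["o1"]] <- if (weakIG) strong$values else weak$values
  cols[[paste0(fam, ";g__G2")]] <- strong$values
  cols[["o2"]] <- strong$values
  X <- do.call(cbind, cols)
  rownames(X) <- sprintf("S%02d", 1:40)
  labels <- stats::setNames(weak$labels, rownames(X))
  list(tree = tr, ext = makeTable(X, normalized = FALSE), labels = labels,
       fam = fam, retained = colnames(X))
}

test_that("phase 3 keeps a node that passes the mean on any path through it", {
  fx <- pathFixture(weakIG = FALSE)
  res <- igPathFilter(fx$retained, fx$ext, fx$tree, fx$labels)
  # family is weak but ties the mean on the all-weak G1 path -> kept
  expect_setequal(res$kept, fx$retained)
  expect_equal(res$s2, 0)
  expect_equal(unname(res$ig[fx$fam]), 1 - oracleEntropy(c(rep("A", 16), rep("B", 4))),
               tolerance = 1e-9)

  # make the G1 path strong too: the family now fails on both paths
  fx2 <- pathFixture(weakIG = TRUE)
  res2 <- igPathFilter(fx2$retained, fx2$ext, fx2$tree, fx2$labels)
  expect_setequal(res2$kept, setdiff(fx2$retained, fx2$fam))
  expect_equal(res2$s2, 1)
})

test_that("phase 3 always discards zero-IG nodes and supports global averaging", {
  fx <- pathFixture(weakIG = FALSE)
  # zero out the G1 column: IG 0 -> discarded though it ties the path mean trivially
  X <- abundances(fx$ext)
  g1 <- paste0(fx$fam, ";g__G1")
  X[, g1] <- 0.5
  res <- igPathFilter(colnames(X), makeTable(X, normalized = FALSE),
                      fx$tree, fx$labels)
  expect_false(g1 %in% res$kept)
  # global averaging: one mean across all retained nodes
  resG <- igPathFilter(fx$retained, fx$ext, fx$tree, fx$labels,
                       phase3Average = "global")
  expect_setequal(resG$kept, c(paste0(fx$fam, ";g__G2"), "o2"))
  expect_equal(resG$s2, 3)
})

test_that("phase 4 keeps incomplete leaves at or above the global average IG", {
  ig <- c(x = 0.5, y = 0.2, z = 0)
  res <- igLeafFilter(c("x", "y", "z"), ig, globalAvgIG = 0.5)
  expect_equal(res$final, "x")   # tie with the global average is kept
  expect_equal(res$s3, 2)
  # zero IG is discarded even when the global average is zero
  res0 <- igLeafFilter("z", ig, globalAvgIG = 0)
  expect_equal(res0$s3, 1)
})

test_that("runHFE prunes redundant OTUs and keeps the separating genus", {
  tr <- tinyTree()
  n <- 40
  labels <- stats::setNames(factor(rep(c("A", "B"), each = n / 2)),
                            sprintf("S%02d", 1:n))
  v <- ifelse(labels == "A", 0.6, 0.2)
  X <- cbind(otu1 = v / 2, otu2 = v / 2, otu3 = 1 - v)
  rownames(X) <- names(labels)
  res <- runHFE(makeTable(X, normalized = TRUE), labels, tr)
  genus <- grep("g__Blautia$", tr@nodes$id, value = TRUE)
  expect_true(genus %in% selectedFeatures(res))
  expect_equal(unname(igScores(res)[genus]), 1)
  # the genus's OTUs track its aggregate perfectly -> pruned in phase 2
  expect_false(any(c("otu1", "otu2") %in% selectedFeatures(res)))
})

test_that("count identity and determinism hold on randomized inputs", {
  for (s in 1:6) {
    set.seed(s)
    tr <- randomTaxonomy(sample(10:50, 1),
                         incompleteFraction = runif(1, 0, 0.5), seed = s)
    ds <- generateDataset(tr, nSamples = 2 * sample(5:15, 1),
                          effectSize = sample(c(1, 2, 3), 1), seed = s)
    res <- runHFE(ds$table, ds$labels, tr)
    dc <- discardCounts(res)
    expect_identical(length(selectedFeatures(res)) + sum(dc),
                     nOtus(tr) + nInternalNodes(tr))
    res2 <- runHFE(ds$table, ds$labels, tr)
    expect_identical(selectedFeatures(res), selectedFeatures(res2))
    expect_identical(igScores(res), igScores(res2))
  }
})

test_that("labels independent of all features give a near-empty selection", {
  tr <- randomTaxonomy(80, incompleteFraction = 0.3, seed = 31)
  ds <- generateDataset(tr, nSamples = 60, effectSize = 3, seed = 31)
  set.seed(99)
  perm <- stats::setNames(sample(ds$labels), names(ds$labels))
  res <- runHFE(ds$table, perm, tr)
  expect_lte(length(selectedFeatures(res)),
             0.05 * (nOtus(tr) + nInternalNodes(tr)))
})

test_that("a single-OTU, single-rank tree runs through all phases", {
  tr <- buildTaxonomy("o1", c(o1 = "k__K"))
  labels <- c(S1 = "A", S2 = "B", S3 = "A", S4 = "B")
  X <- matrix(c(1, 1, 1, 1), ncol = 1,
              dimnames = list(names(labels), "o1"))
  res <- runHFE(makeTable(X, normalized = FALSE), labels, tr)
  dc <- discardCounts(res)
  expect_identical(length(selectedFeatures(res)) + sum(dc), 2L)
})
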