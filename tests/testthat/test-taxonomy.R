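test_that("parseLineage handles complete, truncated and placeholder lineages", {
  lin <- parseLineage(paste("k__Bacteria; p__Firmicutes; c__Clostridia;",
                            "o__Clostridiales; f__Lachnospiraceae;",
                            "g__Coprococcus; s__"))
  expect_length(lin$names, 6)
  expect_false(lin$complete)
  expect_equal(unname(lin$names["genus"]), "Coprococcus")

  lin1 <- parseLineage("k__Bacteria")
  expect_length(lin1$names, 1)
  expect_false(lin1$complete)

  full <- parseLineage(tinyLineages()[["otu1"]])
  expect_length(full$names, 7)
  expect_true(full$complete)
})

test_that("parseLineage rejects malformed input by naming the token", {
  expect_error(parseLineage("k__Bacteria; x__Oops"), "x__Oops")
  expect_error(parseLineage("p__Firmicutes; k__Bacteria"), "p__Firmicutes")
  expect_error(parseLineage("k__Bacteria; g__Early"), "g__Early")
  expect_error(parseLineage(""), "empty")
})

test_that("formatLineage round-trips parsed lineages", {
  for (s in c(tinyLineages(),
              "k__Bacteria",
              "k__Bacteria; p__Firmicutes; c__Clostridia")) {
    canonical <- paste(strsplit(s, ";\\s*")[[1]], collapse = "; ")
    expect_identical(formatLineage(parseLineage(s)), canonical)
  }
  # padded placeholders parse back to the same lineage
  padded <- formatLineage(parseLineage("k__Bacteria; p__Firmicutes"), pad = TRUE)
  expect_match(padded, "s__$")
  expect_identical(parseLineage(padded)$names,
                   parseLineage("k__Bacteria; p__Firmicutes")$names)
})

test_that("buildTaxonomy merges shared paths and counts m, m'", {
  # two OTUs with identical complete lineages: one node per rank
  two <- buildTaxonomy(c("a", "b"),
                       c(a = tinyLineages()[["otu1"]],
                         b = tinyLineages()[["otu1"]]))
  expect_equal(nOtus(two), 2)
  expect_equal(nInternalNodes(two), 7)
  expect_equal(length(unique(two@otus$node)), 1)

  tr <- tinyTree()
  expect_equal(nOtus(tr), 3)
  # shared k..f (5) + genus + 2 species = 8 distinct taxa
  expect_equal(nInternalNodes(tr), 8)
  fam <- "k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__Lachnospiraceae"
  # otu3 attaches at the family (leaf in incomplete path)
  expect_equal(tr@otus$node[tr@otus$otu == "otu3"], fam)
  # the family's children are genus Blautia and (via attachment) otu3
  genus <- tr@nodes$id[tr@nodes$parent == fam & !is.na(tr@nodes$parent)]
  expect_equal(genus, paste0(fam, ";g__Blautia"))
  # exhaustive node enumeration on the tiny tree
  expected <- c(
    "k__Bacteria",
    "k__Bacteria;p__Firmicutes",
    "k__Bacteria;p__Firmicutes;c__Clostridia",
    "k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales",
    fam, paste0(fam, ";g__Blautia"),
    paste0(fam, ";g__Blautia;s__producta"),
    paste0(fam, ";g__Blautia;s__obeum"))
  expect_setequal(tr@nodes$id, expected)
})

test_that("buildTaxonomy rejects duplicates and empty input", {
  expect_error(buildTaxonomy(c("a", "a"), c(a = "k__Bacteria")), "duplicate")
  expect_error(buildTaxonomy(character(), list()), "no OTUs")
  expect_error(buildTaxonomy("a", c(b = "k__Bacteria")), "no lineage")
})

test_that("incompleteLeaves returns exactly the truncated OTUs", {
  expect_setequal(incompleteLeaves(tinyTree()), "otu3")
  allComplete <- buildTaxonomy(c("a", "b"),
                               c(a = tinyLineages()[["otu1"]],
                                 b = tinyLineages()[["otu2"]]))
  expect_length(incompleteLeaves(allComplete), 0)
  allKingdom <- buildTaxonomy(c("a", "b"),
                              c(a = "k__Bacteria", b = "k__Archaea"))
  expect_setequal(incompleteLeaves(allKingdom), c("a", "b"))
})

test_that("tree edge and path structure is consistent", {
  for (seed in 1:5) {
    tr <- randomTaxonomy(40, incompleteFraction = 0.3, seed = seed)
    edges <- taxhfe:::.treeEdges(tr)
    nKingdoms <- sum(is.na(tr@nodes$parent))
    # every node except the kingdoms (children of the virtual super-root)
    # is the child of exactly one edge
    expect_equal(nrow(edges), nInternalNodes(tr) + nOtus(tr) - nKingdoms)
    expect_false(anyDuplicated(edges$child) > 0)
    # parent rank above child rank on internal edges
    ri <- function(id) match(tr@nodes$rank[match(id, tr@nodes$id)], TAX_RANKS)
    internal <- edges$child %in% tr@nodes$id
    expect_true(all(ri(edges$parent[internal]) < ri(edges$child[internal])))
    # every incomplete leaf attaches at the rank of its deepest named taxon
    paths <- taxhfe:::.otuPaths(tr)
    for (o in incompleteLeaves(tr)) {
      p <- paths[[o]]
      att <- tr@otus$node[tr@otus$otu == o]
      expect_identical(p[length(p) - 1L], att)
      depth <- length(strsplit(att, ";", fixed = TRUE)[[1]])
      expect_lt(depth, 7)
    }
  }
})
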