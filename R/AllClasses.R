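#' Taxonomic ranks used by the eight-level hierarchy
#'
#' The seven Greengenes ranks from kingdom down to species, plus an
#' eighth "otu" level at the bottom for the OTU features themselves.
#' The vector is ordered from highest to lowest rank.
#'
#' @format Character vector of length 8.
#' @export
TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family",
               "genus", "species", "otu")

#' Greengenes rank prefixes (kingdom..species)
#' @noRd
.RANK_PREFIX <- c(kingdom = "k__", phylum = "p__", class = "c__",
                  order = "o__", family = "f__", genus = "g__",
                  species = "s__")

.rankIndex <- function(rank) match(rank, TAX_RANKS)

#' TaxonomyTree: the eight-level rank hierarchy over OTUs
#'
#' Holds the internal taxon nodes (kingdom through species) parsed from
#' Greengenes-style lineage strings, and the attachment point of every
#' OTU. An OTU whose lineage stops above species level attaches directly
#' under its deepest named taxon ("leaf in an incomplete path"). Node
#' identifiers are the full rank-prefixed path (e.g.
#' `"k__Bacteria;p__Firmicutes"`), which keeps recurring genus names under
#' different families distinct. A virtual super-root above kingdom joins
#' multi-kingdom tables; it is never a feature and is not stored as a node.
#'
#' @slot nodes data.frame with columns `id` (path identifier), `name`
#'   (taxon name, prefix stripped), `rank` (one of [TAX_RANKS] above
#'   "otu") and `parent` (parent node id, `NA` for kingdom nodes).
#' @slot otus data.frame with columns `otu` (OTU identifier), `node`
#'   (attachment node id) and `complete` (TRUE when named to species).
#' @export
setClass("TaxonomyTree", representation(
  nodes = "data.frame",
  otus  = "data.frame"
))

setValidity("TaxonomyTree", function(object) {
  nd <- object@nodes
  ot <- object@otus
  msgs <- character()
  if (!all(c("id", "name", "rank", "parent") %in% names(nd)))
    msgs <- c(msgs, "nodes must have columns id, name, rank, parent")
  if (!all(c("otu", "node", "complete") %in% names(ot)))
    msgs <- c(msgs, "otus must have columns otu, node, complete")
  if (length(msgs)) return(msgs)
  if (anyDuplicated(nd$id)) msgs <- c(msgs, "duplicate node ids")
  if (anyDuplicated(ot$otu)) msgs <- c(msgs, "duplicate OTU ids")
  if (!all(nd$rank %in% TAX_RANKS[1:7]))
    msgs <- c(msgs, "internal node ranks must be kingdom..species")
  hasParent <- !is.na(nd$parent)
  pidx <- match(nd$parent[hasParent], nd$id)
  if (anyNA(pidx)) {
    msgs <- c(msgs, "parent ids must reference existing nodes")
  } else if (any(.rankIndex(nd$rank[pidx]) >= .rankIndex(nd$rank[hasParent]))) {
    msgs <- c(msgs, "parent rank must be above child rank")
  }
  if (!all(ot$node %in% nd$id))
    msgs <- c(msgs, "OTU attachment nodes must exist")
  if (length(msgs)) msgs else TRUE
})

#' AbundanceTable: samples x features abundance matrix
#'
#' Abundances are stored samples-in-rows, features-in-columns (the
#' in-memory orientation of the pipeline; classic OTU tables on disk are
#' OTUs x samples and are transposed once at the I/O boundary). Feature
#' columns are OTU identifiers and, after taxonomic aggregation,
#' internal-taxon path identifiers.
#'
#' @slot values numeric matrix, samples x features, non-negative, with
#'   unique row (sample) and column (feature) names.
#' @slot normalized logical; TRUE when every sample row sums to 1.
#' @slot lineages named character vector of raw lineage strings captured
#'   from an embedded "taxonomy" column (possibly empty).
#' @export
setClass("AbundanceTable", representation(
  values = "matrix",
  normalized = "logical",
  lineages = "character"
))

setValidity("AbundanceTable", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "values must have sample and feature names")
  else {
    if (anyDuplicated(rownames(v))) msgs <- c(msgs, "duplicate sample ids")
    if (anyDuplicated(colnames(v))) msgs <- c(msgs, "duplicate feature ids")
  }
  if (any(v < 0)) msgs <- c(msgs, "negative abundances are not allowed")
  if (isTRUE(object@normalized)) {
    bad <- abs(rowSums(v) - 1) > 1e-9
    if (any(bad))
      msgs <- c(msgs, paste0("normalized table has rows not summing to 1: ",
                             paste(utils::head(rownames(v)[bad], 3),
                                   collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' HFEResult: outcome of the four HFE phases
#'
#' @slot selected character vector of selected feature identifiers (OTU
#'   ids and internal-taxon path ids), in extended-table column order.
#' @slot igScores named numeric vector, information gain in bits for every
#'   selected feature.
#' @slot s1,s2,s3 integer discard counts of the correlation filter
#'   (phase 2), the per-path IG filter (phase 3) and the incomplete-leaf
#'   IG filter (phase 4).
#' @slot theta numeric, the Pearson correlation threshold used.
#' @slot m,mPrime integer, number of OTU features and of internal taxon
#'   nodes; `length(selected) == m + mPrime - s1 - s2 - s3` always holds.
#' @slot phase3Average character, `"per-path"` or `"global"`.
#' @slot globalAvgIG numeric, mean IG of the nodes kept by phase 3 (the
#'   phase-4 threshold).
#' @export
setClass("HFEResult", representation(
  selected = "character",
  igScores = "numeric",
  s1 = "integer", s2 = "integer", s3 = "integer",
  theta = "numeric",
  m = "integer", mPrime = "integer",
  phase3Average = "character",
  globalAvgIG = "numeric"
))

setValidity("HFEResult", function(object) {
  msgs <- character()
  if (length(object@selected) !=
      object@m + object@mPrime - object@s1 - object@s2 - object@s3)
    msgs <- c(msgs, "count identity |selected| = m + m' - s1 - s2 - s3 violated")
  if (!all(object@selected %in% names(object@igScores)))
    msgs <- c(msgs, "every selected feature needs an IG score")
  if (any(object@igScores < -1e-12)) msgs <- c(msgs, "IG scores must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' FoldPlan: stratified cross-validation assignment
#'
#' @slot k integer fold count.
#' @slot assignments named integer vector, sample id -> fold index in 1..k.
#' @slot seed integer seed the plan was drawn with.
#' @slot stratified logical.
#' @export
setClass("FoldPlan", representation(
  k = "integer", assignments = "integer",
  seed = "integer", stratified = "logical"
))

setValidity("FoldPlan", function(object) {
  msgs <- character()
  if (object@k < 2) msgs <- c(msgs, "k must be >= 2")
  if (is.null(names(object@assignments)))
    msgs <- c(msgs, "assignments must be named by sample id")
  if (!all(object@assignments %in% seq_len(object@k)))
    msgs <- c(msgs, "fold indices must lie in 1..k")
  if (length(msgs)) msgs else TRUE
})

#' EvaluationReport: per-fold cross-validation metrics
#'
#' @slot metrics data.frame with one row per fold: `fold`, `auc`,
#'   `precision`, `recall`, `f`, `nFeatures`.
#' @slot selections list of per-fold selected feature id vectors.
#' @slot classifier character, adapter name.
#' @slot theta numeric threshold used (NA in baseline mode).
#' @slot baseline logical; TRUE when selection was disabled (raw OTUs).
#' @export
setClass("EvaluationReport", representation(
  metrics = "data.frame",
  selections = "list",
  classifier = "character",
  theta = "numeric",
  baseline = "logical"
))
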