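#' Phase 1: aggregate OTU abundances up the taxonomy
#'
#' Extends a normalized OTU table with one feature per internal taxon:
#' in a bottom-up traversal every taxon's relative abundance per sample
#' is the sum of its children's, which telescopes to the sum over all
#' its OTU descendants. The feature space grows from m (OTUs) to
#' m + m' (OTUs plus internal nodes); OTU columns are unchanged. In a
#' single-kingdom table the kingdom feature is 1 in every sample.
#'
#' @param table a normalized [AbundanceTable-class] whose features are
#'   exactly the tree's OTUs.
#' @param tree a [TaxonomyTree-class].
#' @return An [AbundanceTable-class] with m + m' features (OTU columns
#'   first, then internal taxa in tree order).
#' @export
aggregateTaxa <- function(table, tree) {
  stopifnot(methods::is(table, "AbundanceTable"),
            methods::is(tree, "TaxonomyTree"))
  if (!isNormalized(table))
    stop("aggregate over relative abundances; call normalizeRelative() first")
  feats <- featureIds(table)
  stray <- setdiff(feats, otuIds(tree))
  if (length(stray))
    stop("table feature(s) not in taxonomy: ",
         paste(utils::head(stray, 3), collapse = ", "))
  miss <- setdiff(otuIds(tree), feats)
  if (length(miss))
    stop("taxonomy OTU(s) missing from table: ",
         paste(utils::head(miss, 3), collapse = ", "))
  X <- abundances(table)
  desc <- .otuDescendants(tree)
  agg <- vapply(desc, function(d) rowSums(X[, d, drop = FALSE]),
                numeric(nrow(X)))
  if (nrow(X) == 1L) agg <- matrix(agg, nrow = 1L,
                                   dimnames = list(rownames(X), names(desc)))
  ext <- cbind(X, agg)
  if (anyDuplicated(colnames(ext)))
    stop("OTU ids collide with taxon path ids")
  methods::new("AbundanceTable", values = ext, normalized = FALSE,
               lineages = table@lineages)
}

#' Phase 2: correlation-based parent-child pruning
#'
#' For every parent-child edge of the taxonomy (child = internal taxon
#' or OTU leaf, parent = its immediate parent), the Pearson correlation
#' between the two feature columns is computed over the given samples.
#' A child whose correlation exceeds `theta` strictly is discarded as
#' redundant with its parent (correlation is a redundancy heuristic
#' here, not a network estimate); `rho == theta` keeps the child. A
#' zero-variance column makes the correlation undefined; it is treated
#' as 0 and the child kept. Kingdom-level nodes hang off the virtual
#' super-root and are never discarded in this phase. Discarded nodes
#' leave the candidate feature set but remain path members for phase 3.
#'
#' @param extended an [AbundanceTable-class] from [aggregateTaxa()].
#' @param tree a [TaxonomyTree-class].
#' @param theta correlation threshold in (0, 1); default 0.7.
#' @param samples optional character vector restricting the computation
#'   to a training subset of samples.
#' @return list with `retained` (feature ids, extended-table order),
#'   `s1` (discard count) and `rho` (named per-edge correlations).
#' @export
correlationFilter <- function(extended, tree, theta = 0.7, samples = NULL) {
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0 || theta >= 1)
    stop("theta must lie strictly between 0 and 1")
  X <- abundances(extended)
  if (!is.null(samples)) X <- X[samples, , drop = FALSE]
  edges <- .treeEdges(tree)
  miss <- setdiff(unique(c(edges$child, edges$parent)), colnames(X))
  if (length(miss))
    stop("extended table lacks feature(s): ",
         paste(utils::head(miss, 3), collapse = ", "))
  n <- nrow(X)
  mu <- colMeans(X)
  sdv <- sqrt(colSums((X - rep(mu, each = n))^2) / (n - 1))
  Z <- (X - rep(mu, each = n)) / rep(ifelse(sdv > 0, sdv, 1), each = n)
  rho <- colSums(Z[, edges$child, drop = FALSE] *
                 Z[, edges$parent, drop = FALSE]) / (n - 1)
  rho[sdv[edges$child] == 0 | sdv[edges$parent] == 0] <- 0
  names(rho) <- edges$child
  discarded <- edges$child[rho > theta]
  list(retained = setdiff(colnames(abundances(extended)), discarded),
       s1 = length(discarded), rho = rho)
}

#' Phase 3: per-path information-gain filtering
#'
#' Every OTU's lineage defines a root-to-leaf path. For each retained
#' node on a path the information gain with respect to the labels is
#' computed ([mdlpDiscretize()] then [informationGain()]), the path's
#' mean IG over its retained nodes is the threshold, and a node survives
#' if on at least one path through it its IG reaches the path mean
#' (ties kept) and is strictly positive. Leaves of incomplete paths
#' contribute to the path means but are exempt from the discard
#' decision — they are adjudicated by phase 4. With
#' `phase3Average = "global"` a single mean over all retained nodes
#' replaces the per-path means.
#'
#' @param retained character vector of phase-2 survivors.
#' @param extended the [AbundanceTable-class] from [aggregateTaxa()].
#' @param tree a [TaxonomyTree-class].
#' @param labels named factor of classes covering the samples used.
#' @param samples optional training-sample subset.
#' @param phase3Average `"per-path"` (default) or `"global"`.
#' @return list with `kept` (surviving non-exempt features), `s2`,
#'   `globalAvgIG` (mean IG of the kept nodes; phase 4's threshold),
#'   `ig` (named IG of every retained feature) and `exempt` (retained
#'   incomplete-path leaves, passed through to phase 4).
#' @export
igPathFilter <- function(retained, extended, tree, labels, samples = NULL,
                         phase3Average = c("per-path", "global")) {
  phase3Average <- match.arg(phase3Average)
  X <- abundances(extended)
  if (is.null(samples)) samples <- rownames(X)
  X <- X[samples, , drop = FALSE]
  y <- labels[samples]
  universe <- colnames(X)
  colIdx <- match(retained, universe)
  ig <- vapply(seq_along(retained),
               function(j) .featureIG(X[, colIdx[j]], y), numeric(1))
  names(ig) <- retained
  exempt <- intersect(incompleteLeaves(tree), retained)
  candidates <- setdiff(retained, exempt)
  tol <- 1e-12
  if (phase3Average == "global") {
    thr <- if (length(retained)) mean(ig[retained]) else 0
    pass <- candidates[ig[candidates] >= thr - tol & ig[candidates] > 0]
  } else {
    # integer-indexed masks over the feature universe keep this linear
    igArr <- rep(NA_real_, length(universe))
    igArr[colIdx] <- ig
    retMask <- logical(length(universe))
    retMask[colIdx] <- TRUE
    passMask <- logical(length(universe))
    paths <- .otuPaths(tree)
    flatIdx <- match(unlist(paths, use.names = FALSE), universe)
    pathIdx <- split(flatIdx, rep.int(seq_along(paths), lengths(paths)))
    for (p in pathIdx) {
      p <- p[!is.na(p)]  # path nodes absent from the table cannot be retained
      onPath <- p[retMask[p]]
      if (!length(onPath)) next
      thr <- mean(igArr[onPath])
      ok <- onPath[igArr[onPath] >= thr - tol & igArr[onPath] > 0]
      passMask[ok] <- TRUE
    }
    pass <- intersect(candidates, universe[passMask])
  }
  kept <- intersect(retained, pass)  # keep extended-table order semantics
  list(kept = kept, s2 = length(candidates) - length(kept),
       globalAvgIG = if (length(kept)) mean(ig[kept]) else 0,
       ig = ig, exempt = exempt)
}

#' Phase 4: information-gain filtering of incomplete-path leaves
#'
#' OTUs with incomplete taxonomic information, exempted from phase 3,
#' are kept exactly when their IG reaches the global average IG of the
#' nodes that survived phase 3 (ties kept) and is strictly positive.
#' There is no cap on how many leaves this phase may discard.
#'
#' @param exempt character vector of retained incomplete-path leaves.
#' @param ig named numeric IG scores covering `exempt`.
#' @param globalAvgIG the phase-3 survivors' mean IG.
#' @return list with `final` (kept leaves) and `s3` (discard count).
#' @export
igLeafFilter <- function(exempt, ig, globalAvgIG) {
  tol <- 1e-12
  keep <- exempt[ig[exempt] >= globalAvgIG - tol & ig[exempt] > 0]
  list(final = keep, s3 = length(exempt) - length(keep))
}

#' Run the full four-phase HFE selection
#'
#' Aggregates taxa (phase 1), prunes children correlated with their
#' parents above `theta` (phase 2), filters nodes by per-path
#' information gain under MDL discretization (phase 3) and filters
#' incomplete-path leaves against the global average IG (phase 4), on
#' the given (training) samples only. The result always satisfies
#' `|selected| = m + m' - s1 - s2 - s3`. Deterministic for fixed inputs.
#'
#' @param table an [AbundanceTable-class] over the tree's OTUs (counts
#'   are normalized per sample automatically).
#' @param labels named factor/character of per-sample classes (>= 2).
#' @param tree a [TaxonomyTree-class].
#' @param theta correlation threshold in (0, 1); default 0.7.
#' @param samples optional character vector of training sample ids;
#'   default all samples.
#' @param phase3Average `"per-path"` (default) or `"global"`; see
#'   [igPathFilter()].
#' @return An [HFEResult-class].
#' @export
runHFE <- function(table, labels, tree, theta = 0.7, samples = NULL,
                   phase3Average = c("per-path", "global")) {
  phase3Average <- match.arg(phase3Average)
  table <- normalizeRelative(table)
  labels <- .alignLabels(table, labels)
  names(labels) <- sampleIds(table)
  if (nlevels(labels) < 2) stop("need >= 2 classes")
  extended <- aggregateTaxa(table, tree)
  .hfeOnExtended(extended, labels, tree, theta, samples, phase3Average)
}

#' Project a table onto a selected feature set
#'
#' Subsets the columns of an (extended) abundance table to a selection,
#' preserving sample order. The result holds relative abundances but its
#' rows no longer sum to 1, so it is flagged non-normalized.
#'
#' @param extended an [AbundanceTable-class], typically from
#'   [aggregateTaxa()].
#' @param features an [HFEResult-class] or character vector of feature
#'   ids.
#' @return An [AbundanceTable-class] with the selected columns.
#' @export
projectFeatures <- function(extended, features) {
  if (methods::is(features, "HFEResult")) features <- selectedFeatures(features)
  miss <- setdiff(features, featureIds(extended))
  if (length(miss))
    stop("feature(s) not in table: ", paste(utils::head(miss, 3), collapse = ", "))
  methods::new("AbundanceTable",
               values = abundances(extended)[, features, drop = FALSE],
               normalized = FALSE, lineages = character())
}

#' HFE phases 2-4 on a precomputed extended table
#' @noRd
.hfeOnExtended <- function(extended, labels, tree, theta, samples = NULL,
                           phase3Average = "per-path") {
  if (is.null(samples)) samples <- sampleIds(extended)
  p2 <- correlationFilter(extended, tree, theta, samples)
  p3 <- igPathFilter(p2$retained, extended, tree, labels, samples,
                     phase3Average)
  p4 <- igLeafFilter(p3$exempt, p3$ig, p3$globalAvgIG)
  sel <- featureIds(extended)[featureIds(extended) %in% c(p3$kept, p4$final)]
  methods::new("HFEResult",
    selected = sel,
    igScores = p3$ig[sel],
    s1 = p2$s1, s2 = p3$s2, s3 = p4$s3,
    theta = theta,
    m = nOtus(tree), mPrime = nInternalNodes(tree),
    phase3Average = phase3Average,
    globalAvgIG = p3$globalAvgIG)
}
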