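#' Generate a random eight-level taxonomy
#'
#' Builds a rank hierarchy top-down: each taxon gets a Poisson-distributed
#' number of children at the next rank (at least one), until species
#' level; OTUs are then dealt across species. A configurable fraction of
#' OTUs gets its lineage truncated at family or genus level (drawn
#' uniformly between the two), emulating partial 16S sequences that can
#' be classified with confidence only down to those ranks.
#'
#' @param nOtus number of OTUs (>= 1).
#' @param branching named numeric of mean child counts per parent at
#'   ranks phylum..species (kingdom count is `branching["kingdom"]`,
#'   default 1).
#' @param incompleteFraction fraction in \[0, 1) of OTUs with truncated
#'   lineages.
#' @param seed integer seed; the tree is reproducible per seed.
#' @return A [TaxonomyTree-class].
#' @export
randomTaxonomy <- function(nOtus,
                           branching = c(kingdom = 1, phylum = 5, class = 2,
                                         order = 1.5, family = 1.5,
                                         genus = 3, species = 1.5),
                           incompleteFraction = 0, seed = 1) {
  stopifnot(nOtus >= 1)
  if (incompleteFraction < 0 || incompleteFraction >= 1)
    stop("incompleteFraction must lie in [0, 1)")
  br <- c(kingdom = 1, phylum = 5, class = 2, order = 1.5, family = 1.5,
          genus = 3, species = 1.5)
  br[names(branching)] <- branching
  set.seed(seed)
  # grow a matrix of species-level lineages rank by rank
  lin <- matrix(paste0("K", seq_len(max(1, round(br[["kingdom"]])))), ncol = 1)
  for (r in 2:7) {
    tag <- c("K", "P", "C", "O", "F", "G", "S")[r]
    rows <- list()
    for (i in seq_len(nrow(lin))) {
      nk <- max(1L, stats::rpois(1, br[[TAX_RANKS[r]]]))
      for (j in seq_len(nk))
        rows[[length(rows) + 1L]] <- c(lin[i, ], paste0(tag, i, "_", j))
    }
    lin <- do.call(rbind, rows)
  }
  # deal OTUs across species leaves
  sp <- sample(seq_len(nrow(lin)), nOtus, replace = nOtus > nrow(lin))
  otuIds <- sprintf("%d", 1000000L + seq_len(nOtus))
  truncAt <- rep(7L, nOtus)
  nInc <- round(incompleteFraction * nOtus)
  if (nInc > 0) {
    idx <- sample(seq_len(nOtus), nInc)
    truncAt[idx] <- sample(c(5L, 6L), nInc, replace = TRUE)  # family/genus
  }
  lineStr <- vapply(seq_len(nOtus), function(i) {
    d <- truncAt[i]
    paste(paste0(.RANK_PREFIX[1:d], lin[sp[i], 1:d]), collapse = "; ")
  }, character(1))
  names(lineStr) <- otuIds
  buildTaxonomy(otuIds, lineStr)
}

#' Generate a case/control abundance table with a planted clade effect
#'
#' Emulates compositional 16S profiles. Per-OTU baseline means are
#' hierarchical log-normal: every taxon at every rank draws a log-normal
#' size factor (sdlog `rankSdLog`) and an OTU's mean abundance is the
#' product of the factors along its path, so the marginal distribution
#' across OTUs is long-tailed (total sdlog about `rankSdLog * sqrt(8)`)
#' while sibling clades at each rank are of comparable scale, as in real
#' taxonomies. Within each sample, every genus carries a
#' shared log-normal fluctuation (sdlog `cladeSdLog`) that all its OTUs
#' inherit — taxonomically related organisms respond coherently to
#' their environment, which is the very rationale for aggregating
#' features by taxon. OTUs whose lineage is truncated above genus level
#' belong to an unobserved genus of their own and get a private
#' fluctuation instead. On top of that, each OTU gets independent gamma
#' noise with coefficient of variation `noise`. The planted taxon's OTU
#' descendants are multiplied by `effectSize` in case samples *before*
#' per-sample renormalization (so, compositionally, everything else
#' shifts slightly too — the realistic hard case), and rows are
#' renormalized to 1. Classes are balanced. With `effectSize = 1` cases
#' and controls are exchangeable (null model).
#'
#' @param tree a [TaxonomyTree-class], e.g. from [randomTaxonomy()].
#' @param nSamples total samples (>= 4; half case, half control).
#' @param effectRank rank at which to plant the effect (default
#'   `"genus"`).
#' @param effectSize multiplicative factor(s) >= 1 applied to the
#'   planted clade's OTUs in case samples; recycled along
#'   `plantedNode`.
#' @param noise per-OTU gamma coefficient of variation (default 0.5).
#' @param cladeSdLog sdlog of the shared per-genus per-sample log-normal
#'   fluctuation (default 1).
#' @param rankSdLog sdlog of the per-taxon log-normal size factor,
#'   either a scalar or a vector over ranks kingdom..species. The
#'   default profile puts the size heterogeneity high up (phyla and
#'   classes differ by orders of magnitude, as in real communities) and
#'   keeps sibling genera/species of comparable scale (the
#'   within-family balance seen in 16S surveys).
#' @param otuSdLog sdlog of the OTU-level private size factor
#'   (default 0.8).
#' @param nEffects number of planted clades when `plantedNode` is NULL
#'   (default 1); case/control conditions in real surveys are often
#'   polymicrobial, and planting several clades emulates that.
#' @param plantedNode optional node id(s); default picks, reproducibly,
#'   random node(s) of `effectRank` with at least 2 OTU descendants whose
#'   parent has other children too — a clade whose rank-level identity
#'   is identifiable (if the planted taxon were its parent's sole
#'   member, its feature column would be numerically indistinguishable
#'   from the parent's and "which rank carries the trait" would have no
#'   answer). Falls back to the node with most OTU descendants if no
#'   node qualifies.
#' @param seed integer seed; all randomness flows from it.
#' @return list with `table` (normalized [AbundanceTable-class]),
#'   `labels` (named factor, case/control) and `truth` (list: planted
#'   node, rank, effect size, noise, seed).
#' @export
generateDataset <- function(tree, nSamples = 100, effectRank = "genus",
                            effectSize = 3, noise = 0.5, cladeSdLog = 0.5,
                            rankSdLog = c(kingdom = 0, phylum = 1.2,
                                          class = 1, order = 1,
                                          family = 0.8, genus = 0.3,
                                          species = 0.3),
                            otuSdLog = 0.8, plantedNode = NULL,
                            nEffects = 1, seed = 1) {
  stopifnot(nSamples >= 4, all(effectSize >= 1), noise > 0, cladeSdLog >= 0,
            all(rankSdLog >= 0), otuSdLog >= 0, nEffects >= 1)
  if (length(rankSdLog) == 1L) rankSdLog <- rep(rankSdLog, 7L)
  names(rankSdLog) <- TAX_RANKS[1:7]
  set.seed(seed + 1L)
  nd <- tree@nodes
  desc <- .otuDescendants(tree)
  plantedCand <- NULL
  if (is.null(plantedNode)) {
    cand <- nd$id[nd$rank == effectRank]
    if (!length(cand)) stop("no node at rank ", effectRank)
    sizes <- lengths(desc[cand])
    parent <- nd$parent[match(cand, nd$id)]
    siblings <- table(factor(parent, levels = unique(parent)))
    eligible <- cand[sizes >= 2 & !is.na(parent) &
                     as.integer(siblings[match(parent, names(siblings))]) >= 2]
    plantedCand <- if (length(eligible)) eligible else
      cand[which.max(sizes)]
  } else if (!all(plantedNode %in% nd$id)) {
    stop("plantedNode not in tree: ",
         plantedNode[!plantedNode %in% nd$id][1])
  }
  m <- nOtus(tree)
  # hierarchical baseline means: product of per-taxon factors along the
  # path plus an OTU-level factor; an OTU attached above species gets a
  # correspondingly larger private factor so mean scale is depth-invariant
  nodeFactor <- stats::setNames(
    stats::rlnorm(nrow(nd), 0, rankSdLog[nd$rank]), nd$id)
  paths <- .otuPaths(tree)
  baseMean <- vapply(seq_len(m), function(i) {
    p <- paths[[i]]
    prod(nodeFactor[p[-length(p)]]) * stats::rlnorm(1, 0, otuSdLog)
  }, numeric(1))
  names(baseMean) <- otuIds(tree)
  if (is.null(plantedNode)) {
    # among eligible nodes, prefer ones holding a minority of their
    # parent's baseline abundance: a clade that IS its parent,
    # numerically, gives the rank-attribution question no answer
    share <- vapply(plantedCand, function(id) {
      par <- nd$parent[match(id, nd$id)]
      sum(baseMean[desc[[id]]]) / sum(baseMean[desc[[par]]])
    }, numeric(1))
    minority <- plantedCand[share <= 0.15]
    pool <- if (length(minority) >= nEffects) minority else
      plantedCand[order(share)][seq_len(min(nEffects, length(plantedCand)))]
    plantedNode <- pool[sample.int(length(pool), min(nEffects, length(pool)))]
  }
  effectSize <- rep_len(effectSize, length(plantedNode))
  plantedOtus <- unique(unlist(desc[plantedNode]))
  # shared-fluctuation group: the genus on the OTU's path when named
  # (attachment at genus rank or below), else the OTU itself
  attachRank <- nd$rank[match(tree@otus$node, nd$id)]
  group <- ifelse(.rankIndex(attachRank) >= .rankIndex("genus"),
                  vapply(strsplit(tree@otus$node, ";", fixed = TRUE),
                         function(p) paste(p[1:6], collapse = ";"), character(1)),
                  tree@otus$otu)
  groupIdx <- match(group, unique(group))
  nGroups <- max(groupIdx)
  shape <- 1 / noise^2
  labels <- factor(rep(c("case", "control"), length.out = nSamples),
                   levels = c("case", "control"))
  sampleIds <- sprintf("S%03d", seq_len(nSamples))
  names(labels) <- sampleIds
  X <- matrix(0, nSamples, m, dimnames = list(sampleIds, otuIds(tree)))
  for (i in seq_len(nSamples)) {
    cladeF <- stats::rlnorm(nGroups, meanlog = 0, sdlog = cladeSdLog)
    mu <- baseMean * cladeF[groupIdx]
    if (labels[i] == "case")
      for (j in seq_along(plantedNode))
        mu[desc[[plantedNode[j]]]] <- mu[desc[[plantedNode[j]]]] * effectSize[j]
    X[i, ] <- stats::rgamma(m, shape = shape, rate = shape / mu)
  }
  # guard against an (astronomically unlikely) all-zero row
  zero <- rowSums(X) == 0
  if (any(zero)) X[zero, 1] <- min(baseMean)
  tab <- abundanceTable(X, normalized = FALSE)
  list(table = normalizeRelative(tab), labels = labels,
       truth = list(plantedNode = plantedNode, effectRank = effectRank,
                    effectSize = effectSize, plantedOtus = plantedOtus,
                    noise = noise, nSamples = nSamples, seed = seed))
}

#' Did an HFE selection recover the planted taxon?
#'
#' TRUE when the selection contains the planted node itself or a taxon
#' within `withinRanks` rank steps of it on its own lineage (its
#' ancestors up to that many ranks, or internal descendants that many
#' ranks below). Aggregates one rank away carry nearly the same signal,
#' so recovery is judged up to this resolution.
#'
#' @param result an [HFEResult-class] (or character vector of selected
#'   feature ids).
#' @param tree the [TaxonomyTree-class] the data were generated on.
#' @param plantedNode the planted node id.
#' @param withinRanks how many rank steps count as a hit (default 1).
#' @return logical scalar.
#' @export
recoveredPlanted <- function(result, tree, plantedNode, withinRanks = 1) {
  sel <- if (methods::is(result, "HFEResult")) selectedFeatures(result) else result
  nd <- tree@nodes
  parentOf <- stats::setNames(nd$parent, nd$id)
  hits <- plantedNode
  up <- plantedNode
  for (i in seq_len(withinRanks)) {
    up <- parentOf[[up]]
    if (is.na(up)) break
    hits <- c(hits, up)
  }
  frontier <- plantedNode
  for (i in seq_len(withinRanks)) {
    frontier <- nd$id[!is.na(nd$parent) & nd$parent %in% frontier]
    hits <- c(hits, frontier)
  }
  any(hits %in% sel)
}

#' Write a synthetic dataset to disk (OTU table, taxonomy, labels, truth)
#'
#' Emits the classic on-disk trio consumed by the pipeline plus a JSON
#' record of the planted truth, under `prefix`.
#'
#' @param dataset list from [generateDataset()].
#' @param tree the [TaxonomyTree-class] used.
#' @param prefix output path prefix (directory created if needed).
#' @return invisible character vector of the four file paths.
#' @export
writeDataset <- function(dataset, tree, prefix) {
  dir.create(dirname(paste0(prefix, "x")), recursive = TRUE,
             showWarnings = FALSE)
  paths <- paste0(prefix, c("otu_table.tsv", "taxonomy.tsv", "labels.tsv",
                            "truth.json"))
  lin <- stats::setNames(.treeLineages(tree), otuIds(tree))
  writeOtuTable(dataset$table, paths[1])
  writeLines(paste(names(lin), lin, sep = "\t"), paths[2])
  writeLines(paste(names(dataset$labels), as.character(dataset$labels),
                   sep = "\t"), paths[3])
  jsonlite::write_json(dataset$truth[c("plantedNode", "effectRank",
                                       "effectSize", "noise", "nSamples",
                                       "seed")],
                       paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
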