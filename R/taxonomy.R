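#' Parse a Greengenes-style lineage string
#'
#' Splits a semicolon-delimited lineage such as
#' `"k__Bacteria; p__Firmicutes; ...; g__Coprococcus; s__"` into its named
#' ranks. Tokens with an empty name after the prefix (e.g. `"s__"`) are
#' placeholders for unassigned ranks and are treated as absent, so the
#' example above parses to six named ranks and `complete = FALSE`. A
#' lineage is complete only when all seven ranks down to species are
#' named. Whitespace around separators is ignored.
#'
#' @param lineage character scalar, semicolon-delimited with Greengenes
#'   prefixes `k__`, `p__`, `c__`, `o__`, `f__`, `g__`, `s__` in rank order.
#' @return A `Lineage`: list with `names` (character vector of taxon names
#'   named by rank, kingdom downward) and `complete` (logical).
#' @examples
#' parseLineage("k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales")
#' @export
parseLineage <- function(lineage) {
  stopifnot(is.character(lineage), length(lineage) == 1L, !is.na(lineage))
  tokens <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  if (length(tokens) == 0L || all(tokens == ""))
    stop("empty lineage string")
  # drop trailing empty tokens produced by "...;s__;" style strings
  while (length(tokens) && tokens[length(tokens)] == "")
    tokens <- tokens[-length(tokens)]
  if (length(tokens) > 7L)
    stop("lineage has more than 7 rank tokens: ", lineage)
  prefixes <- substr(tokens, 1L, 3L)
  ranks <- match(prefixes, .RANK_PREFIX)
  if (anyNA(ranks)) {
    bad <- tokens[which(is.na(ranks))[1]]
    stop("malformed rank prefix in lineage token: '", bad, "'")
  }
  if (any(ranks != seq_along(ranks))) {
    bad <- tokens[which(ranks != seq_along(ranks))[1]]
    stop("out-of-order or skipped rank at token: '", bad, "'")
  }
  nm <- substring(tokens, 4L)
  named <- nm != ""
  # a placeholder ("g__") means this and everything below is unassigned;
  # a named rank below a placeholder would be a gap in the middle
  if (any(named) && any(!named) && max(which(named)) > min(which(!named))) {
    bad <- tokens[min(which(!named))]
    stop("named rank below empty placeholder '", bad, "'")
  }
  keep <- which(named)
  out <- nm[keep]
  names(out) <- TAX_RANKS[keep]
  structure(list(names = out, complete = length(out) == 7L),
            class = "Lineage")
}

#' Format a Lineage back to its canonical Greengenes string
#'
#' Inverse of [parseLineage()]: named ranks get their prefixes back,
#' joined by `"; "`. Parsing then formatting is the identity on canonical
#' strings.
#'
#' @param lineage a `Lineage` as returned by [parseLineage()].
#' @param pad logical; pad with empty placeholders (`"s__"` etc.) down to
#'   species, the way Greengenes taxonomy files print truncated lineages.
#' @return character scalar.
#' @export
formatLineage <- function(lineage, pad = FALSE) {
  nm <- lineage$names
  toks <- paste0(.RANK_PREFIX[names(nm)], nm)
  if (pad && length(nm) < 7L)
    toks <- c(toks, .RANK_PREFIX[(length(nm) + 1L):7L])
  paste(toks, collapse = "; ")
}

#' Build the eight-level taxonomy tree from OTU lineages
#'
#' Merges identical (rank, name)-path prefixes into single internal nodes
#' and attaches every OTU below its deepest named taxon. OTUs named all
#' the way to species attach under their species node; OTUs with
#' truncated lineages attach higher up and become leaves in incomplete
#' paths. Node identifiers are full prefixed paths so that a genus name
#' recurring under two families yields two distinct nodes.
#'
#' @param otuIds character vector of unique OTU identifiers.
#' @param lineages either a named list of `Lineage` objects or a named
#'   character vector of lineage strings; names must cover `otuIds`.
#' @return A [TaxonomyTree-class].
#' @examples
#' tr <- buildTaxonomy(c("o1", "o2"),
#'   c(o1 = "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Lachnospiraceae; g__Blautia; s__producta",
#'     o2 = "k__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__Lachnospiraceae"))
#' incompleteLeaves(tr)
#' @export
buildTaxonomy <- function(otuIds, lineages) {
  if (length(otuIds) == 0L) stop("no OTUs given")
  if (anyDuplicated(otuIds))
    stop("duplicate OTU id: ", otuIds[duplicated(otuIds)][1])
  if (is.character(lineages)) lineages <- lapply(lineages, parseLineage)
  missing <- setdiff(otuIds, names(lineages))
  if (length(missing))
    stop("no lineage for OTU(s): ", paste(utils::head(missing, 3), collapse = ", "))
  lineages <- lineages[otuIds]

  nodeId <- character(); nodeName <- character()
  nodeRank <- character(); nodeParent <- character()
  seen <- new.env(parent = emptyenv())
  attach <- character(length(otuIds))
  complete <- logical(length(otuIds))
  for (i in seq_along(otuIds)) {
    lin <- lineages[[i]]
    nm <- lin$names
    path <- character(length(nm))
    acc <- ""
    for (d in seq_along(nm)) {
      tok <- paste0(.RANK_PREFIX[names(nm)[d]], nm[[d]])
      acc <- if (d == 1L) tok else paste0(acc, ";", tok)
      path[d] <- acc
      if (is.null(seen[[acc]])) {
        seen[[acc]] <- TRUE
        nodeId <- c(nodeId, acc)
        nodeName <- c(nodeName, nm[[d]])
        nodeRank <- c(nodeRank, names(nm)[d])
        nodeParent <- c(nodeParent, if (d == 1L) NA_character_ else path[d - 1L])
      }
    }
    attach[i] <- path[length(path)]
    complete[i] <- lin$complete
  }
  methods::new("TaxonomyTree",
    nodes = data.frame(id = nodeId, name = nodeName, rank = nodeRank,
                       parent = nodeParent, stringsAsFactors = FALSE),
    otus = data.frame(otu = as.character(otuIds), node = attach,
                      complete = complete, stringsAsFactors = FALSE))
}

#' OTUs that are leaves in incomplete paths
#'
#' Returns the identifiers of OTUs whose lineage is not named all the way
#' down to species; these attach under a higher rank and are handled by
#' the dedicated leaf-filtering phase of HFE rather than the path filter.
#'
#' @param tree a [TaxonomyTree-class].
#' @return character vector of OTU ids (possibly empty).
#' @export
incompleteLeaves <- function(tree) {
  stopifnot(methods::is(tree, "TaxonomyTree"))
  tree@otus$otu[!tree@otus$complete]
}

#' Parent-child feature edges of a taxonomy tree
#'
#' One row per edge whose child is a candidate feature: internal node ->
#' internal parent, and OTU -> attachment node. Kingdom-level nodes hang
#' off the virtual super-root, which is not a feature, so they have no
#' edge here.
#'
#' @return data.frame with columns `child`, `parent` (feature ids).
#' @noRd
.treeEdges <- function(tree) {
  nd <- tree@nodes
  internal <- nd[!is.na(nd$parent), c("id", "parent")]
  rbind(data.frame(child = internal$id, parent = internal$parent,
                   stringsAsFactors = FALSE),
        data.frame(child = tree@otus$otu, parent = tree@otus$node,
                   stringsAsFactors = FALSE))
}

#' Root-to-leaf feature paths, one per OTU
#'
#' Each path lists the internal-taxon ids from kingdom down to the OTU's
#' attachment node, followed by the OTU id itself.
#'
#' @return named list (by OTU id) of character vectors.
#' @noRd
.otuPaths <- function(tree) {
  nd <- tree@nodes
  parentOf <- stats::setNames(nd$parent, nd$id)
  chainCache <- new.env(parent = emptyenv())
  chain <- function(id) {
    got <- chainCache[[id]]
    if (!is.null(got)) return(got)
    p <- parentOf[[id]]
    res <- if (is.na(p)) id else c(chain(p), id)
    chainCache[[id]] <- res
    res
  }
  out <- lapply(seq_len(nrow(tree@otus)), function(i)
    c(chain(tree@otus$node[i]), tree@otus$otu[i]))
  names(out) <- tree@otus$otu
  out
}

#' Map each internal node to its OTU descendants
#' @return named list: node id -> character vector of OTU ids.
#' @noRd
.otuDescendants <- function(tree) {
  paths <- .otuPaths(tree)
  nodeVec <- unlist(lapply(paths, function(p) p[-length(p)]),
                    use.names = FALSE)
  otuVec <- rep(tree@otus$otu, times = lengths(paths) - 1L)
  split(otuVec, factor(nodeVec, levels = tree@nodes$id))
}

#' Reconstruct per-OTU lineage strings from a tree (for writing)
#' @noRd
.treeLineages <- function(tree, pad = TRUE) {
  # node id is the canonical path with bare ";" separators; reprint with "; "
  vapply(seq_len(nrow(tree@otus)), function(i) {
    toks <- strsplit(tree@otus$node[i], ";", fixed = TRUE)[[1]]
    if (pad && length(toks) < 7L)
      toks <- c(toks, unname(.RANK_PREFIX[(length(toks) + 1L):7L]))
    paste(toks, collapse = "; ")
  }, character(1))
}
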