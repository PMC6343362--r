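## Mapping shared lesions onto branches by binary-character Fitch parsimony
## with delayed transformation (deltran), and per-taxon lesion counting with
## shared-lesion attribution.

## leaves of a clade label: a tip, an internal node label of the tree, or an
## entry of the user-supplied clades list
.resolveClade <- function(label, tree, clades = NULL) {
  if (label %in% tree$tip.label) {
    return(label)
  }
  if (!is.null(clades) && label %in% names(clades)) {
    return(clades[[label]])
  }
  nl <- tree$node.label
  if (!is.null(nl) && label %in% nl) {
    node <- which(nl == label) + length(tree$tip.label)
    return(ape::extract.clade(tree, node)$tip.label)
  }
  .pgkStop("lookupError", "unknown taxon or clade label: %s", label)
}

#' Per-taxon inactivating-mutation counts
#'
#' A taxon's lesion count is the number of lesions unique to it plus the
#' lesions shared by every clade on its root-to-tip path that carries
#' records. Shared lesions are rows whose \code{taxon} field names a clade
#' (an internal node label of the tree, or an entry of \code{clades}).
#'
#' @param lesions Lesion table; the \code{taxon} column may contain tip or
#'   clade labels.
#' @param tree \code{ape::phylo} covering all referenced tips.
#' @param clades Optional named list mapping clade labels to tip-label
#'   vectors, for clades not labelled in the tree.
#' @return Named integer vector of counts for every tip of the tree.
#' @export
countLesions <- function(lesions, tree, clades = NULL) {
  counts <- stats::setNames(integer(length(tree$tip.label)), tree$tip.label)
  if (!nrow(lesions)) {
    return(counts)
  }
  for (lab in unique(lesions$taxon)) {
    tips <- .resolveClade(lab, tree, clades)
    n <- sum(lesions$taxon == lab)
    counts[tips] <- counts[tips] + n
  }
  counts
}

#' Map lesions to branches by deltran parsimony
#'
#' Optimises each lesion's presence/absence as a binary character on the
#' rooted tree by Fitch parsimony with delayed transformation: the ancestral
#' state at the root is absence (genes start intact), and where the
#' reconstruction is ambiguous, state changes are pushed toward the tips. A
#' monophyletic presence set therefore maps to the clade's stem branch,
#' while a paraphyletic set yields independent gains on the smallest
#' clades or terminal branches that cover it.
#'
#' @param tree Rooted \code{ape::phylo}.
#' @param presence Named list: lesion id -> character vector of tips
#'   carrying the lesion (non-empty subsets of the tip set).
#' @return Named list: lesion id -> character vector of branch ids (see
#'   [edgeIds()]) on which the lesion is gained; the parsimony cost (number
#'   of state changes, including any secondary losses) is attached as
#'   attribute \code{"cost"} on each element.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1)ab:1,C:1)r;")
#' mapLesionsDeltran(tr, list(l1 = c("A", "B"), l2 = c("A", "C")))
mapLesionsDeltran <- function(tree, presence) {
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  nTips <- length(tr$tip.label)
  nNode <- tr$Nnode
  ids <- edgeIds(tr)
  root <- edge[nrow(edge), 1L]

  lapply(presence, function(tips) {
    bad <- setdiff(tips, tr$tip.label)
    if (length(bad) || !length(tips)) {
      .pgkStop("lookupError",
               "presence set must be a non-empty subset of the tips (%s)",
               paste(bad, collapse = ", "))
    }
    ## min-cost (Sankoff) up-pass over states 0 = absent, 1 = present
    M <- nTips + 1        # effectively infinite cost
    cost <- matrix(0, nTips + nNode, 2L)
    tipHas <- tr$tip.label %in% tips
    cost[seq_len(nTips), 1L] <- ifelse(tipHas, M, 0)
    cost[seq_len(nTips), 2L] <- ifelse(tipHas, 0, M)
    for (e in seq_len(nrow(edge))) {
      par <- edge[e, 1L]
      chi <- edge[e, 2L]
      cost[par, 1L] <- cost[par, 1L] +
        min(cost[chi, 1L], cost[chi, 2L] + 1)
      cost[par, 2L] <- cost[par, 2L] +
        min(cost[chi, 2L], cost[chi, 1L] + 1)
    }
    ## down-pass with the ancestral gene intact (root state 0); on equal
    ## cost a child keeps the parent state, delaying changes toward the tips
    state <- integer(nTips + nNode)
    state[root] <- 0L
    gains <- character(0)
    nChanges <- 0L
    for (e in rev(seq_len(nrow(edge)))) {       # preorder
      par <- edge[e, 1L]
      chi <- edge[e, 2L]
      sPar <- state[par]
      keep <- cost[chi, sPar + 1L]
      flip <- cost[chi, 2L - sPar] + 1
      if (keep <= flip) {
        state[chi] <- sPar
      } else {
        state[chi] <- 1L - sPar
        nChanges <- nChanges + 1L
        if (state[chi] == 1L) gains <- c(gains, ids[e])
      }
    }
    structure(gains, cost = nChanges)
  })
}
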