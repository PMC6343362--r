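## Constructors, accessors and show() methods.

#' Construct a GeneStructure
#'
#' @param exons \code{data.frame} with columns \code{exon}, \code{start},
#'   \code{end} (1-based inclusive coordinates on the unaligned reference
#'   coding sequence).
#' @param donor,acceptor Character vectors of per-intron splice
#'   dinucleotides; default canonical GT / AG for every intron.
#' @return A \linkS4class{GeneStructure}.
#' @export
#' @examples
#' gs <- geneStructure(data.frame(exon = 1:2, start = c(1, 101),
#'                                end = c(90, 130)))
#' codingLength(gs)
geneStructure <- function(exons,
                          donor = rep("GT", max(0L, nrow(exons) - 1L)),
                          acceptor = rep("AG", max(0L, nrow(exons) - 1L))) {
  exons <- as.data.frame(exons)
  exons$exon <- as.integer(exons$exon)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  new("GeneStructure", exons = exons,
      donor = toupper(donor), acceptor = toupper(acceptor))
}

#' @rdname geneStructure
#' @param x A \code{GeneStructure}.
#' @export
exonTable <- function(x) x@exons

#' @rdname geneStructure
#' @export
donorSites <- function(x) x@donor

#' @rdname geneStructure
#' @export
acceptorSites <- function(x) x@acceptor

#' @rdname geneStructure
#' @export
codingLength <- function(x) sum(x@exons$end - x@exons$start + 1L)

#' Construct a BranchCategoryMap
#'
#' @param assignments Named character vector mapping branch ids (see
#'   [edgeIds()]) to category labels, or a two-column \code{data.frame}
#'   (\code{branch}, \code{category}).
#' @param categories Ordered category labels; defaults to the order of first
#'   appearance. The first category is the rate-scaling reference of
#'   [fitBranchModel()].
#' @return A \linkS4class{BranchCategoryMap}.
#' @export
#' @examples
#' branchCategoryMap(c(A = "background", B = "pseudogenic"))
branchCategoryMap <- function(assignments, categories = NULL) {
  if (is.data.frame(assignments)) {
    a <- as.character(assignments$category)
    names(a) <- as.character(assignments$branch)
    assignments <- a
  }
  if (is.null(categories)) categories <- unique(unname(assignments))
  new("BranchCategoryMap", assignments = assignments,
      categories = categories)
}

#' @rdname branchCategoryMap
#' @param x A \code{BranchCategoryMap}.
#' @export
branchAssignments <- function(x) x@assignments

#' @rdname branchCategoryMap
#' @export
categoryLabels <- function(x) x@categories

#' Construct a SimTruth
#'
#' @param branchOmegas \code{data.frame} with columns \code{branch} and
#'   \code{omega}; optional columns \code{omegaPost} and \code{switchAge}
#'   declare a within-branch functional-to-pseudogenic switch (the branch
#'   segment older than \code{switchAge} evolves at \code{omega}, the younger
#'   segment at \code{omegaPost}).
#' @param kappa Transition/transversion ratio.
#' @param pi 61 sense-codon frequencies (default uniform).
#' @param rate Expected substitutions per codon per branch-length unit under
#'   the first regime (use e.g. substitutions/codon/Ma for trees in ages
#'   mode).
#' @param lesions Optional \code{data.frame} of injected lesions.
#' @param seed Integer seed recorded with the truth.
#' @return A \linkS4class{SimTruth}.
#' @export
simTruth <- function(branchOmegas, kappa = 2, pi = rep(1 / 61, 61),
                     rate = 1, lesions = emptyLesionTable(), seed = 1L) {
  bo <- as.data.frame(branchOmegas)
  if (is.null(bo$omegaPost)) bo$omegaPost <- NA_real_
  if (is.null(bo$switchAge)) bo$switchAge <- NA_real_
  bo$branch <- as.character(bo$branch)
  new("SimTruth", branchOmegas = bo, kappa = kappa, pi = pi,
      rate = rate, lesions = lesions, seed = as.integer(seed))
}

#' @rdname simTruth
#' @param x A \code{SimTruth}.
#' @export
branchOmegas <- function(x) x@branchOmegas

#' @rdname simTruth
#' @export
truthLesions <- function(x) x@lesions

## ---- SelectionFit accessors -------------------------------------------

#' Accessors for SelectionFit objects
#'
#' @param x A \linkS4class{SelectionFit}.
#' @return \code{lnL}: the maximised log-likelihood; \code{omegaHat}: named
#'   per-category dN/dS estimates (\code{NA} where undefined);
#'   \code{substitutionCounts}: \code{data.frame} of per-category N*dN and
#'   S*dS; \code{kappaHat}: the estimated transition/transversion ratio;
#'   \code{fittedBranchLengths}: named branch lengths.
#' @export
lnL <- function(x) x@lnL

#' @rdname lnL
#' @export
omegaHat <- function(x) x@omega

#' @rdname lnL
#' @export
kappaHat <- function(x) x@kappa

#' @rdname lnL
#' @export
substitutionCounts <- function(x) {
  data.frame(category = names(x@NdN), dNdS = unname(x@omega),
             NdN = unname(x@NdN), SdS = unname(x@SdS))
}

#' @rdname lnL
#' @export
fittedBranchLengths <- function(x) x@branchLengths

## ---- show methods ------------------------------------------------------

setMethod("show", "GeneStructure", function(object) {
  ex <- object@exons
  cat(sprintf("GeneStructure: %d exon(s), %d coding nt (%d codons)\n",
              nrow(ex), codingLength(object), codingLength(object) %/% 3L))
  print(utils::head(ex, 12L), row.names = FALSE)
  if (nrow(ex) > 1L) {
    cat("donors:   ", paste(object@donor, collapse = " "), "\n")
    cat("acceptors:", paste(object@acceptor, collapse = " "), "\n")
  }
  invisible(NULL)
})

setMethod("show", "BranchCategoryMap", function(object) {
  cat(sprintf("BranchCategoryMap: %d branch(es), %d categories (%s)\n",
              length(object@assignments), length(object@categories),
              paste(object@categories, collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf(
    "SimTruth: %d branch regime(s), kappa = %.3g, rate = %.3g, seed = %d\n",
    nrow(object@branchOmegas), object@kappa, object@rate, object@seed))
  nsw <- sum(!is.na(object@branchOmegas$switchAge))
  if (nsw) cat(sprintf("  %d within-branch selection switch(es)\n", nsw))
  if (nrow(object@lesions)) {
    cat(sprintf("  %d injected lesion(s)\n", nrow(object@lesions)))
  }
  invisible(NULL)
})

setMethod("show", "SelectionFit", function(object) {
  cat(sprintf("SelectionFit (%s): lnL = %.4f, kappa = %.4f\n",
              object@freqMode, object@lnL, object@kappa))
  print(substitutionCounts(object), row.names = FALSE, digits = 5)
  invisible(NULL)
})

setMethod("show", "CodonModelSpec", function(object) {
  cat(sprintf("CodonModelSpec (%s): kappa = %.3g, %d omega categories\n",
              object@freqMode, object@kappa, length(object@omegas)))
  invisible(NULL)
})

## ---- small shared helpers ---------------------------------------------

#' Branch identifiers of a tree
#'
#' Every branch is identified by the label of the node it leads to: the tip
#' label for terminal branches, the node label for internal branches (or
#' \code{"node<N>"} when internal nodes are unlabelled). These ids are the
#' keys of [branchCategoryMap()] assignments and of fitted branch lengths.
#'
#' @param tree An \code{ape::phylo}.
#' @return Character vector of branch ids in the tree's edge order.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1)ab:1,C:2);")
#' edgeIds(tr)
edgeIds <- function(tree) {
  child <- tree$edge[, 2L]
  nTips <- length(tree$tip.label)
  lab <- character(length(child))
  isTip <- child <= nTips
  lab[isTip] <- tree$tip.label[child[isTip]]
  nl <- tree$node.label
  inner <- child[!isTip]
  innerLab <- paste0("node", inner)
  if (!is.null(nl)) {
    have <- !is.na(nl[inner - nTips]) & nzchar(nl[inner - nTips])
    innerLab[have] <- nl[inner - nTips][have]
  }
  lab[!isTip] <- innerLab
  lab
}

.alnMatrix <- function(alignment) {
  if (is.matrix(alignment)) {
    return(alignment)
  }
  m <- as.matrix(alignment)
  rownames(m) <- names(alignment)
  m
}

.checkPi <- function(pi) {
  if (length(pi) != 61L || any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("pi must be 61 nonnegative sense-codon frequencies summing to 1",
         call. = FALSE)
  }
  invisible(pi)
}
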