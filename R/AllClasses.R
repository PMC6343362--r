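#' @import methods
NULL

#' Exon/intron structure of a protein-coding gene
#'
#' Holds the exon coordinates of a gene on its unaligned reference coding
#' sequence (1-based, inclusive), together with the observed donor and
#' acceptor splice-site dinucleotides of each intron. The total exon length
#' must be a multiple of three so the structure defines a reading frame.
#'
#' @slot exons \code{data.frame} with columns \code{exon}, \code{start},
#'   \code{end}; non-overlapping, ascending, 1-based inclusive.
#' @slot donor Character vector of donor dinucleotides, one per intron
#'   (canonical \code{"GT"}).
#' @slot acceptor Character vector of acceptor dinucleotides, one per intron
#'   (canonical \code{"AG"}).
#' @seealso [readGeneStructure()], [exonTable()], [codingLength()]
#' @export
setClass("GeneStructure",
         representation(exons = "data.frame",
                        donor = "character",
                        acceptor = "character"))

setValidity("GeneStructure", function(object) {
  ex <- object@exons
  msg <- character(0)
  need <- c("exon", "start", "end")
  if (!all(need %in% names(ex))) {
    return("exons must have columns exon, start, end")
  }
  if (nrow(ex) < 1L) msg <- c(msg, "at least one exon is required")
  if (any(ex$start > ex$end)) msg <- c(msg, "exon start > end")
  if (any(ex$start < 1L)) msg <- c(msg, "coordinates are 1-based")
  if (nrow(ex) > 1L) {
    if (is.unsorted(ex$start, strictly = TRUE)) {
      msg <- c(msg, "exons must be in ascending order")
    }
    if (any(ex$start[-1L] <= ex$end[-nrow(ex)])) {
      msg <- c(msg, "exons overlap")
    }
  }
  len <- sum(ex$end - ex$start + 1L)
  if (len %% 3L != 0L) {
    msg <- c(msg, sprintf("total exon length %d is not a multiple of 3", len))
  }
  nIntron <- nrow(ex) - 1L
  if (length(object@donor) != nIntron || length(object@acceptor) != nIntron) {
    msg <- c(msg, "need one donor and one acceptor dinucleotide per intron")
  }
  if (length(msg)) msg else TRUE
})

#' Assignment of phylogeny branches to dN/dS categories
#'
#' Maps every branch of a tree (identified by the label of the node the
#' branch leads to, see [edgeIds()]) to a named category, e.g. background,
#' transitional or pseudogenic. The first category in \code{categories} is the
#' scaling reference of [fitBranchModel()].
#'
#' @slot assignments Named character vector: branch id -> category label.
#' @slot categories Ordered character vector of category labels.
#' @seealso [branchCategoryMap()], [readBranchCategories()]
#' @export
setClass("BranchCategoryMap",
         representation(assignments = "character",
                        categories = "character"))

setValidity("BranchCategoryMap", function(object) {
  msg <- character(0)
  if (length(object@categories) < 1L) msg <- c(msg, "need >= 1 category")
  if (anyDuplicated(object@categories)) {
    msg <- c(msg, "duplicated category labels")
  }
  if (is.null(names(object@assignments)) ||
      anyDuplicated(names(object@assignments))) {
    msg <- c(msg, "assignments must be uniquely named by branch id")
  }
  bad <- setdiff(unique(object@assignments), object@categories)
  if (length(bad)) {
    msg <- c(msg, paste("assignments use unknown categories:",
                        paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated gene-loss data set
#'
#' Records everything the simulator drew or was given: the per-branch dN/dS
#' regime (a single ratio, or a functional/pseudogenic pair with the age at
#' which selection switched off within the branch), the global
#' transition/transversion ratio kappa, the sense-codon equilibrium
#' frequencies, the clock rate converting branch-length units to expected
#' substitutions per codon, any injected lesions, and the seed.
#'
#' @slot branchOmegas \code{data.frame} with columns \code{branch},
#'   \code{omega}, \code{omegaPost}, \code{switchAge}; \code{omegaPost} and
#'   \code{switchAge} are \code{NA} except on switch branches, where the
#'   older branch segment evolves at \code{omega} and the segment younger
#'   than \code{switchAge} at \code{omegaPost}.
#' @slot kappa Transition/transversion ratio (single global value).
#' @slot pi Numeric vector of 61 sense-codon frequencies (sums to 1).
#' @slot rate Expected substitutions per codon per branch-length unit under
#'   the first rate regime; 1 when branch lengths are already in
#'   substitutions per codon.
#' @slot lesions \code{data.frame} of injected lesion records (may be empty).
#' @slot seed Integer seed.
#' @seealso [simTruth()], [simulateCodonAlignment()]
#' @export
setClass("SimTruth",
         representation(branchOmegas = "data.frame",
                        kappa = "numeric",
                        pi = "numeric",
                        rate = "numeric",
                        lesions = "data.frame",
                        seed = "integer"))

setValidity("SimTruth", function(object) {
  msg <- character(0)
  bo <- object@branchOmegas
  need <- c("branch", "omega", "omegaPost", "switchAge")
  if (!all(need %in% names(bo))) {
    return("branchOmegas needs columns branch, omega, omegaPost, switchAge")
  }
  if (any(bo$omega < 0, na.rm = TRUE) || any(bo$omegaPost < 0, na.rm = TRUE)) {
    msg <- c(msg, "omega values must be nonnegative")
  }
  if (length(object@pi) != 61L || abs(sum(object@pi) - 1) > 1e-12 ||
      any(object@pi < 0)) {
    msg <- c(msg, "pi must be 61 nonnegative frequencies summing to 1")
  }
  if (object@kappa < 0) msg <- c(msg, "kappa must be nonnegative")
  if (object@rate <= 0) msg <- c(msg, "rate must be positive")
  if (length(msg)) msg else TRUE
})

#' GY94 codon model specification
#'
#' @slot kappa Transition/transversion ratio.
#' @slot pi Numeric vector of 61 sense-codon equilibrium frequencies.
#' @slot freqMode \code{"CF1"} or \code{"CF2"}.
#' @slot omegas Named numeric vector of per-category dN/dS ratios.
#' @export
setClass("CodonModelSpec",
         representation(kappa = "numeric", pi = "numeric",
                        freqMode = "character", omegas = "numeric"))

setValidity("CodonModelSpec", function(object) {
  msg <- character(0)
  if (length(object@pi) != 61L || any(object@pi < 0) ||
      abs(sum(object@pi) - 1) > 1e-12) {
    msg <- c(msg, "pi must be 61 nonnegative frequencies summing to 1")
  }
  if (object@kappa < 0) msg <- c(msg, "kappa must be nonnegative")
  if (any(object@omegas < 0)) msg <- c(msg, "omegas must be nonnegative")
  if (!object@freqMode %in% c("CF1", "CF2")) {
    msg <- c(msg, "freqMode must be CF1 or CF2")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted branch-category selection model
#'
#' Result of [fitBranchModel()]: the maximised log-likelihood, the estimated
#' kappa, per-category dN/dS estimates (with \code{NA} as the undefined
#' sentinel when a category carries no synonymous substitutions), expected
#' substitution counts N*dN and S*dS per category, and fitted branch lengths
#' in expected substitutions per codon under the first category.
#'
#' @slot lnL Maximised log-likelihood.
#' @slot kappa Estimated transition/transversion ratio.
#' @slot omega Named per-category dN/dS estimates (\code{NA} = undefined).
#' @slot NdN,SdS Named per-category expected nonsynonymous / synonymous
#'   substitution counts.
#' @slot branchLengths Named fitted branch lengths (by branch id).
#' @slot pi The 61 sense-codon frequencies used.
#' @slot freqMode \code{"CF1"} or \code{"CF2"}.
#' @slot convergence Optimiser convergence code (0 = converged).
#' @export
setClass("SelectionFit",
         representation(lnL = "numeric", kappa = "numeric",
                        omega = "numeric", NdN = "numeric", SdS = "numeric",
                        branchLengths = "numeric", pi = "numeric",
                        freqMode = "character", convergence = "integer"))

setValidity("SelectionFit", function(object) {
  msg <- character(0)
  if (!is.finite(object@lnL)) msg <- c(msg, "lnL must be finite")
  if (any(object@NdN < 0) || any(object@SdS < 0)) {
    msg <- c(msg, "expected substitution counts must be nonnegative")
  }
  if (length(msg)) msg else TRUE
})
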