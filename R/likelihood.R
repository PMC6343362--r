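## Felsenstein pruning over 61 sense-codon states and maximum-likelihood
## fitting of the GY94 branch-category model.

## ---- tip state coding -------------------------------------------------

.iupacSets <- function() {
  m <- Biostrings::IUPAC_CODE_MAP
  sets <- strsplit(unname(m), "")
  names(sets) <- names(m)
  sets[["N"]] <- c("A", "C", "G", "T")
  sets[["-"]] <- c("A", "C", "G", "T")
  sets[["?"]] <- c("A", "C", "G", "T")
  sets[["."]] <- c("A", "C", "G", "T")
  sets
}

## Encode one taxon row (character vector of bases, length 3*ncodons) as
## per-codon states: a positive integer for a pure sense codon, 0 for fully
## missing, -k pointing into an ambiguity list otherwise.
.encodeTipCodons <- function(bases, ambStore) {
  .codonSetup()
  sense <- .codonEnv$sense
  nc <- length(bases) %/% 3L
  dim(bases) <- c(3L, nc)
  pure <- matrix(bases %in% c("A", "C", "G", "T"), 3L, nc)
  codon <- paste0(bases[1L, ], bases[2L, ], bases[3L, ])
  idx <- match(codon, sense)
  states <- integer(nc)
  sets <- .iupacSets()
  for (s in seq_len(nc)) {
    if (all(pure[, s])) {
      if (is.na(idx[s])) {
        ## observed stop codon: outside the sense-state space, treat as missing
        states[s] <- 0L
      } else {
        states[s] <- idx[s]
      }
      next
    }
    triple <- lapply(bases[, s], function(b) {
      out <- sets[[b]]
      if (is.null(out)) c("A", "C", "G", "T") else out
    })
    if (all(lengths(triple) == 4L)) {
      states[s] <- 0L
      next
    }
    cods <- as.vector(outer(outer(triple[[1L]], triple[[2L]], paste0),
                            triple[[3L]], paste0))
    comp <- stats::na.omit(match(cods, sense))
    if (length(comp) == 0L || length(comp) == 61L) {
      states[s] <- 0L
    } else {
      key <- paste(sort(comp), collapse = ",")
      pos <- match(key, ambStore$keys)
      if (is.na(pos)) {
        ambStore$keys <- c(ambStore$keys, key)
        ambStore$sets <- c(ambStore$sets, list(sort(comp)))
        pos <- length(ambStore$keys)
      }
      states[s] <- -pos
    }
  }
  states
}

## Build the compressed pruning data for an alignment + tree: per-tip codon
## state vectors, site-pattern compression, and postorder edge traversal.
.pruningData <- function(alignment, tree) {
  mat <- .alnMatrix(alignment)
  if (ncol(mat) %% 3L != 0L) {
    stop("alignment length is not a multiple of 3", call. = FALSE)
  }
  tips <- tree$tip.label
  if (!setequal(rownames(mat), tips)) {
    stop("alignment taxa and tree tip labels differ", call. = FALSE)
  }
  mat <- mat[tips, , drop = FALSE]
  ambStore <- new.env(parent = emptyenv())
  ambStore$keys <- character(0)
  ambStore$sets <- list()
  states <- t(vapply(seq_len(nrow(mat)),
                     function(i) .encodeTipCodons(mat[i, ], ambStore),
                     integer(ncol(mat) %/% 3L)))
  ## site-pattern compression
  key <- apply(states, 2L, paste, collapse = ".")
  upat <- match(key, unique(key))
  first <- !duplicated(upat)
  patStates <- states[, first, drop = FALSE]
  w <- as.vector(table(factor(upat, levels = seq_len(sum(first)))))

  tr <- ape::reorder.phylo(tree, "postorder")
  list(patStates = patStates, weights = w, ambSets = ambStore$sets,
       tree = tr, nTips = length(tips), nCodons = ncol(mat) %/% 3L)
}

## Tip conditional-likelihood matrix (61 x npat) for a tip given its branch's
## P matrix: column selection for pure states, explicit sums for ambiguity.
.tipContribution <- function(P, states, ambSets) {
  npat <- length(states)
  out <- matrix(1, 61L, npat)
  pure <- states > 0L
  if (any(pure)) {
    out[, pure] <- P[, states[pure], drop = FALSE]
  }
  amb <- states < 0L
  for (s in which(amb)) {
    set <- ambSets[[-states[s]]]
    out[, s] <- rowSums(P[, set, drop = FALSE])
  }
  out
}

## Log-likelihood by pruning given per-edge P matrices (list indexed by edge
## row of pd$tree$edge) and root frequencies pi.
.pruneLnL <- function(pd, Plist, pi) {
  tr <- pd$tree
  edge <- tr$edge
  nTips <- pd$nTips
  npat <- ncol(pd$patStates)
  nNode <- tr$Nnode
  partial <- vector("list", nTips + nNode)
  logscale <- numeric(npat)
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1L]
    chi <- edge[e, 2L]
    if (chi <= nTips) {
      contrib <- .tipContribution(Plist[[e]], pd$patStates[chi, ], pd$ambSets)
    } else {
      contrib <- Plist[[e]] %*% partial[[chi]]
    }
    if (is.null(partial[[par]])) {
      partial[[par]] <- contrib
    } else {
      partial[[par]] <- partial[[par]] * contrib
    }
  }
  root <- edge[nrow(edge), 1L]
  L <- partial[[root]]
  site <- as.vector(pi %*% L)
  bad <- site <= 0 | !is.finite(site)
  if (any(bad)) {
    return(-Inf)
  }
  sum(pd$weights * (log(site) + logscale))
}

## ---- the branch-category likelihood ----------------------------------

## Per-edge category index vector from a BranchCategoryMap, in the edge order
## of the postorder tree inside pd.
.edgeCategories <- function(pd, categories) {
  tr <- pd$tree
  ids <- edgeIds(tr)
  assign <- branchAssignments(categories)
  miss <- setdiff(ids, names(assign))
  if (length(miss)) {
    stop("branches without a category assignment: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cats <- categoryLabels(categories)
  match(unname(assign[ids]), cats)
}

## Core evaluator: lnL for given kappa, per-category omega vector, per-edge
## branch lengths (postorder edge order), pi, and per-edge category index.
## Scaled so one branch-length unit is one expected substitution per codon
## under the first (background) category.
.branchModelLnL <- function(pd, kappa, omegas, blens, pi, edgeCat,
                            scaleCat = 1L) {
  Qs <- lapply(omegas, .gy94Q, kappa = kappa, pi = pi)
  scale <- .meanRate(Qs[[scaleCat]], pi)
  if (!is.finite(scale) || scale <= 0) return(-Inf)
  eigs <- lapply(Qs, function(Q) .eigenQ(Q / scale, pi))
  Plist <- vector("list", length(blens))
  for (e in seq_along(blens)) {
    Plist[[e]] <- .probMatrix(eigs[[edgeCat[e]]], blens[e])
  }
  .pruneLnL(pd, Plist, pi)
}

#' Likelihood-ratio test against a fixed dN/dS value
#'
#' Compares a model in which one branch category's dN/dS is free against the
#' same model with that ratio fixed (e.g. at the neutral value 1.0), using a
#' chi-squared test with one degree of freedom on twice the log-likelihood
#' difference.
#'
#' @param lnLFree Log-likelihood of the model with the ratio free.
#' @param lnLFixed Log-likelihood of the model with the ratio fixed.
#' @return A list with elements \code{statistic} (2 * delta lnL), \code{df}
#'   and \code{p.value}.
#' @export
#' @examples
#' lrtFixedOmega(-1000, -1000.475)  # p about 0.33
lrtFixedOmega <- function(lnLFree, lnLFixed) {
  if (!is.finite(lnLFree) || !is.finite(lnLFixed)) {
    stop("log-likelihoods must be finite", call. = FALSE)
  }
  if (lnLFree < lnLFixed - 1e-6) {
    stop("free model has lower likelihood than the constrained model",
         call. = FALSE)
  }
  stat <- max(0, 2 * (lnLFree - lnLFixed))
  list(statistic = stat, df = 1L,
       p.value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Fit a branch-category GY94 codon model by maximum likelihood
#'
#' Estimates the transition/transversion ratio kappa, one dN/dS ratio per
#' branch category, and all branch lengths by maximising the pruning
#' likelihood of a codon alignment on a fixed tree topology. The rate matrix
#' is scaled so that one branch-length unit equals one expected substitution
#' per codon under the first category (conventionally the background
#' category). Expected nonsynonymous and synonymous substitution counts
#' (N*dN, S*dS) are reported per category from the equilibrium flux of the
#' scaled rate matrix times total branch length times alignment length.
#'
#' @param alignment A gapped codon alignment (\code{DNAStringSet}); columns
#'   that are not A/C/G/T are treated as (partially) missing data, with IUPAC
#'   ambiguity codes expanded to their compatible codon states.
#' @param tree An \code{ape::phylo} tree whose tips match the alignment; the
#'   input branch lengths are used only as starting values.
#' @param categories A \linkS4class{BranchCategoryMap} assigning every branch
#'   to a category.
#' @param freqMode Codon equilibrium frequency model, \code{"CF1"} (pooled
#'   nucleotide frequencies) or \code{"CF2"} (position-specific frequencies);
#'   ignored when \code{pi} is supplied.
#' @param pi Optional explicit vector of 61 sense-codon frequencies.
#' @param fixOmega Optional named numeric vector fixing the dN/dS of some
#'   categories (names are category labels), e.g. \code{c(pseudogenic = 1)}
#'   for a neutrality test.
#' @param nStarts Number of optimisation starts; the first uses neutral-ish
#'   defaults, later starts randomise kappa and the free dN/dS ratios.
#' @param seed Integer seed controlling the random restarts.
#' @param control List of optimiser settings: \code{maxit}, \code{factr}.
#' @return A \linkS4class{SelectionFit}.
#' @seealso [buildCodonFrequencies()], [lrtFixedOmega()],
#'   [simulateCodonAlignment()]
#' @export
fitBranchModel <- function(alignment, tree, categories,
                           freqMode = c("CF1", "CF2"), pi = NULL,
                           fixOmega = NULL, nStarts = 3L, seed = 1L,
                           control = list()) {
  freqMode <- match.arg(freqMode)
  if (is.null(pi)) {
    pi <- buildCodonFrequencies(alignment, freqMode)
  }
  .checkPi(pi)
  pd <- .pruningData(alignment, tree)
  edgeCat <- .edgeCategories(pd, categories)
  cats <- categoryLabels(categories)
  ncat <- length(cats)
  used <- sort(unique(edgeCat))
  if (!all(seq_len(ncat) %in% used)) {
    cats <- cats[used]
    edgeCat <- match(edgeCat, used)
    ncat <- length(cats)
  }
  fixed <- rep(NA_real_, ncat)
  if (!is.null(fixOmega)) {
    bad <- setdiff(names(fixOmega), cats)
    if (length(bad)) {
      stop("fixOmega names not in category set: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    fixed[match(names(fixOmega), cats)] <- fixOmega
  }
  freeIdx <- which(is.na(fixed))
  nEdge <- nrow(pd$tree$edge)

  startBl <- pd$tree$edge.length
  if (is.null(startBl) || any(!is.finite(startBl)) || all(startBl <= 0)) {
    startBl <- rep(0.1, nEdge)
  }
  startBl <- pmax(startBl, 1e-4)
  ## if the tree is in time units its scale can be far from
  ## substitutions/codon; normalise the start to a moderate total length
  tot <- sum(startBl)
  if (tot > 5 * nEdge * 0.2) startBl <- startBl * (nEdge * 0.2) / tot

  maxit <- if (is.null(control$maxit)) 500L else control$maxit
  factr <- if (is.null(control$factr)) 1e4 else control$factr

  unpack <- function(par) {
    om <- fixed
    om[freeIdx] <- exp(par[seq_along(freeIdx)])
    list(kappa = exp(par[length(freeIdx) + 1L]),
         omegas = om,
         blens = exp(par[(length(freeIdx) + 2L):length(par)]))
  }
  negLnL <- function(par) {
    p <- unpack(par)
    ll <- .branchModelLnL(pd, p$kappa, p$omegas, p$blens, pi, edgeCat)
    if (!is.finite(ll)) 1e12 else -ll
  }
  lower <- c(rep(log(1e-4), length(freeIdx)), log(0.05), rep(log(1e-7), nEdge))
  upper <- c(rep(log(50), length(freeIdx)), log(100), rep(log(20), nEdge))

  set.seed(seed)
  best <- NULL
  for (s in seq_len(max(1L, nStarts))) {
    if (s == 1L) {
      om0 <- rep(0.5, length(freeIdx))
      k0 <- 2
      bl0 <- startBl
    } else {
      om0 <- exp(stats::runif(length(freeIdx), log(0.1), log(2)))
      k0 <- exp(stats::runif(1, log(0.5), log(8)))
      bl0 <- if (is.null(best)) startBl else
        pmax(best$blens, 1e-6) * exp(stats::rnorm(nEdge, 0, 0.1))
    }
    par0 <- log(c(om0, k0, bl0))
    opt <- stats::optim(par0, negLnL, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = maxit, factr = factr))
    if (is.null(best) || opt$value < best$value) {
      p <- unpack(opt$par)
      best <- list(value = opt$value, kappa = p$kappa, omegas = p$omegas,
                   blens = p$blens, convergence = opt$convergence)
    }
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("branch-model optimisation failed to produce a finite likelihood",
         call. = FALSE)
  }

  ## expected substitution counts per category from the scaled-rate flux
  Qs <- lapply(best$omegas, .gy94Q, kappa = best$kappa, pi = pi)
  scale <- .meanRate(Qs[[1L]], pi)
  NdN <- SdS <- numeric(ncat)
  for (k in seq_len(ncat)) {
    fl <- .fluxNS(Qs[[k]] / scale, pi)
    tcat <- sum(best$blens[edgeCat == k])
    NdN[k] <- fl["N"] * tcat * pd$nCodons
    SdS[k] <- fl["S"] * tcat * pd$nCodons
  }
  omegaOut <- best$omegas
  ## categories with (numerically) no synonymous substitutions have an
  ## unidentifiable ratio: report the undefined sentinel, keep raw counts
  undef <- SdS < 1e-8 | omegaOut >= 50 * (1 - 1e-6)
  omegaOut[undef] <- NA_real_
  names(omegaOut) <- names(NdN) <- names(SdS) <- cats

  ids <- edgeIds(pd$tree)
  bl <- best$blens
  names(bl) <- ids
  new("SelectionFit",
      lnL = -best$value, kappa = best$kappa, omega = omegaOut,
      NdN = NdN, SdS = SdS, branchLengths = bl, pi = pi,
      freqMode = freqMode, convergence = as.integer(best$convergence))
}
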