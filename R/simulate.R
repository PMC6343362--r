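## Codon-alignment simulation under the GY94 model with per-branch dN/dS
## regimes, including within-branch functional-to-pseudogenic switches.

#' Simulate a codon alignment under a GY94 branch model
#'
#' Draws a root sequence from the equilibrium frequencies and evolves it
#' along the tree, each branch using its own dN/dS regime from the supplied
#' \linkS4class{SimTruth}. On a switch branch the segment older than the
#' switch age evolves at the functional ratio and the younger segment at the
#' pseudogenic ratio (this requires a tree in ages mode, see
#' [readTreeFile()]). Transitions are sampled per codon from exact
#' matrix-exponential transition probabilities. The rate matrix is scaled so
#' that one branch-length unit times \code{rate} equals one expected
#' substitution per codon under the first regime listed in the truth. Stop
#' codons are excluded from the state space, so simulated sequences never
#' contain internal stops and injected stops are unambiguous ground truth.
#'
#' The call is deterministic given the seed stored in \code{truth}; all draws
#' come from one stream in a fixed order (root sequence first, then branches
#' in preorder).
#'
#' @param tree \code{ape::phylo}, every branch id (see [edgeIds()]) present in
#'   \code{branchOmegas(truth)$branch}. Branches absent from the truth table
#'   are an error.
#' @param truth A \linkS4class{SimTruth}.
#' @param nCodons Number of codons to simulate (>= 1).
#' @return A \code{DNAStringSet} of ungapped tip sequences, width
#'   \code{3 * nCodons}.
#' @seealso [simTruth()], [fitBranchModel()]
#' @export
simulateCodonAlignment <- function(tree, truth, nCodons) {
  stopifnot(nCodons >= 1L)
  methods::validObject(truth)
  pi <- truth@pi
  bo <- truth@branchOmegas
  ids <- edgeIds(tree)
  miss <- setdiff(ids, bo$branch)
  if (length(miss)) {
    .pgkStop("truthError", "branches without an omega regime: %s",
             paste(miss, collapse = ", "))
  }
  hasSwitch <- any(!is.na(bo$switchAge[match(ids, bo$branch)]))
  ages <- tree$age
  if (hasSwitch && is.null(ages)) {
    .pgkStop("truthError",
             "switch branches require a tree in ages mode (node ages)")
  }

  ## scaled eigensystems, one per distinct omega
  refOmega <- bo$omega[1L]
  scale <- .meanRate(.gy94Q(truth@kappa, refOmega, pi), pi)
  allOm <- unique(stats::na.omit(c(bo$omega, bo$omegaPost)))
  eigs <- lapply(allOm, function(w) {
    .eigenQ(.gy94Q(truth@kappa, w, pi) / scale, pi)
  })
  names(eigs) <- as.character(allOm)

  set.seed(truth@seed)
  nTips <- length(tree$tip.label)
  nNode <- tree$Nnode
  states <- matrix(NA_integer_, nTips + nNode, nCodons)
  tr <- ape::reorder.phylo(tree, "postorder")
  preorder <- rev(seq_len(nrow(tr$edge)))
  root <- tr$edge[nrow(tr$edge), 1L]
  states[root, ] <- sample.int(61L, nCodons, replace = TRUE, prob = pi)

  evolve <- function(parentStates, P) {
    out <- integer(length(parentStates))
    for (s in unique(parentStates)) {
      idx <- parentStates == s
      out[idx] <- sample.int(61L, sum(idx), replace = TRUE, prob = P[s, ])
    }
    out
  }

  idsPost <- edgeIds(tr)
  for (e in preorder) {
    par <- tr$edge[e, 1L]
    chi <- tr$edge[e, 2L]
    row <- bo[match(idsPost[e], bo$branch), ]
    if (!is.na(row$switchAge)) {
      tb <- ages[par]
      te <- ages[chi]
      ti <- row$switchAge
      if (ti > tb + 1e-9 || ti < te - 1e-9) {
        .pgkStop("truthError",
                 "switch age %.4g outside branch span [%.4g, %.4g] on %s",
                 ti, te, tb, idsPost[e])
      }
      P <- .probMatrix(eigs[[as.character(row$omega)]],
                       (tb - ti) * truth@rate) %*%
           .probMatrix(eigs[[as.character(row$omegaPost)]],
                       (ti - te) * truth@rate)
    } else {
      len <- tr$edge.length[e]
      P <- .probMatrix(eigs[[as.character(row$omega)]], len * truth@rate)
    }
    states[chi, ] <- evolve(states[par, ], P)
  }

  sense <- senseCodons()
  seqs <- vapply(seq_len(nTips),
                 function(i) paste(sense[states[i, ]], collapse = ""),
                 character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- tree$tip.label
  out
}

#' Counting-based dN/dS between two ungapped codon sequences
#'
#' Nei-Gojobori-style counting estimator used as an independent check on
#' simulated data: nonsynonymous and synonymous sites are counted from the
#' reference sequence, differences are classified per codon averaging over
#' single-step mutational paths through sense codons. Site counts can be
#' weighted by a transition/transversion ratio (modified counting), without
#' which the estimator is downward-biased for kappa > 1. No multiple-hit
#' correction; intended for closely related sequences.
#'
#' @param ref,query Ungapped codon sequences of equal length (character
#'   strings).
#' @param kappa Transition/transversion ratio used to weight mutational
#'   opportunities in the site counts (default 1 = classic equal weighting).
#' @return List with \code{dN}, \code{dS} and \code{omega} (\code{NA} when
#'   \code{dS} is 0).
#' @export
countingDnDs <- function(ref, query, kappa = 1) {
  .codonSetup()
  sense <- .codonEnv$sense
  r <- .splitCodons(ref)
  q <- .splitCodons(query)
  stopifnot(length(r) == length(q))
  p <- .codonEnv$pairs
  aa <- .codonEnv$senseAA
  ## per-codon counts of nonsynonymous/synonymous sites (out of 3),
  ## mutational opportunities weighted by kappa for transitions
  nsSites <- vapply(seq_along(sense), function(i) {
    nb <- which(p$i == i)
    if (!length(nb)) return(3)
    w <- ifelse(p$transition[nb], kappa, 1)
    3 * sum(w * p$nonsyn[nb]) / sum(w)
  }, numeric(1))
  N <- S <- Nd <- Sd <- 0
  for (k in seq_along(r)) {
    i <- match(r[k], sense)
    j <- match(q[k], sense)
    if (is.na(i) || is.na(j)) next
    N <- N + nsSites[i]
    S <- S + 3 - nsSites[i]
    if (i == j) next
    diffPos <- which(.codonEnv$chars[i, ] != .codonEnv$chars[j, ])
    if (length(diffPos) == 1L) {
      if (aa[i] != aa[j]) Nd <- Nd + 1 else Sd <- Sd + 1
    } else {
      ## average over single-step paths through sense codons
      paths <- .codonPaths(i, j, diffPos)
      if (length(paths)) {
        steps <- colMeans(do.call(rbind, paths))
        Nd <- Nd + steps[1L]
        Sd <- Sd + steps[2L]
      }
    }
  }
  dN <- if (N > 0) Nd / N else NA_real_
  dS <- if (S > 0) Sd / S else NA_real_
  list(dN = dN, dS = dS,
       omega = if (!is.na(dS) && dS > 0) dN / dS else NA_real_)
}

## all orderings of the differing positions, stepping through sense codons;
## returns per-path c(nonsyn, syn) step counts
.codonPaths <- function(i, j, diffPos) {
  chars <- .codonEnv$chars
  sense <- .codonEnv$sense
  aa <- .codonEnv$senseAA
  perms <- if (length(diffPos) == 2L) {
    list(diffPos, rev(diffPos))
  } else {
    list(diffPos[c(1, 2, 3)], diffPos[c(1, 3, 2)], diffPos[c(2, 1, 3)],
         diffPos[c(2, 3, 1)], diffPos[c(3, 1, 2)], diffPos[c(3, 2, 1)])
  }
  out <- list()
  for (ord in perms) {
    cur <- chars[i, ]
    curIdx <- i
    ns <- sy <- 0
    ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- chars[j, pos]
      nxtIdx <- match(paste(nxt, collapse = ""), sense)
      if (is.na(nxtIdx)) { ok <- FALSE; break }    # path through a stop
      if (aa[curIdx] != aa[nxtIdx]) ns <- ns + 1 else sy <- sy + 1
      cur <- nxt
      curIdx <- nxtIdx
    }
    if (ok) out[[length(out) + 1L]] <- c(ns, sy)
  }
  out
}

.splitCodons <- function(s) {
  s <- toupper(as.character(s))
  n <- nchar(s)
  stopifnot(n %% 3L == 0L)
  substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
}
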