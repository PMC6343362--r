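## Internal codon-state machinery shared by the simulator and the
## likelihood code: the 61 sense codons of the universal genetic code,
## single-nucleotide neighbour classification (transition/transversion,
## synonymous/nonsynonymous), and the GY94 rate matrix.

.codonEnv <- new.env(parent = emptyenv())

#' @importFrom Biostrings GENETIC_CODE
.codonSetup <- function() {
  if (!is.null(.codonEnv$sense)) {
    return(invisible(NULL))
  }
  nt <- c("A", "C", "G", "T")
  g <- expand.grid(p3 = nt, p2 = nt, p1 = nt,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  codons <- paste0(g$p1, g$p2, g$p3)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  sense <- codons[aa != "*"]
  senseAA <- aa[aa != "*"]
  n <- length(sense)                      # 61
  stopifnot(n == 61L)
  chars <- do.call(rbind, strsplit(sense, ""))

  ## single-nucleotide neighbours among sense codons
  ii <- integer(0); jj <- integer(0); ts <- logical(0); ns <- logical(0)
  isTransition <- function(a, b) {
    (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  }
  for (i in seq_len(n)) {
    d <- chars != matrix(chars[i, ], n, 3L, byrow = TRUE)
    nb <- which(rowSums(d) == 1L)
    for (j in nb) {
      pos <- which(d[j, ])
      ii <- c(ii, i); jj <- c(jj, j)
      ts <- c(ts, isTransition(chars[i, pos], chars[j, pos]))
      ns <- c(ns, senseAA[i] != senseAA[j])
    }
  }
  .codonEnv$sense <- sense
  .codonEnv$senseAA <- senseAA
  .codonEnv$stops <- codons[aa == "*"]
  .codonEnv$chars <- chars
  .codonEnv$pairs <- list(i = ii, j = jj, transition = ts, nonsyn = ns)
  invisible(NULL)
}

#' Sense codons of the universal genetic code
#'
#' Returns the 61 sense codons (universal code, stop codons excluded) in the
#' fixed lexicographic order used for all codon-state vectors and matrices in
#' the package.
#'
#' @return Character vector of length 61.
#' @export
#' @examples
#' head(senseCodons())
senseCodons <- function() {
  .codonSetup()
  .codonEnv$sense
}

.stopCodons <- function() {
  .codonSetup()
  .codonEnv$stops
}

.senseAA <- function() {
  .codonSetup()
  .codonEnv$senseAA
}

## GY94 instantaneous rate matrix on the 61 sense codons (unscaled).
## q(i->j) = 0 for multi-nucleotide changes; pi_j, kappa*pi_j, omega*pi_j,
## omega*kappa*pi_j for synonymous transversion/transition and nonsynonymous
## transversion/transition respectively.
.gy94Q <- function(kappa, omega, pi) {
  .codonSetup()
  p <- .codonEnv$pairs
  n <- 61L
  Q <- matrix(0, n, n)
  rate <- pi[p$j] * ifelse(p$transition, kappa, 1) * ifelse(p$nonsyn, omega, 1)
  Q[cbind(p$i, p$j)] <- rate
  diag(Q) <- -rowSums(Q)
  Q
}

## Mean substitution rate of Q at equilibrium pi (expected events per codon
## per unit time); used to normalise branch-length units.
.meanRate <- function(Q, pi) {
  -sum(pi * diag(Q))
}

## Nonsynonymous and synonymous flux of a rate matrix at equilibrium:
## rho_N = sum_{i != j, nonsyn} pi_i q_ij, rho_S likewise.
.fluxNS <- function(Q, pi) {
  .codonSetup()
  p <- .codonEnv$pairs
  q <- Q[cbind(p$i, p$j)]
  c(N = sum(pi[p$i] * q * p$nonsyn),
    S = sum(pi[p$i] * q * !p$nonsyn))
}

## Eigendecomposition of a reversible Q via the pi-symmetrised matrix.
## Returns A, B and lambda such that P(t) = A %*% diag(exp(lambda * t)) %*% B.
.eigenQ <- function(Q, pi) {
  sp <- sqrt(pi)
  S <- Q * (sp %o% (1 / sp))
  S <- (S + t(S)) / 2                    # kill asymmetry from roundoff
  e <- eigen(S, symmetric = TRUE)
  list(A = e$vectors / sp, B = t(e$vectors) * rep(sp, each = 61L),
       lambda = e$values)
}

## Transition probability matrix P(t) from an .eigenQ decomposition.
.probMatrix <- function(eig, t) {
  P <- eig$A %*% (exp(eig$lambda * t) * eig$B)
  P[P < 0] <- 0
  P
}
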