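## Percent-intact reading frames, gene classification, the convergent-loss
## screen, and the phylogenetic GLS association test.

#' Percent of the reading frame left intact by a set of lesions
#'
#' For one gene and one species, \code{%intact = 100 * intact codons /
#' total reference codons}, where a codon is non-intact iff it lies in a
#' deleted exon, or at or downstream of the first frameshift or premature
#' stop codon in reading order. Exons tagged as missing data (NBR/NRM) are
#' excluded from both numerator and denominator. Splice-site and
#' start-codon records do not enter the statistic under this definition.
#' Lesion positions are taken from the \code{refStart} column (reference
#' coding-sequence coordinates).
#'
#' @param lesions Lesion table for one or more species.
#' @param structure \linkS4class{GeneStructure}.
#' @param taxa Species to report; defaults to the taxa present in
#'   \code{lesions}.
#' @return Named numeric vector of percentages in [0, 100] (NA if every exon
#'   of a species is missing data).
#' @export
#' @examples
#' gs <- geneStructure(data.frame(exon = 1, start = 1, end = 900))
#' les <- data.frame(taxon = "sp1", exon = 1, refStart = 361, refEnd = 363,
#'                   class = "premature_stop")
#' computePctIntact(les, gs)   # first lesion at codon 121 -> 40%
computePctIntact <- function(lesions, structure, taxa = NULL) {
  lesions <- .asLesionTable(lesions)
  ex <- exonTable(structure)
  L <- codingLength(structure)
  nCod <- L %/% 3L
  if (is.null(taxa)) taxa <- unique(lesions$taxon)
  if (any(!is.na(lesions$refStart) & (lesions$refStart < 1L |
                                      lesions$refStart > L))) {
    .pgkStop("coordinateError", "lesion outside the gene bounds [1, %d]", L)
  }
  exonOfCodon <- ex$exon[findInterval(3L * seq_len(nCod) - 2L, ex$start)]

  out <- stats::setNames(numeric(length(taxa)), taxa)
  for (tx in taxa) {
    lt <- lesions[lesions$taxon == tx, , drop = FALSE]
    missingExons <- lt$exon[lt$class %in% c("exon_no_blast", "exon_no_reads")]
    deletedExons <- lt$exon[lt$class == "exon_deletion"]
    keep <- !(exonOfCodon %in% missingExons)
    nonIntact <- exonOfCodon %in% deletedExons
    trunc <- lt[lt$class %in% c("frameshift_deletion",
                                "frameshift_insertion") |
                  (lt$class == "premature_stop" &
                     (is.na(lt$subtype) | lt$subtype != "terminal")),
                , drop = FALSE]
    if (nrow(trunc)) {
      firstCodon <- min((trunc$refStart + 2L) %/% 3L)
      nonIntact <- nonIntact | seq_len(nCod) >= firstCodon
    }
    denom <- sum(keep)
    out[tx] <- if (denom == 0L) NA_real_ else
      100 * sum(keep & !nonIntact) / denom
  }
  out
}

#' Classify genes from percent-intact values
#'
#' A gene is \code{inactivated} when %intact is below 80, \code{intact} when
#' %intact is at least 90, and \code{ambiguous} in between.
#'
#' @param pct Numeric vector of percentages in [0, 100] (NA allowed).
#' @return Character vector in \code{{"inactivated", "intact", "ambiguous"}}.
#' @export
#' @examples
#' classifyGene(c(79.99, 80, 90, 85))
classifyGene <- function(pct) {
  if (any(pct < 0 | pct > 100, na.rm = TRUE)) {
    .pgkStop("valueError", "%%intact values must lie in [0, 100]")
  }
  out <- rep(NA_character_, length(pct))
  out[!is.na(pct) & pct < 80] <- "inactivated"
  out[!is.na(pct) & pct >= 90] <- "intact"
  out[!is.na(pct) & pct >= 80 & pct < 90] <- "ambiguous"
  out
}

#' Screen a percent-intact matrix for convergently inactivated genes
#'
#' A gene is a candidate when it is inactivated (%intact < 80) in at least
#' \code{minFocalLost} of the focal (toothless/enamelless) species and intact
#' (%intact >= 90) in at least 90 percent of the background species.
#' Candidates are ranked by the number of focal species with an inactivated
#' copy (largest first), then by the number of background species without an
#' intact copy (smallest first), then by gene id.
#'
#' @param profile Numeric gene-by-species matrix of %intact values.
#' @param focalSpecies,backgroundSpecies Disjoint character vectors of
#'   column names.
#' @param minFocalLost Minimum focal species with an inactivated gene
#'   (default 2).
#' @param minBackgroundIntact Minimum fraction of background species with an
#'   intact gene (default 0.90, compared as a real number).
#' @param tree Optional \code{ape::phylo} with branch lengths covering all
#'   screened species; when supplied, a phylogeny-corrected P-value for the
#'   association between %intact and focal status is computed per gene with
#'   [pglsFit()].
#' @return List with \code{candidates} (ranked \code{data.frame} with columns
#'   \code{gene}, \code{nFocalLost}, \code{nBackgroundNotIntact}, and
#'   \code{pglsP} when \code{tree} is given) and \code{all} (the same
#'   statistics for every gene plus a \code{candidate} flag).
#' @export
screenConvergentLosses <- function(profile, focalSpecies, backgroundSpecies,
                                   minFocalLost = 2L,
                                   minBackgroundIntact = 0.90, tree = NULL) {
  if (length(backgroundSpecies) == 0L) {
    .pgkStop("parameterError", "background species set is empty")
  }
  if (length(intersect(focalSpecies, backgroundSpecies))) {
    .pgkStop("parameterError", "focal and background sets must be disjoint")
  }
  miss <- setdiff(c(focalSpecies, backgroundSpecies), colnames(profile))
  if (length(miss)) {
    .pgkStop("inputError", "species missing from the matrix: %s",
             paste(miss, collapse = ", "))
  }
  genes <- rownames(profile)
  cls <- apply(profile, 2L, classifyGene)
  rownames(cls) <- genes
  nFocalLost <- rowSums(cls[, focalSpecies, drop = FALSE] == "inactivated",
                        na.rm = TRUE)
  nBgIntact <- rowSums(cls[, backgroundSpecies, drop = FALSE] == "intact",
                       na.rm = TRUE)
  nBgNotIntact <- length(backgroundSpecies) - nBgIntact
  cand <- nFocalLost >= minFocalLost &
    nBgIntact >= minBackgroundIntact * length(backgroundSpecies)

  all <- data.frame(gene = genes, nFocalLost = nFocalLost,
                    nBackgroundNotIntact = nBgNotIntact,
                    candidate = cand, row.names = NULL,
                    stringsAsFactors = FALSE)
  if (!is.null(tree)) {
    species <- c(focalSpecies, backgroundSpecies)
    x <- stats::setNames(as.numeric(species %in% focalSpecies), species)
    all$pglsP <- vapply(genes, function(g) {
      y <- profile[g, species]
      pglsFit(tree, y, x)$p.value
    }, numeric(1))
  }
  ord <- order(-all$nFocalLost, all$nBackgroundNotIntact, all$gene,
               method = "radix")
  ranked <- all[ord, , drop = FALSE]
  candidates <- ranked[ranked$candidate, setdiff(names(ranked), "candidate"),
                       drop = FALSE]
  rownames(candidates) <- rownames(ranked) <- NULL
  list(candidates = candidates, all = ranked)
}

#' Phylogenetic generalized least squares association test
#'
#' Regresses a continuous per-species variable on a predictor under a
#' Brownian-motion covariance: \code{V[i, j]} is the shared root-to-tip path
#' length of species i and j on the tree. The slope is the GLS estimate
#' \code{(X' V^-1 X)^-1 X' V^-1 y} with an intercept, tested two-sided
#' against a t distribution with n - 2 degrees of freedom.
#'
#' @param tree \code{ape::phylo} with branch lengths covering all species.
#' @param y Named numeric response (e.g. %intact per species).
#' @param x Named numeric predictor (e.g. 0/1 focal status).
#' @return List with \code{slope}, \code{se}, \code{t}, \code{p.value},
#'   \code{intercept} and \code{df}.
#' @export
pglsFit <- function(tree, y, x) {
  species <- tree$tip.label
  if (!all(species %in% names(y)) || !all(species %in% names(x))) {
    .pgkStop("inputError", "y and x must be named and cover all tree tips")
  }
  y <- y[species]
  x <- x[species]
  n <- length(species)
  if (n < 3L) .pgkStop("inputError", "need at least 3 species")
  V <- ape::vcv(tree)
  Lc <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(Lc)) {
    .pgkStop("covarianceError",
             "Brownian covariance matrix is singular on this tree")
  }
  ## whiten: V = Lc' Lc, so backsolving by Lc' gives iid errors
  z <- backsolve(Lc, y, transpose = TRUE)
  X <- cbind(intercept = 1, slope = x)
  W <- backsolve(Lc, X, transpose = TRUE)
  colnames(W) <- colnames(X)
  XtX <- crossprod(W)
  if (rcond(XtX) < 1e-14) {
    .pgkStop("covarianceError", "design is singular (constant predictor?)")
  }
  beta <- solve(XtX, crossprod(W, z))
  resid <- z - W %*% beta
  df <- n - 2L
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 * diag(solve(XtX)))
  slope <- beta["slope", 1L]
  scale <- max(1, mean(z^2))
  if (sigma2 <= 1e-20 * scale) {
    ## exact fit: a (numerically) zero slope is no association at all
    slope <- if (abs(slope) <= 1e-10 * sqrt(scale)) 0 else slope
    tval <- if (slope == 0) 0 else Inf
    p <- if (slope == 0) 1 else 0
  } else {
    tval <- slope / se["slope"]
    p <- 2 * stats::pt(-abs(tval), df = df)
  }
  list(slope = unname(slope), se = unname(se["slope"]), t = unname(tval),
       p.value = unname(p), intercept = unname(beta["intercept", 1L]),
       df = df)
}

#' Generate a gene-by-species percent-intact matrix with planted losses
#'
#' Simulates the input of the convergent-loss screen: \code{nConvergent}
#' genes are lost in every focal species (the planted convergent losses);
#' other focal cells are lost sporadically with probability
#' \code{lossRateFocal}, and background cells with probability
#' \code{bgLossRate}. Lost cells draw %intact uniformly from [0, 75);
#' retained cells draw \code{100 - |Normal(0, noiseSd)|}, truncated to
#' [0, 100].
#'
#' @param nGenes Number of genes.
#' @param tree Species tree (\code{ape::phylo}); its tips are the species.
#' @param focalSpecies Subset of tips forming the focal (trait-loss) set.
#' @param lossRateFocal Sporadic loss probability in focal species for
#'   non-planted genes (default 0.05).
#' @param noiseSd Standard deviation of the retained-cell noise, percentage
#'   points (default 3).
#' @param seed Integer seed; truth labels are deterministic given the seed.
#' @param nConvergent Number of planted convergent genes (default 3).
#' @param bgLossRate Sporadic loss probability in background species
#'   (default 0.02).
#' @return List with \code{matrix} (genes x species %intact),
#'   \code{truth} (logical lost/retained matrix) and \code{convergentGenes}
#'   (character vector of planted gene ids).
#' @export
generateScreenMatrix <- function(nGenes, tree, focalSpecies,
                                 lossRateFocal = 0.05, noiseSd = 3,
                                 seed = 1L, nConvergent = 3L,
                                 bgLossRate = 0.02) {
  species <- tree$tip.label
  if (!all(focalSpecies %in% species)) {
    .pgkStop("parameterError", "focal species must be tree tips")
  }
  for (p in c(lossRateFocal, bgLossRate)) {
    if (p < 0 || p > 1) {
      .pgkStop("parameterError", "loss probabilities must lie in [0, 1]")
    }
  }
  if (noiseSd < 0) .pgkStop("parameterError", "noiseSd must be >= 0")
  if (nConvergent > nGenes) {
    .pgkStop("parameterError", "nConvergent exceeds nGenes")
  }
  set.seed(seed)
  genes <- sprintf("gene%03d", seq_len(nGenes))
  lost <- matrix(FALSE, nGenes, length(species),
                 dimnames = list(genes, species))
  conv <- if (nConvergent > 0L) sort(sample(genes, nConvergent)) else
    character(0)
  lost[conv, focalSpecies] <- TRUE
  bg <- setdiff(species, focalSpecies)
  other <- setdiff(genes, conv)
  lost[other, focalSpecies] <-
    matrix(stats::runif(length(other) * length(focalSpecies)) < lossRateFocal,
           length(other), length(focalSpecies))
  lost[, bg] <- matrix(stats::runif(nGenes * length(bg)) < bgLossRate,
                       nGenes, length(bg))
  m <- matrix(0, nGenes, length(species), dimnames = list(genes, species))
  nLost <- sum(lost)
  m[lost] <- stats::runif(nLost, 0, 75)
  m[!lost] <- pmin(100, pmax(0, 100 - abs(stats::rnorm(sum(!lost), 0,
                                                       noiseSd))))
  list(matrix = m, truth = lost, convergentGenes = conv)
}
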