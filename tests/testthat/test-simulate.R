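test_that("zero-length trees copy the root draw; seeds make runs identical", {
  tr <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  tru <- simTruth(data.frame(branch = edgeIds(tr), omega = 0.5), seed = 3L)
  aln <- simulateCodonAlignment(tr, tru, 50)
  expect_equal(length(unique(as.character(aln))), 1L)

  tr2 <- ape::read.tree(text = "((A:0.2,B:0.2):0.1,C:0.3);")
  tru2 <- simTruth(data.frame(branch = edgeIds(tr2), omega = 0.5), seed = 9L)
  a1 <- simulateCodonAlignment(tr2, tru2, 100)
  a2 <- simulateCodonAlignment(tr2, tru2, 100)
  expect_identical(as.character(a1), as.character(a2))
  ## no stop codons can be generated
  expect_false(any(vapply(pseudogeneKit:::.splitCodons(as.character(a1[1])),
                          function(cd) cd %in% c("TAA", "TAG", "TGA"),
                          logical(1))))
})

test_that("long-branch codon frequencies converge to the equilibrium", {
  tr <- ape::read.tree(text = "(A:0,B:25);")
  set.seed(5)
  pi <- runif(61, 0.5, 1.5)
  pi <- pi / sum(pi)
  tru <- simTruth(data.frame(branch = edgeIds(tr), omega = 0.7),
                  kappa = 2, pi = pi, seed = 21L)
  aln <- simulateCodonAlignment(tr, tru, 1e5)
  cods <- pseudogeneKit:::.splitCodons(as.character(aln["B"]))
  obs <- table(factor(cods, levels = senseCodons()))
  gof <- stats::chisq.test(obs, p = pi)
  expect_gt(gof$p.value, 0.01)
})

test_that("counting dN/dS of neutral simulations is 1 within Monte Carlo error", {
  tr <- ape::read.tree(text = "(A:0,B:0.4);")
  tru <- simTruth(data.frame(branch = edgeIds(tr), omega = 1), kappa = 2,
                  seed = 13L)
  aln <- simulateCodonAlignment(tr, tru, 20000)
  est <- countingDnDs(as.character(aln["A"]), as.character(aln["B"]),
                      kappa = 2)
  expect_gt(est$omega, 0.9)
  expect_lt(est$omega, 1.1)
})

test_that("within-branch selection switches need ages and a valid switch age", {
  tr <- readTreeFile(ape::read.tree(text = "((A:10,B:10)ab:10,C:20)r;"),
                     mode = "ages")
  ids <- edgeIds(tr)
  bo <- data.frame(branch = ids, omega = 0.5)
  bo$omegaPost <- ifelse(bo$branch == "A", 1, NA)
  bo$switchAge <- ifelse(bo$branch == "A", 4, NA)
  tru <- simTruth(bo, rate = 0.02, seed = 2L)
  expect_s4_class(tru, "SimTruth")
  aln <- simulateCodonAlignment(tr, tru, 30)
  expect_equal(unname(Biostrings::width(aln)), rep(90L, 3L))

  bad <- bo
  bad$switchAge[bad$branch == "A"] <- 25       # outside [0, 10]
  expect_error(simulateCodonAlignment(tr, simTruth(bad, rate = 0.02,
                                                   seed = 2L), 30),
               class = "truthError")
  ## switch on a lengths-mode tree is a truth error
  trL <- ape::read.tree(text = "((A:10,B:10)ab:10,C:20)r;")
  expect_error(simulateCodonAlignment(trL, simTruth(bo, rate = 0.02,
                                                    seed = 2L), 30),
               class = "truthError")
})

test_that("lesion injection is reversible bookkeeping", {
  aln <- makeFixtureAln(c("ref", "q1"), 60, seed = 8)
  gs <- makeStructure(60, 3)

  ## empty directive list: alignment unchanged, empty truth
  out <- injectLesions(aln, gs, NULL, referenceTaxon = "ref")
  expect_identical(as.character(out$alignment), as.character(aln))
  expect_equal(nrow(out$lesions), 0L)

  ## a 1-nt deletion at codon 10 shifts the downstream translation frame
  dir <- data.frame(taxon = "q1", class = "D", exon = 1L, at = 28L,
                    length = 1L)
  mut <- injectLesions(aln, gs, dir, referenceTaxon = "ref", seed = 1)
  qDegap <- gsub("-", "", as.character(mut$alignment["q1"]))
  refChars <- as.character(aln["ref"])
  aaRef <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(refChars, 1, 177))))
  aaMut <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(qDegap, 1, 177)), no.init.codon = TRUE))
  expect_equal(substr(aaRef, 1, 9), substr(aaMut, 1, 9))
  expect_false(substr(aaRef, 11, 59) == substr(aaMut, 11, 59))

  ## colliding directives are an injection error
  dir2 <- data.frame(taxon = "q1", class = "D", exon = 1L, at = 28L,
                     length = 2L)
  expect_error(injectLesions(mut$alignment, gs, dir2, referenceTaxon = "ref"),
               class = "injectionError")
})

test_that("screen matrices honour their truth labels and degenerate settings", {
  tr <- ape::rtree(10, rooted = TRUE)
  tr$tip.label <- sprintf("sp%02d", 1:10)
  ## no losses, no noise -> all cells exactly 100
  g0 <- generateScreenMatrix(15, tr, focalSpecies = c("sp01", "sp02"),
                             lossRateFocal = 0, noiseSd = 0, seed = 4,
                             nConvergent = 0, bgLossRate = 0)
  expect_true(all(g0$matrix == 100))
  expect_false(any(g0$truth))

  ## truth labels deterministic under a fixed seed
  g1 <- generateScreenMatrix(30, tr, focalSpecies = c("sp01", "sp02"),
                             seed = 77)
  g2 <- generateScreenMatrix(30, tr, focalSpecies = c("sp01", "sp02"),
                             seed = 77)
  expect_identical(g1$truth, g2$truth)
  expect_identical(g1$convergentGenes, g2$convergentGenes)
  ## lost cells live in [0, 75), retained cells near 100
  expect_true(all(g1$matrix[g1$truth] < 75))
  expect_true(all(g1$matrix[!g1$truth] > 75))

  expect_error(generateScreenMatrix(10, tr, "sp01", lossRateFocal = 1.5),
               class = "parameterError")
  expect_error(generateScreenMatrix(10, tr, "nope"),
               class = "parameterError")
})
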