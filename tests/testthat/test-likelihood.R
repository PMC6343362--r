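test_that("zero-length trees give the closed-form site-frequency likelihood", {
  aln <- makeFixtureAln(c("A", "B", "C"), 10, seed = 14)
  tr <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  pi <- buildCodonFrequencies(aln, "CF1")
  pd <- pseudogeneKit:::.pruningData(aln, tr)
  ll <- pseudogeneKit:::.branchModelLnL(pd, kappa = 2, omegas = 0.5,
                                        blens = rep(0, 4), pi = pi,
                                        edgeCat = rep(1L, 4))
  obs <- pseudogeneKit:::.splitCodons(as.character(aln[1]))
  obs <- obs[obs %in% senseCodons()]   # the terminal stop is missing data
  expect_equal(ll, sum(log(pi[obs])), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("pruning equals brute-force summation over ancestral states", {
  set.seed(31)
  tr <- ape::read.tree(text = "((A:0.15,B:0.3):0.2,C:0.4);")
  tru <- simTruth(data.frame(branch = edgeIds(tr), omega = 0.6), kappa = 3,
                  seed = 77L)
  aln <- simulateCodonAlignment(tr, tru, 5)
  pi <- rep(1 / 61, 61)
  pd <- pseudogeneKit:::.pruningData(aln, tr)
  ids <- edgeIds(ape::reorder.phylo(tr, "postorder"))
  blens <- ape::reorder.phylo(tr, "postorder")$edge.length
  ll <- pseudogeneKit:::.branchModelLnL(pd, kappa = 3, omegas = 0.6,
                                        blens = blens, pi = pi,
                                        edgeCat = rep(1L, 4))
  oracle <- bruteCodonLnL(aln, tr, kappa = 3, omega = 0.6, pi = pi)
  expect_equal(ll, oracle, tolerance = 1e-8)
})

test_that("the likelihood is invariant to root placement (pulley principle)", {
  set.seed(8)
  base <- ape::read.tree(text =
    "((A:0.1,B:0.2):0.15,(C:0.25,D:0.1):0.05);")
  tru <- simTruth(data.frame(branch = edgeIds(base), omega = 0.5),
                  kappa = 2, seed = 5L)
  aln <- simulateCodonAlignment(base, tru, 40)
  pi <- rep(1 / 61, 61)
  lnLof <- function(tree) {
    pd <- pseudogeneKit:::.pruningData(aln, tree)
    tr <- pd$tree
    pseudogeneKit:::.branchModelLnL(pd, 2, 0.5, tr$edge.length, pi,
                                    rep(1L, nrow(tr$edge)))
  }
  l0 <- lnLof(base)
  for (og in c("A", "C", "D")) {
    rerooted <- ape::root(ape::unroot(base), outgroup = og,
                          resolve.root = TRUE)
    expect_equal(lnLof(rerooted), l0, tolerance = 1e-8)
  }
})

test_that("simulated dN/dS is recovered by the maximum-likelihood fit", {
  setup <- eightTaxonSetup()
  oneCat <- branchCategoryMap(
    data.frame(branch = setup$ids, category = "background"))
  tru <- simTruth(data.frame(branch = setup$ids, omega = 0.5), kappa = 2,
                  seed = 101L)
  aln <- simulateCodonAlignment(setup$tree, tru, 2000)
  fit <- fitBranchModel(aln, setup$tree, oneCat, "CF1", nStarts = 1)
  expect_gt(omegaHat(fit)["background"], 0.45)
  expect_lt(omegaHat(fit)["background"], 0.55)
  expect_gt(kappaHat(fit), 1.7)
  expect_lt(kappaHat(fit), 2.3)
  ## fitted branch lengths recover the simulated scale
  expect_equal(mean(fittedBranchLengths(fit)), 0.1, tolerance = 0.02)
  ## expected substitution counts are positive and finite
  counts <- substitutionCounts(fit)
  expect_true(all(counts$NdN > 0) && all(counts$SdS > 0))
})

test_that("adding a category never decreases the optimised likelihood", {
  setup <- eightTaxonSetup()
  tru <- simTruth(data.frame(branch = setup$ids,
                             omega = ifelse(setup$ids %in% setup$pseudo,
                                            0.9, 0.4)),
                  kappa = 2, seed = 55L)
  aln <- simulateCodonAlignment(setup$tree, tru, 400)
  oneCat <- branchCategoryMap(
    data.frame(branch = setup$ids, category = "background"))
  fit1 <- fitBranchModel(aln, setup$tree, oneCat, "CF1", nStarts = 1)
  fit2 <- fitBranchModel(aln, setup$tree, setup$categories, "CF1",
                         nStarts = 1)
  expect_gte(lnL(fit2), lnL(fit1) - 1e-4)
})

test_that("fixing a category's omega constrains the fit for an LRT", {
  setup <- eightTaxonSetup()
  tru <- simTruth(data.frame(branch = setup$ids,
                             omega = ifelse(setup$ids %in% setup$pseudo,
                                            1, 0.5)),
                  kappa = 2, seed = 7L)
  aln <- simulateCodonAlignment(setup$tree, tru, 300)
  free <- fitBranchModel(aln, setup$tree, setup$categories, "CF1",
                         nStarts = 1)
  fixed <- fitBranchModel(aln, setup$tree, setup$categories, "CF1",
                          fixOmega = c(pseudogenic = 1), nStarts = 1)
  expect_equal(unname(omegaHat(fixed)["pseudogenic"]), 1)
  expect_gte(lnL(free), lnL(fixed) - 1e-6)
  ## data were simulated at the fixed value: the test should not reject
  p <- lrtFixedOmega(lnL(free), lnL(fixed))$p.value
  expect_gt(p, 0.01)
})
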