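test_that("percent intact follows the truncation-plus-exon-loss rule", {
  gs <- makeStructure(300, 10)

  ## no lesions -> 100
  expect_equal(unname(computePctIntact(emptyLesionTable(), gs,
                                       taxa = "sp")), 100)

  ## stop at codon 121 of 300 -> 40
  stop121 <- data.frame(taxon = "sp", exon = 5L, refStart = 361L,
                        refEnd = 363L, class = "premature_stop")
  expect_equal(unname(computePctIntact(stop121, gs)), 40)

  ## whole-gene deletion -> 0
  allDel <- data.frame(taxon = "sp", exon = 1:10,
                       refStart = exonTable(gs)$start,
                       refEnd = exonTable(gs)$end, class = "exon_deletion")
  expect_equal(unname(computePctIntact(allDel, gs)), 0)

  ## missing-data exons leave numerator and denominator
  nbr <- data.frame(taxon = "sp", exon = 1L, refStart = 1L, refEnd = 90L,
                    class = "exon_no_blast")
  expect_equal(unname(computePctIntact(nbr, gs)), 100)
  nbrStop <- rbind(nbr, data.frame(taxon = "sp", exon = 5L, refStart = 361L,
                                   refEnd = 363L, class = "premature_stop"))
  ## 300 - 30 codons counted; intact = codons 31..120 of the remainder
  expect_equal(unname(computePctIntact(nbrStop, gs)), 100 * 90 / 270)

  ## a terminal-stop record does not truncate
  term <- data.frame(taxon = "sp", exon = 10L, refStart = 898L,
                     refEnd = 900L, class = "premature_stop",
                     subtype = "terminal")
  expect_equal(unname(computePctIntact(term, gs)), 100)

  expect_error(computePctIntact(data.frame(taxon = "sp", exon = 1L,
                                           refStart = 10000L,
                                           refEnd = 10002L,
                                           class = "premature_stop"), gs),
               class = "coordinateError")
})

test_that("gene classification is the documented step function", {
  expect_equal(classifyGene(c(0, 79.999, 80, 85, 89.999, 90, 100)),
               c("inactivated", "inactivated", "ambiguous", "ambiguous",
                 "ambiguous", "intact", "intact"))
  expect_error(classifyGene(101), class = "valueError")
  expect_error(classifyGene(-0.5), class = "valueError")
})

test_that("the convergent-loss screen recovers planted genes exactly", {
  tr <- ape::rtree(61, rooted = TRUE)
  tr$tip.label <- sprintf("sp%02d", 1:61)
  focal <- c("sp01", "sp02", "sp03", "sp04")
  bg <- setdiff(tr$tip.label, focal)
  gen <- generateScreenMatrix(50, tr, focal, seed = 11)

  res <- screenConvergentLosses(gen$matrix, focal, bg)

  ## oracle: apply the published thresholds to the generator's truth labels
  lostF <- rowSums(gen$truth[, focal])
  intactBg <- rowSums(!gen$truth[, bg] &
                        gen$matrix[, bg] >= 90)
  oracle <- rownames(gen$matrix)[lostF >= 2 & intactBg >= 0.9 * length(bg)]
  expect_setequal(res$candidates$gene, oracle)
  expect_true(all(gen$convergentGenes %in% oracle))
  ## the planted genes occupy the top ranks (maximal focal losses)
  top <- res$candidates$gene[seq_along(gen$convergentGenes)]
  expect_setequal(top, gen$convergentGenes)

  ## all cells 100 -> empty candidate list
  m100 <- matrix(100, 5, 10,
                 dimnames = list(paste0("g", 1:5), tr$tip.label[1:10]))
  res100 <- screenConvergentLosses(m100, c("sp01", "sp02"),
                                   tr$tip.label[3:10])
  expect_equal(nrow(res100$candidates), 0L)
})

test_that("screen ranking uses the two sort keys and the documented tie-break", {
  species <- c(paste0("f", 1:4), paste0("b", 1:10))
  m <- matrix(100, 3, 14, dimnames = list(c("gB", "gA", "gC"), species))
  ## gA and gB: 4 focal losses each; gB has 3 non-intact background species,
  ## gA has 1; gC: 3 focal losses
  m["gA", paste0("f", 1:4)] <- 10
  m["gB", paste0("f", 1:4)] <- 10
  m["gC", paste0("f", 1:3)] <- 10
  m["gA", "b1"] <- 85
  m["gB", c("b1", "b2", "b3")] <- 85
  res <- screenConvergentLosses(m, paste0("f", 1:4), paste0("b", 1:10),
                                minBackgroundIntact = 0.5)
  expect_equal(res$candidates$gene, c("gA", "gB", "gC"))
  expect_equal(res$candidates$nBackgroundNotIntact, c(1L, 3L, 0L))

  ## row/column permutation invariance
  perm <- m[c(3, 1, 2), sample(ncol(m))]
  res2 <- screenConvergentLosses(perm, paste0("f", 1:4), paste0("b", 1:10),
                                 minBackgroundIntact = 0.5)
  expect_equal(res2$candidates, res$candidates)

  expect_error(screenConvergentLosses(m, "f1", character(0)),
               class = "parameterError")
  expect_error(screenConvergentLosses(m, "f1", c("f1", "b1")),
               class = "parameterError")
})

test_that("PGLS reduces to OLS on a star tree and matches direct algebra", {
  ## star tree with equal terminal branches: V is proportional to identity
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1,F:1);")
  set.seed(21)
  y <- stats::setNames(rnorm(6, 90, 5), star$tip.label)
  x <- stats::setNames(c(1, 1, 1, 0, 0, 0), star$tip.label)
  fit <- pglsFit(star, y, x)
  ols <- summary(stats::lm(y ~ x))$coefficients
  expect_equal(fit$slope, ols["x", "Estimate"], tolerance = 1e-10)
  expect_equal(fit$se, ols["x", "Std. Error"], tolerance = 1e-10)
  expect_equal(fit$p.value, ols["x", "Pr(>|t|)"], tolerance = 1e-10)

  ## constant response: slope 0, P = 1
  yc <- stats::setNames(rep(50, 6), star$tip.label)
  fitc <- pglsFit(star, yc, x)
  expect_equal(fitc$slope, 0)
  expect_equal(fitc$p.value, 1)

  ## 6-leaf non-star fixture against the explicit GLS matrix formula
  tr <- ape::read.tree(text =
    "(((A:1,B:2):1.5,(C:0.5,D:1):2):1,(E:2,F:1.2):2.4);")
  y2 <- stats::setNames(c(95, 88, 40, 40, 99, 97), tr$tip.label)
  x2 <- stats::setNames(c(0, 0, 1, 1, 0, 0), tr$tip.label)
  fit2 <- pglsFit(tr, y2, x2)
  V <- ape::vcv(tr)
  X <- cbind(1, x2[rownames(V)])
  yv <- y2[rownames(V)]
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% yv)
  resid <- yv - X %*% beta
  s2 <- as.numeric(t(resid) %*% Vi %*% resid) / 4
  se <- sqrt(s2 * solve(t(X) %*% Vi %*% X)[2, 2])
  expect_equal(fit2$slope, beta[2, 1], tolerance = 1e-10)
  expect_equal(fit2$se, se, tolerance = 1e-10)
  expect_equal(fit2$p.value, 2 * stats::pt(-abs(beta[2, 1] / se), 4),
               tolerance = 1e-10)

  ## degenerate tree: zero-length star collapses the covariance
  zero <- ape::read.tree(text = "(A:0,B:0,C:0,D:0);")
  yz <- stats::setNames(rnorm(4), zero$tip.label)
  xz <- stats::setNames(c(1, 1, 0, 0), zero$tip.label)
  expect_error(pglsFit(zero, yz, xz), class = "covarianceError")
})
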