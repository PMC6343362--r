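test_that("inject -> scan round trip recovers every lesion class exactly", {
  taxa <- c("ref", sprintf("t%d", 1:6))
  aln <- makeFixtureAln(taxa, 120, seed = 2)
  gs <- makeStructure(120, 5)
  dir <- data.frame(
    taxon = c("t1", "t1", "t2", "t2", "t3", "t3", "t4", "t4", "t5", "t6"),
    class = c("S", "D", "I", "Do", "SCM", "Ac", "NBR", "S", "ED", "NRM"),
    exon  = c(2L, 3L, 2L, 2L, 1L, 3L, 4L, 5L, 3L, 2L))
  inj <- injectLesions(aln, gs, dir, referenceTaxon = "ref", seed = 31)
  tags <- data.frame(taxon = c("t4", "t6"), exon = c(4L, 2L),
                     tag = c("NBR", "NRM"))
  found <- scanAlignment(inj$alignment, "ref", gs,
                         spliceDinucs = inj$spliceDinucs,
                         evidenceTags = tags)
  truth <- inj$lesions
  keyOf <- function(d) paste(d$taxon, d$class, d$start, d$end, d$intron,
                             sep = "|")
  expect_setequal(keyOf(found), keyOf(truth))          # precision = recall = 1
  ## no spurious calls on untouched taxa
  expect_false(any(found$taxon %in% c("ref")))
  expect_equal(sort(unique(found$taxon)), sort(unique(dir$taxon)))
})

test_that("a query identical to the reference yields no records", {
  aln <- makeFixtureAln(c("ref", "q"), 50, seed = 6)
  gs <- makeStructure(50, 2)
  expect_equal(nrow(scanTaxon(aln, "ref", "q", gs)), 0L)
})

test_that("scan output is invariant to the order of taxa in the alignment", {
  taxa <- c("ref", "t1", "t2")
  aln <- makeFixtureAln(taxa, 60, seed = 3)
  gs <- makeStructure(60, 3)
  dir <- data.frame(taxon = c("t1", "t2"), class = c("S", "D"),
                    exon = c(2L, 3L))
  inj <- injectLesions(aln, gs, dir, referenceTaxon = "ref", seed = 8)
  shuffled <- inj$alignment[c(3, 1, 2)]
  a <- scanAlignment(inj$alignment, "ref", gs, queryTaxa = c("t1", "t2"))
  b <- scanAlignment(shuffled, "ref", gs, queryTaxa = c("t1", "t2"))
  expect_equal(a, b)
})

test_that("four stops in four exons mirror the armadillo pattern", {
  aln <- makeFixtureAln(c("ref", "arm"), 400, seed = 10)
  gs <- makeStructure(400, 10)
  dir <- data.frame(taxon = "arm", class = "S", exon = c(1L, 3L, 5L, 10L))
  inj <- injectLesions(aln, gs, dir, referenceTaxon = "ref", seed = 12)
  found <- scanTaxon(inj$alignment, "ref", "arm", gs)
  expect_equal(nrow(found), 4L)
  expect_true(all(found$class == "premature_stop"))
  expect_equal(found$start, sort(inj$lesions$start))
  expect_equal(found$end, found$start + 2L)
})

test_that("stop calling frame: reference frame by default, query frame on request", {
  ## 60-codon toy with a 2-nt deletion at codon 50 engineering a downstream
  ## out-of-frame TAA
  nCod <- 60L
  cds <- makeCds(nCod, seed = 42)
  ## plant TAA straddling reference codons 53/54 so the +2-shifted query
  ## frame (after a 2-nt deletion) reads it in frame
  substr(cds, 159, 161) <- "TAA"
  aln <- Biostrings::DNAStringSet(c(ref = cds, q = cds))
  gs <- makeStructure(nCod, 1)
  dir <- data.frame(taxon = "q", class = "D", exon = 1L, at = 148L,
                    length = 2L)
  inj <- injectLesions(aln, gs, dir, referenceTaxon = "ref", seed = 1)

  refFrame <- scanTaxon(inj$alignment, "ref", "q", gs)
  expect_equal(refFrame$class, "frameshift_deletion")

  qFrame <- scanTaxon(inj$alignment, "ref", "q", gs, stopFrame = "query")
  expect_true("frameshift_deletion" %in% qFrame$class)
  qStops <- qFrame[qFrame$class == "premature_stop", ]
  expect_gt(nrow(qStops), 0L)
  ## oracle: direct translation of the degapped query in its own frame
  qDegap <- gsub("-", "", as.character(inj$alignment["q"]))
  usable <- nchar(qDegap) - nchar(qDegap) %% 3
  aa <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(qDegap, 1, usable)))), "")[[1]]
  oracleStops <- which(aa[-length(aa)] == "*")
  expect_equal(nrow(qStops), length(oracleStops))
})

test_that("a mutated terminal stop is called as an altered stop", {
  aln <- makeFixtureAln(c("ref", "q"), 40, seed = 5)
  m <- as.matrix(aln)
  rownames(m) <- names(aln)
  m["q", 118:120] <- c("T", "G", "C")     # TAA -> TGC
  aln2 <- pseudogeneKit:::.matToDss(m)
  gs <- makeStructure(40, 1)
  found <- scanTaxon(aln2, "ref", "q", gs)
  expect_equal(found$class, "premature_stop")
  expect_equal(found$subtype, "terminal")
})

test_that("an intact reference is a precondition", {
  aln <- makeFixtureAln(c("ref", "q"), 30, seed = 7)
  m <- as.matrix(aln)
  rownames(m) <- names(aln)
  m["ref", 1:3] <- c("G", "T", "G")       # reference loses its start
  gs <- makeStructure(30, 1)
  expect_error(scanTaxon(pseudogeneKit:::.matToDss(m), "ref", "q", gs),
               class = "referenceFrameError")
})

test_that("GC donors warn instead of being called lesions", {
  aln <- makeFixtureAln(c("ref", "q"), 30, seed = 9)
  gs <- makeStructure(30, 2)
  sd <- data.frame(taxon = "q", intron = 1L, donor = "GC", acceptor = "AG")
  expect_warning(out <- scanTaxon(aln, "ref", "q", gs, spliceDinucs = sd),
                 "GC donor")
  expect_equal(nrow(out), 0L)
})

test_that("alternative splice sites rescue frame-preserving offsets", {
  ## canonical GT six nt upstream, inside the exon: exon 6 bp shorter
  res <- findAlternativeSpliceSite("CAGGTAAGG", "ATAAGTCC", "donor")
  expect_equal(res$verdict, "rescued_with_offset")
  expect_equal(res$offset, -6L)

  ## no canonical site within the window
  res2 <- findAlternativeSpliceSite("CACCCAACC", "ATAACCCC", "donor")
  expect_equal(res2$verdict, "not_rescued")
  expect_true(is.na(res2$offset))

  ## nearest candidate at -4 is not frame-preserving; -9 wins
  exon <- "CCCCGTCCCGTCC"   # GT at offsets -9 and -4 from the donor
  res3 <- findAlternativeSpliceSite(exon, "ATAACCCC", "donor")
  expect_equal(res3$offset, -9L)

  ## acceptor geometry: AG inside the exon shortens it
  res4 <- findAlternativeSpliceSite("CAGCCC", "TTTTTTAG", "acceptor")
  expect_equal(res4$offset, -3L)

  ## the sperm-whale-style case: a GT far downstream is outside the default
  ## window and the site stays unrescued
  farIntron <- paste0("AT", strrep("C", 73), "GTAAA")
  expect_equal(findAlternativeSpliceSite("CAG", farIntron, "donor")$verdict,
               "not_rescued")
  expect_equal(findAlternativeSpliceSite("CAG", farIntron, "donor",
                                         window = 80)$offset, 75L)
})
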