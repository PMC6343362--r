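## Fixture builders shared across the test files. Everything is generated in
## code; no binary data.

## intact coding sequence: ATG ... TAA with no internal stop
makeCds <- function(nCodons, seed = 1L) {
  set.seed(seed)
  sense <- senseCodons()
  body <- sample(setdiff(sense, "ATG"), nCodons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

## alignment of identical intact copies of one CDS
makeFixtureAln <- function(taxa, nCodons, seed = 1L) {
  cds <- makeCds(nCodons, seed)
  aln <- Biostrings::DNAStringSet(rep(cds, length(taxa)))
  names(aln) <- taxa
  aln
}

## contiguous exon tiling of a coding sequence
makeStructure <- function(nCodons, nExons) {
  L <- 3L * nCodons
  cuts <- round(seq(0, L, length.out = nExons + 1L))
  geneStructure(data.frame(exon = seq_len(nExons),
                           start = cuts[-length(cuts)] + 1L,
                           end = cuts[-1L]))
}

## balanced 8-taxon tree with a pseudogenic clade (E..H), used by the
## simulation-recovery tests
eightTaxonSetup <- function(edgeLen = 0.1) {
  txt <- sprintf(paste0("(((A:%1$g,B:%1$g)ab:%1$g,(C:%1$g,D:%1$g)cd:%1$g)",
                        "abcd:%1$g,((E:%1$g,F:%1$g)ef:%1$g,",
                        "(G:%1$g,H:%1$g)gh:%1$g)efgh:%1$g)root;"), edgeLen)
  tree <- ape::read.tree(text = txt)
  ids <- edgeIds(tree)
  pseudo <- c("E", "F", "G", "H", "ef", "gh", "efgh")
  categories <- branchCategoryMap(
    data.frame(branch = ids,
               category = ifelse(ids %in% pseudo, "pseudogenic",
                                 "background")),
    categories = c("background", "pseudogenic"))
  list(tree = tree, ids = ids, pseudo = pseudo, categories = categories)
}

## lesion records reproducing the pangolin shared/own counting pattern:
## 12 genus-level lesions (9 coding + 3 splice), 3 more in M. javanica,
## 2 more in M. pentadactyla
manisFixture <- function() {
  tree <- ape::read.tree(text = paste0(
    "(Outgroup:60,(Carnivore:50,(Manis_pentadactyla:13,",
    "Manis_javanica:13)Manis:37)x:10)r;"))
  shared <- data.frame(
    taxon = "Manis",
    exon = c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 8L, NA, NA, NA),
    intron = c(rep(NA_integer_, 9L), 4L, 5L, 6L),
    refStart = c(195L, 265L, 345L, 518L, 561L, 657L, 672L, 687L, 1088L,
                 NA, NA, NA),
    class = c("frameshift_deletion", "frameshift_deletion",
              "frameshift_deletion", "frameshift_deletion",
              "frameshift_deletion", "frameshift_insertion",
              "premature_stop", "frameshift_insertion",
              "frameshift_deletion", "splice_donor", "splice_donor",
              "splice_donor"),
    context = c(rep(NA_character_, 9L), "AT", "CT", "CT"))
  own_j <- data.frame(
    taxon = "Manis_javanica",
    exon = c(2L, 7L, NA), intron = c(NA, NA, 9L),
    refStart = c(350L, 851L, NA),
    class = c("frameshift_deletion", "frameshift_insertion",
              "splice_donor"),
    context = c(NA, NA, "AC"))
  own_p <- data.frame(
    taxon = "Manis_pentadactyla",
    exon = c(1L, 2L), intron = c(NA_integer_, NA_integer_),
    refStart = c(123L, 203L),
    class = c("premature_stop", "frameshift_insertion"),
    context = c(NA_character_, NA_character_))
  list(tree = tree, lesions = rbind(shared, own_j, own_p),
       clades = list(Manis = c("Manis_pentadactyla", "Manis_javanica")))
}

## exhaustive minimum-cost binary parsimony with the root fixed at absence;
## independent oracle for the deltran mapping
bruteParsimonyCost <- function(tree, tips) {
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  nTips <- length(tr$tip.label)
  nNode <- tr$Nnode
  root <- edge[nrow(edge), 1L]
  tipState <- as.integer(tr$tip.label %in% tips)
  inner <- setdiff(seq_len(nTips + nNode), c(seq_len(nTips), root))
  best <- Inf
  for (mask in 0:(2^length(inner) - 1L)) {
    state <- integer(nTips + nNode)
    state[seq_len(nTips)] <- tipState
    state[root] <- 0L
    if (length(inner)) {
      state[inner] <- bitwAnd(bitwShiftR(mask, seq_along(inner) - 1L), 1L)
    }
    cost <- sum(state[edge[, 1L]] != state[edge[, 2L]])
    best <- min(best, cost)
  }
  best
}

## brute-force codon log-likelihood by explicit summation over all ancestral
## states, with transition matrices from an independent matrix exponential
bruteCodonLnL <- function(alignment, tree, kappa, omega, pi) {
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  nTips <- length(tr$tip.label)
  nNode <- tr$Nnode
  root <- edge[nrow(edge), 1L]
  Q <- pseudogeneKit:::.gy94Q(kappa, omega, pi)
  Q <- Q / -sum(pi * diag(Q))
  Plist <- lapply(seq_len(nrow(edge)), function(e) {
    as.matrix(Matrix::expm(Q * tr$edge.length[e]))
  })
  mat <- as.matrix(alignment)
  rownames(mat) <- names(alignment)
  mat <- mat[tr$tip.label, , drop = FALSE]
  sense <- senseCodons()
  nCod <- ncol(mat) %/% 3L
  tipStates <- sapply(seq_len(nCod), function(s) {
    match(paste0(mat[, 3 * s - 2], mat[, 3 * s - 1], mat[, 3 * s]), sense)
  })
  if (is.null(dim(tipStates))) tipStates <- matrix(tipStates, nrow = nTips)
  innerNodes <- setdiff(unique(as.vector(edge)), seq_len(nTips))
  lnL <- 0
  for (s in seq_len(nCod)) {
    grid <- do.call(expand.grid, rep(list(1:61), length(innerNodes)))
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      state <- integer(nTips + nNode)
      state[seq_len(nTips)] <- tipStates[, s]
      state[innerNodes] <- as.integer(grid[g, ])
      p <- pi[state[root]]
      for (e in seq_len(nrow(edge))) {
        p <- p * Plist[[e]][state[edge[e, 1L]], state[edge[e, 2L]]]
      }
      tot <- tot + p
    }
    lnL <- lnL + log(tot)
  }
  lnL
}

## tips below a branch id as produced by edgeIds()
cladeTips <- function(tree, id) {
  if (id %in% tree$tip.label) {
    return(id)
  }
  nTips <- length(tree$tip.label)
  node <- if (grepl("^node[0-9]+$", id) && (is.null(tree$node.label) ||
              !id %in% tree$node.label)) {
    as.integer(sub("^node", "", id))
  } else {
    which(tree$node.label == id) + nTips
  }
  ape::extract.clade(tree, node)$tip.label
}
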