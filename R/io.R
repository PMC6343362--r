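## Readers and writers for the formats the pipeline touches: FASTA codon
## alignments, newick trees (branch-length or node-age mode), gene-structure
## TSVs, branch-category TSVs and lesion tables. Readers validate type
## invariants and raise classed conditions rather than coercing silently.

.pgkStop <- function(class, msg, ...) {
  stop(structure(class = c(class, "pseudogeneKitError", "error", "condition"),
                 list(message = sprintf(msg, ...), call = NULL)))
}

#' Read a codon alignment from FASTA
#'
#' Sequences are uppercased and U is mapped to T. All records must have equal
#' length and unique labels; the gap character is \code{"-"} and \code{"N"}
#' denotes missing data (not a gap).
#'
#' @param path FASTA file.
#' @return A \code{Biostrings::DNAStringSet} of equal-width gapped sequences.
#' @export
readAlignment <- function(path) {
  if (!file.exists(path)) {
    .pgkStop("inputError", "file not found: %s", path)
  }
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) {
    .pgkStop("inputError", "no FASTA records in %s", path)
  }
  if (anyDuplicated(names(raw))) {
    .pgkStop("inputError", "duplicate sequence labels in %s", path)
  }
  if (length(unique(Biostrings::width(raw))) != 1L) {
    .pgkStop("alignmentFormatError",
             "records have unequal lengths in %s", path)
  }
  seqs <- toupper(as.character(raw))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(raw)
  out
}

#' @rdname readAlignment
#' @param alignment A \code{DNAStringSet} (or named character vector).
#' @export
writeAlignment <- function(alignment, path) {
  if (!methods::is(alignment, "XStringSet")) {
    alignment <- Biostrings::DNAStringSet(alignment)
  }
  Biostrings::writeXStringSet(alignment, filepath = path)
  invisible(path)
}

#' Read a newick tree in branch-length or node-age mode
#'
#' In \code{"ages"} mode the tree must be ultrametric (within \code{tol});
#' node ages in units of the branch lengths (e.g. Ma) are attached as the
#' \code{age} component, measured back from the tips (tips at age 0).
#'
#' @param path Newick file (or a \code{phylo} object).
#' @param mode \code{"lengths"} (default) or \code{"ages"}.
#' @param tol Ultrametricity tolerance in \code{"ages"} mode.
#' @return An \code{ape::phylo}; in ages mode with an extra \code{age}
#'   component (numeric, indexed by node number) and \code{units = "age"}.
#' @export
readTreeFile <- function(path, mode = c("lengths", "ages"), tol = 1e-6) {
  mode <- match.arg(mode)
  tree <- if (inherits(path, "phylo")) path else ape::read.tree(path)
  if (is.null(tree)) {
    .pgkStop("inputError", "could not parse newick input")
  }
  if (is.null(tree$edge.length)) {
    .pgkStop("treeUnitsError", "tree has no branch lengths")
  }
  if (any(tree$edge.length < 0)) {
    .pgkStop("treeUnitsError", "negative branch lengths")
  }
  if (mode == "ages") {
    tree <- nodeAges(tree, tol = tol)
  } else {
    attr(tree, "units") <- "lengths"
  }
  tree
}

#' @rdname readTreeFile
#' @param tree An \code{ape::phylo} with branch lengths in time units.
#' @export
nodeAges <- function(tree, tol = 1e-6) {
  depth <- ape::node.depth.edgelength(tree)
  nTips <- length(tree$tip.label)
  tipDepth <- depth[seq_len(nTips)]
  rootAge <- max(depth)
  if (diff(range(tipDepth)) > tol * max(1, rootAge)) {
    .pgkStop("treeUnitsError",
             "tree is not ultrametric (tip depth spread %.3g); ages mode %s",
             diff(range(tipDepth)), "requires an ultrametric tree")
  }
  age <- rootAge - depth
  age[seq_len(nTips)] <- 0
  tree$age <- age
  attr(tree, "units") <- "age"
  tree
}

#' Read a gene structure from TSV
#'
#' Expects columns \code{exon_index}, \code{start}, \code{end}, \code{donor},
#' \code{acceptor} (donor/acceptor empty or NA on the last exon). Coordinates
#' are 1-based inclusive on the unaligned reference coding sequence.
#'
#' @param path TSV file with a header row.
#' @return A \linkS4class{GeneStructure}.
#' @export
readGeneStructure <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("exon_index", "start", "end", "donor", "acceptor")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    .pgkStop("inputError", "gene structure lacks columns: %s",
             paste(miss, collapse = ", "))
  }
  df <- df[order(df$exon_index), , drop = FALSE]
  ex <- data.frame(exon = as.integer(df$exon_index),
                   start = as.integer(df$start),
                   end = as.integer(df$end))
  if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)])) {
    .pgkStop("structureError", "exons overlap or are out of order")
  }
  len <- sum(ex$end - ex$start + 1L)
  if (len %% 3L != 0L) {
    .pgkStop("frameError",
             "total exon length %d is not divisible by 3", len)
  }
  don <- toupper(df$donor[-nrow(df)])
  acc <- toupper(df$acceptor[-nrow(df)])
  don[is.na(don)] <- "GT"
  acc[is.na(acc)] <- "AG"
  geneStructure(ex, donor = don, acceptor = acc)
}

#' @rdname readGeneStructure
#' @param structure A \code{GeneStructure}.
#' @export
writeGeneStructure <- function(structure, path) {
  ex <- exonTable(structure)
  n <- nrow(ex)
  df <- data.frame(exon_index = ex$exon, start = ex$start, end = ex$end,
                   donor = c(donorSites(structure), NA),
                   acceptor = c(acceptorSites(structure), NA))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a branch-category assignment table
#'
#' TSV with columns \code{branch} and \code{category}; branch ids follow
#' [edgeIds()].
#'
#' @param path TSV file.
#' @param categories Optional explicit category ordering.
#' @return A \linkS4class{BranchCategoryMap}.
#' @export
readBranchCategories <- function(path, categories = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("branch", "category") %in% names(df))) {
    .pgkStop("inputError", "category table needs columns branch, category")
  }
  branchCategoryMap(df, categories = categories)
}

#' @rdname readBranchCategories
#' @param x A \code{BranchCategoryMap}.
#' @export
writeBranchCategories <- function(x, path) {
  df <- data.frame(branch = names(branchAssignments(x)),
                   category = unname(branchAssignments(x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- lesion tables ------------------------------------------------------

#' Lesion record tables
#'
#' A lesion table is a \code{data.frame} with one row per inactivating
#' mutation call: \code{taxon} (a tip label, or a clade label for shared
#' lesions), \code{exon} / \code{intron} (integer, one of the two is
#' \code{NA}), \code{start} / \code{end} (1-based inclusive alignment
#' columns; \code{NA} for splice-site records), \code{refStart} /
#' \code{refEnd} (coordinates on the unaligned reference coding sequence),
#' \code{class} (one of [lesionClasses()]), \code{subtype} (free annotation,
#' e.g. \code{"terminal"} for an altered terminal stop codon) and
#' \code{context} (short observed-sequence context such as the mutated
#' splice dinucleotide).
#'
#' @return \code{emptyLesionTable()}: a zero-row lesion table;
#'   \code{lesionClasses()}: the fixed class vocabulary with its
#'   conventional short codes as names.
#' @export
emptyLesionTable <- function() {
  data.frame(taxon = character(0), exon = integer(0), intron = integer(0),
             start = integer(0), end = integer(0),
             refStart = integer(0), refEnd = integer(0),
             class = character(0), subtype = character(0),
             context = character(0), stringsAsFactors = FALSE)
}

#' @rdname emptyLesionTable
#' @export
lesionClasses <- function() {
  c(D = "frameshift_deletion", I = "frameshift_insertion",
    S = "premature_stop", SCM = "start_codon_mutation",
    Do = "splice_donor", Ac = "splice_acceptor",
    NBR = "exon_no_blast", NRM = "exon_no_reads",
    ED = "exon_deletion")
}

.asLesionTable <- function(df) {
  out <- emptyLesionTable()
  for (nm in names(out)) {
    if (is.null(df[[nm]])) {
      df[[nm]] <- rep(NA, nrow(df))
    }
  }
  df <- df[, names(out), drop = FALSE]
  df$taxon <- as.character(df$taxon)
  df$exon <- as.integer(df$exon)
  df$intron <- as.integer(df$intron)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$refStart <- as.integer(df$refStart)
  df$refEnd <- as.integer(df$refEnd)
  df$class <- as.character(df$class)
  df$subtype <- as.character(df$subtype)
  df$context <- as.character(df$context)
  bad <- setdiff(unique(df$class), unname(lesionClasses()))
  if (length(bad)) {
    .pgkStop("inputError", "unknown lesion classes: %s",
             paste(bad, collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Read / write lesion tables
#'
#' @param path TSV file with the lesion-table columns (see
#'   [emptyLesionTable()]).
#' @return A validated lesion \code{data.frame}.
#' @export
readLesionTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .asLesionTable(df)
}

#' @rdname readLesionTable
#' @param lesions A lesion table.
#' @export
writeLesionTable <- function(lesions, path) {
  utils::write.table(lesions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a gene-by-species percent-intact matrix
#'
#' TSV with a \code{gene} column followed by one column per species; values
#' are percentages in [0, 100].
#'
#' @param path TSV file.
#' @return Numeric matrix (genes x species) with gene rownames.
#' @export
readPctIntactMatrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "gene") {
    .pgkStop("inputError", "first column of a %%intact matrix must be 'gene'")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene
  if (any(m < 0 | m > 100, na.rm = TRUE)) {
    .pgkStop("inputError", "%%intact values must lie in [0, 100]")
  }
  m
}

#' @rdname readPctIntactMatrix
#' @param m Numeric gene-by-species matrix.
#' @export
writePctIntactMatrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
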