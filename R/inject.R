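## Injection of inactivating lesions of every scanned class into a codon
## alignment, returning the mutated alignment together with ground-truth
## records in final alignment coordinates.

.normLesionClass <- function(x) {
  codes <- lesionClasses()
  out <- ifelse(x %in% names(codes), unname(codes[x]), x)
  bad <- setdiff(unique(out), unname(codes))
  if (length(bad)) {
    .pgkStop("inputError", "unknown lesion class(es): %s",
             paste(bad, collapse = ", "))
  }
  out
}

#' Inject inactivating lesions into a codon alignment
#'
#' Mutates an alignment according to a table of lesion directives and
#' returns the mutated alignment, the per-taxon splice-site observation
#' table, and ground-truth lesion records with coordinates on the final
#' alignment. Frameshift directives insert or delete a run whose length is
#' not a multiple of 3; stop directives overwrite a codon of the reference
#' reading frame with TAA/TAG/TGA; start directives mutate the initiator
#' ATG; splice directives mutate the named intron's donor or acceptor
#' dinucleotide in the splice table; exon-loss directives replace the exon
#' with \code{N} (evidence tag \code{"NBR"} or \code{"NRM"}) or delete it
#' (\code{exon_deletion}). Random choices (positions, stop codon identity,
#' mutated dinucleotides, inserted bases) come from a single stream seeded
#' once, in directive order.
#'
#' @param alignment Gapped codon alignment (\code{DNAStringSet}); the
#'   reference taxon must carry an intact reading frame.
#' @param structure \linkS4class{GeneStructure} of the reference.
#' @param directives \code{data.frame} with columns \code{taxon},
#'   \code{class} (full names or Table-style codes \code{D}, \code{I},
#'   \code{S}, \code{SCM}, \code{Do}, \code{Ac}, \code{NBR}, \code{NRM},
#'   \code{ED}) and \code{exon} (intron index for splice classes); optional
#'   columns \code{at} (reference codon for stops, reference start for
#'   deletions, reference anchor position for insertions), \code{length}
#'   (indel length in nt) and \code{dinuc} (mutated splice dinucleotide).
#'   Unspecified positions are drawn at random within the exon.
#' @param referenceTaxon Reference taxon name (default: first sequence).
#' @param seed Integer seed.
#' @return List with \code{alignment} (mutated \code{DNAStringSet}),
#'   \code{spliceDinucs} (\code{data.frame} taxon/intron/donor/acceptor for
#'   all taxa) and \code{lesions} (ground-truth lesion table).
#' @seealso [scanTaxon()], [simulateCodonAlignment()]
#' @export
injectLesions <- function(alignment, structure, directives,
                          referenceTaxon = NULL, seed = 1L) {
  mat <- .alnMatrix(alignment)
  if (is.null(referenceTaxon)) referenceTaxon <- rownames(mat)[1L]
  maps <- .refMaps(mat, referenceTaxon, structure)
  ex <- exonTable(structure)
  nIntron <- nrow(ex) - 1L
  taxa <- rownames(mat)

  ## canonical splice observations for every taxon
  splice <- if (nIntron > 0L) {
    data.frame(taxon = rep(taxa, each = nIntron),
               intron = rep(seq_len(nIntron), length(taxa)),
               donor = "GT", acceptor = "AG", stringsAsFactors = FALSE)
  } else {
    data.frame(taxon = character(0), intron = integer(0),
               donor = character(0), acceptor = character(0))
  }

  if (is.null(directives) || nrow(directives) == 0L) {
    return(list(alignment = .matToDss(mat), spliceDinucs = splice,
                lesions = emptyLesionTable()))
  }
  directives <- as.data.frame(directives)
  directives$class <- .normLesionClass(as.character(directives$class))
  for (opt in c("at", "length")) {
    if (is.null(directives[[opt]])) directives[[opt]] <- NA_integer_
  }
  if (is.null(directives[[("dinuc")]])) directives$dinuc <- NA_character_

  set.seed(seed)
  recs <- list()
  insertions <- list()
  add <- function(...) recs[[length(recs) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  stopAlts <- c("TAA", "TAG", "TGA")

  codonCols <- function(cod) maps$refCols[(3L * cod - 2L):(3L * cod)]

  for (d in seq_len(nrow(directives))) {
    dd <- directives[d, ]
    tx <- as.character(dd$taxon)
    if (!tx %in% taxa) .pgkStop("inputError", "unknown taxon %s", tx)
    cls <- dd$class
    if (cls %in% c("splice_donor", "splice_acceptor")) {
      intron <- as.integer(dd$exon)
      if (is.na(intron) || intron < 1L || intron > nIntron) {
        .pgkStop("inputError", "invalid intron index for splice directive")
      }
      row <- which(splice$taxon == tx & splice$intron == intron)
      if (cls == "splice_donor") {
        din <- if (!is.na(dd$dinuc)) toupper(dd$dinuc) else
          sample(c("AT", "CT", "TT", "GA", "AA", "CA"), 1L)
        splice$donor[row] <- din
      } else {
        din <- if (!is.na(dd$dinuc)) toupper(dd$dinuc) else
          sample(c("AT", "AA", "TG", "CG", "GG", "AC"), 1L)
        splice$acceptor[row] <- din
      }
      anchorRef <- if (cls == "splice_donor") ex$end[intron] else
        ex$end[intron] + 1L
      add(taxon = tx, exon = NA_integer_, intron = intron,
          start = NA_integer_, end = NA_integer_,
          refStart = anchorRef, refEnd = anchorRef,
          class = cls, subtype = NA_character_, context = din)
      next
    }

    exo <- as.integer(dd$exon)
    if (is.na(exo) || !exo %in% ex$exon) {
      .pgkStop("inputError", "directive %d: invalid exon", d)
    }
    exRow <- match(exo, ex$exon)
    exSpan <- ex$start[exRow]:ex$end[exRow]

    if (cls %in% c("exon_no_blast", "exon_no_reads", "exon_deletion")) {
      cols <- maps$refCols[exSpan]
      mat[tx, cols] <- if (cls == "exon_deletion") "-" else "N"
      add(taxon = tx, exon = exo, intron = NA_integer_,
          start = min(cols), end = max(cols),
          refStart = min(exSpan), refEnd = max(exSpan),
          class = cls, subtype = NA_character_, context = NA_character_)
      next
    }

    if (cls == "premature_stop") {
      cods <- unique((exSpan + 2L) %/% 3L)
      cods <- cods[cods > 1L & cods < maps$nCod]
      cods <- cods[vapply(cods, function(cc) {
        all((3L * cc - 2L):(3L * cc) %in% exSpan)
      }, logical(1))]
      if (!is.na(dd$at)) cods <- intersect(cods, as.integer(dd$at))
      ok <- vapply(cods, function(cc) {
        chars <- mat[tx, codonCols(cc)]
        all(chars %in% c("A", "C", "G", "T")) &&
          !(paste(chars, collapse = "") %in% stopAlts)
      }, logical(1))
      cods <- cods[ok]
      if (!length(cods)) {
        .pgkStop("injectionError",
                 "no injectable stop position in exon %d of %s", exo, tx)
      }
      cod <- if (length(cods) > 1L) sample(cods, 1L) else cods
      newStop <- sample(stopAlts, 1L)
      cols <- codonCols(cod)
      mat[tx, cols] <- strsplit(newStop, "")[[1L]]
      add(taxon = tx, exon = exo, intron = NA_integer_,
          start = min(cols), end = max(cols),
          refStart = 3L * cod - 2L, refEnd = 3L * cod,
          class = cls, subtype = NA_character_, context = newStop)
      next
    }

    if (cls == "start_codon_mutation") {
      cols <- maps$refCols[1:3]
      newStart <- sample(c("GTG", "ACG", "ATA", "ATT", "CTG"), 1L)
      mat[tx, cols] <- strsplit(newStart, "")[[1L]]
      add(taxon = tx, exon = ex$exon[1L], intron = NA_integer_,
          start = min(cols), end = max(cols), refStart = 1L, refEnd = 3L,
          class = cls, subtype = NA_character_, context = newStart)
      next
    }

    if (cls == "frameshift_deletion") {
      len <- if (!is.na(dd$length)) as.integer(dd$length) else sample(1:2, 1L)
      if (len %% 3L == 0L) {
        .pgkStop("inputError", "frameshift length must not be a multiple of 3")
      }
      starts <- exSpan[seq_len(max(0L, length(exSpan) - len + 1L))]
      if (!is.na(dd$at)) starts <- intersect(starts, as.integer(dd$at))
      pick <- NA_integer_
      for (p in starts[sample.int(length(starts))]) {
        span <- p:(p + len - 1L)
        cols <- maps$refCols[span]
        if (any(diff(cols) != 1L)) next          # ref gap inside the span
        flank <- c(min(cols) - 1L, max(cols) + 1L)
        flank <- flank[flank >= 1L & flank <= ncol(mat)]
        if (any(mat[tx, cols] == "-") || any(mat[tx, flank] == "-")) next
        pick <- p
        break
      }
      if (is.na(pick)) {
        .pgkStop("injectionError",
                 "deletion in exon %d of %s collides with an existing gap",
                 exo, tx)
      }
      span <- pick:(pick + len - 1L)
      cols <- maps$refCols[span]
      ctx <- paste(mat[tx, cols], collapse = "")
      mat[tx, cols] <- "-"
      add(taxon = tx, exon = exo, intron = NA_integer_,
          start = min(cols), end = max(cols),
          refStart = min(span), refEnd = max(span),
          class = cls, subtype = NA_character_, context = ctx)
      next
    }

    if (cls == "frameshift_insertion") {
      len <- if (!is.na(dd$length)) as.integer(dd$length) else sample(1:2, 1L)
      if (len %% 3L == 0L) {
        .pgkStop("inputError", "frameshift length must not be a multiple of 3")
      }
      anchors <- exSpan[exSpan < max(exSpan)]
      if (!is.na(dd$at)) anchors <- intersect(anchors, as.integer(dd$at))
      pick <- NA_integer_
      for (p in anchors[sample.int(length(anchors))]) {
        c0 <- maps$refCols[p]
        if (c0 + 1L <= ncol(mat) &&
            mat[tx, c0] != "-" && mat[tx, c0 + 1L] != "-" &&
            maps$refCols[p + 1L] == c0 + 1L) {
          pick <- p
          break
        }
      }
      if (is.na(pick)) {
        .pgkStop("injectionError",
                 "insertion in exon %d of %s collides with an existing gap",
                 exo, tx)
      }
      bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      insertions[[length(insertions) + 1L]] <- list(
        col = maps$refCols[pick], taxon = tx, bases = bases,
        exon = exo, refAnchor = pick)
      next
    }
    .pgkStop("inputError", "unhandled lesion class %s", cls)
  }

  out <- do.call(rbind, c(recs, list(emptyLesionTable())))

  ## apply insertions right-to-left so earlier columns stay valid, shifting
  ## already-recorded coordinates past the insertion point
  if (length(insertions)) {
    ord <- order(vapply(insertions, `[[`, numeric(1), "col"),
                 decreasing = TRUE)
    for (insn in insertions[ord]) {
      c0 <- insn$col
      len <- length(insn$bases)
      newBlock <- matrix("-", nrow(mat), len)
      newBlock[match(insn$taxon, taxa), ] <- insn$bases
      left <- mat[, seq_len(c0), drop = FALSE]
      right <- if (c0 < ncol(mat)) {
        mat[, (c0 + 1L):ncol(mat), drop = FALSE]
      } else {
        NULL
      }
      mat <- cbind(left, newBlock, right)
      if (nrow(out)) {
        shift <- !is.na(out$start) & out$start > c0
        out$start[shift] <- out$start[shift] + len
        shiftE <- !is.na(out$end) & out$end > c0
        out$end[shiftE] <- out$end[shiftE] + len
      }
      out <- rbind(out, data.frame(
        taxon = insn$taxon, exon = insn$exon, intron = NA_integer_,
        start = c0 + 1L, end = c0 + len,
        refStart = insn$refAnchor, refEnd = insn$refAnchor,
        class = "frameshift_insertion", subtype = NA_character_,
        context = paste(insn$bases, collapse = ""),
        stringsAsFactors = FALSE))
    }
  }

  out <- out[order(out$taxon, out$refStart, out$start,
                   method = "radix", na.last = TRUE), , drop = FALSE]
  list(alignment = .matToDss(mat), spliceDinucs = splice,
       lesions = .asLesionTable(out))
}

.matToDss <- function(mat) {
  out <- Biostrings::DNAStringSet(apply(mat, 1L, paste, collapse = ""))
  names(out) <- rownames(mat)
  out
}
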