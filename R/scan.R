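## Detection and classification of inactivating mutations from a codon-aware
## alignment plus gene structure, with splice-rescue search.

## Coordinate maps between the unaligned reference coding sequence and the
## alignment, plus reference reading-frame checks.
.refMaps <- function(mat, referenceTaxon, structure) {
  if (!referenceTaxon %in% rownames(mat)) {
    .pgkStop("inputError", "reference taxon %s not in alignment",
             referenceTaxon)
  }
  refRow <- mat[referenceTaxon, ]
  refCols <- which(refRow != "-")
  L <- length(refCols)
  if (L != codingLength(structure)) {
    .pgkStop("referenceFrameError",
             "reference degapped length %d != gene structure length %d",
             L, codingLength(structure))
  }
  if (L %% 3L != 0L) {
    .pgkStop("referenceFrameError", "reference length not divisible by 3")
  }
  refSeq <- refRow[refCols]
  if (paste(refSeq[1:3], collapse = "") != "ATG") {
    .pgkStop("referenceFrameError", "reference does not start with ATG")
  }
  stops <- .stopCodons()
  nCod <- L %/% 3L
  refCodons <- paste0(refSeq[seq(1L, L, 3L)], refSeq[seq(2L, L, 3L)],
                      refSeq[seq(3L, L, 3L)])
  if (any(refCodons[-nCod] %in% stops)) {
    .pgkStop("referenceFrameError", "reference has an internal stop codon")
  }
  ex <- exonTable(structure)
  if (ex$start[1L] != 1L || ex$end[nrow(ex)] != L ||
      (nrow(ex) > 1L && any(ex$start[-1L] != ex$end[-nrow(ex)] + 1L))) {
    .pgkStop("structureError",
             "exons must tile the reference coding sequence contiguously")
  }
  exonOf <- integer(L)
  for (k in seq_len(nrow(ex))) {
    exonOf[ex$start[k]:ex$end[k]] <- ex$exon[k]
  }
  list(refCols = refCols, L = L, nCod = nCod, exonOf = exonOf,
       terminalIsStop = refCodons[nCod] %in% stops,
       refCodons = refCodons)
}

#' Scan one taxon for inactivating mutations
#'
#' Compares a query taxon against an intact reference reading frame and
#' reports every inactivating lesion: frameshift indels (gap runs whose
#' length is not a multiple of 3, deletions in the query vs insertions
#' relative to the reference), premature stop codons evaluated by default in
#' the reference reading frame (excluding the terminal stop; a mutated
#' terminal stop is reported as a \code{premature_stop} with subtype
#' \code{"terminal"}), a non-ATG start codon, non-canonical splice
#' dinucleotides from the supplied per-taxon observations (GC donors are
#' flagged with a warning, not a lesion record), and exons that are entirely
#' missing data (\code{N}) or entirely deleted. Records are sorted by
#' alignment position.
#'
#' @param alignment Gapped codon alignment (\code{DNAStringSet}).
#' @param referenceTaxon Taxon with an intact reading frame (checked).
#' @param queryTaxon Taxon to scan.
#' @param structure \linkS4class{GeneStructure} of the reference coding
#'   sequence.
#' @param spliceDinucs Optional \code{data.frame} with columns \code{taxon},
#'   \code{intron}, \code{donor}, \code{acceptor} of observed splice
#'   dinucleotides; rows for other taxa are ignored. Sites already rescued by
#'   an alternative splice site (see [findAlternativeSpliceSite()]) should be
#'   reset to canonical before scanning.
#' @param evidenceTags Optional \code{data.frame} with columns \code{taxon},
#'   \code{exon}, \code{tag} (\code{"NBR"} assembly gap or \code{"NRM"} no
#'   reads) classifying missing-data exons; defaults to \code{"NBR"}.
#' @param stopFrame \code{"reference"} (default): stops are called in the
#'   reference reading frame; \code{"query"}: stops are additionally called
#'   in the query's own (frameshifted) frame.
#' @return A lesion table (see [emptyLesionTable()]).
#' @seealso [injectLesions()], [computePctIntact()]
#' @export
scanTaxon <- function(alignment, referenceTaxon, queryTaxon, structure,
                      spliceDinucs = NULL, evidenceTags = NULL,
                      stopFrame = c("reference", "query")) {
  stopFrame <- match.arg(stopFrame)
  mat <- .alnMatrix(alignment)
  maps <- .refMaps(mat, referenceTaxon, structure)
  if (!queryTaxon %in% rownames(mat)) {
    .pgkStop("inputError", "query taxon %s not in alignment", queryTaxon)
  }
  q <- mat[queryTaxon, ]
  r <- mat[referenceTaxon, ]
  recs <- list()
  add <- function(...) recs[[length(recs) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)

  ## ---- whole-exon states: deleted or missing ---------------------------
  ex <- exonTable(structure)
  exonState <- character(nrow(ex))      # "", "deleted", "missing"
  for (k in seq_len(nrow(ex))) {
    cols <- maps$refCols[ex$start[k]:ex$end[k]]
    chars <- q[cols]
    if (all(chars == "-")) {
      exonState[k] <- "deleted"
      add(taxon = queryTaxon, exon = ex$exon[k], intron = NA_integer_,
          start = min(cols), end = max(cols),
          refStart = ex$start[k], refEnd = ex$end[k],
          class = "exon_deletion", subtype = NA_character_,
          context = NA_character_)
    } else if (all(chars %in% c("N", "-")) && any(chars == "N")) {
      exonState[k] <- "missing"
      tag <- "NBR"
      if (!is.null(evidenceTags)) {
        hit <- evidenceTags$taxon == queryTaxon & evidenceTags$exon == ex$exon[k]
        if (any(hit)) tag <- toupper(evidenceTags$tag[which(hit)[1L]])
      }
      add(taxon = queryTaxon, exon = ex$exon[k], intron = NA_integer_,
          start = min(cols), end = max(cols),
          refStart = ex$start[k], refEnd = ex$end[k],
          class = if (tag == "NRM") "exon_no_reads" else "exon_no_blast",
          subtype = NA_character_, context = NA_character_)
    }
  }
  skipRef <- maps$exonOf %in% ex$exon[exonState != ""]   # per-CDS-position

  ## ---- gap runs (frameshift indels) ------------------------------------
  ## deletion: query gap where reference has a base; insertion: reference
  ## gap where query has a base. Adjacent runs of different type are
  ## separate events; runs inside deleted/missing exons are skipped.
  isDel <- q == "-" & r != "-"
  isIns <- r == "-" & q != "-"
  refIdxOfCol <- rep(NA_integer_, ncol(mat))
  refIdxOfCol[maps$refCols] <- seq_len(maps$L)
  lastRefBefore <- cummax(ifelse(is.na(refIdxOfCol), 0L, refIdxOfCol))

  runStarts <- function(flag) {
    d <- diff(c(FALSE, flag))
    list(starts = which(d == 1L), ends = which(diff(c(flag, FALSE)) == -1L))
  }
  del <- runStarts(isDel)
  for (k in seq_along(del$starts)) {
    s <- del$starts[k]; e <- del$ends[k]
    refSpan <- refIdxOfCol[s:e]
    refSpan <- refSpan[!is.na(refSpan)]
    if (all(skipRef[refSpan])) next
    len <- length(refSpan)                 # deleted reference bases
    if (len %% 3L == 0L) next              # in-frame deletion: not a lesion
    exo <- maps$exonOf[refSpan[1L]]
    add(taxon = queryTaxon, exon = exo, intron = NA_integer_,
        start = s, end = e, refStart = min(refSpan), refEnd = max(refSpan),
        class = "frameshift_deletion", subtype = NA_character_,
        context = paste(r[s:e], collapse = ""))
  }
  ins <- runStarts(isIns)
  for (k in seq_along(ins$starts)) {
    s <- ins$starts[k]; e <- ins$ends[k]
    len <- e - s + 1L
    if (len %% 3L == 0L) next
    anchor <- lastRefBefore[s]             # ref position preceding the run
    if (anchor > 0L && skipRef[anchor]) next
    exo <- if (anchor > 0L) maps$exonOf[anchor] else maps$exonOf[1L]
    add(taxon = queryTaxon, exon = exo, intron = NA_integer_,
        start = s, end = e,
        refStart = max(1L, anchor), refEnd = max(1L, anchor),
        class = "frameshift_insertion", subtype = NA_character_,
        context = paste(q[s:e], collapse = ""))
  }

  ## ---- start codon ------------------------------------------------------
  startCols <- maps$refCols[1:3]
  startCodon <- paste(q[startCols], collapse = "")
  if (all(q[startCols] %in% c("A", "C", "G", "T")) && startCodon != "ATG" &&
      !skipRef[1L]) {
    add(taxon = queryTaxon, exon = maps$exonOf[1L], intron = NA_integer_,
        start = startCols[1L], end = startCols[3L],
        refStart = 1L, refEnd = 3L,
        class = "start_codon_mutation", subtype = NA_character_,
        context = startCodon)
  }

  ## ---- premature stops in the reference frame --------------------------
  stops <- .stopCodons()
  for (cod in seq_len(maps$nCod)) {
    refPos <- (3L * cod - 2L):(3L * cod)
    if (any(skipRef[refPos])) next
    cols <- maps$refCols[refPos]
    codon <- q[cols]
    if (!all(codon %in% c("A", "C", "G", "T"))) next
    codonStr <- paste(codon, collapse = "")
    if (cod < maps$nCod) {
      if (codonStr %in% stops) {
        add(taxon = queryTaxon, exon = maps$exonOf[refPos[1L]],
            intron = NA_integer_, start = min(cols), end = max(cols),
            refStart = refPos[1L], refEnd = refPos[3L],
            class = "premature_stop", subtype = NA_character_,
            context = codonStr)
      }
    } else if (maps$terminalIsStop && !(codonStr %in% stops)) {
      add(taxon = queryTaxon, exon = maps$exonOf[refPos[1L]],
          intron = NA_integer_, start = min(cols), end = max(cols),
          refStart = refPos[1L], refEnd = refPos[3L],
          class = "premature_stop", subtype = "terminal",
          context = codonStr)
    }
  }

  ## ---- premature stops in the query's own (shifted) frame --------------
  if (stopFrame == "query") {
    keep <- which(q != "-" & !(refIdxOfCol %in% which(skipRef)))
    bases <- q[keep]
    nq <- length(bases) - length(bases) %% 3L
    for (i in seq_len(max(0L, nq %/% 3L - 1L))) {
      codon <- bases[(3L * i - 2L):(3L * i)]
      if (!all(codon %in% c("A", "C", "G", "T"))) next
      codonStr <- paste(codon, collapse = "")
      if (codonStr %in% stops) {
        cols <- keep[(3L * i - 2L):(3L * i)]
        refAt <- lastRefBefore[cols[1L]]
        already <- vapply(recs, function(d) {
          d$class == "premature_stop" && !is.na(d$start) &&
            d$start == min(cols)
        }, logical(1))
        if (any(already)) next
        add(taxon = queryTaxon, exon = maps$exonOf[max(1L, refAt)],
            intron = NA_integer_, start = min(cols), end = max(cols),
            refStart = max(1L, refAt), refEnd = max(1L, refAt),
            class = "premature_stop", subtype = "query_frame",
            context = codonStr)
      }
    }
  }

  ## ---- splice dinucleotides --------------------------------------------
  if (!is.null(spliceDinucs)) {
    sd <- spliceDinucs[spliceDinucs$taxon == queryTaxon, , drop = FALSE]
    for (k in seq_len(nrow(sd))) {
      intron <- as.integer(sd$intron[k])
      donorPos <- ex$end[match(intron, ex$exon)]       # exon i / intron i
      don <- toupper(sd$donor[k])
      if (!is.na(don) && don != "GT") {
        if (don == "GC") {
          warning(sprintf(
            "%s intron %d: GC donor (minor splice class), not called a lesion",
            queryTaxon, intron), call. = FALSE)
        } else {
          add(taxon = queryTaxon, exon = NA_integer_, intron = intron,
              start = NA_integer_, end = NA_integer_,
              refStart = donorPos, refEnd = donorPos,
              class = "splice_donor", subtype = NA_character_,
              context = don)
        }
      }
      acc <- toupper(sd$acceptor[k])
      if (!is.na(acc) && acc != "AG") {
        add(taxon = queryTaxon, exon = NA_integer_, intron = intron,
            start = NA_integer_, end = NA_integer_,
            refStart = donorPos + 1L, refEnd = donorPos + 1L,
            class = "splice_acceptor", subtype = NA_character_,
            context = acc)
      }
    }
  }

  if (!length(recs)) {
    return(emptyLesionTable())
  }
  out <- do.call(rbind, recs)
  out <- out[order(out$refStart, out$start, method = "radix",
                   na.last = TRUE), , drop = FALSE]
  .asLesionTable(out)
}

#' Scan all taxa of an alignment for inactivating mutations
#'
#' @inheritParams scanTaxon
#' @param queryTaxa Taxa to scan; defaults to every taxon except the
#'   reference.
#' @return One combined lesion table.
#' @export
scanAlignment <- function(alignment, referenceTaxon, structure,
                          queryTaxa = NULL, spliceDinucs = NULL,
                          evidenceTags = NULL,
                          stopFrame = c("reference", "query")) {
  stopFrame <- match.arg(stopFrame)
  if (is.null(queryTaxa)) {
    queryTaxa <- setdiff(names(alignment), referenceTaxon)
  }
  tabs <- lapply(queryTaxa, function(tx) {
    scanTaxon(alignment, referenceTaxon, tx, structure,
              spliceDinucs = spliceDinucs, evidenceTags = evidenceTags,
              stopFrame = stopFrame)
  })
  do.call(rbind, c(tabs, list(emptyLesionTable())))
}

#' Search for a rescuing alternative splice site
#'
#' When a canonical splice dinucleotide is mutated, a nearby canonical site
#' whose use changes the exon length by a multiple of 3 preserves the reading
#' frame and rescues the gene. The search scans up to \code{window}
#' nucleotides on each side of the canonical site for a \code{GT} (donor) or
#' \code{AG} (acceptor); among frame-preserving candidates the nearest wins,
#' with a shorter exon preferred on an exact distance tie. The returned
#' offset is the signed change in exon length (negative = shorter exon).
#'
#' @param exonSeq For donors, the 3' end of the upstream exon; for
#'   acceptors, the 5' start of the downstream exon.
#' @param intronSeq For donors, the intron sequence beginning with the
#'   (possibly mutated) donor site; for acceptors, the intron sequence ending
#'   with the acceptor site.
#' @param site \code{"donor"} or \code{"acceptor"}.
#' @param window Maximum distance searched on each side (nt); default 30.
#' @return List with \code{verdict} (\code{"rescued_with_offset"} or
#'   \code{"not_rescued"}) and \code{offset} (nt, \code{NA} if not rescued).
#' @export
#' @examples
#' # canonical GT 6 nt upstream of a mutated donor: exon 6 bp shorter
#' findAlternativeSpliceSite("CAGGTAAGG", "ATAAGTCC", "donor")
findAlternativeSpliceSite <- function(exonSeq, intronSeq,
                                      site = c("donor", "acceptor"),
                                      window = 30L) {
  site <- match.arg(site)
  stopifnot(window >= 0L)
  exonSeq <- toupper(as.character(exonSeq))
  intronSeq <- toupper(as.character(intronSeq))
  if (site == "donor") {
    s <- strsplit(paste0(exonSeq, intronSeq), "")[[1L]]
    canon <- nchar(exonSeq) + 1L          # donor start in s
    target <- c("G", "T")
    offsetOf <- function(pos) pos - canon # = exon length change
  } else {
    s <- strsplit(paste0(intronSeq, exonSeq), "")[[1L]]
    canon <- nchar(intronSeq) - 1L        # acceptor start in s
    target <- c("A", "G")
    offsetOf <- function(pos) canon - pos # positive when acceptor moves 5'
  }
  cand <- integer(0)
  for (pos in seq_len(length(s) - 1L)) {
    if (pos == canon) next
    if (s[pos] == target[1L] && s[pos + 1L] == target[2L]) {
      off <- offsetOf(pos)
      if (off != 0L && abs(off) <= window && off %% 3L == 0L) {
        cand <- c(cand, off)
      }
    }
  }
  if (!length(cand)) {
    return(list(verdict = "not_rescued", offset = NA_integer_))
  }
  cand <- cand[order(abs(cand), cand)]   # nearest; shorter exon on ties
  list(verdict = "rescued_with_offset", offset = cand[1L])
}
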