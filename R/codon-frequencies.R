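## Codon equilibrium frequencies from observed nucleotide composition, and
## the alignment preprocessing applied before selection analyses.

#' Codon equilibrium frequencies from an alignment
#'
#' Builds GY94 sense-codon equilibrium frequencies from observed nucleotide
#' composition. \code{CF1} pools nucleotide frequencies across the three
#' codon positions (F1x4-style); \code{CF2} uses position-specific
#' frequencies (F3x4-style). In both modes stop-codon mass is removed and the
#' 61 sense-codon frequencies renormalised to sum to 1. Gaps and ambiguity
#' characters are ignored in the counts.
#'
#' @param alignment A gapped codon alignment (\code{DNAStringSet} or
#'   character matrix); its width must be a multiple of 3.
#' @param mode \code{"CF1"} or \code{"CF2"}.
#' @return Named numeric vector of 61 frequencies in [senseCodons()] order.
#' @export
#' @examples
#' aln <- Biostrings::DNAStringSet(c(a = "ATGGCC", b = "ATGGCA"))
#' round(sum(buildCodonFrequencies(aln, "CF1")), 12)
buildCodonFrequencies <- function(alignment, mode = c("CF1", "CF2")) {
  mode <- match.arg(mode)
  if (length(alignment) == 0L) {
    .pgkStop("inputError", "empty alignment")
  }
  mat <- .alnMatrix(alignment)
  if (nrow(mat) == 0L || ncol(mat) == 0L) {
    .pgkStop("inputError", "empty alignment")
  }
  if (ncol(mat) %% 3L != 0L) {
    .pgkStop("frameError", "alignment width is not a multiple of 3")
  }
  nt <- c("A", "C", "G", "T")
  posOf <- rep_len(1:3, ncol(mat))
  counts <- matrix(0, 3L, 4L, dimnames = list(NULL, nt))
  for (p in 1:3) {
    sub <- mat[, posOf == p, drop = FALSE]
    tab <- table(factor(sub[sub %in% nt], levels = nt))
    counts[p, ] <- as.numeric(tab)
  }
  if (mode == "CF1") {
    f <- colSums(counts)
    if (sum(f) == 0) .pgkStop("inputError", "no unambiguous nucleotides")
    f <- f / sum(f)
    fpos <- rbind(f, f, f)
  } else {
    if (any(rowSums(counts) == 0)) {
      .pgkStop("inputError", "a codon position has no unambiguous bases")
    }
    fpos <- counts / rowSums(counts)
  }
  sense <- senseCodons()
  chars <- .codonEnv$chars
  pi <- fpos[1L, chars[, 1L]] * fpos[2L, chars[, 2L]] * fpos[3L, chars[, 3L]]
  s <- sum(pi)
  if (s <= 0) {
    .pgkStop("inputError", "degenerate composition: all sense codons have %s",
             "zero frequency")
  }
  pi <- pi / s
  names(pi) <- sense
  pi
}

#' Prepare an alignment for codon selection analyses
#'
#' Applies the preprocessing used before branch-model fitting: alignment
#' columns created by frameshift insertions are deleted for all taxa, as are
#' in-frame insertion columns carried by at most \code{maxCarriers} taxa, and
#' each premature stop codon is recoded as missing data (\code{NNN}) in the
#' affected taxon. Terminal-stop (subtype \code{"terminal"}) records are left
#' untouched.
#'
#' @param alignment Gapped codon alignment (\code{DNAStringSet}).
#' @param lesions Lesion table (see [emptyLesionTable()]); rows of class
#'   \code{frameshift_insertion} mark columns for removal and rows of class
#'   \code{premature_stop} mark codons for recoding.
#' @param maxCarriers In-frame insertion columns present in at most this many
#'   taxa (gaps in all others) are also removed; set to 0 to disable the
#'   automatic detection.
#' @return A \code{DNAStringSet} whose width is a multiple of 3.
#' @export
preprocessAlignment <- function(alignment, lesions = emptyLesionTable(),
                                maxCarriers = 2L) {
  mat <- .alnMatrix(alignment)
  lesions <- .asLesionTable(lesions)
  drop <- rep(FALSE, ncol(mat))

  ins <- lesions[lesions$class == "frameshift_insertion" &
                   !is.na(lesions$start), , drop = FALSE]
  for (k in seq_len(nrow(ins))) {
    drop[ins$start[k]:ins$end[k]] <- TRUE
  }

  if (maxCarriers > 0L && nrow(mat) > maxCarriers) {
    ## detect taxon-unique in-frame insertion columns: maximal runs of
    ## columns sharing the same small carrier set, gap in all other taxa
    gap <- mat == "-"
    carrierKey <- apply(!gap, 2L, function(z) paste(which(z), collapse = ","))
    nCarrier <- colSums(!gap)
    cand <- nCarrier > 0L & nCarrier <= maxCarriers
    if (any(cand)) {
      runId <- cumsum(c(TRUE, carrierKey[-1L] != carrierKey[-length(carrierKey)]))
      for (rid in unique(runId[cand])) {
        cols <- which(runId == rid)
        if (all(cand[cols]) && length(cols) %% 3L == 0L) {
          drop[cols] <- TRUE
        }
      }
    }
  }

  stops <- lesions[lesions$class == "premature_stop" &
                     !is.na(lesions$start) &
                     (is.na(lesions$subtype) | lesions$subtype != "terminal"),
                   , drop = FALSE]
  for (k in seq_len(nrow(stops))) {
    tx <- stops$taxon[k]
    if (!tx %in% rownames(mat)) next
    mat[tx, stops$start[k]:stops$end[k]] <- "N"
  }

  out <- mat[, !drop, drop = FALSE]
  if (ncol(out) %% 3L != 0L) {
    .pgkStop("consistencyError",
             "post-removal alignment width %d is not a multiple of 3",
             ncol(out))
  }
  res <- Biostrings::DNAStringSet(apply(out, 1L, paste, collapse = ""))
  names(res) <- rownames(mat)
  res
}
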