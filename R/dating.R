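## Closed-form dating of gene inactivation on transitional branches from
## mixture dN/dS values.
##
## A transitional branch runs from age tB (older) to age tE (younger, 0 for
## terminal branches). The gene is functional (dN/dS = omegaF) until the
## inactivation age tI and pseudogenic (dN/dS = omegaP) afterwards, so the
## branch-wide ratio omegaT is a weighted mixture of the two regimes. With a
## single synonymous rate the weights are the segment durations; with two
## rates the pseudogenic segment's weight is scaled by r = sP/sF, the ratio
## of the pseudogenic to the functional synonymous rate.

.checkProblem <- function(omegaT, omegaF, omegaP, tB, tE, r = 1) {
  if (!(tB > tE) || tE < 0) {
    .pgkStop("degenerateProblemError",
             "need branch ages tB > tE >= 0 (got tB = %g, tE = %g)", tB, tE)
  }
  if (omegaP <= omegaF) {
    .pgkStop("degenerateProblemError",
             "omegaP (%g) must exceed omegaF (%g) for an interior solution",
             omegaP, omegaF)
  }
  if (r <= 0) {
    .pgkStop("degenerateProblemError", "rate ratio r must be positive")
  }
  invisible(NULL)
}

.clampEstimate <- function(tI, tB, tE) {
  if (tI >= tB) {
    list(tI = tB, clamped = "at_t_b")
  } else if (tI <= tE) {
    list(tI = tE, clamped = "at_t_e")
  } else {
    list(tI = tI, clamped = "none")
  }
}

#' Date gene inactivation on a transitional branch (one synonymous rate)
#'
#' Solves the duration-weighted mixture
#' \code{omegaT = (omegaF * (tB - tI) + omegaP * (tI - tE)) / (tB - tE)}
#' for the inactivation age \code{tI}, assuming the synonymous rate is the
#' same before and after inactivation. The estimate is clamped to the branch
#' span: \code{omegaT >= omegaP} dates the inactivation to the branch origin
#' (\code{at_t_b}) and \code{omegaT <= omegaF} to the branch end
#' (\code{at_t_e}).
#'
#' @param omegaT Observed dN/dS of the transitional branch.
#' @param omegaF Functional (background) dN/dS.
#' @param omegaP Fully pseudogenic dN/dS (fixed at 1.0 or estimated); must
#'   exceed \code{omegaF}.
#' @param tB Branch-begin age (Ma before present).
#' @param tE Branch-end age (Ma; 0 for terminal branches).
#' @return List with \code{tI} (Ma), \code{clamped} (\code{"none"},
#'   \code{"at_t_b"} or \code{"at_t_e"}) and the inputs.
#' @seealso [estimateTwoRate()], [gridEstimate()]
#' @export
#' @examples
#' estimateOneRate(0.9609, 0.4904, 1.0, tB = 45.45)$tI   # 41.96
estimateOneRate <- function(omegaT, omegaF, omegaP, tB, tE = 0) {
  .checkProblem(omegaT, omegaF, omegaP, tB, tE)
  tI <- tE + (tB - tE) * (omegaT - omegaF) / (omegaP - omegaF)
  c(.clampEstimate(tI, tB, tE),
    list(omegaT = omegaT, omegaF = omegaF, omegaP = omegaP,
         tB = tB, tE = tE, rateModel = "one"))
}

#' Date gene inactivation allowing two synonymous rates
#'
#' As [estimateOneRate()], but the pseudogenic segment's synonymous rate is
#' \code{r} times the functional one, so the mixture weights become
#' synonymous fluxes rather than durations:
#' \code{omegaT = (omegaF * sF * (tB - tI) + omegaP * sP * (tI - tE)) /
#' (sF * (tB - tI) + sP * (tI - tE))}, giving
#' \code{tI = tE + (tB - tE) * (omegaT - omegaF) /
#' ((omegaT - omegaF) + r * (omegaP - omegaT))}. With \code{r = 1} this
#' reduces exactly to the one-rate estimate; \code{tI} is non-increasing in
#' \code{r}.
#'
#' @inheritParams estimateOneRate
#' @param r Synonymous rate ratio \code{sP / sF} (> 0; default 1).
#' @return List as in [estimateOneRate()].
#' @export
#' @examples
#' estimateTwoRate(0.9609, 0.4904, 1.0, tB = 45.45, r = 1.43)$tI
estimateTwoRate <- function(omegaT, omegaF, omegaP, tB, tE = 0, r = 1) {
  .checkProblem(omegaT, omegaF, omegaP, tB, tE, r)
  if (omegaT >= omegaP) {
    est <- .clampEstimate(tB, tB, tE)
  } else if (omegaT <= omegaF) {
    est <- .clampEstimate(tE, tB, tE)
  } else {
    denom <- (omegaT - omegaF) + r * (omegaP - omegaT)
    if (denom <= 0) {
      .pgkStop("degenerateProblemError",
               "synonymous-flux denominator is nonpositive (%.4g)", denom)
    }
    est <- .clampEstimate(tE + (tB - tE) * (omegaT - omegaF) / denom, tB, tE)
  }
  c(est, list(omegaT = omegaT, omegaF = omegaF, omegaP = omegaP,
              tB = tB, tE = tE, r = r, rateModel = "two"))
}

#' Full 2 x 2 x 2 grid of inactivation-time estimates
#'
#' Dates one transitional branch under all eight combinations of codon
#' frequency model (CF1 / CF2 input dN/dS values), pseudogenic dN/dS fixed
#' at 1.0 versus estimated, and one versus two synonymous rates, and reports
#' the per-cell estimates, their arithmetic mean and range. Clamped cells
#' (constrained by the branch's divergence times) are included in the mean.
#'
#' @param omegaT Named numeric, transitional-branch dN/dS per frequency mode,
#'   e.g. \code{c(CF1 = 0.9609, CF2 = 1.0190)}.
#' @param omegaF Named numeric, functional dN/dS per frequency mode.
#' @param omegaPEst Named numeric, estimated pseudogenic dN/dS per frequency
#'   mode (the fixed alternative is always 1.0).
#' @param tB,tE Branch ages (Ma); \code{tE = 0} for terminal branches.
#' @param r Synonymous rate ratio used by the two-rate cells.
#' @return List with \code{grid} (\code{data.frame}: \code{freqMode},
#'   \code{omegaPTag}, \code{rateModel}, \code{omegaT}, \code{omegaF},
#'   \code{omegaP}, \code{tI}, \code{clamped}), \code{mean} and \code{range}
#'   over the valid cells. Degenerate cells get \code{NA} with a warning.
#' @export
gridEstimate <- function(omegaT, omegaF, omegaPEst, tB, tE = 0, r = 1) {
  modes <- c("CF1", "CF2")
  if (!all(modes %in% names(omegaT)) || !all(modes %in% names(omegaF)) ||
      !all(modes %in% names(omegaPEst))) {
    .pgkStop("inputError",
             "omegaT, omegaF and omegaPEst must be named with CF1 and CF2")
  }
  cells <- expand.grid(freqMode = modes, omegaPTag = c("fixed", "estimated"),
                       rateModel = c("one", "two"),
                       stringsAsFactors = FALSE)
  cells <- cells[order(cells$freqMode, cells$omegaPTag, cells$rateModel), ]
  grid <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    fm <- cells$freqMode[k]
    op <- if (cells$omegaPTag[k] == "fixed") 1.0 else omegaPEst[[fm]]
    est <- tryCatch({
      if (cells$rateModel[k] == "one") {
        estimateOneRate(omegaT[[fm]], omegaF[[fm]], op, tB, tE)
      } else {
        estimateTwoRate(omegaT[[fm]], omegaF[[fm]], op, tB, tE, r)
      }
    }, pseudogeneKitError = function(e) {
      warning(sprintf("grid cell %s/%s/%s-rate: %s", fm, cells$omegaPTag[k],
                      cells$rateModel[k], conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    data.frame(freqMode = fm, omegaPTag = cells$omegaPTag[k],
               rateModel = cells$rateModel[k],
               omegaT = omegaT[[fm]], omegaF = omegaF[[fm]], omegaP = op,
               tI = if (is.null(est)) NA_real_ else est$tI,
               clamped = if (is.null(est)) NA_character_ else est$clamped,
               stringsAsFactors = FALSE)
  }))
  rownames(grid) <- NULL
  valid <- !is.na(grid$tI)
  list(grid = grid,
       mean = mean(grid$tI[valid]),
       range = if (any(valid)) range(grid$tI[valid]) else c(NA_real_,
                                                            NA_real_))
}

#' Synonymous rate ratio from substitution counts and durations
#'
#' Estimates \code{r = sP / sF} as the ratio of per-time synonymous
#' substitution rates: \code{(SdS_p / T_p) / (SdS_f / T_f)}, where SdS are
#' expected synonymous counts (e.g. from [substitutionCounts()]) and T the
#' summed durations (Ma) of the branches in each category.
#'
#' @param SdSPseudo,tPseudo Synonymous count and total duration of the
#'   pseudogenic category.
#' @param SdSFunc,tFunc Synonymous count and total duration of the
#'   functional category.
#' @return The rate ratio r.
#' @export
synRateRatio <- function(SdSPseudo, tPseudo, SdSFunc, tFunc) {
  if (min(tPseudo, tFunc) <= 0 || SdSFunc <= 0) {
    .pgkStop("degenerateProblemError",
             "durations must be positive and functional SdS nonzero")
  }
  (SdSPseudo / tPseudo) / (SdSFunc / tFunc)
}

#' Least-squares fit of a single global synonymous rate ratio
#'
#' Given transitional-branch problems with observed two-rate inactivation
#' dates, finds the single \code{r} minimising the sum of squared
#' differences between [estimateTwoRate()] predictions and the observed
#' dates. Used to reconcile one-rate and two-rate dating columns that were
#' produced with an unreported common rate ratio.
#'
#' @param problems \code{data.frame} with columns \code{omegaT},
#'   \code{omegaF}, \code{omegaP}, \code{tB}, \code{tE} and \code{tiObs}
#'   (observed two-rate estimates).
#' @param interval Search interval for r.
#' @return List with \code{r} and the achieved \code{sse}.
#' @export
fitRateRatio <- function(problems, interval = c(0.05, 20)) {
  sse <- function(r) {
    pred <- vapply(seq_len(nrow(problems)), function(k) {
      estimateTwoRate(problems$omegaT[k], problems$omegaF[k],
                      problems$omegaP[k], problems$tB[k], problems$tE[k],
                      r)$tI
    }, numeric(1))
    sum((pred - problems$tiObs)^2)
  }
  opt <- stats::optimize(sse, interval = interval, tol = 1e-8)
  list(r = opt$minimum, sse = opt$objective)
}
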