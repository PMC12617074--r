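## Split-time estimation from relative cross-coalescence rates.
##
## RCCR r(t) = 2*lambda_01 / (lambda_00 + lambda_11) is ~1 while two
## populations still coalesce as one (panmictic ancestor) and drops to 0
## after complete isolation; the time where it crosses 0.5 dates the split.

#' Relative cross-coalescence rate curve
#'
#' \code{r(t) = 2 * lambda_01 / (lambda_00 + lambda_11)} evaluated at each
#' segment midpoint; the final segment is dropped when its right boundary is
#' infinite.  Values slightly above 1 can arise from estimation noise and
#' are kept.
#'
#' @param series a \linkS4class{CrossCoalSeries}.
#' @return data.frame with columns \code{t_mid}, \code{r}, times increasing.
#' @export
rccr <- function(series) {
  stopifnot(is(series, "CrossCoalSeries"))
  tb <- rateTable(series)
  tb <- tb[is.finite(tb$t_right), , drop = FALSE]
  if (nrow(tb) == 0) stop("no finite segments in cross-coalescence series")
  den <- tb$lambda_00 + tb$lambda_11
  if (any(den == 0))
    stop(sprintf("row %d: within-population rates sum to zero",
                 which(den == 0)[1]))
  data.frame(t_mid = (tb$t_left + tb$t_right) / 2, r = 2 * tb$lambda_01 / den)
}

#' Estimate a population split time from an RCCR curve
#'
#' Scans from the present toward the past for the first adjacent pair with
#' \code{r[i] < threshold <= r[i+1]} and linearly interpolates the time at
#' which r equals the threshold.  A curve that never falls below the
#' threshold is read as panmixia (split 0, flag \code{"no_split"}); one that
#' never reaches it is unresolved (split NA, flag \code{"unresolved"}).
#'
#' @param curve data.frame from \code{\link{rccr}} (columns t_mid, r).
#' @param threshold crossing level, default 0.5 (half the within rate).
#' @param crossing \code{"recent"} (default) takes the most recent crossing
#'   when noise produces several; \code{"oldest"} takes the last.
#' @param smooth apply a 3-point running median before crossing detection
#'   (off by default; the raw rule is the reference behaviour).
#' @return list with \code{split_years} and \code{flag}
#'   (\code{"ok"}, \code{"no_split"} or \code{"unresolved"}).
#' @export
estimateSplit <- function(curve, threshold = 0.5,
                          crossing = c("recent", "oldest"), smooth = FALSE) {
  crossing <- match.arg(crossing)
  t <- curve$t_mid; r <- curve$r
  if (any(diff(t) <= 0)) stop("time axis must be strictly increasing")
  if (smooth && length(r) >= 3) r <- stats::runmed(r, 3)
  idx <- which(r[-length(r)] < threshold & r[-1] >= threshold)
  if (length(idx) == 0) {
    if (all(r >= threshold))
      return(list(split_years = 0, flag = "no_split"))
    return(list(split_years = NA_real_, flag = "unresolved"))
  }
  i <- if (crossing == "recent") idx[1] else idx[length(idx)]
  frac <- (threshold - r[i]) / (r[i + 1] - r[i])
  list(split_years = t[i] + frac * (t[i + 1] - t[i]), flag = "ok")
}

#' Split times for many population pairs
#'
#' @param seriesList named list of \linkS4class{CrossCoalSeries}, one per
#'   population pair; names of the form "spec|pop1|pop2" are split into
#'   columns when possible.
#' @param ... passed to \code{\link{estimateSplit}}.
#' @return data.frame with columns \code{pair}, \code{split_years},
#'   \code{flag}.
#' @export
splitTimeTable <- function(seriesList, ...) {
  rows <- lapply(names(seriesList), function(nm) {
    est <- estimateSplit(rccr(seriesList[[nm]]), ...)
    data.frame(pair = nm, split_years = est$split_years, flag = est$flag)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
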