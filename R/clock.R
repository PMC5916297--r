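## Molecular-clock calibration arithmetic for the sequence locus.
##
## A calibration point is a pairwise p-distance between two taxa and
## their divergence time window; the pairwise divergence rate is halved
## to obtain the per-lineage substitution rate of the locus.

#' Pairwise divergence rate from a p-distance and a divergence time
#'
#' \eqn{100 \cdot p / t} percent per million years.
#'
#' @param p pairwise p-distance in (0, 1]
#' @param tMy divergence time in million years (> 0)
#' @return divergence rate in percent per million years
#' @examples
#' divergenceRate(0.199, 87)   # 0.229 %/My
#' @export
divergenceRate <- function(p, tMy) {
  if (tMy <= 0) stop("domain error: tMy must be > 0")
  if (p <= 0 || p > 1) stop("domain error: p must be in (0, 1]")
  100 * p / tMy
}

#' Per-lineage locus substitution rate from a pairwise divergence rate
#'
#' The pairwise rate is halved (two lineages accumulate the divergence),
#' converted from percent per site per million years to substitutions
#' per site per year, and multiplied by the locus length:
#' \eqn{(r/100)/2 \cdot L / 10^6} substitutions per year per locus.
#'
#' @param ratePctPerMy pairwise divergence rate, percent per million years
#' @param L locus length in sites
#' @return substitutions per year per locus
#' @examples
#' locusSubstitutionRate(0.229, 623)   # 7.13e-7
#' @export
locusSubstitutionRate <- function(ratePctPerMy, L) {
  if (ratePctPerMy <= 0) stop("domain error: rate must be > 0")
  if (L <= 0) stop("domain error: L must be > 0")
  (ratePctPerMy / 100) / 2 * L / 1e6
}

#' Build a clock calibration from p-distance calibration points
#'
#' Each point is a list/row with \code{p} and one or two divergence times
#' (\code{tMyMin}, \code{tMyMax}; a single time may be given as
#' \code{tMy}). Older times give slower rates, so the locus-rate minimum
#' comes from the oldest calibration bound and the maximum from the
#' youngest; the mean is the midpoint of the two, the value used for
#' demographic scaling.
#'
#' @param calPoints list of calibration points
#' @param L locus length in sites
#' @return list of class "kelpconn_clock" with \code{calibrations}
#'   (data.frame p, tMy, ratePctPerMy, locusRate), \code{rateLocusMin},
#'   \code{rateLocusMax}, \code{rateLocusMean}, \code{L}
#' @export
buildCalibration <- function(calPoints, L = 623L) {
  if (!length(calPoints)) stop("domain error: no calibration points")
  rows <- list()
  for (cp in calPoints) {
    ts <- unique(stats::na.omit(c(cp$tMy, cp$tMyMin, cp$tMyMax)))
    if (!length(ts)) stop("calibration point lacks a divergence time")
    for (t in ts) {
      r <- divergenceRate(cp$p, t)
      rows[[length(rows) + 1L]] <-
        data.frame(p = cp$p, tMy = t, ratePctPerMy = r,
                   locusRate = locusSubstitutionRate(r, L))
    }
  }
  cal <- do.call(rbind, rows)
  mn <- min(cal$locusRate); mx <- max(cal$locusRate)
  structure(list(calibrations = cal, rateLocusMin = mn, rateLocusMax = mx,
                 rateLocusMean = (mn + mx) / 2, L = L),
            class = "kelpconn_clock")
}

#' @export
print.kelpconn_clock <- function(x, ...) {
  cat(sprintf("Clock calibration (%d bp locus):\n", x$L))
  print(x$calibrations, row.names = FALSE)
  cat(sprintf("  locus rate min %.3g, max %.3g, mean %.3g subst/yr\n",
              x$rateLocusMin, x$rateLocusMax, x$rateLocusMean))
  invisible(x)
}
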