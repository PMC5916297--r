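## Equilibrium (Wright island model) versus nonequilibrium (coalescent)
## connectivity: the island-model inversion of F_ST, the Crow-Aoki
## half-time of the approach to equilibrium, and the correlation /
## below-unity comparison of the two kinds of migration estimate.

#' Island-model effective migrants from F_ST
#'
#' Inverts Wright's infinite-island relation \eqn{F_{ST} = 1/(4Nm + 1)}:
#' \eqn{Nm = (1 - F_{ST})/(4 F_{ST})}. The finite-deme corrected variant
#' divides by \eqn{(d/(d-1))^2}.
#'
#' @param fst value in (0, 1]
#' @param nDemes optional deme count for the finite-island correction
#'   (default Inf: no correction, the classical inversion)
#' @return effective migrants per generation (Nm)
#' @examples
#' islandNmFromFst(0.2)     # 1.0
#' islandNmFromFst(0.268)   # 0.683
#' @export
islandNmFromFst <- function(fst, nDemes = Inf) {
  if (any(fst <= 0)) stop("domain error: F_ST <= 0 implies unbounded migration")
  if (any(fst > 1)) stop("domain error: F_ST must be <= 1")
  corr <- if (is.finite(nDemes)) (nDemes / (nDemes - 1))^2 else 1
  (1 - fst) / (4 * fst) / corr
}

#' F_ST expected under the island model at equilibrium
#'
#' Inverse companion of \code{\link{islandNmFromFst}}:
#' \eqn{F_{ST} = 1/(4Nm\,c + 1)} with \eqn{c = (d/(d-1))^2} when a finite
#' deme count is given.
#' @param nm effective migrants per generation (>= 0)
#' @param nDemes optional deme count
#' @return F_ST in (0, 1]
#' @export
fstFromIslandNm <- function(nm, nDemes = Inf) {
  if (any(nm < 0)) stop("domain error: Nm must be >= 0")
  corr <- if (is.finite(nDemes)) (nDemes / (nDemes - 1))^2 else 1
  1 / (4 * nm * corr + 1)
}

#' Crow-Aoki half-time of the approach to equilibrium differentiation
#'
#' Generations for F_ST to reach half its equilibrium value after
#' subdivision: \eqn{\ln 2 / (2m + 1/(2N_e))}.
#'
#' @param m migration rate (>= 0)
#' @param Ne effective population size (> 0)
#' @return generations
#' @examples
#' crowAokiHalfTime(0, 500)      # 693.15
#' crowAokiHalfTime(0.01, 1e6)   # 34.66
#' @export
crowAokiHalfTime <- function(m, Ne) {
  if (Ne <= 0) stop("domain error: Ne must be > 0")
  if (m < 0) stop("domain error: m must be >= 0")
  log(2) / (2 * m + 1 / (2 * Ne))
}

#' Compare equilibrium and nonequilibrium connectivity estimates
#'
#' For every population pair, the equilibrium estimate is the island-model
#' inversion of the pairwise F_ST and the nonequilibrium estimate is the
#' mean of the two directional coalescent migration estimates
#' (\eqn{(M_{a\to b} + M_{b\to a})/2}). Reports the Pearson correlation on
#' untransformed values with its two-tailed p-value from
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}}, the fraction of pairs whose
#' coalescent estimate falls below the equilibrium one, and the
#' least-squares regression line.
#'
#' @param pairwiseFst either a \code{\linkS4class{PairwiseStructure}} or a
#'   named numeric vector of pairwise F_ST keyed "POP1:POP2"
#' @param imResults named list (same "POP1:POP2" keys) of
#'   \code{\linkS4class{IMParams}}, or a data.frame with columns
#'   \code{pair}, \code{Ma} and \code{Mb} (directional effective migrants)
#' @param nDemes optional deme count for the corrected island inversion
#' @return a \code{\linkS4class{ConnectivityComparison}}
#' @export
compareConnectivity <- function(pairwiseFst, imResults, nDemes = Inf) {
  fst <- if (is(pairwiseFst, "PairwiseStructure")) {
    m <- pairwiseFst@index
    pops <- rownames(m)
    idx <- which(upper.tri(m), arr.ind = TRUE)
    stats::setNames(m[upper.tri(m)],
                    paste(pops[idx[, 1]], pops[idx[, 2]], sep = ":"))
  } else pairwiseFst

  noneq <- if (is.data.frame(imResults)) {
    stats::setNames((imResults$Ma + imResults$Mb) / 2, imResults$pair)
  } else {
    vapply(imResults, function(p) mean(effectiveMigrants(p)), numeric(1))
  }
  if (!setequal(names(fst), names(noneq)))
    stop("key error: pair sets differ between F_ST and IM inputs")
  pairs <- names(fst)
  if (length(pairs) < 3) stop("need >= 3 pairs for a correlation")
  eq <- vapply(fst[pairs], islandNmFromFst, numeric(1), nDemes = nDemes)
  ne <- noneq[pairs]
  n <- length(pairs)
  flagged <- stats::sd(eq) == 0 || stats::sd(ne) == 0
  if (flagged) {
    r <- NA_real_; p <- NA_real_; slope <- NA_real_; intercept <- NA_real_
  } else {
    r <- stats::cor(eq, ne)
    if (abs(r) >= 1) { p <- 0 } else {
      tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    slope <- stats::cov(eq, ne) / stats::var(eq)
    intercept <- mean(ne) - slope * mean(eq)
  }
  new("ConnectivityComparison",
      pairs = data.frame(pair = pairs, eqNm = unname(eq), noneqM = unname(ne),
                         stringsAsFactors = FALSE),
      r = r, p = p, nPairs = n,
      fracBelowUnity = mean(ne < eq),
      slope = slope, intercept = intercept)
}

#' Scatter plot of equilibrium vs nonequilibrium connectivity
#'
#' Equilibrium (island model) estimates on x, coalescent estimates on y,
#' with the dashed line of unity and the solid regression line.
#'
#' @param comparison a \code{\linkS4class{ConnectivityComparison}}
#' @param ... passed to \code{plot}
#' @export
plotConnectivity <- function(comparison, ...) {
  df <- comparison@pairs
  lim <- range(c(df$eqNm, df$noneqM, 0))
  graphics::plot(df$eqNm, df$noneqM, xlim = lim, ylim = lim,
                 xlab = "equilibrium estimate (island-model Nm)",
                 ylab = "coalescent estimate (mean 2Nm)",
                 pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  if (is.finite(comparison@slope))
    graphics::abline(comparison@intercept, comparison@slope)
  invisible(comparison)
}

#' @importFrom stats cov na.omit
NULL
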