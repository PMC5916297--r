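## Isolation-with-migration coalescent simulation, summary statistics and
## rejection-ABC inference in demographic units.

#' Construct an IMParams object
#'
#' @param Na,Nb,Nanc effective population sizes (individuals)
#' @param Tsplit split time in years
#' @param mAB,mBA forward-in-time per-generation migration fractions
#'   (a to b, b to a)
#' @param generationTime years per generation (default 1, so years equal
#'   generations)
#' @return an \code{\linkS4class{IMParams}}
#' @export
imParams <- function(Na, Nb, Nanc, Tsplit, mAB = 0, mBA = 0,
                     generationTime = 1) {
  new("IMParams", Na = Na, Nb = Nb, Nanc = Nanc, Tsplit = Tsplit,
      mAB = mAB, mBA = mBA, generationTime = generationTime)
}

#' Sampling/mutation configuration for the IM simulator
#'
#' @param nSeq length-2 integer: haploid-locus sequences sampled per
#'   population (0 to skip the sequence marker)
#' @param nInd length-2 integer: diploid individuals genotyped per
#'   population (0 to skip microsatellites)
#' @param L sequence locus length in sites (default 623)
#' @param muSeq sequence substitutions per locus per year
#' @param nMicrosatLoci number of microsatellite loci
#' @param muMicrosat microsatellite mutations per locus per generation
#'   (default 0.001564, the cross-taxon average used for kelp)
#' @param microsatRateMultipliers per-locus multipliers on
#'   \code{muMicrosat} (e.g. 10 for a hypervariable locus)
#' @param generationTime years per generation
#' @param microsatRoot ancestral repeat count (arbitrary origin)
#' @return validated list of class "kelpconn_config"
#' @export
sampleConfig <- function(nSeq = c(20L, 20L), nInd = c(20L, 20L), L = 623L,
                         muSeq = 1.85e-6, nMicrosatLoci = 10L,
                         muMicrosat = 0.001564,
                         microsatRateMultipliers = rep(1, nMicrosatLoci),
                         generationTime = 1, microsatRoot = 30L) {
  stopifnot(length(nSeq) == 2L, length(nInd) == 2L, all(nSeq >= 0),
            all(nInd >= 0), L > 0, muSeq >= 0, muMicrosat >= 0,
            generationTime > 0,
            length(microsatRateMultipliers) == nMicrosatLoci)
  if (sum(nSeq) + sum(nInd) == 0) stop("at least one marker must be sampled")
  structure(list(nSeq = as.integer(nSeq), nInd = as.integer(nInd),
                 L = as.integer(L), muSeq = muSeq,
                 nMicrosatLoci = as.integer(nMicrosatLoci),
                 muMicrosat = muMicrosat,
                 microsatRateMultipliers = microsatRateMultipliers,
                 generationTime = generationTime,
                 microsatRoot = as.integer(microsatRoot)),
            class = "kelpconn_config")
}

BASES <- c("A", "C", "G", "T")

seqMatrixToAlignment <- function(mat, ids) {
  seqs <- apply(mat, 1L, function(r) paste(BASES[r + 1L], collapse = ""))
  haplotypeAlignment(stats::setNames(seqs, ids))
}

#' Simulate a two-population isolation-with-migration dataset
#'
#' Structured coalescent backward in time: within-deme coalescence at
#' rate \eqn{\binom{k}{2}/(2N)} per generation for diploid nuclear loci
#' and \eqn{\binom{k}{2}/N} for the haploid organelle locus; backward
#' migration per lineage in deme i at rate \eqn{m_{ji} N_j / N_i}
#' (forward rates are the user-facing parameterization); at the split
#' time all lineages merge into an ancestral pool. Sequence mutations are
#' finite-sites Jukes-Cantor at \code{muSeq}/L per site-year; microsatellites
#' follow an unbounded single-step model. With \code{mAB = mBA = 0} the
#' pure-isolation sub-model is obtained. Deterministic given \code{seed}.
#'
#' @param params an \code{\linkS4class{IMParams}}
#' @param config a \code{\link{sampleConfig}}
#' @param seed integer RNG seed
#' @param popCodes length-2 population codes (default c("A","B"))
#' @return a \code{\linkS4class{SimulatedDataset}}
#' @export
simulateIM <- function(params, config, seed, popCodes = c("A", "B")) {
  stopifnot(is(params, "IMParams"), inherits(config, "kelpconn_config"))
  sizes <- c(params@Na, params@Nb)
  active <- (config$nSeq > 1) | (config$nInd > 0)
  if (any(sizes[active] <= 0) || (params@Nanc <= 0))
    stop("parameter error: zero effective size with lineages to coalesce")
  set.seed(seed)
  T_gen <- params@Tsplit / params@generationTime
  mF <- matrix(0, 2, 2)
  mF[1, 2] <- params@mAB; mF[2, 1] <- params@mBA
  muSeqGen <- config$muSeq * params@generationTime
  muMicro <- config$muMicrosat * config$microsatRateMultipliers
  raw <- cpp_simulate_dataset(config$nSeq, config$nInd,
                              c(params@Na, params@Nb), params@Nanc,
                              mF, T_gen, config$L, muSeqGen,
                              as.numeric(muMicro), c(0, 0),
                              config$microsatRoot)
  popSeq <- rep(popCodes, config$nSeq)
  alignment <- NULL
  populationOf <- character(0)
  if (sum(config$nSeq) > 0) {
    ids <- paste0(popSeq, "_", unlist(lapply(config$nSeq, seq_len)))
    alignment <- seqMatrixToAlignment(raw$seq, ids)
    populationOf <- stats::setNames(popSeq, ids)
  }
  genotypes <- NULL
  if (!is.null(raw$microA)) {
    popInd <- rep(popCodes, config$nInd)
    genotypes <- genotypeMatrix(
      raw$microA, raw$microB, population = popInd,
      ids = paste0(popInd, "_g", unlist(lapply(config$nInd, seq_len))),
      loci = paste0("ms", seq_len(config$nMicrosatLoci)))
  }
  new("SimulatedDataset", alignment = alignment, populationOf = populationOf,
      genotypes = genotypes,
      trueParams = list(params = params, config = config), seed = seed)
}

summaryNames <- function(config) {
  nm <- character(0)
  if (sum(config$nSeq) > 0)
    nm <- c(nm, "seq_nh_a", "seq_h_a", "seq_pi_a",
            "seq_nh_b", "seq_h_b", "seq_pi_b", "seq_shared", "seq_phist")
  if (config$nMicrosatLoci > 0 && sum(config$nInd) > 0)
    nm <- c(nm, "ms_k_a", "ms_k_b", "ms_he_a", "ms_he_b",
            "ms_var_a", "ms_var_b", "ms_dmu2", "ms_shared", "ms_fst")
  nm
}

## mean expected heterozygosity / allele count / allele-size variance
## per population, averaged over loci
microsatPopStats <- function(genotypes) {
  A <- genotypes@alleleA; B <- genotypes@alleleB
  pops <- levels(genotypes@population)
  out <- list()
  for (p in pops) {
    sel <- genotypes@population == p
    k <- he <- v <- 0
    nL <- ncol(A)
    for (l in seq_len(nL)) {
      g <- c(A[sel, l], B[sel, l]); g <- g[!is.na(g)]
      f <- table(g) / length(g)
      k <- k + length(f)
      he <- he + length(g) / (length(g) - 1) * (1 - sum(f^2))
      v <- v + stats::var(g)
    }
    out[[p]] <- c(k = k / nL, he = he / nL, var = v / nL)
  }
  out
}

## between-population microsatellite divergence for the first two
## populations: Goldstein's (delta mu)^2 and the shared-allele count,
## averaged over loci
microsatPairStats <- function(genotypes) {
  A <- genotypes@alleleA; B <- genotypes@alleleB
  pops <- levels(genotypes@population)[1:2]
  nL <- ncol(A)
  dmu2 <- shared <- 0
  for (l in seq_len(nL)) {
    g1 <- c(A[genotypes@population == pops[1], l],
            B[genotypes@population == pops[1], l])
    g2 <- c(A[genotypes@population == pops[2], l],
            B[genotypes@population == pops[2], l])
    g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
    if (!length(g1) || !length(g2)) next
    dmu2 <- dmu2 + (mean(g1) - mean(g2))^2
    shared <- shared + length(intersect(unique(g1), unique(g2)))
  }
  c(dmu2 = dmu2 / nL, shared = shared / nL)
}

#' Summary-statistic vector of a simulated or observed dataset
#'
#' Deterministic; delegates to the diversity and AMOVA machinery. Per
#' population: haplotype count, haplotype diversity, nucleotide diversity
#' (sequence marker), mean allele count, expected heterozygosity and
#' allele-size variance over loci (microsatellites). Between populations:
#' shared haplotype count, pairwise Phi_ST / F_ST (0 when undefined on
#' monomorphic data, so the vector is always finite), Goldstein's
#' (delta mu)^2 and the mean shared-allele count.
#'
#' @param dataset a \code{\linkS4class{SimulatedDataset}}
#' @return named numeric vector with a fixed ordering
#' @export
summarizeDataset <- function(dataset) {
  out <- numeric(0)
  cfgpops <- c("a", "b")
  if (is(dataset@alignment, "HaplotypeAlignment")) {
    ft <- collapseHaplotypes(dataset@alignment, dataset@populationOf)
    cts <- hapCounts(ft)
    L <- alignmentLength(dataset@alignment)
    D <- pairwiseHamming(hapSequences(ft))
    vals <- numeric(0)
    for (p in seq_len(nrow(cts))) {
      cc <- cts[p, ]
      hd <- haplotypeDiversity(cc)
      pd <- nucleotideDiversity(cc, D, L)
      vals <- c(vals, sum(cc > 0), hd["h"], pd["pi"])
    }
    out <- c(out, vals)
    if (nrow(cts) >= 2L) {
      shared <- sum(cts[1, ] > 0 & cts[2, ] > 0)
      phi <- amovaHaplotypic(ft, D, nPermutations = 0)@indices["PhiST"]
      if (!is.finite(phi)) phi <- 0
      out <- c(out, shared, phi)
    }
  }
  if (is(dataset@genotypes, "GenotypeMatrix") &&
      ncol(dataset@genotypes@alleleA) > 0) {
    st <- microsatPopStats(dataset@genotypes)
    pr <- microsatPairStats(dataset@genotypes)
    fst <- amovaGenotypic(dataset@genotypes, nPermutations = 0)@indices["FST"]
    if (!is.finite(fst)) fst <- 0
    out <- c(out,
             st[[1]]["k"], st[[2]]["k"], st[[1]]["he"], st[[2]]["he"],
             st[[1]]["var"], st[[2]]["var"], pr["dmu2"], pr["shared"], fst)
  }
  cfg <- dataset@trueParams$config
  nm <- if (!is.null(cfg)) summaryNames(cfg) else NULL
  if (!is.null(nm) && length(nm) == length(out)) names(out) <- nm
  out
}

## expand a compact prior spec into per-draw 6-parameter rows.
## priors: named list of c(min,max); recognized names:
##   Na, Nb, Nanc, Tsplit (years), mAB, mBA   -- direct
##   N  (shared Na = Nb, and Nanc unless given), M (shared 2Nm both ways),
##   m  (shared fraction both ways)
drawPriorMatrix <- function(priors, nSims, generationTime) {
  draw <- function(nm) stats::runif(nSims, priors[[nm]][1], priors[[nm]][2])
  has <- function(nm) nm %in% names(priors)
  N <- if (has("N")) draw("N") else NULL
  Na <- if (has("Na")) draw("Na") else N
  Nb <- if (has("Nb")) draw("Nb") else N
  Nanc <- if (has("Nanc")) draw("Nanc") else if (!is.null(N)) N else (Na + Nb) / 2
  if (is.null(Na) || is.null(Nb)) stop("priors must determine Na and Nb (or N)")
  Tyears <- if (has("Tsplit")) draw("Tsplit") else stop("priors must include Tsplit")
  mAB <- mBA <- NULL
  if (has("M")) {
    M <- draw("M")
    mAB <- M / (2 * Nb); mBA <- M / (2 * Na)
  }
  if (has("m")) mAB <- mBA <- draw("m")
  if (has("mAB")) mAB <- draw("mAB")
  if (has("mBA")) mBA <- draw("mBA")
  if (is.null(mAB)) mAB <- rep(0, nSims)
  if (is.null(mBA)) mBA <- rep(0, nSims)
  cbind(Na = Na, Nb = Nb, Nanc = Nanc, T_gen = Tyears / generationTime,
        mAB = mAB, mBA = mBA)
}

## report natural parameters for the accepted draws, in the prior's own
## parameterization (N / M / m aggregates included when declared)
acceptedFrame <- function(pm, priors, generationTime) {
  df <- data.frame(Na = pm[, "Na"], Nb = pm[, "Nb"], Nanc = pm[, "Nanc"],
                   Tsplit = pm[, "T_gen"] * generationTime,
                   mAB = pm[, "mAB"], mBA = pm[, "mBA"])
  if ("N" %in% names(priors)) df$N <- df$Na
  if ("M" %in% names(priors)) df$M <- 2 * df$Nb * df$mAB
  if ("m" %in% names(priors)) df$m <- df$mAB
  df
}

hpdInterval <- function(x, mass = 0.9) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, ceiling(mass * n))
  if (m >= n) return(c(x[1], x[n]))
  width <- x[seq(m, n)] - x[seq_len(n - m + 1)]
  i <- which.min(width)
  c(x[i], x[i + m - 1])
}

kdeMode <- function(x, w = NULL) {
  if (length(unique(x)) == 1L) return(x[1])
  bw <- stats::bw.nrd0(x)
  d <- if (is.null(w)) stats::density(x, bw = bw) else
    stats::density(x, bw = bw, weights = w / sum(w))
  d$x[which.max(d$y)]
}

#' Rejection-ABC inference of IM parameters
#'
#' Draws parameters from uniform priors, simulates with
#' \code{\link{simulateIM}}'s engine, computes the summary vector, and
#' accepts the draws whose Euclidean distance to the observed summaries
#' (each summary standardized by its median absolute deviation over the
#' simulation pool) falls in the smallest \code{toleranceQuantile}
#' fraction. Point estimates are marginal weighted-KDE modes
#' (Epanechnikov weights on distance); intervals are 90\% highest-density
#' intervals of the accepted draws. An optional local-linear regression
#' adjustment is available.
#'
#' @param observed named summary vector from \code{\link{summarizeDataset}}
#' @param config the \code{\link{sampleConfig}} used for the observed data
#' @param priors named list of \code{c(min, max)} ranges; direct names
#'   Na, Nb, Nanc, Tsplit (years), mAB, mBA, or the aggregates N (shared
#'   size), m (shared fraction), M (shared effective migrants 2Nm)
#' @param nSims number of simulations (>= 1000 recommended; warns below)
#' @param toleranceQuantile accepted fraction (default 0.01)
#' @param seed RNG seed
#' @param regressionAdjust apply local-linear adjustment (default FALSE)
#' @return an \code{\linkS4class{IMPosterior}}
#' @export
abcInfer <- function(observed, config, priors, nSims = 20000L,
                     toleranceQuantile = 0.01, seed,
                     regressionAdjust = FALSE) {
  stopifnot(inherits(config, "kelpconn_config"))
  if (nSims < 1000) warning("nSims < 1000: posterior will be unreliable")
  set.seed(seed)
  pm <- drawPriorMatrix(priors, nSims, config$generationTime)
  muMicro <- config$muMicrosat * config$microsatRateMultipliers
  S <- cpp_abc_summaries(pm, config$nSeq[1], config$nSeq[2],
                         config$nInd[1], config$nInd[2], config$L,
                         config$muSeq * config$generationTime,
                         as.numeric(muMicro), config$microsatRoot)
  colnames(S) <- summaryNames(config)
  obs <- observed[colnames(S)]
  if (anyNA(obs)) stop("observed summaries missing entries: ",
                       paste(colnames(S)[is.na(obs)], collapse = ", "))
  scale <- apply(S, 2, stats::mad)
  usable <- scale > 0
  if (any(!usable))
    warning("dropping zero-variance summaries: ",
            paste(colnames(S)[!usable], collapse = ", "))
  if (any(usable)) {
    Z <- sweep(S[, usable, drop = FALSE], 2, scale[usable], "/")
    zobs <- obs[usable] / scale[usable]
    dist <- sqrt(rowSums(sweep(Z, 2, zobs, "-")^2))
  } else {
    ## no informative summary: every draw is equally close, so the
    ## acceptance set is a plain prior sample
    Z <- NULL
    dist <- rep(0, nSims)
  }
  nAccept <- ceiling(toleranceQuantile * nSims)
  ord <- order(dist)[seq_len(nAccept)]
  if (!length(ord)) stop("empty acceptance")
  acc <- acceptedFrame(pm[ord, , drop = FALSE], priors, config$generationTime)
  dmax <- max(dist[ord])
  w <- if (dmax > 0) 1 - (dist[ord] / dmax)^2 else rep(1, nAccept)
  w[w <= 0] <- min(w[w > 0], 1e-6)

  if (regressionAdjust && dmax > 0 && !is.null(Z)) {
    X <- cbind(1, sweep(Z[ord, , drop = FALSE], 2, zobs, "-"))
    for (nm in names(acc)) {
      fit <- try(stats::lm.wfit(X, acc[[nm]], w), silent = TRUE)
      if (!inherits(fit, "try-error") && !anyNA(fit$coefficients))
        acc[[nm]] <- fit$coefficients[1] + fit$residuals
    }
  }
  est <- vapply(acc, function(x) kdeMode(x, w), numeric(1))
  lo <- vapply(acc, function(x) hpdInterval(x)[1], numeric(1))
  hi <- vapply(acc, function(x) hpdInterval(x)[2], numeric(1))
  acc$distance <- dist[ord]
  new("IMPosterior", accepted = acc, pointEstimates = est,
      hpdLower = lo, hpdUpper = hi, nSims = nSims,
      toleranceQuantile = toleranceQuantile, seed = seed)
}

#' Convert coalescent-scaled IM parameters to demographic units
#'
#' Scaled parameters follow the mutation-rate scaling of IM-style
#' inference: \eqn{\theta_x} is the population mutation rate of
#' population x, \eqn{\tau} the split time in expected mutations, and
#' \eqn{m^*} the migration fraction divided by the per-generation locus
#' mutation rate. With \eqn{\mu_g = \mu_{yr} \cdot g} (mutations per
#' locus per generation):
#' \deqn{N = \theta / (2\mu_g) \textrm{ (haploid locus) or } \theta/(4\mu_g)
#' \textrm{ (diploid)}, \quad T_{years} = \tau/\mu_{yr}, \quad m = m^* \mu_g.}
#'
#' @param scaled named list/vector with entries thetaA, thetaB, thetaAnc,
#'   tau, mScaledAB, mScaledBA (migration entries optional, default 0)
#' @param muLocusPerYear substitutions per locus per year (> 0)
#' @param generationTime years per generation
#' @param ploidy "haploid" (organelle) or "diploid" (nuclear)
#' @return an \code{\linkS4class{IMParams}}
#' @seealso \code{\link{demographicToScaled}} for the inverse
#' @export
scaleToDemographic <- function(scaled, muLocusPerYear, generationTime = 1,
                               ploidy = c("haploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  if (muLocusPerYear <= 0) stop("domain error: mu must be > 0")
  s <- as.list(scaled)
  muGen <- muLocusPerYear * generationTime
  k <- if (ploidy == "haploid") 2 else 4
  mAB <- if (!is.null(s$mScaledAB)) s$mScaledAB * muGen else 0
  mBA <- if (!is.null(s$mScaledBA)) s$mScaledBA * muGen else 0
  imParams(Na = s$thetaA / (k * muGen), Nb = s$thetaB / (k * muGen),
           Nanc = s$thetaAnc / (k * muGen),
           Tsplit = s$tau / muLocusPerYear,
           mAB = mAB, mBA = mBA, generationTime = generationTime)
}

#' Convert demographic IM parameters to the coalescent scaling
#'
#' Inverse of \code{\link{scaleToDemographic}}; the round trip is exact.
#' @param params an \code{\linkS4class{IMParams}}
#' @param muLocusPerYear substitutions per locus per year (> 0)
#' @param ploidy "haploid" or "diploid"
#' @return named list thetaA, thetaB, thetaAnc, tau, mScaledAB, mScaledBA
#' @export
demographicToScaled <- function(params, muLocusPerYear,
                                ploidy = c("haploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  if (muLocusPerYear <= 0) stop("domain error: mu must be > 0")
  muGen <- muLocusPerYear * params@generationTime
  k <- if (ploidy == "haploid") 2 else 4
  list(thetaA = k * muGen * params@Na, thetaB = k * muGen * params@Nb,
       thetaAnc = k * muGen * params@Nanc,
       tau = params@Tsplit * muLocusPerYear,
       mScaledAB = params@mAB / muGen, mScaledBA = params@mBA / muGen)
}
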