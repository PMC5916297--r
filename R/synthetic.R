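## Study-shaped synthetic data: a nine-population design mirroring the
## sampling table of the kelp survey (191 sequences / 213 genotyped
## individuals), generated under a many-deme split-with-migration model,
## plus a small deterministic haplotype fixture.

#' Default study design
#'
#' Populations, per-population sample sizes for both markers, and
#' per-population selfing probabilities (chosen so that single-generation
#' selfing at diploid formation, F_IS ~ s/2, reproduces the observed
#' inbreeding levels structurally; negative observed F_IS maps to 0).
#' Structure targets: mitochondrial Phi_ST ~ 0.93 and microsatellite
#' F_ST ~ 0.27, the regime of the study system.
#'
#' @param populations data.frame with columns code, nSeq, nGeno, selfing
#' @param L sequence locus length
#' @param nMicrosatLoci number of microsatellite loci
#' @param hypervariableMultiplier mutation-rate multiplier for the last
#'   locus (emulates one highly variable marker)
#' @param N,Nanc deme and ancestral effective sizes (individuals)
#' @param m symmetric forward migration fraction between demes (near zero:
#'   the deep mitochondrial divergence of the study system requires
#'   essentially no gene flow)
#' @param Tsplit split time in generations before present; the default
#'   places about six expected mutations on the deme branches of the
#'   sequence locus (\eqn{T = 6/(d \mu)}), the variable-site regime of
#'   the study alignment
#' @param muSeq sequence substitutions per locus per year
#' @param muMicrosat microsatellite mutations per locus per generation
#' @param targetPhiST,targetFst structure targets in [0,1] recorded in the
#'   truth record; a warning reports strongly discrepant achieved values
#' @return list of class "kelpconn_design"
#' @export
studyDesign <- function(
    populations = data.frame(
      code = c("SL", "SN", "SF1", "SF2", "SS", "SD", "SW", "SI", "SB"),
      nSeq = c(19L, 29L, 17L, 13L, 3L, 22L, 25L, 30L, 33L),
      nGeno = c(31L, 29L, 18L, 14L, 6L, 22L, 30L, 30L, 33L),
      selfing = c(0, 0.26, 0, 0.13, 0, 0.35, 0.77, 0, 0.23),
      stringsAsFactors = FALSE),
    L = 623L, nMicrosatLoci = 10L, hypervariableMultiplier = 10,
    N = 700, Nanc = 700, m = 1e-6, Tsplit = NULL,
    muSeq = 1.85e-6, muMicrosat = 0.001564,
    targetPhiST = 0.93, targetFst = 0.27) {
  stopifnot(all(populations$nSeq >= 0), all(populations$nGeno >= 0),
            all(populations$selfing >= 0 & populations$selfing <= 1),
            targetPhiST >= 0, targetPhiST <= 1, targetFst >= 0, targetFst <= 1)
  d <- nrow(populations)
  if (is.null(Tsplit)) {
    ## deep radiation: ~6 expected mutations on the d deme branches of the
    ## sequence locus, while within-deme sequence diversity stays tiny
    Tsplit <- round(6 / (d * muSeq) / 500) * 500
  }
  structure(list(populations = populations, L = as.integer(L),
                 nMicrosatLoci = as.integer(nMicrosatLoci),
                 hypervariableMultiplier = hypervariableMultiplier,
                 N = N, Nanc = Nanc, m = m, Tsplit = Tsplit,
                 muSeq = muSeq, muMicrosat = muMicrosat,
                 targetPhiST = targetPhiST, targetFst = targetFst),
            class = "kelpconn_design")
}

#' Generate a study-shaped synthetic dataset
#'
#' Simulates the design's populations under a many-deme structured
#' coalescent: all demes split from a common ancestral pool
#' \code{Tsplit} generations ago and exchange symmetric migrants at rate
#' \code{m} thereafter; the haploid sequence locus and the diploid
#' microsatellite panel share this demography. Inbreeding is imposed by
#' per-population selfing probability at diploid formation. Deterministic
#' given \code{seed}. The truth record carries the design and the
#' achieved overall Phi_ST / F_ST; achieved values far from the design
#' targets trigger a warning.
#'
#' @param design a \code{\link{studyDesign}}
#' @param seed RNG seed
#' @return a \code{\linkS4class{SimulatedDataset}}
#' @export
generateStudyLike <- function(design = studyDesign(), seed) {
  stopifnot(inherits(design, "kelpconn_design"))
  set.seed(seed)
  pops <- design$populations
  d <- nrow(pops)
  mF <- matrix(design$m, d, d); diag(mF) <- 0
  mult <- rep(1, design$nMicrosatLoci)
  if (design$nMicrosatLoci > 0)
    mult[design$nMicrosatLoci] <- design$hypervariableMultiplier
  raw <- cpp_simulate_dataset(
    pops$nSeq, pops$nGeno, rep(design$N, d), design$Nanc, mF,
    design$Tsplit, design$L, design$muSeq,  # generation time 1 year
    design$muMicrosat * mult, pops$selfing, 500L)
  popSeq <- rep(pops$code, pops$nSeq)
  ids <- paste0(popSeq, "_", unlist(lapply(pops$nSeq, seq_len)))
  alignment <- seqMatrixToAlignment(raw$seq, ids)
  populationOf <- stats::setNames(popSeq, ids)
  popInd <- rep(pops$code, pops$nGeno)
  genotypes <- genotypeMatrix(
    raw$microA, raw$microB, population = popInd,
    ids = paste0(popInd, "_g", unlist(lapply(pops$nGeno, seq_len))),
    loci = paste0("ms", seq_len(design$nMicrosatLoci)))

  ft <- collapseHaplotypes(alignment, populationOf)
  achievedPhi <- amovaHaplotypic(ft, nPermutations = 0)@indices["PhiST"]
  achievedFst <- amovaGenotypic(genotypes, nPermutations = 0)@indices["FST"]
  if (is.finite(achievedPhi) && abs(achievedPhi - design$targetPhiST) > 0.2)
    warning(sprintf("achieved Phi_ST %.3f far from target %.3f",
                    achievedPhi, design$targetPhiST))
  if (is.finite(achievedFst) && abs(achievedFst - design$targetFst) > 0.2)
    warning(sprintf("achieved F_ST %.3f far from target %.3f",
                    achievedFst, design$targetFst))
  new("SimulatedDataset", alignment = alignment, populationOf = populationOf,
      genotypes = genotypes,
      trueParams = list(design = design,
                        achieved = list(PhiST = unname(achievedPhi),
                                        FST = unname(achievedFst))),
      seed = seed)
}

#' Deterministic seven-haplotype fixture
#'
#' A fixed 623 bp alignment of seven haplotypes (a-g) differing at six
#' variable sites whose one-step neighbor graph is a known tree, with
#' per-population counts for nine populations (several fixed for a single
#' haplotype). The minimum spanning network of the fixture is exactly
#' that tree (six edges).
#'
#' @return list with \code{alignment} (\code{HaplotypeAlignment} of the
#'   seven haplotypes), \code{freqTable} (\code{HaplotypeFreqTable}) and
#'   \code{edges} (the expected spanning-tree edges)
#' @export
fixtureHaplotypes <- function() {
  L <- 623L
  base <- strsplit(paste(rep("ACGT", ceiling(L / 4)), collapse = ""), "")[[1]][1:L]
  sites <- c(50L, 150L, 250L, 350L, 450L, 550L)
  flip <- function(s, pos) { s[pos] <- chartr("ACGT", "TGCA", s[pos]); s }
  hap <- list()
  hap$a <- base
  hap$b <- flip(base, sites[1])
  hap$c <- flip(base, sites[2])
  hap$d <- flip(flip(base, sites[2]), sites[3])   # c + 1 step
  hap$e <- flip(base, sites[4])
  hap$f <- flip(flip(base, sites[4]), sites[5])   # e + 1 step
  hap$g <- flip(base, sites[6])
  seqs <- vapply(hap, paste, character(1), collapse = "")
  counts <- rbind(
    SL  = c(a = 19, b = 0,  c = 0, d = 0, e = 0,  f = 0, g = 0),
    SN  = c(29, 0, 0, 0, 0, 0, 0),
    SF1 = c(0, 17, 0, 0, 0, 0, 0),
    SF2 = c(0, 12, 0, 0, 0, 0, 1),
    SS  = c(2, 0, 0, 0, 0, 0, 1),
    SD  = c(18, 0, 1, 3, 0, 0, 0),
    SW  = c(0, 0, 0, 0, 25, 0, 0),
    SI  = c(29, 0, 1, 0, 0, 0, 0),
    SB  = c(0, 0, 0, 0, 32, 1, 0))
  colnames(counts) <- names(hap)
  edges <- data.frame(from = c("a", "a", "a", "a", "c", "e"),
                      to = c("b", "c", "e", "g", "d", "f"),
                      steps = 1L, stringsAsFactors = FALSE)
  list(alignment = haplotypeAlignment(seqs),
       freqTable = haplotypeFreqTable(counts, haplotypeSeqs = seqs),
       edges = edges)
}

#' Write the deterministic fixture to files
#'
#' FASTA of the seven haplotypes plus a per-population count CSV; used to
#' provision plain-text fixtures.
#' @param dir output directory
#' @return invisibly, the two paths
#' @export
writeFixtureHaplotypes <- function(dir = ".") {
  fx <- fixtureHaplotypes()
  fa <- file.path(dir, "coi_fixture.fasta")
  cs <- file.path(dir, "coi_fixture_counts.csv")
  writeFastaAlignment(fx$alignment, fa)
  utils::write.csv(data.frame(population = rownames(hapCounts(fx$freqTable)),
                              hapCounts(fx$freqTable),
                              check.names = FALSE),
                   cs, row.names = FALSE, quote = FALSE)
  invisible(c(fa, cs))
}
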