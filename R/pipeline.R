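## Full-analysis orchestration: data -> diversity -> network -> AMOVA /
## pairwise structure -> PCoA -> per-pair ABC-IM -> equilibrium
## comparison, with a run log and plain-text artifacts.

#' Default run configuration
#'
#' @param fasta,popmap,genotypesCsv,metadata input paths (popmap: CSV with
#'   columns id, population); all NULL when \code{design} is given, in
#'   which case data are generated synthetically
#' @param design optional \code{\link{studyDesign}} for synthetic input
#' @param L,muSeq,muMicrosat,generationTime marker settings
#' @param nPermutations permutations for AMOVA and pairwise tests
#' @param minN populations whose smallest marker sample size falls below
#'   this are excluded from structure analyses (they stay in the
#'   diversity table)
#' @param abc list with nSims, tolerance, priors (see \code{\link{abcInfer}})
#' @param seed RNG seed recorded in all outputs
#' @param outDir output directory
#' @return list of class "kelpconn_runconfig"
#' @export
runConfig <- function(fasta = NULL, popmap = NULL, genotypesCsv = NULL,
                      metadata = NULL, design = NULL,
                      L = 623L, muSeq = 1.85e-6, muMicrosat = 0.001564,
                      generationTime = 1, nPermutations = 999L, minN = 4L,
                      abc = list(nSims = 2000L, tolerance = 0.02,
                                 priors = list(N = c(5, 500),
                                               Tsplit = c(10, 5000),
                                               M = c(0.01, 5))),
                      seed = 1L, outDir = tempfile("kelpconn_run")) {
  structure(list(fasta = fasta, popmap = popmap, genotypesCsv = genotypesCsv,
                 metadata = metadata, design = design, L = L, muSeq = muSeq,
                 muMicrosat = muMicrosat, generationTime = generationTime,
                 nPermutations = nPermutations, minN = minN, abc = abc,
                 seed = seed, outDir = outDir),
            class = "kelpconn_runconfig")
}

#' Read a run configuration from YAML
#' @param path YAML file with the fields of \code{\link{runConfig}}
#' @return a "kelpconn_runconfig"
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  y$design <- NULL  # designs are R-side objects; synthetic runs set them in code
  do.call(runConfig, y)
}

pairKey <- function(a, b) paste(a, b, sep = ":")

## observed 2-population slice wrapped as a dataset for summarizeDataset
pairDataset <- function(alignment, populationOf, genotypes, popA, popB,
                        config) {
  aln <- NULL; pom <- character(0)
  if (!is.null(alignment) && sum(config$nSeq) > 0) {
    keep <- names(populationOf)[populationOf %in% c(popA, popB)]
    ord <- keep[order(match(populationOf[keep], c(popA, popB)))]
    aln <- haplotypeAlignment(stats::setNames(
      as.character(alignment@sequences[ord]), ord))
    pom <- populationOf[ord]
  }
  gm <- NULL
  if (!is.null(genotypes) && sum(config$nInd) > 0) {
    sel <- which(as.character(genotypes@population) %in% c(popA, popB))
    sel <- sel[order(match(as.character(genotypes@population)[sel],
                           c(popA, popB)))]
    gm <- genotypeMatrix(genotypes@alleleA[sel, , drop = FALSE],
                         genotypes@alleleB[sel, , drop = FALSE],
                         as.character(genotypes@population)[sel])
  }
  new("SimulatedDataset", alignment = aln, populationOf = pom,
      genotypes = gm, trueParams = list(config = config), seed = 0)
}

#' Run the full connectivity analysis
#'
#' Reads (or synthesizes) the data and writes: a diversity table CSV,
#' AMOVA CSV, pairwise Phi_ST/F_ST TSVs, network edge list, PCoA
#' coordinates CSV, per-pair ABC-IM estimates JSON, the
#' equilibrium-vs-coalescent comparison CSV with a scatter plot, and a
#' JSON run log with seed and package version. Populations below the
#' \code{minN} threshold are excluded from structure analyses but remain
#' in the diversity table. Any stage failure is logged; partial outputs
#' are retained and the function then signals an error.
#'
#' @param config a \code{\link{runConfig}} or path to a YAML file
#' @return invisibly, named list of artifact paths
#' @export
runFullAnalysis <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "kelpconn_runconfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  failures <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", name, conditionMessage(e)))
      NULL
    })
  }
  out <- function(f) file.path(config$outDir, f)
  set.seed(config$seed)

  ## ---- inputs ----
  if (!is.null(config$design)) {
    ds <- generateStudyLike(config$design, seed = config$seed)
    alignment <- ds@alignment; populationOf <- ds@populationOf
    genotypes <- ds@genotypes
  } else {
    alignment <- if (!is.null(config$fasta)) readFastaAlignment(config$fasta) else NULL
    populationOf <- if (!is.null(config$popmap)) {
      pm <- utils::read.csv(config$popmap, stringsAsFactors = FALSE)
      stats::setNames(pm$population, pm$id)
    } else character(0)
    genotypes <- if (!is.null(config$genotypesCsv))
      readGenotypes(config$genotypesCsv, "csv") else NULL
  }

  ft <- if (!is.null(alignment)) collapseHaplotypes(alignment, populationOf) else NULL

  ## ---- diversity table (all populations) ----
  stage("diversity", {
    div <- diversityTable(ft, L = config$L)
    utils::write.csv(div, out("diversity.csv"), row.names = FALSE)
    paths$diversity <- out("diversity.csv")
  })

  ## ---- haplotype network ----
  stage("network", {
    net <- minimumSpanningNetwork(ft)
    exportNetwork(net, out("network_edges.tsv"), out("network.dot"))
    paths$network <- out("network_edges.tsv")
  })

  ## ---- exclusions for structure analyses ----
  nBySeq <- if (!is.null(ft)) rowSums(hapCounts(ft)) else NULL
  nByGeno <- if (!is.null(genotypes)) table(genotypes@population) else NULL
  allPops <- union(names(nBySeq), names(nByGeno))
  minPer <- vapply(allPops, function(p) {
    min(c(if (!is.null(nBySeq) && p %in% names(nBySeq)) nBySeq[p],
          if (!is.null(nByGeno) && p %in% names(nByGeno)) nByGeno[p]))
  }, numeric(1))
  keepPops <- allPops[minPer >= config$minN]
  if (length(keepPops) < length(allPops))
    message("excluding from structure analyses (n < ", config$minN, "): ",
            paste(setdiff(allPops, keepPops), collapse = ", "))

  ftS <- NULL
  if (!is.null(ft)) {
    cts <- hapCounts(ft)
    cts <- cts[rownames(cts) %in% keepPops, , drop = FALSE]
    cts <- cts[, colSums(cts) > 0, drop = FALSE]
    ftS <- new("HaplotypeFreqTable", counts = cts,
               haplotypeSeqs = hapSequences(ft)[colnames(cts)])
  }
  gmS <- NULL
  if (!is.null(genotypes)) {
    sel <- which(as.character(genotypes@population) %in% keepPops)
    gmS <- genotypeMatrix(genotypes@alleleA[sel, , drop = FALSE],
                          genotypes@alleleB[sel, , drop = FALSE],
                          as.character(genotypes@population)[sel])
  }

  ## ---- AMOVA + pairwise ----
  pwF <- NULL
  stage("amova", {
    rows <- list()
    if (!is.null(ftS)) {
      ah <- amovaHaplotypic(ftS, nPermutations = config$nPermutations,
                            seed = config$seed)
      rows$hap <- cbind(marker = "COI", ah@components)
      rows$hapIdx <- data.frame(marker = "COI", component = "index PhiST",
                                df = NA, SS = NA, variance = ah@indices["PhiST"],
                                percent = NA)
    }
    if (!is.null(gmS)) {
      ag <- amovaGenotypic(gmS, nPermutations = config$nPermutations,
                           seed = config$seed)
      rows$gen <- cbind(marker = "microsat", ag@components)
      rows$genIdx <- data.frame(marker = "microsat",
                                component = paste("index", names(ag@indices)),
                                df = NA, SS = NA, variance = unname(ag@indices),
                                percent = NA)
    }
    utils::write.csv(do.call(rbind, rows), out("amova.csv"), row.names = FALSE)
    paths$amova <- out("amova.csv")
  })
  stage("pairwise", {
    if (!is.null(ftS) && nrow(hapCounts(ftS)) >= 2) {
      pwP <- pairwiseStructure(ftS, "haplotypic", config$nPermutations,
                               seed = config$seed)
      utils::write.table(pwP@index, out("pairwise_phist.tsv"), sep = "\t",
                         quote = FALSE, col.names = NA)
      paths$pairwisePhi <- out("pairwise_phist.tsv")
    }
    if (!is.null(gmS) && nlevels(gmS@population) >= 2) {
      pwF <- pairwiseStructure(gmS, "genotypic", config$nPermutations,
                                seed = config$seed)
      utils::write.table(pwF@index, out("pairwise_fst.tsv"), sep = "\t",
                         quote = FALSE, col.names = NA)
      paths$pairwiseFst <- out("pairwise_fst.tsv")
    }
  })

  ## ---- PCoA on individual genetic distances ----
  stage("pcoa", {
    if (!is.null(gmS)) {
      pc <- pcoaAnalysis(genotypeDistance(gmS), nAxes = 2L)
      co <- data.frame(id = rownames(pc$coordinates),
                       population = as.character(gmS@population),
                       pc$coordinates)
      utils::write.csv(co, out("pcoa.csv"), row.names = FALSE)
      paths$pcoa <- out("pcoa.csv")
    }
  })

  ## ---- per-pair ABC-IM ----
  imEst <- list()
  stage("abc_im", {
    if (!is.null(gmS) && nlevels(gmS@population) >= 2) {
      pops <- levels(gmS@population)
      for (i in seq_len(length(pops) - 1)) for (j in seq(i + 1, length(pops))) {
        nInd <- c(sum(gmS@population == pops[i]), sum(gmS@population == pops[j]))
        cfg <- sampleConfig(nSeq = c(0L, 0L), nInd = nInd, L = config$L,
                            muSeq = config$muSeq,
                            nMicrosatLoci = ncol(gmS@alleleA),
                            muMicrosat = config$muMicrosat,
                            generationTime = config$generationTime)
        obs <- summarizeDataset(pairDataset(alignment, populationOf, gmS,
                                            pops[i], pops[j], cfg))
        names(obs) <- summaryNames(cfg)
        post <- abcInfer(obs, cfg, config$abc$priors,
                         nSims = config$abc$nSims,
                         toleranceQuantile = config$abc$tolerance,
                         seed = config$seed + 1000L * i + j)
        key <- pairKey(pops[i], pops[j])
        imEst[[key]] <- list(pair = key,
                              point = as.list(post@pointEstimates),
                              hpd90 = list(lower = as.list(post@hpdLower),
                                           upper = as.list(post@hpdUpper)))
      }
      jsonlite::write_json(imEst, out("im_estimates.json"), auto_unbox = TRUE,
                           digits = NA)
      paths$imEstimates <- out("im_estimates.json")
    }
  })

  ## ---- equilibrium vs nonequilibrium comparison ----
  stage("comparison", {
    if (!is.null(pwF) && length(imEst) >= 3) {
      m <- pwF@index
      pops <- rownames(m)
      fst <- c()
      for (i in seq_len(length(pops) - 1)) for (j in seq(i + 1, length(pops)))
        fst[pairKey(pops[i], pops[j])] <- m[i, j]
      ok <- fst > 0 & fst <= 1
      dirM <- function(x, nSlot, mSlot) {
        if (!is.null(x$point$M)) x$point$M
        else 2 * x$point[[nSlot]] * x$point[[mSlot]]
      }
      imdf <- data.frame(
        pair = names(imEst),
        Ma = vapply(imEst, dirM, numeric(1), nSlot = "Nb", mSlot = "mAB"),
        Mb = vapply(imEst, dirM, numeric(1), nSlot = "Na", mSlot = "mBA"),
        stringsAsFactors = FALSE)
      cmp <- compareConnectivity(fst[ok], imdf[imdf$pair %in% names(fst)[ok], ])
      utils::write.csv(cmp@pairs, out("comparison.csv"), row.names = FALSE)
      grDevices::png(out("comparison.png"), width = 700, height = 700)
      plotConnectivity(cmp, main = sprintf("r = %.3f (p = %.3g)", cmp@r, cmp@p))
      grDevices::dev.off()
      paths$comparison <- out("comparison.csv")
    }
  })

  ## ---- run log ----
  log <- list(seed = config$seed,
              package = as.character(utils::packageVersion("kelpconn")),
              r_version = R.version.string,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              excluded_populations = setdiff(allPops, keepPops),
              failures = failures,
              artifacts = unlist(paths))
  jsonlite::write_json(log, out("run_log.json"), auto_unbox = TRUE)
  paths$log <- out("run_log.json")
  if (length(failures))
    stop("pipeline stage failure(s): ", paste(failures, collapse = " | "))
  invisible(paths)
}
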