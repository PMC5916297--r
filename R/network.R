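## Minimum spanning network among haplotypes.
##
## Kruskal's algorithm with deterministic tie-breaking (edges sorted by
## weight, then by lexicographic label pair), plus "alternative" links:
## non-tree edges whose weight equals the largest weight on the tree path
## between their endpoints, i.e. edges that could replace a tree edge at
## no cost.

#' Minimum spanning network among observed haplotypes
#'
#' @param freqTable a \code{HaplotypeFreqTable}; only haplotypes with a
#'   positive total count become nodes.
#' @param distances symmetric substitution-count matrix covering all
#'   observed haplotypes (defaults to Hamming distances of the attached
#'   sequences).
#' @return list with \code{nodes} (label, count, per-population counts),
#'   \code{edges} and \code{alternativeEdges} (data.frames from, to,
#'   steps). Edges form a minimum spanning tree per connected component.
#' @export
minimumSpanningNetwork <- function(freqTable, distances = NULL) {
  cts <- hapCounts(freqTable)
  keep <- colSums(cts) > 0
  labs <- colnames(cts)[keep]
  if (is.null(distances)) {
    seqs <- hapSequences(freqTable)
    if (!length(seqs)) stop("need haplotype sequences or a distance matrix")
    distances <- pairwiseHamming(seqs[labs])
  }
  if (!all(labs %in% rownames(distances)))
    stop("distances must cover all observed haplotypes")
  D <- as.matrix(distances)[labs, labs, drop = FALSE]
  n <- length(labs)
  nodes <- data.frame(label = labs, count = colSums(cts[, labs, drop = FALSE]),
                      stringsAsFactors = FALSE)
  nodes <- cbind(nodes, t(cts[, labs, drop = FALSE]))
  rownames(nodes) <- NULL
  empty <- data.frame(from = character(0), to = character(0),
                      steps = integer(0), stringsAsFactors = FALSE)
  if (n < 2)
    return(list(nodes = nodes, edges = empty, alternativeEdges = empty))

  ## candidate edges sorted by (weight, label pair)
  idx <- which(upper.tri(D), arr.ind = TRUE)
  cand <- data.frame(from = labs[idx[, 1]], to = labs[idx[, 2]],
                     steps = D[idx], stringsAsFactors = FALSE)
  swap <- cand$from > cand$to
  tmp <- cand$from[swap]; cand$from[swap] <- cand$to[swap]; cand$to[swap] <- tmp
  cand <- cand[order(cand$steps, cand$from, cand$to), , drop = FALSE]

  parent <- seq_len(n); names(parent) <- labs
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  in_tree <- logical(nrow(cand))
  for (e in seq_len(nrow(cand))) {
    ri <- find(match(cand$from[e], labs)); rj <- find(match(cand$to[e], labs))
    if (ri != rj) { parent[ri] <- rj; in_tree[e] <- TRUE }
  }
  edges <- cand[in_tree, , drop = FALSE]
  rownames(edges) <- NULL

  ## alternative links: non-tree edge (u,v,w) with w == max weight on the
  ## tree path u..v
  adj <- lapply(labs, function(x) list())
  names(adj) <- labs
  for (e in seq_len(nrow(edges))) {
    adj[[edges$from[e]]][[edges$to[e]]] <- edges$steps[e]
    adj[[edges$to[e]]][[edges$from[e]]] <- edges$steps[e]
  }
  maxOnPath <- function(u, v) {
    ## DFS from u to v over the tree, tracking max edge weight
    stack <- list(list(node = u, maxw = -Inf))
    seen <- stats::setNames(logical(n), labs)
    seen[u] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (cur$node == v) return(cur$maxw)
      for (nb in names(adj[[cur$node]])) {
        if (!seen[nb]) {
          seen[nb] <- TRUE
          stack[[length(stack) + 1L]] <-
            list(node = nb, maxw = max(cur$maxw, adj[[cur$node]][[nb]]))
        }
      }
    }
    Inf   # different components
  }
  alt <- cand[!in_tree, , drop = FALSE]
  if (nrow(alt)) {
    ok <- vapply(seq_len(nrow(alt)), function(e)
      alt$steps[e] <= maxOnPath(alt$from[e], alt$to[e]), logical(1))
    alt <- alt[ok, , drop = FALSE]
  }
  rownames(alt) <- NULL
  list(nodes = nodes, edges = edges, alternativeEdges = alt)
}

#' Export a minimum spanning network
#'
#' Writes the edge list as TSV (columns from, to, steps, type) and
#' optionally a DOT file for plotting.
#'
#' @param network result of \code{\link{minimumSpanningNetwork}}
#' @param tsvPath edge-list TSV output path
#' @param dotPath optional DOT output path
#' @export
exportNetwork <- function(network, tsvPath, dotPath = NULL) {
  ed <- rbind(
    if (nrow(network$edges)) cbind(network$edges, type = "tree"),
    if (nrow(network$alternativeEdges))
      cbind(network$alternativeEdges, type = "alternative"))
  if (is.null(ed)) ed <- data.frame(from = character(0), to = character(0),
                                    steps = integer(0), type = character(0))
  utils::write.table(ed, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dotPath)) {
    con <- file(dotPath, "w"); on.exit(close(con))
    writeLines("graph msn {", con)
    for (i in seq_len(nrow(network$nodes)))
      writeLines(sprintf('  %s [width=%f];', network$nodes$label[i],
                         sqrt(network$nodes$count[i])), con)
    for (i in seq_len(nrow(ed)))
      writeLines(sprintf('  %s -- %s [label="%d"%s];', ed$from[i], ed$to[i],
                         ed$steps[i],
                         if (ed$type[i] == "alternative") ", style=dashed" else ""),
                 con)
    writeLines("}", con)
  }
  invisible(tsvPath)
}
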