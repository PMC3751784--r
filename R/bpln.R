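## The BPLN baseline: per directed process pair, a one-sided Fisher's exact
## test for over-representation of one process's genes among the
## subnetwork neighbors of the other's, BH-corrected across all directed
## tests jointly, then undirected (a link is reported when either direction
## is significant).

#' Subnetwork induced by the perturbed cross-annotated interactions
#'
#' Returns the network whose edge set is \eqn{D} and whose gene set is the
#' set of endpoints of \eqn{D}.
#'
#' @param index a [CrossAnnotationIndex-class].
#' @return an [InteractionNetwork-class].
#' @export
perturbedSubnetwork <- function(index) {
  stopifnot(is(index, "CrossAnnotationIndex"))
  edges <- index@interactions[index@perturbed, , drop = FALSE]
  interactionNetwork(edges)
}

## One-sided (over-representation) Fisher p-value for the 2x2 table with
## overlap a, row total K (adjacent genes), column total n (to-process
## genes), universe N. Hypergeometric upper tail P(X >= a).
fisherUpperTail <- function(a, K, n, N) {
  phyper(a - 1, K, N - K, n, lower.tail = FALSE)
}

#' Directed BPLN link test
#'
#' Counts the genes of `toProcess` that are adjacent, in the subnetwork, to
#' at least one gene of `fromProcess`, and tests this count for
#' over-representation among the subnetwork's genes with a one-sided
#' Fisher's exact test. The universe is the set of genes present in the
#' subnetwork; a gene annotated to both processes counts toward the
#' `toProcess` margin and is adjacent only via neighbors other than itself
#' (self-loops do not exist).
#'
#' @param subnetwork an [InteractionNetwork-class] (typically
#'   [perturbedSubnetwork()]).
#' @param catalog a [ProcessCatalog-class]; both processes must be present.
#' @param fromProcess,toProcess process identifiers.
#' @return list with elements `count` and `pValue`.
#' @export
directedLinkTest <- function(subnetwork, catalog, fromProcess, toProcess) {
  stopifnot(is(subnetwork, "InteractionNetwork"),
            is(catalog, "ProcessCatalog"))
  sets <- catalog@sets
  for (p in c(fromProcess, toProcess))
    if (!p %in% names(sets))
      stop("process not in catalog: ", p, call. = FALSE)
  universe <- subnetwork@genes
  N <- length(universe)
  toGenes <- universe[universe %in% sets[[toProcess]]]
  fromGenes <- sets[[fromProcess]]
  e <- subnetwork@edges
  adjacent <- unique(c(e[e[, 2L] %in% fromGenes, 1L],
                       e[e[, 1L] %in% fromGenes, 2L]))
  a <- sum(toGenes %in% adjacent)
  list(count = a,
       pValue = fisherUpperTail(a, length(adjacent), length(toGenes), N))
}

#' Compute the BPLN over all directed process pairs
#'
#' Tests every ordered pair of distinct catalog processes on the given
#' subnetwork, skipping untestable pairs (no `toProcess` gene in the
#' universe), applies Benjamini-Hochberg correction across all tests
#' jointly, and reports an undirected link whenever either direction has a
#' q-value at or below the threshold.
#'
#' @param subnetwork an [InteractionNetwork-class], typically the perturbed
#'   subnetwork.
#' @param catalog a [ProcessCatalog-class].
#' @param qThreshold q-value cutoff, default 0.05.
#' @return a [BPLNResult-class].
#' @export
computeBPLN <- function(subnetwork, catalog, qThreshold = 0.05) {
  stopifnot(is(subnetwork, "InteractionNetwork"),
            is(catalog, "ProcessCatalog"))
  procs <- names(catalog@sets)
  universe <- subnetwork@genes
  N <- length(universe)
  sets <- lapply(catalog@sets, function(g) universe[universe %in% g])
  ## adjacency of each universe gene to each process, precomputed
  e <- subnetwork@edges
  adjTo <- lapply(catalog@sets, function(g)
    unique(c(e[e[, 2L] %in% g, 1L], e[e[, 1L] %in% g, 2L])))
  rows <- list()
  for (from in procs) {
    for (to in procs) {
      if (from == to) next
      toGenes <- sets[[to]]
      if (!length(toGenes)) next   # untestable
      adjacent <- adjTo[[from]]
      a <- sum(toGenes %in% adjacent)
      rows[[length(rows) + 1L]] <- data.frame(
        fromProcess = from, toProcess = to, count = a,
        pValue = fisherUpperTail(a, length(adjacent), length(toGenes), N),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stop("no testable ordered process pair on this subnetwork",
         call. = FALSE)
  tests <- do.call(rbind, rows)
  tests$qValue <- p.adjust(tests$pValue, method = "BH")
  sig <- tests[tests$qValue <= qThreshold, , drop = FALSE]
  und <- if (nrow(sig))
    canonicalPairs(sig$fromProcess, sig$toProcess)
  else emptyPairMatrix()
  und <- sortPairs(und[!duplicated(pairIds(und)), , drop = FALSE])
  new("BPLNResult", tests = tests, undirectedLinks = und,
      qThreshold = qThreshold)
}

#' Significance threshold producing a target number of BPLN links
#'
#' Scans the undirected link-level p-values (the smaller of the two
#' directions) and returns the smallest such p-value whose cutoff yields at
#' least `targetLinks` undirected links — i.e. a number of links as close
#' to, but not fewer than, the target.
#'
#' @param result a [BPLNResult-class].
#' @param targetLinks desired minimum number of undirected links.
#' @return the p-value threshold (a single numeric).
#' @export
bplnThresholdSweep <- function(result, targetLinks) {
  stopifnot(is(result, "BPLNResult"), targetLinks >= 1)
  t <- result@tests
  und <- canonicalPairs(t$fromProcess, t$toProcess)
  minP <- tapply(t$pValue, pairIds(und), min)
  if (targetLinks > length(minP))
    stop("target of ", targetLinks, " links unattainable: only ",
         length(minP), " testable undirected pairs", call. = FALSE)
  sort(as.numeric(minP))[targetLinks]
}

#' Write the BPLN result tables
#'
#' Writes the directed test table (`<prefix>_tests.tsv`) and the undirected
#' link table (`<prefix>_links.tsv`, mirroring the BPN link format).
#'
#' @param result a [BPLNResult-class].
#' @param prefix output path prefix.
#' @export
writeBPLN <- function(result, prefix) {
  stopifnot(is(result, "BPLNResult"))
  t <- result@tests
  names(t) <- c("from_process", "to_process", "count", "p_value", "q_value")
  write.table(t, paste0(prefix, "_tests.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  und <- data.frame(process_a = result@undirectedLinks[, 1L],
                    process_b = result@undirectedLinks[, 2L])
  write.table(und, paste0(prefix, "_links.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}
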