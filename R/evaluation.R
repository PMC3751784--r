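## Redundancy within a BPN and consistency across replicate BPNs.

#' Jaccard index of two sets
#'
#' \eqn{|A \cap B| / |A \cup B|}; two empty sets have index 0 (avoiding a
#' spurious perfect overlap between links that explain nothing).
#'
#' @param a,b vectors treated as sets.
#' @return a number in \[0, 1\].
#' @export
jaccardIndex <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

## Explained-interaction id sets of each BPN link, optionally restricted by
## perturbation status (NA = all).
linkExplainedSets <- function(bpn, index, perturbed = NA) {
  df <- bpn@links
  ids <- pairIds(index@interactions)
  lapply(seq_len(nrow(df)), function(k) {
    ix <- index@crossSets[[resolveLink(index,
                                       c(df$processA[k], df$processB[k]))]]
    if (!is.na(perturbed))
      ix <- ix[index@perturbed[ix] == perturbed]
    ids[ix]
  })
}

#' Redundancy of the links within a BPN
#'
#' For every pair of BPN links, the Jaccard index of their explained
#' interactions (restricted to perturbed or unperturbed interactions);
#' each link's maximum JI against all other links; the histogram of those
#' maxima in bins of width 0.2 (right-open except the last, \[0.8, 1\]); and
#' the links-per-interaction distribution: for each k, the fraction of
#' explained interactions (by the full cross sets) explained by exactly k
#' links.
#'
#' Links whose restricted comparison sets are all empty have an undefined
#' maximum JI; they are excluded from the histogram and counted in
#' `nLinksNoComparison`.
#'
#' @param bpn a [BPN-class].
#' @param index the [CrossAnnotationIndex-class].
#' @param perturbedOnly TRUE to compare perturbed explained interactions,
#'   FALSE for unperturbed.
#' @return list with elements `maxJI` (named per link), `histogram`
#'   (fractions over the five bins), `linksPerInteraction` (named fractions
#'   over k), `nLinksNoComparison`.
#' @export
linkRedundancy <- function(bpn, index, perturbedOnly = TRUE) {
  stopifnot(is(bpn, "BPN"), is(index, "CrossAnnotationIndex"))
  df <- bpn@links
  n <- nrow(df)
  linkNames <- pairIds(canonicalPairs(df$processA, df$processB))
  bins <- c("[0,0.2)", "[0.2,0.4)", "[0.4,0.6)", "[0.6,0.8)", "[0.8,1]")
  emptyHist <- setNames(rep(NA_real_, 5L), bins)
  ## links-per-interaction over the union of full cross sets
  allIx <- unlist(lapply(seq_len(n), function(k)
    index@crossSets[[resolveLink(index,
                                 c(df$processA[k], df$processB[k]))]]),
    use.names = FALSE)
  kTab <- if (length(allIx)) table(table(allIx)) else table(integer(0))
  kFrac <- if (length(allIx)) as.numeric(kTab) / sum(kTab) else numeric(0)
  names(kFrac) <- names(kTab)
  if (n < 2L) {
    return(list(maxJI = setNames(rep(NA_real_, n), linkNames),
                histogram = emptyHist,
                linksPerInteraction = kFrac,
                nLinksNoComparison = 0L))
  }
  sets <- linkExplainedSets(bpn, index, perturbed = perturbedOnly)
  maxJI <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ## a link with an empty set still compares as 0 against non-empty sets;
    ## only all-empty comparisons are undefined
    defined <- lengths(sets[-i]) > 0L | length(sets[[i]]) > 0L
    if (!any(defined)) next
    ji <- vapply(which(defined), function(j0) {
      j <- seq_len(n)[-i][j0]
      jaccardIndex(sets[[i]], sets[[j]])
    }, numeric(1))
    maxJI[i] <- max(ji)
  }
  names(maxJI) <- linkNames
  ok <- !is.na(maxJI)
  hist <- if (any(ok)) {
    cuts <- findInterval(maxJI[ok], c(0, 0.2, 0.4, 0.6, 0.8),
                         rightmost.closed = FALSE)
    setNames(tabulate(cuts, nbins = 5L) / sum(ok), bins)
  } else emptyHist
  list(maxJI = maxJI, histogram = hist, linksPerInteraction = kFrac,
       nLinksNoComparison = sum(!ok))
}

#' Overlap between two BPNs
#'
#' Three Jaccard indices: over the two link sets, over their explained
#' perturbed interactions, and over their explained unperturbed
#' interactions.
#'
#' @param bpnA,bpnB [BPN-class] objects on the same index.
#' @param index the shared [CrossAnnotationIndex-class].
#' @return named numeric vector `c(linkJI, perturbedJI, unperturbedJI)`.
#' @export
bpnOverlap <- function(bpnA, bpnB, index) {
  stopifnot(is(bpnA, "BPN"), is(bpnB, "BPN"))
  idsA <- pairIds(canonicalPairs(bpnA@links$processA, bpnA@links$processB))
  idsB <- pairIds(canonicalPairs(bpnB@links$processA, bpnB@links$processB))
  expl <- function(bpn, pert)
    unique(unlist(linkExplainedSets(bpn, index, perturbed = pert),
                  use.names = FALSE))
  c(linkJI = jaccardIndex(idsA, idsB),
    perturbedJI = jaccardIndex(expl(bpnA, TRUE), expl(bpnB, TRUE)),
    unperturbedJI = jaccardIndex(expl(bpnA, FALSE), expl(bpnB, FALSE)))
}

#' Pairwise overlap matrix across replicate BPNs
#'
#' @param bpns list of [BPN-class] objects on the same index.
#' @param index the shared [CrossAnnotationIndex-class].
#' @return list of three symmetric matrices (`linkJI`, `perturbedJI`,
#'   `unperturbedJI`) plus their off-diagonal means under `means`.
#' @export
bpnOverlapMatrix <- function(bpns, index) {
  n <- length(bpns)
  out <- lapply(1:3, function(i) diag(1, n))
  names(out) <- c("linkJI", "perturbedJI", "unperturbedJI")
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ov <- bpnOverlap(bpns[[i]], bpns[[j]], index)
        for (k in 1:3) out[[k]][i, j] <- out[[k]][j, i] <- ov[[k]]
      }
    }
  }
  means <- vapply(out, function(m)
    if (n >= 2L) mean(m[upper.tri(m)]) else NA_real_, numeric(1))
  c(out, list(means = means))
}

#' Summary of the interactions a BPN explains
#'
#' Counts over the union of the BPN links' cross sets, plus the fraction of
#' the perturbed interactions \eqn{D} explained and the fraction of the
#' candidate links \eqn{L} used.
#'
#' @param bpn a [BPN-class].
#' @param index the [CrossAnnotationIndex-class].
#' @return named numeric vector `c(nExplained, nExplainedPerturbed,
#'   fractionPerturbedExplained, fractionLinksUsed)`.
#' @export
explainedSummary <- function(bpn, index) {
  stopifnot(is(bpn, "BPN"), is(index, "CrossAnnotationIndex"))
  df <- bpn@links
  if (!nrow(df)) {
    return(c(nExplained = 0, nExplainedPerturbed = 0,
             fractionPerturbedExplained = 0, fractionLinksUsed = 0))
  }
  ix <- unique(unlist(lapply(seq_len(nrow(df)), function(k)
    index@crossSets[[resolveLink(index,
                                 c(df$processA[k], df$processB[k]))]]),
    use.names = FALSE))
  nD <- sum(index@perturbed)
  c(nExplained = length(ix),
    nExplainedPerturbed = sum(index@perturbed[ix]),
    fractionPerturbedExplained =
      if (nD) sum(index@perturbed[ix]) / nD else 0,
    fractionLinksUsed = nrow(df) / nPossibleLinks(index))
}

#' Write redundancy tables
#'
#' Writes `<prefix>_maxji.tsv` (per-link maxima for perturbed and
#' unperturbed comparisons), `<prefix>_hist.tsv` (the two max-JI
#' histograms) and `<prefix>_k.tsv` (links-per-interaction fractions).
#'
#' @param bpn a [BPN-class].
#' @param index the [CrossAnnotationIndex-class].
#' @param prefix output path prefix.
#' @export
writeRedundancy <- function(bpn, index, prefix) {
  rp <- linkRedundancy(bpn, index, perturbedOnly = TRUE)
  ru <- linkRedundancy(bpn, index, perturbedOnly = FALSE)
  df <- bpn@links
  write.table(data.frame(process_a = df$processA, process_b = df$processB,
                         max_ji_perturbed = unname(rp$maxJI),
                         max_ji_unperturbed = unname(ru$maxJI)),
              paste0(prefix, "_maxji.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(bin = names(rp$histogram),
                         fraction_perturbed = unname(rp$histogram),
                         fraction_unperturbed = unname(ru$histogram)),
              paste0(prefix, "_hist.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(k = names(rp$linksPerInteraction),
                         fraction = unname(rp$linksPerInteraction)),
              paste0(prefix, "_k.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}
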