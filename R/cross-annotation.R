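## Building the cross-annotation index: candidate links L, per-link cross
## sets C_ij, the global cross-annotated set C and its perturbed subset D.

#' Cross-annotate an interaction network with process annotations
#'
#' For each unordered pair of distinct processes \eqn{(p_i, p_j)}, the cross
#' set \eqn{C_{ij}} contains every interaction \eqn{(u, v)} with
#' \eqn{p_i \in P_u} and \eqn{p_j \in P_v} (in either orientation), excluding
#' interactions whose two endpoints both carry both processes
#' (\eqn{\{p_i, p_j\} \not\subseteq P_u \cap P_v}). The exclusion is applied
#' per pair, not per edge: an interaction between identically-annotated genes
#' can still be cross-annotated by pairs its endpoints do not fully share.
#' An interaction is perturbed when both its endpoint genes are perturbed.
#'
#' Candidate links are the process pairs with a non-empty cross set; pairs
#' that cross-annotate nothing can never explain an interaction and are
#' excluded from the proposal space. Set `linkUniverse = "all"` to count all
#' \eqn{\binom{|P|}{2}} pairs in the likelihood's link-prior term instead
#' (see the vignette for why this is exact despite proposals being restricted
#' to cross-annotating pairs).
#'
#' @param network an [InteractionNetwork-class].
#' @param catalog a [ProcessCatalog-class].
#' @param profile a [PerturbationProfile-class]; use an empty profile to
#'   build an index with no perturbed interactions.
#' @param linkUniverse `"cross"` (default) or `"all"`.
#' @return a [CrossAnnotationIndex-class].
#' @examples
#' fx <- figure10Fixture()
#' idx <- crossAnnotate(fx$network, fx$catalog, fx$profile)
#' crossSet(idx, c("p1", "p3"))
#' @export
crossAnnotate <- function(network, catalog, profile,
                          linkUniverse = c("cross", "all")) {
  stopifnot(is(network, "InteractionNetwork"),
            is(catalog, "ProcessCatalog"),
            is(profile, "PerturbationProfile"))
  linkUniverse <- match.arg(linkUniverse)
  ann <- geneAnnotations(catalog)
  e <- network@edges
  iu <- match(e[, 1L], names(ann))
  iv <- match(e[, 2L], names(ann))
  recs <- vector("list", nrow(e))
  for (k in seq_len(nrow(e))) {
    if (is.na(iu[k]) || is.na(iv[k])) next
    A <- ann[[iu[k]]]; B <- ann[[iv[k]]]
    pi <- rep(A, times = length(B))
    pj <- rep(B, each = length(A))
    keep <- pi != pj
    if (!any(keep)) next
    pi <- pi[keep]; pj <- pj[keep]
    shared <- A[A %in% B]
    if (length(shared) >= 2L) {
      drop <- pi %in% shared & pj %in% shared
      pi <- pi[!drop]; pj <- pj[!drop]
      if (!length(pi)) next
    }
    recs[[k]] <- unique(pairIds(canonicalPairs(pi, pj)))
  }
  edgeIdx <- rep(seq_len(nrow(e)), lengths(recs))
  ids <- unlist(recs, use.names = FALSE)
  if (is.null(ids)) ids <- character(0)
  crossByLink <- split(edgeIdx, ids)       # sorted by link id
  covered <- sort(unique(edgeIdx))
  interactions <- e[covered, , drop = FALSE]
  crossSets <- lapply(crossByLink, function(ix) match(ix, covered))
  pg <- perturbedGenes(profile)
  perturbed <- interactions[, 1L] %in% pg & interactions[, 2L] %in% pg
  new("CrossAnnotationIndex",
      links = idsToPairs(names(crossByLink)),
      crossSets = unname(crossSets),
      interactions = interactions,
      perturbed = as.logical(perturbed),
      nProcesses = length(catalog),
      linkUniverse = linkUniverse)
}

#' Per-link perturbed cross sets
#'
#' \eqn{D_{ij} = C_{ij} \cap D}: the perturbed interactions cross-annotated
#' by a given link.
#'
#' @param index a [CrossAnnotationIndex-class].
#' @param link a link (row index, id, or two process identifiers).
#' @return two-column character matrix of interactions.
#' @export
perturbedCrossSet <- function(index, link) {
  i <- resolveLink(index, link)
  ix <- index@crossSets[[i]]
  index@interactions[ix[index@perturbed[ix]], , drop = FALSE]
}

#' Input statistics for a cross-annotated instance
#'
#' The four headline counts summarizing an instance: number of processes,
#' number of cross-annotating process pairs, number of cross-annotated
#' interactions \eqn{|C|}, and number of perturbed cross-annotated
#' interactions \eqn{|D|}.
#'
#' @param index a [CrossAnnotationIndex-class].
#' @param catalog the [ProcessCatalog-class] the index was built from.
#' @return named integer vector with elements `nProcesses`,
#'   `nCrossAnnotatingPairs`, `nCrossAnnotatedInteractions`,
#'   `nPerturbedInteractions`.
#' @export
inputStatistics <- function(index, catalog) {
  stopifnot(is(index, "CrossAnnotationIndex"), is(catalog, "ProcessCatalog"))
  c(nProcesses = length(catalog),
    nCrossAnnotatingPairs = nrow(index@links),
    nCrossAnnotatedInteractions = nrow(index@interactions),
    nPerturbedInteractions = sum(index@perturbed))
}

#' Export the per-link index as TSV
#'
#' Writes one row per candidate link: the two processes, the size of its
#' cross set and the size of its perturbed cross set.
#'
#' @param index a [CrossAnnotationIndex-class].
#' @param path output path.
#' @export
writeIndexTable <- function(index, path) {
  stopifnot(is(index, "CrossAnnotationIndex"))
  nPert <- vapply(index@crossSets,
                  function(ix) sum(index@perturbed[ix]), integer(1))
  df <- data.frame(process_a = index@links[, 1L],
                   process_b = index@links[, 2L],
                   n_cross_annotated = lengths(index@crossSets),
                   n_perturbed = nPert)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
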