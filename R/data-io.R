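## Input readers, writers and the screening rules applied before inference.
## Identifier handling is exact-string and case-sensitive; cross-namespace
## identifier mapping is the user's responsibility upstream.

#' Construct a ProcessCatalog from a named list of gene sets
#'
#' @param sets named list of character vectors (process -> genes). Gene
#'   entries are deduplicated per process.
#' @return a [ProcessCatalog-class].
#' @export
processCatalog <- function(sets = list()) {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (length(sets)) {
    checkNoTabs(names(sets), "process")
    checkNoTabs(unlist(sets, use.names = FALSE), "gene")
  }
  new("ProcessCatalog", sets = sets)
}

#' Construct an InteractionNetwork
#'
#' Self-loops are dropped and duplicate pairs (in either orientation)
#' collapsed.
#'
#' @param edges two-column character matrix or data.frame of gene pairs.
#' @param genes optional gene universe; defaults to the edge endpoints.
#'   Genes with no interactions may be listed here.
#' @return an [InteractionNetwork-class].
#' @export
interactionNetwork <- function(edges, genes = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- emptyPairMatrix()
  if (ncol(edges) != 2L) stop("edges must have two columns", call. = FALSE)
  mode(edges) <- "character"
  keep <- edges[, 1L] != edges[, 2L]
  edges <- canonicalPairs(edges[keep, 1L], edges[keep, 2L])
  edges <- sortPairs(edges[!duplicated(pairIds(edges)), , drop = FALSE])
  genes <- sort(unique(c(as.character(genes %||% character(0)), c(edges))))
  checkNoTabs(genes, "gene")
  new("InteractionNetwork", genes = genes, edges = edges)
}

#' Flag perturbed genes from a p-value table
#'
#' A gene is perturbed when its differential-expression p-value is at or
#' below the threshold (boundary inclusive). Genes absent from the table are
#' treated as unperturbed downstream: perturbation requires positive
#' evidence.
#'
#' @param pvalues named numeric vector, or a two-column data.frame
#'   (gene, p-value).
#' @param threshold p-value cutoff, default 0.05.
#' @return a [PerturbationProfile-class].
#' @export
flagPerturbed <- function(pvalues, threshold = 0.05) {
  if (is.data.frame(pvalues)) {
    if (ncol(pvalues) < 2L)
      stop("p-value table must have two columns (gene, p-value)",
           call. = FALSE)
    pvalues <- setNames(as.numeric(pvalues[[2L]]),
                        as.character(pvalues[[1L]]))
  }
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  new("PerturbationProfile", pvalues = pvalues, threshold = threshold)
}

#' Screen processes by size and optional significance
#'
#' Retains processes whose gene count lies in `[minGenes, maxGenes]` (the
#' defaults remove overly-specific and overly-general processes) and, when a
#' process-level significance table is supplied, whose q-value is at or
#' below `qThreshold`; processes with no q-value are then dropped. The
#' operation is idempotent and its output is always a subset of its input.
#'
#' @param catalog a [ProcessCatalog-class].
#' @param qvalues optional named numeric vector of per-process q-values
#'   (e.g. GSEA false discovery rates), or NULL to apply the size filter
#'   only.
#' @param qThreshold q-value cutoff, default 0.1.
#' @param minGenes,maxGenes inclusive size bounds, defaults 10 and 300.
#' @return the screened [ProcessCatalog-class].
#' @export
screenProcesses <- function(catalog, qvalues = NULL, qThreshold = 0.1,
                            minGenes = 10L, maxGenes = 300L) {
  stopifnot(is(catalog, "ProcessCatalog"))
  sets <- catalog@sets
  sz <- lengths(sets)
  keep <- sz >= minGenes & sz <= maxGenes
  if (!is.null(qvalues)) {
    q <- qvalues[match(names(sets), names(qvalues))]
    keep <- keep & !is.na(q) & q <= qThreshold
  }
  processCatalog(sets[keep])
}

## ---- GMT ----

#' Read gene sets in GMT format
#'
#' One process per line: name, description, then one or more gene
#' identifiers, tab-separated. The description field is discarded and
#' duplicate gene entries within a line are deduplicated.
#'
#' @param path path to a GMT file.
#' @return a [ProcessCatalog-class].
#' @export
readGeneSets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(processCatalog())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("malformed GMT line ", which(nf < 3L)[1L],
         ": fewer than 3 tab-separated fields", call. = FALSE)
  nms <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nms))
    stop("duplicate process name in GMT: ", nms[duplicated(nms)][1L],
         call. = FALSE)
  sets <- lapply(parts, function(f) f[-(1:2)][nzchar(f[-(1:2)])])
  names(sets) <- nms
  processCatalog(sets)
}

#' Write gene sets in GMT format
#'
#' @param catalog a [ProcessCatalog-class].
#' @param path output path.
#' @param descriptions optional character vector of descriptions (recycled);
#'   defaults to "na".
#' @export
writeGeneSets <- function(catalog, path, descriptions = "na") {
  stopifnot(is(catalog, "ProcessCatalog"))
  sets <- catalog@sets
  desc <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

## ---- interaction networks ----

#' Read an undirected interaction network from an edge list or SIF file
#'
#' Edge-list format: `geneA<TAB>geneB[<TAB>score]`. When `scoreThreshold`
#' is given, only rows whose score meets or exceeds it are retained
#' (e.g. 500 for medium-confidence STRING-style scores). SIF format:
#' `geneA<TAB>relation<TAB>geneB`; the relation is ignored. Self-loops are
#' dropped and duplicate pairs in either orientation collapsed.
#'
#' @param path input path.
#' @param scoreThreshold numeric score cutoff, or NULL to keep all rows
#'   (edge-list format only).
#' @param format `"edgelist"` (default) or `"sif"`.
#' @param header skip a first header line (detected automatically when the
#'   third field of the first line is non-numeric with a threshold set).
#' @return an [InteractionNetwork-class].
#' @export
readInteractions <- function(path, scoreThreshold = NULL,
                             format = c("edgelist", "sif")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(interactionNetwork(emptyPairMatrix()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (format == "sif") {
    if (any(nf != 3L))
      stop("malformed SIF line ", which(nf != 3L)[1L],
           ": expected 3 tab-separated fields", call. = FALSE)
    a <- vapply(parts, `[[`, character(1), 1L)
    b <- vapply(parts, `[[`, character(1), 3L)
    return(interactionNetwork(cbind(a, b)))
  }
  if (any(nf < 2L))
    stop("malformed edge-list line ", which(nf < 2L)[1L],
         ": expected at least 2 tab-separated fields", call. = FALSE)
  a <- vapply(parts, `[[`, character(1), 1L)
  b <- vapply(parts, `[[`, character(1), 2L)
  if (!is.null(scoreThreshold)) {
    if (any(nf < 3L))
      stop("score threshold set but line ", which(nf < 3L)[1L],
           " has no score column", call. = FALSE)
    sc <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
    if (is.na(sc[1L]) && length(sc) > 1L && !anyNA(sc[-1L])) {
      ## header line
      a <- a[-1L]; b <- b[-1L]; sc <- sc[-1L]
    }
    if (anyNA(sc))
      stop("non-numeric score on line ", which(is.na(sc))[1L], call. = FALSE)
    keep <- sc >= scoreThreshold
    a <- a[keep]; b <- b[keep]
  }
  interactionNetwork(cbind(a, b))
}

#' Write an interaction network as a two-column edge list
#'
#' @param network an [InteractionNetwork-class].
#' @param path output path.
#' @export
writeInteractions <- function(network, path) {
  stopifnot(is(network, "InteractionNetwork"))
  write.table(network@edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## ---- p-values and process significance ----

#' Read a per-gene p-value table
#'
#' Two tab-separated columns: gene, p-value. A header line is detected by a
#' non-numeric second field and skipped.
#'
#' @param path input path.
#' @return named numeric vector of p-values.
#' @export
readPvalues <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(setNames(numeric(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop("malformed p-value line ", which(nf < 2L)[1L], call. = FALSE)
  g <- vapply(parts, `[[`, character(1), 1L)
  p <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (is.na(p[1L])) { g <- g[-1L]; p <- p[-1L] }   # header
  if (anyNA(p))
    stop("non-numeric p-value on line ", which(is.na(p))[1L], call. = FALSE)
  setNames(p, g)
}

#' Write a per-gene p-value table
#' @param profile a [PerturbationProfile-class].
#' @param path output path.
#' @export
writePvalues <- function(profile, path) {
  stopifnot(is(profile, "PerturbationProfile"))
  p <- profile@pvalues
  write.table(data.frame(gene = names(p), pvalue = unname(p)), path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a per-process significance (q-value) table
#'
#' Two tab-separated columns: process, q-value; header detected by a
#' non-numeric second field.
#'
#' @param path input path.
#' @return named numeric vector of q-values.
#' @export
readProcessSignificance <- function(path) readPvalues(path)
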