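## Generics and accessors. Slot access from user code should go through
## these; the slot layout is not part of the API.

#' @rdname ProcessCatalog-class
#' @param object,x an object of the documented class
#' @export
setGeneric("processNames", function(object) standardGeneric("processNames"))

#' @rdname ProcessCatalog-class
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' @rdname ProcessCatalog-class
#' @export
setGeneric("geneAnnotations", function(object) standardGeneric("geneAnnotations"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("genes", function(object) standardGeneric("genes"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("edges", function(object) standardGeneric("edges"))

#' @rdname PerturbationProfile-class
#' @export
setGeneric("perturbedGenes", function(object) standardGeneric("perturbedGenes"))

#' @rdname CrossAnnotationIndex-class
#' @export
setGeneric("candidateLinks", function(object) standardGeneric("candidateLinks"))

#' @rdname CrossAnnotationIndex-class
#' @export
setGeneric("linkIds", function(object) standardGeneric("linkIds"))

#' @rdname CrossAnnotationIndex-class
#' @export
setGeneric("interactions", function(object) standardGeneric("interactions"))

#' @rdname CrossAnnotationIndex-class
#' @export
setGeneric("perturbedMask", function(object) standardGeneric("perturbedMask"))

#' @rdname CrossAnnotationIndex-class
#' @param link a link: either a row index, a link id, or a length-2
#'   character vector of process identifiers.
#' @export
setGeneric("crossSet", function(object, link) standardGeneric("crossSet"))

#' @rdname CrossAnnotationIndex-class
#' @export
setGeneric("nPossibleLinks", function(object) standardGeneric("nPossibleLinks"))

#' @rdname BPN-class
#' @export
setGeneric("bpnLinks", function(object) standardGeneric("bpnLinks"))

#' @rdname BPN-class
#' @export
setGeneric("parameterModes", function(object) standardGeneric("parameterModes"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("plantedLinks", function(object) standardGeneric("plantedLinks"))


## ---- ProcessCatalog ----

#' @rdname ProcessCatalog-class
#' @export
setMethod("processNames", "ProcessCatalog", function(object) names(object@sets))

#' @rdname ProcessCatalog-class
#' @export
setMethod("geneSets", "ProcessCatalog", function(object) object@sets)

#' @rdname ProcessCatalog-class
#' @export
setMethod("geneAnnotations", "ProcessCatalog", function(object) {
  s <- object@sets
  if (!length(s)) return(list())
  g <- unlist(s, use.names = FALSE)
  p <- rep(names(s), lengths(s))
  split(p, g)
})

#' @rdname ProcessCatalog-class
#' @export
setMethod("length", "ProcessCatalog", function(x) length(x@sets))

setMethod("show", "ProcessCatalog", function(object) {
  n <- length(object@sets)
  cat("ProcessCatalog with", n, "processes")
  if (n) {
    sz <- lengths(object@sets)
    cat(" (", length(unique(unlist(object@sets, use.names = FALSE))),
        " distinct genes; set sizes ", min(sz), "-", max(sz), ")", sep = "")
  }
  cat("\n")
})

## ---- InteractionNetwork ----

#' @rdname InteractionNetwork-class
#' @export
setMethod("genes", "InteractionNetwork", function(object) object@genes)

#' @rdname InteractionNetwork-class
#' @export
setMethod("edges", "InteractionNetwork", function(object) object@edges)

setMethod("show", "InteractionNetwork", function(object) {
  cat("InteractionNetwork:", length(object@genes), "genes,",
      nrow(object@edges), "interactions\n")
})

## ---- PerturbationProfile ----

#' @rdname PerturbationProfile-class
#' @export
setMethod("perturbedGenes", "PerturbationProfile", function(object) {
  names(object@pvalues)[object@pvalues <= object@threshold]
})

setMethod("show", "PerturbationProfile", function(object) {
  cat("PerturbationProfile:", length(object@pvalues), "genes,",
      sum(object@pvalues <= object@threshold),
      sprintf("perturbed (p <= %g)\n", object@threshold))
})

## ---- CrossAnnotationIndex ----

#' @rdname CrossAnnotationIndex-class
#' @export
setMethod("candidateLinks", "CrossAnnotationIndex",
          function(object) object@links)

#' @rdname CrossAnnotationIndex-class
#' @export
setMethod("linkIds", "CrossAnnotationIndex",
          function(object) pairIds(object@links))

#' @rdname CrossAnnotationIndex-class
#' @export
setMethod("interactions", "CrossAnnotationIndex",
          function(object) object@interactions)

#' @rdname CrossAnnotationIndex-class
#' @export
setMethod("perturbedMask", "CrossAnnotationIndex",
          function(object) object@perturbed)

#' @rdname CrossAnnotationIndex-class
#' @export
setMethod("nPossibleLinks", "CrossAnnotationIndex", function(object) {
  if (object@linkUniverse == "all")
    choose(as.numeric(object@nProcesses), 2)
  else
    as.numeric(nrow(object@links))
})

## Resolve a link argument to a row index of index@links.
resolveLink <- function(index, link) {
  if (is.numeric(link)) {
    i <- as.integer(link)
    if (length(i) != 1L || is.na(i) || i < 1L || i > nrow(index@links))
      stop("link index out of range", call. = FALSE)
    return(i)
  }
  id <- if (length(link) == 2L)
    pairIds(canonicalPairs(link[1L], link[2L]))
  else as.character(link)
  i <- match(id, pairIds(index@links))
  if (is.na(i))
    stop("link not among the candidate links: ", id, call. = FALSE)
  i
}

#' @rdname CrossAnnotationIndex-class
#' @export
setMethod("crossSet", "CrossAnnotationIndex", function(object, link) {
  i <- resolveLink(object, link)
  object@interactions[object@crossSets[[i]], , drop = FALSE]
})

setMethod("show", "CrossAnnotationIndex", function(object) {
  cat("CrossAnnotationIndex:", nrow(object@links), "candidate links,",
      nrow(object@interactions), "cross-annotated interactions (",
      sum(object@perturbed), "perturbed );",
      "link universe:", object@linkUniverse, "\n")
})

## ---- ConfusionSets ----

#' Counts of the four confusion classes
#'
#' @param sets a [ConfusionSets-class] object.
#' @return named integer vector with elements `I11`, `I10`, `I01`, `I00`.
#' @export
confusionCounts <- function(sets) {
  stopifnot(is(sets, "ConfusionSets"))
  c(I11 = nrow(sets@I11), I10 = nrow(sets@I10),
    I01 = nrow(sets@I01), I00 = nrow(sets@I00))
}

setMethod("show", "ConfusionSets", function(object) {
  cc <- confusionCounts(object)
  cat("ConfusionSets: |I11| =", cc["I11"], "|I10| =", cc["I10"],
      "|I01| =", cc["I01"], "|I00| =", cc["I00"], "\n")
})

## ---- BPNState ----

setMethod("show", "BPNState", function(object) {
  p <- object@parameters
  cat(sprintf(
    "BPNState: %d links in X; lambda = %g, alpha = %g, beta = %g\n",
    sum(object@inLinks), p@lambda, p@alpha, p@beta))
})

## ---- ChainRecord ----

setMethod("show", "ChainRecord", function(object) {
  cat("ChainRecord:", format(object@totalRecorded, big.mark = ","),
      "recorded steps;", length(object@linkVisits), "candidate links;",
      sprintf("acceptance rate %.3f\n", object@acceptanceRate))
})

## ---- BPN ----

#' @rdname BPN-class
#' @export
setMethod("bpnLinks", "BPN", function(object) object@links)

#' @rdname BPN-class
#' @export
setMethod("parameterModes", "BPN", function(object) object@parameterModes)

setMethod("show", "BPN", function(object) {
  cat("BPN with", nrow(object@links), "links (theta =", object@theta, ")\n")
  if (nrow(object@links)) {
    print(head(object@links, 10L), row.names = FALSE)
    if (nrow(object@links) > 10L) cat("...\n")
  }
  m <- object@parameterModes
  cat(sprintf("posterior modes: lambda = %g, alpha = %g, beta = %g\n",
              m[["lambda"]], m[["alpha"]], m[["beta"]]))
})

## ---- BPLNResult ----

setMethod("show", "BPLNResult", function(object) {
  cat("BPLNResult:", nrow(object@tests), "directed tests,",
      nrow(object@undirectedLinks),
      sprintf("undirected links at q <= %g\n", object@qThreshold))
})

#' Directed BPLN test table
#' @param result a [BPLNResult-class].
#' @return data.frame of directed tests.
#' @export
bplnTests <- function(result) {
  stopifnot(is(result, "BPLNResult"))
  result@tests
}

#' Undirected BPLN links
#' @param result a [BPLNResult-class].
#' @return two-column character matrix of linked process pairs.
#' @export
bplnLinks <- function(result) {
  stopifnot(is(result, "BPLNResult"))
  result@undirectedLinks
}

## ---- SyntheticTruth ----

#' @rdname SyntheticTruth-class
#' @export
setMethod("plantedLinks", "SyntheticTruth", function(object) object@plantedLinks)

setMethod("show", "SyntheticTruth", function(object) {
  p <- object@plantedParameters
  cat("SyntheticTruth (", object@mode, " mode): ",
      nrow(object@plantedLinks), " planted links of ",
      nrow(object@index@links), " candidates; planted lambda = ", p@lambda,
      ", alpha = ", p@alpha, ", beta = ", p@beta, "\n", sep = "")
})
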