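## Central S4 classes. Interactions and links are stored as canonical
## unordered pairs: two-column character matrices whose rows satisfy
## col1 < col2, so set operations are orientation-stable.

#' ProcessCatalog: gene-set annotations of biological processes
#'
#' Holds the process universe \eqn{P} as a named list mapping each process
#' identifier to its set of annotated genes. The inverse view (gene to the
#' set of processes annotating it, \eqn{P_v}) is available through
#' [geneAnnotations()].
#'
#' @slot sets named list of character vectors; names are process identifiers,
#'   elements are deduplicated gene identifiers.
#' @seealso [readGeneSets()], [screenProcesses()]
#' @export
setClass("ProcessCatalog", representation(sets = "list"))

setValidity("ProcessCatalog", function(object) {
  s <- object@sets
  if (length(s) == 0L) return(TRUE)
  if (is.null(names(s)) || any(names(s) == "") || anyDuplicated(names(s)))
    return("process identifiers must be unique and non-empty")
  bad <- !vapply(s, function(g) is.character(g) && length(g) >= 1L &&
                   !anyDuplicated(g) && !anyNA(g), logical(1))
  if (any(bad))
    return(paste0("processes with empty or duplicated gene sets: ",
                  paste(names(s)[bad], collapse = ", ")))
  TRUE
})

#' InteractionNetwork: an undirected gene-gene interaction network
#'
#' The graph \eqn{G(V, E)}: a gene universe and a set of undirected
#' interactions without self-loops or duplicate pairs.
#'
#' @slot genes character vector of gene identifiers (the vertex set V).
#' @slot edges two-column character matrix of canonical unordered pairs
#'   (each row sorted lexicographically).
#' @seealso [readInteractions()]
#' @export
setClass("InteractionNetwork",
         representation(genes = "character", edges = "matrix"))

setValidity("InteractionNetwork", function(object) {
  e <- object@edges
  if (!is.character(e) || ncol(e) != 2L)
    return("edges must be a two-column character matrix")
  if (nrow(e)) {
    if (any(e[, 1L] == e[, 2L])) return("self-loops are not allowed")
    if (any(e[, 1L] > e[, 2L])) return("edge rows must be canonically sorted")
    if (anyDuplicated(paste(e[, 1L], e[, 2L], sep = "\t")))
      return("duplicate edges")
    if (!all(c(e) %in% object@genes))
      return("every edge endpoint must be in the gene set")
  }
  if (anyDuplicated(object@genes)) return("duplicate gene identifiers")
  TRUE
})

#' PerturbationProfile: per-gene differential-expression evidence
#'
#' Stores per-gene p-values (e.g. from a differential-expression analysis)
#' and the cutoff below which a gene is called perturbed. Genes absent from
#' the table are treated as unperturbed: perturbation requires positive
#' evidence.
#'
#' @slot pvalues named numeric vector of p-values in \[0, 1\].
#' @slot threshold p-value cutoff; genes with \eqn{p \le} threshold are
#'   perturbed (default 0.05).
#' @seealso [flagPerturbed()], [perturbedGenes()]
#' @export
setClass("PerturbationProfile",
         representation(pvalues = "numeric", threshold = "numeric"))

setValidity("PerturbationProfile", function(object) {
  p <- object@pvalues
  if (length(p) && (is.null(names(p)) || any(names(p) == "")))
    return("p-values must be named by gene")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    return("p-values must lie in [0, 1]")
  if (anyDuplicated(names(p))) return("duplicate gene identifiers")
  if (length(object@threshold) != 1L || is.na(object@threshold) ||
      object@threshold < 0 || object@threshold > 1)
    return("threshold must be a single value in [0, 1]")
  TRUE
})

#' CrossAnnotationIndex: candidate links and their cross-annotated interactions
#'
#' The derived structure the sampler operates on. A candidate link is an
#' unordered pair of distinct processes; its cross set \eqn{C_{ij}} contains
#' every interaction with one endpoint annotated by one process and the other
#' endpoint by the other process, excluding interactions whose two endpoints
#' both carry both processes. \eqn{C} is the union of all cross sets and
#' \eqn{D \subseteq C} the subset whose two endpoint genes are both perturbed.
#'
#' @slot links two-column character matrix of candidate links (canonical
#'   unordered process pairs), one row per link with a non-empty cross set.
#' @slot crossSets list, parallel to the rows of `links`, of integer indices
#'   into the rows of `interactions`.
#' @slot interactions two-column character matrix holding \eqn{C}.
#' @slot perturbed logical vector over the rows of `interactions`; TRUE marks
#'   membership in \eqn{D}.
#' @slot nProcesses number of processes in the catalog the index was built
#'   from (used when `linkUniverse = "all"`).
#' @slot linkUniverse either `"cross"` (the link universe L is the set of
#'   cross-annotating pairs; default) or `"all"` (L is all process pairs;
#'   only the prior term of the likelihood changes, see the vignette).
#' @seealso [crossAnnotate()]
#' @export
setClass("CrossAnnotationIndex",
         representation(links = "matrix", crossSets = "list",
                        interactions = "matrix", perturbed = "logical",
                        nProcesses = "integer", linkUniverse = "character"))

setValidity("CrossAnnotationIndex", function(object) {
  nC <- nrow(object@interactions)
  nL <- nrow(object@links)
  if (length(object@crossSets) != nL)
    return("crossSets must be parallel to links")
  if (length(object@perturbed) != nC)
    return("perturbed must be parallel to interactions")
  if (anyNA(object@perturbed)) return("perturbed flags must not be NA")
  if (nL) {
    if (any(object@links[, 1L] >= object@links[, 2L]))
      return("link rows must be canonical pairs of distinct processes")
    if (anyDuplicated(paste(object@links[, 1L], object@links[, 2L], "\t")))
      return("duplicate links")
    ok <- vapply(object@crossSets, function(ix)
      length(ix) >= 1L && !anyNA(ix) && all(ix >= 1L & ix <= nC) &&
        !anyDuplicated(ix), logical(1))
    if (!all(ok))
      return("every candidate link must have a valid non-empty cross set")
    covered <- sort(unique(unlist(object@crossSets, use.names = FALSE)))
    if (!identical(covered, seq_len(nC)))
      return("interactions must be exactly the union of the cross sets")
  } else if (nC) {
    return("interactions present without any candidate link")
  }
  if (!object@linkUniverse %in% c("cross", "all"))
    return("linkUniverse must be 'cross' or 'all'")
  if (object@nProcesses < 0L) return("nProcesses must be non-negative")
  TRUE
})

#' ParameterConfiguration: the noise-model parameters
#'
#' The triple \eqn{\Phi = (\lambda, \alpha, \beta)}: the link prior, the
#' false-positive rate (probability a perturbed interaction is explained by
#' no link) and the false-negative rate (probability an unperturbed
#' interaction is explained). Inference restricts the values to discrete
#' grids (see [parameterGrids()]); planted values in simulations may lie off
#' the grids.
#'
#' @slot lambda,alpha,beta single numeric values in (0, 1).
#' @export
setClass("ParameterConfiguration",
         representation(lambda = "numeric", alpha = "numeric",
                        beta = "numeric"))

setValidity("ParameterConfiguration", function(object) {
  for (nm in c("lambda", "alpha", "beta")) {
    v <- slot(object, nm)
    if (length(v) != 1L || is.na(v) || v <= 0 || v >= 1)
      return(paste0(nm, " must be a single value in (0, 1)"))
  }
  TRUE
})

#' ConfusionSets: the four-way partition of cross-annotated interactions
#'
#' Given a link set X, every interaction in \eqn{C} is classified by whether
#' it is perturbed (in \eqn{D}) and whether it is explained (in the cross set
#' of at least one link of X): \eqn{I_{11}} true positives, \eqn{I_{10}}
#' false positives (perturbed but unexplained), \eqn{I_{01}} false negatives
#' (explained but unperturbed), \eqn{I_{00}} true negatives.
#'
#' @slot I11,I10,I01,I00 two-column character matrices of canonical
#'   interaction pairs.
#' @seealso [classifyInteractions()]
#' @export
setClass("ConfusionSets",
         representation(I11 = "matrix", I10 = "matrix",
                        I01 = "matrix", I00 = "matrix"))

#' BPNState: a Markov-chain state
#'
#' A state \eqn{m(\Phi, X)}: a parameter configuration plus the current link
#' set, with the per-interaction explanation count (number of links of X
#' whose cross set contains the interaction) cached so that single-link
#' toggles cost time proportional to the toggled link's cross set.
#'
#' @slot parameters a [ParameterConfiguration-class].
#' @slot inLinks logical vector over the index's candidate links (X).
#' @slot explanationCount integer vector over the index's interactions.
#' @seealso [newBPNState()], [toggleDelta()], [applyToggle()]
#' @export
setClass("BPNState",
         representation(parameters = "ParameterConfiguration",
                        inLinks = "logical", explanationCount = "integer"))

#' ChainConfig: settings for one MCMC run
#'
#' @slot burnInSteps steps run before recording starts (default 1e7).
#' @slot sampleSteps recorded steps (default 1e8).
#' @slot rho probability a proposal is a link toggle rather than a parameter
#'   change (default 0.9).
#' @slot theta posterior link-probability threshold for reporting (default
#'   0.7).
#' @slot seed integer RNG seed.
#' @slot betaMax optional cap on the beta grid (NA for none); a remedy for
#'   the explain-nothing local optimum at large beta.
#' @slot fixedParameters NULL, or a [ParameterConfiguration-class] to pin
#'   \eqn{\Phi} (parameter moves are then disabled and every proposal is a
#'   link toggle).
#' @slot recordStates record per-link-set visit counts (requires at most 24
#'   candidate links; used for stationarity diagnostics).
#' @slot traceThin record the state log-likelihood every `traceThin` recorded
#'   steps (0 disables the trace).
#' @seealso [chainConfig()], [runChain()]
#' @export
setClass("ChainConfig",
         representation(burnInSteps = "numeric", sampleSteps = "numeric",
                        rho = "numeric", theta = "numeric", seed = "integer",
                        betaMax = "numeric", fixedParameters = "ANY",
                        recordStates = "logical", traceThin = "numeric"))

setValidity("ChainConfig", function(object) {
  if (object@burnInSteps < 0 || object@sampleSteps < 0)
    return("step counts must be non-negative")
  if (object@rho < 0 || object@rho > 1) return("rho must lie in [0, 1]")
  if (object@theta < 0 || object@theta > 1) return("theta must lie in [0, 1]")
  if (!is.na(object@betaMax) && (object@betaMax <= 0 || object@betaMax >= 1))
    return("betaMax must lie in (0, 1) or be NA")
  if (!is.null(object@fixedParameters) &&
      !is(object@fixedParameters, "ParameterConfiguration"))
    return("fixedParameters must be NULL or a ParameterConfiguration")
  TRUE
})

#' ChainRecord: streaming visit counters from one MCMC run
#'
#' @slot linkVisits numeric vector (named by link id) counting recorded steps
#'   whose state contained each candidate link.
#' @slot parameterVisits list with elements `lambda`, `alpha`, `beta`: numeric
#'   vectors named by grid value, counting recorded steps at each value.
#' @slot totalRecorded number of recorded steps.
#' @slot acceptanceRate fraction of proposals accepted (over burn-in and
#'   sampling).
#' @slot stateVisits per-link-set visit counts indexed by bitmask + 1 (empty
#'   unless requested).
#' @slot likelihoodTrace thinned log-likelihood trace (empty unless
#'   requested).
#' @slot grids the parameter grids used.
#' @slot config the [ChainConfig-class] that produced the record.
#' @seealso [runChain()], [reportBPN()]
#' @export
setClass("ChainRecord",
         representation(linkVisits = "numeric", parameterVisits = "list",
                        totalRecorded = "numeric", acceptanceRate = "numeric",
                        stateVisits = "numeric", likelihoodTrace = "numeric",
                        grids = "list", config = "ChainConfig"))

#' BPN: the reported biological process network
#'
#' Links whose posterior probability (fraction of recorded MCMC steps
#' containing the link) meets or exceeds the report threshold, together with
#' the posterior over each noise parameter.
#'
#' @slot links data.frame with columns `processA`, `processB`, `probability`,
#'   `nExplained`, `nExplainedPerturbed`, ordered by decreasing probability.
#' @slot theta the report threshold used.
#' @slot parameterPosteriors list of data.frames (`value`, `fraction`) for
#'   lambda, alpha, beta.
#' @slot parameterModes named numeric vector of posterior modes (ties broken
#'   toward the smallest grid value).
#' @seealso [reportBPN()]
#' @export
setClass("BPN",
         representation(links = "data.frame", theta = "numeric",
                        parameterPosteriors = "list",
                        parameterModes = "numeric"))

#' BPLNResult: the Fisher-exact-test baseline
#'
#' @slot tests data.frame of directed tests: `fromProcess`, `toProcess`,
#'   `count`, `pValue`, `qValue` (BH across all directed tests jointly).
#' @slot undirectedLinks two-column character matrix of process pairs
#'   significant (q at or below the threshold) in either direction.
#' @slot qThreshold the q-value cutoff used.
#' @seealso [computeBPLN()]
#' @export
setClass("BPLNResult",
         representation(tests = "data.frame", undirectedLinks = "matrix",
                        qThreshold = "numeric"))

#' SyntheticTruth: a generated instance with its planted ground truth
#'
#' @slot plantedLinks two-column character matrix: the planted link set X*.
#' @slot plantedParameters the planted \eqn{(\lambda^*, \alpha^*, \beta^*)}.
#' @slot catalog,network,profile the generated inputs.
#' @slot index the effective [CrossAnnotationIndex-class] (in interaction
#'   mode, carries the exact sampled perturbation labels; in gene mode,
#'   recomputed from the emitted p-value profile).
#' @slot seed the generator seed.
#' @slot mode `"interaction"` or `"gene"` (see [generateInstance()]).
#' @export
setClass("SyntheticTruth",
         representation(plantedLinks = "matrix",
                        plantedParameters = "ParameterConfiguration",
                        catalog = "ProcessCatalog",
                        network = "InteractionNetwork",
                        profile = "PerturbationProfile",
                        index = "CrossAnnotationIndex",
                        seed = "integer", mode = "character"))
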