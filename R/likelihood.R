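## The Bernoulli likelihood over link sets and noise parameters, with
## incremental updates for single-link toggles and single-parameter moves.
## All likelihood arithmetic is in log space; the uniform prior over
## parameter configurations is a dropped constant.

#' Discrete inference grids for the noise parameters
#'
#' The link prior lambda takes 17 values:
#' \{1e-5, 5e-5, 1e-4, 5e-4, 1e-3, 5e-3, 0.01\} together with
#' \{0.05 k : 1 <= k <= 10\}; the false-positive rate alpha and the
#' false-negative rate beta each take the 19 values \{0.05 k : 1 <= k < 20\}.
#' Grid values are computed once here and reused everywhere so equal
#' parameters compare identically.
#'
#' @param betaMax optional cap on the beta grid (values above it are
#'   removed), a remedy for the large-beta local optimum in which the chain
#'   explains nothing; NA (default) leaves the grid uncapped.
#' @return list with numeric elements `lambda`, `alpha`, `beta`.
#' @export
parameterGrids <- function(betaMax = NA) {
  lambda <- c(0.00001, 0.00005, 0.0001, 0.0005, 0.001, 0.005, 0.01,
              0.05 * (1:10))
  ab <- 0.05 * (1:19)
  beta <- ab
  if (!is.na(betaMax)) beta <- beta[beta <= betaMax + 1e-12]
  list(lambda = lambda, alpha = ab, beta = beta)
}

## Snap a value onto a grid; error when off-grid.
matchGrid <- function(value, grid, what = "value") {
  i <- which(abs(grid - value) < 1e-9)
  if (length(i) != 1L)
    stop(what, " = ", value, " is not on its grid", call. = FALSE)
  i
}

#' Construct a ParameterConfiguration
#'
#' @param lambda link prior probability.
#' @param alpha false-positive rate: prior probability that a perturbed
#'   interaction is explained by no link.
#' @param beta false-negative rate: prior probability that an unperturbed
#'   interaction is explained by some link.
#' @return a [ParameterConfiguration-class]. Values must lie in (0, 1) but
#'   need not be on the inference grids (planted simulation values may be
#'   off-grid); operations that require grid membership check it themselves.
#' @export
parameterConfiguration <- function(lambda, alpha, beta) {
  new("ParameterConfiguration", lambda = lambda, alpha = alpha, beta = beta)
}

## Resolve a link-set argument to a logical mask over index@links rows.
## Accepts: logical mask, integer indices, character ids, or a 2-column
## matrix / length-2 vector of process identifiers.
resolveLinkSet <- function(index, links) {
  nL <- nrow(index@links)
  if (is.null(links)) return(logical(nL))
  if (is.logical(links)) {
    stopifnot(length(links) == nL)
    return(links)
  }
  mask <- logical(nL)
  if (is.numeric(links)) {
    if (length(links) && (any(links < 1) || any(links > nL)))
      stop("link index out of range", call. = FALSE)
    mask[as.integer(links)] <- TRUE
    return(mask)
  }
  if (is.matrix(links)) {
    ids <- pairIds(canonicalPairs(links[, 1L], links[, 2L]))
  } else if (is.character(links) && length(links) == 2L &&
             !any(grepl("\t", links, fixed = TRUE))) {
    ids <- pairIds(canonicalPairs(links[1L], links[2L]))
  } else {
    ids <- as.character(links)
  }
  i <- match(ids, pairIds(index@links))
  if (anyNA(i))
    stop("links not among the candidate links: ",
         paste(ids[is.na(i)], collapse = ", "), call. = FALSE)
  mask[i] <- TRUE
  mask
}

## Explanation counts for a link mask: per interaction, the number of links
## in X whose cross set contains it.
explanationCounts <- function(index, mask) {
  nC <- nrow(index@interactions)
  ix <- unlist(index@crossSets[mask], use.names = FALSE)
  if (is.null(ix)) ix <- integer(0)
  tabulate(ix, nbins = nC)
}

#' Classify cross-annotated interactions against a link set
#'
#' Partitions \eqn{C} into the four confusion classes given the link set X:
#' explained means contained in the cross set of at least one link of X.
#'
#' @param index a [CrossAnnotationIndex-class].
#' @param links the link set X, as a logical mask over the candidate links,
#'   integer row indices, link ids, or a two-column process-pair matrix.
#' @return a [ConfusionSets-class].
#' @examples
#' fx <- figure10Fixture()
#' idx <- crossAnnotate(fx$network, fx$catalog, fx$profile)
#' classifyInteractions(idx, fx$referenceLinks)
#' @export
classifyInteractions <- function(index, links) {
  stopifnot(is(index, "CrossAnnotationIndex"))
  mask <- resolveLinkSet(index, links)
  explained <- explanationCounts(index, mask) > 0L
  D <- index@perturbed
  m <- index@interactions
  new("ConfusionSets",
      I11 = m[D & explained, , drop = FALSE],
      I10 = m[D & !explained, , drop = FALSE],
      I01 = m[!D & explained, , drop = FALSE],
      I00 = m[!D & !explained, , drop = FALSE])
}

## Log-likelihood from the sufficient counts.
logLikFromCounts <- function(nX, nL, n11, n10, n01, n00, lambda, alpha, beta) {
  nX * log(lambda) + (nL - nX) * log1p(-lambda) +
    n10 * log(alpha) + n00 * log1p(-alpha) +
    n01 * log(beta) + n11 * log1p(-beta)
}

#' Log-likelihood of a link set under a parameter configuration
#'
#' Computes \deqn{|X|\ln\lambda + |L \setminus X|\ln(1-\lambda) +
#' |I_{10}|\ln\alpha + |I_{00}|\ln(1-\alpha) + |I_{01}|\ln\beta +
#' |I_{11}|\ln(1-\beta),} the log of the joint probability of the
#' configuration up to the constant uniform prior over parameter
#' configurations. \eqn{|L|} is [nPossibleLinks()] of the index (the
#' cross-annotating pairs by default).
#'
#' @param params a [ParameterConfiguration-class].
#' @param links the link set X (see [classifyInteractions()] for accepted
#'   forms).
#' @param index a [CrossAnnotationIndex-class].
#' @return a single numeric log-likelihood.
#' @export
logLikelihood <- function(params, links, index) {
  stopifnot(is(params, "ParameterConfiguration"))
  mask <- resolveLinkSet(index, links)
  explained <- explanationCounts(index, mask) > 0L
  D <- index@perturbed
  logLikFromCounts(sum(mask), nPossibleLinks(index),
                   n11 = sum(D & explained), n10 = sum(D & !explained),
                   n01 = sum(!D & explained), n00 = sum(!D & !explained),
                   params@lambda, params@alpha, params@beta)
}

#' Construct a Markov-chain state
#'
#' @param index a [CrossAnnotationIndex-class].
#' @param params a [ParameterConfiguration-class].
#' @param links initial link set X (default empty).
#' @return a [BPNState-class] with the explanation counts cached.
#' @export
newBPNState <- function(index, params, links = NULL) {
  mask <- resolveLinkSet(index, links)
  new("BPNState", parameters = params, inLinks = mask,
      explanationCount = explanationCounts(index, mask))
}

## Sufficient counts of a state.
stateCounts <- function(state, index) {
  D <- index@perturbed
  explained <- state@explanationCount > 0L
  c(nX = sum(state@inLinks),
    n11 = sum(D & explained), n10 = sum(D & !explained),
    n01 = sum(!D & explained), n00 = sum(!D & !explained))
}

#' Log-likelihood of a chain state
#'
#' @param state a [BPNState-class].
#' @param index the [CrossAnnotationIndex-class] the state lives on.
#' @return a single numeric log-likelihood.
#' @export
stateLogLikelihood <- function(state, index) {
  cc <- stateCounts(state, index)
  p <- state@parameters
  logLikFromCounts(cc["nX"], nPossibleLinks(index), cc["n11"], cc["n10"],
                   cc["n01"], cc["n00"], p@lambda, p@alpha, p@beta)
}

#' Log-likelihood change from toggling one link
#'
#' Returns the log-likelihood after toggling `link` (added if absent from X,
#' removed if present) minus the log-likelihood of the current state,
#' computed in time proportional to the toggled link's cross set using only
#' the 0/1 transitions of the cached explanation counts.
#'
#' @param state a [BPNState-class].
#' @param link the link to toggle (row index, id, or two process
#'   identifiers).
#' @param index the [CrossAnnotationIndex-class].
#' @return a single numeric delta.
#' @seealso [applyToggle()]
#' @export
toggleDelta <- function(state, link, index) {
  i <- resolveLink(index, link)
  ix <- index@crossSets[[i]]
  p <- state@parameters
  adding <- !state@inLinks[i]
  cnt <- state@explanationCount[ix]
  pert <- index@perturbed[ix]
  if (adding) {
    newly <- cnt == 0L            # transitions 0 -> 1
    d11 <- sum(newly & pert); d01 <- sum(newly & !pert)
    dX <- 1
  } else {
    lost <- cnt == 1L             # transitions 1 -> 0
    d11 <- -sum(lost & pert); d01 <- -sum(lost & !pert)
    dX <- -1
  }
  ## Each interaction entering I11 leaves I10 (D is fixed), and each
  ## entering I01 leaves I00; removals reverse the signs via d11/d01/dX.
  dX * (log(p@lambda) - log1p(-p@lambda)) +
    d11 * (log1p(-p@beta) - log(p@alpha)) +
    d01 * (log(p@beta) - log1p(-p@alpha))
}

#' Apply a link toggle to a state
#'
#' @inheritParams toggleDelta
#' @return the updated [BPNState-class].
#' @export
applyToggle <- function(state, link, index) {
  i <- resolveLink(index, link)
  ix <- index@crossSets[[i]]
  delta <- if (state@inLinks[i]) -1L else 1L
  state@explanationCount[ix] <- state@explanationCount[ix] + delta
  state@inLinks[i] <- !state@inLinks[i]
  state
}

#' Log-likelihood change from moving one parameter
#'
#' Uses the cached sufficient counts of the state; no interaction sets are
#' recomputed. The new value must lie on the parameter's grid.
#'
#' @param state a [BPNState-class].
#' @param which one of `"lambda"`, `"alpha"`, `"beta"`.
#' @param newValue the proposed grid value.
#' @param index the [CrossAnnotationIndex-class].
#' @param grids the parameter grids (default [parameterGrids()]).
#' @return a single numeric delta.
#' @export
parameterDelta <- function(state, which = c("lambda", "alpha", "beta"),
                           newValue, index, grids = parameterGrids()) {
  which <- match.arg(which)
  newValue <- grids[[which]][matchGrid(newValue, grids[[which]], which)]
  cc <- stateCounts(state, index)
  p <- state@parameters
  old <- slot(p, which)
  switch(which,
    lambda = cc[["nX"]] * (log(newValue) - log(old)) +
      (nPossibleLinks(index) - cc[["nX"]]) *
        (log1p(-newValue) - log1p(-old)),
    alpha = cc[["n10"]] * (log(newValue) - log(old)) +
      cc[["n00"]] * (log1p(-newValue) - log1p(-old)),
    beta = cc[["n01"]] * (log(newValue) - log(old)) +
      cc[["n11"]] * (log1p(-newValue) - log1p(-old)))
}
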