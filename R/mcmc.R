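## Running the Metropolis-Hastings chain, recording visit frequencies and
## reporting the BPN.

#' Construct a ChainConfig
#'
#' Defaults follow the published protocol: 1e7 burn-in steps, 1e8 recorded
#' steps, link-move probability rho = 0.9 and report threshold theta = 0.7.
#' Scale the step counts down for exploratory runs.
#'
#' @param burnInSteps,sampleSteps chain lengths.
#' @param rho probability a proposal is a link toggle.
#' @param theta posterior link-probability report threshold.
#' @param seed integer RNG seed; a run is fully reproducible given the
#'   config.
#' @param betaMax optional cap on the beta grid (NA = none).
#' @param fixedParameters NULL, or a [ParameterConfiguration-class] (grid
#'   values) to pin the parameters; parameter moves are then disabled.
#' @param recordStates record per-link-set visit counts (at most 20
#'   candidate links); for stationarity diagnostics.
#' @param traceThin record the log-likelihood every `traceThin` recorded
#'   steps (0 = off).
#' @return a [ChainConfig-class].
#' @export
chainConfig <- function(burnInSteps = 1e7, sampleSteps = 1e8, rho = 0.9,
                        theta = 0.7, seed = 1L, betaMax = NA,
                        fixedParameters = NULL, recordStates = FALSE,
                        traceThin = 0) {
  new("ChainConfig", burnInSteps = as.numeric(burnInSteps),
      sampleSteps = as.numeric(sampleSteps), rho = rho, theta = theta,
      seed = as.integer(seed), betaMax = as.numeric(betaMax),
      fixedParameters = fixedParameters,
      recordStates = recordStates, traceThin = as.numeric(traceThin))
}

#' Metropolis-Hastings acceptance probability
#'
#' Both move types preserve the total neighbor count of a state, so the
#' Hastings correction cancels and the acceptance probability is
#' `min(1, exp(delta))`: any proposal with a greater likelihood is always
#' accepted, and unfavorable proposals are accepted with probability equal
#' to the likelihood ratio, which lets the chain escape local optima.
#'
#' @param delta proposed-state log-likelihood minus current-state
#'   log-likelihood.
#' @return a probability in (0, 1].
#' @export
acceptanceProbability <- function(delta) {
  pmin(1, exp(delta))
}

#' Draw one proposal from the chain's proposal distribution
#'
#' With probability rho a link drawn uniformly from the candidate links is
#' toggled (added if absent, removed if present, realizing the
#' one-more-or-one-fewer-link neighborhood with a constant neighbor count);
#' otherwise a (parameter, alternative grid value) pair is drawn uniformly
#' from all such pairs (52 under the default grids). This R-level generator
#' mirrors the proposal used inside [runChain()]'s compiled kernel and is
#' mainly useful for inspecting the proposal distribution itself.
#'
#' @param state a [BPNState-class].
#' @param index a [CrossAnnotationIndex-class].
#' @param config a [ChainConfig-class].
#' @param grids parameter grids (default derived from `config`).
#' @return a list: either `list(type = "link", link = <row index>)` or
#'   `list(type = "parameter", which = <name>, value = <grid value>)`.
#' @export
proposeMove <- function(state, index, config, grids = NULL) {
  grids <- grids %||% parameterGrids(config@betaMax)
  nL <- nrow(index@links)
  paramMoves <- is.null(config@fixedParameters)
  if (!paramMoves || runif(1) < config@rho) {
    return(list(type = "link", link = sample.int(nL, 1L)))
  }
  sizes <- lengths(grids) - 1L              # neighbors per parameter
  r <- sample.int(sum(sizes), 1L)           # uniform over all 52 neighbors
  cum <- cumsum(sizes)
  k <- min(which(r <= cum))
  which <- names(sizes)[k]
  offset <- r - c(0L, cum)[k]               # 1 .. sizes[k]
  grid <- grids[[which]]
  cur <- matchGrid(slot(state@parameters, which), grid, which)
  newIdx <- if (offset >= cur) offset + 1L else offset
  list(type = "parameter", which = which, value = grid[newIdx])
}

#' Run one Metropolis-Hastings chain
#'
#' The chain starts at \eqn{X = \emptyset} with each parameter drawn
#' uniformly at random from its grid (unless pinned by
#' `config@fixedParameters`). It runs `burnInSteps` proposals without
#' recording, then `sampleSteps` proposals, counting the current state once
#' per step (whether or not the proposal was accepted) into per-link and
#' per-parameter-value visit counters.
#'
#' @param index a [CrossAnnotationIndex-class] with at least one candidate
#'   link.
#' @param config a [ChainConfig-class].
#' @return a [ChainRecord-class].
#' @export
runChain <- function(index, config = chainConfig()) {
  stopifnot(is(index, "CrossAnnotationIndex"), is(config, "ChainConfig"))
  nL <- nrow(index@links)
  if (nL == 0L)
    stop("no candidate links: nothing to sample", call. = FALSE)
  if (config@recordStates && nL > 20L)
    stop("recordStates requires at most 20 candidate links", call. = FALSE)
  grids <- parameterGrids(config@betaMax)
  set.seed(config@seed)
  fixed <- config@fixedParameters
  if (is.null(fixed)) {
    start <- vapply(grids, function(g) sample.int(length(g), 1L), integer(1))
    paramMoves <- TRUE
  } else {
    start <- c(lambda = matchGrid(fixed@lambda, grids$lambda, "lambda"),
               alpha = matchGrid(fixed@alpha, grids$alpha, "alpha"),
               beta = matchGrid(fixed@beta, grids$beta, "beta"))
    paramMoves <- FALSE
  }
  res <- chain_kernel(index@crossSets, index@perturbed,
                      nPossibleLinks(index),
                      grids$lambda, grids$alpha, grids$beta,
                      start[["lambda"]] - 1L, start[["alpha"]] - 1L,
                      start[["beta"]] - 1L,
                      config@rho, paramMoves,
                      config@burnInSteps, config@sampleSteps,
                      config@recordStates, as.integer(config@traceThin))
  new("ChainRecord",
      linkVisits = setNames(res$linkVisits, linkIds(index)),
      parameterVisits = list(
        lambda = setNames(res$lambdaVisits, as.character(grids$lambda)),
        alpha = setNames(res$alphaVisits, as.character(grids$alpha)),
        beta = setNames(res$betaVisits, as.character(grids$beta))),
      totalRecorded = res$totalRecorded,
      acceptanceRate = res$accepted / res$totalProposals,
      stateVisits = as.numeric(res$stateVisits),
      likelihoodTrace = as.numeric(res$likelihoodTrace),
      grids = grids, config = config)
}

#' Report the BPN from a chain record
#'
#' The posterior probability of a link is the fraction of recorded steps
#' whose state contained it; the BPN consists of the links whose probability
#' meets or exceeds theta. Parameter posteriors are the per-grid-value visit
#' fractions; the reported mode breaks ties toward the smallest grid value.
#'
#' @param record a [ChainRecord-class] with at least one recorded step.
#' @param index the [CrossAnnotationIndex-class] the chain ran on.
#' @param theta report threshold (default 0.7).
#' @return a [BPN-class].
#' @export
reportBPN <- function(record, index, theta = 0.7) {
  stopifnot(is(record, "ChainRecord"), is(index, "CrossAnnotationIndex"))
  if (record@totalRecorded <= 0)
    stop("chain record contains no recorded steps", call. = FALSE)
  pr <- record@linkVisits / record@totalRecorded
  sel <- which(pr >= theta)
  sel <- sel[order(-pr[sel], names(pr)[sel])]
  links <- index@links[sel, , drop = FALSE]
  nPert <- vapply(index@crossSets[sel],
                  function(ix) sum(index@perturbed[ix]), integer(1))
  df <- data.frame(processA = links[, 1L], processB = links[, 2L],
                   probability = unname(pr[sel]),
                   nExplained = lengths(index@crossSets[sel]),
                   nExplainedPerturbed = if (length(sel)) nPert else integer(0),
                   stringsAsFactors = FALSE)
  post <- lapply(record@parameterVisits, function(v) {
    data.frame(value = as.numeric(names(v)),
               fraction = unname(v) / record@totalRecorded)
  })
  modes <- vapply(post, function(p) p$value[which.max(p$fraction)],
                  numeric(1))
  new("BPN", links = df, theta = theta, parameterPosteriors = post,
      parameterModes = modes)
}

#' Run independent replicate chains
#'
#' Runs `nRuns` chains whose seeds are `config@seed + 0:(nRuns-1)`, all
#' other settings shared, and reports each chain's BPN at the config's
#' theta.
#'
#' @param index a [CrossAnnotationIndex-class].
#' @param config a [ChainConfig-class].
#' @param nRuns number of replicates (default 5).
#' @return list of `nRuns` elements, each `list(record =, bpn =)`.
#' @export
runReplicates <- function(index, config = chainConfig(), nRuns = 5L) {
  stopifnot(nRuns >= 1L)
  lapply(seq_len(nRuns) - 1L, function(k) {
    cfg <- config
    cfg@seed <- config@seed + as.integer(k)
    rec <- runChain(index, cfg)
    list(record = rec, bpn = reportBPN(rec, index, cfg@theta))
  })
}

#' Enumerate all link-set states at fixed parameters
#'
#' Exhaustively scores every subset of the candidate links (at most 20)
#' under a pinned parameter configuration. Used to validate that chain
#' visit frequencies converge to the normalized likelihood.
#'
#' @param index a [CrossAnnotationIndex-class] with at most 20 candidate
#'   links.
#' @param params a [ParameterConfiguration-class].
#' @return data.frame with columns `mask` (bitmask over links, bit k set =
#'   link k+1 in X) and `logLik`.
#' @export
enumerateLinkStates <- function(index, params) {
  nL <- nrow(index@links)
  stopifnot(nL >= 1L, nL <= 20L)
  nC <- nrow(index@interactions)
  D <- index@perturbed
  nStates <- 2^nL
  membership <- matrix(FALSE, nC, nL)
  for (l in seq_len(nL)) membership[index@crossSets[[l]], l] <- TRUE
  masks <- 0:(nStates - 1)
  logLik <- numeric(nStates)
  Lp <- nPossibleLinks(index)
  for (m in masks) {
    bits <- which(bitwAnd(m, bitwShiftL(1L, 0:(nL - 1L))) != 0L)
    explained <- if (length(bits))
      rowSums(membership[, bits, drop = FALSE]) > 0L
    else rep(FALSE, nC)
    logLik[m + 1L] <- logLikFromCounts(
      length(bits), Lp,
      n11 = sum(D & explained), n10 = sum(D & !explained),
      n01 = sum(!D & explained), n00 = sum(!D & !explained),
      params@lambda, params@alpha, params@beta)
  }
  data.frame(mask = masks, logLik = logLik)
}

## ---- output writers ----

#' Write a BPN link table as TSV
#' @param bpn a [BPN-class].
#' @param path output path.
#' @export
writeBPN <- function(bpn, path) {
  stopifnot(is(bpn, "BPN"))
  df <- bpn@links
  names(df) <- c("process_a", "process_b", "probability", "n_explained",
                 "n_explained_perturbed")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BPN link table written by [writeBPN()]
#' @param path input path.
#' @param theta report threshold recorded in the returned object.
#' @return a [BPN-class] (parameter posteriors empty).
#' @export
readBPN <- function(path, theta = 0.7) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("process_a", "process_b", "probability", "n_explained",
            "n_explained_perturbed")
  if (!all(need %in% names(df)))
    stop("malformed BPN file: ", path, call. = FALSE)
  names(df)[match(need, names(df))] <-
    c("processA", "processB", "probability", "nExplained",
      "nExplainedPerturbed")
  new("BPN", links = df, theta = theta,
      parameterPosteriors = list(), parameterModes = numeric(0))
}

#' Write parameter posteriors as TSV
#' @param bpn a [BPN-class].
#' @param path output path.
#' @export
writeParameterPosteriors <- function(bpn, path) {
  stopifnot(is(bpn, "BPN"))
  rows <- do.call(rbind, lapply(names(bpn@parameterPosteriors), function(nm) {
    p <- bpn@parameterPosteriors[[nm]]
    data.frame(parameter = nm, grid_value = p$value,
               posterior_fraction = p$fraction)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a BPN as a graph for external viewers
#'
#' Nodes are processes; edges are the reported links carrying their
#' posterior probability. SIF uses the relation `link`; GraphML is written
#' through igraph with a `probability` edge attribute.
#'
#' @param bpn a [BPN-class].
#' @param path output path.
#' @param format `"sif"` or `"graphml"`.
#' @export
writeBPNGraph <- function(bpn, path, format = c("sif", "graphml")) {
  stopifnot(is(bpn, "BPN"))
  format <- match.arg(format)
  df <- bpn@links
  if (format == "sif") {
    writeLines(if (nrow(df))
      paste(df$processA, "link", df$processB, sep = "\t")
    else character(0), path)
  } else {
    g <- igraph::graph_from_data_frame(
      df[, c("processA", "processB")], directed = FALSE)
    igraph::E(g)$probability <- df$probability
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Write a run summary as JSON
#'
#' Echoes the chain configuration and records total steps, acceptance rate
#' and the posterior parameter modes.
#'
#' @param record a [ChainRecord-class].
#' @param bpn the [BPN-class] reported from it.
#' @param path output path.
#' @export
writeRunSummary <- function(record, bpn, path) {
  cfg <- record@config
  out <- list(
    config = list(burnInSteps = cfg@burnInSteps,
                  sampleSteps = cfg@sampleSteps, rho = cfg@rho,
                  theta = bpn@theta, seed = cfg@seed,
                  betaMax = if (is.na(cfg@betaMax)) NULL else cfg@betaMax),
    totalRecorded = record@totalRecorded,
    acceptanceRate = record@acceptanceRate,
    nLinksReported = nrow(bpn@links),
    posteriorModes = as.list(bpn@parameterModes))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
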