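## Shared helpers: the worked-example index, random small instances for
## brute-force oracles, and construction of BPN objects without a chain.

fixtureIndex <- function() {
  fx <- figure10Fixture()
  c(fx, list(index = crossAnnotate(fx$network, fx$catalog, fx$profile)))
}

## Build a BPN object directly from a link matrix (bypassing MCMC), for
## evaluation-metric tests.
makeBPN <- function(index, links, theta = 0.7, probability = 1) {
  links <- matrix(as.character(links), ncol = 2L)
  nPert <- integer(nrow(links)); nAll <- integer(nrow(links))
  for (k in seq_len(nrow(links))) {
    cs <- crossSet(index, links[k, ])
    pc <- perturbedCrossSet(index, links[k, ])
    nAll[k] <- nrow(cs); nPert[k] <- nrow(pc)
  }
  df <- data.frame(processA = links[, 1L], processB = links[, 2L],
                   probability = rep_len(probability, nrow(links)),
                   nExplained = nAll, nExplainedPerturbed = nPert,
                   stringsAsFactors = FALSE)
  new("BPN", links = df, theta = theta,
      parameterPosteriors = list(), parameterModes = numeric(0))
}

## Random tiny instance for exhaustive oracles.
randomTinyInstance <- function(seed, nGenes = 8L, nProcesses = 4L,
                               edgeP = 0.5, annP = 0.4, pertP = 0.5) {
  set.seed(seed)
  genes <- paste0("g", seq_len(nGenes))
  sets <- lapply(seq_len(nProcesses), function(i) {
    g <- genes[runif(nGenes) < annP]
    if (!length(g)) g <- sample(genes, 1L)
    g
  })
  names(sets) <- paste0("q", seq_len(nProcesses))
  pairs <- t(combn(genes, 2L))
  pairs <- pairs[runif(nrow(pairs)) < edgeP, , drop = FALSE]
  pv <- stats::setNames(ifelse(runif(nGenes) < pertP, 0.01, 0.5), genes)
  list(catalog = processCatalog(sets),
       network = interactionNetwork(pairs, genes = genes),
       profile = flagPerturbed(pv))
}

## Literal triple-loop application of the cross-annotation definition:
## for every edge and every ordered pair of distinct processes, test the
## membership and exclusion conditions directly.
bruteForceCross <- function(network, catalog, profile) {
  sets <- geneSets(catalog)
  procs <- names(sets)
  e <- edges(network)
  pg <- perturbedGenes(profile)
  out <- list()
  for (k in seq_len(nrow(e))) {
    u <- e[k, 1L]; v <- e[k, 2L]
    Pu <- procs[vapply(sets, function(s) u %in% s, logical(1))]
    Pv <- procs[vapply(sets, function(s) v %in% s, logical(1))]
    for (pi in procs) for (pj in procs) {
      if (pi == pj) next
      hit <- (pi %in% Pu && pj %in% Pv) || (pi %in% Pv && pj %in% Pu)
      if (!hit) next
      both <- pi %in% Pu && pi %in% Pv && pj %in% Pu && pj %in% Pv
      if (both) next
      id <- paste(sort(c(pi, pj)), collapse = "\t")
      eid <- paste(sort(c(u, v)), collapse = "\t")
      out[[id]] <- sort(unique(c(out[[id]], eid)))
    }
  }
  D <- character(0)
  for (k in seq_len(nrow(e))) {
    if (e[k, 1L] %in% pg && e[k, 2L] %in% pg)
      D <- c(D, paste(sort(e[k, ]), collapse = "\t"))
  }
  allC <- sort(unique(unlist(out, use.names = FALSE)))
  list(cross = out[order(names(out))], C = allC,
       D = sort(intersect(D, allC)))
}

## Explicit hypergeometric upper-tail oracle via binomial coefficients.
tailSumOracle <- function(a, K, n, N) {
  hi <- min(K, n)
  if (a > hi) return(0)
  lo <- max(a, 0L, K + n - N)
  sum(choose(K, lo:hi) * choose(N - K, n - (lo:hi))) / choose(N, n)
}

## Step-up BH reference, written independently of p.adjust.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}

## Interaction ids of a pair matrix.
rowIds <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  sort(paste(m[, 1L], m[, 2L], sep = "\t"))
}
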