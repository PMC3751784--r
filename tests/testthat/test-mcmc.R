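test_that("acceptance probability follows min(1, exp(delta))", {
  expect_identical(acceptanceProbability(0), 1)
  expect_identical(acceptanceProbability(3.7), 1)
  expect_equal(acceptanceProbability(-1), exp(-1), tolerance = 1e-12)
})

test_that("the proposal mixes link and parameter moves at rate rho", {
  fx <- fixtureIndex()
  idx <- fx$index
  st <- newBPNState(idx, parameterConfiguration(0.05, 0.2, 0.35))

  set.seed(1)
  onlyLinks <- replicate(200, proposeMove(
    st, idx, chainConfig(rho = 1))$type)
  expect_true(all(onlyLinks == "link"))
  onlyParams <- replicate(200, proposeMove(
    st, idx, chainConfig(rho = 0))$type)
  expect_true(all(onlyParams == "parameter"))

  set.seed(2)
  types <- replicate(20000, proposeMove(st, idx, chainConfig(rho = 0.9))$type)
  frac <- mean(types == "link")
  expect_lt(abs(frac - 0.9), 3 * sqrt(0.9 * 0.1 / 20000) + 1e-3)

  ## parameter proposals never return the current value and stay on-grid
  params <- Filter(function(m) m$type == "parameter",
                   lapply(1:500, function(i) {
                     set.seed(i)
                     proposeMove(st, idx, chainConfig(rho = 0))
                   }))
  g <- parameterGrids()
  for (m in params) {
    expect_true(m$value %in% g[[m$which]])
    expect_false(isTRUE(all.equal(m$value, slot(st@parameters, m$which))))
  }
})

test_that("every state is reachable: proposals cover all links and parameters", {
  fx <- fixtureIndex()
  idx <- fx$index
  st <- newBPNState(idx, parameterConfiguration(0.05, 0.2, 0.35))
  set.seed(5)
  moves <- lapply(1:3000, function(i) proposeMove(st, idx,
                                                  chainConfig(rho = 0.5)))
  linksSeen <- unique(vapply(Filter(function(m) m$type == "link", moves),
                             `[[`, integer(1), "link"))
  expect_setequal(linksSeen, seq_len(nrow(candidateLinks(idx))))
  paramMoves <- Filter(function(m) m$type == "parameter", moves)
  expect_setequal(unique(vapply(paramMoves, `[[`, character(1), "which")),
                  c("lambda", "alpha", "beta"))
  ## all 52 (parameter, other value) neighbors occur
  nb <- unique(vapply(paramMoves, function(m)
    paste(m$which, m$value), character(1)))
  expect_length(nb, (17 - 1) + (19 - 1) + (19 - 1))
})

test_that("chains are deterministic given a seed and respect step counts", {
  fx <- fixtureIndex()
  cfg <- chainConfig(burnInSteps = 1000, sampleSteps = 5000, seed = 9)
  a <- runChain(fx$index, cfg)
  b <- runChain(fx$index, cfg)
  expect_identical(a@linkVisits, b@linkVisits)
  expect_identical(a@parameterVisits, b@parameterVisits)
  expect_identical(a@acceptanceRate, b@acceptanceRate)

  expect_true(all(a@linkVisits <= a@totalRecorded))
  for (v in a@parameterVisits)
    expect_equal(sum(v), a@totalRecorded)

  zero <- runChain(fx$index, chainConfig(burnInSteps = 100,
                                         sampleSteps = 0, seed = 1))
  expect_identical(zero@totalRecorded, 0)
  expect_error(reportBPN(zero, fx$index), "no recorded steps")

  solo <- crossAnnotate(fx$network, processCatalog(list(p1 = c("v2", "v3"))),
                        fx$profile)
  expect_error(runChain(solo, cfg), "no candidate links")
})

test_that("run-length visit counters agree with direct per-step counting", {
  ## replay the chain with an R-level mirror: visits from the kernel must
  ## equal naive counting of the recorded states
  fx <- fixtureIndex()
  cfg <- chainConfig(burnInSteps = 200, sampleSteps = 3000, seed = 31,
                     recordStates = TRUE,
                     fixedParameters = parameterConfiguration(0.1, 0.2, 0.35))
  rec <- runChain(fx$index, cfg)
  ## per-link visits are the bitmask-weighted sums of state visits
  nL <- nrow(candidateLinks(fx$index))
  for (l in seq_len(nL)) {
    masks <- which(bitwAnd(seq_len(2^nL) - 1L, bitwShiftL(1L, l - 1L)) != 0L)
    expect_equal(unname(rec@linkVisits[l]), sum(rec@stateVisits[masks]))
  }
  expect_equal(sum(rec@stateVisits), rec@totalRecorded)
})

test_that("reporting applies the meets-or-exceeds threshold and tie rules", {
  fx <- fixtureIndex()
  ids <- linkIds(fx$index)
  grids <- parameterGrids()
  visits <- setNames(c(8000, 6999, 7000, 100), ids)
  pv <- lapply(grids, function(g) {
    v <- setNames(rep(0, length(g)), as.character(g))
    v[1L] <- 5000; v[2L] <- 5000   # tie -> smallest value wins
    v
  })
  rec <- new("ChainRecord", linkVisits = visits, parameterVisits = pv,
             totalRecorded = 10000, acceptanceRate = 0.5,
             stateVisits = numeric(0), likelihoodTrace = numeric(0),
             grids = grids, config = chainConfig())
  bpn <- reportBPN(rec, fx$index, theta = 0.7)
  expect_identical(nrow(bpnLinks(bpn)), 2L)           # 0.8 and 0.70 kept
  expect_equal(sort(bpnLinks(bpn)$probability), c(0.7, 0.8))
  expect_equal(unname(parameterModes(bpn)),
               c(grids$lambda[1L], grids$alpha[1L], grids$beta[1L]))
  ## all links below theta is a legitimate empty BPN
  none <- reportBPN(rec, fx$index, theta = 0.9)
  expect_identical(nrow(bpnLinks(none)), 0L)
})

test_that("replicates differ only by derived seeds and are reproducible", {
  fx <- fixtureIndex()
  cfg <- chainConfig(burnInSteps = 500, sampleSteps = 2000, seed = 17)
  runs <- runReplicates(fx$index, cfg, nRuns = 3L)
  expect_length(runs, 3L)
  single <- runChain(fx$index, cfg)
  expect_identical(runs[[1L]]$record@linkVisits, single@linkVisits)
  cfg2 <- chainConfig(burnInSteps = 500, sampleSteps = 2000, seed = 18)
  expect_identical(runs[[2L]]$record@linkVisits,
                   runChain(fx$index, cfg2)@linkVisits)
  again <- runReplicates(fx$index, cfg, nRuns = 3L)
  for (k in 1:3)
    expect_identical(runs[[k]]$record@linkVisits,
                     again[[k]]$record@linkVisits)
})

test_that("visit frequencies track the enumerated posterior on a small instance", {
  fx <- fixtureIndex()
  phi <- parameterConfiguration(0.05, 0.2, 0.35)
  cfg <- chainConfig(burnInSteps = 1e4, sampleSteps = 2e5, seed = 3,
                     fixedParameters = phi, recordStates = TRUE)
  rec <- runChain(fx$index, cfg)
  en <- enumerateLinkStates(fx$index, phi)
  pRef <- exp(en$logLik - max(en$logLik)); pRef <- pRef / sum(pRef)
  pEmp <- rec@stateVisits / rec@totalRecorded
  expect_lt(0.5 * sum(abs(pRef - pEmp)), 0.03)
})
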