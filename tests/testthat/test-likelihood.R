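test_that("classification reproduces the worked example's confusion sets", {
  fx <- fixtureIndex()
  cs <- classifyInteractions(fx$index, fx$referenceLinks)
  expect_identical(rowIds(cs@I11), c("v1\tv3", "v2\tv3"))
  expect_identical(rowIds(cs@I10), "v1\tv2")
  expect_identical(rowIds(cs@I01), "v3\tv5")
  expect_identical(rowIds(cs@I00), "v5\tv6")

  none <- classifyInteractions(fx$index, NULL)
  expect_identical(unname(confusionCounts(none)), c(0L, 3L, 0L, 2L))
  all <- classifyInteractions(fx$index, seq_len(4L))
  expect_identical(confusionCounts(all)[["I10"]], 0L)
  expect_identical(confusionCounts(all)[["I00"]], 0L)
  expect_error(classifyInteractions(fx$index, c("p1", "p9")), "candidate")
})

test_that("the confusion classes always partition C", {
  for (seed in 1:5) {
    inst <- randomTinyInstance(seed)
    idx <- crossAnnotate(inst$network, inst$catalog, inst$profile)
    nL <- nrow(candidateLinks(idx))
    if (nL == 0L) next
    set.seed(seed + 100)
    mask <- runif(nL) < 0.5
    cc <- confusionCounts(classifyInteractions(idx, mask))
    expect_identical(cc[["I11"]] + cc[["I10"]],
                     sum(perturbedMask(idx)))
    expect_identical(sum(cc), nrow(interactions(idx)))
  }
})

test_that("log-likelihood matches direct arithmetic on the fixture", {
  fx <- fixtureIndex()
  idx <- fx$index
  ## all Bernoulli factors 1/2: (|L| + |C|) ln(1/2)
  expect_equal(logLikelihood(parameterConfiguration(0.5, 0.5, 0.5),
                             fx$referenceLinks, idx),
               9 * log(0.5), tolerance = 1e-12)
  p <- parameterConfiguration(0.05, 0.2, 0.35)
  expect_equal(logLikelihood(p, fx$referenceLinks, idx),
               2 * log(0.05) + 2 * log(0.95) + log(0.2) + log(0.8) +
                 log(0.35) + 2 * log(0.65), tolerance = 1e-12)
  expect_equal(logLikelihood(p, NULL, idx),
               4 * log(0.95) + 3 * log(0.2) + 2 * log(0.8),
               tolerance = 1e-12)
})

test_that("adding links never shrinks the explained set", {
  inst <- randomTinyInstance(3)
  idx <- crossAnnotate(inst$network, inst$catalog, inst$profile)
  nL <- nrow(candidateLinks(idx))
  mask <- logical(nL)
  prev <- confusionCounts(classifyInteractions(idx, mask))
  for (l in seq_len(nL)) {
    mask[l] <- TRUE
    cur <- confusionCounts(classifyInteractions(idx, mask))
    expect_gte(cur[["I11"]], prev[["I11"]])
    expect_gte(cur[["I01"]], prev[["I01"]])
    prev <- cur
  }
})

test_that("toggle deltas are involutive and match full recomputation", {
  fx <- fixtureIndex()
  idx <- fx$index
  p <- parameterConfiguration(0.05, 0.2, 0.35)
  st <- newBPNState(idx, p, fx$referenceLinks)
  d1 <- toggleDelta(st, 1L, idx)
  st2 <- applyToggle(st, 1L, idx)
  d2 <- toggleDelta(st2, 1L, idx)
  expect_equal(d1 + d2, 0, tolerance = 1e-12)

  full <- function(state) logLikelihood(state@parameters,
                                        state@inLinks, idx)
  expect_equal(d1, full(st2) - full(st), tolerance = 1e-12)
})

test_that("a redundant link's toggle delta is the bare prior odds", {
  ## two processes with identical cross sets: second link explains nothing new
  catalog <- processCatalog(list(a = "x", b = "y", c = "x"))
  network <- interactionNetwork(rbind(c("x", "y")))
  profile <- flagPerturbed(c(x = 0.01, y = 0.01))
  idx <- crossAnnotate(network, catalog, profile)
  expect_identical(nrow(candidateLinks(idx)), 2L)  # (a,b) and (b,c)
  p <- parameterConfiguration(0.2, 0.3, 0.4)
  st <- newBPNState(idx, p, 1L)
  expect_equal(toggleDelta(st, 2L, idx), log(0.2) - log(0.8),
               tolerance = 1e-12)
})

test_that("parameter deltas match the closed form and full recomputation", {
  fx <- fixtureIndex()
  idx <- fx$index
  p <- parameterConfiguration(0.05, 0.2, 0.35)
  st <- newBPNState(idx, p, fx$referenceLinks)
  expect_equal(parameterDelta(st, "lambda", 0.05, idx), 0, tolerance = 1e-12)
  ## |X| = 2, |L| = 4
  expect_equal(parameterDelta(st, "lambda", 0.1, idx),
               2 * (log(0.1) - log(0.05)) + 2 * (log(0.9) - log(0.95)),
               tolerance = 1e-12)
  expect_error(parameterDelta(st, "alpha", 0.33, idx), "grid")

  for (seed in 1:5) {
    set.seed(seed)
    g <- parameterGrids()
    which <- sample(c("lambda", "alpha", "beta"), 1L)
    newVal <- sample(g[[which]], 1L)
    pNew <- p
    slot(pNew, which) <- newVal
    expect_equal(parameterDelta(st, which, newVal, idx),
                 logLikelihood(pNew, fx$referenceLinks, idx) -
                   logLikelihood(p, fx$referenceLinks, idx),
                 tolerance = 1e-9)
  }
})

test_that("the inference grids have the documented sizes and bounds", {
  g <- parameterGrids()
  expect_length(g$lambda, 17L)
  expect_length(g$alpha, 19L)
  expect_length(g$beta, 19L)
  expect_true(all(unlist(g) > 0 & unlist(g) < 1))
  capped <- parameterGrids(0.7)
  expect_length(capped$beta, 14L)
  expect_lte(max(capped$beta), 0.7 + 1e-9)
})
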