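test_that("the worked-example fixture reproduces every printed set", {
  fx <- figure10Fixture()
  ann <- geneAnnotations(fx$catalog)
  expect_identical(sort(ann$v3), c("p1", "p3"))
  expect_identical(sort(ann$v4), c("p1", "p3"))
  expect_identical(ann$v1, "p2")
  idx <- crossAnnotate(fx$network, fx$catalog, fx$profile)
  expect_identical(rowIds(crossSet(idx, c("p1", "p3"))),
                   c("v2\tv3", "v3\tv5"))
  expect_identical(rowIds(perturbedCrossSet(idx, c("p1", "p3"))), "v2\tv3")
  expect_false("v3\tv4" %in% rowIds(interactions(idx)))
})

test_that("generation is deterministic in the seed", {
  a <- generateInstance(nProcesses = 6L, genesPerProcess = c(5L, 8L),
                        nBackgroundGenes = 5L, edgeProbability = 0.2,
                        seed = 42L)
  b <- generateInstance(nProcesses = 6L, genesPerProcess = c(5L, 8L),
                        nBackgroundGenes = 5L, edgeProbability = 0.2,
                        seed = 42L)
  expect_identical(geneSets(a@catalog), geneSets(b@catalog))
  expect_identical(edges(a@network), edges(b@network))
  expect_identical(plantedLinks(a), plantedLinks(b))
  expect_identical(perturbedMask(truthIndex(a)), perturbedMask(truthIndex(b)))
  c <- generateInstance(nProcesses = 6L, genesPerProcess = c(5L, 8L),
                        nBackgroundGenes = 5L, edgeProbability = 0.2,
                        seed = 43L)
  expect_false(identical(edges(a@network), edges(c@network)))
})

test_that("the noiseless limit reproduces the planted explained set exactly", {
  truth <- generateInstance(nProcesses = 8L, genesPerProcess = c(5L, 10L),
                            nBackgroundGenes = 0L, edgeProbability = 0.3,
                            planted = parameterConfiguration(0.3, 1e-12,
                                                             1e-12),
                            seed = 7L)
  idx <- truthIndex(truth)
  expect_gte(nrow(plantedLinks(truth)), 1L)
  explained <- classifyInteractions(idx, plantedLinks(truth))
  expect_identical(nrow(explained@I10), 0L)  # every perturbed is explained
  expect_identical(nrow(explained@I01), 0L)  # nothing unexplained perturbed
})

test_that("generated instances satisfy the index invariants", {
  truth <- generateInstance(nProcesses = 10L, genesPerProcess = c(8L, 15L),
                            nBackgroundGenes = 10L, edgeProbability = 0.1,
                            seed = 5L)
  idx <- truthIndex(truth)
  expect_true(validObject(idx))
  expect_true(all(pairIds(plantedLinks(truth)) %in% linkIds(idx)))
  ## gene mode: the emitted profile's perturbed set covers the labels
  g <- generateInstance(nProcesses = 10L, genesPerProcess = c(8L, 15L),
                        nBackgroundGenes = 10L, edgeProbability = 0.1,
                        seed = 5L, mode = "gene")
  ip <- interactions(truthIndex(g))
  pg <- perturbedGenes(g@profile)
  expect_identical(unname(perturbedMask(truthIndex(g))),
                   unname(ip[, 1L] %in% pg & ip[, 2L] %in% pg))
})

test_that("realized noise rates concentrate around the planted rates", {
  truth <- generateInstance(nProcesses = 20L, genesPerProcess = c(15L, 25L),
                            nBackgroundGenes = 20L, edgeProbability = 0.08,
                            planted = parameterConfiguration(0.05, 0.2, 0.35),
                            seed = 9L)
  idx <- truthIndex(truth)
  expect_gte(nrow(interactions(idx)), 1000L)
  explained <- classifyInteractions(idx, plantedLinks(truth))
  nExp <- nrow(explained@I11) + nrow(explained@I01)
  nUn <- nrow(explained@I10) + nrow(explained@I00)
  alphaHat <- nrow(explained@I10) / nUn
  oneMinusBetaHat <- nrow(explained@I11) / nExp
  expect_lt(abs(alphaHat - 0.2), 4 * sqrt(0.2 * 0.8 / nUn))
  expect_lt(abs(oneMinusBetaHat - 0.65), 4 * sqrt(0.65 * 0.35 / nExp))
  ## balanced realization hits the rounded expectation exactly
  bal <- generateInstance(nProcesses = 20L, genesPerProcess = c(15L, 25L),
                          nBackgroundGenes = 20L, edgeProbability = 0.08,
                          planted = parameterConfiguration(0.05, 0.2, 0.35),
                          seed = 9L, balancedNoise = TRUE)
  cb <- classifyInteractions(truthIndex(bal), plantedLinks(bal))
  nExpB <- nrow(cb@I11) + nrow(cb@I01)
  expect_identical(nrow(cb@I11), as.integer(round(0.65 * nExpB)))
})

test_that("recovery metrics score links and parameter modes", {
  truth <- generateInstance(nProcesses = 6L, genesPerProcess = c(5L, 8L),
                            nBackgroundGenes = 0L, edgeProbability = 0.3,
                            planted = parameterConfiguration(0.3, 0.2, 0.35),
                            seed = 3L)
  exact <- makeBPN(truthIndex(truth), plantedLinks(truth))
  exact@parameterModes <- c(lambda = 0.3, alpha = 0.2, beta = 0.35)
  m <- recoveryMetrics(truth, exact)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$f1, 1)
  expect_true(all(m$modeMatches))

  none <- makeBPN(truthIndex(truth), matrix(character(0), ncol = 2))
  m0 <- recoveryMetrics(truth, none)
  expect_identical(m0$precision, 0)
  expect_identical(m0$recall, 0)

  ## off-grid planted values compare to the nearest grid point
  offGrid <- truth
  offGrid@plantedParameters <- parameterConfiguration(0.012, 0.21, 0.34)
  exact@parameterModes <- c(lambda = 0.01, alpha = 0.2, beta = 0.35)
  expect_true(all(recoveryMetrics(offGrid, exact)$modeMatches))
})

test_that("instances write to the standard formats and reload losslessly", {
  truth <- generateInstance(nProcesses = 6L, genesPerProcess = c(5L, 8L),
                            nBackgroundGenes = 5L, edgeProbability = 0.2,
                            seed = 21L)
  dir <- withr::local_tempdir()
  writeInstance(truth, dir)
  cat2 <- readGeneSets(file.path(dir, "genesets.gmt"))
  expect_identical(geneSets(cat2), geneSets(truth@catalog))
  nw2 <- readInteractions(file.path(dir, "network.tsv"))
  expect_identical(edges(nw2), edges(truth@network))
  pv2 <- readPvalues(file.path(dir, "pvalues.tsv"))
  expect_identical(sort(names(pv2)), sort(names(truth@profile@pvalues)))
  expect_identical(perturbedGenes(flagPerturbed(pv2)),
                   perturbedGenes(truth@profile))
  truthFile <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(truthFile$plantedParameters$lambda, 0.01)
  expect_identical(truthFile$seed, as.integer(truth@seed))
})
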