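test_that("the perturbed subnetwork is induced by D", {
  fx <- fixtureIndex()
  sub <- perturbedSubnetwork(fx$index)
  expect_setequal(genes(sub), c("v1", "v2", "v3"))
  expect_identical(rowIds(edges(sub)), c("v1\tv2", "v1\tv3", "v2\tv3"))

  noPert <- crossAnnotate(fx$network, fx$catalog,
                          flagPerturbed(setNames(numeric(0), character(0))))
  expect_identical(nrow(edges(perturbedSubnetwork(noPert))), 0L)

  allPert <- crossAnnotate(fx$network, fx$catalog,
                           flagPerturbed(setNames(rep(0.01, 6),
                                                  paste0("v", 1:6))))
  expect_identical(edges(perturbedSubnetwork(allPert)),
                   interactions(allPert))
})

test_that("the directed test counts neighbors and matches the tail-sum oracle", {
  ## universe of 10 genes: g1..g5 carry 'to', and g1..g4 are the genes
  ## adjacent to the single 'from' gene h1
  catalog <- processCatalog(list(
    from = c("h1", "h2"),
    to = c("g1", "g2", "g3", "g4", "g5")))
  nw <- interactionNetwork(rbind(
    cbind("h1", c("g1", "g2", "g3", "g4")),
    cbind("u1", "u2"), cbind("u2", "u3"), cbind("u3", "g5"),
    cbind("u4", "u1")))
  expect_identical(length(genes(nw)), 10L)
  res <- directedLinkTest(nw, catalog, "from", "to")
  expect_identical(res$count, 4L)
  K <- 4L  # genes adjacent to 'from' genes: g1..g4
  expect_equal(res$pValue, tailSumOracle(4L, K, 5L, 10L), tolerance = 1e-12)
  expect_equal(res$pValue, 5 / 210, tolerance = 1e-12)

  ## zero count -> p = 1
  catalog0 <- processCatalog(list(from = "u1", to = c("g1", "g2")))
  res0 <- directedLinkTest(nw, catalog0, "from", "to")
  expect_identical(res0$count, 0L)
  expect_identical(res0$pValue, 1)

  ## to-process = universe -> no enrichment possible
  catalogU <- processCatalog(list(from = "h1", to = genes(nw)))
  expect_equal(directedLinkTest(nw, catalogU, "from", "to")$pValue, 1,
               tolerance = 1e-12)

  expect_error(directedLinkTest(nw, catalog, "from", "nope"),
               "not in catalog")
})

test_that("Fisher p-values equal the tail sum for every table with universe <= 30", {
  for (N in c(2:12, 20L, 30L)) {
    for (K in 0:N) {
      for (n in 0:N) {
        los <- max(0L, K + n - N); his <- min(K, n)
        for (a in los:his) {
          expect_equal(mcmcbpn:::fisherUpperTail(a, K, n, N),
                       tailSumOracle(a, K, n, N), tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("Fisher p-values agree with fisher.test on random tables", {
  set.seed(8)
  for (i in 1:50) {
    N <- sample(5:25, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    rng <- max(0, K + n - N):min(K, n)
    a <- rng[sample.int(length(rng), 1)]
    tab <- matrix(c(a, K - a, n - a, N - K - n + a), 2L)
    expect_equal(mcmcbpn:::fisherUpperTail(a, K, n, N),
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("BPLN joins directions, corrects jointly, and obeys BH monotonicity", {
  inst <- randomTinyInstance(6, nGenes = 10L, nProcesses = 4L, pertP = 0.9)
  idx <- crossAnnotate(inst$network, inst$catalog, inst$profile)
  sub <- perturbedSubnetwork(idx)
  res <- computeBPLN(sub, inst$catalog, qThreshold = 0.5)
  t <- bplnTests(res)
  ## q-values: joint family, matching the hand step-up reference
  expect_equal(t$qValue, bhOracle(t$pValue), tolerance = 1e-12)
  expect_true(all(t$qValue >= t$pValue - 1e-15))
  o <- order(t$pValue)
  expect_true(all(diff(t$qValue[o]) >= -1e-15))
  ## undirected links: exactly the pairs significant in either direction
  sig <- t[t$qValue <= 0.5, ]
  ref <- unique(vapply(seq_len(nrow(sig)), function(i)
    paste(sort(c(sig$fromProcess[i], sig$toProcess[i])), collapse = "\t"),
    character(1)))
  expect_setequal(paste(bplnLinks(res)[, 1L], bplnLinks(res)[, 2L],
                        sep = "\t"), ref)
})

test_that("one significant direction suffices for an undirected link", {
  ## h1 ('from') is adjacent to all four 'to' genes; the reverse direction
  ## is weak because only one 'from' gene exists
  catalog <- processCatalog(list(A = "h1", B = c("g1", "g2", "g3", "g4")))
  nw <- interactionNetwork(rbind(
    cbind("h1", c("g1", "g2", "g3", "g4")),
    cbind("u1", c("u2", "u3")), cbind("u2", "u4")))
  res <- computeBPLN(nw, catalog, qThreshold = 0.05)
  t <- bplnTests(res)
  qAB <- t$qValue[t$fromProcess == "A"]
  qBA <- t$qValue[t$fromProcess == "B"]
  expect_lte(qAB, 0.05)
  expect_gt(qBA, 0.05)
  expect_identical(unname(bplnLinks(res)[1L, ]), c("A", "B"))
})

test_that("the threshold sweep returns the smallest cutoff reaching the target", {
  tests <- data.frame(
    fromProcess = c("a", "b", "a", "c", "b", "c"),
    toProcess = c("b", "a", "c", "a", "c", "b"),
    count = 1L,
    pValue = c(1e-30, 0.5, 1e-20, 0.9, 1e-10, 0.8),
    qValue = NA_real_)
  res <- new("BPLNResult", tests = tests,
             undirectedLinks = matrix(character(0), ncol = 2),
             qThreshold = 0.05)
  expect_equal(bplnThresholdSweep(res, 2L), 1e-20)
  expect_equal(bplnThresholdSweep(res, 3L), 1e-10)
  expect_error(bplnThresholdSweep(res, 4L), "unattainable")
})
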