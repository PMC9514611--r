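test_that("compatible supports are downward closed and include the empty set", {
  for (model in list(twoDemeMigrationModel(2), twoDemeIMModel(2),
                     toyMassMigrationModel())) {
    g <- buildStateGraph(model)
    ok <- compatibleSupports(g)
    K <- branchTypeCount(g@bts)
    expect_true(ok[1L])                       # all-zero configuration
    for (U in which(ok) - 1L) {
      for (b in 0:(K - 1L)) {
        sub <- bitwAnd(U, bitwNot(bitwShiftL(1L, b)))
        expect_true(ok[sub + 1L])
      }
    }
  }
})

test_that("compatible configuration counts and enumeration agree", {
  g <- buildStateGraph(twoDemeMigrationModel(2))
  cc <- compatibleConfigurations(g, 2, enumerate = TRUE)
  expect_equal(cc$count, 112)
  expect_equal(nrow(cc$configs), 112L)
  expect_equal(anyDuplicated(cc$configs), 0L)
  expect_true(all(cc$configs >= 0L & cc$configs <= 3L))
  # the all-zero configuration is always present
  expect_true(any(rowSums(cc$configs) == 0L))
  # per-type kmax changes the count accordingly
  cc2 <- compatibleConfigurations(g, c(1, 1, 2, 2))
  expect_lt(cc2$count, cc$count)
})

test_that("no false structural zeros: MC-observed configurations are flagged compatible", {
  for (model in list(twoDemeMigrationModel(2, rate = 0.9, NeB = 0.7),
                     imBenchmarkModel())) {
    g <- buildStateGraph(model)
    ok <- compatibleSupports(g)
    bts <- g@bts
    est <- estimateBsfs(model, theta = 1.2, kmax = 2, reps = 200, seed = 99)
    observed <- which(est@probs > 0)
    G <- as.matrix(expand.grid(rep(list(0:3), branchTypeCount(bts))))
    for (i in observed) {
      mask <- sum(bitwShiftL(1L, which(G[i, ] > 0L) - 1L))
      expect_true(ok[mask + 1L])
    }
  }
})

test_that("array layouts describe dense and indexed storage", {
  g <- buildStateGraph(twoDemeMigrationModel(2))
  ok <- compatibleSupports(g)
  lay <- configArrayLayout(rep(2L, 4L), ok)
  expect_equal(lay$size, 256)
  expect_equal(lay$storage, "dense")
  expect_equal(lay$nStored, 112L)
  expect_equal(dim(lay$mask), rep(4L, 4L))
  # incompatible slots read as exact zero through the mask
  expect_false(all(lay$mask))
  # forcing the indexed path stores the same configurations
  lay2 <- configArrayLayout(rep(2L, 4L), ok, denseLimit = 10)
  expect_equal(lay2$storage, "indexed")
  expect_equal(lay2$nStored, 112L)
  expect_error(configArrayLayout(c(-1L, 2L), ok), "non-negative")
})

test_that("equiprobable classes follow same-deme label exchangeability", {
  m <- singleDemeModel(3)
  bts <- enumerateBranchTypes(m, phased = TRUE, rooted = TRUE)
  expect_equal(bts@labels, c("0_0_1", "0_1_0", "0_1_1", "1_0_0", "1_0_1", "1_1_0"))
  # {k_ab = 1, k_b = 1} is equiprobable to {k_bc = 1, k_c = 1}
  idx <- function(lbl) match(lbl, bts@labels)
  cfg1 <- integer(6); cfg1[idx("1_1_0")] <- 1L; cfg1[idx("0_1_0")] <- 1L
  cfg2 <- integer(6); cfg2[idx("0_1_1")] <- 1L; cfg2[idx("0_0_1")] <- 1L
  cls <- equiprobableClasses(bts, rbind(cfg1, cfg2))
  expect_equal(cls$classKey[1L], cls$classKey[2L])
  expect_equal(sum(cls$representative), 1L)

  # a fully symmetric configuration is its own (singleton) class
  cfg3 <- rep(1L, 6)
  cls3 <- equiprobableClasses(bts, rbind(cfg3))
  expect_equal(sum(cls3$representative), 1L)

  # orbits partition the full configuration space (kmax = 1 everywhere)
  G <- as.matrix(expand.grid(rep(list(0:1), 6)))
  clsAll <- equiprobableClasses(bts, G)
  orbitSizes <- table(clsAll$classKey)
  expect_equal(sum(orbitSizes), 64L)
  expect_equal(length(orbitSizes), sum(clsAll$representative))
  # group order for 3 exchangeable samples is 6; orbit sizes divide it
  expect_true(all(orbitSizes %in% c(1L, 2L, 3L, 6L)))

  # unphased sets are already collapsed: identity partition
  btsU <- enumerateBranchTypes(twoDemeMigrationModel(2))
  GU <- as.matrix(expand.grid(rep(list(0:1), 4)))
  clsU <- equiprobableClasses(btsU, GU)
  expect_equal(sum(clsU$representative), nrow(GU))
})
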