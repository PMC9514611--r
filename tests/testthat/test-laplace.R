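test_that("closed-form inverse Laplace matches the matrix-exponential oracle", {
  # frozen small cases
  expect_equal(inverseLaplaceProduct(1, 1), exp(-1))
  expect_equal(inverseLaplaceProduct(c(1, 2), 1), exp(-1) - exp(-2), tolerance = 1e-12)
  expect_equal(inverseLaplaceProduct(c(1, 1), 1), exp(-1), tolerance = 1e-12)
  expect_equal(inverseLaplaceProduct(numeric(0), 2), 1)
  expect_error(inverseLaplaceProduct(1, -1), ">= 0")

  # random pole sets, including zeros, repeats and near-confluent pairs;
  # distinct poles are kept >= 0.05 apart so that the double-precision
  # oracle itself retains the compared digits
  set.seed(42)
  drawPoles <- function(k) {
    repeat {
      c <- stats::runif(k, 0, 4)
      if (k == 1L || min(dist(c)) > 0.05) return(c)
    }
  }
  for (rep in 1:40) {
    k <- sample(1:6, 1)
    c <- drawPoles(k)
    if (rep %% 4 == 0) c[1] <- 0                      # residual 1/delta pole
    if (rep %% 5 == 0 && k >= 2) c[2] <- c[1]         # exact repeat
    if (rep %% 7 == 0 && k >= 2) c[2] <- c[1] + 1e-11 # near-confluent
    # t bounded away from 0: as t -> 0 the partial-fraction terms cancel to
    # order t^(k-1) and no double-precision method retains 1e-9 digits
    t <- stats::runif(1, 0.5, 3)
    expect_equal(inverseLaplaceProduct(c, t), expmInverseLaplace(c, t),
                 tolerance = 1e-9, info = paste(rep, paste(signif(c, 4), collapse = ",")))
  }
  # high-multiplicity confluent case: L^-1[1/(c+s)^4](t) = t^3 e^{-ct}/6
  expect_equal(inverseLaplaceProduct(rep(2, 4), 0.7),
               0.7^3 * exp(-2 * 0.7) / 6, tolerance = 1e-12)
})

test_that("edge evaluation follows the competing-risk form", {
  g <- buildStateGraph(singleDemeModel(2))
  expect_equal(nEdges(g), 1L)
  eq <- g@edges$eq[1L]
  expect_equal(evalEdge(g, eq, rateVector(g, omega = 0)), 1)
  expect_equal(evalEdge(g, eq, rateVector(g, omega = 0.5)), 1 / (1 + 2 * 0.5))
  expect_error(evalEdge(g, eq, rateVector(g, omega = 0) * 0), "degenerate")
})

test_that("graph propagation equals exhaustive path enumeration", {
  # random DAGs with scalar values
  set.seed(7)
  for (rep in 1:20) {
    d <- randomDag(sample(4:12, 1))
    vals <- stats::runif(length(d$children), -1, 1)
    expect_equal(propagateGraph(d$children, d$roots, vals),
                 bruteForcePathSum(d$children, d$roots, vals),
                 tolerance = 1e-12)
  }
  # custom operators: polynomial coefficient vectors under convolution
  polyMul <- function(a, b) {
    out <- numeric(length(a))
    for (i in seq_along(a)) {
      for (j in seq_len(length(a) - i + 1L)) out[i + j - 1L] <- out[i + j - 1L] + a[i] * b[j]
    }
    out
  }
  chain <- list(2L, 3L, integer(0))
  vals <- list(c(1, 1, 0), c(1, 2, 0), c(2, 0, 1))
  expect_equal(propagateGraph(chain, 1L, vals, add = `+`, mul = polyMul,
                              zero = numeric(3)),
               polyMul(polyMul(vals[[1]], vals[[2]]), vals[[3]]))

  # fixture computational graphs, scalar node values
  set.seed(8)
  for (model in list(twoDemeMigrationModel(2, rate = 0.7),
                     toyMassMigrationModel(),
                     twoDemeIMModel(2, rate = 1.3, T = 0.8))) {
    cg <- collapseGraph(buildStateGraph(model))
    omega <- stats::runif(branchTypeCount(cg@graph@bts), 0, 0.5)
    vals <- compNodeValues(cg, omega)
    expect_equal(propagateGraph(cg@children, cg@roots, vals),
                 bruteForcePathSum(cg@children, cg@roots, vals),
                 tolerance = 1e-12)
  }
})

test_that("the Laplace transform is a proper generating function", {
  # total probability at omega = 0, with and without a discrete event
  for (model in list(singleDemeModel(2), singleDemeModel(4),
                     twoDemeMigrationModel(2, rate = 0.7),
                     twoDemeMigrationModel(3, rate = 1.4, NeB = 0.5))) {
    expect_equal(evaluateLaplace(model, omega = 0), 1, tolerance = 1e-12)
  }
  for (T in c(0, 0.3, 1.5, 10)) {
    expect_equal(evaluateLaplace(toyMassMigrationModel(T), omega = 0), 1,
                 tolerance = 1e-12)
    expect_equal(evaluateLaplace(twoDemeIMModel(2, rate = 1.3, T = T), omega = 0),
                 1, tolerance = 1e-12)
  }

  # n = 2 closed form E[e^{-2 omega T2}] = 1/(1 + 2 omega)
  for (w in c(0.1, 0.5, 1, 3)) {
    expect_equal(evaluateLaplace(singleDemeModel(2), omega = w), 1 / (1 + 2 * w),
                 tolerance = 1e-12)
  }
  # -d/domega at 0 recovers E[L_total] = 2
  h <- 1e-6
  expect_equal((1 - evaluateLaplace(singleDemeModel(2), h)) / h, 2, tolerance = 1e-4)

  # complete monotonicity on a grid: values in (0, 1], non-increasing in omega
  cg <- collapseGraph(buildStateGraph(twoDemeIMModel(2, rate = 1.3, T = 1.2)))
  grid <- seq(0, 2, by = 0.25)
  vals <- vapply(grid, function(w) evaluateLaplace(cg = cg, omega = w, model = NULL), 0)
  expect_true(all(vals > 0 & vals <= 1))
  expect_true(all(diff(vals) <= 0))
})

test_that("collapsing shares identical delta prefixes and covers all paths", {
  g <- buildStateGraph(toyMassMigrationModel())
  cg <- collapseGraph(g)
  expect_equal(sum(cg@kind == "collapsed"), 2L)   # two distinct prefixes
  expect_equal(sum(cg@kind == "plain"), 4L)       # four post-event edges
  expect_equal(nNodes(cg), 6L)
  # a migration-only model collapses to the pure edge dual
  g2 <- buildStateGraph(twoDemeMigrationModel(2))
  cg2 <- collapseGraph(g2)
  expect_true(all(cg2@kind == "plain"))
  expect_equal(nNodes(cg2), nEdges(g2))
  # IM models have pending-absorption paths, carried as zero-pole nodes
  cgi <- collapseGraph(buildStateGraph(twoDemeIMModel(2, rate = 1, T = 1)))
  expect_true(any(cgi@zeroPole))
})
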