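test_that("compensated summation survives catastrophic cancellation", {
  expect_identical(compensatedSum(c(1e16, 1, -1e16)), 1)
  expect_identical(compensatedSum(numeric(0)), 0)
  expect_identical(compensatedSum(rep(0, 5)), 0)
  # permutation invariance on an ill-conditioned vector
  set.seed(3)
  x <- c(10^stats::runif(20, 10, 16) * sample(c(-1, 1), 20, TRUE), stats::runif(20))
  ref <- compensatedSum(sort(x))
  for (rep in 1:5) {
    expect_equal(compensatedSum(sample(x)), ref, tolerance = 1e-15)
  }
})

test_that("truncated series products match naive polynomial multiplication", {
  one <- array(c(1, 0, 0), dim = 3L)
  B <- array(stats::runif(3), dim = 3L)
  expect_equal(seriesProduct(one, B), B)
  expect_equal(as.numeric(seriesProduct(array(c(1, 1, 0)), array(c(1, 1, 0)))),
               c(1, 2, 1))
  set.seed(5)
  for (rep in 1:10) {
    dims <- sample(2:4, sample(1:4, 1), replace = TRUE)
    A <- array(stats::rnorm(prod(dims)), dim = dims)
    B <- array(stats::rnorm(prod(dims)), dim = dims)
    expect_equal(seriesProduct(A, B), naiveSeriesProduct(A, B), tolerance = 1e-12)
  }
  expect_error(seriesProduct(array(0, 2), array(0, 3)), "shapes")
})

test_that("reciprocal-polynomial coefficients match calculus and finite differences", {
  # closed 1-D checks: f = b + c x
  co <- inversePolyCoeffs(2, 1, kmax = 3, at = 0.3)
  f0 <- 1 + 2 * 0.3
  expect_equal(as.numeric(co), (-2)^(0:3) / f0^(1:4))
  expect_error(inversePolyCoeffs(1, -0.3, kmax = 2, at = 0.3), "pole")

  # K = 2 table against the symbolic-differentiation oracle
  cvec <- c(0.8, 1.7); b <- 2.1; x0 <- c(0.4, 0.2)
  S <- inversePolyCoeffs(cvec, b, kmax = c(2, 2), at = x0)
  G <- as.matrix(expand.grid(0:2, 0:2))
  for (i in seq_len(nrow(G))) {
    k <- as.integer(G[i, ])
    expect_equal(S[i], symCoeff("1/(2.1 + 0.8*x1 + 1.7*x2)", x0, k),
                 tolerance = 1e-9, info = paste(k, collapse = ","))
  }
  # and against plain finite differences at the loose FD tolerance
  f <- function(x) 1 / (b + sum(cvec * x))
  expect_equal(S[3, 3], fdCoeff(f, x0, c(2L, 2L)), tolerance = 1e-5)
})

test_that("exponential-polynomial coefficients match calculus and finite differences", {
  cc <- -0.9; cvec <- c(1.2, 0.5); b <- 0.7; x0 <- c(0.1, 0.6)
  S <- expPolyCoeffs(cc, cvec, b, kmax = c(2, 2), at = x0)
  e0 <- exp(cc * (b + sum(cvec * x0)))
  expect_equal(S[1, 1], e0)
  expect_equal(S[2, 1], cc * cvec[1] * e0)
  G <- as.matrix(expand.grid(0:2, 0:2))
  for (i in seq_len(nrow(G))) {
    k <- as.integer(G[i, ])
    expect_equal(S[i], symCoeff("exp(-0.9*(0.7 + 1.2*x1 + 0.5*x2))", x0, k),
                 tolerance = 1e-9)
  }
})

test_that("collapsed-node series match the scalar inversion under perturbation", {
  T <- 0.8
  # single pole: reduces to the exponential block
  p1 <- list(list(const = 0.5, coeffs = c(2, 1)))
  expect_equal(invertedNodeSeries(p1, T, kmax = c(2, 2), at = c(0.3, 0.1)),
               expPolyCoeffs(-T, c(2, 1), 0.5, kmax = c(2, 2), at = c(0.3, 0.1)))
  # omega-independent poles give a constant series
  p0 <- list(list(const = 1, coeffs = c(0, 0)), list(const = 2, coeffs = c(0, 0)))
  S0 <- invertedNodeSeries(p0, T, kmax = c(1, 1), at = c(0, 0))
  expect_equal(S0[1, 1], exp(-T) - exp(-2 * T), tolerance = 1e-12)
  expect_equal(S0[2, 1], 0)

  # general case against the symbolic oracle applied to the partial-fraction
  # closed form of three distinct first-degree poles
  poles <- list(list(const = 0.4, coeffs = c(2, 1)),
                list(const = 1.3, coeffs = c(1, 3)),
                list(const = 0, coeffs = c(0, 0)))
  x0 <- c(0.25, 0.15)
  S <- invertedNodeSeries(poles, T, kmax = c(2, 2), at = x0)
  cexp <- vapply(poles, function(p) {
    sprintf("(%.17g + %.17g*x1 + %.17g*x2)", p$const, p$coeffs[1], p$coeffs[2])
  }, "")
  terms <- vapply(seq_along(cexp), function(i) {
    denom <- paste(sprintf("(%s - %s)", cexp[-i], cexp[i]), collapse = "*")
    sprintf("exp(-%s*%.17g)/(%s)", cexp[i], T, denom)
  }, "")
  closedForm <- paste(terms, collapse = " + ")
  G <- as.matrix(expand.grid(0:2, 0:2))
  for (i in seq_len(nrow(G))) {
    k <- as.integer(G[i, ])
    expect_equal(S[i], symCoeff(closedForm, x0, k), tolerance = 1e-9,
                 info = paste(k, collapse = ","))
  }

  # confluent: two identical first-degree poles, L^-1 = T e^{-c(x) T}
  conf <- list(list(const = 0.6, coeffs = c(1, 2)), list(const = 0.6, coeffs = c(1, 2)))
  Sc <- invertedNodeSeries(conf, T, kmax = c(2, 2), at = x0)
  confForm <- sprintf("%.17g*exp(-(0.6 + x1 + 2*x2)*%.17g)", T, T)
  for (i in seq_len(nrow(G))) {
    k <- as.integer(G[i, ])
    expect_equal(Sc[i], symCoeff(confForm, x0, k), tolerance = 1e-9)
  }
  # distinct polynomials colliding at the expansion point are refused
  bad <- list(list(const = 1, coeffs = c(1, 0)), list(const = 1, coeffs = c(0, 1)))
  expect_error(invertedNodeSeries(bad, T, kmax = c(1, 1), at = c(0.2, 0.2)),
               "degenerate")
})

test_that("series propagation is consistent with scalar evaluation and brute force", {
  # single-path model: the root series is the single node's series
  cg1 <- collapseGraph(buildStateGraph(singleDemeModel(2)))
  S1 <- propagateSeries(cg1, kmax = 3, at = 0.5)
  expect_equal(S1, inversePolyCoeffs(2, 1, kmax = 3, at = 0.5))

  # k = 0 coefficient equals the scalar transform at the expansion point
  for (model in list(twoDemeMigrationModel(2, rate = 0.7),
                     toyMassMigrationModel(0.9),
                     twoDemeIMModel(2, rate = 1.3, T = 0.8))) {
    cg <- collapseGraph(buildStateGraph(model))
    S <- propagateSeries(cg, kmax = 1, at = 0.6)
    expect_equal(S[matrix(1L, 1L, length(dim(S)))],
                 evaluateLaplace(cg = cg, omega = 0.6, model = NULL),
                 tolerance = 1e-12)
  }

  # full table against brute-force truncated path products (toy model, 3 paths)
  cg <- collapseGraph(buildStateGraph(toyMassMigrationModel(1.1)))
  km <- rep(1L, branchTypeCount(cg@graph@bts))
  at <- 0.35
  S <- propagateSeries(cg, kmax = km, at = at)
  nodeSeries <- lapply(seq_len(nNodes(cg)), function(i) {
    gfcoal:::.compNodeSeries(cg, i, km, rep(at, length(km)), 1.1,
                             rateVector(cg@graph)[seq_len(ncol(cg@graph@eqQ) - length(km))])
  })
  brute <- array(0, dim = km + 1L)
  walk <- function(u, acc) {
    acc <- seriesProduct(acc, nodeSeries[[u]])
    if (!length(cg@children[[u]])) {
      brute <<- brute + acc
      return(invisible())
    }
    for (v in cg@children[[u]]) walk(v, acc)
  }
  one <- array(0, dim = km + 1L); one[1L] <- 1
  for (u in cg@roots) walk(u, one)
  expect_equal(S, brute, tolerance = 1e-12)
})
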