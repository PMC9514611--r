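# Independent oracles and fixture builders used across the test suite.

# Matrix-exponential inverse-Laplace oracle: for the bidiagonal matrix M
# with diagonal -c_i and unit superdiagonal, (sI - M)^{-1}[1, k] equals
# prod_i 1/(c_i + s), so L^{-1}[prod 1/(c_i + s)](t) = expm(M t)[1, k].
# Handles repeated poles and poles at zero without special cases, and is
# completely independent of the partial-fraction code under test.
expmInverseLaplace <- function(c, t) {
  k <- length(c)
  if (k == 0L) return(1)
  M <- diag(-c, nrow = k)
  if (k > 1L) M[cbind(seq_len(k - 1L), seq.int(2L, k))] <- 1
  as.numeric(Matrix::expm(Matrix::Matrix(M * t))[1L, k])
}

# Naive truncated multivariate polynomial product (full double loop, plain
# summation) as the oracle for seriesProduct().
naiveSeriesProduct <- function(A, B) {
  dims <- dim(A)
  G <- as.matrix(expand.grid(lapply(dims, function(d) 0:(d - 1L))))
  C <- array(0, dim = dims)
  lin <- function(k) {
    mult <- c(1, cumprod(dims[-length(dims)]))
    as.integer(sum(k * mult)) + 1L
  }
  for (i in seq_len(nrow(G))) {
    for (j in seq_len(nrow(G))) {
      k <- G[i, ] + G[j, ]
      if (all(k < dims)) {
        C[lin(k)] <- C[lin(k)] + A[i] * B[j]
      }
    }
  }
  C
}

# Exhaustive path-product sum over an adjacency-list DAG: the propagation
# oracle (sum over every root-to-leaf path of the product of node values).
bruteForcePathSum <- function(children, roots, values) {
  total <- 0
  walk <- function(u, acc) {
    acc <- acc * values[[u]]
    if (!length(children[[u]])) {
      total <<- total + acc
      return(invisible())
    }
    for (v in children[[u]]) walk(v, acc)
  }
  for (u in roots) walk(u, 1)
  total
}

# Random DAG on n nodes: edges only from lower to higher index, roots are
# the in-degree-zero nodes.
randomDag <- function(n, p = 0.4) {
  children <- vector("list", n)
  hasParent <- logical(n)
  for (u in seq_len(n - 1L)) {
    ch <- which(stats::runif(n - u) < p) + u
    if (u < n && !length(ch)) ch <- n
    children[[u]] <- ch
    hasParent[ch] <- TRUE
  }
  children[[n]] <- integer(0)
  list(children = children, roots = which(!hasParent))
}

# Central finite-difference estimate of the Taylor COEFFICIENT of `f` at
# multi-index k around x0 (coefficient = derivative / prod(k!)), with one
# Richardson extrapolation step to kill the leading h^2 truncation error
# while keeping h large enough that iterated differencing retains digits.
fdCoeff <- function(f, x0, k, h = 0.02) {
  iterated <- function(h) {
    diffOnce <- function(g, dim) {
      force(g); force(dim); force(h)
      function(x) (g(replace(x, dim, x[dim] + h)) - g(replace(x, dim, x[dim] - h))) / (2 * h)
    }
    g <- f
    for (d in seq_along(k)) {
      for (rep in seq_len(k[d])) g <- diffOnce(g, d)
    }
    g(x0)
  }
  (4 * iterated(h / 2) - iterated(h)) / 3 / prod(factorial(k))
}

# Symbolic-differentiation oracle: Taylor coefficient of a closed-form
# expression (text in variables x1, x2, ...) via repeated stats::D().
symCoeff <- function(exprText, x0, k) {
  e <- str2lang(exprText)
  for (d in seq_along(k)) {
    for (rep in seq_len(k[d])) e <- stats::D(e, paste0("x", d))
  }
  env <- as.list(stats::setNames(x0, paste0("x", seq_along(x0))))
  eval(e, envir = env) / prod(factorial(k))
}

# The toy model of the worked example: two demes, 2 unphased samples in A
# and 1 in B, no migration, one mass migration B -> A at time T.
toyMassMigrationModel <- function(T = 1.5) {
  coalModel(sizes = c(A = 1, B = 1), samples = c(A = 2, B = 1),
            split = list(from = "B", to = "A", time = T))
}

# Fig-3-style IM fixture in scaled units: reference deme A, sizes relative
# to NeA = 1.3e6, per-lineage migration rate 2*NeA*me, T in 2*NeA
# generations.
imBenchmarkModel <- function() {
  NeA <- 1.3e6; NeB <- 0.6e6; NeAB <- 1.5e6
  twoDemeIMModel(n = 2, rate = 2 * NeA * 7e-7, T = 1e7 / (2 * NeA),
                 NeA = 1, NeB = NeB / NeA, NeAB = NeAB / NeA)
}

# Brute-force enumeration of unphased branch-type count vectors.
bruteUnphasedTypes <- function(totals, rooted) {
  G <- as.matrix(expand.grid(lapply(totals, function(m) 0:m)))
  keep <- rowSums(G) > 0 & rowSums(G) < sum(totals)
  G <- G[keep, , drop = FALSE]
  if (rooted) return(nrow(G))
  seen <- character(0)
  for (i in seq_len(nrow(G))) {
    a <- paste(G[i, ], collapse = "_")
    b <- paste(totals - G[i, ], collapse = "_")
    key <- paste(sort(c(a, b)), collapse = "|")
    seen <- union(seen, key)
  }
  length(seen)
}

# Scalar evaluation of every computational-graph node, for brute-force
# cross-checks of the propagation step.
compNodeValues <- function(cg, omega, T = NULL) {
  g <- cg@graph
  if (is.null(T) && !is.null(splitEvent(g@model))) T <- splitEvent(g@model)$time
  r <- rateVector(g, omega = omega)
  vapply(seq_len(nNodes(cg)), function(i) {
    gfcoal:::.compNodeValue(cg, i, r, if (is.null(T)) 0 else T)
  }, 0)
}
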