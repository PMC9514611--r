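# Truncated multivariate Taylor series in the branch-type dummy variables.
# A series table is a plain numeric array with one dimension per branch type
# (extent kmax_i + 1; extent 1 for types not being expanded) holding the
# Taylor COEFFICIENTS around the expansion point -- coefficients rather than
# derivatives, which keeps entries smaller by a factor (sum k)! and reduces
# cumulative rounding error. Every inner summation uses compensated
# summation to guard against catastrophic cancellation: coefficient terms
# alternate in sign.

.planCache <- new.env(parent = emptyenv())

.seriesGrid <- function(dims) {
  g <- as.matrix(expand.grid(lapply(dims, function(d) 0:(d - 1L)),
                             KEEP.OUT.ATTRS = FALSE))
  dimnames(g) <- NULL
  g
}

# index pairs (ja, jb) contributing to each output cell of the truncated
# convolution, grouped by output linear index; cached per shape.
.productPlan <- function(dims) {
  key <- paste(dims, collapse = "x")
  plan <- get0(key, envir = .planCache)
  if (!is.null(plan)) return(plan)
  G <- .seriesGrid(dims)
  N <- nrow(G)
  ja <- rep(seq_len(N), times = N)
  jb <- rep(seq_len(N), each = N)
  S <- G[ja, , drop = FALSE] + G[jb, , drop = FALSE]
  ok <- rowSums(S >= matrix(dims, nrow(S), length(dims), byrow = TRUE)) == 0L
  ja <- ja[ok]; jb <- jb[ok]
  mult <- c(1, cumprod(dims[-length(dims)]))
  out <- as.integer(S[ok, , drop = FALSE] %*% mult) + 1L
  o <- order(out)
  plan <- list(ja = ja[o], jb = jb[o],
               ptr = c(0L, cumsum(tabulate(out, nbins = N))), N = N)
  assign(key, plan, envir = .planCache)
  plan
}

.constSeries <- function(value, dims) {
  s <- array(0, dim = dims)
  s[1L] <- value
  s
}

#' Product of two truncated Taylor series
#'
#' Multi-index convolution truncated to the common shape:
#' \eqn{C[k] = \sum_{j \le k} A[j] B[k-j]}, every inner sum computed with
#' [compensatedSum()].
#'
#' @param A,B numeric arrays of identical shape (coefficients around the
#'   same expansion point).
#' @return array of the same shape.
#' @examples
#' seriesProduct(array(c(1, 1, 0)), array(c(1, 1, 0)))  # (1+x)^2 -> 1, 2, 1
#' @export
seriesProduct <- function(A, B) {
  dims <- dim(A)
  if (is.null(dims)) dims <- length(A)
  dimsB <- if (is.null(dim(B))) length(B) else dim(B)
  if (!identical(as.integer(dims), as.integer(dimsB))) {
    stop("series shapes differ")
  }
  plan <- .productPlan(dims)
  a <- as.numeric(A)
  b <- as.numeric(B)
  prods <- a[plan$ja] * b[plan$jb]
  out <- numeric(plan$N)
  ptr <- plan$ptr
  for (n in seq_len(plan$N)) {
    lo <- ptr[n] + 1L
    hi <- ptr[n + 1L]
    if (hi >= lo) out[n] <- compensatedSum(prods[lo:hi])
  }
  array(out, dim = dims)
}

#' Taylor coefficients of the reciprocal of a first-degree polynomial
#'
#' For \eqn{f(x) = b + \sum_i c_i x_i}, the Taylor coefficient of
#' \eqn{1/f} at multi-index \eqn{k} around the point `at` is
#' \deqn{(-1)^s \frac{s!}{\prod_i k_i!} \frac{\prod_i c_i^{k_i}}{f(at)^{s+1}},
#'  \quad s = \sum_i k_i}
#' (the derivative divided by \eqn{\prod k_i!}).
#'
#' @param coeffs numeric vector of first-degree coefficients \eqn{c_i}.
#' @param const the constant term \eqn{b}.
#' @param kmax integer vector of truncation orders per variable.
#' @param at expansion point (recycled to `length(coeffs)`).
#' @return numeric array of shape `kmax + 1`.
#' @export
inversePolyCoeffs <- function(coeffs, const, kmax, at = 0) {
  dims <- as.integer(kmax) + 1L
  at <- rep_len(at, length(coeffs))
  f0 <- const + sum(coeffs * at)
  if (f0 == 0) stop("pole at the expansion point: f(at) = 0")
  G <- .seriesGrid(dims)
  s <- rowSums(G)
  vals <- vapply(seq_len(nrow(G)), function(i) {
    k <- G[i, ]
    (-1)^s[i] * exp(lfactorial(s[i]) - sum(lfactorial(k))) *
      prod(coeffs^k) / f0^(s[i] + 1)
  }, 0)
  array(vals, dim = dims)
}

#' Taylor coefficients of the exponential of a scaled first-degree polynomial
#'
#' For \eqn{e^{c f(x)}} with \eqn{f(x) = b + \sum_i c_i x_i}, the
#' coefficient at multi-index \eqn{k} is
#' \eqn{c^s (\prod_i c_i^{k_i}) e^{c f(at)} / \prod_i k_i!}.
#'
#' @param scale the outer factor \eqn{c}.
#' @inheritParams inversePolyCoeffs
#' @return numeric array of shape `kmax + 1`.
#' @export
expPolyCoeffs <- function(scale, coeffs, const, kmax, at = 0) {
  dims <- as.integer(kmax) + 1L
  at <- rep_len(at, length(coeffs))
  e0 <- exp(scale * (const + sum(coeffs * at)))
  G <- .seriesGrid(dims)
  s <- rowSums(G)
  vals <- vapply(seq_len(nrow(G)), function(i) {
    k <- G[i, ]
    scale^s[i] * prod(coeffs^k) * e0 * exp(-sum(lfactorial(k)))
  }, 0)
  array(vals, dim = dims)
}

#' Series expansion of a collapsed (inverted) node
#'
#' The inverse Laplace transform of a collapsed path prefix is, per pole
#' group, a product of building blocks \eqn{e^{c f(x)} / \prod_j f_j(x)}
#' where each \eqn{f} is first-degree in the dummy variables. This routine
#' assembles the full truncated series: exponential factors from
#' [expPolyCoeffs()], reciprocal pole-difference factors from
#' [inversePolyCoeffs()], combined with [seriesProduct()]; repeated poles
#' (identical first-degree polynomials) are handled by the confluent
#' recursion, and the contributions of all pole groups are accumulated with
#' compensated summation.
#'
#' @param poles list of poles, each `list(const =, coeffs =)` describing the
#'   non-delta part \eqn{c_i(x) = b_i + \sum o_{ik} x_k}.
#' @param T the discrete-event time.
#' @param kmax truncation orders per variable.
#' @param at expansion point.
#' @param tol near-degeneracy tolerance: pole groups with distinct
#'   polynomials whose values at `at` are closer than this (relative) are
#'   refused, since the distinct-pole formula is then unstable.
#' @return numeric array of shape `kmax + 1`.
#' @export
invertedNodeSeries <- function(poles, T, kmax, at = 0, tol = 1e-9) {
  dims <- as.integer(kmax) + 1L
  if (!length(poles)) return(.constSeries(1, dims))
  K <- length(kmax)
  at <- rep_len(at, K)
  keys <- vapply(poles, function(p) {
    paste(c(p$const, p$coeffs), collapse = ",")
  }, "")
  groups <- split(seq_along(poles), factor(keys, levels = unique(keys)))
  gb <- vapply(groups, function(ix) poles[[ix[1L]]]$const, 0)
  gco <- lapply(groups, function(ix) rep_len(poles[[ix[1L]]]$coeffs, K))
  gm <- lengths(groups)
  f0 <- vapply(seq_along(groups), function(i) gb[i] + sum(gco[[i]] * at), 0)
  if (length(f0) > 1L) {
    dd <- abs(outer(f0, f0, "-"))
    diag(dd) <- Inf
    if (any(dd < tol * pmax(1, abs(f0)))) {
      stop("near-degenerate distinct poles at the expansion point; ",
           "perturb the model rates")
    }
  }
  acc <- list(sum = array(0, dim = dims), err = array(0, dim = dims))
  for (i in seq_along(groups)) {
    mi <- gm[i]
    E <- expPolyCoeffs(-T, gco[[i]], gb[i], kmax, at)
    inv <- lapply(seq_along(groups)[-i], function(j) {
      inversePolyCoeffs(gco[[j]] - gco[[i]], gb[j] - gb[i], kmax, at)
    })
    mj <- gm[seq_along(groups)[-i]]
    B <- vector("list", mi)
    B0 <- .constSeries(1, dims)
    for (j in seq_along(inv)) {
      for (rep in seq_len(mj[j])) B0 <- seriesProduct(B0, inv[[j]])
    }
    B[[1L]] <- B0
    if (mi > 1L) {
      # u_s = sum_j m_j / (c_j - c_i)^s as series, then the log-derivative
      # recursion r*B_r = sum_s (-1)^s u_s B_{r-s}
      u <- vector("list", mi - 1L)
      pw <- inv
      for (s in seq_len(mi - 1L)) {
        if (s > 1L) pw <- lapply(seq_along(inv), function(j) {
          seriesProduct(pw[[j]], inv[[j]])
        })
        us <- array(0, dim = dims)
        for (j in seq_along(inv)) us <- us + mj[j] * pw[[j]]
        u[[s]] <- us
      }
      for (r in seq_len(mi - 1L)) {
        Br <- array(0, dim = dims)
        for (s in seq_len(r)) {
          Br <- Br + (-1)^s * seriesProduct(u[[s]], B[[r - s + 1L]])
        }
        B[[r + 1L]] <- Br / r
      }
    }
    for (r in seq_len(mi) - 1L) {
      p <- mi - r                     # remaining pole order
      term <- (T^(p - 1) / factorial(p - 1)) * seriesProduct(B[[r + 1L]], E)
      acc <- .accumCompensated(acc, term)
    }
  }
  acc$sum + acc$err
}

# Series value of one computational-graph node.
.compNodeSeries <- function(cg, i, kmax, at, T, lambdaR) {
  g <- cg@graph
  dims <- as.integer(kmax) + 1L
  ds <- g@deltaSlot
  nRate <- ncol(g@eqQ) - branchTypeCount(g@bts)
  eqSeries <- function(eq) {
    q <- g@eqQ[eq, ]
    b <- sum(q[seq_len(nRate)] * lambdaR)       # delta slot of lambdaR is 0
    o <- as.numeric(q[-seq_len(nRate)])
    p <- g@eqP[eq, ]
    num <- p[["l"]] * lambdaR[[p[["slot"]]]]
    num * inversePolyCoeffs(o, b, kmax, at)
  }
  if (cg@kind[i] == "plain") return(eqSeries(cg@eq[i]))
  poles <- list()
  const <- 1
  extra <- NULL
  for (e in cg@prefix[[i]]) {
    eq <- g@edges$eq[e]
    q <- g@eqQ[eq, ]
    p <- g@eqP[eq, ]
    if (!is.na(ds) && q[ds] > 0L) {
      b <- sum(q[seq_len(nRate)] * lambdaR)
      poles[[length(poles) + 1L]] <- list(const = b,
                                          coeffs = as.numeric(q[-seq_len(nRate)]))
      if (p[["slot"]] != ds) const <- const * p[["l"]] * lambdaR[[p[["slot"]]]]
    } else {
      extra <- if (is.null(extra)) eqSeries(eq) else seriesProduct(extra, eqSeries(eq))
    }
  }
  if (cg@zeroPole[i]) {
    poles[[length(poles) + 1L]] <- list(const = 0, coeffs = numeric(branchTypeCount(g@bts)))
  }
  out <- const * invertedNodeSeries(poles, T, kmax, at)
  if (!is.null(extra)) out <- seriesProduct(out, extra)
  out
}

#' Propagate truncated Taylor series through the computational graph
#'
#' Runs the graph propagation with truncated-series addition (elementwise)
#' and multiplication ([seriesProduct()]): the result is the Taylor
#' coefficient table of the (inverted, when a discrete event is present)
#' Laplace transform of the joint branch-length distribution around the
#' expansion point `at`. Its k = 0 entry equals [evaluateLaplace()] at `at`.
#'
#' @param cg a [CompGraph-class].
#' @param kmax integer vector of truncation orders, one per branch type
#'   (entry 0 leaves the type unexpanded).
#' @param at expansion point, scalar or per-type (types with `at = 0` and
#'   `kmax = 0` are effectively unmarked).
#' @param T discrete-event time, if the model has one.
#' @return numeric array of shape `kmax + 1`.
#' @export
propagateSeries <- function(cg, kmax, at = 0, T = NULL) {
  g <- cg@graph
  K <- branchTypeCount(g@bts)
  kmax <- as.integer(rep_len(kmax, K))
  at <- rep_len(at, K)
  if (is.null(T) && !is.null(splitEvent(g@model))) T <- splitEvent(g@model)$time
  if (!is.na(g@deltaSlot) && is.null(T)) {
    stop("model has a discrete event: supply its time T")
  }
  if (is.null(T)) T <- 0
  lambdaR <- rateVector(g, omega = 0, delta = 0)
  lambdaR <- lambdaR[seq_len(ncol(g@eqQ) - K)]
  dims <- kmax + 1L
  values <- lapply(seq_len(nNodes(cg)), function(i) {
    .compNodeSeries(cg, i, kmax, at, T, lambdaR)
  })
  propagateGraph(cg@children, cg@roots, values,
                 add = `+`, mul = seriesProduct,
                 zero = array(0, dim = dims))
}
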