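# Evaluation of the Laplace transform on the graph. The state graph is first
# turned into a computational graph whose nodes represent the edge equations
# (edge -> node dual). When the model contains a discrete event, every
# root-to-event path prefix is collapsed into a single node whose value is
# the closed-form inverse Laplace transform (partial fractions over the
# prefix poles) evaluated at the event time T; paths that reach the mrca
# while the event is still pending collapse whole, with an extra pole at
# zero carrying the residual 1/delta of the compound-distribution identity.

#' Computational graph of a model
#'
#' Nodes represent equations: either a single state-graph edge ("plain") or
#' a collapsed delta-prefix ("collapsed"). Edges point from each node to the
#' possible continuation equations; implicitly they represent
#' multiplication, and alternative children are summed before multiplying,
#' so that the value propagated to the (virtual) root equals the sum over
#' all paths of the product of node values along each path.
#'
#' @slot graph the underlying [StateGraph-class].
#' @slot kind character, "plain" or "collapsed" per node.
#' @slot eq equation index of each plain node (NA for collapsed).
#' @slot prefix list: for collapsed nodes, the state-graph edge indices of
#'   the collapsed path prefix (up to and including the delta edge).
#' @slot zeroPole logical: collapsed node for a path that absorbed before
#'   the event fired (adds the pole at zero).
#' @slot children adjacency list (children summed before multiplication).
#' @slot roots children of the virtual root.
#' @export
setClass("CompGraph",
  representation(
    graph = "StateGraph",
    kind = "character",
    eq = "integer",
    prefix = "list",
    zeroPole = "logical",
    children = "list",
    roots = "integer"
  )
)

#' Collapse a state graph into its computational graph
#'
#' Models without a discrete event yield the plain edge-to-node dual, which
#' shares every common path suffix. With a discrete event, the part of each
#' path leading up to (and including) the delta edge becomes one collapsed
#' node, to be evaluated by the closed-form inverse Laplace transform;
#' identical prefixes are shared. The collapse necessarily duplicates
#' pre-event equations across prefixes, which is why models with discrete
#' events produce larger computational graphs than purely continuous ones.
#'
#' @param g a [StateGraph-class].
#' @return a [CompGraph-class].
#' @export
collapseGraph <- function(g) {
  hasDelta <- any(g@edges$delta)
  outE <- g@outEdges
  childOf <- g@edges$child
  if (!hasDelta) {
    m <- nEdges(g)
    children <- lapply(seq_len(m), function(e) outE[[childOf[e]]])
    return(new("CompGraph", graph = g,
               kind = rep("plain", m), eq = g@edges$eq,
               prefix = rep(list(integer(0)), m),
               zeroPole = rep(FALSE, m),
               children = children, roots = outE[[1L]]))
  }
  # plain nodes: edges whose parent state is past the event
  plainEdges <- which(!g@pending[g@edges$parent])
  plainId <- integer(nEdges(g))
  plainId[plainEdges] <- seq_along(plainEdges)
  kind <- rep("plain", length(plainEdges))
  eq <- g@edges$eq[plainEdges]
  prefix <- rep(list(integer(0)), length(plainEdges))
  zeroPole <- rep(FALSE, length(plainEdges))
  children <- lapply(plainEdges, function(e) plainId[outE[[childOf[e]]]])
  roots <- integer(0)
  addCollapsed <- function(edges, zp, kids) {
    kind[[length(kind) + 1L]] <<- "collapsed"
    eq[[length(eq) + 1L]] <<- NA_integer_
    prefix[[length(prefix) + 1L]] <<- edges
    zeroPole[[length(zeroPole) + 1L]] <<- zp
    children[[length(children) + 1L]] <<- kids
    roots <<- c(roots, length(kind))
  }
  # DFS through the pending region, one collapsed node per distinct prefix
  walk <- function(u, path) {
    if (nrow(g@nodes[[u]]) == 1L) {     # absorbed while the event was pending
      addCollapsed(path, TRUE, integer(0))
      return(invisible())
    }
    for (e in outE[[u]]) {
      if (g@edges$delta[e]) {
        addCollapsed(c(path, e), FALSE, plainId[outE[[childOf[e]]]])
      } else {
        walk(childOf[e], c(path, e))
      }
    }
  }
  walk(1L, integer(0))
  new("CompGraph", graph = g, kind = kind, eq = eq, prefix = prefix,
      zeroPole = zeroPole, children = children, roots = roots)
}

#' @describeIn CompGraph-class number of computational nodes. For models
#'   without a discrete event this equals the number of state-graph edges.
#' @param x a `CompGraph`.
#' @export
setMethod("nNodes", "CompGraph", function(x) length(x@kind))

setMethod("show", "CompGraph", function(object) {
  cat("CompGraph:", length(object@kind), "nodes (",
      sum(object@kind == "plain"), "plain,",
      sum(object@kind == "collapsed"), "collapsed ),",
      length(object@roots), "root children\n")
  invisible(object)
})

#' Assemble a rate vector
#'
#' Builds the point r = (lambda, delta, omega) at which edge equations are
#' evaluated: model rates in the lambda slots, `delta` in the dummy slot of
#' the discrete event (when present), and the per-branch-type dummy values
#' in the omega slots.
#'
#' @param g a [StateGraph-class].
#' @param omega numeric scalar (recycled) or vector of length
#'   `branchTypeCount(g@bts)`.
#' @param delta value for the delta slot (used by scalar checks only; the
#'   production path inverts in delta analytically).
#' @return named numeric vector over the graph's rate slots.
#' @export
rateVector <- function(g, omega = 0, delta = 0) {
  model <- g@model
  K <- branchTypeCount(g@bts)
  omega <- rep_len(omega, K)
  mig <- migrationRoutes(model)
  r <- c(unname(coalescenceRates(model)),
         if (nrow(mig)) mig$rate,
         if (!is.na(g@deltaSlot)) delta,
         omega)
  names(r) <- g@slotNames
  r
}

#' Evaluate a single edge equation
#'
#' The transform attached to an edge is the probability that its event
#' happens before all competing processes, including the Poisson marking
#' processes at rates omega: \eqn{f^\star = (p \cdot r)/(q \cdot r)}.
#'
#' @param g a [StateGraph-class].
#' @param eq equation index (column `eq` of `g@edges`).
#' @param r rate vector from [rateVector()].
#' @return numeric scalar in (0, 1] when all omega and delta are zero.
#' @export
evalEdge <- function(g, eq, r) {
  p <- g@eqP[eq, ]
  den <- sum(g@eqQ[eq, ] * r)
  if (den <= 0) stop("degenerate rates: q . r must be positive")
  p[["l"]] * r[[p[["slot"]]]] / den
}

#' Closed-form inverse Laplace transform of a product of simple poles
#'
#' Computes \eqn{L^{-1}[\prod_i 1/(c_i + \delta)](T)} by partial fractions.
#' For pairwise distinct poles this is
#' \eqn{\sum_i e^{-c_i T} \prod_{j \ne i} 1/(c_j - c_i)}. Poles closer than
#' `tol` (relative) are grouped and handled with the confluent higher-order
#' formula, computed through a logarithmic-derivative recursion, so repeated
#' and near-repeated poles are numerically stable. An empty pole set returns
#' 1 (the event at exactly T with no waiting factors).
#'
#' @param c numeric vector of non-delta pole parts (may include 0).
#' @param T evaluation time, >= 0.
#' @param tol relative grouping tolerance for confluent poles.
#' @return numeric scalar.
#' @examples
#' inverseLaplaceProduct(c(1, 2), 1)  # exp(-1) - exp(-2)
#' inverseLaplaceProduct(c(1, 1), 1)  # T * exp(-T) = exp(-1)
#' @export
inverseLaplaceProduct <- function(c, T, tol = 1e-9) {
  if (length(T) != 1L || is.na(T) || T < 0) stop("T must be a single value >= 0")
  if (!length(c)) return(1)
  o <- order(c)
  cs <- c[o]
  # group near-equal poles
  grpVal <- cs[1L]
  vals <- numeric(0)
  mult <- integer(0)
  for (x in cs) {
    if (length(vals) && abs(x - vals[length(vals)]) < tol * max(1, abs(x))) {
      mult[length(mult)] <- mult[length(mult)] + 1L
    } else {
      vals <- c(vals, x)
      mult <- c(mult, 1L)
    }
  }
  terms <- numeric(0)
  for (i in seq_along(vals)) {
    ci <- vals[i]
    mi <- mult[i]
    d <- vals[-i] - ci
    mj <- mult[-i]
    # Taylor coefficients B_r of prod_j (c_j + s)^{-m_j} around s = -c_i,
    # via the logarithmic-derivative recursion with power sums u_s.
    B <- numeric(mi)
    B[1L] <- prod(d^(-mj))
    if (mi > 1L) {
      u <- vapply(seq_len(mi - 1L), function(s) sum(mj / d^s), 0)
      for (r in seq_len(mi - 1L)) {
        s <- seq_len(r)
        B[r + 1L] <- sum((-1)^s * u[s] * B[r + 1L - s]) / r
      }
    }
    p <- mi - seq_len(mi) + 1L   # remaining pole order per coefficient
    terms <- c(terms, B * T^(p - 1L) * exp(-ci * T) / factorial(p - 1L))
  }
  compensatedSum(terms)
}

# Scalar value of one computational node at rate vector r (delta part of q
# removed analytically; T only used for collapsed nodes).
.compNodeValue <- function(cg, i, r, T) {
  g <- cg@graph
  if (cg@kind[i] == "plain") return(evalEdge(g, cg@eq[i], r))
  ds <- g@deltaSlot
  poles <- numeric(0)
  const <- 1
  for (e in cg@prefix[[i]]) {
    eq <- g@edges$eq[e]
    p <- g@eqP[eq, ]
    if (g@eqQ[eq, ds] > 0L) {
      poles <- c(poles, sum(g@eqQ[eq, -ds] * r[-ds]))
      if (p[["slot"]] != ds) const <- const * p[["l"]] * r[[p[["slot"]]]]
      # the delta edge's numerator delta cancels the global 1/delta factor
    } else {
      # pending state whose event is momentarily a no-op: plain factor
      const <- const * evalEdge(g, eq, r)
    }
  }
  if (cg@zeroPole[i]) poles <- c(poles, 0)
  const * inverseLaplaceProduct(poles, T)
}

#' Propagate values through a DAG given as an adjacency list
#'
#' The generic propagation step: in an order that visits children before
#' parents, the values of a node's children are summed and the node's own
#' value is multiplied in; the return value is the sum over the root
#' children. With scalar values and ordinary arithmetic the result equals
#' the sum over all root-to-leaf paths of the product of node values; `add`
#' and `mul` may be replaced by any commutative pair with distributivity
#' (e.g. truncated-series addition and multiplication).
#'
#' @param children adjacency list (integer indices), leaves have length 0.
#' @param roots indices of the virtual root's children.
#' @param values list (or vector) of initial node values.
#' @param add,mul binary operators.
#' @param zero additive identity for `add`.
#' @return the propagated root value.
#' @export
propagateGraph <- function(children, roots, values,
                           add = `+`, mul = `*`, zero = 0) {
  values <- as.list(values)
  for (u in .evalOrder(children)) {
    ch <- children[[u]]
    if (!length(ch)) next
    temp <- zero
    for (v in ch) temp <- add(temp, values[[v]])
    values[[u]] <- mul(temp, values[[u]])
  }
  out <- zero
  for (v in roots) out <- add(out, values[[v]])
  out
}

#' Evaluate the Laplace transform of the joint branch-length distribution
#'
#' Evaluates \eqn{E[\exp(-\sum_k \omega_k L_k)]} at the given dummy-variable
#' point, where \eqn{L_k} is the total length of branch type \eqn{k}. For
#' models with a discrete event the transform is the one already inverted
#' with respect to the event's dummy variable, i.e. conditioned on the event
#' happening at time `T`. At omega = 0 the value is 1 (total probability).
#'
#' @param model a [CoalModel-class] (ignored if `cg` is given).
#' @param omega scalar or per-branch-type vector of dummy values, >= 0.
#' @param T event time; required iff the model has a discrete event.
#' @param phased,rooted branch-type flags.
#' @param cg optionally a pre-built [CompGraph-class] to avoid rebuilding.
#' @return numeric scalar in (0, 1].
#' @examples
#' evaluateLaplace(singleDemeModel(2), omega = 0.5)  # 1/(1+2*0.5) = 0.5
#' @export
evaluateLaplace <- function(model, omega = 0, T = NULL,
                            phased = FALSE, rooted = FALSE, cg = NULL) {
  if (is.null(cg)) cg <- collapseGraph(buildStateGraph(model, phased, rooted))
  g <- cg@graph
  if (is.null(T) && !is.null(splitEvent(g@model))) T <- splitEvent(g@model)$time
  if (!is.na(g@deltaSlot) && is.null(T)) {
    stop("model has a discrete event: supply its time T")
  }
  r <- rateVector(g, omega = omega)
  values <- lapply(seq_len(nNodes(cg)), function(i) .compNodeValue(cg, i, r, if (is.null(T)) 0 else T))
  propagateGraph(cg@children, cg@roots, values)
}
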