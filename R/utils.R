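# Small numeric and graph utilities shared across the package.

#' Compensated (error-free) summation
#'
#' Sums a numeric vector with the Ogita-Rump-Oishi compensated summation
#' scheme: every partial sum is split into its floating-point result and the
#' exact rounding error (Knuth's TwoSum transformation), and the accumulated
#' error term is folded back in at the end. For ill-conditioned sums (large
#' cancellation) this recovers the correctly rounded result where naive
#' left-to-right accumulation in double precision loses all significant
#' digits.
#'
#' @param values numeric vector of finite values.
#' @return length-one numeric, the compensated sum.
#' @examples
#' compensatedSum(c(1e16, 1, -1e16))  # 1, naive accumulation gives 0
#' @export
compensatedSum <- function(values) {
  s <- 0
  err <- 0
  for (x in values) {
    t <- s + x
    bv <- t - s
    err <- err + (s - (t - bv)) + (x - bv)
    s <- t
  }
  s + err
}

# TwoSum on running (sum, err) pairs for elementwise array accumulation:
# returns list(sum, err) such that sum + err == old sum + old err + x exactly
# (per component, up to the usual error-free-transformation guarantee).
.accumCompensated <- function(state, x) {
  s <- state$sum
  t <- s + x
  bv <- t - s
  state$err <- state$err + (s - (t - bv)) + (x - bv)
  state$sum <- t
  state
}

# Evaluation order for a DAG given as a children adjacency list: every node
# appears after all of its children (Kahn's algorithm on reversed edges).
.evalOrder <- function(children) {
  n <- length(children)
  remaining <- vapply(children, length, 1L)
  parents <- vector("list", n)
  for (u in seq_len(n)) {
    for (v in children[[u]]) parents[[v]] <- c(parents[[v]], u)
  }
  queue <- which(remaining == 0L)
  ord <- integer(0)
  while (length(queue)) {
    u <- queue[[1L]]
    queue <- queue[-1L]
    ord <- c(ord, u)
    for (p in parents[[u]]) {
      remaining[[p]] <- remaining[[p]] - 1L
      if (remaining[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (length(ord) != n) stop("graph is cyclic")
  ord
}

# TRUE if the directed edge set (from[i] -> to[i]) over `nodes` has a cycle.
.hasDirectedCycle <- function(from, to, nodes) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (t in to) indeg[[t]] <- indeg[[t]] + 1L
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    u <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (t in to[from == u]) {
      indeg[[t]] <- indeg[[t]] - 1L
      if (indeg[[t]] == 0L) queue <- c(queue, t)
    }
  }
  seen < length(nodes)
}

# Lexicographically smaller of two equal-length integer vectors.
.lexMin <- function(a, b) {
  d <- which(a != b)
  if (!length(d)) return(a)
  if (a[d[1L]] < b[d[1L]]) a else b
}
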