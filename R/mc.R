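# Monte-Carlo estimator of bSFS probabilities: simulate structured
# coalescent genealogies under the identical event semantics as the exact
# engine, record the total branch length per branch type, and average the
# multivariate Poisson probabilities of each mutation configuration across
# replicates. Mutations are never placed; only branch lengths are used, so
# every replicate contributes a probability vector that sums to one exactly
# and the average is an unbiased estimate of the bSFS.

#' Simulate per-branch-type total lengths of one genealogy
#'
#' Draws one structured-coalescent genealogy under the model: waiting times
#' are exponential with the current total rate, the event kind is chosen
#' proportionally to the rates (coalescence at \eqn{\lambda_d {m_d \choose
#' 2}}, migration at the per-lineage route rate), and the discrete event, if
#' any, is applied deterministically at its time T. Between events the
#' elapsed time is added to the total length of every extant lineage's
#' branch type. Uses R's global RNG.
#'
#' @param model a [CoalModel-class].
#' @param bts a [BranchTypeSet-class] for the model (built if missing).
#' @param phased,rooted flags used when `bts` is missing.
#' @return numeric vector of per-branch-type total lengths (coalescent
#'   units of `2 Ne_ref` generations).
#' @export
simulateBranchLengths <- function(model, bts = NULL,
                                  phased = FALSE, rooted = FALSE) {
  if (is.null(bts)) bts <- enumerateBranchTypes(model, phased, rooted)
  demes <- demeNames(model)
  D <- length(demes)
  C <- length(bts@classTotals)
  lambda <- unname(coalescenceRates(model))
  mig <- migrationRoutes(model)
  migFrom <- match(mig$from, demes)
  migTo <- match(mig$to, demes)
  sp <- splitEvent(model)
  spFrom <- if (!is.null(sp)) match(sp$from, demes) else integer(0)
  spTo <- if (!is.null(sp)) match(sp$to, demes) else NA_integer_
  pending <- !is.null(sp)

  # initial lineages, deme-major (same convention as the state graph)
  rows <- list()
  cursor <- 0L
  for (d in seq_len(D)) {
    nd <- sampleCounts(model)[[d]]
    if (nd == 0L) next
    for (s in seq_len(nd)) {
      v <- integer(C)
      if (bts@phased) {
        cursor <- cursor + 1L
        v[cursor] <- 1L
      } else {
        v[match(demes[d], bts@classNames)] <- 1L
      }
      rows[[length(rows) + 1L]] <- c(d, v)
    }
  }
  mat <- do.call(rbind, rows)

  K <- branchTypeCount(bts)
  lens <- numeric(K)
  typeOf <- function(v) get(.btKey(.foldCounts(v, bts)), envir = bts@lookup)
  now <- 0
  while (nrow(mat) > 1L) {
    md <- tabulate(mat[, 1L], nbins = D)
    active <- if (!nrow(mig)) logical(0)
      else if (is.null(sp) || pending) rep(TRUE, nrow(mig))
      else !(migFrom %in% spFrom | migTo %in% spFrom)
    rates <- c(lambda * choose(md, 2L),
               if (nrow(mig)) ifelse(active, md[migFrom] * mig$rate, 0))
    tot <- sum(rates)
    dt <- if (tot > 0) stats::rexp(1L, tot) else Inf
    if (pending && now + dt > sp$time) {
      dt <- sp$time - now
      for (i in seq_len(nrow(mat))) {
        ti <- typeOf(mat[i, -1L])
        lens[ti] <- lens[ti] + dt
      }
      mat[mat[, 1L] %in% spFrom, 1L] <- spTo
      now <- sp$time
      pending <- FALSE
      next
    }
    if (!is.finite(dt)) stop("model deadlocked before the mrca")
    for (i in seq_len(nrow(mat))) {
      ti <- typeOf(mat[i, -1L])
      lens[ti] <- lens[ti] + dt
    }
    now <- now + dt
    ev <- sample.int(length(rates), 1L, prob = rates)
    if (ev <= D) {
      idx <- which(mat[, 1L] == ev)
      pair <- sample(idx, 2L)
      merged <- mat[pair[1L], ]
      merged[-1L] <- mat[pair[1L], -1L] + mat[pair[2L], -1L]
      mat <- rbind(mat[-pair, , drop = FALSE], merged)
    } else {
      r <- ev - D
      idx <- which(mat[, 1L] == migFrom[r])
      mv <- if (length(idx) == 1L) idx else sample(idx, 1L)
      mat[mv, 1L] <- migTo[r]
    }
  }
  lens
}

#' Monte-Carlo estimate of the bSFS
#'
#' Averages, over simulated genealogies, the product over branch types of
#' Poisson probabilities \eqn{P(k_i; (\theta/2) t_i)} (residual bins use
#' the Poisson tail), where \eqn{t_i} is the simulated total length of type
#' i. Replicate r seeds its own RNG stream derived from `(seed, r)`, so
#' increasing `reps` extends rather than reshuffles the estimate.
#'
#' @param model a [CoalModel-class].
#' @param theta scaled block mutation rate, > 0.
#' @param kmax scalar or per-type truncation vector.
#' @param reps number of replicates, >= 1.
#' @param seed integer seed.
#' @param phased,rooted branch-type flags.
#' @return a [ConfigArray-class] with `mode = "mc"` and per-entry standard
#'   errors in `@se`; `@compatible` flags entries observed with positive
#'   probability.
#' @export
estimateBsfs <- function(model, theta, kmax = 2, reps = 1000L, seed = 1L,
                         phased = FALSE, rooted = FALSE) {
  if (theta <= 0) stop("theta must be > 0")
  if (reps < 1L) stop("reps must be >= 1")
  bts <- enumerateBranchTypes(model, phased, rooted)
  K <- branchTypeCount(bts)
  kmax <- as.integer(rep_len(kmax, K))
  dims <- kmax + 2L
  if (prod(as.numeric(dims)) > 1e6) {
    stop("configuration array too large for the dense MC estimator")
  }
  acc <- array(0, dim = dims)
  acc2 <- array(0, dim = dims)
  for (r in seq_len(reps)) {
    set.seed((as.numeric(seed) * 1009 + r) %% 2147483647)
    lens <- simulateBranchLengths(model, bts = bts)
    perType <- lapply(seq_len(K), function(i) {
      lam <- theta / 2 * lens[i]
      c(stats::dpois(0:kmax[i], lam),
        stats::ppois(kmax[i], lam, lower.tail = FALSE))
    })
    p <- Reduce(function(a, b) outer(a, b), perType)
    acc <- acc + p
    acc2 <- acc2 + p * p
  }
  est <- acc / reps
  se <- sqrt(pmax(acc2 / reps - est^2, 0) / reps)
  new("ConfigArray", probs = est, se = array(se, dim = dims),
      kmax = kmax, bts = bts, theta = theta,
      time = if (is.null(splitEvent(model))) NA_real_ else splitEvent(model)$time,
      mode = "mc", compatible = array(est > 0, dim = dims))
}
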