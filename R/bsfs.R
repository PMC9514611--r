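# Exact tabulation of block-wise mutation-configuration probabilities (the
# generalized bSFS). Mutations arrive on branch type i as a Poisson process
# with rate theta/2 per unit branch length, so
#   P(k) = E[ prod_i e^{-(theta/2) L_i} ((theta/2) L_i)^{k_i} / k_i! ]
#        = (-theta/2)^{sum k} * c_k,
# where c_k is the Taylor coefficient of the transform at multi-index k
# around the expansion point omega_i = theta/2. Residual bins (k_i > kmax_i)
# are recovered from marginal tables in which the affected types are
# unmarked (omega_i = 0), combined by inclusion-exclusion.

#' Mutation-configuration probability array
#'
#' @slot probs numeric array of shape `kmax + 2` per branch type; the last
#'   index of each dimension is the ">kmax" residual bin.
#' @slot se matching array of Monte-Carlo standard errors (length-zero array
#'   for exact results).
#' @slot kmax integer truncation vector.
#' @slot bts the [BranchTypeSet-class] giving the dimension order.
#' @slot theta scaled block mutation rate (4 Ne_ref mu per block).
#' @slot time discrete-event time (NA when the model has none).
#' @slot mode "exact" or "mc".
#' @slot compatible logical array marking configurations that are not
#'   structural zeros.
#' @export
setClass("ConfigArray",
  representation(
    probs = "array",
    se = "array",
    kmax = "integer",
    bts = "BranchTypeSet",
    theta = "numeric",
    time = "numeric",
    mode = "character",
    compatible = "array"
  )
)

setValidity("ConfigArray", function(object) {
  msg <- character(0)
  if (!identical(dim(object@probs), dim(object@compatible))) {
    msg <- c(msg, "probs and compatible must share a shape")
  }
  if (any(object@probs < -1e-9) || any(object@probs > 1 + 1e-9)) {
    msg <- c(msg, "probabilities must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ConfigArray-class total probability mass (1 up to float
#'   error for exact results).
#' @param x a `ConfigArray`.
#' @export
setGeneric("totalMass", function(x) standardGeneric("totalMass"))

#' @export
setMethod("totalMass", "ConfigArray", function(x) sum(x@probs))

setMethod("show", "ConfigArray", function(object) {
  cat("ConfigArray (", object@mode, "): ", length(object@probs),
      " entries over ", branchTypeCount(object@bts), " branch types (kmax = ",
      paste(object@kmax, collapse = ","), ")\n", sep = "")
  cat("  stored non-zero slots:", sum(object@compatible),
      "; total mass:", format(totalMass(object), digits = 12), "\n")
  invisible(object)
})

# linear index into an array of extents `dims` for 0-based multi-index k.
.linIndex <- function(k, dims) {
  mult <- c(1, cumprod(dims[-length(dims)]))
  as.integer(sum(k * mult)) + 1L
}

#' Exact block-wise mutation-configuration probabilities
#'
#' Computes the full probability array for all mutation configurations with
#' entries in `0..kmax_i + 1` per branch type by propagating truncated
#' Taylor series through the computational graph. One series propagation is
#' run per subset of branch types that must be unmarked for the residual
#' bins; incompatible configurations (structural zeros) are set to exact 0.
#'
#' @param model a [CoalModel-class].
#' @param theta scaled block mutation rate, > 0 (mutations mark each branch
#'   type at rate `theta/2` per unit branch length).
#' @param kmax scalar or per-type truncation vector.
#' @param T discrete-event time (required iff the model has one).
#' @param phased,rooted branch-type flags.
#' @return a [ConfigArray-class]; entries sum to 1 up to float error.
#' @examples
#' ca <- bsfsProbabilities(singleDemeModel(2), theta = 1, kmax = 3)
#' ca@probs[1:4]  # theta^k/(1+theta)^(k+1) for k = 0..3
#' @export
bsfsProbabilities <- function(model, theta, kmax = 2, T = NULL,
                              phased = FALSE, rooted = FALSE) {
  if (length(theta) != 1L || theta <= 0) stop("theta must be a single value > 0")
  if (is.null(T) && !is.null(splitEvent(model))) T <- splitEvent(model)$time
  g <- buildStateGraph(model, phased, rooted)
  cg <- collapseGraph(g)
  bts <- g@bts
  K <- branchTypeCount(bts)
  kmax <- as.integer(rep_len(kmax, K))
  if (any(kmax < 0L)) stop("kmax entries must be non-negative")
  supports <- compatibleSupports(g)
  dims <- kmax + 2L

  # one probability table per subset U of unmarked types: entries are the
  # within-bound probabilities with types in U integrated out (any count).
  allMasks <- 0:(2^K - 1L)
  bitsOf <- function(U) which(bitwAnd(U, bitwShiftL(1L, 0:(K - 1L))) > 0L)
  probTable <- function(U) {
    un <- bitsOf(U)
    km <- kmax
    at <- rep(theta / 2, K)
    if (length(un)) {
      km[un] <- 0L
      at[un] <- 0
    }
    S <- propagateSeries(cg, kmax = km, at = at, T = T)
    G <- .seriesGrid(km + 1L)
    p <- vapply(seq_len(nrow(G)), function(i) {
      (-theta / 2)^sum(G[i, ]) * as.numeric(S)[i]
    }, 0)
    array(p, dim = km + 1L)
  }
  tables <- new.env(parent = emptyenv())
  getTable <- function(U) {
    key <- as.character(U)
    t <- get0(key, envir = tables)
    if (is.null(t)) {
      t <- probTable(U)
      assign(key, t, envir = tables)
    }
    t
  }

  probs <- array(0, dim = dims)
  compat <- array(FALSE, dim = dims)
  G <- .seriesGrid(dims)
  for (i in seq_len(nrow(G))) {
    k <- G[i, ]
    suppMask <- sum(bitwShiftL(1L, which(k > 0L) - 1L))
    ok <- supports[suppMask + 1L]
    compat[i] <- ok
    if (!ok) next
    S <- which(k == kmax + 1L)               # types in the residual bin
    if (!length(S)) {
      probs[i] <- getTable(0L)[.linIndex(k, kmax + 1L)]
      next
    }
    # inclusion-exclusion over which residual types are within-bound summed
    Smask <- sum(bitwShiftL(1L, S - 1L))
    terms <- numeric(0)
    for (Rmask in allMasks[bitwAnd(allMasks, Smask) == allMasks]) {
      Rset <- bitsOf(Rmask)
      Umask <- Smask - Rmask                 # unmarked types: S minus R
      tab <- getTable(Umask)
      kmU <- kmax
      kmU[bitsOf(Umask)] <- 0L
      # sum the table over k_R = 0..kmax_R with other entries fixed
      fixed <- k
      fixed[bitsOf(Umask)] <- 0L
      idxList <- lapply(seq_len(K), function(j) {
        if (j %in% Rset) 0:kmax[j] else fixed[j]
      })
      cells <- as.matrix(expand.grid(idxList, KEEP.OUT.ATTRS = FALSE))
      vals <- vapply(seq_len(nrow(cells)), function(r) {
        tab[.linIndex(cells[r, ], kmU + 1L)]
      }, 0)
      terms <- c(terms, (-1)^length(Rset) * compensatedSum(vals))
    }
    probs[i] <- compensatedSum(terms)
  }
  # numerical dust below zero is clamped; structural zeros are exact by mask
  probs[probs < 0 & probs > -1e-10] <- 0
  new("ConfigArray", probs = probs, se = array(numeric(0)),
      kmax = kmax, bts = bts, theta = theta,
      time = if (is.null(T)) NA_real_ else T,
      mode = "exact", compatible = compat)
}

#' Write a configuration array as TSV
#'
#' One row per compatible configuration: per-branch-type counts (the
#' residual bin printed as `kmax + 1`), the probability, and for
#' Monte-Carlo estimates the standard error. Header lines (prefixed `#`)
#' record the branch-type order, flags, theta and kmax.
#'
#' @param x a [ConfigArray-class].
#' @param file path or connection.
#' @export
writeConfigTSV <- function(x, file = "") {
  K <- branchTypeCount(x@bts)
  G <- .seriesGrid(dim(x@probs))
  keep <- as.logical(x@compatible)
  hdr <- c(
    paste0("# branch types: ", paste(x@bts@labels, collapse = "\t")),
    paste0("# phased: ", x@bts@phased, "; rooted: ", x@bts@rooted),
    paste0("# theta: ", x@theta, "; kmax: ", paste(x@kmax, collapse = ","),
           if (!is.na(x@time)) paste0("; T: ", x@time)),
    paste0("# mode: ", x@mode))
  cols <- c(x@bts@labels, "probability", if (length(x@se)) "se")
  body <- cbind(G[keep, , drop = FALSE],
                formatC(x@probs[keep], digits = 17, format = "g"))
  if (length(x@se)) body <- cbind(body, formatC(x@se[keep], digits = 8, format = "g"))
  lines <- c(hdr, paste(cols, collapse = "\t"),
             apply(body, 1L, paste, collapse = "\t"))
  writeLines(lines, con = file)
  invisible(lines)
}
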