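# Mutation configurations: vectors k = (k_1 .. k_K) of per-branch-type
# mutation counts within a block, each entry in 0..kmax_i+1 with the last
# bin aggregating all outcomes above kmax_i. Many configurations are
# structural zeros: their positively counted branch types can never jointly
# occur along a genealogy. Compatibility is decided at the level of
# branch-type SUPPORT sets (bitmasks), by a single backwards sweep over the
# state graph, and then expanded to configurations; this avoids touching the
# full prod(kmax_i + 2) array.

# bitmask of branch types present in a state (the mrca branch has no type).
.stateSupport <- function(g, u) {
  mat <- g@nodes[[u]]
  bts <- g@bts
  mask <- 0L
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, -1L]
    if (all(v == bts@classTotals)) next
    ti <- get0(.btKey(.foldCounts(v, bts)), envir = bts@lookup)
    mask <- bitwOr(mask, bitwShiftL(1L, ti - 1L))
  }
  mask
}

#' Compatible branch-type support sets
#'
#' A support set U of branch types is compatible when at least one
#' root-to-absorption path visits, for every type in U, a state containing a
#' lineage of that type. Computed by dynamic programming over states
#' (children before parents): a set U is realizable from a state s iff
#' U minus the types present in s is realizable from one of its children.
#' The result is downward closed (shrinking the support keeps it
#' compatible).
#'
#' @param g a [StateGraph-class].
#' @return logical vector of length `2^K` indexed by support bitmask + 1
#'   (bit i-1 = branch type i).
#' @export
compatibleSupports <- function(g) {
  K <- branchTypeCount(g@bts)
  if (K > 20L) stop("support enumeration limited to 20 branch types")
  M <- bitwShiftL(1L, K)
  allMasks <- 0:(M - 1L)
  nn <- length(g@nodes)
  reach <- vector("list", nn)
  childrenOf <- lapply(seq_len(nn), function(u) unique(g@edges$child[g@outEdges[[u]]]))
  base <- c(TRUE, rep(FALSE, M - 1L))
  for (u in .nodeOrder(g)) {
    ch <- childrenOf[[u]]
    if (!length(ch)) {
      reach[[u]] <- base
      next
    }
    supp <- .stateSupport(g, u)
    remap <- bitwAnd(allMasks, bitwNot(supp)) + 1L
    acc <- rep(FALSE, M)
    for (v in ch) acc <- acc | reach[[v]][remap]
    reach[[u]] <- acc
  }
  reach[[1L]]
}

#' Compatible mutation configurations
#'
#' Counts (and optionally enumerates) the mutation configurations with
#' non-zero probability for a graph and truncation vector: a configuration
#' is compatible iff its set of positive entries (residual bins included) is
#' a compatible support. The all-zero configuration is always compatible.
#'
#' @param g a [StateGraph-class].
#' @param kmax scalar or per-type truncation vector.
#' @param enumerate also return the configurations as an integer matrix
#'   (one row per configuration; entries 0..kmax+1)?
#' @return list with `count`, `supports` (logical by bitmask), and when
#'   requested `configs`.
#' @export
compatibleConfigurations <- function(g, kmax, enumerate = FALSE) {
  K <- branchTypeCount(g@bts)
  kmax <- as.integer(rep_len(kmax, K))
  ok <- compatibleSupports(g)
  masks <- which(ok) - 1L
  bits <- function(m) which(bitwAnd(m, bitwShiftL(1L, 0:(K - 1L))) > 0L)
  sizes <- vapply(masks, function(m) prod((kmax + 1)[bits(m)]), 0)
  out <- list(count = sum(sizes), supports = ok)
  if (enumerate) {
    rowsPerMask <- lapply(masks, function(m) {
      b <- bits(m)
      if (!length(b)) return(matrix(0L, 1L, K))
      vals <- expand.grid(lapply(b, function(i) seq_len(kmax[i] + 1L)),
                          KEEP.OUT.ATTRS = FALSE)
      cfg <- matrix(0L, nrow(vals), K)
      for (j in seq_along(b)) cfg[, b[j]] <- as.integer(vals[[j]])
      cfg
    })
    cfgs <- do.call(rbind, rowsPerMask)
    colnames(cfgs) <- g@bts@labels
    out$configs <- cfgs
  }
  out
}

#' Storage layout for a mutation-configuration array
#'
#' Describes the full array of size `prod(kmax + 2)` and the subset of
#' slots actually stored. Up to `denseLimit` slots a dense logical mask is
#' kept; above it only the compatible configurations are indexed (hash map
#' from configuration key to storage slot), with incompatible entries
#' readable as exact zero.
#'
#' @param kmax per-branch-type truncation vector (entries >= 0).
#' @param supports logical compatibility vector from [compatibleSupports()].
#' @param denseLimit switch-over size for the dense representation.
#' @return list with `dims`, `size`, `storage` ("dense" or "indexed"), and
#'   `mask` (dense logical array) or `index` (environment) plus `nStored`.
#' @export
configArrayLayout <- function(kmax, supports, denseLimit = 1e7) {
  kmax <- as.integer(kmax)
  if (any(kmax < 0L)) stop("kmax entries must be non-negative")
  K <- length(kmax)
  dims <- kmax + 2L
  size <- prod(as.numeric(dims))
  supportOf <- function(cfg) {
    sum(bitwShiftL(1L, which(cfg > 0L) - 1L))
  }
  if (size <= denseLimit) {
    G <- .seriesGrid(dims)
    m <- vapply(seq_len(nrow(G)), function(i) supports[supportOf(G[i, ]) + 1L], TRUE)
    list(dims = dims, size = size, storage = "dense",
         mask = array(m, dim = dims), nStored = sum(m))
  } else {
    idx <- new.env(parent = emptyenv())
    n <- 0L
    masks <- which(supports) - 1L
    bits <- function(mm) which(bitwAnd(mm, bitwShiftL(1L, 0:(K - 1L))) > 0L)
    for (mm in masks) {
      b <- bits(mm)
      vals <- if (length(b)) {
        as.matrix(expand.grid(lapply(b, function(i) seq_len(kmax[i] + 1L)),
                              KEEP.OUT.ATTRS = FALSE))
      } else matrix(integer(0), 1L, 0L)
      for (r in seq_len(nrow(vals))) {
        cfg <- integer(K)
        if (length(b)) cfg[b] <- vals[r, ]
        n <- n + 1L
        assign(paste(cfg, collapse = "_"), n, envir = idx)
      }
    }
    list(dims = dims, size = size, storage = "indexed", index = idx, nStored = n)
  }
}

#' Classes of equiprobable mutation configurations (phased samples)
#'
#' The coalescent is exchangeable over samples within a deme, so
#' configurations that differ only by a permutation of same-deme sample
#' labels have identical probability. Given phased branch types, this
#' returns the induced permutation group on type indices and assigns each
#' supplied configuration to its orbit (class), keyed by the
#' lexicographically smallest permuted configuration. With unphased types
#' the labels already collapse the symmetry and the partition is the
#' identity.
#'
#' @param bts a [BranchTypeSet-class].
#' @param configs integer matrix, one configuration per row (columns =
#'   branch types).
#' @return list with `classKey` (character per row), `representative`
#'   (logical per row: first member of its class), and `typePerms` (matrix
#'   of type permutations, one row per group element).
#' @export
equiprobableClasses <- function(bts, configs) {
  configs <- as.matrix(configs)
  K <- branchTypeCount(bts)
  stopifnot(ncol(configs) == K)
  if (!bts@phased) {
    key <- apply(configs, 1L, paste, collapse = "_")
    return(list(classKey = key, representative = !duplicated(key),
                typePerms = matrix(seq_len(K), 1L)))
  }
  # per-deme blocks of origin classes (classNames are deme-major labels)
  demeOf <- sub("[0-9]+$", "", bts@classNames)
  blocks <- split(seq_along(bts@classNames), demeOf)
  permsOf <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in permsOf(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  blockPerms <- lapply(blocks, permsOf)
  combos <- expand.grid(lapply(blockPerms, seq_along), KEEP.OUT.ATTRS = FALSE)
  typePerms <- matrix(0L, nrow(combos), K)
  for (gi in seq_len(nrow(combos))) {
    colPerm <- integer(length(bts@classNames))
    for (b in seq_along(blocks)) {
      colPerm[blocks[[b]]] <- blockPerms[[b]][[combos[gi, b]]]
    }
    for (t in seq_len(K)) {
      img <- .foldCounts(bts@counts[t, colPerm], bts)
      typePerms[gi, t] <- get(.btKey(img), envir = bts@lookup)
    }
  }
  classKey <- character(nrow(configs))
  for (r in seq_len(nrow(configs))) {
    best <- NULL
    for (gi in seq_len(nrow(typePerms))) {
      moved <- integer(K)
      moved[typePerms[gi, ]] <- configs[r, ]
      best <- if (is.null(best)) moved else .lexMin(best, moved)
    }
    classKey[r] <- paste(best, collapse = "_")
  }
  list(classKey = classKey,
       representative = !duplicated(classKey),
       typePerms = typePerms)
}
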