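# Recursive generation of the coalescent state-space graph. A state is the
# per-deme collection of extant ancestral lineages; transitions are
# coalescence (within a deme), unidirectional migration (one lineage moves
# along a declared route) and the optional discrete event (all lineages in
# the source demes move at once into the destination). Each edge carries an
# equation: the Laplace transform of the waiting time to that event given
# the competing processes, stored as a pair of integer coefficient vectors
# (p, q) against the global rate vector r = (lambda, delta, omega).

#' Coalescent state-space graph
#'
#' @slot model the [CoalModel-class] the graph was built from.
#' @slot bts the [BranchTypeSet-class] used for the omega slots.
#' @slot nodes list of state matrices; row = lineage, column 1 = deme index,
#'   remaining columns = per-origin-class subtended sample counts. Node 1 is
#'   the sampling configuration.
#' @slot pending logical per node: TRUE while the discrete event has not yet
#'   fired (always FALSE for models without one).
#' @slot edges data.frame with columns `parent`, `child`, `eq`, `slot`, `l`,
#'   `delta` (edge realizes the discrete event).
#' @slot eqP two-column integer matrix (`slot`, `l`): the one-hot numerator
#'   of each unique equation.
#' @slot eqQ integer matrix, one row per unique equation: the full
#'   denominator coefficient vector over (lambda slots, delta, omega slots).
#' @slot slotNames names of the rate-vector slots (lambda/delta then omega).
#' @slot deltaSlot index of the delta slot (NA when no discrete event).
#' @slot outEdges list: edge indices leaving each node.
#' @slot absorbing indices of absorbing (single-lineage) states.
#' @export
setClass("StateGraph",
  representation(
    model = "CoalModel",
    bts = "BranchTypeSet",
    nodes = "list",
    pending = "logical",
    edges = "data.frame",
    eqP = "matrix",
    eqQ = "matrix",
    slotNames = "character",
    deltaSlot = "integer",
    outEdges = "list",
    absorbing = "integer"
  )
)

.canonState <- function(mat) {
  keys <- apply(mat, 1L, paste, collapse = ",")
  o <- order(keys)
  list(mat = mat[o, , drop = FALSE], key = paste(keys[o], collapse = ";"))
}

#' Build the state-space graph of a model
#'
#' Starting from the sampling configuration the graph is generated
#' recursively: all state transitions depend only on the current lineage
#' configuration and the set of competing processes. States that are
#' identical after canonical (sorted) multiset encoding are merged, which is
#' what keeps the graph polynomially smaller than the space of labeled
#' histories. Node numbering is BFS discovery order (node 1 = root); edge
#' and equation numbering is discovery order, with equations deduplicated by
#' their (p, q) value in a global table.
#'
#' The discrete event is treated as a competing exponential process with a
#' dummy rate delta: every state reachable before the event has fired emits
#' a delta edge (unless the event would be a no-op because its source demes
#' are empty), and the delta slot of q counts the event among the competing
#' processes. After the event has fired, migration routes involving a source
#' deme of the event are disabled.
#'
#' @param model a [CoalModel-class].
#' @param phased,rooted flags passed to [enumerateBranchTypes()].
#' @param bts optionally a pre-built [BranchTypeSet-class] (overrides flags).
#' @return a [StateGraph-class].
#' @examples
#' g <- buildStateGraph(twoDemeMigrationModel(2))
#' nNodes(g)  # 30
#' @export
buildStateGraph <- function(model, phased = FALSE, rooted = FALSE, bts = NULL) {
  stopifnot(validObject(model))
  if (is.null(bts)) bts <- enumerateBranchTypes(model, phased, rooted)
  demes <- demeNames(model)
  D <- length(demes)
  C <- length(bts@classTotals)
  K <- branchTypeCount(bts)
  mig <- migrationRoutes(model)
  R <- nrow(mig)
  sp <- splitEvent(model)
  hasDelta <- !is.null(sp)
  nSlots <- D + R + as.integer(hasDelta)
  deltaSlot <- if (hasDelta) nSlots else NA_integer_
  slotNames <- c(paste0("C_", demes),
                 if (R) paste0("M_", mig$from, "_", mig$to),
                 if (hasDelta) "delta",
                 paste0("w_", bts@labels))
  migFromIdx <- match(mig$from, demes)
  migToIdx <- match(mig$to, demes)
  spFromIdx <- if (hasDelta) match(sp$from, demes) else integer(0)
  spToIdx <- if (hasDelta) match(sp$to, demes) else NA_integer_
  # can a migration route repopulate an emptied split source?
  refillable <- hasDelta && any(mig$to %in% sp$from)

  # --- sampling configuration ---------------------------------------------
  rows <- list()
  classCursor <- 0L
  for (d in seq_len(D)) {
    nd <- sampleCounts(model)[[d]]
    if (nd == 0L) next
    for (s in seq_len(nd)) {
      v <- integer(C)
      if (bts@phased) {
        classCursor <- classCursor + 1L
        v[classCursor] <- 1L
      } else {
        v[match(demes[d], bts@classNames)] <- 1L
      }
      rows[[length(rows) + 1L]] <- c(d, v)
    }
  }
  root <- do.call(rbind, rows)

  # --- bookkeeping ---------------------------------------------------------
  nodes <- vector("list", 512L)
  pend <- logical(512L)
  nNode <- 0L
  keyEnv <- new.env(parent = emptyenv())
  eqEnv <- new.env(parent = emptyenv())
  eqPs <- list()
  eqQs <- list()

  canonPending <- function(mat, pending) {
    if (!hasDelta) return(FALSE)
    if (pending && !refillable && !any(mat[, 1L] %in% spFromIdx)) return(FALSE)
    pending
  }
  addNode <- function(mat, pending) {
    pending <- canonPending(mat, pending)
    cs <- .canonState(mat)
    key <- paste0(cs$key, if (pending) "|P" else "|F")
    idx <- get0(key, envir = keyEnv)
    if (!is.null(idx)) return(idx)
    nNode <<- nNode + 1L
    if (nNode > length(nodes)) {
      length(nodes) <<- 2L * length(nodes)
      length(pend) <<- length(nodes)
    }
    nodes[[nNode]] <<- cs$mat
    pend[[nNode]] <<- pending
    assign(key, nNode, envir = keyEnv)
    nNode
  }
  eqIndex <- function(slot, l, q) {
    key <- paste(slot, l, paste(q, collapse = ","), sep = "|")
    idx <- get0(key, envir = eqEnv)
    if (!is.null(idx)) return(idx)
    idx <- length(eqPs) + 1L
    eqPs[[idx]] <<- c(slot, l)
    eqQs[[idx]] <<- q
    assign(key, idx, envir = eqEnv)
    idx
  }

  routeActive <- function(pending) {
    if (!R) return(logical(0))
    if (!hasDelta || pending) return(rep(TRUE, R))
    !(migFromIdx %in% spFromIdx | migToIdx %in% spFromIdx)
  }

  stateQ <- function(mat, pending, md, active) {
    q <- integer(nSlots + K)
    q[seq_len(D)] <- as.integer(choose(md, 2L))
    if (R) q[D + which(active)] <- md[migFromIdx[active]]
    if (hasDelta && pending && any(md[spFromIdx] > 0L)) q[deltaSlot] <- 1L
    for (i in seq_len(nrow(mat))) {
      ti <- get0(.btKey(.foldCounts(mat[i, -1L], bts)), envir = bts@lookup)
      if (is.null(ti)) stop("internal: lineage without branch type")
      q[nSlots + ti] <- q[nSlots + ti] + 1L
    }
    q
  }

  expandNode <- function(mat, pending, md, active) {
    out <- list()
    emit <- function(child, slot, l, childPending) {
      out[[length(out) + 1L]] <<- list(mat = child, slot = slot, l = l,
                                       pending = childPending)
    }
    # coalescence: all unordered pairs within a deme, identical outcomes merged
    for (d in which(md >= 2L)) {
      idx <- which(mat[, 1L] == d)
      acc <- new.env(parent = emptyenv())
      mats <- list()
      for (a in seq_len(length(idx) - 1L)) {
        for (b in seq.int(a + 1L, length(idx))) {
          i <- idx[a]; j <- idx[b]
          merged <- mat[i, ]
          merged[-1L] <- mat[i, -1L] + mat[j, -1L]
          child <- rbind(mat[-c(i, j), , drop = FALSE], merged)
          cs <- .canonState(child)
          cnt <- get0(cs$key, envir = acc)
          if (is.null(cnt)) {
            assign(cs$key, 1L, envir = acc)
            mats[[cs$key]] <- cs$mat
          } else {
            assign(cs$key, cnt + 1L, envir = acc)
          }
        }
      }
      for (key in names(mats)) {
        emit(mats[[key]], d, get(key, envir = acc), pending)
      }
    }
    # migration: one lineage moves; lineages with identical labels pooled
    for (r in which(active)) {
      src <- which(mat[, 1L] == migFromIdx[r])
      if (!length(src)) next
      keys <- apply(mat[src, -1L, drop = FALSE], 1L, paste, collapse = ",")
      for (grp in split(src, keys)) {
        child <- mat
        child[grp[1L], 1L] <- migToIdx[r]
        emit(child, D + r, length(grp), pending)
      }
    }
    # discrete event: all lineages in the source demes move to the destination
    if (hasDelta && pending && any(md[spFromIdx] > 0L)) {
      child <- mat
      child[child[, 1L] %in% spFromIdx, 1L] <- spToIdx
      emit(child, deltaSlot, 1L, FALSE)
    }
    out
  }

  # --- BFS -----------------------------------------------------------------
  addNode(root, hasDelta)
  eParent <- vector("list", 512L)
  eChild <- vector("list", 512L)
  eEq <- vector("list", 512L)
  eSlot <- vector("list", 512L)
  eL <- vector("list", 512L)
  u <- 0L
  while (u < nNode) {
    u <- u + 1L
    mat <- nodes[[u]]
    if (nrow(mat) == 1L) next  # absorbing: the mrca
    if (u > length(eParent)) {
      for (nm in c("eParent", "eChild", "eEq", "eSlot", "eL")) {
        assign(nm, {x <- get(nm); length(x) <- 2L * max(length(x), u); x})
      }
    }
    pending <- pend[[u]]
    md <- tabulate(mat[, 1L], nbins = D)
    active <- routeActive(pending)
    q <- stateQ(mat, pending, md, active)
    trans <- expandNode(mat, pending, md, active)
    if (!length(trans)) {
      stop("model has a state with no outgoing events before the mrca; ",
           "the sample cannot find a common ancestor under this model")
    }
    ch <- integer(length(trans)); eq <- integer(length(trans))
    sl <- integer(length(trans)); ll <- integer(length(trans))
    for (i in seq_along(trans)) {
      tr <- trans[[i]]
      ch[i] <- addNode(tr$mat, tr$pending)
      eq[i] <- eqIndex(tr$slot, tr$l, q)
      sl[i] <- tr$slot
      ll[i] <- tr$l
    }
    eParent[[u]] <- rep.int(u, length(trans))
    eChild[[u]] <- ch
    eEq[[u]] <- eq
    eSlot[[u]] <- sl
    eL[[u]] <- ll
  }
  nodes <- nodes[seq_len(nNode)]
  pend <- pend[seq_len(nNode)]
  edges <- data.frame(parent = unlist(eParent), child = unlist(eChild),
                      eq = unlist(eEq), slot = unlist(eSlot), l = unlist(eL))
  edges$delta <- !is.na(deltaSlot) & edges$slot == deltaSlot
  outEdges <- vector("list", nNode)
  byParent <- split(seq_len(nrow(edges)), factor(edges$parent, levels = seq_len(nNode)))
  for (i in seq_len(nNode)) outEdges[[i]] <- byParent[[i]]
  eqP <- do.call(rbind, eqPs)
  colnames(eqP) <- c("slot", "l")
  eqQ <- do.call(rbind, eqQs)
  colnames(eqQ) <- slotNames
  g <- new("StateGraph", model = model, bts = bts,
           nodes = nodes, pending = pend, edges = edges,
           eqP = eqP, eqQ = eqQ, slotNames = slotNames,
           deltaSlot = deltaSlot, outEdges = outEdges,
           absorbing = which(vapply(nodes, nrow, 1L) == 1L))
  .nodeOrder(g)  # errors if the construction ever produced a cycle
  g
}

# children-before-parents order over graph nodes (absorbing states first).
.nodeOrder <- function(g) {
  children <- lapply(seq_len(length(g@nodes)), function(u) {
    unique(g@edges$child[g@outEdges[[u]]])
  })
  .evalOrder(children)
}

#' @describeIn StateGraph-class number of states.
#' @param x,object a `StateGraph`.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @export
setMethod("nNodes", "StateGraph", function(x) length(x@nodes))

#' @describeIn StateGraph-class number of edges.
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @export
setMethod("nEdges", "StateGraph", function(x) nrow(x@edges))

#' Number of root-to-absorption paths
#'
#' Counted by dynamic programming without enumerating paths.
#' @param g a [StateGraph-class].
#' @return numeric path count.
#' @export
pathCount <- function(g) {
  cnt <- numeric(length(g@nodes))
  cnt[g@absorbing] <- 1
  for (u in .nodeOrder(g)) {
    es <- g@outEdges[[u]]
    if (length(es)) cnt[u] <- sum(cnt[g@edges$child[es]])
  }
  cnt[1L]
}

#' Enumerate all root-to-absorption paths
#'
#' @param g a [StateGraph-class].
#' @param limit abort if more than this many paths exist.
#' @return list of integer vectors of edge indices.
#' @export
enumeratePaths <- function(g, limit = 1e5) {
  if (pathCount(g) > limit) stop("more than ", limit, " paths; raise `limit`")
  res <- list()
  walk <- function(u, path) {
    es <- g@outEdges[[u]]
    if (!length(es)) {
      res[[length(res) + 1L]] <<- path
      return(invisible())
    }
    for (e in es) walk(g@edges$child[e], c(path, e))
  }
  walk(1L, integer(0))
  res
}

.stateLabel <- function(mat, demes) {
  paste(vapply(seq_along(demes), function(d) {
    rows <- which(mat[, 1L] == d)
    inner <- paste(apply(mat[rows, -1L, drop = FALSE], 1L, paste, collapse = ""),
                   collapse = ",")
    paste0(demes[d], ":[", inner, "]")
  }, ""), collapse = " ")
}

#' Export a state graph as DOT text (debugging aid)
#'
#' Node labels show the lineage configuration per deme (each lineage printed
#' as its origin-class count vector); edge labels give the equation index.
#'
#' @param g a [StateGraph-class].
#' @param file connection or file name ("" prints to stdout).
#' @export
exportDOT <- function(g, file = "") {
  demes <- demeNames(g@model)
  labs <- vapply(g@nodes, .stateLabel, "", demes = demes)
  lines <- c("digraph stategraph {",
             sprintf("  n%d [label=\"%s%s\"];", seq_along(labs), labs,
                     ifelse(g@pending, "", ifelse(rep(!is.na(g@deltaSlot), length(labs)), " *", ""))),
             sprintf("  n%d -> n%d [label=\"e%d\"];",
                     g@edges$parent, g@edges$child, g@edges$eq),
             "}")
  writeLines(lines, con = file)
  invisible(lines)
}

setMethod("show", "StateGraph", function(object) {
  cat("StateGraph:", length(object@nodes), "nodes,", nrow(object@edges),
      "edges,", nrow(object@eqQ), "unique equations\n")
  cat("  model:", length(object@model@demes), "deme(s);",
      if (!is.na(object@deltaSlot)) "one discrete event;" else "no discrete event;",
      branchTypeCount(object@bts), "branch types\n")
  invisible(object)
})
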