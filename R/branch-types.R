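# Branch types: equivalence classes of genealogy branches labeled by the
# samples they subtend. A lineage is represented throughout the package as an
# integer vector of per-origin-class subtended sample counts: with phase
# information every sample is its own origin class (so the count vector is a
# 0/1 subset indicator); without phase, samples are labeled by the deme they
# were collected from and the classes are the sampled demes. Root (ancestral
# state) information is discarded by folding each type with its complement
# relative to the full sample.

#' Set of distinguishable branch types
#'
#' @slot counts integer matrix, one row per canonical branch type, one column
#'   per origin class; entry = number of subtended samples from that class.
#' @slot labels character labels (underscore-joined counts, in the class
#'   order given by `classNames`).
#' @slot phased,rooted logical flags the set was built with.
#' @slot classNames names of the origin classes (deme names, or deme-major
#'   sample labels such as `a1` when phased).
#' @slot classTotals total sample count per origin class.
#' @slot lookup environment mapping a count-vector key to its canonical type
#'   index (both members of a folded pair map to the shared index).
#' @export
setClass("BranchTypeSet",
  representation(
    counts = "matrix",
    labels = "character",
    phased = "logical",
    rooted = "logical",
    classNames = "character",
    classTotals = "integer",
    lookup = "environment"
  )
)

.btKey <- function(counts) paste(counts, collapse = "_")

#' Enumerate the branch types of a model
#'
#' For a phased, rooted sample of size \eqn{n} there are \eqn{2^n - 2} types
#' (every non-empty proper subset of the samples). Unphased samples are
#' labeled by their deme of origin, which collapses types to per-deme
#' subtended-count vectors. Discarding root information folds each type with
#' its complement relative to the full sample; the canonical representative
#' of a folded pair is the lexicographically smaller count vector, and the
#' set is ordered lexicographically. Each branch type receives one dummy
#' variable in the Laplace transform of the branch-length distribution.
#'
#' @param model a [CoalModel-class].
#' @param phased keep the identity of individual samples?
#' @param rooted keep root information (no complement folding)?
#' @return a [BranchTypeSet-class].
#' @examples
#' enumerateBranchTypes(singleDemeModel(3), phased = TRUE, rooted = TRUE)
#' @export
enumerateBranchTypes <- function(model, phased = FALSE, rooted = FALSE) {
  n <- sum(sampleCounts(model))
  if (n < 2L) stop("invalid model: at least two samples are required")
  if (phased) {
    sampled <- demeNames(model)[sampleCounts(model) > 0L]
    classNames <- unlist(lapply(sampled, function(d) {
      paste0(tolower(d), seq_len(sampleCounts(model)[[d]]))
    }))
    classTotals <- rep(1L, length(classNames))
  } else {
    classNames <- demeNames(model)[sampleCounts(model) > 0L]
    classTotals <- unname(sampleCounts(model)[classNames])
  }
  grid <- as.matrix(expand.grid(lapply(classTotals, function(m) 0:m),
                                KEEP.OUT.ATTRS = FALSE))
  dimnames(grid) <- NULL
  storage.mode(grid) <- "integer"
  keep <- rowSums(grid) > 0L & rowSums(grid) < n
  grid <- grid[keep, , drop = FALSE]
  if (!rooted) {
    reps <- grid
    for (i in seq_len(nrow(grid))) {
      reps[i, ] <- .lexMin(grid[i, ], classTotals - grid[i, ])
    }
    grid <- unique(reps)
  }
  ord <- do.call(order, as.data.frame(grid))
  grid <- grid[ord, , drop = FALSE]
  lookup <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(grid))) {
    v <- grid[i, ]
    assign(.btKey(v), i, envir = lookup)
    if (!rooted) assign(.btKey(classTotals - v), i, envir = lookup)
  }
  new("BranchTypeSet",
      counts = grid,
      labels = apply(grid, 1L, paste, collapse = "_"),
      phased = phased, rooted = rooted,
      classNames = classNames, classTotals = classTotals,
      lookup = lookup)
}

#' Number of branch types
#' @param x a [BranchTypeSet-class].
#' @export
setGeneric("branchTypeCount", function(x) standardGeneric("branchTypeCount"))

#' @export
setMethod("branchTypeCount", "BranchTypeSet", function(x) nrow(x@counts))

setMethod("show", "BranchTypeSet", function(object) {
  cat("BranchTypeSet:", nrow(object@counts), "types,",
      if (object@phased) "phased" else "unphased",
      if (object@rooted) "rooted" else "unrooted (folded)", "\n")
  cat("  classes:", paste0(object@classNames, "(", object@classTotals, ")",
                           collapse = " "), "\n")
  cat("  types:", paste(object@labels, collapse = " "), "\n")
  invisible(object)
})

#' Canonical index of a lineage's branch type
#'
#' Maps a lineage, given as its per-origin-class subtended-count vector, to
#' the index of its canonical branch type. In unrooted mode a lineage and its
#' complement share an index (the folding map is an involution). A lineage
#' subtending the full sample is the root (mrca) branch and carries no type.
#'
#' @param counts integer vector of subtended-sample counts per origin class.
#' @param bts a [BranchTypeSet-class].
#' @return integer type index.
#' @export
branchTypeIndex <- function(counts, bts) {
  counts <- as.integer(counts)
  if (length(counts) != length(bts@classTotals)) {
    stop("count vector length does not match the origin classes")
  }
  if (any(counts < 0L) || any(counts > bts@classTotals)) {
    stop("count vector outside the sampled range")
  }
  if (all(counts == 0L)) stop("empty lineage has no branch type")
  if (all(counts == bts@classTotals)) {
    stop("root lineage (full sample): no branch type")
  }
  idx <- get0(.btKey(counts), envir = bts@lookup)
  if (is.null(idx)) stop("unknown branch type: ", .btKey(counts))
  idx
}

# Fold a count vector onto its canonical representative (identity if rooted).
.foldCounts <- function(counts, bts) {
  if (bts@rooted) counts else .lexMin(counts, bts@classTotals - counts)
}
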