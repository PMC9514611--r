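#' @import methods
NULL

#' Structured-coalescent demographic model
#'
#' An S4 container for a demographic model: a set of demes with relative
#' effective sizes, per-deme sample counts, continuous unidirectional
#' migration routes, and at most one discrete event (a population split,
#' viewed backwards in time as a mass migration of all lineages from the
#' source demes into the destination deme at a fixed time).
#'
#' Coalescence rates are expressed relative to a reference deme: the pairwise
#' coalescence rate in deme \eqn{d} is \eqn{\lambda_d = N_{ref} / N_d}, and
#' one unit of time corresponds to \eqn{2 N_{ref}} generations. Migration
#' rates are per-lineage rates on the same time scale.
#'
#' @slot demes character vector of deme identifiers.
#' @slot sizes numeric, effective size of each deme (any common scale).
#' @slot samples integer, number of sampled lineages per deme.
#' @slot reference identifier of the reference deme.
#' @slot migration data.frame with columns `from`, `to`, `rate`.
#' @slot split empty list, or `list(from =, to =, time =)` for the single
#'   discrete event (`from` may name several source demes).
#' @slot lambda numeric, derived coalescence rates \eqn{N_{ref}/N_d}.
#'
#' @seealso [coalModel()], [twoDemeMigrationModel()], [twoDemeIMModel()]
#' @export
setClass("CoalModel",
  representation(
    demes = "character",
    sizes = "numeric",
    samples = "integer",
    reference = "character",
    migration = "data.frame",
    split = "list",
    lambda = "numeric"
  )
)

setValidity("CoalModel", function(object) {
  msg <- character(0)
  d <- object@demes
  if (anyDuplicated(d)) msg <- c(msg, "duplicated deme names")
  if (length(object@sizes) != length(d) || !all(object@sizes > 0)) {
    msg <- c(msg, "one strictly positive relative size per deme is required")
  }
  if (length(object@samples) != length(d) || any(object@samples < 0L)) {
    msg <- c(msg, "sample counts must be non-negative")
  }
  if (sum(object@samples) < 2L) msg <- c(msg, "total sample size must be at least 2")
  if (length(object@reference) != 1L || !(object@reference %in% d)) {
    msg <- c(msg, "reference deme must be one of the model demes")
  }
  mig <- object@migration
  if (nrow(mig)) {
    if (!all(c("from", "to", "rate") %in% names(mig))) {
      msg <- c(msg, "migration must have columns from, to, rate")
    } else {
      if (!all(mig$from %in% d) || !all(mig$to %in% d)) {
        msg <- c(msg, "migration route names an unknown deme")
      }
      if (any(mig$from == mig$to)) msg <- c(msg, "migration route from a deme to itself")
      if (!all(mig$rate > 0)) msg <- c(msg, "migration rates must be strictly positive")
      if (anyDuplicated(paste(mig$from, mig$to))) msg <- c(msg, "duplicated migration route")
      if (all(mig$from %in% d) && all(mig$to %in% d) &&
          .hasDirectedCycle(mig$from, mig$to, d)) {
        msg <- c(msg, "migration routes form a directed cycle (unsupported)")
      }
    }
  }
  sp <- object@split
  if (length(sp)) {
    if (!all(c("from", "to", "time") %in% names(sp))) {
      msg <- c(msg, "split must have entries from, to, time")
    } else {
      if (!all(sp$from %in% d) || length(sp$to) != 1L || !(sp$to %in% d)) {
        msg <- c(msg, "split event names an unknown deme")
      }
      if (sp$to %in% sp$from) msg <- c(msg, "split destination cannot also be a source")
      if (length(sp$time) != 1L || sp$time < 0) msg <- c(msg, "split time must be >= 0")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a demographic model
#'
#' @param sizes named numeric vector of (relative) effective deme sizes; the
#'   names define the demes.
#' @param samples named numeric/integer vector of sample counts; demes absent
#'   from the vector carry zero samples.
#' @param migration optional data.frame with columns `from`, `to`, `rate`
#'   (per-lineage migration rate, backwards in time, in coalescent units of
#'   \eqn{2 N_{ref}} generations). Routes must be acyclic.
#' @param split optional `list(from =, to =, time =)`: the single discrete
#'   event, moving all lineages in the `from` deme(s) into `to` at scaled
#'   time `time` (backwards).
#' @param reference deme whose size sets the time scale; defaults to the
#'   first deme.
#' @return a validated [CoalModel-class] object.
#' @examples
#' coalModel(sizes = c(A = 1, B = 1), samples = c(A = 2, B = 2),
#'           migration = data.frame(from = "A", to = "B", rate = 1))
#' @export
coalModel <- function(sizes, samples, migration = NULL, split = NULL,
                      reference = names(sizes)[1L]) {
  demes <- names(sizes)
  if (is.null(demes) || !all(nzchar(demes))) stop("sizes must be a named vector")
  full <- stats::setNames(integer(length(demes)), demes)
  if (length(samples)) {
    if (is.null(names(samples))) stop("samples must be a named vector")
    unknown <- setdiff(names(samples), demes)
    if (length(unknown)) stop("samples name unknown deme(s): ", paste(unknown, collapse = ", "))
    full[names(samples)] <- as.integer(samples)
  }
  if (is.null(migration)) {
    migration <- data.frame(from = character(0), to = character(0), rate = numeric(0))
  } else {
    migration <- as.data.frame(migration, stringsAsFactors = FALSE)
  }
  if (is.null(split)) split <- list()
  lambda <- stats::setNames(unname(sizes[reference] / sizes), demes)
  new("CoalModel",
      demes = demes, sizes = stats::setNames(as.numeric(sizes), demes),
      samples = full, reference = reference,
      migration = migration, split = split, lambda = lambda)
}

#' @describeIn CoalModel-class deme identifiers.
#' @param object,x a `CoalModel`.
#' @export
setGeneric("demeNames", function(x) standardGeneric("demeNames"))

#' @export
setMethod("demeNames", "CoalModel", function(x) x@demes)

#' @describeIn CoalModel-class per-deme sample counts (named integer vector).
#' @export
setGeneric("sampleCounts", function(x) standardGeneric("sampleCounts"))

#' @export
setMethod("sampleCounts", "CoalModel", function(x) x@samples)

#' @describeIn CoalModel-class per-deme pairwise coalescence rates
#'   \eqn{N_{ref}/N_d}.
#' @export
setGeneric("coalescenceRates", function(x) standardGeneric("coalescenceRates"))

#' @export
setMethod("coalescenceRates", "CoalModel", function(x) x@lambda)

#' @describeIn CoalModel-class migration routes (data.frame from/to/rate).
#' @export
setGeneric("migrationRoutes", function(x) standardGeneric("migrationRoutes"))

#' @export
setMethod("migrationRoutes", "CoalModel", function(x) x@migration)

#' @describeIn CoalModel-class the discrete event, or NULL when absent.
#' @export
setGeneric("splitEvent", function(x) standardGeneric("splitEvent"))

#' @export
setMethod("splitEvent", "CoalModel", function(x) {
  if (length(x@split)) x@split else NULL
})

setMethod("show", "CoalModel", function(object) {
  cat("CoalModel with", length(object@demes), "deme(s):",
      paste0(object@demes, "(n=", object@samples, ", lambda=",
             signif(object@lambda, 4), ")", collapse = " "), "\n")
  if (nrow(object@migration)) {
    cat("  migration:",
        paste0(object@migration$from, "->", object@migration$to,
               " @", signif(object@migration$rate, 4), collapse = ", "), "\n")
  }
  if (length(object@split)) {
    cat("  split: {", paste(object@split$from, collapse = ","), "} -> ",
        object@split$to, " at T=", signif(object@split$time, 4), "\n", sep = "")
  }
  invisible(object)
})

#' Two-deme model with unidirectional migration only
#'
#' Demes `A` and `B`, `n` samples in each, continuous migration of lineages
#' from `A` to `B` (backwards in time) at per-lineage rate `rate`. This is
#' the maximally connected benchmark model: without a discrete event every
#' lineage history is a sequence of competing exponentials.
#'
#' @param n samples per deme (or length-2 vector `c(nA, nB)`).
#' @param rate scaled per-lineage migration rate.
#' @param NeA,NeB effective sizes (reference is `A`).
#' @return a [CoalModel-class].
#' @export
twoDemeMigrationModel <- function(n = 2, rate = 1, NeA = 1, NeB = 1) {
  n <- rep(n, length.out = 2L)
  coalModel(sizes = c(A = NeA, B = NeB),
            samples = c(A = n[1L], B = n[2L]),
            migration = data.frame(from = "A", to = "B", rate = rate),
            reference = "A")
}

#' Two-population isolation-with-migration (IM) model
#'
#' Demes `A` and `B` descend from an ancestral deme `AB`. Backwards in time,
#' lineages migrate from `A` to `B` at a constant per-lineage rate until the
#' split time `T`, at which all lineages in `A` and `B` move into `AB` (a
#' mass migration) and migration ceases.
#'
#' @param n samples per extant deme (or `c(nA, nB)`).
#' @param rate scaled per-lineage migration rate A -> B (backwards in time).
#' @param T scaled split time (units of `2 NeA` generations when `A` is the
#'   reference).
#' @param NeA,NeB,NeAB effective sizes; `A` is the reference deme.
#' @return a [CoalModel-class].
#' @export
twoDemeIMModel <- function(n = 2, rate = 1, T = 1.5,
                           NeA = 1, NeB = 1, NeAB = 1) {
  n <- rep(n, length.out = 2L)
  coalModel(sizes = c(A = NeA, B = NeB, AB = NeAB),
            samples = c(A = n[1L], B = n[2L]),
            migration = data.frame(from = "A", to = "B", rate = rate),
            split = list(from = c("A", "B"), to = "AB", time = T),
            reference = "A")
}

#' Single-deme constant-size model
#'
#' @param n number of sampled lineages (>= 2).
#' @return a [CoalModel-class].
#' @export
singleDemeModel <- function(n = 2) {
  coalModel(sizes = c(A = 1), samples = c(A = n))
}
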