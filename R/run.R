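# Run-configuration plumbing: a plain hierarchical YAML config describing
# the model and computation, consumed by runPipeline() and by the command
# line script shipped in inst/cli/gfcoal.R.

#' Read a run configuration
#'
#' The config is a YAML file with a `model` block (`sizes`, `samples`,
#' optional `migration` routes, optional `split` event, optional
#' `reference`) and top-level computation settings: `mode` ("exact", "mc"
#' or "graph-stats"), `theta`, `kmax` (scalar broadcast or per-type vector
#' in the canonical branch-type order), `phased`, `rooted`, and for MC runs
#' `reps` and `seed`.
#'
#' @param path path to a YAML file.
#' @return a validated run-config list with a constructed `model` entry.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  buildRunConfig(cfg)
}

#' Validate a run configuration list
#'
#' @param cfg a list with the structure documented in [readRunConfig()].
#' @return the config with defaults filled in and `model` replaced by a
#'   [CoalModel-class].
#' @export
buildRunConfig <- function(cfg) {
  fail <- function(key, why) stop("invalid config key '", key, "': ", why, call. = FALSE)
  if (is.null(cfg$model)) fail("model", "missing")
  mb <- cfg$model
  if (is.null(mb$sizes)) fail("model.sizes", "missing")
  if (is.null(mb$samples)) fail("model.samples", "missing")
  sizes <- unlist(mb$sizes)
  samples <- unlist(mb$samples)
  migration <- if (!is.null(mb$migration)) {
    do.call(rbind, lapply(mb$migration, function(m) {
      if (is.null(m$from) || is.null(m$to) || is.null(m$rate)) {
        fail("model.migration", "each route needs from, to, rate")
      }
      data.frame(from = m$from, to = m$to, rate = as.numeric(m$rate))
    }))
  } else NULL
  split <- if (!is.null(mb$split)) {
    if (is.null(mb$split$from) || is.null(mb$split$to) || is.null(mb$split$time)) {
      fail("model.split", "needs from, to, time")
    }
    list(from = unlist(mb$split$from), to = mb$split$to,
         time = as.numeric(mb$split$time))
  } else NULL
  model <- coalModel(sizes = sizes, samples = samples,
                     migration = migration, split = split,
                     reference = if (!is.null(mb$reference)) mb$reference else names(sizes)[1L])
  mode <- if (is.null(cfg$mode)) "exact" else cfg$mode
  if (!mode %in% c("exact", "mc", "graph-stats")) {
    fail("mode", "must be exact, mc or graph-stats")
  }
  out <- list(
    model = model,
    mode = mode,
    theta = if (!is.null(cfg$theta)) as.numeric(cfg$theta) else NULL,
    kmax = if (!is.null(cfg$kmax)) as.integer(unlist(cfg$kmax)) else 2L,
    phased = isTRUE(cfg$phased),
    rooted = isTRUE(cfg$rooted),
    reps = if (!is.null(cfg$reps)) as.integer(cfg$reps) else 1000L,
    seed = if (!is.null(cfg$seed)) as.integer(cfg$seed) else 1L,
    out = cfg$out
  )
  if (mode %in% c("exact", "mc")) {
    if (is.null(out$theta) || out$theta <= 0) fail("theta", "required and > 0 for exact/mc modes")
  }
  bts <- enumerateBranchTypes(model, out$phased, out$rooted)
  if (length(out$kmax) > 1L && length(out$kmax) != branchTypeCount(bts)) {
    fail("kmax", paste0("length must be 1 or ", branchTypeCount(bts),
                        " (branch-type order: ", paste(bts@labels, collapse = ", "), ")"))
  }
  out
}

#' Structural summary of a model's graphs
#'
#' The quantities that summarize the size of the evaluation problem: state
#' count, state-graph edge count, unique equations, computational-graph
#' node count (edges for continuous models; collapsed prefixes plus
#' post-event edges with a discrete event), path count, branch-type count,
#' full configuration-array size and the number of compatible (non
#' structural-zero) configurations.
#'
#' @param model a [CoalModel-class].
#' @param kmax truncation (scalar or per-type).
#' @param phased,rooted branch-type flags.
#' @return named list of counts.
#' @export
graphStats <- function(model, kmax = 2, phased = FALSE, rooted = FALSE) {
  g <- buildStateGraph(model, phased, rooted)
  cg <- collapseGraph(g)
  K <- branchTypeCount(g@bts)
  km <- as.integer(rep_len(kmax, K))
  cc <- compatibleConfigurations(g, km)
  list(states = nNodes(g),
       edges = nEdges(g),
       uniqueEquations = nrow(g@eqQ),
       graphNodes = nNodes(cg),
       paths = pathCount(g),
       branchTypes = K,
       arraySize = prod(as.numeric(km) + 2),
       compatibleConfigurations = cc$count)
}

#' Run a configured computation
#'
#' Dispatches on `mode`: "exact" writes the exact [bsfsProbabilities()]
#' table as TSV, "mc" the [estimateBsfs()] estimate with standard errors,
#' and "graph-stats" a two-column key/value TSV of [graphStats()].
#'
#' @param cfg config list from [readRunConfig()]/[buildRunConfig()].
#' @param out output path (overrides `cfg$out`; NULL prints to stdout).
#' @return the result object, invisibly.
#' @export
runPipeline <- function(cfg, out = NULL) {
  if (is.null(out)) out <- if (is.null(cfg$out)) "" else cfg$out
  res <- switch(cfg$mode,
    "graph-stats" = {
      st <- graphStats(cfg$model, cfg$kmax, cfg$phased, cfg$rooted)
      writeLines(c("# gfcoal graph-stats",
                   paste(names(st), unlist(st), sep = "\t")), con = out)
      st
    },
    "exact" = {
      ca <- bsfsProbabilities(cfg$model, theta = cfg$theta, kmax = cfg$kmax,
                              phased = cfg$phased, rooted = cfg$rooted)
      writeConfigTSV(ca, out)
      ca
    },
    "mc" = {
      ca <- estimateBsfs(cfg$model, theta = cfg$theta, kmax = cfg$kmax,
                         reps = cfg$reps, seed = cfg$seed,
                         phased = cfg$phased, rooted = cfg$rooted)
      writeConfigTSV(ca, out)
      ca
    })
  invisible(res)
}
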