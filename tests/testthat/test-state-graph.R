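test_that("the toy mass-migration model reproduces the canonical graph shape", {
  g <- buildStateGraph(toyMassMigrationModel())
  expect_equal(nNodes(g), 6L)
  expect_equal(nEdges(g), 7L)
  paths <- enumeratePaths(g)
  expect_equal(length(paths), 3L)
  expect_true(all(lengths(paths) == 3L))
  # two delta edges in the graph; each path crosses exactly one
  expect_equal(sum(g@edges$delta), 2L)
  expect_true(all(vapply(paths, function(p) sum(g@edges$delta[p]), 0) == 1))
  # one post-event edge is shared by two paths (common suffixes merge)
  lastEdges <- vapply(paths, function(p) p[length(p)], 0L)
  expect_equal(length(unique(lastEdges)), 2L)
  # no delta edge leaves a state whose source deme is already empty
  for (e in which(g@edges$delta)) {
    parent <- g@nodes[[g@edges$parent[e]]]
    expect_true(any(parent[, 1L] == 2L))   # deme B occupied
  }
  # after the event has fired no further delta edges occur on any path
  for (p in paths) {
    d <- which(g@edges$delta[p])
    expect_true(all(!g@edges$delta[p][-seq_len(d)]))
  }
})

test_that("coalescence and migration multiplicities sum to the combinatorial counts", {
  g <- buildStateGraph(twoDemeMigrationModel(3, rate = 0.7))
  D <- 2L
  for (u in seq_len(nNodes(g))) {
    es <- g@outEdges[[u]]
    if (!length(es)) next
    md <- tabulate(g@nodes[[u]][, 1L], nbins = D)
    for (d in seq_len(D)) {
      coal <- es[g@edges$slot[es] == d]
      expect_equal(sum(g@edges$l[coal]), choose(md[d], 2L))
    }
    migr <- es[g@edges$slot[es] == D + 1L]      # the single A -> B route
    expect_equal(sum(g@edges$l[migr]), md[1L])
  }
  # unphased merging: {a,a,b} coalescences give children with l = 1 and l = 2
  g2 <- buildStateGraph(toyMassMigrationModel())
  threeLin <- which(vapply(g2@nodes, function(m) {
    nrow(m) == 3L && all(m[, 1L] == 1L)
  }, TRUE))
  expect_length(threeLin, 1L)
  ls <- sort(g2@edges$l[g2@outEdges[[threeLin]]])
  expect_equal(ls, c(1L, 2L))
  # two identical lineages migrating produce one child with l = 2
  g3 <- buildStateGraph(twoDemeMigrationModel(2, rate = 1))
  rootMig <- g3@outEdges[[1L]][g3@edges$slot[g3@outEdges[[1L]]] == 3L]
  expect_length(rootMig, 1L)
  expect_equal(g3@edges$l[rootMig], 2L)
})

test_that("edge equations are competing-risk probabilities that sum to one", {
  set.seed(11)
  for (model in list(twoDemeMigrationModel(2, rate = 0.7),
                     toyMassMigrationModel(),
                     twoDemeIMModel(2, rate = 1.3, T = 1))) {
    g <- buildStateGraph(model)
    for (rep in 1:3) {
      # random positive event rates, omega = 0
      r <- rateVector(g, omega = 0, delta = stats::runif(1, 0.1, 2))
      ii <- seq_len(length(r) - branchTypeCount(g@bts))
      r[ii] <- r[ii] * stats::runif(length(ii), 0.5, 2)
      for (u in seq_len(nNodes(g))) {
        es <- g@outEdges[[u]]
        if (!length(es)) next
        probs <- vapply(g@edges$eq[es], function(e) evalEdge(g, e, r), 0)
        expect_true(all(probs > 0 & probs <= 1))
        expect_equal(sum(probs), 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("graphs are acyclic, end in absorbing states, and reject deadlocked models", {
  for (model in list(twoDemeMigrationModel(2), twoDemeIMModel(2),
                     toyMassMigrationModel(), singleDemeModel(4))) {
    g <- buildStateGraph(model)
    expect_silent(gfcoal:::.nodeOrder(g))      # errors on a cycle
    for (p in enumeratePaths(g, limit = 1e4)) {
      final <- g@edges$child[p[length(p)]]
      expect_true(final %in% g@absorbing)
      expect_equal(nrow(g@nodes[[final]]), 1L)
    }
  }
  # two isolated demes can never find a common ancestor
  stranded <- coalModel(sizes = c(A = 1, B = 1), samples = c(A = 1, B = 1))
  expect_error(buildStateGraph(stranded), "common ancestor")
})

test_that("structural counts match the reference benchmark values", {
  expect_equal(nNodes(buildStateGraph(twoDemeMigrationModel(2))), 17L)
  g3 <- buildStateGraph(twoDemeMigrationModel(3))
  expect_equal(nEdges(g3), 196L)
  expect_equal(nNodes(collapseGraph(g3)), 196L)
  expect_equal(pathCount(buildStateGraph(twoDemeMigrationModel(2))), 21)
})

test_that("DOT export writes one labeled node per state", {
  g <- buildStateGraph(toyMassMigrationModel())
  lines <- exportDOT(g, file = tempfile())
  expect_equal(sum(grepl("label=", lines)) , nNodes(g) + nEdges(g))
})
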