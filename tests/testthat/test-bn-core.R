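test_that("topological order respects edges and reports cycles", {
  expect_equal(topological_order(new_dag(c("A", "B", "C"))), c("A", "B", "C"))
  expect_equal(topological_order(new_dag(c("A", "B", "C"),
                                         rbind(c("A", "B"), c("B", "C")))),
               c("A", "B", "C"))
  # deterministic tie-break by node order
  expect_equal(topological_order(new_dag(c("C", "B", "A"),
                                         rbind(c("C", "A")))),
               c("C", "B", "A"))
  expect_error(new_dag(c("A", "B"), rbind(c("A", "B"), c("B", "A"))),
               "cycle: ")
  expect_error(new_dag(c("A"), rbind(c("A", "A"))), "self-loop")
  expect_error(new_dag(c("A", "B"), rbind(c("A", "B"), c("A", "B"))),
               "duplicate")
  expect_error(new_dag(c("A"), rbind(c("A", "Z"))), "not in node set")
})

two_node_bn <- function() {
  dag <- new_dag(c("A", "B"), rbind(c("A", "B")))
  bayesian_network(dag,
                   list(A = c("0", "1"), B = c("0", "1")),
                   list(A = matrix(c(0.7, 0.3), 1),
                        B = matrix(c(0.8, 0.2, 0.1, 0.9), 2, byrow = TRUE)))
}

test_that("joint probability is the chain-rule product", {
  bn <- two_node_bn()
  expect_equal(joint_probability(bn, list(A = "1", B = "0")), 0.03)
  expect_equal(joint_probability(bn, list(A = "0", B = "1")), 0.14)
  expect_error(joint_probability(bn, list(A = "1")), "incomplete")
  # normalization over all complete assignments of a random net
  bn5 <- rand_bn(V = 5, max_parents = 2, seed = 11)
  grid <- expand.grid(bn5$states, stringsAsFactors = FALSE)
  total <- sum(vapply(seq_len(nrow(grid)), function(i)
    joint_probability(bn5, as.list(grid[i, ])), 0))
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("posterior queries follow Bayes rule and marginalization", {
  bn <- two_node_bn()
  expect_equal(unname(query_posterior(bn, "A", list(B = "1"))["1"]),
               0.27 / 0.41, tolerance = 1e-12)
  # empty evidence returns the prior
  expect_equal(unname(query_posterior(bn, "A")), c(0.7, 0.3))
  expect_error(query_posterior(bn, "A", list(A = "1")), "target")
  # zero-probability evidence raises
  bn0 <- bayesian_network(bn$dag, bn$states,
                          list(A = matrix(c(1, 0), 1),
                               B = matrix(c(1, 0, 0.5, 0.5), 2, byrow = TRUE)))
  expect_error(query_posterior(bn0, "B", list(A = "1")), "probability zero")
})

test_that("variable elimination agrees with brute-force enumeration", {
  # the acceptance suite runs the full 20-network sweep; spot-check here
  set.seed(5)
  for (s in 1:6) {
    bn <- rand_bn(V = 7, max_parents = 3, seed = 100 + s)
    nodes <- bn$dag$nodes
    for (r in 1:4) {
      tgt <- sample(nodes, 1)
      evn <- sample(setdiff(nodes, tgt), sample(0:4, 1))
      ev <- lapply(evn, function(v) sample(bn$states[[v]], 1))
      names(ev) <- evn
      expect_equal(query_posterior(bn, tgt, ev),
                   brute_force_posterior(bn, tgt, ev), tolerance = 1e-9)
    }
  }
})

test_that("posteriors are normalized and consistent with joint ratios", {
  bn <- rand_bn(V = 6, max_parents = 2, seed = 21)
  nodes <- bn$dag$nodes
  for (v in nodes)
    expect_equal(sum(query_posterior(bn, v)), 1, tolerance = 1e-12)
  # complete evidence on all other nodes = normalized joint ratios
  set.seed(3)
  ev <- lapply(nodes[-3], function(v) sample(bn$states[[v]], 1))
  names(ev) <- nodes[-3]
  tgt <- nodes[3]
  joints <- vapply(bn$states[[tgt]], function(s)
    joint_probability(bn, c(ev, setNames(list(s), tgt))), 0)
  expect_equal(unname(query_posterior(bn, tgt, ev)),
               unname(joints / sum(joints)), tolerance = 1e-12)
})

test_that("predicted risk marginalizes missing predictors", {
  # outcome -> smoking, outcome -> CRP-bin with hand-specified CPTs
  dag <- new_dag(c("LC", "smoking", "CRP"),
                 rbind(c("LC", "smoking"), c("LC", "CRP")))
  bn <- bayesian_network(dag,
                         list(LC = c("non-LC", "LC"),
                              smoking = c("never", "ever"),
                              CRP = c("within", "above")),
                         list(LC = matrix(c(0.75, 0.25), 1),
                              smoking = matrix(c(0.3, 0.7, 0.1, 0.9), 2,
                                               byrow = TRUE),
                              CRP = matrix(c(0.8, 0.2, 0.5, 0.5), 2,
                                           byrow = TRUE)),
                         outcome = "LC")
  # hand Bayes: P(LC | ever, above) = .25*.9*.5 / (.25*.9*.5 + .75*.7*.2)
  expect_equal(predict_risk(bn, list(smoking = "ever", CRP = "above")),
               0.1125 / (0.1125 + 0.105), tolerance = 1e-12)
  # all predictors missing: prior
  expect_equal(predict_risk(bn, list(smoking = NA, CRP = NA)), 0.25)
  # partial evidence stays a probability
  p <- predict_risk(bn, list(smoking = "never", CRP = NA))
  expect_true(p >= 0 && p <= 1)
})

test_that("network JSON and DAG edge-list files round-trip", {
  bn <- rand_bn(V = 5, max_parents = 2, seed = 31)
  path <- withr::local_tempfile(fileext = ".json")
  write_bn(bn, path)
  back <- read_bn(path)
  expect_equal(back$dag$nodes, bn$dag$nodes)
  expect_equal(back$dag$edges, bn$dag$edges)
  expect_equal(back$states, bn$states)
  for (v in bn$dag$nodes)
    expect_equal(back$cpts[[v]], bn$cpts[[v]], tolerance = 1e-15)

  dpath <- withr::local_tempfile(fileext = ".tsv")
  write_dag(bn$dag, dpath)
  dback <- read_dag(dpath, nodes = bn$dag$nodes)
  expect_equal(dback$edges[order(dback$edges[, 1], dback$edges[, 2]), ,
                           drop = FALSE],
               bn$dag$edges[order(bn$dag$edges[, 1], bn$dag$edges[, 2]), ,
                            drop = FALSE])
  expect_warning(read_dag(withr::local_tempfile(lines = "# only comments")),
                 "empty DAG")
  expect_match(as_dot(bn$dag), "digraph")
})
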